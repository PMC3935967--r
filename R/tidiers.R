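#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained scorer
#'
#' One row per feature with its learned min-max scaling range.
#'
#' @param x a `meftop_scorer`.
#' @param ... unused.
#' @return tibble with columns `feature`, `group`, `scale_min`, `scale_max`.
#' @export
tidy.meftop_scorer <- function(x, ...) {
  tibble::tibble(feature = x$feature_names,
                 group = as.character(feature_groups()),
                 scale_min = unname(x$scale_min),
                 scale_max = unname(x$scale_min + x$scale_span))
}

#' Glance at a trained scorer
#'
#' @param x a `meftop_scorer`.
#' @param ... unused.
#' @return one-row tibble: kernel, hyperparameters, support-vector count,
#'   training size and M-score weight.
#' @export
glance.meftop_scorer <- function(x, ...) {
  tibble::tibble(kernel = x$kernel, cost = x$cost, gamma = x$gamma,
                 epsilon = x$epsilon, n_support = nrow(x$support_vectors),
                 n_train = x$n_train, mscore_weight = x$mscore_weight)
}

#' Tidy an evaluation report
#'
#' Long format: one row per metric/stratum/statistic.
#'
#' @param x a `meftop_evaluation` tibble from [evaluate_selection()].
#' @param ... unused.
#' @return tibble with columns `metric`, `stratum`, `statistic`, `value`.
#' @export
tidy.meftop_evaluation <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                      cols = -c("metric", "stratum"),
                      names_to = "statistic", values_to = "value")
}
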