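# Scoring: threading Z-score standardization, the weighted epsilon-SVR
# P-score (TM-score estimate), the combined M-score, ranking, the training
# cost function, and scorer serialization.

#' Standardize raw threading scores within a decoy set
#'
#' `Z_k = (S_k - mean(S)) / sd(S)` with the population (mean-square) standard
#' deviation; all zeros when the scores are constant.
#'
#' @param raw_scores numeric vector of per-model raw scores (length >= 2).
#' @return numeric vector of Z-scores with mean 0.
#' @export
z_score <- function(raw_scores) {
  if (length(raw_scores) < 2) stop("need at least 2 raw scores")
  mu <- mean(raw_scores)
  sd_pop <- sqrt(mean((raw_scores - mu)^2))
  if (sd_pop < 1e-12) return(rep(0, length(raw_scores)))
  (raw_scores - mu) / sd_pop
}

#' Train the weighted SVR model-quality scorer
#'
#' Fits an epsilon-SVR with RBF kernel on min-max scaled features, with
#' per-instance weights proportional to the TM-score label (a better model
#' contributes more to the fit). The weights are realized as integer
#' replication counts `max(1, round(10 * tm))`, so a TM = 0.8 instance
#' carries exactly twice the weight of a TM = 0.4 instance. Training is
#' deterministic given the data order and configuration.
#'
#' @param features tibble (or data frame) containing the 37 feature columns
#'   of [feature_names()]; extra columns are ignored.
#' @param tm_labels numeric TM-score labels in `[0, 1]`, length `nrow(features)`
#'   (>= 20, not all equal).
#' @param cost,gamma,epsilon SVR hyperparameters (defaults: `cost = 10`,
#'   `gamma = 1/37`, `epsilon = 0.1`).
#' @param mscore_weight weight `n` of the P-score in the M-score
#'   `M = Z + n P` (default 2; see [select_mscore_weight()]).
#' @param weight_instances replicate instances by TM-score weight (default
#'   `TRUE`).
#' @return object of class `meftop_scorer`.
#' @export
train_scorer <- function(features, tm_labels, cost = 10, gamma = 1 / 37,
                         epsilon = 0.1, mscore_weight = 2,
                         weight_instances = TRUE) {
  x <- as.matrix(as.data.frame(features)[, feature_names(), drop = FALSE])
  stopifnot(nrow(x) == length(tm_labels))
  if (nrow(x) < 20) stop("need at least 20 labeled feature vectors")
  if (any(tm_labels < 0 | tm_labels > 1)) stop("TM labels must be in [0, 1]")
  if (stats::sd(tm_labels) < 1e-12) stop("degenerate labels: all equal")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  span <- ifelse(hi - lo < 1e-12, 1, hi - lo)
  xs <- sweep(sweep(x, 2, lo), 2, span, `/`)
  if (weight_instances) {
    reps <- pmax(1L, as.integer(round(10 * tm_labels)))
    idx <- rep(seq_len(nrow(xs)), times = reps)
  } else {
    idx <- seq_len(nrow(xs))
  }
  fit <- e1071::svm(x = xs[idx, , drop = FALSE], y = tm_labels[idx],
                    type = "eps-regression", kernel = "radial",
                    cost = cost, gamma = gamma, epsilon = epsilon,
                    scale = FALSE)
  structure(
    list(version = 1L,
         feature_names = feature_names(),
         scale_min = lo, scale_span = span,
         kernel = "radial", cost = cost, gamma = gamma, epsilon = epsilon,
         support_vectors = unname(as.matrix(fit$SV)),
         coefs = as.numeric(fit$coefs),
         rho = as.numeric(fit$rho),
         mscore_weight = mscore_weight,
         n_train = nrow(x)),
    class = "meftop_scorer")
}

#' @export
print.meftop_scorer <- function(x, ...) {
  cat(sprintf(
    "<meftop_scorer> eps-SVR (RBF): %d SVs, C=%g, gamma=%g, eps=%g, n=%g\n",
    nrow(x$support_vectors), x$cost, x$gamma, x$epsilon, x$mscore_weight))
  invisible(x)
}

#' Predict the P-score (TM-score estimate) of models
#'
#' Evaluates the SVR regression function directly from its support-vector
#' expansion, `f(x) = sum_i coef_i K(sv_i, x) - rho` with the RBF kernel, on
#' min-max scaled features. Reported values are clipped to `[0, 1]`; the raw
#' regression value is available with `clip = FALSE`.
#'
#' @param scorer a trained `meftop_scorer`.
#' @param features tibble or matrix containing the 37 feature columns.
#' @param clip clip predictions into `[0, 1]` (default `TRUE`).
#' @return numeric vector of P-scores.
#' @export
p_score <- function(scorer, features, clip = TRUE) {
  x <- as.matrix(as.data.frame(features)[, scorer$feature_names, drop = FALSE])
  if (any(!is.finite(x))) stop("non-finite feature values")
  xs <- sweep(sweep(x, 2, scorer$scale_min), 2, scorer$scale_span, `/`)
  sv <- scorer$support_vectors
  # ||sv_i - x_j||^2 via the expanded square
  d2 <- outer(rowSums(sv^2), rowSums(xs^2), `+`) - 2 * sv %*% t(xs)
  d2[d2 < 0] <- 0
  pred <- as.numeric(crossprod(exp(-scorer$gamma * d2), scorer$coefs)) - scorer$rho
  if (clip) pmin(pmax(pred, 0), 1) else pred
}

#' Combined M-score
#'
#' `M = Z + n P`: the threading Z-score plus `n` times the P-score.
#'
#' @param z threading Z-score(s).
#' @param p P-score(s).
#' @param n non-negative P-score weight.
#' @return numeric M-score(s).
#' @export
m_score <- function(z, p, n) {
  stopifnot(n >= 0)
  z + n * p
}

#' Score and rank the models of a decoy set
#'
#' Computes the requested metric for every model and returns the set sorted
#' by it (descending; ties broken by `model_id`, so the ranking is a stable
#' permutation of the input).
#'
#' @param features tibble with `model_id` and the 37 feature columns.
#' @param scorer a `meftop_scorer` (required for metrics `p` and `m`).
#' @param raw_scores per-model threading raw scores aligned with `features`
#'   rows (required for metrics `z` and `m`).
#' @param metric one of `"z"`, `"p"`, `"m"`.
#' @return tibble with `model_id`, available score columns (`z`, `p`, `m`),
#'   and `rank`, sorted by the chosen metric.
#' @export
rank_models <- function(features, scorer = NULL, raw_scores = NULL,
                        metric = c("m", "p", "z")) {
  metric <- match.arg(metric)
  out <- tibble::tibble(model_id = features$model_id)
  if (metric %in% c("z", "m")) {
    if (is.null(raw_scores)) stop("metric '", metric, "' requires raw_scores")
    out$z <- z_score(raw_scores)
  }
  if (metric %in% c("p", "m")) {
    if (is.null(scorer)) stop("metric '", metric, "' requires a scorer")
    out$p <- p_score(scorer, features)
  }
  if (metric == "m") out$m <- m_score(out$z, out$p, scorer$mscore_weight)
  out <- dplyr::arrange(out, dplyr::desc(.data[[metric]]), .data$model_id)
  out$rank <- seq_len(nrow(out))
  out
}

#' Training cost function for scorer optimization
#'
#' `F = mean(rank of native) - n * mean(Z_svm) + lambda * missed`, where
#' `rank of native` is the rank of the native structure in each training
#' pool when ranked by the scorer, `Z_svm` is the per-target standardized
#' P-score of the native, and `missed` counts targets whose native is not
#' ranked first. Lower is better.
#'
#' @param native_ranks integer vector: per-target rank of the native.
#' @param native_z_svm numeric vector: per-target standardized P-score of
#'   the native.
#' @param n weight of the Z_svm term (default 1).
#' @param lambda weight of the missed count (default 1).
#' @return cost value.
#' @export
cost_f <- function(native_ranks, native_z_svm, n = 1, lambda = 1) {
  if (length(native_ranks) == 0) stop("empty target set")
  missed <- sum(native_ranks != 1)
  mean(native_ranks) - n * mean(native_z_svm) + lambda * missed
}

#' Grid-search SVR hyperparameters under the training cost function
#'
#' Trains one scorer per (cost, gamma, epsilon) combination, ranks each
#' validation pool (which must contain the native, labelled `tm = 1`) by
#' P-score, and keeps the combination minimizing [cost_f()]. Deterministic.
#'
#' @param train_features,train_tm training feature tibble and labels.
#' @param val_features tibble with `target_id`, `model_id`, `tm`, and the 37
#'   features; each target's pool must include its native model.
#' @param cost_grid,gamma_grid,epsilon_grid grids to search.
#' @param ... passed to [cost_f()].
#' @return list with `scorer` (refit at the best setting), `best` (one-row
#'   tibble) and `grid` (all settings with their cost values).
#' @export
tune_scorer <- function(train_features, train_tm, val_features,
                        cost_grid = c(1, 10, 100),
                        gamma_grid = c(1 / 37, 0.1),
                        epsilon_grid = 0.1, ...) {
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                      epsilon = epsilon_grid)
  grid$cost_f <- NA_real_
  scorers <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sc <- train_scorer(train_features, train_tm, cost = grid$cost[g],
                       gamma = grid$gamma[g], epsilon = grid$epsilon[g])
    scorers[[g]] <- sc
    per_target <- val_features |>
      dplyr::group_by(.data$target_id) |>
      dplyr::group_split()
    ranks <- zsvm <- numeric(length(per_target))
    for (t in seq_along(per_target)) {
      df <- per_target[[t]]
      p <- p_score(sc, df, clip = FALSE)
      native_i <- which.max(df$tm)
      ranks[t] <- rank(-p, ties.method = "min")[native_i]
      zsvm[t] <- z_score(p)[native_i]
    }
    grid$cost_f[g] <- cost_f(ranks, zsvm, ...)
  }
  best <- which.min(grid$cost_f)
  list(scorer = scorers[[best]], best = tibble::as_tibble(grid[best, ]),
       grid = tibble::as_tibble(grid))
}

#' Select the M-score weight on validation decoy sets
#'
#' Scans `n` over a grid and keeps the value maximizing Top1% of M-score
#' selection (ties: lower average rank, then smaller `n`).
#'
#' @param scored tibble with `target_id`, `model_id`, `tm`, `z`, `p`.
#' @param grid candidate weights (default `seq(0.5, 10, by = 0.5)`).
#' @return the selected weight.
#' @export
select_mscore_weight <- function(scored, grid = seq(0.5, 10, by = 0.5)) {
  best <- NULL
  for (n in grid) {
    df <- dplyr::mutate(scored, m = m_score(.data$z, .data$p, n))
    ev <- evaluate_selection(df, metrics = "m")
    ev <- ev[ev$stratum == "all", ]
    key <- c(ev$top1_pct, -ev$avg_rank)
    if (is.null(best) || key[1] > best$key[1] ||
        (key[1] == best$key[1] && key[2] > best$key[2])) {
      best <- list(n = n, key = key)
    }
  }
  best$n
}

#' Save / load a trained scorer
#'
#' Single-file versioned JSON with full double precision, so a reloaded
#' scorer reproduces predictions bit for bit.
#'
#' @param scorer a `meftop_scorer`.
#' @param path file path.
#' @return `path` (write) or the scorer (read).
#' @export
write_scorer <- function(scorer, path) {
  payload <- unclass(scorer)
  # all doubles go through %.17g strings so the round trip is exact
  payload$support_vectors <- apply(scorer$support_vectors, 1, function(r)
    sprintf("%.17g", r), simplify = FALSE)
  for (f in c("coefs", "rho", "scale_min", "scale_span",
              "cost", "gamma", "epsilon", "mscore_weight"))
    payload[[f]] <- sprintf("%.17g", scorer[[f]])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- p$support_vectors
  sv <- if (is.matrix(sv)) matrix(as.numeric(sv), nrow(sv))
        else do.call(rbind, lapply(sv, as.numeric))
  structure(
    list(version = p$version,
         feature_names = p$feature_names,
         scale_min = stats::setNames(as.numeric(p$scale_min), p$feature_names),
         scale_span = stats::setNames(as.numeric(p$scale_span), p$feature_names),
         kernel = p$kernel, cost = as.numeric(p$cost),
         gamma = as.numeric(p$gamma), epsilon = as.numeric(p$epsilon),
         support_vectors = sv,
         coefs = as.numeric(p$coefs),
         rho = as.numeric(p$rho),
         mscore_weight = as.numeric(p$mscore_weight),
         n_train = as.integer(p$n_train)),
    class = "meftop_scorer")
}
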