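#' TM-score between a model and the native structure
#'
#' Length-normalized structural similarity in (0, 1] for two structures of
#' the same sequence (residue correspondence is by index). The score is
#' `max (1/L) sum 1 / (1 + (d_i/d0)^2)` over superpositions, with
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8` floored at 0.5. Superpositions are
#' searched exhaustively from contiguous seed fragments: every window of
#' length >= 4 is superposed by least squares (Kabsch), then iteratively
#' refined on the subset of residues within a distance cutoff until the
#' subset is stable, keeping the best full-chain score seen (compiled
#' search kernel; a few ms per call for chains under ~100 residues).
#'
#' @param model,native [structure_model()]s of equal length (CA traces used).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, native) {
  if (length(model) != length(native))
    stop("model length (", length(model), ") != native length (",
         length(native), ")")
  tm_score_xyz(model$ca, native$ca)
}

tm_d0 <- function(l) max(1.24 * sign(l - 15) * abs(l - 15)^(1 / 3) - 1.8, 0.5)

tm_score_xyz <- function(mobile, fixed) {
  .tm_score_search(mobile, fixed, tm_d0(nrow(mobile)))
}

#' Fraction of targets whose selected model is native-like
#'
#' A selection is native-like when its TM-score is strictly greater than
#' `cutoff` (default 0.4).
#'
#' @param selected_tm TM-scores of the top-ranked model, one per target.
#' @param cutoff native-likeness threshold (default 0.4, strict `>`).
#' @return percentage in `[0, 100]`.
#' @export
top1_percent <- function(selected_tm, cutoff = 0.4) {
  stopifnot(length(selected_tm) >= 1)
  100 * mean(selected_tm > cutoff)
}

#' Average true-quality rank of the selected models
#'
#' For each target, the rank of the selected model when all candidate models
#' are sorted by true TM-score descending (ties receive their average rank);
#' the mean over targets is returned.
#'
#' @param scored tibble with columns `target_id`, `model_id`, `tm`.
#' @param selections tibble with columns `target_id`, `model_id` naming the
#'   selected model per target.
#' @return mean rank (>= 1).
#' @export
average_rank <- function(scored, selections) {
  ranks <- scored |>
    dplyr::group_by(.data$target_id) |>
    dplyr::mutate(tm_rank = rank(-.data$tm, ties.method = "average")) |>
    dplyr::ungroup() |>
    dplyr::inner_join(selections, by = c("target_id", "model_id"))
  stopifnot(nrow(ranks) == nrow(selections))
  mean(ranks$tm_rank)
}

#' Per-target Pearson correlation between a score and true quality
#'
#' @param scored tibble with columns `target_id`, `tm`, and the score column.
#' @param score column name of the predicted score (default `"p"`).
#' @return tibble with one row: `mean_cc`, `sd_cc`, `n_targets`. Targets
#'   where either side is constant contribute a correlation of 0.
#' @export
per_target_cc <- function(scored, score = "p") {
  ccs <- scored |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(cc = safe_cor(.data[[score]], .data$tm), .groups = "drop")
  tibble::tibble(mean_cc = mean(ccs$cc), sd_cc = stats::sd(ccs$cc),
                 n_targets = nrow(ccs))
}

#' Evaluate model selection under one or more ranking metrics
#'
#' For each metric column present in `scored` (any of `z`, `p`, `m`), ranks
#' the models of every target, selects the top model, and reports Top1%,
#' average true-TM rank, the sum and mean of selected TM-scores, and the
#' per-target correlation between the metric and TM. When a per-target
#' `z_best` column is supplied, the same summary is additionally reported
#' for the strata of targets below each cutoff in `strata`.
#'
#' @param scored tibble with `target_id`, `model_id`, `tm`, and metric
#'   columns among `z`, `p`, `m`; optionally a per-target `z_best`.
#' @param metrics metric columns to evaluate (default those present).
#' @param strata optimal-Z cutoffs for stratified reporting (default
#'   `c(4, 5, 6)`, used only when `z_best` is present).
#' @return tibble of class `meftop_evaluation`: one row per metric (and per
#'   stratum) with columns `metric`, `stratum`, `n_targets`, `top1_pct`,
#'   `avg_rank`, `sum_tm`, `mean_tm`, `mean_cc`, `sd_cc`.
#' @export
evaluate_selection <- function(scored,
                               metrics = intersect(c("z", "p", "m"), names(scored)),
                               strata = c(4, 5, 6)) {
  stopifnot(length(metrics) > 0, "tm" %in% names(scored))
  eval_subset <- function(df, metric, stratum) {
    sel <- df |>
      dplyr::group_by(.data$target_id) |>
      dplyr::arrange(dplyr::desc(.data[[metric]]), .data$model_id,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    cc <- per_target_cc(df, score = metric)
    tibble::tibble(
      metric = metric, stratum = stratum, n_targets = nrow(sel),
      top1_pct = top1_percent(sel$tm),
      avg_rank = average_rank(df, sel[, c("target_id", "model_id")]),
      sum_tm = sum(sel$tm), mean_tm = mean(sel$tm),
      mean_cc = cc$mean_cc, sd_cc = cc$sd_cc)
  }
  out <- dplyr::bind_rows(lapply(metrics, function(m)
    eval_subset(scored, m, "all")))
  if ("z_best" %in% names(scored)) {
    for (cut in strata) {
      sub <- dplyr::filter(scored, .data$z_best < cut)
      if (nrow(sub) == 0) next
      out <- dplyr::bind_rows(out, lapply(metrics, function(m)
        eval_subset(sub, m, paste0("z_best<", cut))))
    }
  }
  class(out) <- c("meftop_evaluation", class(out))
  out
}
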