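#' Names of the 37 model-evaluation features
#'
#' Fixed ordering contract: 14 traditional 1D features, 10 traditional 2D
#' contact-map features, 6 SSE contact features, 7 topology features.
#'
#' @return character vector of length 37.
#' @export
feature_names <- function() {
  c(
    # 14 one-dimensional
    paste0("ss_", c("helix", "strand", "coil", "exposed", "buried"), "_seq"),
    paste0("ss_", c("helix", "strand", "coil", "exposed", "buried"), "_mod"),
    paste0("comp_", c("cosine", "correlation", "gaussian", "dot")),
    # 10 two-dimensional
    paste0(c("order_cosine_", "order_correlation_",
             "number_cosine_", "number_correlation_"), 8),
    paste0(c("order_cosine_", "order_correlation_",
             "number_cosine_", "number_correlation_"), 12),
    "f_res_8", "f_res_12",
    # 6 SSE contact
    c("f_sse", "sse_number_cosine", "sse_number_correlation",
      "sse_distance_similarity", "sse_length_ratio_pooled",
      "sse_length_ratio_mean"),
    # 7 topology
    c("rg_gaussian", "rg_ratio", "hc_radius_ratio", "hc_count_ratio",
      "hc_sse_ratio", "frag_span", "frag_torsion"))
}

#' Feature group of each feature
#'
#' @return factor of length 37 with levels `traditional_1d`,
#'   `traditional_2d`, `sse_contact`, `topology`.
#' @export
feature_groups <- function() {
  factor(rep(c("traditional_1d", "traditional_2d", "sse_contact", "topology"),
             times = c(14, 10, 6, 7)),
         levels = c("traditional_1d", "traditional_2d", "sse_contact", "topology"))
}

#' Assemble the 37-feature vector for one (profile, model) pair
#'
#' Runs all four feature groups against an annotated model (the model is
#' annotated on the fly when its SS/RSA states are missing). Any
#' non-finite sub-feature is replaced by the documented zero convention.
#'
#' @param profile a [target_profile()].
#' @param model a [structure_model()] of the same length as the profile.
#' @param sse_model_threshold model-side SCM cutoff for SSE contact
#'   strength, Angstrom (default 8.5). Set to 8 to match the sequence-side
#'   <8 A probability class exactly (the consistency configuration used by
#'   the zero-noise chain tests).
#' @param gamma Gaussian-kernel width for the composition similarity.
#' @return named numeric vector of length 37 in [feature_names()] order.
#' @export
assemble_features <- function(profile, model, sse_model_threshold = 8.5,
                              gamma = 1) {
  if (length(profile) != length(model))
    stop("profile length (", length(profile), ") != model length (",
         length(model), ")")
  if (anyNA(model$ss) || anyNA(model$rsa)) model <- annotate_model(model)
  out <- c(features_1d(profile, model, gamma = gamma),
           features_2d(profile, model),
           features_sse_group(profile, model,
                              model_threshold = sse_model_threshold),
           features_topology_group(profile, model))
  out[!is.finite(out)] <- 0
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Extract the feature matrix of a decoy set
#'
#' Tidy surface over [assemble_features()]: one row per model, the 37
#' features as columns, plus identifier columns.
#'
#' @param models list of [structure_model()]s (a decoy set for one target).
#' @param profile the target's [target_profile()].
#' @param ... passed to [assemble_features()].
#' @return tibble with columns `target_id`, `model_id`, and the 37 features.
#' @export
extract_features <- function(models, profile, ...) {
  rows <- purrr::map(models, function(m) {
    fv <- assemble_features(profile, m, ...)
    tibble::tibble(target_id = profile$target_id, model_id = m$model_id,
                   !!!as.list(fv))
  })
  dplyr::bind_rows(rows)
}

# TSV round trip for feature matrices (header = feature names).
write_feature_matrix <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_feature_matrix <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE))
}
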