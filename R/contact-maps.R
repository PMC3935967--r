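#' Residue contact map from side-chain centers of mass
#'
#' Two residues i, j are in contact when their sequence separation
#' `|i - j| >= min_separation` and the distance between their side-chain
#' centers of mass is strictly below `threshold`. The defaults follow the
#' standard two-threshold setup (8 and 12 Angstrom, separation >= 6).
#'
#' @param model a [structure_model()].
#' @param threshold contact distance threshold in Angstrom (strict `<`).
#' @param min_separation minimum `|i - j|` (default 6).
#' @return a symmetric 0/1 integer matrix; all-zero (still valid) for models
#'   shorter than `min_separation + 1` residues.
#' @export
contact_map <- function(model, threshold = 8, min_separation = 6) {
  stopifnot(threshold > 0)
  len <- length(model)
  d <- as.matrix(stats::dist(model$scm))
  sep <- abs(outer(seq_len(len), seq_len(len), `-`))
  m <- (d < threshold & sep >= min_separation) * 1L
  dimnames(m) <- NULL
  m
}

#' Per-residue contact order and contact number profiles
#'
#' Works on either a binary model contact map or a predicted contact
#' probability matrix. For residue i,
#' `number_i = sum_j C_ij` and
#' `order_i = sum_j C_ij * |i - j| / sum_j C_ij` (0 when residue i has no
#' contact weight).
#'
#' @param cmap symmetric contact matrix (binary or probabilities).
#' @return a list with numeric vectors `order` and `number`.
#' @export
contact_profiles <- function(cmap) {
  len <- nrow(cmap)
  sep <- abs(outer(seq_len(len), seq_len(len), `-`))
  number <- rowSums(cmap)
  order <- ifelse(number > 0, rowSums(cmap * sep) / number, 0)
  list(order = unname(order), number = unname(number))
}

#' Radius of gyration of the CA trace
#'
#' Mass-unweighted root-mean-square distance of CA atoms from their centroid.
#'
#' @param model a [structure_model()].
#' @return radius in Angstrom (0 for a single residue).
#' @export
radius_of_gyration <- function(model) {
  xyz <- model$ca
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Write a contact map as 3-column text
#'
#' `i j value` triples (1-based, upper triangle, nonzero entries only),
#' the same dialect [read_profile()] consumes for probability maps.
#'
#' @param cmap symmetric contact matrix (binary or probabilities).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cmap, path) {
  idx <- which(upper.tri(cmap) & cmap != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], value = cmap[idx])
  utils::write.table(df[order(df$i, df$j), ], path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
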