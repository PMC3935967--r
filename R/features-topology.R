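# 3D topology features: radius-of-gyration agreement with the
# length-scaling law, hydrophobic-core descriptors, and local
# fragment-conformation potentials. All features are bounded in [0, 1] and
# rigid-motion invariant.

hydrophobic_set <- c("A", "V", "L", "I", "M", "F", "W", "C")

#' Radius-of-gyration agreement features
#'
#' The expected radius of gyration of a globular chain of length `L` follows
#' the power law `R_pred = k L^m` (defaults `k = 2.2`, `m = 0.38`, the
#' standard globular-protein fit). The model radius is compared to it with a
#' Gaussian agreement (width `0.2 R_pred`) and a min/max ratio.
#'
#' @param model a [structure_model()].
#' @param seq_length target sequence length `L`.
#' @param k,m power-law constants.
#' @return named numeric vector `(rg_gaussian, rg_ratio)`, both in `[0, 1]`.
#' @export
gyration_features <- function(model, seq_length, k = 2.2, m = 0.38) {
  r_pred <- k * seq_length^m
  r_mod <- radius_of_gyration(model)
  sigma <- 0.2 * r_pred
  c(rg_gaussian = exp(-(r_mod - r_pred)^2 / sigma^2),
    rg_ratio = if (max(r_mod, r_pred) > 0) min(r_mod, r_pred) / max(r_mod, r_pred) else 0)
}

#' Detect the hydrophobic core of a model
#'
#' Single-linkage clustering of the SCMs of hydrophobic residues
#' (A,V,L,I,M,F,W,C) at the given linkage distance; the largest cluster
#' (ties broken toward the cluster containing the lowest residue index) is
#' the hydrophobic core (HC).
#'
#' @param model an annotated [structure_model()].
#' @param linkage single-linkage cut distance in Angstrom (default 6.5).
#' @return list with `members` (residue indices), `radius` (gyration radius
#'   of member SCMs), `n_residues`, and `n_sses` (number of model SSEs
#'   contributing at least one member).
#' @export
detect_hc <- function(model, linkage = 6.5) {
  hyd <- which(model$aa %in% hydrophobic_set)
  empty <- list(members = integer(0), radius = 0, n_residues = 0L, n_sses = 0L)
  if (length(hyd) == 0) return(empty)
  if (length(hyd) == 1) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(model$scm[hyd, , drop = FALSE]),
                        method = "single")
    cl <- stats::cutree(hc, h = linkage)
  }
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(big) > 1) {
    # tie: cluster containing the lowest residue index wins
    firsts <- vapply(big, function(b) min(hyd[cl == b]), 0L)
    big <- big[which.min(firsts)]
  }
  members <- hyd[cl == big]
  xyz <- model$scm[members, , drop = FALSE]
  ctr <- colMeans(xyz)
  radius <- sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
  sses <- if (anyNA(model$ss)) identify_sses(rep("C", length(model))) else identify_sses(model$ss)
  n_sses <- 0L
  if (nrow(sses) > 0)
    n_sses <- sum(vapply(seq_len(nrow(sses)), function(i)
      any(members >= sses$start[i] & members <= sses$end[i]), logical(1)))
  list(members = members, radius = radius,
       n_residues = length(members), n_sses = n_sses)
}

#' Hydrophobic-core agreement features
#'
#' Compares the model's detected hydrophobic core with sequence-side
#' expectations: expected member count `rho * (hydrophobic residues in the
#' sequence)`, expected radius `k_hc * count^m` (the gyration-law exponent),
#' and expected SSE count = number of predicted SSEs containing at least two
#' hydrophobic residues. Each comparison is a min/max ratio in `[0, 1]`
#' (0 when either side is 0).
#'
#' @param hc result of [detect_hc()].
#' @param profile a [target_profile()].
#' @param rho expected core fraction of hydrophobic residues (default 0.9,
#'   calibrated on the package's idealized folds, whose inward-facing side
#'   chains almost all join the core).
#' @param k_hc,m radius power-law constants (defaults 2.35 and 0.38, the
#'   former fitted on the same folds).
#' @return named numeric vector `(hc_radius_ratio, hc_count_ratio,
#'   hc_sse_ratio)`.
#' @export
hc_features <- function(hc, profile, rho = 0.9, k_hc = 2.35, m = 0.38) {
  ratio <- function(a, b) if (a <= 0 || b <= 0) 0 else min(a, b) / max(a, b)
  n_hyd_seq <- sum(profile$sequence %in% hydrophobic_set)
  exp_count <- rho * n_hyd_seq
  exp_radius <- if (exp_count > 0) k_hc * exp_count^m else 0
  tsse <- identify_sses(profile$ss_pred)
  exp_sses <- 0L
  if (nrow(tsse) > 0)
    exp_sses <- sum(vapply(seq_len(nrow(tsse)), function(i)
      sum(profile$sequence[tsse$start[i]:tsse$end[i]] %in% hydrophobic_set) >= 2,
      logical(1)))
  c(hc_radius_ratio = ratio(hc$radius, exp_radius),
    hc_count_ratio = ratio(hc$n_residues, exp_count),
    hc_sse_ratio = ratio(hc$n_sses, exp_sses))
}

#' Local fragment-conformation potentials
#'
#' Over all 5-residue windows whose majority state (at least 3 of 5) is H or
#' E: the first feature is a Gaussian transform of the mean squared deviation
#' of the CA(i)-CA(i+4) span from the ideal for the window's state (helix
#' 6.2 A, strand 12.4 A); the second is the fraction of those windows whose
#' CA virtual torsion (residues i..i+3) falls in the canonical range for the
#' state (helix 45..65 deg, strand within 30 deg of 180). Both are 0 when no
#' window qualifies.
#'
#' @param model an annotated [structure_model()] with at least 5 residues.
#' @param sigma_f Gaussian width for the span deviation, Angstrom (default 2).
#' @return named numeric vector `(frag_span, frag_torsion)`.
#' @export
fragment_potentials <- function(model, sigma_f = 2) {
  len <- length(model)
  zero <- c(frag_span = 0, frag_torsion = 0)
  if (len < 5) return(zero)
  sq_dev <- numeric(0)
  canon <- logical(0)
  for (i in seq_len(len - 4)) {
    win <- model$ss[i:(i + 4)]
    state <- if (sum(win == "H") >= 3) "H" else if (sum(win == "E") >= 3) "E" else next
    span <- vnorm(model$ca[i + 4, ] - model$ca[i, ])
    ideal <- if (state == "H") 6.2 else 12.4
    sq_dev <- c(sq_dev, (span - ideal)^2)
    tor <- dihedral(model$ca[i, ], model$ca[i + 1, ],
                    model$ca[i + 2, ], model$ca[i + 3, ])
    canon <- c(canon, if (state == "H") tor >= 45 && tor <= 65
               else abs(tor) >= 150)
  }
  if (length(sq_dev) == 0) return(zero)
  c(frag_span = exp(-mean(sq_dev) / sigma_f^2),
    frag_torsion = mean(canon))
}

# The 7 topology features for a (profile, model) pair.
features_topology_group <- function(profile, model) {
  c(gyration_features(model, length(profile)),
    hc_features(detect_hc(model), profile),
    fragment_potentials(model))
}
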