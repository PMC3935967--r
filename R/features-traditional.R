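# Traditional 1D and 2D features: composition fractions of SS/RSA states and
# their similarity transforms, contact order/number profile similarities at
# the 8 and 12 A contact classes, and the overall contact match score f_res.

#' Composition fractions of secondary-structure and accessibility states
#'
#' @param ss character vector of H/E/C states.
#' @param rsa character vector of e/b states.
#' @return named numeric vector `(helix, strand, coil, exposed, buried)`;
#'   the SS entries sum to 1 and the RSA entries sum to 1.
#' @export
composition_1d <- function(ss, rsa) {
  if (length(ss) == 0 || length(rsa) == 0) stop("empty state vector")
  c(helix = mean(ss == "H"), strand = mean(ss == "E"), coil = mean(ss == "C"),
    exposed = mean(rsa == "e"), buried = mean(rsa == "b"))
}

#' Similarity transforms of two composition vectors
#'
#' Returns the four similarity scores between equal-length vectors:
#' cosine (0 when either vector is zero), Pearson correlation (0 when either
#' side has zero variance), the Gaussian kernel `exp(-gamma ||u - v||^2)`,
#' and the dot product.
#'
#' @param u,v numeric vectors of equal length (>= 2 for correlation).
#' @param gamma Gaussian kernel width (default 1).
#' @return named numeric vector `(cosine, correlation, gaussian, dot)`.
#' @export
vector_similarities <- function(u, v, gamma = 1) {
  stopifnot(length(u) == length(v))
  c(cosine = cosine_sim(u, v),
    correlation = safe_cor(u, v),
    gaussian = exp(-gamma * sum((u - v)^2)),
    dot = sum(u * v))
}

cosine_sim <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) return(0)
  sum(u * v) / (nu * nv)
}

safe_cor <- function(u, v) {
  if (length(u) < 2 || stats::sd(u) < 1e-12 || stats::sd(v) < 1e-12) return(0)
  stats::cor(u, v)
}

#' Overall contact match score between predicted and model contacts
#'
#' Averages, over all eligible residue pairs (`i < j`, `|i - j| >= 6`), the
#' agreement `C_ij N_ij + (1 - C_ij)(1 - N_ij)` between the predicted contact
#' probability `C` and the binary model contact `N`; lies in `[0, 1]` and
#' equals 1 when `C` is binary and identical to `N`.
#'
#' @param cprob predicted contact probability matrix.
#' @param nmap binary model contact map at the matching threshold class.
#' @param min_separation minimum `|i - j|` (default 6).
#' @return the match score; 0 (with a warning) when no pair is eligible.
#' @export
f_res <- function(cprob, nmap, min_separation = 6) {
  n <- nrow(cprob)
  stopifnot(nrow(nmap) == n)
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  elig <- upper.tri(cprob) & sep >= min_separation
  if (!any(elig)) {
    warning("no residue pair at separation >= ", min_separation,
            "; f_res defined as 0")
    return(0)
  }
  cc <- cprob[elig]; nn <- nmap[elig]
  mean(cc * nn + (1 - cc) * (1 - nn))
}

# The 14 one-dimensional features: 5 sequence-side fractions, 5 model-side
# fractions, 4 similarity transforms.
features_1d <- function(profile, model, gamma = 1) {
  seq_comp <- composition_1d(profile$ss_pred, profile$rsa_pred)
  mod_comp <- composition_1d(model$ss, model$rsa)
  sims <- vector_similarities(seq_comp, mod_comp, gamma = gamma)
  out <- c(seq_comp, mod_comp, sims)
  names(out) <- c(paste0("ss_", c("helix", "strand", "coil", "exposed", "buried"), "_seq"),
                  paste0("ss_", c("helix", "strand", "coil", "exposed", "buried"), "_mod"),
                  paste0("comp_", c("cosine", "correlation", "gaussian", "dot")))
  out
}

# The 10 two-dimensional features: contact order/number profile similarities
# (cosine + correlation) at both thresholds, plus f_res at both thresholds.
features_2d <- function(profile, model) {
  out <- numeric(0)
  for (thr in c(8, 12)) {
    cprob <- if (thr == 8) profile$contact_prob_8 else profile$contact_prob_12
    nmap <- contact_map(model, thr)
    pseq <- contact_profiles(cprob)
    pmod <- contact_profiles(nmap)
    out <- c(out,
             stats::setNames(
               c(cosine_sim(pseq$order, pmod$order),
                 safe_cor(pseq$order, pmod$order),
                 cosine_sim(pseq$number, pmod$number),
                 safe_cor(pseq$number, pmod$number)),
               paste0(c("order_cosine_", "order_correlation_",
                        "number_cosine_", "number_correlation_"), thr)))
  }
  out <- c(out,
           f_res_8 = f_res(profile$contact_prob_8, contact_map(model, 8)),
           f_res_12 = f_res(profile$contact_prob_12, contact_map(model, 12)))
  out
}
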