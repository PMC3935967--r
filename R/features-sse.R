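# Secondary-structure-element (SSE) contact features: segmentation,
# model/sequence SSE correspondence, contact-strength agreement (f_SSE),
# SSE contact-number similarities, SSE pair-distance similarity, and SSE
# length ratios.

#' Identify secondary structure elements
#'
#' An SSE is a maximal run of at least `min_length` consecutive residues
#' sharing the helix or strand state.
#'
#' @param ss character vector of H/E/C states.
#' @param min_length minimum run length (default 4).
#' @return tibble with columns `kind` ("H"/"E"), `start`, `end`, `length`,
#'   in sequence order; zero rows when no SSE qualifies.
#' @export
#' @examples
#' identify_sses(strsplit("CCHHHHHCCEEEECC", "")[[1]])
identify_sses <- function(ss, min_length = 4) {
  r <- rle(ss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values %in% c("H", "E") & r$lengths >= min_length
  tibble::tibble(kind = r$values[keep], start = starts[keep], end = ends[keep],
                 length = r$lengths[keep])
}

#' Correspond model SSEs with target-sequence SSEs
#'
#' Greedy one-to-one, order-preserving matching: walking both lists in
#' sequence order, each model SSE is paired with the unmatched target SSE of
#' minimal `|start difference|` (earlier target SSE wins ties), subject to
#' pairs never crossing. Unmatched SSEs on either side are excluded from all
#' SSE features.
#'
#' @param model_sses,target_sses tibbles from [identify_sses()].
#' @return tibble with columns `model` and `target` (row indices into the two
#'   inputs); zero rows when either side is empty.
#' @export
correspond_sses <- function(model_sses, target_sses) {
  nm <- nrow(model_sses); nt <- nrow(target_sses)
  empty <- tibble::tibble(model = integer(0), target = integer(0))
  if (nm == 0 || nt == 0) return(empty)
  pairs <- empty
  next_t <- 1L
  for (i in seq_len(nm)) {
    if (next_t > nt) break
    cand <- next_t:nt
    diffs <- abs(model_sses$start[i] - target_sses$start[cand])
    j <- cand[which.min(diffs)]   # which.min takes the earliest on ties
    # keep the pairing order-preserving: j is >= next_t by construction
    pairs <- tibble::add_row(pairs, model = i, target = j)
    next_t <- j + 1L
  }
  pairs
}

#' SSE pairwise contact strength
#'
#' Model side: the number of residue pairs (one residue from each SSE,
#' sequence separation >= 6) whose SCM distance is strictly below
#' `threshold` (default 8.5 A). Sequence side: the sum of predicted contact
#' probabilities over the same residue pairs (the <8 A-class map).
#' Row-normalized strengths (entry ij divided by the length of SSE i) are
#' produced by [normalize_strength()].
#'
#' @param sses tibble from [identify_sses()].
#' @param model a [structure_model()] (model side), or `NULL`.
#' @param cprob predicted contact probability matrix (sequence side), or
#'   `NULL`. Exactly one of `model`/`cprob` must be given.
#' @param threshold model-side SCM distance cutoff in Angstrom.
#' @param min_separation minimum residue separation (default 6).
#' @return symmetric matrix of raw strengths over SSEs.
#' @export
sse_contact_strength <- function(sses, model = NULL, cprob = NULL,
                                 threshold = 8.5, min_separation = 6) {
  stopifnot(xor(is.null(model), is.null(cprob)))
  k <- nrow(sses)
  s <- matrix(0, k, k)
  if (k < 2) return(s)
  pairmat <- if (is.null(cprob)) {
    d <- as.matrix(stats::dist(model$scm))
    n <- nrow(d)
    sep <- abs(outer(seq_len(n), seq_len(n), `-`))
    (d < threshold & sep >= min_separation) * 1
  } else cprob  # band already zeroed by the profile invariant
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ri <- sses$start[i]:sses$end[i]
      rj <- sses$start[j]:sses$end[j]
      s[i, j] <- s[j, i] <- sum(pairmat[ri, rj])
    }
  }
  s
}

# Entry ij divided by the length of SSE i (generally asymmetric).
normalize_strength <- function(strength, sses) {
  sweep(strength, 1, sses$length, `/`)
}

#' Overall SSE contact-strength match score
#'
#' Bounded L1-type agreement of the row-length-normalized strengths over
#' corresponding SSEs (both orientations of each pair):
#' `f_SSE = 1 - sum |C_S - N_S| / sum max(C_S, N_S, eps)`. Equals 1 when the
#' normalized strengths coincide (including the no-contacts-on-both-sides
#' case) and 0 when their supports are disjoint or there is no
#' correspondence.
#'
#' @param strength_model,strength_target row-normalized strength matrices
#'   over the *corresponding* SSEs, aligned by the correspondence.
#' @param eps guard for the denominator (default 1e-9).
#' @return match score in `[0, 1]`.
#' @export
f_sse <- function(strength_model, strength_target, eps = 1e-9) {
  k <- nrow(strength_model)
  if (k == 0 || is.null(k)) return(0)
  stopifnot(all(dim(strength_model) == dim(strength_target)))
  off <- !diag(k)
  if (k == 1) return(0)
  cs <- strength_target[off]; ns <- strength_model[off]
  num <- sum(abs(cs - ns))
  den <- sum(pmax(cs, ns, eps))
  max(0, 1 - num / den)
}

#' SSE pair distances
#'
#' Model side: the minimum SCM-SCM distance over residue pairs of the two
#' SSEs. Sequence side: estimated from the maximum predicted contact
#' probability `p` between residues of the pair by linear interpolation
#' between the ideal contact distance and the map's distance threshold,
#' `D = D0 + k (Dm - D0) (P0 - p)`, clipped to `[D0, cap]`.
#'
#' @inheritParams sse_contact_strength
#' @param d0 ideal contact distance (default 3.8 A).
#' @param dm distance threshold of the contact class (default 8 A).
#' @param p0 ideal contact probability (default 1).
#' @param k interpolation constant (default 1).
#' @param cap upper clip for the estimate (default 20 A).
#' @return symmetric matrix of distances in Angstrom.
#' @export
sse_pair_distance <- function(sses, model = NULL, cprob = NULL,
                              d0 = 3.8, dm = 8, p0 = 1, k = 1, cap = 20) {
  stopifnot(xor(is.null(model), is.null(cprob)))
  nk <- nrow(sses)
  out <- matrix(0, nk, nk)
  if (nk < 2) return(out)
  for (i in seq_len(nk - 1)) {
    for (j in (i + 1):nk) {
      ri <- sses$start[i]:sses$end[i]
      rj <- sses$start[j]:sses$end[j]
      if (is.null(cprob)) {
        d <- min(sqrt(outer(rowSums(model$scm[ri, , drop = FALSE]^2),
                            rowSums(model$scm[rj, , drop = FALSE]^2), `+`) -
                        2 * model$scm[ri, , drop = FALSE] %*%
                          t(model$scm[rj, , drop = FALSE])))
      } else {
        p <- max(cprob[ri, rj])
        d <- min(max(d0 + k * (dm - d0) * (p0 - p), d0), cap)
      }
      out[i, j] <- out[j, i] <- d
    }
  }
  out
}

#' Similarity of model and predicted SSE pair distances
#'
#' Mean over corresponding SSE pairs of a Gaussian agreement
#' `exp(-(D_model - D_target)^2 / sigma^2)`.
#'
#' @param d_model,d_target aligned symmetric distance matrices.
#' @param sigma width in Angstrom (default 4).
#' @return similarity in `[0, 1]`; 0 when there is no SSE pair.
#' @export
sse_distance_similarity <- function(d_model, d_target, sigma = 4) {
  k <- nrow(d_model)
  if (is.null(k) || k < 2) return(0)
  up <- upper.tri(d_model)
  mean(exp(-(d_model[up] - d_target[up])^2 / sigma^2))
}

#' SSE length ratios over corresponding pairs
#'
#' `r1` pools lengths (`sum min / sum max`); `r2` averages per-pair
#' `min / max` ratios. Both are in `(0, 1]`, or `(0, 0)` without
#' correspondence.
#'
#' @param len_model,len_target lengths of the corresponding SSEs.
#' @return named numeric vector `(pooled, mean_pairwise)`.
#' @export
sse_length_ratios <- function(len_model, len_target) {
  if (length(len_model) == 0) return(c(pooled = 0, mean_pairwise = 0))
  c(pooled = sum(pmin(len_model, len_target)) / sum(pmax(len_model, len_target)),
    mean_pairwise = mean(pmin(len_model, len_target) / pmax(len_model, len_target)))
}

# The 6 SSE contact features for a (profile, model) pair.
features_sse_group <- function(profile, model, model_threshold = 8.5) {
  zero <- c(f_sse = 0, sse_number_cosine = 0, sse_number_correlation = 0,
            sse_distance_similarity = 0, sse_length_ratio_pooled = 0,
            sse_length_ratio_mean = 0)
  msse <- identify_sses(model$ss)
  tsse <- identify_sses(profile$ss_pred)
  pairs <- correspond_sses(msse, tsse)
  if (nrow(pairs) == 0) return(zero)
  msel <- msse[pairs$model, , drop = FALSE]
  tsel <- tsse[pairs$target, , drop = FALSE]
  sm <- sse_contact_strength(msel, model = model, threshold = model_threshold)
  st <- sse_contact_strength(tsel, cprob = profile$contact_prob_8)
  fm <- rowSums(sm)
  ft <- rowSums(st)
  dm <- sse_pair_distance(msel, model = model)
  dt <- sse_pair_distance(tsel, cprob = profile$contact_prob_8)
  lr <- sse_length_ratios(msel$length, tsel$length)
  c(f_sse = f_sse(normalize_strength(sm, msel), normalize_strength(st, tsel)),
    sse_number_cosine = cosine_sim(fm, ft),
    sse_number_correlation = safe_cor(fm, ft),
    sse_distance_similarity = sse_distance_similarity(dm, dt),
    sse_length_ratio_pooled = unname(lr["pooled"]),
    sse_length_ratio_mean = unname(lr["mean_pairwise"]))
}
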