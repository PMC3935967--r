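# Internal 3-state secondary-structure assignment.
#
# Backbone hydrogen bonds are detected with the classic Kabsch-Sander
# electrostatic model: the amide H is placed 1 A from N along the direction of
# the preceding C=O bond, and the donor/acceptor energy
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  [kcal/mol]
# marks a bond when E < -0.5. n-turns (n = 3,4,5) and beta bridges are then
# read off the bond pattern and collapsed to 3 states: helix classes -> H,
# strand/bridge classes -> E, everything else -> C. Residues flanking a chain
# break (consecutive CA-CA > 4.5 A) are forced to coil.

hbond_energy_matrix <- function(model, break_after) {
  len <- length(model)
  if (is.null(model$n) || is.null(model$c) || is.null(model$o))
    return(matrix(Inf, len, len))
  h <- matrix(NA_real_, len, 3)
  for (i in 2:len) {
    if (break_after[i - 1]) next
    co <- model$c[i - 1, ] - model$o[i - 1, ]
    if (any(is.na(co)) || any(is.na(model$n[i, ]))) next
    h[i, ] <- model$n[i, ] + unit(co)
  }
  dmat <- function(a, b) {
    # pairwise distances between rows of a (donor side) and b (acceptor side)
    out <- matrix(Inf, nrow(a), nrow(b))
    ok_a <- stats::complete.cases(a); ok_b <- stats::complete.cases(b)
    if (!any(ok_a) || !any(ok_b)) return(out)
    d <- sqrt(outer(rowSums(a[ok_a, , drop = FALSE]^2), rowSums(b[ok_b, , drop = FALSE]^2), `+`) -
                2 * a[ok_a, , drop = FALSE] %*% t(b[ok_b, , drop = FALSE]))
    out[ok_a, ok_b] <- d
    out
  }
  r_on <- dmat(model$n, model$o)
  r_ch <- dmat(h, model$c)
  r_oh <- dmat(h, model$o)
  r_cn <- dmat(model$n, model$c)
  e <- 0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  e[!is.finite(e)] <- Inf
  # a residue cannot bond to itself or its immediate neighbours
  e[abs(row(e) - col(e)) <= 1] <- Inf
  e
}

#' Assign 3-state secondary structure from backbone geometry
#'
#' Deterministic hydrogen-bond-based assigner (Kabsch-Sander energy model,
#' 8-state-like patterns collapsed to H/E/C): two consecutive n-turns
#' (n = 3, 4, 5) mark a helix, parallel/antiparallel bridge patterns mark
#' strands (isolated bridges included), everything else is coil. Models
#' without full backbone (CA-only) are assigned all-coil. Residues adjacent
#' to a chain break (CA-CA distance above `break_cutoff`) are forced to coil.
#'
#' @param model a [structure_model()].
#' @param break_cutoff chain-break CA-CA distance in Angstrom (default 4.5).
#' @param energy_cutoff hydrogen-bond energy cutoff in kcal/mol (default -0.5).
#' @return the model with `$ss` filled with "H"/"E"/"C".
#' @export
assign_ss <- function(model, break_cutoff = 4.5, energy_cutoff = -0.5) {
  len <- length(model)
  ss <- rep("C", len)
  if (len < 3) {
    model$ss <- ss
    return(model)
  }
  dca <- sqrt(rowSums((model$ca[-1, , drop = FALSE] -
                         model$ca[-len, , drop = FALSE])^2))
  break_after <- c(dca > break_cutoff, FALSE)   # break between i and i+1
  e <- hbond_energy_matrix(model, break_after)
  hb <- e < energy_cutoff                       # hb[d, a]: N-H of d to C=O of a

  spans_break <- function(i, j) {
    lo <- min(i, j); hi <- max(i, j)
    if (hi - lo > 12) return(FALSE)             # only guards local patterns
    any(break_after[lo:(hi - 1)])
  }
  turn <- matrix(FALSE, 3, len)                 # turn[n-2, i]: Hbond(i+n -> i)
  for (n in 3:5) {
    for (i in seq_len(len - n)) {
      if (hb[i + n, i] && !any(break_after[i:(i + n - 1)]))
        turn[n - 2, i] <- TRUE
    }
  }
  helix <- rep(FALSE, len)
  for (n in 3:5) {
    for (i in 2:max(2, len - n)) {
      if (turn[n - 2, i - 1] && turn[n - 2, i])
        helix[i:(i + n - 1)] <- TRUE
    }
  }
  bridge <- rep(FALSE, len)
  for (i in 2:(len - 1)) {
    for (j in 2:(len - 1)) {
      if (abs(i - j) < 3) next
      par <- (hb[j, i - 1] && hb[i + 1, j]) || (hb[i, j - 1] && hb[j + 1, i])
      anti <- (hb[i, j] && hb[j, i]) || (hb[j + 1, i - 1] && hb[i + 1, j - 1])
      if (par || anti) bridge[c(i, j)] <- TRUE
    }
  }
  ss[bridge] <- "E"
  ss[helix] <- "H"
  # flanks of a chain break can only be coil
  brk <- which(break_after[seq_len(len - 1)])
  ss[unique(c(brk, brk + 1))] <- "C"
  model$ss <- ss
  model
}

#' Assign 2-state relative solvent accessibility
#'
#' Burial is estimated with a neighbour-count proxy: the number of SCM
#' neighbours within `radius` of each residue's SCM is mapped linearly onto a
#' pseudo relative accessibility `1 - count / saturation` (clipped to
#' `[0, 1]`), and thresholded into exposed/buried states. The saturation
#' count was calibrated on the package's idealized synthetic folds so that
#' core residues of a compact globule fall below the default 25% threshold.
#'
#' @param model a [structure_model()].
#' @param threshold relative-accessibility cutoff; residues at or above it
#'   are exposed (default 0.25).
#' @param radius neighbour radius in Angstrom (default 10).
#' @param saturation neighbour count treated as fully buried (default 24).
#' @return the model with `$rsa` filled with "e"/"b".
#' @export
assign_rsa <- function(model, threshold = 0.25, radius = 10, saturation = 24) {
  counts <- neighbor_counts(model$scm, radius)
  acc <- pmin(pmax(1 - counts / saturation, 0), 1)
  model$rsa <- unname(ifelse(acc >= threshold, "e", "b"))
  model
}

neighbor_counts <- function(xyz, radius) {
  d <- as.matrix(stats::dist(xyz))
  rowSums(d < radius) - 1L
}

#' @describeIn assign_ss convenience wrapper running [assign_ss()] then
#'   [assign_rsa()].
#' @param ... passed on to the two assigners.
#' @export
annotate_model <- function(model, ...) {
  assign_rsa(assign_ss(model))
}

#' Read secondary-structure states from a DSSP output file
#'
#' For users who prefer the classic external toolchain over the internal
#' assigner: parses the per-residue section of a DSSP (.dssp) file and
#' collapses the 8-state codes to 3 states (H/G/I -> H, E/B -> E,
#' everything else -> C). Chain-break marker lines ("!") are skipped.
#'
#' @param path path to a DSSP output file.
#' @return character vector of H/E/C states in file order.
#' @export
read_dssp_ss <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) == 0) stop("not a DSSP file: ", path)
  body <- lines[(start[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17 & substr(body, 14, 14) != "!"]
  code <- substr(body, 17, 17)
  ifelse(code %in% c("H", "G", "I"), "H",
         ifelse(code %in% c("E", "B"), "E", "C"))
}
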