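# Synthetic fixtures: idealized toy folds, graded decoy ensembles, and
# emulated threading raw scores. Helices and strands are built with ideal
# backbone internal coordinates, packed as rigid blocks on an arc (strand
# neighbours spin-scanned into hydrogen-bonding register), and connected by
# interpolated loops. All randomness flows through one seeded stream per
# generator call.

bond_geo <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                 ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                 ang_ca_c_o = 120.8)

sse_torsions <- list(H = c(phi = -57, psi = -47), E = c(phi = -139, psi = 135))

# Side-chain center-of-mass distance from CA along the CB direction, by
# residue type (rough ideal values in Angstrom).
scm_distance <- c(G = 0, A = 1.5, S = 1.9, C = 2.0, T = 1.9, V = 1.95,
                  P = 1.9, D = 2.5, N = 2.5, I = 2.3, L = 2.6, M = 2.9,
                  E = 3.1, Q = 3.1, H = 3.1, F = 3.4, K = 3.5, Y = 3.8,
                  W = 3.9, R = 4.1)

# Ideal backbone fragment with constant (phi, psi); returns N/CA/C/O matrices.
build_fragment <- function(kind, len) {
  t <- sse_torsions[[kind]]
  n <- ca <- cc <- oo <- matrix(NA_real_, len, 3)
  n[1, ] <- c(0, 0, 0)
  ca[1, ] <- c(bond_geo$n_ca, 0, 0)
  a <- bond_geo$ang_n_ca_c * pi / 180
  cc[1, ] <- ca[1, ] + bond_geo$ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(len)) {
    if (i > 1) {
      cc[i, ] <- place_atom(cc[i - 1, ], n[i, ], ca[i, ],
                            bond_geo$ca_c, bond_geo$ang_n_ca_c, t["phi"])
    }
    if (i < len) {
      n[i + 1, ] <- place_atom(n[i, ], ca[i, ], cc[i, ],
                               bond_geo$c_n, bond_geo$ang_ca_c_n, t["psi"])
      ca[i + 1, ] <- place_atom(ca[i, ], cc[i, ], n[i + 1, ],
                                bond_geo$n_ca, bond_geo$ang_c_n_ca, 180)
      oo[i, ] <- place_atom(n[i + 1, ], ca[i, ], cc[i, ],
                            bond_geo$c_o, bond_geo$ang_ca_c_o, 180)
    } else {
      oo[i, ] <- place_atom(n[i, ], ca[i, ], cc[i, ],
                            bond_geo$c_o, bond_geo$ang_ca_c_o, t["psi"] + 180)
    }
  }
  list(n = n, ca = ca, c = cc, o = oo)
}

rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- vcross(a, b)
  s <- vnorm(v); cth <- sum(a * b)
  if (s < 1e-9) {
    if (cth > 0) return(diag(3))
    # 180 degrees: rotate about any perpendicular axis
    p <- unit(vcross(a, if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    return(rotation_axis_angle(p, pi))
  }
  rotation_axis_angle(v / s, atan2(s, cth))
}

rotation_axis_angle <- function(axis, theta) {
  axis <- unit(axis)
  k <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * k + (1 - cos(theta)) * (k %*% k)
}

transform_block <- function(frag, rot, shift) {
  lapply(frag, function(m) sweep(m %*% t(rot), 2, shift, `+`))
}

# Count backbone hydrogen bonds between two placed fragments (used to spin
# strand blocks into register).
interblock_hbonds <- function(f1, f2) {
  mini <- structure_model(
    aa = rep("A", nrow(f1$ca) + nrow(f2$ca)),
    ca = rbind(f1$ca, f2$ca), n_xyz = rbind(f1$n, f2$n),
    c_xyz = rbind(f1$c, f2$c), o_xyz = rbind(f1$o, f2$o))
  len <- length(mini)
  brk <- rep(FALSE, len)
  brk[nrow(f1$ca)] <- TRUE
  e <- hbond_energy_matrix(mini, brk)
  a <- seq_len(nrow(f1$ca)); b <- setdiff(seq_len(len), a)
  sum(e[a, b] < -0.5) + sum(e[b, a] < -0.5)
}

min_block_dist <- function(f1, f2) {
  min(sqrt(outer(rowSums(f1$ca^2), rowSums(f2$ca^2), `+`) -
             2 * f1$ca %*% t(f2$ca)))
}

# CA path for a loop of n_loop residues bridging p_from -> p_to, bulging away
# from the fold centroid.
loop_path <- function(p_from, p_to, n_loop, centroid) {
  mid <- (p_from + p_to) / 2
  out_dir <- unit(mid - centroid)
  if (vnorm(out_dir) < 1e-6) out_dir <- c(0, 0, 1)
  ctrl <- mid + 4 * out_dir
  tt <- seq(0, 1, length.out = n_loop + 2)[2:(n_loop + 1)]
  t(vapply(tt, function(u)
    (1 - u)^2 * p_from + 2 * u * (1 - u) * ctrl + u^2 * p_to, numeric(3)))
}

# Crude backbone for loop residues from their CA path (loops are coil; the
# geometry only needs to avoid spurious hydrogen-bond patterns).
loop_backbone <- function(ca_path, prev_ca, next_ca) {
  nl <- nrow(ca_path)
  ext <- rbind(prev_ca, ca_path, next_ca)
  n <- cc <- oo <- matrix(NA_real_, nl, 3)
  for (k in seq_len(nl)) {
    dir <- unit(ext[k + 2, ] - ext[k, ])
    perp <- unit(vcross(dir, c(0.267, 0.534, 0.801)))
    if (vnorm(perp) < 1e-6) perp <- unit(vcross(dir, c(1, 0, 0)))
    n[k, ] <- ca_path[k, ] - 1.46 * dir + 0.3 * perp
    cc[k, ] <- ca_path[k, ] + 1.52 * dir + 0.3 * perp
    oo[k, ] <- cc[k, ] + 1.23 * perp
  }
  list(n = n, ca = ca_path, c = cc, o = oo)
}

parse_layout <- function(layout) {
  if (is.character(layout)) {
    m <- regmatches(layout, regexec("^([HE])([0-9]+)$", layout))
    bad <- vapply(m, length, 0L) != 3
    if (any(bad)) stop("layout entries must look like 'H8' or 'E5'")
    data.frame(kind = vapply(m, `[`, "", 2),
               len = as.integer(vapply(m, `[`, "", 3)))
  } else {
    as.data.frame(layout)
  }
}

#' Build an idealized native fold
#'
#' Constructs a toy single-domain protein from a secondary-structure layout
#' (e.g. `c("H8", "E5", "E5", "H10")`): each element is built with ideal
#' helical or strand backbone torsions, the blocks are packed as rigid
#' bodies on an arc with antiparallel axes (consecutive strands are
#' spin-scanned into mutual hydrogen-bond register at ~4.2 A), and
#' connecting loops are interpolated. Residue identities are then chosen so
#' that side chains facing the fold centroid are hydrophobic, giving the
#' fold a detectable hydrophobic core. Deterministic given `seed`.
#'
#' @param layout character vector of SSE blocks (`"H<len>"` / `"E<len>"`,
#'   lengths >= 4).
#' @param seed integer seed.
#' @param model_id label.
#' @return an annotated [structure_model()] with attribute `segments` (tibble
#'   of `kind`, `start`, `end` for the SSE blocks).
#' @export
build_native <- function(layout, seed = 1, model_id = "native") {
  blocks <- parse_layout(layout)
  if (nrow(blocks) == 0) stop("empty layout")
  if (any(blocks$len < 4)) stop("SSE blocks must have length >= 4")
  rng <- local_rng(seed)
  nb <- nrow(blocks)

  frags <- lapply(seq_len(nb), function(i) build_fragment(blocks$kind[i], blocks$len[i]))
  # lateral spacing between consecutive blocks
  gaps <- if (nb > 1) vapply(seq_len(nb - 1), function(i) {
    pair <- paste0(blocks$kind[i], blocks$kind[i + 1])
    switch(pair, EE = 4.2, HH = 10.4, 9.0)
  }, 0) else numeric(0)

  # arc placement: chord spacing = gap; arc radius from total perimeter
  centers <- matrix(0, nb, 3)
  if (nb > 1) {
    per <- sum(gaps)
    rad <- max(per / (2 * pi * 0.70), max(gaps) / 2 + 0.5)
    th <- c(0, cumsum(2 * asin(pmin(gaps / (2 * rad), 1))))
    centers <- cbind(rad * cos(th), rad * sin(th), 0)
    centers <- sweep(centers, 2, colMeans(centers))
  }

  placed <- vector("list", nb)
  for (i in seq_len(nb)) {
    f <- frags[[i]]
    ctr <- colMeans(f$ca)
    axis <- stats::prcomp(f$ca)$rotation[, 1]
    target_axis <- c(0, 0, ifelse(i %% 2 == 1, 1, -1))
    rot0 <- rotation_between(axis, target_axis)
    base <- transform_block(f, rot0, centers[i, ] - as.numeric(rot0 %*% ctr))
    if (i > 1 && blocks$kind[i] == "E" && blocks$kind[i - 1] == "E") {
      # spin/shift scan for hydrogen-bond register with the previous strand
      best <- NULL
      for (ang in seq(0, 355, by = 5)) for (dz in seq(-2, 2, by = 0.2)) {
        rot <- rotation_axis_angle(c(0, 0, 1), ang * pi / 180)
        cand <- lapply(base, function(m) {
          sweep(sweep(m, 2, centers[i, ]) %*% t(rot), 2,
                centers[i, ] + c(0, 0, dz), `+`)
        })
        if (min_block_dist(placed[[i - 1]], cand) < 3.4) next
        hb <- interblock_hbonds(placed[[i - 1]], cand)
        if (is.null(best) || hb > best$hb) best <- list(hb = hb, cand = cand)
      }
      if (!is.null(best)) base <- best$cand
    } else if (i > 1) {
      # pick the spin giving the loosest packing against the previous block
      best <- NULL
      for (ang in seq(0, 330, by = 30)) {
        rot <- rotation_axis_angle(c(0, 0, 1), ang * pi / 180)
        cand <- lapply(base, function(m)
          sweep(sweep(m, 2, centers[i, ]) %*% t(rot), 2, centers[i, ], `+`))
        d <- min_block_dist(placed[[i - 1]], cand)
        if (is.null(best) || d > best$d) best <- list(d = d, cand = cand)
      }
      base <- best$cand
    }
    placed[[i]] <- base
  }

  assemble_fold(blocks, placed, rng, model_id)
}

# Stitch placed SSE blocks together with loops, assign residue identities
# and SCMs, and annotate.
assemble_fold <- function(blocks, placed, rng, model_id) {
  nb <- nrow(blocks)
  centroid <- colMeans(do.call(rbind, lapply(placed, `[[`, "ca")))
  segs <- list(); kinds <- character(0)
  pieces <- list()
  pos <- 0L
  seg_rows <- NULL
  for (i in seq_len(nb)) {
    if (i > 1) {
      p_from <- placed[[i - 1]]$ca[nrow(placed[[i - 1]]$ca), ]
      p_to <- placed[[i]]$ca[1, ]
      gap <- vnorm(p_to - p_from)
      n_loop <- max(2L, as.integer(ceiling((gap + 4) / 3.4)))
      path <- loop_path(p_from, p_to, n_loop, centroid)
      pieces[[length(pieces) + 1]] <- c(loop_backbone(path, p_from, p_to),
                                        list(kind = "L"))
      pos <- pos + n_loop
    }
    st <- pos + 1L
    pieces[[length(pieces) + 1]] <- c(placed[[i]], list(kind = blocks$kind[i]))
    pos <- pos + blocks$len[i]
    seg_rows <- rbind(seg_rows, data.frame(kind = blocks$kind[i], start = st, end = pos))
  }
  n_all <- do.call(rbind, lapply(pieces, `[[`, "n"))
  ca_all <- do.call(rbind, lapply(pieces, `[[`, "ca"))
  c_all <- do.call(rbind, lapply(pieces, `[[`, "c"))
  o_all <- do.call(rbind, lapply(pieces, `[[`, "o"))
  kind_all <- unlist(lapply(pieces, function(p) rep(p$kind, nrow(p$ca))))
  len <- nrow(ca_all)

  hydro <- c("L", "V", "I", "F", "A", "M")
  polar <- c("S", "E", "K", "T", "Q", "N", "D", "R")
  loopaa <- c("G", "S", "T", "N")
  aa <- character(len)
  scm <- ca_all
  hi <- pi_ <- li <- 0L
  for (r in seq_len(len)) {
    cb <- place_atom(c_all[r, ], n_all[r, ], ca_all[r, ], 1.53, 110.5, 122.5)
    cb_dir <- unit(cb - ca_all[r, ])
    if (kind_all[r] == "L") {
      li <- li + 1L
      aa[r] <- loopaa[(li - 1L) %% length(loopaa) + 1L]
    } else if (sum(cb_dir * unit(centroid - ca_all[r, ])) > 0.1) {
      hi <- hi + 1L
      aa[r] <- hydro[(hi - 1L) %% length(hydro) + 1L]
    } else {
      pi_ <- pi_ + 1L
      aa[r] <- polar[(pi_ - 1L) %% length(polar) + 1L]
    }
    scm[r, ] <- ca_all[r, ] + scm_distance[[aa[r]]] * cb_dir
  }
  model <- structure_model(aa, ca = ca_all, n_xyz = n_all, c_xyz = c_all,
                           o_xyz = o_all, scm = scm, model_id = model_id)
  model <- annotate_model(model)
  attr(model, "segments") <- tibble::as_tibble(seg_rows)
  model
}

#' Generate a graded decoy ensemble for a native fold
#'
#' Decoys are produced by rigid-body perturbation of the native's SSE
#' blocks: each block is rotated and translated with magnitudes scaling with
#' the decoy's grade, blocks are occasionally swapped (scrambling the fold
#' topology while preserving local structure, the signature error of
#' low-homology threading models), atoms receive a small jitter, and loops
#' are rebuilt. Grade 0 reproduces the native. Each decoy is labelled with
#' its TM-score to the native.
#'
#' @param native a [build_native()] fold (attribute `segments` required).
#' @param grades perturbation magnitudes cycled over the ensemble; the
#'   default is skewed toward heavy perturbation so native-like decoys are
#'   the minority of a pool, as in low-homology threading decoy sets.
#' @param n number of decoys (>= 2).
#' @param seed integer seed.
#' @return list with `models` (list of annotated [structure_model()]) and
#'   `tm` (numeric TM-scores to the native).
#' @export
make_decoys <- function(native, grades = c(0.3, 1.5, 2.5, 4, 4, 6, 6, 8, 8, 10),
                        n = 50, seed = 1) {
  stopifnot(n >= 2)
  segs <- attr(native, "segments")
  if (is.null(segs)) stop("native has no `segments` attribute")
  rng <- local_rng(seed)
  models <- vector("list", n)
  tm <- numeric(n)
  for (d in seq_len(n)) {
    g <- grades[(d - 1L) %% length(grades) + 1L]
    dec <- perturb_fold(native, segs, g, rng)
    dec$model_id <- sprintf("decoy%03d", d)
    models[[d]] <- annotate_model(dec)
    tm[d] <- tm_score(models[[d]], native)
  }
  list(models = models, tm = tm)
}

perturb_fold <- function(native, segs, grade, rng) {
  model <- native
  nb <- nrow(segs)
  if (grade > 0) {
    shift_rows <- function(model, rows, rot, shift, pivot) {
      for (fld in c("n", "ca", "c", "o", "scm")) {
        m <- model[[fld]][rows, , drop = FALSE]
        model[[fld]][rows, ] <- sweep(sweep(m, 2, pivot) %*% t(rot), 2,
                                      pivot + shift, `+`)
      }
      model
    }
    for (b in seq_len(nb)) {
      rows <- segs$start[b]:segs$end[b]
      pivot <- colMeans(native$ca[rows, , drop = FALSE])
      axis <- rng$rnorm(3)
      theta <- rng$rnorm(1, 0, grade * 10) * pi / 180
      shift <- rng$rnorm(3, 0, grade * 1.2)
      model <- shift_rows(model, rows, rotation_axis_angle(axis, theta),
                          shift, pivot)
    }
    if (nb >= 2 && rng$runif(1) < min(0.7, 0.15 * grade)) {
      pair <- rng$sample_int(nb, 2)
      r1 <- segs$start[pair[1]]:segs$end[pair[1]]
      r2 <- segs$start[pair[2]]:segs$end[pair[2]]
      c1 <- colMeans(model$ca[r1, , drop = FALSE])
      c2 <- colMeans(model$ca[r2, , drop = FALSE])
      model <- shift_rows(model, r1, diag(3), c2 - c1, c1)
      model <- shift_rows(model, r2, diag(3), c1 - c2, c2)
    }
    for (fld in c("n", "ca", "c", "o", "scm")) {
      jit <- matrix(rng$rnorm(3 * nrow(model$ca), 0, grade * 0.08),
                    ncol = 3)
      model[[fld]] <- model[[fld]] + jit
    }
    model <- rebuild_loops(model, segs)
  }
  model$ss <- rep(NA_character_, length(model))
  model$rsa <- rep(NA_character_, length(model))
  model
}

rebuild_loops <- function(model, segs) {
  centroid <- colMeans(model$ca)
  nb <- nrow(segs)
  for (b in seq_len(nb - 1)) {
    rows <- (segs$end[b] + 1L):(segs$start[b + 1L] - 1L)
    if (length(rows) == 0) next
    p_from <- model$ca[segs$end[b], ]
    p_to <- model$ca[segs$start[b + 1L], ]
    path <- loop_path(p_from, p_to, length(rows), centroid)
    bb <- loop_backbone(path, p_from, p_to)
    model$ca[rows, ] <- bb$ca
    model$n[rows, ] <- bb$n
    model$c[rows, ] <- bb$c
    model$o[rows, ] <- bb$o
    model$scm[rows, ] <- bb$ca
  }
  model
}

#' Emulate threading raw scores for a decoy set
#'
#' `S = a * TM + N(0, z_noise)`: a raw alignment score positively correlated
#' with model quality, with Gaussian corruption whose magnitude emulates how
#' unreliable the threading score is (large `z_noise` = dawn region).
#'
#' @param tm numeric TM-score labels.
#' @param z_noise Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param a signal scale (default 10).
#' @return numeric raw scores.
#' @export
make_raw_scores <- function(tm, z_noise, seed = 1, a = 10) {
  stopifnot(z_noise >= 0)
  rng <- local_rng(seed)
  a * tm + rng$rnorm(length(tm), 0, z_noise)
}

fixture_layouts <- list(
  c("H10", "H8", "H9"),
  c("E8", "E8", "H10"),
  c("H12", "E8", "E8", "H8"),
  c("E8", "E8", "E8"),
  c("H9", "E8", "H9"),
  c("H14", "H10", "E8", "E8"))

#' Generate a full synthetic study: targets, profiles, decoys, raw scores
#'
#' Builds `n_targets` toy folds (layouts cycled from an internal pool of
#' mixed helix/strand topologies), a noisy target profile for each, a graded
#' decoy ensemble with TM-score labels, and corrupted threading raw scores.
#' The noise defaults describe the regime the package targets: moderately
#' reliable sequence predictions (SS flip 8%, RSA flip 12%, contact miss 15%,
#' background 3%, jitter 0.05) and a dawn-region threading score
#' (`z_noise = 8`, leaving only a weak rank correlation between the raw
#' score and true model quality).
#'
#' @param n_targets number of targets.
#' @param decoys_per_target decoys per target (default 50).
#' @param seed integer seed (mandatory; everything is derived from it).
#' @param z_noise threading-score corruption (default 8).
#' @param grades decoy perturbation grades (see [make_decoys()]).
#' @param ss_flip,rsa_flip,eps,beta,sigma profile noise
#'   (see [profile_from_structure()]).
#' @return list of per-target lists, each with `target_id`, `native`,
#'   `profile`, `models`, `tm`, `raw_scores`, `z_best`.
#' @export
make_fixture_set <- function(n_targets, decoys_per_target = 50, seed = 1,
                             z_noise = 8,
                             grades = c(0.3, 1.5, 2.5, 4, 4, 6, 6, 8, 8, 10),
                             ss_flip = 0.08, rsa_flip = 0.12,
                             eps = 0.15, beta = 0.03, sigma = 0.05) {
  rng <- local_rng(seed)
  out <- vector("list", n_targets)
  for (t in seq_len(n_targets)) {
    layout <- fixture_layouts[[(t - 1L) %% length(fixture_layouts) + 1L]]
    id <- sprintf("target%03d", t)
    native <- build_native(layout, seed = rng$child_seed(), model_id = id)
    profile <- profile_from_structure(
      native, ss_flip = ss_flip, rsa_flip = rsa_flip, eps = eps, beta = beta,
      sigma = sigma, seed = rng$child_seed(), target_id = id)
    dec <- make_decoys(native, grades = grades, n = decoys_per_target,
                       seed = rng$child_seed())
    raw <- make_raw_scores(dec$tm, z_noise = z_noise, seed = rng$child_seed())
    out[[t]] <- list(target_id = id, native = native, profile = profile,
                     models = dec$models, tm = dec$tm, raw_scores = raw,
                     z_best = max(z_score(raw)))
  }
  out
}
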