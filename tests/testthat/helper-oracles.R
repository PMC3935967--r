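# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

oracle_contact_map <- function(scm, threshold, min_sep = 6) {
  n <- nrow(scm)
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < min_sep) next
    if (sqrt(sum((scm[i, ] - scm[j, ])^2)) < threshold) m[i, j] <- 1L
  }
  m
}

oracle_contact_profiles <- function(cmap) {
  n <- nrow(cmap)
  ord <- num <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0; w <- 0
    for (j in seq_len(n)) {
      s <- s + cmap[i, j]
      w <- w + cmap[i, j] * abs(i - j)
    }
    num[i] <- s
    ord[i] <- if (s > 0) w / s else 0
  }
  list(order = ord, number = num)
}

oracle_sses <- function(ss, min_length = 4) {
  out <- NULL
  i <- 1
  n <- length(ss)
  while (i <= n) {
    j <- i
    while (j < n && ss[j + 1] == ss[i]) j <- j + 1
    if (ss[i] %in% c("H", "E") && (j - i + 1) >= min_length)
      out <- rbind(out, data.frame(kind = ss[i], start = i, end = j,
                                   length = j - i + 1))
    i <- j + 1
  }
  if (is.null(out)) data.frame(kind = character(0), start = integer(0),
                               end = integer(0), length = integer(0))
  else out
}

oracle_f_res <- function(cprob, nmap, min_sep = 6) {
  n <- nrow(cprob)
  total <- 0; p <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j - i < min_sep) next
    p <- p + 1
    total <- total + cprob[i, j] * nmap[i, j] + (1 - cprob[i, j]) * (1 - nmap[i, j])
  }
  if (p == 0) 0 else total / p
}

# Exhaustive-seed superposition: every contiguous window of every length >= 4
# is taken as a seed, superposed by Kabsch (via svd, written out here), and
# iteratively refined on the residues within the distance cutoff, tracking
# the best full-chain TM sum. Same mathematical definition as the package
# path, independently coded with naive loops and a denser seed set.
oracle_tm <- function(mobile, fixed) {
  l <- nrow(mobile)
  d0 <- max(1.24 * sign(l - 15) * abs(l - 15)^(1 / 3) - 1.8, 0.5)
  fit_once <- function(idx) {
    a <- mobile[idx, , drop = FALSE]
    b <- fixed[idx, , drop = FALSE]
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    sv <- svd(crossprod(ac, bc))
    rot <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    moved <- sweep(sweep(mobile, 2, colMeans(a)) %*% t(rot), 2, colMeans(b), `+`)
    sqrt(rowSums((moved - fixed)^2))
  }
  best <- 0
  for (len in 4:l) for (s in 1:(l - len + 1)) {
    idx <- s:(s + len - 1)
    for (it in 1:20) {
      d <- fit_once(idx)
      best <- max(best, mean(1 / (1 + (d / d0)^2)))
      dcut <- max(d0, 3)
      nxt <- which(d < dcut)
      while (length(nxt) < 3 && dcut < 50) {
        dcut <- dcut + 0.5
        nxt <- which(d < dcut)
      }
      if (length(nxt) < 3 || identical(nxt, idx)) break
      idx <- nxt
    }
  }
  best
}

# Random compact CA/SCM cloud posing as a structure model (unannotated).
random_ca_model <- function(n, seed, spread = 8) {
  set.seed(seed)
  ca <- matrix(stats::rnorm(3 * n, sd = spread), ncol = 3)
  scm <- ca + matrix(stats::rnorm(3 * n, sd = 1), ncol = 3)
  structure_model(sample(c("A", "L", "S", "G", "K", "F"), n, replace = TRUE),
                  ca = ca, scm = scm,
                  model_id = paste0("rand", seed))
}

random_ss_string <- function(n, seed) {
  set.seed(seed)
  sample(c("H", "E", "C"), n, replace = TRUE, prob = c(0.4, 0.25, 0.35))
}
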