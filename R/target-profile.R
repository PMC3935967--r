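#' Target profile: sequence-side predictions
#'
#' A `target_profile` bundles everything predicted from the target sequence
#' alone, against which candidate structure models are compared: the
#' amino-acid sequence, per-residue 3-state secondary structure (H/E/C),
#' per-residue 2-state relative solvent accessibility (e/b), and symmetric
#' residue-residue contact probability matrices for the <8 A and <12 A
#' contact classes. Probabilities inside the `|i - j| < 6` band are zero.
#'
#' @param sequence one-letter amino-acid string or character vector.
#' @param ss_pred character vector (or string) of H/E/C states, length n.
#' @param rsa_pred character vector (or string) of e/b states, length n.
#' @param contact_prob_8,contact_prob_12 symmetric n x n matrices in `[0,1]`.
#' @param target_id label.
#' @return An object of class `target_profile`.
#' @export
target_profile <- function(sequence, ss_pred, rsa_pred,
                           contact_prob_8, contact_prob_12,
                           target_id = "target") {
  as_chars <- function(x) if (length(x) == 1 && nchar(x[1]) > 1)
    strsplit(x, "")[[1]] else as.character(x)
  sequence <- as_chars(sequence)
  ss_pred <- as_chars(ss_pred)
  rsa_pred <- as_chars(rsa_pred)
  n <- length(sequence)
  if (length(ss_pred) != n)
    stop("secondary-structure prediction length (", length(ss_pred),
         ") does not match sequence length (", n, ")")
  if (length(rsa_pred) != n)
    stop("accessibility prediction length (", length(rsa_pred),
         ") does not match sequence length (", n, ")")
  stopifnot(all(ss_pred %in% c("H", "E", "C")), all(rsa_pred %in% c("e", "b")))
  val_cmap <- function(m, label) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(n, n)))
      stop(label, " must be ", n, " x ", n)
    if (any(m < 0 | m > 1)) stop(label, ": probabilities outside [0, 1]")
    if (max(abs(m - t(m))) > 1e-8) stop(label, " must be symmetric")
    band <- abs(outer(seq_len(n), seq_len(n), `-`)) < 6
    if (any(m[band] != 0)) {
      warning(label, ": entries at sequence separation < 6 zeroed")
      m[band] <- 0
    }
    unname(m)
  }
  structure(
    list(target_id = target_id, sequence = sequence,
         ss_pred = ss_pred, rsa_pred = rsa_pred,
         contact_prob_8 = val_cmap(contact_prob_8, "contact_prob_8"),
         contact_prob_12 = val_cmap(contact_prob_12, "contact_prob_12")),
    class = "target_profile")
}

#' @export
length.target_profile <- function(x) length(x$sequence)

#' @export
print.target_profile <- function(x, ...) {
  cat(sprintf("<target_profile> %s: %d residues\n", x$target_id, length(x)))
  cat("  seq: ", paste(x$sequence, collapse = ""), "\n", sep = "")
  cat("  ss:  ", paste(x$ss_pred, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Read a target profile from plain-text prediction files
#'
#' File dialects: FASTA for the sequence; a single line of H/E/C characters
#' for secondary structure; a single line of e/b characters for
#' accessibility; whitespace-separated `i j p` triples (1-based, upper
#' triangle sufficient) for each contact probability map. Contact entries at
#' sequence separation < 6 are zeroed with a warning.
#'
#' @param seq_path FASTA file with the target sequence.
#' @param ss_path secondary-structure state file.
#' @param rsa_path accessibility state file.
#' @param cmap8_path,cmap12_path contact probability files for the <8 A and
#'   <12 A classes.
#' @param target_id label; defaults to the FASTA record name.
#' @return A [target_profile()].
#' @export
read_profile <- function(seq_path, ss_path, rsa_path, cmap8_path, cmap12_path,
                         target_id = NULL) {
  fas <- bio3d::read.fasta(seq_path)
  sequence <- as.character(fas$ali[1, ])
  sequence <- sequence[sequence != "-"]
  if (is.null(target_id)) target_id <- rownames(fas$ali)[1]
  n <- length(sequence)
  read_states <- function(path, allowed, label) {
    ln <- trimws(readLines(path, warn = FALSE))
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    st <- strsplit(paste(ln, collapse = ""), "")[[1]]
    if (length(st) != n)
      stop(label, " file ", path, " has ", length(st),
           " states for a ", n, "-residue sequence")
    if (!all(st %in% allowed))
      stop(label, " file ", path, " contains states outside {",
           paste(allowed, collapse = ","), "}")
    st
  }
  read_cmap <- function(path) {
    df <- utils::read.table(path, col.names = c("i", "j", "p"))
    if (any(df$i < 1 | df$j < 1 | df$i > n | df$j > n))
      stop("contact file ", path, " has residue indices outside 1..", n)
    if (any(df$p < 0 | df$p > 1))
      stop("contact file ", path, " has probabilities outside [0, 1]")
    m <- matrix(0, n, n)
    m[cbind(df$i, df$j)] <- df$p
    m[cbind(df$j, df$i)] <- df$p
    m
  }
  target_profile(sequence,
                 read_states(ss_path, c("H", "E", "C"), "secondary-structure"),
                 read_states(rsa_path, c("e", "b"), "accessibility"),
                 read_cmap(cmap8_path), read_cmap(cmap12_path),
                 target_id = target_id)
}

#' Write a target profile to the plain-text prediction formats
#'
#' @param profile a [target_profile()].
#' @param dir output directory (created if needed); files are named
#'   `<target_id>.fasta`, `.ss`, `.rsa`, `.cmap8`, `.cmap12`.
#' @return named character vector of the five paths, invisibly.
#' @export
write_profile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- profile$target_id
  paths <- file.path(dir, paste0(id, c(".fasta", ".ss", ".rsa", ".cmap8", ".cmap12")))
  names(paths) <- c("seq", "ss", "rsa", "cmap8", "cmap12")
  writeLines(c(paste0(">", id), paste(profile$sequence, collapse = "")), paths["seq"])
  writeLines(paste(profile$ss_pred, collapse = ""), paths["ss"])
  writeLines(paste(profile$rsa_pred, collapse = ""), paths["rsa"])
  write_contact_map(profile$contact_prob_8, paths["cmap8"])
  write_contact_map(profile$contact_prob_12, paths["cmap12"])
  invisible(paths)
}

#' Synthesize a noisy target profile from a native structure
#'
#' Emulates sequence-based predictors: the native's assigned secondary
#' structure and accessibility states are copied then flipped independently
#' at the given error rates, and contact probabilities are smoothed true
#' contacts, `C_ij = clip(N_ij (1 - eps) + (1 - N_ij) beta + N(0, sigma), 0, 1)`,
#' symmetrized and zeroed inside the separation band. With all noise at zero
#' the profile reproduces the native annotation exactly.
#'
#' @param native an annotated [structure_model()] (run [annotate_model()]
#'   first if `$ss` is `NA`).
#' @param ss_flip,rsa_flip per-residue state flip probabilities.
#' @param eps missed-contact rate (true contacts get probability `1 - eps`).
#' @param beta background probability for non-contacts.
#' @param sigma Gaussian jitter added to every eligible probability.
#' @param seed integer seed; the generator is fully reproducible.
#' @param target_id label; defaults to the native's model id.
#' @return A [target_profile()].
#' @export
profile_from_structure <- function(native, ss_flip = 0, rsa_flip = 0,
                                   eps = 0, beta = 0, sigma = 0,
                                   seed = 1, target_id = NULL) {
  if (anyNA(native$ss) || anyNA(native$rsa)) native <- annotate_model(native)
  if (is.null(target_id)) target_id <- native$model_id
  n <- length(native)
  rng <- local_rng(seed)
  flip_states <- function(states, rate, alphabet) {
    do_flip <- rng$runif(n) < rate
    vapply(seq_len(n), function(i) {
      if (!do_flip[i]) return(states[i])
      others <- setdiff(alphabet, states[i])
      others[rng$sample_int(length(others), 1)]
    }, "")
  }
  noisy_cmap <- function(ncontact) {
    m <- ncontact * (1 - eps) + (1 - ncontact) * beta
    if (sigma > 0) {
      jit <- matrix(rng$rnorm(n * n, 0, sigma), n, n)
      jit <- (jit + t(jit)) / 2
      m <- m + jit
    }
    m <- pmin(pmax((m + t(m)) / 2, 0), 1)
    m[abs(outer(seq_len(n), seq_len(n), `-`)) < 6] <- 0
    m
  }
  target_profile(
    sequence = native$aa,
    ss_pred = flip_states(native$ss, ss_flip, c("H", "E", "C")),
    rsa_pred = flip_states(native$rsa, rsa_flip, c("e", "b")),
    contact_prob_8 = noisy_cmap(contact_map(native, 8)),
    contact_prob_12 = noisy_cmap(contact_map(native, 12)),
    target_id = target_id)
}
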