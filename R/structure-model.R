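#' Protein structure model container
#'
#' A `structure_model` holds one single-chain protein model at residue
#' resolution: backbone N/CA/C/O coordinates, the side-chain center of mass
#' (SCM) of each residue, and -- once annotated -- per-residue 3-state
#' secondary structure and 2-state relative solvent accessibility.
#'
#' Residues are renumbered 1..length after parsing; the author numbering of
#' the source file is kept in `$source_resno`. The SCM is the mean coordinate
#' of the side-chain heavy atoms, falling back to CA for glycine (or any
#' residue without side-chain heavy atoms).
#'
#' @param aa character vector of one-letter amino-acid codes.
#' @param ca,n_xyz,c_xyz,o_xyz numeric length x 3 coordinate matrices
#'   (Angstrom); `ca` is mandatory, the rest may be `NULL` for CA-only models.
#' @param scm numeric length x 3 matrix of side-chain centers of mass;
#'   defaults to `ca` when `NULL`.
#' @param model_id label for the model.
#' @param source_resno optional integer vector of original residue numbers.
#'
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(aa, ca, n_xyz = NULL, c_xyz = NULL, o_xyz = NULL,
                            scm = NULL, model_id = "model",
                            source_resno = NULL) {
  ca <- as.matrix(ca)
  stopifnot(ncol(ca) == 3, length(aa) == nrow(ca))
  if (any(!is.finite(ca))) stop("CA coordinates must be finite for every residue")
  len <- length(aa)
  if (is.null(scm)) scm <- ca
  scm <- as.matrix(scm)
  stopifnot(nrow(scm) == len, ncol(scm) == 3)
  chk <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    stopifnot(nrow(m) == len, ncol(m) == 3)
    m
  }
  structure(
    list(model_id = model_id,
         aa = as.character(aa),
         ca = ca, n = chk(n_xyz), c = chk(c_xyz), o = chk(o_xyz),
         scm = scm,
         ss = rep(NA_character_, len),
         rsa = rep(NA_character_, len),
         source_resno = if (is.null(source_resno)) seq_len(len) else source_resno),
    class = "structure_model")
}

#' @export
length.structure_model <- function(x) length(x$aa)

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d residues\n", x$model_id, length(x)))
  if (!anyNA(x$ss)) cat("  SS: ", paste(x$ss, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @describeIn structure_model per-residue tibble view (index, aa, ss, rsa,
#'   CA and SCM coordinates).
#' @param x a `structure_model`.
#' @param ... unused.
#' @export
as_tibble.structure_model <- function(x, ...) {
  tibble::tibble(
    index = seq_along(x$aa), aa = x$aa, ss = x$ss, rsa = x$rsa,
    ca_x = x$ca[, 1], ca_y = x$ca[, 2], ca_z = x$ca[, 3],
    scm_x = x$scm[, 1], scm_y = x$scm[, 2], scm_z = x$scm[, 3])
}

backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Read a PDB structure model
#'
#' Parses ATOM records of a single-chain PDB file (the first chain is taken if
#' several are present) into a [structure_model()]. Alternate locations keep
#' the highest-occupancy copy, insertion codes are collapsed into the 1..n
#' renumbering, waters and hetero residues are skipped (selenomethionine is
#' read as methionine), and residues missing a CA atom are dropped with a
#' warning. The side-chain center of mass is the unweighted mean of the
#' side-chain heavy atoms (CA for glycine).
#'
#' @param path path to a PDB file.
#' @param model_id label for the model; defaults to the file name.
#' @return A [structure_model()].
#' @export
#' @examples
#' pdb <- system.file("extdata", "toy_helix.pdb", package = "meftop")
#' read_pdb_model(pdb)
read_pdb_model <- function(path, model_id = NULL) {
  if (is.null(model_id)) model_id <- sub("\\.pdb$", "", basename(path))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  # MSE comes through as HETATM; treat it as MET, drop all other heteros.
  at$resid[at$resid == "MSE"] <- "MET"
  at <- at[at$type == "ATOM" | at$resid == "MET", , drop = FALSE]
  at <- at[at$resid %in% bio3d::aa.table$aa3, , drop = FALSE]
  if (nrow(at) == 0) stop("no protein ATOM records in ", path)
  first_chain <- at$chain[!is.na(at$chain)][1]
  if (!is.na(first_chain))
    at <- at[!is.na(at$chain) & at$chain == first_chain, , drop = FALSE]
  # drop hydrogens
  at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]
  ins <- ifelse(is.na(at$insert), "", at$insert)
  res_key <- paste(at$resno, ins, sep = "_")
  keys <- unique(res_key)

  pick_alt <- function(df) {
    # keep highest-occupancy altloc per atom name
    df <- df[order(df$elety, -replace(df$o, is.na(df$o), 1)), , drop = FALSE]
    df[!duplicated(df$elety), , drop = FALSE]
  }

  aa <- character(0); resno <- integer(0)
  ca <- n_m <- c_m <- o_m <- scm <- NULL
  rows <- list()
  for (k in keys) {
    df <- pick_alt(at[res_key == k, , drop = FALSE])
    coords <- as.matrix(df[, c("x", "y", "z")])
    rownames(coords) <- df$elety
    if (!"CA" %in% df$elety) {
      warning("residue ", k, " has no CA atom; dropped")
      next
    }
    side <- coords[!rownames(coords) %in% backbone_atoms, , drop = FALSE]
    rows[[length(rows) + 1]] <- list(
      aa = bio3d::aa321(df$resid[1]),
      resno = df$resno[1],
      ca = coords["CA", ],
      n = if ("N" %in% rownames(coords)) coords["N", ] else rep(NA_real_, 3),
      c = if ("C" %in% rownames(coords)) coords["C", ] else rep(NA_real_, 3),
      o = if ("O" %in% rownames(coords)) coords["O", ] else rep(NA_real_, 3),
      scm = if (nrow(side) > 0) colMeans(side) else coords["CA", ])
  }
  if (length(rows) == 0) stop("no usable residues in ", path)
  grab <- function(f) do.call(rbind, lapply(rows, `[[`, f))
  structure_model(
    aa = vapply(rows, `[[`, "", "aa"),
    ca = grab("ca"), n_xyz = grab("n"), c_xyz = grab("c"), o_xyz = grab("o"),
    scm = grab("scm"), model_id = model_id,
    source_resno = vapply(rows, `[[`, 0, "resno"))
}

#' Write a structure model as a PDB file
#'
#' Backbone atoms are written as ATOM records; the side-chain center of mass
#' is emitted as a pseudo-atom named `SCM` so a written model round-trips
#' through [read_pdb_model()] with its contact geometry intact.
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_model <- function(model, path) {
  len <- length(model)
  atoms <- list()
  aa3 <- bio3d::aa123(model$aa)
  for (i in seq_len(len)) {
    add <- function(name, xyz) {
      if (is.null(xyz) || any(is.na(xyz))) return()
      atoms[[length(atoms) + 1]] <<- data.frame(
        elety = name, resid = aa3[i], resno = i,
        x = xyz[1], y = xyz[2], z = xyz[3])
    }
    add("N", model$n[i, ]); add("CA", model$ca[i, ]); add("C", model$c[i, ])
    add("O", model$o[i, ])
    if (model$aa[i] != "G" && vnorm(model$scm[i, ] - model$ca[i, ]) > 1e-9)
      add("SCM", model$scm[i, ])
  }
  df <- do.call(rbind, atoms)
  na <- nrow(df)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(df[, c("x", "y", "z")]))),
                   eleno = seq_len(na), resno = df$resno, resid = df$resid,
                   elety = df$elety, chain = rep("A", na),
                   o = rep(1, na), b = rep(0, na))
  invisible(path)
}

# Apply a rigid motion; used by fixtures and invariance tests.
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  tr <- function(m) {
    if (is.null(m)) return(NULL)
    ok <- stats::complete.cases(m)
    m[ok, ] <- m[ok, , drop = FALSE] %*% t(rotation)
    sweep(m, 2, translation, `+`)
  }
  model$ca <- tr(model$ca); model$n <- tr(model$n)
  model$c <- tr(model$c); model$o <- tr(model$o); model$scm <- tr(model$scm)
  model
}
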