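## Structure I/O and comparison. PDB parsing/writing is delegated to bio3d;
## a fixed-column pre-scan supplies line-numbered errors for malformed input.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, H = 1.20, D = 1.20)

## element symbol from PDB columns 77-78, falling back to the atom name
guess_element <- function(elesy, name) {
  el <- toupper(trimws(elesy))
  bad <- is.na(el) | !nzchar(el)
  if (any(bad)) {
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", trimws(name[bad])))
    two <- toupper(substr(nm, 1, 2)) %in% c("CL", "BR", "FE", "ZN", "MG", "NA")
    el[bad] <- ifelse(two, toupper(substr(nm, 1, 2)), toupper(substr(nm, 1, 1)))
  }
  el
}

## validate fixed-column numeric fields of ATOM/HETATM lines before handing
## the file to bio3d, so parse errors can cite the offending line
prescan_pdb <- function(lines) {
  idx <- grep("^(ATOM  |HETATM)", lines)
  if (length(idx) == 0)
    stop("no ATOM/HETATM records found in PDB input")
  for (i in idx) {
    ln <- lines[i]
    for (fld in list(c(31, 38, "x"), c(39, 46, "y"), c(47, 54, "z"))) {
      v <- substr(ln, as.integer(fld[1]), as.integer(fld[2]))
      if (is.na(suppressWarnings(as.numeric(v))))
        stop("malformed ", fld[3], " coordinate field '", trimws(v),
             "' at line ", i, " of PDB input")
    }
  }
  invisible(idx)
}

#' Read a PDB structure file
#'
#' Parses ATOM/HETATM records (fixed columns) into one [PDBStructure-class]
#' per MODEL; files without MODEL records yield a single structure.
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer (ties: first in file); insertion codes are kept as part of the
#' residue identity.
#'
#' @param file path to a PDB file, or `NULL` when `text` is given.
#' @param text optional character vector of PDB lines (alternative to `file`).
#' @param multi logical; return a list of structures even for single-model
#'   files.
#' @return A single [PDBStructure-class], or a list of them when the file has
#'   several MODELs (or `multi = TRUE`).
#' @export
readStructure <- function(file = NULL, text = NULL, multi = FALSE) {
  if (is.null(file) && is.null(text)) stop("supply 'file' or 'text'")
  if (is.null(text)) {
    if (!file.exists(file)) stop("PDB file not found: ", file)
    text <- readLines(file, warn = FALSE)
  }
  if (length(text) == 0 || !any(nzchar(text)))
    stop("empty PDB input")
  prescan_pdb(text)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(text, tf)
  nmodel <- max(1L, length(grep("^MODEL", text)))
  pdb <- bio3d::read.pdb(tf, multi = nmodel > 1L, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    bfactor = ifelse(is.na(a$b), 0, a$b),
    element = guess_element(a$elesy, a$elety),
    record = a$type,
    stringsAsFactors = FALSE)

  ## alternate locations: highest occupancy wins, ties broken by file order
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
    keep <- sort(ord[!duplicated(key[ord])])
    atoms <- atoms[keep, , drop = FALSE]
  } else keep <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL

  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1L) {
    out <- lapply(seq_len(nrow(xyz)), function(m) {
      co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
      am <- atoms
      am$x <- co[, 1]; am$y <- co[, 2]; am$z <- co[, 3]
      new("PDBStructure", atoms = am, modelId = as.integer(m))
    })
    return(out)
  }
  s <- new("PDBStructure", atoms = atoms, modelId = 1L)
  if (multi) list(s) else s
}

#' Write structures to a PDB file
#'
#' The inverse of [readStructure()]: a single structure produces a plain PDB
#' file, a list produces a multi-model file with MODEL/ENDMDL records.
#'
#' @param x a [PDBStructure-class] or a list of them (models).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeStructure <- function(x, file) {
  models <- if (is(x, "PDBStructure")) list(x) else x
  stopifnot(length(models) >= 1)
  multi <- length(models) > 1L
  out <- character(0)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  for (m in seq_along(models)) {
    s <- models[[m]]
    a <- s@atoms
    bio3d::write.pdb(file = tf,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = a$record, resno = a$resno, resid = a$resname,
                     eleno = a$serial, elety = a$name, chain = a$chain,
                     insert = ifelse(nzchar(a$insert), a$insert, NA),
                     o = a$occupancy, b = a$bfactor, elesy = a$element,
                     end = FALSE)
    lines <- readLines(tf, warn = FALSE)
    lines <- lines[grepl("^(ATOM|HETATM)", lines)]
    if (multi) lines <- c(sprintf("MODEL     %4d", m), lines, "ENDMDL")
    out <- c(out, lines)
  }
  writeLines(c(out, "END"), file)
  invisible(file)
}

heavy_atoms <- function(s) {
  !(s@atoms$element %in% c("H", "D"))
}

#' Residue pairs across a dimer interface
#'
#' Lists all residue pairs between two chains with any heavy-atom distance at
#' or below `cutoff`, sorted by minimum distance.
#'
#' @param s a [PDBStructure-class].
#' @param chainA,chainB chain identifiers.
#' @param cutoff heavy-atom distance cutoff (Angstrom).
#' @return data.frame with columns `resA`, `resnameA`, `resB`, `resnameB`,
#'   `dist` (minimum heavy-atom distance, Angstrom), sorted by `dist`.
#' @export
interfaceResidues <- function(s, chainA, chainB, cutoff = 4.5) {
  a <- s@atoms
  for (ch in c(chainA, chainB))
    if (!ch %in% a$chain) stop("chain '", ch, "' not present in structure")
  ha <- heavy_atoms(s)
  ia <- which(a$chain == chainA & ha)
  ib <- which(a$chain == chainB & ha)
  if (length(ia) == 0 || length(ib) == 0 || cutoff <= 0)
    return(data.frame(resA = integer(), resnameA = character(),
                      resB = integer(), resnameB = character(),
                      dist = numeric()))
  d <- cross_dist(coords(s, ia), coords(s, ib))
  resA <- a$resno[ia]; resB <- a$resno[ib]
  pairs <- expand.grid(ri = unique(resA), rj = unique(resB))
  mind <- mapply(function(ri, rj) {
    min(d[resA == ri, resB == rj, drop = FALSE])
  }, pairs$ri, pairs$rj)
  keep <- mind <= cutoff
  out <- data.frame(
    resA = pairs$ri[keep],
    resnameA = a$resname[ia][match(pairs$ri[keep], resA)],
    resB = pairs$rj[keep],
    resnameB = a$resname[ib][match(pairs$rj[keep], resB)],
    dist = mind[keep])
  out <- out[order(out$dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## CA atom table of one chain, in residue order
ca_table <- function(s, chain = NULL) {
  a <- s@atoms
  if (is.null(chain)) chain <- a$chain[1]
  ca <- a[a$chain == chain & a$name == "CA", , drop = FALSE]
  ca[order(ca$resno, ca$insert), , drop = FALSE]
}

#' Sequence-aligned residue pairing between two structures
#'
#' Globally aligns the CA-bearing residue sequences of one chain from each
#' structure (BLOSUM62, no end-gap penalties) and returns the matched residue
#' numbers, for use with [caRMSD()].
#'
#' @param a,b [PDBStructure-class] objects.
#' @param chainA,chainB chains to align (default: first chain of each).
#' @return data.frame with columns `resA`, `resB` (author residue numbers of
#'   aligned positions).
#' @export
alignResiduePairing <- function(a, b, chainA = NULL, chainB = NULL) {
  ta <- ca_table(a, chainA); tb <- ca_table(b, chainB)
  if (nrow(ta) == 0 || nrow(tb) == 0) stop("no CA atoms found for alignment")
  sa <- paste(bio3d::aa321(ta$resname), collapse = "")
  sb <- paste(bio3d::aa321(tb$resname), collapse = "")
  al <- Biostrings::pairwiseAlignment(sa, sb, type = "overlap",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5)
  pa <- methods::slot(Biostrings::pattern(al), "range")
  pb <- methods::slot(Biostrings::subject(al), "range")
  ca <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  cb <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  ia <- BiocGenerics::start(pa); ib <- BiocGenerics::start(pb)
  resA <- integer(0); resB <- integer(0)
  for (k in seq_along(ca)) {
    ga <- ca[k] == "-"; gb <- cb[k] == "-"
    if (!ga && !gb) {
      resA <- c(resA, ta$resno[ia]); resB <- c(resB, tb$resno[ib])
    }
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
  }
  data.frame(resA = resA, resB = resB)
}

#' C-alpha RMSD between two structures under a residue pairing
#'
#' Extracts paired CA coordinates, superposes them with the closed-form
#' least-squares fit ([superpose()]) and returns the post-fit RMSD.
#'
#' @param a,b [PDBStructure-class] objects.
#' @param pairing data.frame with columns `resA`, `resB` (residue numbers),
#'   e.g. from [alignResiduePairing()].
#' @param chainA,chainB chains the pairing refers to (default: first chain).
#' @return RMSD in Angstrom, with attributes `n` (paired CAs used) and `fit`
#'   (the [superpose()] result).
#' @export
caRMSD <- function(a, b, pairing, chainA = NULL, chainB = NULL) {
  ta <- ca_table(a, chainA); tb <- ca_table(b, chainB)
  ma <- match(pairing$resA, ta$resno)
  mb <- match(pairing$resB, tb$resno)
  if (anyNA(ma) || anyNA(mb))
    stop("paired residues lack CA atoms: ",
         paste(c(pairing$resA[is.na(ma)], pairing$resB[is.na(mb)]),
               collapse = ", "))
  ca <- as.matrix(ta[ma, c("x", "y", "z")])
  cb <- as.matrix(tb[mb, c("x", "y", "z")])
  fit <- superpose(ca, cb)
  out <- fit$rmsd
  attr(out, "n") <- nrow(ca)
  attr(out, "fit") <- fit
  out
}
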