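## Trajectory-frame analysis of a protein-ligand complex: ligand RMSD series,
## pose-stability classification, hydrogen-bond occupancy and normalized
## ligand-atom x residue contact maps.

#' Construct a FrameSeries
#'
#' @param topology a [PDBStructure-class] containing the protein and a
#'   ligand residue.
#' @param frames list of N x 3 coordinate matrices (one per frame) or a
#'   natoms x 3 x nframes array.
#' @param ligand residue name of the ligand (default "LIG").
#' @param dt frame spacing (metadata only).
#' @return A [FrameSeries-class].
#' @export
frameSeries <- function(topology, frames, ligand = "LIG", dt = 1) {
  if (is.list(frames)) {
    arr <- array(0, c(nrow(topology@atoms), 3L, length(frames)))
    for (k in seq_along(frames)) arr[, , k] <- as.matrix(frames[[k]])
  } else arr <- frames
  new("FrameSeries", topology = topology, coords = arr, ligand = ligand,
      dt = dt)
}

#' Read trajectory frames from a multi-model PDB file
#'
#' @param file multi-model PDB path.
#' @param ligand ligand residue name.
#' @param dt frame spacing (metadata).
#' @return A [FrameSeries-class].
#' @export
readFrameSeries <- function(file, ligand = "LIG", dt = 1) {
  models <- readStructure(file, multi = TRUE)
  frameSeries(models[[1]], lapply(models, coords), ligand = ligand, dt = dt)
}

#' Write a FrameSeries as a multi-model PDB file
#'
#' @param fs a [FrameSeries-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeFrameSeries <- function(fs, file) {
  models <- lapply(seq_len(nFrames(fs)), function(k) {
    a <- fs@topology@atoms
    a$x <- fs@coords[, 1, k]; a$y <- fs@coords[, 2, k]
    a$z <- fs@coords[, 3, k]
    new("PDBStructure", atoms = a, modelId = as.integer(k))
  })
  writeStructure(models, file)
}

lig_idx <- function(fs, heavy = TRUE) {
  a <- fs@topology@atoms
  i <- which(a$resname == fs@ligand)
  if (heavy) i <- i[!(a$element[i] %in% c("H", "D"))]
  i
}

prot_idx <- function(fs) {
  a <- fs@topology@atoms
  which(a$resname != fs@ligand)
}

#' Per-frame ligand RMSD after protein superposition
#'
#' Each frame is superposed on the reference frame using protein CA atoms;
#' the RMSD is then computed over ligand heavy atoms without further
#' fitting, so genuine ligand motion relative to the protein is reported.
#'
#' @param fs a [FrameSeries-class].
#' @param refFrame reference frame index (default 1).
#' @return numeric vector of per-frame RMSDs (Angstrom).
#' @export
ligandRMSDSeries <- function(fs, refFrame = 1L) {
  nf <- nFrames(fs)
  if (nf < 2) stop("at least 2 frames are required")
  a <- fs@topology@atoms
  ca <- which(a$resname != fs@ligand & a$name == "CA")
  if (length(ca) < 3) stop("fewer than 3 protein CA atoms for superposition")
  li <- lig_idx(fs)
  if (!length(li)) stop("ligand residue ", fs@ligand, " has no heavy atoms")
  ref_ca <- fs@coords[ca, , refFrame]
  ref_lig <- fs@coords[li, , refFrame]
  vapply(seq_len(nf), function(k) {
    if (any(!is.finite(fs@coords[li, , k])))
      stop("missing ligand coordinates in frame ", k)
    fit <- superpose(ref_ca, fs@coords[ca, , k])
    lig <- applyTransform(fs@coords[li, , k], fit$rotation, fit$translation)
    sqrt(mean(rowSums((lig - ref_lig)^2)))
  }, numeric(1))
}

#' Normalized ligand-atom x residue contact map
#'
#' Counts, per (protein residue, ligand heavy atom) pair, the frames in
#' which their minimum heavy-atom distance is at or below `cutoff`, and
#' normalizes all counts by the largest so the most frequent contact scores
#' 1.
#'
#' @param fs a [FrameSeries-class].
#' @param cutoff heavy-atom distance cutoff (Angstrom, default 4).
#' @return A [ContactMap-class]; when no contact occurs anywhere the map is
#'   all-zero and carries `status = "no contacts"` in its density attribute.
#' @export
contactMap <- function(fs, cutoff = 4) {
  a <- fs@topology@atoms
  li <- lig_idx(fs)
  if (!length(li)) stop("no ligand heavy atoms (resname ", fs@ligand, ")")
  pi_ <- prot_idx(fs)
  pi_ <- pi_[!(a$element[pi_] %in% c("H", "D"))]
  res_key <- paste(a$chain[pi_], a$resno[pi_], a$resname[pi_], sep = ":")
  res_lvls <- unique(res_key)
  counts <- matrix(0L, length(res_lvls), length(li),
                   dimnames = list(res_lvls, a$name[li]))
  nf <- nFrames(fs)
  for (k in seq_len(nf)) {
    d <- cross_dist(fs@coords[pi_, , k], fs@coords[li, , k])
    hit <- rowsum((d <= cutoff) + 0L, res_key, reorder = FALSE) > 0L
    counts <- counts + hit[res_lvls, , drop = FALSE]
  }
  mx <- max(counts)
  dens <- if (mx > 0) counts / mx else counts * 0
  cm <- new("ContactMap", density = dens, cutoff = cutoff,
            nframes = as.integer(nf))
  if (mx == 0) attr(cm@density, "status") <- "no contacts"
  cm
}

## resolve an atom spec "chain:resno:name" (or plain name, searched in the
## ligand first, then anywhere) to an atom index
match_atom <- function(fs, spec) {
  a <- fs@topology@atoms
  parts <- strsplit(spec, ":")[[1]]
  idx <- if (length(parts) == 3) {
    which(a$chain == parts[1] & a$resno == as.integer(parts[2]) &
            a$name == parts[3])
  } else {
    cand <- which(a$resname == fs@ligand & a$name == spec)
    if (length(cand)) cand else which(a$name == spec)
  }
  if (length(idx) == 0) stop("unknown atom: ", spec)
  if (length(idx) > 1) stop("ambiguous atom spec: ", spec)
  idx
}

#' Hydrogen-bond occupancy over trajectory frames
#'
#' For each specified bond, the fraction of frames in which the
#' donor-acceptor distance is at or below `distCutoff` and the
#' donor-H-acceptor angle is within `angCutoff` degrees of linear.
#'
#' @param fs a [FrameSeries-class].
#' @param bonds data.frame with columns `donor`, `hydrogen`, `acceptor`
#'   (atom specs: "chain:resno:name" or bare atom names, resolved in the
#'   ligand first).
#' @param distCutoff donor-acceptor heavy-atom cutoff (Angstrom, default
#'   3.5).
#' @param angCutoff allowed deviation from linearity (degrees, default 30).
#' @return numeric vector of per-bond occupancies in \[0, 1\].
#' @export
hbondOccupancy <- function(fs, bonds, distCutoff = 3.5, angCutoff = 30) {
  stopifnot(all(c("donor", "hydrogen", "acceptor") %in% names(bonds)))
  nf <- nFrames(fs)
  vapply(seq_len(nrow(bonds)), function(b) {
    di <- match_atom(fs, bonds$donor[b])
    hi <- match_atom(fs, bonds$hydrogen[b])
    ai <- match_atom(fs, bonds$acceptor[b])
    ok <- vapply(seq_len(nf), function(k) {
      dvec <- fs@coords[ai, , k] - fs@coords[di, , k]
      if (sqrt(sum(dvec^2)) > distCutoff) return(FALSE)
      ang <- vec_angle(fs@coords[di, , k] - fs@coords[hi, , k],
                      fs@coords[ai, , k] - fs@coords[hi, , k])
      !is.na(ang) && ang >= 180 - angCutoff
    }, logical(1))
    mean(ok)
  }, numeric(1))
}

#' Classify pose stability from a ligand RMSD series
#'
#' "stable" when at least `fraction` of frames lie below `stableThresh`,
#' "unstable" when fewer than `fraction / 2` do, "semi-stable" otherwise.
#'
#' @param rmsd per-frame ligand RMSD (Angstrom).
#' @param stableThresh RMSD threshold (Angstrom, default 2).
#' @param fraction frame fraction required for "stable" (default 0.8).
#' @return one of "stable", "semi-stable", "unstable".
#' @export
poseStability <- function(rmsd, stableThresh = 2, fraction = 0.8) {
  if (!length(rmsd)) stop("empty RMSD series")
  f <- mean(rmsd < stableThresh)
  if (f >= fraction) "stable"
  else if (f < fraction / 2) "unstable"
  else "semi-stable"
}

#' Export a contact map as TSV
#'
#' @param cm a [ContactMap-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeContactMap <- function(cm, file) {
  d <- as.data.frame(cm@density)
  d <- cbind(residue = rownames(cm@density), d)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
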