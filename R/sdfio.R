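## SD-file (V2000) reading and writing via ChemmineR. Conformers of one
## compound are consecutive records sharing the title (molecule name).

sdf_to_molecule <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (NROW(bb) > 0)
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  else NULL
  m <- Molecule(id, elements, bonds)
  coordsm <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  list(molecule = m, coords = coordsm)
}

#' Read a multi-conformer library from an SD file
#'
#' Records sharing a title are grouped into one [ConformerSet-class]; each
#' record contributes one conformer. Topologies of grouped records must
#' agree.
#'
#' @param file path to an SD file (V2000).
#' @return list of [ConformerSet-class] objects, in first-appearance order.
#' @export
readSDFLibrary <- function(file) {
  if (!file.exists(file)) stop("SD file not found: ", file)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(file))
  ids <- vapply(seq_along(sdfs), function(i) {
    h <- ChemmineR::header(sdfs[[i]])[["Molecule_Name"]]
    if (is.null(h) || !nzchar(trimws(h))) paste0("mol", i) else trimws(h)
  }, character(1))
  out <- list()
  for (i in seq_along(sdfs)) {
    rec <- sdf_to_molecule(sdfs[[i]], ids[i])
    if (is.null(out[[ids[i]]])) {
      out[[ids[i]]] <- conformerSet(rec$molecule, list(rec$coords))
    } else {
      prev <- out[[ids[i]]]
      if (!identical(prev@molecule@atoms$element, rec$molecule@atoms$element))
        stop("conformer records of '", ids[i], "' have differing topology")
      out[[ids[i]]] <- conformerSet(prev@molecule,
                                    c(prev@conformers, list(rec$coords)))
    }
  }
  unname(out)
}

molecule_to_sdf <- function(m, coordsm) {
  n <- nrow(m@atoms)
  ab <- cbind(coordsm, matrix(0, n, 12))
  colnames(ab) <- paste0("C", 1:16)[-4]
  rownames(ab) <- paste(m@atoms$element, seq_len(n), sep = "_")
  nb <- nrow(m@bonds)
  bb <- if (nb > 0) {
    mm <- cbind(m@bonds$i, m@bonds$j, m@bonds$order, rep(0, nb))
    colnames(mm) <- paste0("C", 1:4)
    rownames(mm) <- as.character(seq_len(nb))
    mm
  } else matrix(0, 0, 4, dimnames = list(NULL, paste0("C", 1:4)))
  header <- c(Molecule_Name = m@id, Source = "  cartwheel", Comment = "",
              Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                    n, nb))
  new("SDF", header = header, atomblock = ab, bondblock = bb,
      datablock = character(0))
}

#' Write a multi-conformer library to an SD file
#'
#' @param library list of [ConformerSet-class] objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSDFLibrary <- function(library, file) {
  sdfs <- list(); ids <- character(0)
  for (cs in library) {
    for (k in seq_along(cs@conformers)) {
      sdfs <- c(sdfs, molecule_to_sdf(cs@molecule, cs@conformers[[k]]))
      ids <- c(ids, cs@molecule@id)
    }
  }
  sdfset <- new("SDFset", SDF = sdfs, ID = make.unique(ids))
  ChemmineR::write.SDF(sdfset, file)
  invisible(file)
}
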