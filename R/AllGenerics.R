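## Accessor generics and show() methods. Slots are never touched directly by
## user code; these are the supported surface.

#' @rdname PDBStructure-class
#' @param object,x an object.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname PDBStructure-class
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))
#' @rdname PDBStructure-class
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))
#' @rdname Pharmacophore-class
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname Pharmacophore-class
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname Pharmacophore-class
#' @export
setGeneric("mandatoryCore", function(x) standardGeneric("mandatoryCore"))
#' @rdname Molecule-class
#' @export
setGeneric("molId", function(x) standardGeneric("molId"))
#' @rdname ConformerSet-class
#' @export
setGeneric("molecule", function(x) standardGeneric("molecule"))
#' @rdname ConformerSet-class
#' @export
setGeneric("conformers", function(x) standardGeneric("conformers"))
#' @rdname CSPProfile-class
#' @export
setGeneric("cspData", function(x) standardGeneric("cspData"))
#' @rdname CSPProfile-class
#' @export
setGeneric("notableResidues", function(x) standardGeneric("notableResidues"))
#' @rdname ContactMap-class
#' @export
setGeneric("contactDensity", function(x) standardGeneric("contactDensity"))
#' @rdname FrameSeries-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname PDBStructure-class
#' @export
setMethod("atoms", "PDBStructure", function(x) x@atoms)

#' @describeIn PDBStructure-class N x 3 coordinate matrix (optionally of a
#'   logical/integer atom subset `sel`).
#' @param sel optional atom subset (logical or integer index).
#' @param ... passed on.
#' @export
setMethod("coords", "PDBStructure", function(x, sel = NULL, ...) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
})

#' @rdname PDBStructure-class
#' @export
setMethod("chains", "PDBStructure", function(x) sort(unique(x@atoms$chain)))

#' @rdname Pharmacophore-class
#' @export
setMethod("features", "Pharmacophore", function(x) x@features)
#' @rdname Pharmacophore-class
#' @export
setMethod("exclusions", "Pharmacophore", function(x) x@exclusions)
#' @rdname Pharmacophore-class
#' @export
setMethod("mandatoryCore", "Pharmacophore", function(x) x@mandatory)

#' @rdname Molecule-class
#' @export
setMethod("molId", "Molecule", function(x) x@id)
#' @rdname ConformerSet-class
#' @export
setMethod("molId", "ConformerSet", function(x) x@molecule@id)
#' @rdname ConformerSet-class
#' @export
setMethod("molecule", "ConformerSet", function(x) x@molecule)
#' @rdname ConformerSet-class
#' @export
setMethod("conformers", "ConformerSet", function(x) x@conformers)

#' @rdname CSPProfile-class
#' @export
setMethod("cspData", "CSPProfile", function(x) x@data)
#' @rdname CSPProfile-class
#' @export
setMethod("notableResidues", "CSPProfile",
          function(x) x@data$resno[x@data$notable])

#' @rdname ContactMap-class
#' @export
setMethod("contactDensity", "ContactMap", function(x) x@density)

#' @rdname FrameSeries-class
#' @export
setMethod("nFrames", "FrameSeries", function(x) dim(x@coords)[3])
#' @rdname FrameSeries-class
#' @export
setMethod("atoms", "FrameSeries", function(x) x@topology@atoms)

setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  cat("PDBStructure: model", object@modelId, "-", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno, a$insert))), "residues, chains:",
      paste(sort(unique(a$chain)), collapse = " "), "\n")
})

setMethod("show", "Pharmacophore", function(object) {
  f <- object@features
  cat("Pharmacophore:", nrow(f), "features (",
      paste(names(table(f$kind)), table(f$kind), collapse = ", "), "),",
      nrow(object@exclusions), "exclusion spheres,",
      length(object@mandatory), "mandatory, minMatch =", object@minMatch, "\n")
})

setMethod("show", "Molecule", function(object) {
  cat("Molecule", object@id, ":", nrow(object@atoms), "atoms,",
      nrow(object@bonds), "bonds\n")
})

setMethod("show", "ConformerSet", function(object) {
  cat("ConformerSet", object@molecule@id, ":",
      length(object@conformers), "conformers of",
      nrow(object@molecule@atoms), "atoms\n")
})

setMethod("show", "CSPProfile", function(object) {
  cat("CSPProfile:", nrow(object@data), "residues (",
      paste(object@conditions, collapse = " vs "), "), sigma =",
      signif(object@sigma, 3), "ppm, notable:",
      sum(object@data$notable), "\n")
})

setMethod("show", "TitrationSeries", function(object) {
  cat("TitrationSeries:", nrow(object@delta), "residues x",
      length(object@concentrations), "concentrations (",
      signif(min(object@concentrations) * 1e3, 3), "-",
      signif(max(object@concentrations) * 1e3, 3), "mM ), P =",
      signif(object@Ptotal * 1e3, 3), "mM\n")
})

setMethod("show", "FrameSeries", function(object) {
  cat("FrameSeries:", dim(object@coords)[3], "frames,",
      dim(object@coords)[1], "atoms, ligand", object@ligand, "\n")
})

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap:", nrow(object@density), "residues x",
      ncol(object@density), "ligand atoms over", object@nframes,
      "frames (cutoff", object@cutoff, "A)\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec: seed", object@seed, "- Kd", object@Kd * 1e3,
      "mM, ddMax", object@ddMax, "ppm, noise", object@cspNoise,
      ", jitter", object@jitter, "A\n")
})
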