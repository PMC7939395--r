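## Central S4 containers. Constructors live next to the module code that
## produces each object; validity functions enforce the structural contracts.

setOldClass("data.frame")

#' PDBStructure: one model of a macromolecular structure
#'
#' Holds the parsed atom table of a single MODEL of a PDB file. Atom order is
#' file order; author residue numbering is preserved exactly.
#'
#' @slot atoms data.frame with one row per atom: `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `occupancy`,
#'   `bfactor`, `element`, `record` ("ATOM"/"HETATM").
#' @slot modelId integer model number (1 for single-model files).
#' @export
setClass("PDBStructure",
  representation(atoms = "data.frame", modelId = "integer"),
  validity = function(object) {
    a <- object@atoms
    need <- c("serial", "name", "altloc", "resname", "chain", "resno",
              "insert", "x", "y", "z", "occupancy", "bfactor", "element",
              "record")
    if (!all(need %in% names(a)))
      return(paste("atoms table missing columns:",
                   paste(setdiff(need, names(a)), collapse = ", ")))
    if (nrow(a) > 0) {
      if (any(!is.finite(a$x)) || any(!is.finite(a$y)) || any(!is.finite(a$z)))
        return("atom coordinates must be finite")
      if (any(!nzchar(a$element)))
        return("every atom must carry an element symbol")
      key <- paste(a$chain, a$resno, a$insert, a$name)
      if (anyDuplicated(key))
        return("duplicate (chain, resno, insert, name) atom identity")
    }
    TRUE
  })

#' Pharmacophore: typed 3-D interaction features plus exclusion volumes
#'
#' @slot features data.frame of non-exclusion features: `kind` (one of
#'   "hydrophobic", "aromatic", "donor", "acceptor"), `x`,`y`,`z` center
#'   (Angstrom), `radius` tolerance (Angstrom), `dx`,`dy`,`dz` unit direction
#'   (NA when the feature is not directional) and `label` (provenance, e.g.
#'   the anchoring residue).
#' @slot exclusions data.frame of exclusion spheres: `x`,`y`,`z`, `radius`,
#'   `label`.
#' @slot mandatory integer indices into `features` that every sub-model must
#'   retain (the mandatory core).
#' @slot minMatch minimum number of features a ligand must satisfy.
#' @export
setClass("Pharmacophore",
  representation(features = "data.frame", exclusions = "data.frame",
                 mandatory = "integer", minMatch = "integer"),
  validity = function(object) {
    f <- object@features
    if (nrow(f) > 0) {
      if (!all(f$kind %in% c("hydrophobic", "aromatic", "donor", "acceptor")))
        return("invalid feature kind")
      if (any(f$radius <= 0)) return("feature radius must be positive")
      hasdir <- !is.na(f$dx)
      if (any(hasdir)) {
        n <- sqrt(f$dx[hasdir]^2 + f$dy[hasdir]^2 + f$dz[hasdir]^2)
        if (any(abs(n - 1) > 1e-6))
          return("feature directions must be unit vectors")
      }
    }
    if (nrow(object@exclusions) > 0 && any(object@exclusions$radius <= 0))
      return("exclusion radius must be positive")
    if (length(object@mandatory) &&
        (any(object@mandatory < 1L) || any(object@mandatory > nrow(f))))
      return("mandatory indices out of range")
    if (object@minMatch > nrow(f))
      return("minMatch exceeds feature count")
    TRUE
  })

#' Molecule: a small-molecule connectivity graph
#'
#' @slot id compound identifier (shared across conformers of one compound).
#' @slot atoms data.frame: `element`, `charge` (formal, integer).
#' @slot bonds data.frame: `i`, `j` (1-based atom indices), `order` (integer;
#'   1, 2, 3, or 4 for aromatic, the SD-file convention).
#' @slot name free-text name / source tag.
#' @export
setClass("Molecule",
  representation(id = "character", atoms = "data.frame", bonds = "data.frame",
                 name = "character"),
  validity = function(object) {
    n <- nrow(object@atoms)
    b <- object@bonds
    if (n == 0) return("molecule has no atoms")
    if (nrow(b) > 0) {
      if (any(b$i < 1) || any(b$i > n) || any(b$j < 1) || any(b$j > n))
        return("bond indices out of range")
      if (!all(b$order %in% c(1L, 2L, 3L, 4L)))
        return("bond order must be 1, 2, 3 or 4 (aromatic)")
    }
    TRUE
  })

#' ConformerSet: one molecule with multiple 3-D coordinate sets
#'
#' @slot molecule a [Molecule-class].
#' @slot conformers list of N x 3 coordinate matrices (Angstrom), one row per
#'   atom of the molecule.
#' @slot featurePoints list of data.frames (one per conformer) of typed
#'   ligand feature points as produced by [extractLigandFeatures()].
#' @export
setClass("ConformerSet",
  representation(molecule = "Molecule", conformers = "list",
                 featurePoints = "list"),
  validity = function(object) {
    n <- nrow(object@molecule@atoms)
    for (cf in object@conformers) {
      if (!is.matrix(cf) || ncol(cf) != 3L || nrow(cf) != n)
        return("each conformer must be an N x 3 matrix matching the molecule")
      if (any(!is.finite(cf))) return("conformer coordinates must be finite")
    }
    if (length(object@featurePoints) &&
        length(object@featurePoints) != length(object@conformers))
      return("featurePoints must align with conformers")
    TRUE
  })

#' CSPProfile: per-residue combined chemical-shift perturbations
#'
#' @slot data data.frame: `resno`, `assignment`, `dH`, `dN` (ppm differences),
#'   `delta` (combined CSP, ppm), `notable` (logical).
#' @slot sigma standard deviation of all combined CSPs (ppm).
#' @slot sigmaExp intrinsic experimental error (ppm).
#' @slot missing assignments present in only one peak list.
#' @slot conditions labels of the two compared conditions.
#' @export
setClass("CSPProfile",
  representation(data = "data.frame", sigma = "numeric", sigmaExp = "numeric",
                 missing = "character", conditions = "character"),
  validity = function(object) {
    d <- object@data
    if (nrow(d) > 0 && any(d$delta < 0)) return("combined CSP must be >= 0")
    thr <- max(2 * object@sigma, 2 * object@sigmaExp)
    if (nrow(d) > 0 && !identical(d$notable, d$delta > thr))
      return("notable flags inconsistent with max(2*sigma, 2*sigmaExp) rule")
    TRUE
  })

#' TitrationSeries: per-residue CSP as a function of ligand concentration
#'
#' @slot concentrations ligand concentrations (molar, strictly increasing).
#' @slot Ptotal total protein concentration (molar).
#' @slot delta matrix of combined CSPs (ppm); rows = residues (named by
#'   residue number), columns = concentrations.
#' @export
setClass("TitrationSeries",
  representation(concentrations = "numeric", Ptotal = "numeric",
                 delta = "matrix"),
  validity = function(object) {
    if (any(diff(object@concentrations) <= 0))
      return("concentrations must be strictly increasing")
    if (ncol(object@delta) != length(object@concentrations))
      return("delta columns must align with concentrations")
    if (object@Ptotal <= 0) return("Ptotal must be positive")
    TRUE
  })

#' FrameSeries: trajectory frames of a protein-ligand complex
#'
#' @slot topology a [PDBStructure-class] defining atom identities.
#' @slot coords numeric array natoms x 3 x nframes (Angstrom).
#' @slot ligand residue name identifying the ligand in the topology.
#' @slot dt frame spacing (arbitrary time units; metadata only).
#' @export
setClass("FrameSeries",
  representation(topology = "PDBStructure", coords = "array",
                 ligand = "character", dt = "numeric"),
  validity = function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
      return("coords must be a natoms x 3 x nframes array")
    if (d[1] != nrow(object@topology@atoms))
      return("coords must have one row per topology atom")
    if (!any(object@topology@atoms$resname == object@ligand))
      return(paste("ligand residue", object@ligand, "not in topology"))
    TRUE
  })

#' ContactMap: normalized residue x ligand-atom contact frequencies
#'
#' @slot density matrix in \[0,1\]; rows = protein residues (labels
#'   "chain:resno:resname"), columns = ligand heavy-atom names. Normalized so
#'   the most frequent contact equals 1.
#' @slot cutoff heavy-atom distance cutoff used (Angstrom).
#' @slot nframes number of frames analyzed.
#' @export
setClass("ContactMap",
  representation(density = "matrix", cutoff = "numeric", nframes = "integer"),
  validity = function(object) {
    d <- object@density
    if (length(d) && (any(d < 0) | any(d > 1)))
      return("densities must lie in [0, 1]")
    if (length(d) && any(d > 0) && abs(max(d) - 1) > 1e-12)
      return("maximum density must equal 1 when any contact exists")
    TRUE
  })

#' SyntheticSpec: parameters controlling every synthetic-data generator
#'
#' Identical specs yield bit-identical outputs; the seed governs every source
#' of randomness.
#'
#' @slot seed integer RNG seed.
#' @slot nResidues residues in synthetic peak lists.
#' @slot nDecoys decoy compounds in synthetic libraries.
#' @slot nFrames trajectory frames.
#' @slot concentrations ligand titration concentrations (molar).
#' @slot Ptotal protein concentration (molar).
#' @slot Kd planted dissociation constant (molar).
#' @slot ddMax planted maximal combined CSP at saturation (ppm).
#' @slot displacement planted ligand displacement for unstable/hopping
#'   trajectory modes (Angstrom).
#' @slot contactOccupancy planted fraction of frames with the ligand in its
#'   bound pose for the two-state trajectory mode.
#' @slot cspNoise CSP noise, as a fraction of `ddMax`.
#' @slot jitter coordinate jitter for planted library binders (Angstrom).
#' @export
setClass("SyntheticSpec",
  representation(seed = "integer", nResidues = "integer", nDecoys = "integer",
                 nFrames = "integer", concentrations = "numeric",
                 Ptotal = "numeric", Kd = "numeric", ddMax = "numeric",
                 displacement = "numeric", contactOccupancy = "numeric",
                 cspNoise = "numeric", jitter = "numeric"),
  validity = function(object) {
    if (object@nResidues < 1L || object@nFrames < 1L)
      return("counts must be >= 1")
    if (object@cspNoise < 0 || object@jitter < 0)
      return("noise parameters must be >= 0")
    if (object@Kd <= 0 || object@ddMax <= 0 || object@Ptotal <= 0)
      return("Kd, ddMax and Ptotal must be positive")
    if (object@contactOccupancy < 0 || object@contactOccupancy > 1)
      return("contactOccupancy must lie in [0, 1]")
    TRUE
  })

#' Construct a SyntheticSpec
#'
#' Defaults reproduce the study conditions the generators emulate: a
#' millimolar-affinity ligand (Kd = 2 mM) titrated from 0.125 to 2 mM against
#' 0.1 mM protein, a maximal on-site perturbation of 0.15 ppm with 2 percent
#' relative noise, and 200-frame trajectories.
#'
#' @param seed integer seed.
#' @param nResidues,nDecoys,nFrames counts.
#' @param concentrations molar ligand concentrations (strictly increasing).
#' @param Ptotal molar protein concentration.
#' @param Kd,ddMax planted binding parameters.
#' @param displacement,contactOccupancy trajectory plant parameters.
#' @param cspNoise relative CSP noise (fraction of `ddMax`).
#' @param jitter binder coordinate jitter (Angstrom).
#' @return A [SyntheticSpec-class] object.
#' @export
syntheticSpec <- function(seed = 1L, nResidues = 60L, nDecoys = 20L,
                          nFrames = 200L,
                          concentrations = c(0.125, 0.25, 0.5, 1, 2) * 1e-3,
                          Ptotal = 1e-4, Kd = 2e-3, ddMax = 0.15,
                          displacement = 4, contactOccupancy = 0.6,
                          cspNoise = 0.02, jitter = 0.3) {
  new("SyntheticSpec", seed = as.integer(seed),
      nResidues = as.integer(nResidues), nDecoys = as.integer(nDecoys),
      nFrames = as.integer(nFrames), concentrations = concentrations,
      Ptotal = Ptotal, Kd = Kd, ddMax = ddMax, displacement = displacement,
      contactOccupancy = contactOccupancy, cspNoise = cspNoise,
      jitter = jitter)
}
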