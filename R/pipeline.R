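## Pipeline orchestration: validated config, staged runs with per-stage
## record counts logged to stderr, machine-readable outputs.

config_defaults <- function() list(
  ## inputs
  receptor = NULL, library = NULL, apo = NULL, holo = NULL,
  structure = NULL, structureA = NULL, structureB = NULL, traj = NULL,
  ## screening stage
  ligandChain = "B", receptorChain = "A", ligandResidues = NULL,
  minMatch = 5L, cap = NULL, angTol = 45, minFeatureDistance = 1.5,
  hydrophobicRange = 4.5, hbondRange = 3.5, exclusionRange = 5,
  ## library filter / diversity
  mwMin = 300, mwMax = 500, hbdMin = 1, aromaticMin = 1,
  simThreshold = 0.6,
  ## NMR stage
  site = integer(0), siteRadius = 8, sigmaExp = 0.01,
  ## trajectory stage
  ligand = "LIG", cutoff = 4, distCutoff = 3.5, angCutoff = 30,
  stableThresh = 2, stableFraction = 0.8,
  ## structure comparison
  chainA = NULL, chainB = NULL,
  ## synthetic presets
  preset = "interface", mode = "stable",
  ## general
  outDir = ".", seed = 1L, logLevel = "info")

#' Build a validated pipeline configuration
#'
#' Unknown keys are rejected; every key has a documented default (see
#' the package vignette). The configuration round-trips through YAML via
#' [writeConfig()] / [readConfig()].
#'
#' @param ... named configuration values overriding the defaults.
#' @return A named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  defs <- config_defaults()
  unknown <- setdiff(names(over), names(defs))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (length(over)) defs[names(over)] <- over
  structure(defs, class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  set_ <- Filter(Negate(is.null), unclass(x))
  cat("PipelineConfig (", length(set_), "set keys )\n")
  for (k in names(set_))
    cat(sprintf("  %-18s %s\n", k, paste(format(set_[[k]]), collapse = " ")))
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `PipelineConfig`.
#' @param file path.
#' @return `file` (write) or the re-validated `PipelineConfig` (read).
#' @export
writeConfig <- function(config, file) {
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), file)
  invisible(file)
}

#' @rdname writeConfig
#' @export
readConfig <- function(file) {
  vals <- yaml::read_yaml(file)
  do.call(pipelineConfig, vals)
}

log_stage <- function(config, stage, ...) {
  if (identical(config$logLevel, "quiet")) return(invisible())
  message("[", stage, "] ", ...)
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

as_structure <- function(x, what) {
  if (is(x, "PDBStructure")) return(x)
  if (is.character(x)) {
    s <- readStructure(x)
    return(if (is.list(s)) s[[1]] else s)
  }
  stop("no ", what, " supplied (path or PDBStructure expected)")
}

#' Run the virtual-screening stage
#'
#' Derives a pharmacophore model from the receptor complex, enumerates
#' feature sub-models, filters the library on molecular properties, screens
#' it (rigid-body fitting with exclusion volumes) and applies greedy
#' Tanimoto diversity picking to the ranked hits. Per-stage record counts
#' are logged; primary outputs (`hits.tsv`, `model.json`) are written to
#' `config$outDir`.
#'
#' @param config a [pipelineConfig()] with at least `receptor` and `library`
#'   set (paths or in-memory objects).
#' @return list with `model`, `hits` (ranked data.frame), `diverse` (hit
#'   table after diversity picking) and output file paths.
#' @export
runScreen <- function(config) {
  complex <- stage_try("input", as_structure(config$receptor, "receptor"))
  lib <- stage_try("input", {
    if (is.character(config$library)) readSDFLibrary(config$library)
    else if (is.list(config$library)) config$library
    else stop("no library supplied")
  })
  log_stage(config, "input", length(lib), " compounds in library")

  model <- stage_try("derive_model", {
    m <- deriveModel(complex, config$ligandChain, config$receptorChain,
                     ligandResidues = config$ligandResidues,
                     minFeatureDistance = config$minFeatureDistance,
                     hydrophobicRange = config$hydrophobicRange,
                     hbondRange = config$hbondRange,
                     exclusionRange = config$exclusionRange)
    m@mandatory <- defaultMandatoryCore(m)
    m
  })
  log_stage(config, "derive_model", nrow(model@features), " features, ",
            nrow(model@exclusions), " exclusions")

  mols <- lapply(lib, molecule)
  kept <- stage_try("filter_library",
                    filterLibrary(mols, config$mwMin, config$mwMax,
                                  config$hbdMin, config$aromaticMin))
  kept_ids <- vapply(kept, molId, character(1))
  lib_kept <- lib[vapply(lib, molId, character(1)) %in% kept_ids]
  log_stage(config, "filter_library", length(lib_kept), " of ",
            length(lib), " compounds pass property bounds")

  hits <- stage_try("screen", {
    if (length(lib_kept) == 0)
      data.frame(id = character(), score = numeric(), submodel = integer(),
                 conformer = integer(), nMatched = integer())
    else screenLibrary(lib_kept, model, minMatch = config$minMatch,
                       cap = config$cap, angTol = config$angTol)
  })
  log_stage(config, "screen", nrow(hits), " compounds fit >= ",
            config$minMatch, " features")
  if (nrow(hits) == 0 && length(lib) > 0)
    warning("no compound fit the pharmacophore model")

  diverse <- stage_try("diversity_pick", {
    if (nrow(hits) == 0) hits
    else {
      ranked_mols <- lapply(hits$id, function(id)
        lib_kept[[which(vapply(lib_kept, molId, character(1)) == id)]]@molecule)
      picked <- diversityPick(ranked_mols, config$simThreshold)
      hits[attr(picked, "kept"), , drop = FALSE]
    }
  })
  log_stage(config, "diversity_pick", nrow(diverse), " diverse hits kept")

  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  hits_file <- file.path(config$outDir, "hits.tsv")
  utils::write.table(diverse, hits_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  model_file <- file.path(config$outDir, "model.json")
  writePharmacophore(model, model_file)
  list(model = model, hits = hits, diverse = diverse,
       files = c(hits = hits_file, model = model_file))
}

#' Run the NMR chemical-shift-perturbation stage
#'
#' Computes the CSP profile between two conditions, maps it onto the
#' structure and classifies the compound as a site binder, off-site binder
#' or non-binder. Writes `profile.tsv`, `annotated.pdb` and `verdict.json`.
#'
#' @param config a [pipelineConfig()] with `apo`, `holo`, `structure` and
#'   `site` set.
#' @return list with `profile`, `mapping`, `classification` and file paths.
#' @export
runCSP <- function(config) {
  read_pl <- function(x, cond) {
    if (is.character(x)) readPeakList(x, cond) else x
  }
  apo <- stage_try("input", read_pl(config$apo, "apo"))
  holo <- stage_try("input", read_pl(config$holo, "holo"))
  s <- stage_try("input", as_structure(config$structure, "structure"))
  site <- if (is.character(config$site))
    as.integer(strsplit(config$site, ",")[[1]]) else config$site
  log_stage(config, "input", nrow(apo), " apo / ", nrow(holo), " holo peaks")

  profile <- stage_try("csp_profile",
                       cspProfile(apo, holo, sigmaExp = config$sigmaExp))
  log_stage(config, "csp_profile", nrow(cspData(profile)), " shared residues, ",
            sum(cspData(profile)$notable), " notable")

  mapping <- stage_try("map_to_structure",
                       mapToStructure(profile, s, site,
                                      siteRadius = config$siteRadius))
  classification <- switch(mapping$classification,
                           "no binding" = "non-binder",
                           "site" = "site-binder",
                           "off-site" = "off-site binder")
  log_stage(config, "map_to_structure", "classification: ", classification)

  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  prof_file <- file.path(config$outDir, "profile.tsv")
  d <- cspData(profile)
  utils::write.table(d, prof_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pdb_file <- file.path(config$outDir, "annotated.pdb")
  writeStructure(mapping$structure, pdb_file)
  verdict_file <- file.path(config$outDir, "verdict.json")
  jsonlite::write_json(
    list(classification = classification, fraction = mapping$fraction,
         pvalue = mapping$pvalue, sigma = profile@sigma,
         sigmaExp = profile@sigmaExp,
         notable = d$resno[d$notable]),
    verdict_file, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  list(profile = profile, mapping = mapping,
       classification = classification,
       files = c(profile = prof_file, pdb = pdb_file,
                 verdict = verdict_file))
}

#' Run the trajectory-contacts stage
#'
#' Computes the ligand RMSD series, pose-stability verdict and the
#' normalized contact map. Writes `rmsd.tsv`, `contacts.tsv` and
#' `contacts.json`.
#'
#' @param config a [pipelineConfig()] with `traj` set (multi-model PDB path
#'   or [FrameSeries-class]).
#' @return list with `rmsd`, `stability`, `map` and file paths.
#' @export
runContacts <- function(config) {
  fs <- stage_try("input", {
    if (is(config$traj, "FrameSeries")) config$traj
    else if (is.character(config$traj))
      readFrameSeries(config$traj, ligand = config$ligand)
    else stop("no trajectory supplied")
  })
  log_stage(config, "input", nFrames(fs), " frames")

  rmsd <- stage_try("ligand_rmsd", ligandRMSDSeries(fs))
  stability <- poseStability(rmsd, config$stableThresh,
                             config$stableFraction)
  log_stage(config, "ligand_rmsd", "pose: ", stability)
  cmap <- stage_try("contact_map", contactMap(fs, cutoff = config$cutoff))
  log_stage(config, "contact_map", sum(cmap@density > 0), " contact cells")

  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  rmsd_file <- file.path(config$outDir, "rmsd.tsv")
  utils::write.table(data.frame(frame = seq_along(rmsd), rmsd = rmsd),
                     rmsd_file, sep = "\t", quote = FALSE, row.names = FALSE)
  map_file <- file.path(config$outDir, "contacts.tsv")
  writeContactMap(cmap, map_file)
  json_file <- file.path(config$outDir, "contacts.json")
  jsonlite::write_json(
    list(stability = stability, cutoff = cmap@cutoff,
         nframes = cmap@nframes,
         maxContact = if (length(cmap@density)) {
           i <- which(cmap@density == max(cmap@density), arr.ind = TRUE)[1, ]
           list(residue = rownames(cmap@density)[i[1]],
                atom = colnames(cmap@density)[i[2]])
         } else NULL),
    json_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(rmsd = rmsd, stability = stability, map = cmap,
       files = c(rmsd = rmsd_file, map = map_file, json = json_file))
}

#' Run the structure-comparison stage
#'
#' Sequence-aligns the CA-bearing residues of two structures and reports
#' their C-alpha RMSD with the residue pairs used.
#'
#' @param config a [pipelineConfig()] with `structureA` and `structureB`
#'   set.
#' @return list with `rmsd`, `n`, `pairing`, and the report file path.
#' @export
runCompareStructures <- function(config) {
  a <- stage_try("input", as_structure(config$structureA, "structureA"))
  b <- stage_try("input", as_structure(config$structureB, "structureB"))
  pairing <- stage_try("align",
                       alignResiduePairing(a, b, config$chainA,
                                           config$chainB))
  log_stage(config, "align", nrow(pairing), " residues paired")
  r <- stage_try("ca_rmsd", caRMSD(a, b, pairing, config$chainA,
                                   config$chainB))
  log_stage(config, "ca_rmsd", sprintf("%.3f A over %d CA pairs",
                                       as.numeric(r), attr(r, "n")))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- file.path(config$outDir, "compare.json")
  jsonlite::write_json(
    list(rmsd = as.numeric(r), n = attr(r, "n"), pairing = pairing),
    report, dataframe = "rows", auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  list(rmsd = as.numeric(r), n = attr(r, "n"), pairing = pairing,
       files = c(report = report))
}

#' Generate synthetic inputs
#'
#' Writes the preset's files (interface PDB, library SD file, titration peak
#' lists or trajectory PDB) to `config$outDir`, all derived from
#' `config$seed`.
#'
#' @param config a [pipelineConfig()]; `preset` is one of "interface",
#'   "library", "titration", "trajectory"; `mode` selects the trajectory
#'   stability mode.
#' @return named vector of written file paths.
#' @export
runSimulate <- function(config) {
  spec <- syntheticSpec(seed = config$seed)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- c()
  if (config$preset == "interface") {
    s <- makeToyInterface(spec)
    f <- file.path(config$outDir, "interface.pdb")
    writeStructure(s, f); out <- c(interface = f)
  } else if (config$preset == "library") {
    s <- makeToyInterface(spec)
    model <- deriveModel(s, "B", "A")
    model@mandatory <- defaultMandatoryCore(model)
    lib <- makeLigandLibrary(model, nBinders = 1L, spec = spec)
    f <- file.path(config$outDir, "library.sdf")
    writeSDFLibrary(lib, f)
    fm <- file.path(config$outDir, "model.json")
    writePharmacophore(model, fm)
    out <- c(library = f, model = fm)
  } else if (config$preset == "titration") {
    tp <- makeTitrationPeaks(spec)
    fa <- file.path(config$outDir, "apo.list")
    writePeakList(tp$apo, fa); out <- c(apo = fa)
    for (i in seq_along(tp$holo)) {
      f <- file.path(config$outDir, sprintf("holo_%02d.list", i))
      writePeakList(tp$holo[[i]], f)
      out <- c(out, setNames(f, sprintf("holo_%02d", i)))
    }
  } else if (config$preset == "trajectory") {
    fs <- makeTrajectory(makeToyComplex(spec), mode = config$mode,
                         spec = spec)
    f <- file.path(config$outDir, "trajectory.pdb")
    writeFrameSeries(fs, f); out <- c(trajectory = f)
  } else stop("unknown preset: ", config$preset)
  log_stage(config, "simulate", "wrote ", length(out), " file(s)")
  out
}
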