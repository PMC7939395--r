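## The virtual-screening engine: interface-derived feature models,
## sub-model enumeration with a mandatory core, typed ligand feature points,
## exhaustive rigid-body correspondence fitting with exclusion volumes, and
## library ranking.

DEFAULT_FEATURE_RADII <- c(hydrophobic = 1.5, aromatic = 1.5,
                           donor = 1.0, acceptor = 1.0)

empty_features <- function() {
  data.frame(kind = character(), x = numeric(), y = numeric(), z = numeric(),
             radius = numeric(), dx = numeric(), dy = numeric(),
             dz = numeric(), label = character())
}

feature_row <- function(kind, center, radius, direction = NULL, label = "") {
  if (is.null(direction)) direction <- c(NA_real_, NA_real_, NA_real_)
  data.frame(kind = kind, x = center[1], y = center[2], z = center[3],
             radius = radius, dx = direction[1], dy = direction[2],
             dz = direction[3], label = label)
}

#' Construct a Pharmacophore
#'
#' @param features data.frame of features (see [Pharmacophore-class]).
#' @param exclusions data.frame of exclusion spheres.
#' @param mandatory integer indices of the mandatory core.
#' @param minMatch minimum features a ligand must satisfy (default 5).
#' @return A [Pharmacophore-class] object.
#' @export
pharmacophore <- function(features = empty_features(),
                          exclusions = data.frame(x = numeric(),
                                                  y = numeric(),
                                                  z = numeric(),
                                                  radius = numeric(),
                                                  label = character()),
                          mandatory = integer(0),
                          minMatch = 5L) {
  rownames(features) <- NULL
  rownames(exclusions) <- NULL
  new("Pharmacophore", features = features, exclusions = exclusions,
      mandatory = as.integer(mandatory),
      minMatch = as.integer(max(0L, min(minMatch, nrow(features)))))
}

## hydrogens attached to each heavy atom of a structure (same residue,
## distance <= 1.25 A)
attached_hydrogens <- function(s) {
  a <- s@atoms
  hs <- which(a$element %in% c("H", "D"))
  heavy <- which(!(a$element %in% c("H", "D")))
  out <- vector("list", nrow(a))
  if (length(hs) == 0) return(out)
  xyz <- coords(s)
  for (h in hs) {
    same <- heavy[a$chain[heavy] == a$chain[h] & a$resno[heavy] == a$resno[h]]
    if (!length(same)) next
    d <- sqrt(colSums((t(xyz[same, , drop = FALSE]) - xyz[h, ])^2))
    k <- same[which.min(d)]
    if (min(d) <= 1.25) out[[k]] <- c(out[[k]], h)
  }
  out
}

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "HA", "HN")

#' Derive a pharmacophore model from a dimer interface
#'
#' Treats one chain (or residue range) as the "ligand" and another chain as
#' the receptor, and maps the interactions between them into typed features:
#' hydrophobic features at centroids of apolar ligand side-chain heavy atoms
#' in contact with receptor apolar atoms; hydrogen-bond donor features at
#' ligand N-H/O-H hydrogens within hydrogen-bonding range of receptor
#' acceptors (directed toward the acceptor); acceptor features at ligand
#' acceptor atoms near receptor donors (directed toward the donor); and
#' exclusion spheres on receptor heavy atoms lining the site. Same-kind
#' features closer than `minFeatureDistance` are merged (centroid, largest
#' radius).
#'
#' @param complex a [PDBStructure-class] containing both chains.
#' @param ligandChain chain id of the "ligand" (e.g. the interface loop
#'   peptide).
#' @param receptorChain chain id of the receptor.
#' @param ligandResidues optional residue numbers restricting the ligand
#'   selection.
#' @param minFeatureDistance merge distance for same-kind features
#'   (Angstrom, default 1.5).
#' @param hydrophobicRange heavy-atom contact range for hydrophobic features
#'   (default 4.5 A).
#' @param hbondRange heavy-atom donor-acceptor range (default 3.5 A).
#' @param exclusionRange receptor atoms within this range of any ligand heavy
#'   atom become exclusion spheres (default 5 A).
#' @param radii named tolerance radii per feature kind.
#' @return A [Pharmacophore-class]; empty (with a warning) when no contacts
#'   are found.
#' @export
deriveModel <- function(complex, ligandChain, receptorChain,
                        ligandResidues = NULL, minFeatureDistance = 1.5,
                        hydrophobicRange = 4.5, hbondRange = 3.5,
                        exclusionRange = 5,
                        radii = DEFAULT_FEATURE_RADII) {
  a <- complex@atoms
  lig <- a$chain == ligandChain
  if (!is.null(ligandResidues)) lig <- lig & a$resno %in% ligandResidues
  rec <- a$chain == receptorChain
  if (!any(lig) || !any(rec)) stop("empty ligand or receptor selection")

  xyz <- coords(complex)
  hyd <- attached_hydrogens(complex)
  is_h <- a$element %in% c("H", "D")
  apolar <- a$element %in% c("C", "S", "CL", "BR", "I") & !is_h
  has_h <- lengths(hyd) > 0

  rec_heavy <- which(rec & !is_h)
  rec_apolar <- which(rec & apolar)
  rec_acceptor <- which(rec & (a$element == "O" |
                                 (a$element == "N" & !has_h)))
  rec_donor <- which(rec & a$element %in% c("N", "O") & has_h)
  lig_heavy <- which(lig & !is_h)

  feats <- empty_features()

  ## hydrophobic: per ligand residue, centroid of apolar side-chain heavy
  ## atoms in contact with receptor apolar atoms
  lig_apolar_sc <- which(lig & apolar & !(a$name %in% BACKBONE_NAMES))
  if (length(lig_apolar_sc) && length(rec_apolar)) {
    d <- cross_dist(xyz[lig_apolar_sc, , drop = FALSE],
                    xyz[rec_apolar, , drop = FALSE])
    contact <- apply(d, 1L, min) <= hydrophobicRange
    touching <- lig_apolar_sc[contact]
    for (res in unique(a$resno[touching])) {
      grp <- touching[a$resno[touching] == res]
      ctr <- colMeans(xyz[grp, , drop = FALSE])
      feats <- rbind(feats, feature_row(
        "hydrophobic", ctr, radii[["hydrophobic"]],
        label = paste0(a$resname[grp[1]], res)))
    }
  }

  ## donors: ligand N-H / O-H hydrogens near a receptor acceptor
  lig_donor_heavy <- which(lig & a$element %in% c("N", "O", "S") & has_h)
  for (dh in lig_donor_heavy) {
    if (!length(rec_acceptor)) break
    dacc <- sqrt(colSums((t(xyz[rec_acceptor, , drop = FALSE]) -
                            xyz[dh, ])^2))
    if (min(dacc) > hbondRange) next
    acc <- rec_acceptor[which.min(dacc)]
    for (h in hyd[[dh]]) {
      dir <- unit_vec(xyz[acc, ] - xyz[h, ])
      feats <- rbind(feats, feature_row(
        "donor", xyz[h, ], radii[["donor"]], dir,
        label = paste0(a$resname[dh], a$resno[dh], ":", a$name[dh], "-H")))
    }
  }

  ## acceptors: ligand O (or H-free N) near a receptor donor
  lig_acc <- which(lig & (a$element == "O" | (a$element == "N" & !has_h)))
  for (ac in lig_acc) {
    if (!length(rec_donor)) break
    ddon <- sqrt(colSums((t(xyz[rec_donor, , drop = FALSE]) - xyz[ac, ])^2))
    if (min(ddon) > hbondRange) next
    don <- rec_donor[which.min(ddon)]
    dir <- unit_vec(xyz[don, ] - xyz[ac, ])
    feats <- rbind(feats, feature_row(
      "acceptor", xyz[ac, ], radii[["acceptor"]], dir,
      label = paste0(a$resname[ac], a$resno[ac], ":", a$name[ac])))
  }

  ## exclusion spheres: receptor heavy atoms lining the site
  excl <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                     radius = numeric(), label = character())
  if (length(lig_heavy) && length(rec_heavy)) {
    d <- cross_dist(xyz[rec_heavy, , drop = FALSE],
                    xyz[lig_heavy, , drop = FALSE])
    lining <- rec_heavy[apply(d, 1L, min) <= exclusionRange]
    if (length(lining)) {
      r <- VDW_RADII[a$element[lining]]
      r[is.na(r)] <- 1.7
      excl <- data.frame(x = xyz[lining, 1], y = xyz[lining, 2],
                         z = xyz[lining, 3], radius = unname(r),
                         label = paste0(a$resname[lining], a$resno[lining],
                                        ":", a$name[lining]))
    }
  }

  feats <- merge_features(feats, minFeatureDistance)
  if (nrow(feats) == 0)
    warning("no interface contacts found: empty pharmacophore model")
  pharmacophore(feats, excl, integer(0),
                minMatch = min(5L, max(1L, nrow(feats))))
}

## iteratively merge same-kind features closer than mindist
merge_features <- function(feats, mindist) {
  repeat {
    if (nrow(feats) < 2) return(feats)
    ctrs <- as.matrix(feats[, c("x", "y", "z")])
    d <- cross_dist(ctrs, ctrs)
    diag(d) <- Inf
    same <- outer(feats$kind, feats$kind, "==")
    hit <- which(d < mindist & same, arr.ind = TRUE)
    if (nrow(hit) == 0) return(feats)
    i <- hit[1, 1]; j <- hit[1, 2]
    ctr <- colMeans(ctrs[c(i, j), , drop = FALSE])
    dir <- c(NA_real_, NA_real_, NA_real_)
    dirs <- as.matrix(feats[c(i, j), c("dx", "dy", "dz")])
    if (!anyNA(dirs)) dir <- unit_vec(colMeans(dirs))
    else if (!anyNA(dirs[1, ])) dir <- dirs[1, ]
    else if (!anyNA(dirs[2, ])) dir <- dirs[2, ]
    merged <- feature_row(feats$kind[i], ctr, max(feats$radius[c(i, j)]),
                          if (anyNA(dir)) NULL else dir,
                          label = paste(feats$label[i], feats$label[j],
                                        sep = "+"))
    feats <- rbind(feats[-c(i, j), , drop = FALSE], merged)
    rownames(feats) <- NULL
  }
}

#' Pick a default mandatory core
#'
#' Mirrors the screening protocol's minimum requirement: two
#' hydrophobic/aromatic features plus one hydrogen-bond donor.
#'
#' @param model a [Pharmacophore-class].
#' @return integer feature indices (possibly fewer than 3 when the model is
#'   small).
#' @export
defaultMandatoryCore <- function(model) {
  f <- model@features
  hyd <- which(f$kind %in% c("hydrophobic", "aromatic"))
  don <- which(f$kind == "donor")
  as.integer(c(utils::head(hyd, 2L), utils::head(don, 1L)))
}

#' Enumerate feature sub-models
#'
#' All feature subsets of size at least `minMatch` that contain the mandatory
#' core, in deterministic order (by size, then lexicographically by feature
#' indices). Exclusion spheres are attached to every sub-model.
#'
#' @param model a [Pharmacophore-class].
#' @param minMatch minimum subset size (default 5).
#' @param cap optional maximum number of sub-models returned.
#' @return list of [Pharmacophore-class] sub-models; each carries an
#'   `indices` attribute giving its feature indices in the parent model.
#' @export
enumerateSubmodels <- function(model, minMatch = 5L, cap = NULL) {
  nf <- nrow(model@features)
  mand <- model@mandatory
  if (length(mand) > nf) stop("mandatory core larger than feature set")
  if (minMatch > nf)
    stop("minMatch (", minMatch, ") exceeds feature count (", nf, ")")
  free <- setdiff(seq_len(nf), mand)
  out <- list()
  for (size in seq(max(minMatch, length(mand)), nf)) {
    k <- size - length(mand)
    combos <- if (k == 0) matrix(integer(0), nrow = 0, ncol = 1)
      else utils::combn(free, k)
    sets <- if (k == 0) list(sort(mand))
      else lapply(seq_len(ncol(combos)), function(c_)
        sort(c(mand, combos[, c_])))
    ## lexicographic order of full index vectors within this size
    ord <- order(vapply(sets, function(s)
      paste(sprintf("%03d", s), collapse = ""), character(1)))
    for (s in sets[ord]) {
      sub <- pharmacophore(model@features[s, , drop = FALSE],
                           model@exclusions,
                           mandatory = match(mand, s),
                           minMatch = length(s))
      attr(sub, "indices") <- s
      out <- c(out, sub)
      if (!is.null(cap) && length(out) >= cap) return(out)
    }
  }
  out
}

#' Typed feature points of a ligand conformer
#'
#' Derives the interaction points a conformer offers: donors at H-bearing
#' N/O/S (point at the heavy atom, direction along the O-H/N-H bond when an
#' explicit hydrogen is present), acceptors at O and lone-pair N (direction
#' opposite the mean bond vector), hydrophobic points at centroids of
#' bond-connected groups of two or more apolar heavy atoms outside aromatic
#' rings, and aromatic points at all-aromatic ring centroids (direction =
#' ring normal).
#'
#' @param m a [Molecule-class].
#' @param coordsm N x 3 conformer coordinates.
#' @return data.frame with columns `kind`, `x`,`y`,`z`, `dx`,`dy`,`dz`
#'   (NA when non-directional) and `atoms` (comma-separated atom indices).
#' @export
extractLigandFeatures <- function(m, coordsm) {
  if (is.null(coordsm) || nrow(coordsm) != nrow(m@atoms))
    stop("conformer coordinates missing or mismatched")
  el <- m@atoms$element
  n <- length(el)
  adj <- mol_adjacency(m)
  nh_imp <- implicit_hydrogens(m)
  expl_h <- lapply(seq_len(n), function(i) {
    nbrs <- adj[[i]]
    if (is.null(nbrs)) integer(0) else nbrs[el[nbrs[, 1]] == "H", 1]
  })
  pts <- data.frame(kind = character(), x = numeric(), y = numeric(),
                    z = numeric(), dx = numeric(), dy = numeric(),
                    dz = numeric(), atoms = character())
  add <- function(kind, center, dir, atoms) {
    if (is.null(dir)) dir <- c(NA_real_, NA_real_, NA_real_)
    rbind(pts, data.frame(kind = kind, x = center[1], y = center[2],
                          z = center[3], dx = dir[1], dy = dir[2],
                          dz = dir[3],
                          atoms = paste(atoms, collapse = ",")))
  }

  ## aromatic rings
  rings <- mol_rings(m)
  arom_ring_atoms <- integer(0)
  for (ring in rings) {
    allarom <- TRUE
    for (k in seq_along(ring)) {
      i <- ring[k]; j <- ring[k %% length(ring) + 1L]
      bi <- which((m@bonds$i == i & m@bonds$j == j) |
                    (m@bonds$i == j & m@bonds$j == i))
      if (!length(bi) || m@bonds$order[bi[1]] != 4L) { allarom <- FALSE; break }
    }
    if (!allarom) next
    arom_ring_atoms <- union(arom_ring_atoms, ring)
    rc <- coordsm[ring, , drop = FALSE]
    ctr <- colMeans(rc)
    sv <- svd(sweep(rc, 2L, ctr))
    normal <- sv$v[, 3]
    pts <- add("aromatic", ctr, unit_vec(normal), ring)
  }

  ## donors
  for (i in which(el %in% c("N", "O", "S"))) {
    hs <- expl_h[[i]]
    if (length(hs)) {
      dir <- unit_vec(coordsm[hs[1], ] - coordsm[i, ])
      pts <- add("donor", coordsm[i, ], dir, i)
    } else if (nh_imp[i] >= 1L) {
      pts <- add("donor", coordsm[i, ], NULL, i)
    }
  }

  ## acceptors: any O; N with a lone pair (no H, low connectivity)
  for (i in seq_len(n)) {
    deg <- if (is.null(adj[[i]])) 0L else nrow(adj[[i]])
    isacc <- el[i] == "O" ||
      (el[i] == "N" && length(expl_h[[i]]) == 0 && nh_imp[i] == 0L &&
         deg <= 2L)
    if (!isacc) next
    dir <- NULL
    nbrs <- adj[[i]]
    heavy_nbrs <- if (is.null(nbrs)) integer(0) else
      nbrs[el[nbrs[, 1]] != "H", 1]
    if (length(heavy_nbrs)) {
      v <- coordsm[i, ] - colMeans(coordsm[heavy_nbrs, , drop = FALSE])
      if (sqrt(sum(v^2)) > 1e-6) dir <- unit_vec(v)
    }
    pts <- add("acceptor", coordsm[i, ], dir, i)
  }

  ## hydrophobic groups: connected apolar heavy atoms outside aromatic rings
  apolar <- which(el %in% c("C", "S", "CL", "BR", "I") &
                    !(seq_len(n) %in% arom_ring_atoms))
  if (length(apolar) >= 2) {
    comp <- rep(0L, n); cid <- 0L
    for (seed in apolar) {
      if (comp[seed] != 0L) next
      cid <- cid + 1L
      queue <- seed; comp[seed] <- cid
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        nbrs <- adj[[cur]]
        if (is.null(nbrs)) next
        for (nx in nbrs[, 1])
          if (nx %in% apolar && comp[nx] == 0L) {
            comp[nx] <- cid; queue <- c(queue, nx)
          }
      }
    }
    for (g in seq_len(cid)) {
      grp <- which(comp == g)
      if (length(grp) < 2) next
      pts <- add("hydrophobic", colMeans(coordsm[grp, , drop = FALSE]),
                 NULL, grp)
    }
  }
  rownames(pts) <- NULL
  pts
}

#' Construct a ConformerSet
#'
#' @param mol a [Molecule-class].
#' @param conformerList list of N x 3 coordinate matrices.
#' @return A [ConformerSet-class]; typed feature points are derived for every
#'   conformer at construction.
#' @export
conformerSet <- function(mol, conformerList) {
  conformerList <- lapply(conformerList, function(x) {
    x <- as.matrix(x); dimnames(x) <- NULL; x
  })
  fp <- lapply(conformerList, function(co) extractLigandFeatures(mol, co))
  new("ConformerSet", molecule = mol, conformers = conformerList,
      featurePoints = fp)
}

## model-feature / ligand-point type compatibility
kind_compatible <- function(modelKind, pointKind) {
  switch(modelKind,
         hydrophobic = pointKind %in% c("hydrophobic", "aromatic"),
         aromatic = pointKind %in% c("aromatic", "hydrophobic"),
         donor = pointKind == "donor",
         acceptor = pointKind == "acceptor",
         FALSE)
}

#' Rigid-body fit of a conformer's feature points to a sub-model
#'
#' Exhaustively searches type-compatible injective correspondences between
#' the sub-model's features and the ligand's feature points, pruned by
#' pairwise-distance compatibility. Each complete correspondence is fit by
#' least-squares rigid superposition; it is accepted when every matched point
#' lies within its feature's tolerance radius, directional features agree
#' within `angTol` degrees, and no ligand heavy atom enters an exclusion
#' sphere. The score of an accepted fit is
#' `sum(exp(-d^2 / (2 * (r/2)^2)))` over matched pairs (d = residual center
#' distance, r = feature radius), so a perfect fit scores the matched count.
#'
#' @param points ligand feature points ([extractLigandFeatures()] output).
#' @param sub a [Pharmacophore-class] sub-model; all its features must be
#'   matched.
#' @param conformer optional N x 3 ligand coordinates for the exclusion-volume
#'   clash test (heavy atoms only).
#' @param elements optional element vector aligned with `conformer` rows
#'   (hydrogens are ignored in the clash test).
#' @param angTol angular tolerance for hydrogen-bond directions (degrees,
#'   default 45).
#' @return A list with `score`, `correspondence` (data.frame of `feature`,
#'   `point`), `rotation`, `translation`, `nMatched`, `clash` (always FALSE
#'   for returned fits) -- or `NULL` when no valid fit exists.
#' @export
fitConformer <- function(points, sub, conformer = NULL, elements = NULL,
                         angTol = 45) {
  f <- sub@features
  nf <- nrow(f)
  if (nf < 3L || nrow(points) < nf) return(NULL)   # rigid fit needs >= 3

  fc <- as.matrix(f[, c("x", "y", "z")])
  pc <- as.matrix(points[, c("x", "y", "z")])
  fd <- cross_dist(fc, fc)
  pd <- cross_dist(pc, pc)

  cand <- lapply(seq_len(nf), function(i)
    which(vapply(points$kind, kind_compatible, logical(1),
                 modelKind = f$kind[i])))
  if (any(lengths(cand) == 0)) return(NULL)
  ## assign scarcest features first
  ord <- order(lengths(cand))

  heavy_xyz <- NULL
  if (!is.null(conformer) && nrow(sub@exclusions) > 0) {
    keep <- if (is.null(elements)) rep(TRUE, nrow(conformer))
      else !(toupper(elements) %in% c("H", "D"))
    heavy_xyz <- conformer[keep, , drop = FALSE]
  }
  excl_ctr <- as.matrix(sub@exclusions[, c("x", "y", "z")])
  excl_r <- sub@exclusions$radius

  best <- NULL
  assign_ <- integer(nf)   # model feature index -> point index

  evaluate <- function() {
    mov <- pc[assign_, , drop = FALSE]
    fit <- superpose(fc, mov)
    moved <- applyTransform(mov, fit$rotation, fit$translation)
    d <- sqrt(rowSums((moved - fc)^2))
    if (any(d > f$radius)) return()
    ## directional agreement
    for (i in seq_len(nf)) {
      if (is.na(f$dx[i])) next
      p <- assign_[i]
      pdir <- c(points$dx[p], points$dy[p], points$dz[p])
      if (anyNA(pdir)) next
      ang <- vec_angle(as.numeric(fit$rotation %*% pdir),
                       c(f$dx[i], f$dy[i], f$dz[i]))
      if (!is.na(ang) && ang > angTol) return()
    }
    if (!is.null(heavy_xyz) && length(excl_r)) {
      hx <- applyTransform(heavy_xyz, fit$rotation, fit$translation)
      dmin <- cross_dist(hx, excl_ctr)
      if (any(sweep(dmin, 2L, excl_r, "<"))) return()   # clash: rejected
    }
    score <- sum(exp(-d^2 / (2 * (f$radius / 2)^2)))
    if (is.null(best) || score > best$score)
      best <<- list(score = score,
                    correspondence = data.frame(feature = seq_len(nf),
                                                point = assign_),
                    rotation = fit$rotation,
                    translation = fit$translation,
                    nMatched = nf, clash = FALSE)
  }

  dfs <- function(depth) {
    if (depth > nf) { evaluate(); return() }
    i <- ord[depth]
    for (p in cand[[i]]) {
      if (p %in% assign_[ord[seq_len(depth - 1L)]]) next
      ok <- TRUE
      for (dd in seq_len(depth - 1L)) {
        j <- ord[dd]
        if (abs(fd[i, j] - pd[p, assign_[j]]) > f$radius[i] + f$radius[j]) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_[i] <<- p
      dfs(depth + 1L)
      assign_[i] <<- 0L
    }
  }
  dfs(1L)
  best
}

#' Screen a conformer library against a pharmacophore model
#'
#' For every compound, fits each conformer to each enumerated sub-model and
#' keeps the best valid fit; compounds are ranked by score (descending, ties
#' broken by compound id).
#'
#' @param library list of [ConformerSet-class] objects.
#' @param model a [Pharmacophore-class].
#' @param minMatch minimum feature-subset size (default 5).
#' @param cap optional cap on enumerated sub-models.
#' @param angTol hydrogen-bond angular tolerance (degrees).
#' @return data.frame with one row per fitted compound: `id`, `score`,
#'   `submodel` (index into the enumerated list), `conformer`, `nMatched`.
#'   Compounds with no valid fit are absent.
#' @export
screenLibrary <- function(library, model, minMatch = 5L, cap = NULL,
                          angTol = 45) {
  if (length(library) == 0)
    return(data.frame(id = character(), score = numeric(),
                      submodel = integer(), conformer = integer(),
                      nMatched = integer()))
  subs <- enumerateSubmodels(model, minMatch = minMatch, cap = cap)
  rows <- list()
  for (cs in library) {
    best <- NULL
    for (ci in seq_along(cs@conformers)) {
      pts <- cs@featurePoints[[ci]]
      for (si in seq_along(subs)) {
        fit <- fitConformer(pts, subs[[si]], conformer = cs@conformers[[ci]],
                            elements = cs@molecule@atoms$element,
                            angTol = angTol)
        if (!is.null(fit) &&
            (is.null(best) || fit$score > best$score)) {
          best <- fit; best$submodel <- si; best$conformer <- ci
        }
      }
    }
    if (!is.null(best))
      rows[[length(rows) + 1L]] <-
        data.frame(id = cs@molecule@id, score = best$score,
                   submodel = best$submodel, conformer = best$conformer,
                   nMatched = best$nMatched)
  }
  if (!length(rows))
    return(data.frame(id = character(), score = numeric(),
                      submodel = integer(), conformer = integer(),
                      nMatched = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a pharmacophore model to JSON
#'
#' @param model a [Pharmacophore-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writePharmacophore <- function(model, file) {
  doc <- list(features = model@features, exclusions = model@exclusions,
              mandatory = model@mandatory, minMatch = model@minMatch)
  jsonlite::write_json(doc, file, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(file)
}

#' Read a pharmacophore model from JSON
#'
#' @param file path written by [writePharmacophore()].
#' @return A [Pharmacophore-class].
#' @export
readPharmacophore <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  feats <- as.data.frame(doc$features)
  if (nrow(feats) == 0) feats <- empty_features()
  for (col in c("dx", "dy", "dz"))
    if (!col %in% names(feats)) feats[[col]] <- NA_real_
  excl <- as.data.frame(doc$exclusions)
  if (nrow(excl) == 0)
    excl <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                       radius = numeric(), label = character())
  pharmacophore(feats, excl, as.integer(unlist(doc$mandatory)),
                minMatch = doc$minMatch)
}
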