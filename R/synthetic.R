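## Seeded generators emulating the pipeline's inputs: a loop-into-pocket
## dimer interface, screening libraries with planted binders, fast-exchange
## titration peak lists, and trajectories with planted pose stability.
## Every generator is a pure function of its SyntheticSpec.

atom_row <- function(serial, name, element, resname, chain, resno, xyz,
                     record = "ATOM") {
  data.frame(serial = as.integer(serial), name = name, altloc = "",
             resname = resname, chain = chain, resno = as.integer(resno),
             insert = "", x = xyz[1], y = xyz[2], z = xyz[3],
             occupancy = 1, bfactor = 0, element = element, record = record,
             stringsAsFactors = FALSE)
}

## receptor pocket: three apolar pseudo-residues around a cavity opening
## along +z, rimmed by a backbone carbonyl (acceptor) and an amide (donor)
toy_receptor_atoms <- function() {
  rows <- list(
    atom_row(1, "CA", "C", "LEU", "A", 1, c(4.8, 0, 0)),
    atom_row(2, "CB", "C", "LEU", "A", 1, c(3.2, 0, 0)),
    atom_row(3, "CG", "C", "LEU", "A", 1, c(3.2, 1.5, 0)),
    atom_row(4, "CA", "C", "LEU", "A", 2, c(-4.8, 0, 0)),
    atom_row(5, "CB", "C", "LEU", "A", 2, c(-3.2, 0, 0)),
    atom_row(6, "CG", "C", "LEU", "A", 2, c(-3.2, -1.5, 0)),
    atom_row(7, "CA", "C", "PHE", "A", 3, c(0, -4.8, 0)),
    atom_row(8, "CB", "C", "PHE", "A", 3, c(0, -3.2, 0)),
    atom_row(9, "CG", "C", "PHE", "A", 3, c(0, -3.2, 1.5)),
    ## rim carbonyl (receptor acceptor)
    atom_row(10, "CA", "C", "GLY", "A", 4, c(3.9, 3.0, 3.0)),
    atom_row(11, "C", "C", "GLY", "A", 4, c(3.1, 3.0, 3.3)),
    atom_row(12, "O", "O", "GLY", "A", 4, c(2.3, 3.0, 3.6)),
    ## rim amide (receptor donor), opposite quadrant
    atom_row(13, "N", "N", "THR", "A", 5, c(-2.9, -2.9, 3.0)),
    atom_row(14, "H", "H", "THR", "A", 5, c(-2.9, -2.9, 4.0)),
    atom_row(15, "CA", "C", "THR", "A", 5, c(-3.8, -2.9, 2.4)))
  do.call(rbind, rows)
}

#' Synthetic loop-into-pocket dimer interface
#'
#' Chain A is a small hydrophobic pocket rimmed by a backbone carbonyl and
#' an amide; chain B is a four-residue loop whose central apolar side chain
#' dips into the pocket, flanked by backbone/side-chain hydrogen-bond
#' partners to the rim. The geometry is fixed by construction; planted
#' contacts are recorded in the `truth` attribute.
#'
#' @param spec a [SyntheticSpec-class] (geometry is deterministic; the spec
#'   is carried for interface consistency).
#' @return A two-chain [PDBStructure-class] with a `truth` attribute listing
#'   the planted tip residue and hydrogen-bond partners.
#' @export
makeToyInterface <- function(spec = syntheticSpec()) {
  rec <- toy_receptor_atoms()
  ## chain B loop: backbone trace held away from the pocket (z >= 6.5)
  lig <- list(
    ## res 1: proline-like apolar contact
    atom_row(16, "N", "N", "PRO", "B", 1, c(2.0, -2.0, 7.0)),
    atom_row(17, "CA", "C", "PRO", "B", 1, c(2.0, -2.0, 5.6)),
    atom_row(18, "CB", "C", "PRO", "B", 1, c(2.0, -2.0, 4.2)),
    atom_row(19, "CG", "C", "PRO", "B", 1, c(2.5, -2.5, 3.3)),
    ## res 2: tip isoleucine dipping into the pocket
    atom_row(20, "N", "N", "ILE", "B", 2, c(0, 0, 7.2)),
    atom_row(21, "CA", "C", "ILE", "B", 2, c(0, 0, 5.9)),
    atom_row(22, "CB", "C", "ILE", "B", 2, c(0, 0, 3.2)),
    atom_row(23, "CG1", "C", "ILE", "B", 2, c(0, -0.8, 1.6)),
    ## res 3: serine with backbone amide and hydroxyl donors to the rim
    atom_row(24, "N", "N", "SER", "B", 3, c(2.3, 3.0, 6.5)),
    atom_row(25, "H", "H", "SER", "B", 3, c(2.3, 3.0, 5.5)),
    atom_row(26, "CA", "C", "SER", "B", 3, c(3.0, 3.9, 7.2)),
    atom_row(27, "OG", "O", "SER", "B", 3, c(0.6, 1.0, 5.8)),
    atom_row(28, "HG", "H", "SER", "B", 3, NA),   # placed below
    ## res 4: apolar side chain plus a backbone carbonyl accepting from the
    ## rim amide (pseudo-residue geometry: only distances matter)
    atom_row(29, "N", "N", "LYS", "B", 4, c(-2.0, 2.0, 7.6)),
    atom_row(30, "CA", "C", "LYS", "B", 4, c(-2.0, 2.0, 6.4)),
    atom_row(31, "C", "C", "LYS", "B", 4, c(-2.3, -2.3, 6.9)),
    atom_row(32, "O", "O", "LYS", "B", 4, c(-2.9, -2.9, 5.9)),
    atom_row(33, "CB", "C", "LYS", "B", 4, c(-2.0, 2.0, 4.2)),
    atom_row(34, "CG", "C", "LYS", "B", 4, c(-2.5, 2.5, 3.3)))
  lig <- do.call(rbind, lig)
  ## hydroxyl H 1.0 A from OG toward the rim carbonyl oxygen
  og <- c(0.6, 1.0, 5.8); rec_o <- c(2.3, 3.0, 3.6)
  hg <- og + unit_vec(rec_o - og) * 1.0
  lig[lig$name == "HG", c("x", "y", "z")] <- as.list(hg)

  s <- new("PDBStructure", atoms = rbind(rec, lig), modelId = 1L)
  attr(s, "truth") <- list(
    tipResidue = 2L, ligandChain = "B", receptorChain = "A",
    tipPocketDist = sqrt(sum((c(0, -0.8, 1.6) - c(0, -3.2, 0))^2)),
    hbonds = data.frame(
      donor = c("B:3:N", "B:3:OG", "A:5:N"),
      acceptor = c("A:4:O", "A:4:O", "B:4:O"),
      dist = c(2.9, sqrt(sum((og - rec_o)^2)), 2.9)))
  s
}

## place a two-carbon apolar group centered on `ctr`
place_hydrophobic <- function(ctr) {
  off <- c(0.75, 0, 0)
  list(elements = c("C", "C"), coords = rbind(ctr - off, ctr + off),
       bonds = cbind(1, 2, 1))
}

place_aromatic <- function(ctr, normal) {
  if (anyNA(normal)) normal <- c(0, 0, 1)
  b1 <- unit_vec(if (abs(normal[1]) < 0.9) pracma_cross(normal, c(1, 0, 0))
                 else pracma_cross(normal, c(0, 1, 0)))
  b2 <- pracma_cross(normal, b1)
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  coords <- t(vapply(ang, function(a)
    ctr + 1.39 * (cos(a) * b1 + sin(a) * b2), numeric(3)))
  bonds <- cbind(1:6, c(2:6, 1), 4)
  list(elements = rep("C", 6), coords = coords, bonds = bonds)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## assemble a planted binder whose typed feature points sit on the model's
## feature centers (jittered by at most min(jitter, radius/2))
build_binder <- function(model, id, jitter) {
  f <- model@features
  elements <- character(0); coordsm <- NULL
  bonds <- NULL; anchors <- integer(0)   # one connectable atom per group
  connectors <- character(0)
  for (k in seq_len(nrow(f))) {
    ctr <- as.numeric(f[k, c("x", "y", "z")])
    if (jitter > 0) {
      u <- stats::rnorm(3)
      ctr <- ctr + unit_vec(u) * stats::runif(1, 0, min(jitter, f$radius[k] / 2))
    }
    dir <- as.numeric(f[k, c("dx", "dy", "dz")])
    grp <- switch(f$kind[k],
      hydrophobic = place_hydrophobic(ctr),
      aromatic = place_aromatic(ctr, dir),
      donor = list(elements = c("N", "H"),
                   coords = rbind(ctr, ctr + (if (anyNA(dir)) c(0, 0, 1)
                                              else dir) * 1.0),
                   bonds = cbind(1, 2, 1)),
      acceptor = {
        nb <- ctr - (if (anyNA(dir)) c(0, 0, 1) else dir) * 1.4
        list(elements = c("O", "C"), coords = rbind(ctr, nb),
             bonds = cbind(1, 2, 2))
      })
    base <- length(elements)
    elements <- c(elements, grp$elements)
    coordsm <- rbind(coordsm, grp$coords)
    if (!is.null(grp$bonds))
      bonds <- rbind(bonds, cbind(grp$bonds[, 1] + base,
                                  grp$bonds[, 2] + base, grp$bonds[, 3]))
    ## connect through the carbonyl carbon for acceptors so the oxygen's
    ## lone-pair direction stays the planted one
    anchors <- c(anchors, base + (if (f$kind[k] == "acceptor") 2L else 1L))
    connectors <- c(connectors, f$kind[k])
  }
  ## link groups through polar bridge nitrogens so apolar groups stay
  ## disconnected from each other in the bond graph
  for (k in seq_len(length(anchors) - 1L)) {
    both_apolar <- connectors[k] %in% c("hydrophobic", "aromatic") &&
      connectors[k + 1L] %in% c("hydrophobic", "aromatic")
    if (both_apolar) {
      mid <- (coordsm[anchors[k], ] + coordsm[anchors[k + 1L], ]) / 2
      elements <- c(elements, "N")
      coordsm <- rbind(coordsm, mid + c(0, 0, 6))  # bridge away from features
      b <- length(elements)
      bonds <- rbind(bonds, cbind(anchors[k], b, 1),
                     cbind(b, anchors[k + 1L], 1))
    } else {
      bonds <- rbind(bonds, cbind(anchors[k], anchors[k + 1L], 1))
    }
  }
  m <- Molecule(id, elements, bonds)
  list(molecule = m, coords = unname(coordsm))
}

## random decoy lacking hydrogen-bond donors entirely
build_decoy <- function(id, natoms) {
  ## chain termini are carbons; interior oxygens are ethers (two bonds, no
  ## attached hydrogen), so the decoy offers no donor feature at all
  elements <- c("C", sample(c("C", "C", "C", "O"), natoms - 2, replace = TRUE),
                "C")
  bonds <- cbind(seq_len(natoms - 1), 2:natoms, 1)
  m <- Molecule(id, elements, bonds)
  conf <- function() matrix(stats::runif(natoms * 3, -5, 5), natoms, 3)
  list(molecule = m, confs = list(conf(), conf(), conf()))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c_ <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
           2 * (b * c_ + a * d), a^2 - b^2 + c_^2 - d^2, 2 * (c_ * d - a * b),
           2 * (b * d - a * c_), 2 * (c_ * d + a * b),
           a^2 - b^2 - c_^2 + d^2), 3, 3, byrow = TRUE)
}

#' Synthetic screening library with planted binders
#'
#' Binders are molecules whose typed feature points sit on the model's
#' feature centers (within a jitter of at most half the feature radius),
#' dressed with a consistent molecular graph; additional conformers are
#' rigid transforms of the planted pose. Decoys are random chain molecules
#' with no hydrogen-bond donor (they can never satisfy a mandatory core
#' containing a donor) and random coordinates.
#'
#' @param model the [Pharmacophore-class] to plant binders into.
#' @param nBinders,nDecoys compound counts.
#' @param spec a [SyntheticSpec-class]; `spec@jitter` controls binder
#'   coordinate jitter and `spec@seed` all randomness.
#' @return list of [ConformerSet-class] objects (binders first) with a
#'   `truth` attribute data.frame (`id`, `binder`).
#' @export
makeLigandLibrary <- function(model, nBinders = 1L, nDecoys = NULL,
                              spec = syntheticSpec()) {
  if (is.null(nDecoys)) nDecoys <- spec@nDecoys
  if (nBinders + nDecoys == 0) stop("empty library requested")
  if (nrow(model@features) == 0) stop("cannot plant binders in an empty model")
  with_seed(spec@seed, {
    out <- list()
    for (b in seq_len(nBinders)) {
      rec <- build_binder(model, sprintf("BND%02d", b), spec@jitter)
      confs <- list(rec$coords)
      for (extra in 1:2) {
        R <- random_rotation()
        confs <- c(confs, list(sweep(rec$coords %*% t(R), 2L,
                                     stats::runif(3, -3, 3), "+")))
      }
      out <- c(out, conformerSet(rec$molecule, confs))
    }
    for (d in seq_len(nDecoys)) {
      rec <- build_decoy(sprintf("DEC%02d", d), sample(6:10, 1))
      out <- c(out, conformerSet(rec$molecule, rec$confs))
    }
    attr(out, "truth") <- data.frame(
      id = vapply(out, molId, character(1)),
      binder = rep(c(TRUE, FALSE), c(nBinders, nDecoys)))
    out
  })
}

#' Synthetic fast-exchange titration peak lists
#'
#' Site residues shift along the 1:1 binding isotherm (planted Kd, ddMax)
#' with the combined perturbation split 1:2 between the 1H and 15N
#' dimensions; off-site residues feel only a small baseline wobble. Gaussian
#' noise of sd `spec@cspNoise * spec@ddMax` is added to the planted combined
#' perturbation.
#'
#' @param spec a [SyntheticSpec-class].
#' @param site residue numbers of the binding site (default: 8 residues).
#' @param ddMaxMap optional named vector of per-residue saturation
#'   perturbations (ppm); default `spec@ddMax` for every site residue.
#' @param baselineNoise sd of the off-site peak wobble (ppm, default 0.002).
#' @return list with `apo` (peak list), `holo` (list of peak lists, one per
#'   concentration), `concentrations`, `Ptotal`, `site`, and `truth`
#'   (planted parameters).
#' @export
makeTitrationPeaks <- function(spec = syntheticSpec(),
                               site = c(20:23, 40:43),
                               ddMaxMap = NULL, baselineNoise = 0.002) {
  n <- spec@nResidues
  stopifnot(all(site >= 1 & site <= n))
  if (is.null(ddMaxMap))
    ddMaxMap <- setNames(rep(spec@ddMax, length(site)), site)
  split_h <- 1 / sqrt((1 + 0.14 * 4) / 2)   # combined -> 1H with dN = 2 dH
  with_seed(spec@seed, {
    resno <- seq_len(n)
    apo <- peakList(paste0("A", resno),
                    dH = stats::runif(n, 6.5, 9.5),
                    dN = stats::runif(n, 105, 130), condition = "apo")
    holo <- lapply(seq_along(spec@concentrations), function(ci) {
      L <- spec@concentrations[ci]
      dH <- apo$dH; dN <- apo$dN
      for (r in resno) {
        if (r %in% site) {
          dd <- ddMaxMap[[as.character(r)]] *
            bound_fraction(L, spec@Ptotal, spec@Kd)
          dd <- max(0, dd + stats::rnorm(1, 0, spec@cspNoise * spec@ddMax))
          dH[r] <- dH[r] + dd * split_h
          dN[r] <- dN[r] + dd * split_h * 2
        } else {
          dH[r] <- dH[r] + stats::rnorm(1, 0, baselineNoise)
          dN[r] <- dN[r] + stats::rnorm(1, 0, baselineNoise * 2)
        }
      }
      peakList(paste0("A", resno), dH, dN,
               condition = sprintf("ligand %.3g mM", L * 1e3))
    })
    list(apo = apo, holo = holo, concentrations = spec@concentrations,
         Ptotal = spec@Ptotal, site = site,
         truth = list(Kd = spec@Kd, ddMaxMap = ddMaxMap))
  })
}

#' Synthetic protein-ligand complex for trajectory generation
#'
#' The toy receptor pocket with a small ligand bound: two apolar carbons in
#' the cavity (the deeper one, C1, is the planted closest contact) and a
#' hydroxyl donating a hydrogen bond to the rim carbonyl.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A [PDBStructure-class] with ligand residue "LIG" on chain "L".
#' @export
makeToyComplex <- function(spec = syntheticSpec()) {
  rec <- toy_receptor_atoms()
  o1 <- c(2.3, 3.0, 6.6); rec_o <- c(2.3, 3.0, 3.6)
  h1 <- o1 + unit_vec(rec_o - o1) * 1.0
  lig <- rbind(
    atom_row(16, "C1", "C", "LIG", "L", 1, c(0, -0.8, 1.6), "HETATM"),
    atom_row(17, "C2", "C", "LIG", "L", 1, c(0, 0, 3.2), "HETATM"),
    atom_row(18, "C3", "C", "LIG", "L", 1, c(0.8, 0.3, 4.4), "HETATM"),
    atom_row(19, "O1", "O", "LIG", "L", 1, o1, "HETATM"),
    atom_row(20, "H1", "H", "LIG", "L", 1, h1, "HETATM"))
  s <- new("PDBStructure", atoms = rbind(rec, lig), modelId = 1L)
  attr(s, "truth") <- list(
    deepestContact = c(residue = "A:3:PHE", atom = "C1"),
    hbond = data.frame(donor = "O1", hydrogen = "H1", acceptor = "A:4:O"))
  s
}

#' Synthetic trajectory with a planted pose-stability mode
#'
#' "stable": the ligand jitters (sd 0.5 A) about its pose. "semi": two-state
#' hopping between the pose and a displaced pose (`spec@displacement`), with
#' the bound state occupying `spec@contactOccupancy` of frames. "unstable":
#' the ligand leaves the pocket early and wanders. The protein always gets
#' small jitter (sd 0.1 A).
#'
#' @param complex a [PDBStructure-class] with a ligand residue (e.g. from
#'   [makeToyComplex()]).
#' @param mode "stable", "semi" or "unstable".
#' @param nFrames frame count (default `spec@nFrames`).
#' @param spec a [SyntheticSpec-class].
#' @param ligand ligand residue name.
#' @return A [FrameSeries-class] with a `truth` attribute recording the
#'   planted mode, displacement and bound-state flags per frame.
#' @export
makeTrajectory <- function(complex, mode = c("stable", "semi", "unstable"),
                           nFrames = NULL, spec = syntheticSpec(),
                           ligand = "LIG") {
  mode <- match.arg(mode)
  if (is.null(nFrames)) nFrames <- spec@nFrames
  a <- complex@atoms
  li <- which(a$resname == ligand)
  if (!length(li)) stop("complex has no ligand residue ", ligand)
  base <- coords(complex)
  out_dir <- unit_vec(c(1, 0, 1))   # pocket exit direction
  with_seed(spec@seed, {
    bound <- switch(mode,
      stable = rep(TRUE, nFrames),
      semi = c(TRUE, stats::runif(nFrames - 1) < spec@contactOccupancy),
      unstable = c(TRUE, rep(FALSE, nFrames - 1)))
    frames <- vector("list", nFrames)
    drift <- c(0, 0, 0)
    for (k in seq_len(nFrames)) {
      fr <- base + matrix(stats::rnorm(nrow(base) * 3, 0, 0.1), ncol = 3)
      ## rigid-body ligand jitter (uniform in a 0.3 A sphere) keeps the
      ## planted internal geometry, and hence planted contacts and hydrogen
      ## bonds, intact in bound frames
      jit <- stats::rnorm(3)
      jit <- unit_vec(jit) * stats::runif(1, 0, 0.3)
      ligco <- sweep(base[li, , drop = FALSE], 2L, jit, "+")
      if (mode == "unstable" && k > 1) {
        drift <- drift + stats::rnorm(3, 0, 0.5)
        shift <- spec@displacement * min(1, (k - 1) / (0.08 * nFrames))
        ligco <- sweep(ligco, 2L, shift * out_dir + drift, "+")
      } else if (!bound[k]) {
        ligco <- sweep(ligco, 2L, spec@displacement * out_dir, "+")
      }
      fr[li, ] <- ligco
      frames[[k]] <- fr
    }
    fs <- frameSeries(complex, frames, ligand = ligand)
    attr(fs, "truth") <- list(mode = mode, bound = bound,
                              displacement = spec@displacement)
    fs
  })
}
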