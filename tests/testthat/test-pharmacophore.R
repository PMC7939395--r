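test_that("deriveModel maps planted interface contacts to typed features", {
  s <- mini_interface()
  m <- deriveModel(s, "L", "R")
  f <- features(m)
  expect_equal(sum(f$kind == "hydrophobic"), 1L)
  expect_equal(sum(f$kind == "donor"), 1L)
  expect_equal(nrow(f), 2L)
  ## donor direction within 15 degrees of the planted N->O vector
  don <- f[f$kind == "donor", ]
  ang <- acos(sum(c(don$dx, don$dy, don$dz) * c(0, 0, -1))) * 180 / pi
  expect_lt(ang, 15)
  ## exclusion spheres line the receptor
  expect_gt(nrow(exclusions(m)), 0L)
})

test_that("deriveModel returns an empty model when the ligand is far away", {
  s <- mini_interface()
  lsel <- s@atoms$chain == "L"
  s@atoms$z[lsel] <- s@atoms$z[lsel] + 20
  expect_warning(m <- deriveModel(s, "L", "R"), "empty")
  expect_equal(nrow(features(m)), 0L)
  expect_error(deriveModel(s, "X", "R"), "empty ligand or receptor")
})

test_that("features closer than the minimum feature distance merge", {
  s <- mini_interface()
  ## second apolar ligand side chain 1.0 A from the first
  extra <- cartwheel:::atom_row(7, "CB", "C", "ALA", "L", 2, c(1, 0, 3.5))
  s2 <- new("PDBStructure", atoms = rbind(s@atoms, extra), modelId = 1L)
  m <- deriveModel(s2, "L", "R", minFeatureDistance = 1.5)
  expect_equal(sum(features(m)$kind == "hydrophobic"), 1L)
  m2 <- deriveModel(s2, "L", "R", minFeatureDistance = 0.5)
  expect_equal(sum(features(m2)$kind == "hydrophobic"), 2L)
})

test_that("sub-model enumeration matches the combinatorial count", {
  mk_model <- function(nf, mand) {
    set.seed(41)
    ctr <- matrix(runif(nf * 3, -20, 20), nf, 3)  # far apart: no merging
    feats <- data.frame(kind = rep(c("hydrophobic", "donor"),
                                   length.out = nf),
                        x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                        radius = 1.5, dx = NA_real_, dy = NA_real_,
                        dz = NA_real_, label = "")
    pharmacophore(feats, mandatory = mand, minMatch = 5L)
  }
  m10 <- mk_model(10L, 1:3)
  subs <- enumerateSubmodels(m10, 5L)
  expect_length(subs, 120L)   # sum over k of choose(7, k), k = 2..7
  brute <- sum(vapply(2:7, function(k) choose(7, k), numeric(1)))
  expect_equal(length(subs), as.integer(brute))
  ## every sub-model contains the mandatory core; order is by size
  sizes <- vapply(subs, function(s) nrow(features(s)), integer(1))
  expect_true(all(diff(sizes) >= 0))
  for (s in subs[c(1, 60, 120)])
    expect_true(all(1:3 %in% attr(s, "indices")))

  ## a second configuration against brute force
  m8 <- mk_model(8L, c(2L, 5L))
  expect_length(enumerateSubmodels(m8, 5L),
                as.integer(sum(choose(6, 3:6))))

  expect_length(enumerateSubmodels(m10, 10L), 1L)
  expect_error(enumerateSubmodels(m10, 11L), "exceeds feature count")
  expect_length(enumerateSubmodels(m10, 5L, cap = 7L), 7L)
})

test_that("ligand feature typing follows the published rules", {
  benz <- benzene_conformer()
  pts <- extractLigandFeatures(benz$molecule, benz$coords)
  expect_equal(nrow(pts[pts$kind == "aromatic", ]), 1L)
  expect_equal(as.numeric(pts[pts$kind == "aromatic", c("x", "y", "z")]),
               c(0, 0, 0), tolerance = 1e-8)

  eth <- ethanol_conformer()
  pts <- extractLigandFeatures(eth$molecule, eth$coords)
  don <- pts[pts$kind == "donor", ]
  acc <- pts[pts$kind == "acceptor", ]
  expect_equal(nrow(don), 1L)
  expect_equal(nrow(acc), 1L)
  expect_equal(as.numeric(don[, c("x", "y", "z")]), eth$coords[3, ])
  expect_equal(as.numeric(acc[, c("x", "y", "z")]), eth$coords[3, ])

  ## sulfonyl + aromatic + hydroxyl fragment: ring, two sulfonyl-oxygen
  ## acceptors, one hydroxyl donor
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  co <- rbind(ring,
              c(2.9, 0, 0),        # S
              c(3.5, 1.2, 0.4),    # O (sulfonyl)
              c(3.5, -1.2, -0.4),  # O (sulfonyl)
              c(3.6, 0, 1.4),      # C
              c(4.9, 0.4, 1.8),    # O (hydroxyl)
              c(5.5, 0.4, 1.0))    # H
  m <- Molecule("a11like", c(rep("C", 6), "S", "O", "O", "C", "O", "H"),
                rbind(cbind(1:6, c(2:6, 1), c(1, 2, 1, 2, 1, 2)),
                      c(1, 7, 1), c(7, 8, 2), c(7, 9, 2), c(7, 10, 1),
                      c(10, 11, 1), c(11, 12, 1)))
  pts <- extractLigandFeatures(m, co)
  expect_gte(sum(pts$kind == "aromatic"), 1L)
  expect_gte(sum(pts$kind == "acceptor"), 2L)
  expect_gte(sum(pts$kind == "donor"), 1L)

  expect_error(extractLigandFeatures(m, NULL), "missing")
})

test_that("a perfect placement scores the matched count without clash", {
  s <- makeToyInterface()
  model <- deriveModel(s, "B", "A")
  model@mandatory <- defaultMandatoryCore(model)
  sub <- enumerateSubmodels(model, 5L)[[1]]
  f <- features(sub)
  pts <- data.frame(kind = f$kind, x = f$x, y = f$y, z = f$z,
                    dx = f$dx, dy = f$dy, dz = f$dz, atoms = "")
  fit <- fitConformer(pts, sub)
  expect_equal(fit$score, nrow(f), tolerance = 1e-8)
  expect_false(fit$clash)
  expect_equal(fit$nMatched, nrow(f))
})

test_that("a ligand without donor points cannot satisfy a donor feature", {
  s <- makeToyInterface()
  model <- deriveModel(s, "B", "A")
  model@mandatory <- defaultMandatoryCore(model)
  sub <- enumerateSubmodels(model, 5L)[[1]]
  f <- features(sub)
  pts <- data.frame(kind = ifelse(f$kind == "donor", "hydrophobic", f$kind),
                    x = f$x, y = f$y, z = f$z,
                    dx = NA_real_, dy = NA_real_, dz = NA_real_, atoms = "")
  expect_null(fitConformer(pts, sub))
})

test_that("fitConformer equals the exhaustive correspondence oracle", {
  set.seed(101)
  for (case in 1:25) {
    nf <- sample(3:5, 1)
    np <- sample(nf:8, 1)
    rc <- random_fit_case(nf, np)
    fit <- fitConformer(rc$points, rc$sub)
    oracle <- oracle_fit_score(rc$points, rc$sub)
    if (is.null(oracle)) {
      expect_null(fit)
    } else {
      expect_false(is.null(fit))
      expect_equal(fit$score, oracle, tolerance = 1e-6)
    }
  }
})

test_that("fit score is invariant under rigid transforms of the conformer", {
  s <- makeToyInterface()
  model <- deriveModel(s, "B", "A")
  model@mandatory <- defaultMandatoryCore(model)
  lib <- makeLigandLibrary(model, 1L, 0L, syntheticSpec(seed = 5))
  cs <- lib[[1]]
  sub <- enumerateSubmodels(model, 5L)[[1]]
  base <- fitConformer(cs@featurePoints[[1]], sub,
                       conformer = cs@conformers[[1]],
                       elements = molecule(cs)@atoms$element)
  set.seed(6)
  for (i in 1:4) {
    rt <- random_rigid()
    co <- applyTransform(cs@conformers[[1]], rt$R, rt$t)
    pts <- extractLigandFeatures(molecule(cs), co)
    fit <- fitConformer(pts, sub, conformer = co,
                        elements = molecule(cs)@atoms$element)
    expect_equal(fit$score, base$score, tolerance = 1e-6)
  }
})

test_that("score decreases strictly as a matched residual grows", {
  feats <- data.frame(kind = rep("hydrophobic", 3),
                      x = c(0, 4, 0), y = c(0, 0, 4), z = 0,
                      radius = 1.5, dx = NA_real_, dy = NA_real_,
                      dz = NA_real_, label = "")
  sub <- pharmacophore(feats, mandatory = integer(0), minMatch = 3L)
  mk_pts <- function(off) {
    data.frame(kind = "hydrophobic", x = c(0 + off, 4, 0),
               y = c(0, 0, 4), z = 0, dx = NA_real_, dy = NA_real_,
               dz = NA_real_, atoms = "")
  }
  scores <- vapply(c(0, 0.3, 0.6, 0.9),
                   function(o) fitConformer(mk_pts(o), sub)$score,
                   numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("screening ranks a planted binder first and handles edge cases", {
  s <- makeToyInterface()
  model <- deriveModel(s, "B", "A")
  model@mandatory <- defaultMandatoryCore(model)

  lib <- makeLigandLibrary(model, 1L, 20L, syntheticSpec(seed = 9))
  hits <- screenLibrary(lib, model, minMatch = 5L)
  truth <- attr(lib, "truth")
  expect_equal(hits$id[1], truth$id[truth$binder][1])
  expect_true(all(hits$nMatched >= 5L))

  expect_equal(nrow(screenLibrary(list(), model)), 0L)

  ## single perfect-match compound is rank 1 with maximal score
  one <- makeLigandLibrary(model, 1L, 0L, syntheticSpec(seed = 2, jitter = 0))
  h1 <- screenLibrary(one, model, minMatch = 5L)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$score, h1$nMatched, tolerance = 1e-6)
})

test_that("pharmacophore JSON serialization round-trips", {
  s <- makeToyInterface()
  model <- deriveModel(s, "B", "A")
  model@mandatory <- defaultMandatoryCore(model)
  f <- withr::local_tempfile(fileext = ".json")
  writePharmacophore(model, f)
  back <- readPharmacophore(f)
  expect_equal(features(back), features(model), tolerance = 1e-12)
  expect_equal(exclusions(back)$radius, exclusions(model)$radius)
  expect_equal(mandatoryCore(back), mandatoryCore(model))
})
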