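## deterministic frame builder: ligand shifted by `off` in chosen frames
shifted_frames <- function(cx, offsets) {
  li <- which(atoms(cx)$resname == "LIG")
  base <- coords(cx)
  frames <- lapply(offsets, function(off) {
    fr <- base
    fr[li, ] <- sweep(fr[li, , drop = FALSE], 2L, off, "+")
    fr
  })
  frameSeries(cx, frames, ligand = "LIG")
}

test_that("ligand RMSD is zero for identical frames and exact for shifts", {
  cx <- makeToyComplex()
  fs <- shifted_frames(cx, list(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)))
  expect_equal(ligandRMSDSeries(fs), c(0, 0, 0), tolerance = 1e-10)

  ## rigid 3 A ligand translation after protein superposition
  fs2 <- shifted_frames(cx, list(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(ligandRMSDSeries(fs2), c(0, 3), tolerance = 1e-8)
})

test_that("ligand RMSD series is invariant to whole-frame rigid motion", {
  cx <- makeToyComplex()
  fs <- makeTrajectory(cx, "semi", nFrames = 20L,
                       spec = syntheticSpec(seed = 13))
  base <- ligandRMSDSeries(fs)
  set.seed(14)
  moved <- fs
  for (k in seq_len(nFrames(fs))) {
    rt <- random_rigid()
    moved@coords[, , k] <- applyTransform(fs@coords[, , k], rt$R, rt$t)
  }
  expect_equal(ligandRMSDSeries(moved), base, tolerance = 1e-6)
})

test_that("two-state trajectories show the planted displacement", {
  cx <- makeToyComplex()
  spec <- syntheticSpec(seed = 15)
  fs <- makeTrajectory(cx, "semi", spec = spec)
  r <- ligandRMSDSeries(fs)
  bound <- attr(fs, "truth")$bound
  expect_lt(mean(r[bound]), 1)
  expect_equal(mean(r[!bound]), spec@displacement, tolerance = 0.15)
})

test_that("contact maps count and normalize occupancies exactly", {
  cx <- makeToyComplex()
  ## single frame with one in-range pair at a tight cutoff
  fs1 <- shifted_frames(cx, list(c(0, 0, 0)))
  cm1 <- contactMap(fs1, cutoff = 2.95)  # only the closest pair is in range
  d1 <- contactDensity(cm1)
  expect_equal(sum(d1 == 1), 1L)
  expect_equal(unname(d1["A:3:PHE", "C1"]), 1)

  ## 50 percent vs 100 percent planted occupancy
  offs <- c(rep(list(c(0, 0, 0)), 50),
            rep(list(c(0, 2.05, 0)), 50))   # C1-PHE stays, C1-LEU drops out
  fs <- shifted_frames(cx, offs)
  cm <- contactMap(fs, cutoff = 4.0)
  d <- contactDensity(cm)
  expect_equal(max(d), 1)
  expect_true(any(abs(d - 0.5) < 1e-12))

  ## zero cutoff: all-zero map with empty-contact status
  cm0 <- contactMap(fs1, cutoff = 0)
  expect_true(all(contactDensity(cm0) == 0))
  expect_equal(attr(contactDensity(cm0), "status"), "no contacts")

  ## frame order invariance
  cmr <- contactMap(frameSeries(cx, rev(lapply(seq_len(nFrames(fs)),
                                               function(k) fs@coords[, , k])),
                                ligand = "LIG"), cutoff = 4.0)
  expect_equal(contactDensity(cmr), d, ignore_attr = FALSE)
})

test_that("hydrogen-bond occupancy applies distance and angle criteria", {
  cx <- makeToyComplex()
  bond <- data.frame(donor = "O1", hydrogen = "H1", acceptor = "A:4:O")
  ## ideal planted geometry in every frame
  fs <- shifted_frames(cx, rep(list(c(0, 0, 0)), 10))
  expect_equal(hbondOccupancy(fs, bond), 1.0)
  ## acceptor beyond the cutoff in every frame
  fs2 <- shifted_frames(cx, rep(list(c(0, 0, 5)), 10))
  expect_equal(hbondOccupancy(fs2, bond), 0.0)
  expect_error(hbondOccupancy(fs, data.frame(donor = "OZ", hydrogen = "H1",
                                             acceptor = "A:4:O")),
               "unknown atom")

  ## monotone non-decreasing in the distance cutoff
  fs3 <- makeTrajectory(cx, "semi", nFrames = 60L,
                        spec = syntheticSpec(seed = 16))
  occ <- vapply(c(2.5, 3.0, 3.5, 4.5, 8),
                function(ct) hbondOccupancy(fs3, bond, distCutoff = ct),
                numeric(1))
  expect_true(all(diff(occ) >= 0))
})

test_that("planted hydrogen-bond occupancy is recovered", {
  cx <- makeToyComplex()
  spec <- syntheticSpec(seed = 17, contactOccupancy = 0.7)
  fs <- makeTrajectory(cx, "semi", spec = spec)
  bond <- attr(cx, "truth")$hbond
  occ <- hbondOccupancy(fs, bond)
  planted <- mean(attr(fs, "truth")$bound)
  expect_equal(occ, planted, tolerance = 0.02)
  expect_equal(planted, 0.7, tolerance = 0.1)   # binomial noise only
})

test_that("pose stability classifies against the stated boundaries", {
  expect_equal(poseStability(rep(0, 50)), "stable")
  expect_equal(poseStability(rep(5, 50)), "unstable")
  ## 60 percent below threshold: between fraction/2 and fraction
  series <- c(rep(0.5, 60), rep(4, 40))
  expect_equal(poseStability(series), "semi-stable")
  ## boundary checks
  expect_equal(poseStability(c(rep(1, 80), rep(3, 20))), "stable")
  expect_equal(poseStability(c(rep(1, 39), rep(3, 61))), "unstable")
  expect_error(poseStability(numeric(0)), "empty")
})
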