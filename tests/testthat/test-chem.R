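test_that("molecular properties match hand-computed values", {
  w <- computeProperties(mol_water())
  expect_equal(w$mw, 18.02, tolerance = 0.01)
  expect_equal(w$hbd, 1L)
  expect_equal(w$aromaticRings, 0L)

  b <- computeProperties(mol_benzene())
  expect_equal(b$hbd, 0L)
  expect_equal(b$aromaticRings, 1L)

  p <- computeProperties(mol_phenol())
  expect_equal(p$mw, 94.11, tolerance = 0.01)
  expect_equal(p$hbd, 1L)
  expect_equal(p$aromaticRings, 1L)

  expect_error(computeProperties(Molecule("x", "XX")), "unknown element")
})

test_that("library filter keeps exactly the molecules inside all bounds", {
  ## six molecules with planted properties; only #2 and #5 pass every bound
  ## (mw 300-500, hbd >= 1, aromatic >= 1)
  big_arm <- function(id, extraC, nOH) {
    ## phenol core grown with a saturated chain and hydroxyls
    n6 <- 6L
    els <- c(rep("C", n6), rep("C", extraC), rep("O", nOH))
    ring <- cbind(1:6, c(2:6, 1), c(1, 2, 1, 2, 1, 2))
    chain <- if (extraC > 0)
      cbind(c(6, n6 + seq_len(extraC - 1)), n6 + seq_len(extraC), 1)
    else NULL
    ohs <- if (nOH > 0)
      cbind(rep(n6 + extraC, nOH), n6 + extraC + seq_len(nOH), 1)
    else NULL
    Molecule(id, els, rbind(ring, chain, ohs))
  }
  mols <- list(
    mol_benzene(),                 # 78 Da, no donor: fails every bound
    big_arm("m2", 18, 2),          # ~350 Da, donors, aromatic: passes
    big_arm("m3", 2, 1),           # ~130 Da: too light
    mol_cyclohexane(),             # no aromatic ring, no donor
    big_arm("m5", 22, 3),          # ~420 Da: passes
    big_arm("m6", 40, 2))          # > 500 Da: too heavy
  props <- lapply(mols, computeProperties)
  manual <- vapply(props, function(p)
    p$mw >= 300 && p$mw <= 500 && p$hbd >= 1 && p$aromaticRings >= 1,
    logical(1))
  expect_equal(which(manual), c(2L, 5L))

  kept <- filterLibrary(mols)
  expect_equal(vapply(kept, molId, character(1)), c("m2", "m5"))

  ## rejected exemplar, empty input, idempotence, bad bounds
  expect_length(filterLibrary(list(mol_benzene())), 0L)
  expect_length(filterLibrary(list()), 0L)
  again <- filterLibrary(kept)
  expect_equal(vapply(again, molId, character(1)),
               vapply(kept, molId, character(1)))
  expect_error(filterLibrary(mols, mwMin = 500, mwMax = 300), "mwMin")
})

test_that("fingerprints are deterministic and separate distinct graphs", {
  f1 <- fingerprint(mol_benzene())
  f2 <- fingerprint(mol_benzene())
  expect_identical(f1, f2)
  expect_false(setequal(f1$bits, fingerprint(mol_cyclohexane())$bits))
  expect_gt(length(fingerprint(Molecule("c1", "C"))$bits), 0L)
  expect_true(all(f1$bits < f1$nbits))
})

test_that("tanimoto follows set arithmetic and its invariants", {
  fp <- function(bits) list(bits = bits, nbits = 2048L)
  expect_equal(tanimoto(fp(c(1, 5, 9)), fp(c(1, 5, 9))), 1)
  expect_equal(tanimoto(fp(1:3), fp(4:6)), 0)
  expect_equal(tanimoto(fp(1:3), fp(2:4)), 0.5)
  expect_equal(tanimoto(fp(integer(0)), fp(integer(0))), 1)
  expect_error(tanimoto(fp(1), list(bits = 1, nbits = 1024L)), "mismatch")

  set.seed(31)
  for (i in 1:10) {
    a <- fp(sample(0:2047, 40)); b <- fp(sample(0:2047, 40))
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_gte(tanimoto(a, b), 0); expect_lte(tanimoto(a, b), 1)
  }
})

test_that("greedy diversity picking reproduces the hand-simulated walk", {
  ## all-identical: only the top-ranked survives
  same <- lapply(1:4, function(i) {
    m <- mol_phenol(); m@id <- paste0("p", i); m
  })
  expect_equal(vapply(diversityPick(same, 0.6), molId, character(1)), "p1")

  ## threshold 1.0 with no exact duplicates keeps everything
  varied <- list(mol_benzene(), mol_phenol(), mol_cyclohexane(),
                 mol_water())
  expect_length(diversityPick(varied, 1.0), 4L)

  ## five-molecule case against the oracle walk
  five <- list(mol_phenol(), mol_benzene(), mol_phenol(),
               mol_cyclohexane(), mol_benzene())
  for (i in seq_along(five)) five[[i]]@id <- paste0("m", i)
  fps <- lapply(five, fingerprint)
  sim <- outer(seq_along(five), seq_along(five),
               Vectorize(function(i, j) tanimoto(fps[[i]], fps[[j]])))
  picked <- diversityPick(five, 0.6)
  expect_equal(attr(picked, "kept"), oracle_greedy_pick(sim, 0.6))

  ## kept set is pairwise-dissimilar and contains the leader
  kept <- attr(picked, "kept")
  expect_true(1L %in% kept)
  for (i in kept) for (j in kept)
    if (i != j) expect_lt(sim[i, j], 0.6)
})

test_that("SD files round-trip molecules and conformer grouping", {
  eth <- ethanol_conformer()
  cs <- conformerSet(eth$molecule, list(eth$coords, eth$coords + 1))
  benz <- benzene_conformer()
  cs2 <- conformerSet(benz$molecule, list(benz$coords))
  f <- withr::local_tempfile(fileext = ".sdf")
  writeSDFLibrary(list(cs, cs2), f)
  back <- readSDFLibrary(f)
  expect_length(back, 2L)
  expect_equal(molId(back[[1]]), "ethanol")
  expect_length(conformers(back[[1]]), 2L)
  expect_equal(molecule(back[[2]])@bonds$order, rep(4L, 6))
  expect_equal(conformers(back[[1]])[[2]], eth$coords + 1,
               tolerance = 1e-4, ignore_attr = TRUE)
})
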