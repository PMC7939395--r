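test_that("combined CSP reproduces the weighting equation", {
  expect_equal(combinedCSP(0, 0), 0)
  expect_equal(combinedCSP(0.1, 0), 0.07071, tolerance = 1e-4)
  expect_equal(combinedCSP(0, 1.0), 0.26458, tolerance = 1e-4)
  expect_error(combinedCSP(NA, 0), "finite")

  ## sign symmetry, non-negativity, pure-1H limit
  set.seed(21)
  dH <- rnorm(50); dN <- rnorm(50)
  expect_equal(combinedCSP(dH, dN), combinedCSP(-dH, -dN))
  expect_true(all(combinedCSP(dH, dN) >= 0))
  expect_equal(combinedCSP(dH, 0), abs(dH) / sqrt(2))
})

test_that("CSP profiles flag exactly the planted residue", {
  set.seed(22)
  n <- 50L
  apo <- peakList(paste0("A", 1:n), runif(n, 6.5, 9.5), runif(n, 105, 130),
                  condition = "apo")
  holo <- apo
  holo$dH <- holo$dH + rnorm(n, 0, 0.005 / sqrt(0.5))  # combined sd 0.005
  holo$dH[17] <- apo$dH[17] + 0.1
  p <- cspProfile(apo, holo)
  expect_equal(notableResidues(p), 17L)

  ## identical lists: all zero, nothing notable
  p0 <- cspProfile(apo, apo)
  expect_true(all(cspData(p0)$delta == 0))
  expect_length(notableResidues(p0), 0L)

  ## tiny uniform noise: everything below 2*sigmaExp even above 2*sigma
  tiny <- apo
  tiny$dH <- tiny$dH + runif(n, -0.004, 0.004)
  pt <- cspProfile(apo, tiny, sigmaExp = 0.01)
  expect_true(max(cspData(pt)$delta) > 2 * pt@sigma ||
                sd(cspData(pt)$delta) > 0)  # sanity on the construction
  expect_length(notableResidues(pt), 0L)

  expect_error(cspProfile(apo, peakList("B99", 8, 110)), "shared")
})

test_that("the notable set shrinks as sigmaExp grows", {
  set.seed(23)
  n <- 40L
  apo <- peakList(paste0("A", 1:n), runif(n, 6.5, 9.5), runif(n, 105, 130))
  holo <- apo
  holo$dH <- holo$dH + c(rep(0.002, n - 4), 0.02, 0.04, 0.08, 0.15)
  prev <- NULL
  for (se in c(0.002, 0.01, 0.03, 0.08)) {
    cur <- notableResidues(cspProfile(apo, holo, sigmaExp = se))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("titration fitting recovers planted parameters", {
  ## noise-free: near-exact identifiability
  spec0 <- syntheticSpec(seed = 3, cspNoise = 0)
  tp <- makeTitrationPeaks(spec0)
  ts <- titrationSeries(tp$apo, tp$holo, tp$concentrations, tp$Ptotal)
  fit <- fitTitration(ts, residues = tp$site)
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$Kd - spec0@Kd) / spec0@Kd, 0.01)
  expect_lt(max(abs(fit$ddMax - spec0@ddMax)) / spec0@ddMax, 0.01)

  ## 2 percent noise: within 25 percent
  spec <- syntheticSpec(seed = 3)
  tp <- makeTitrationPeaks(spec)
  ts <- titrationSeries(tp$apo, tp$holo, tp$concentrations, tp$Ptotal)
  fit <- fitTitration(ts, residues = tp$site)
  expect_lt(abs(fit$Kd - spec@Kd) / spec@Kd, 0.25)

  ## clearly unsaturated titration: flag is FALSE
  specu <- syntheticSpec(seed = 4, Kd = 2e-2, cspNoise = 0)
  tpu <- makeTitrationPeaks(specu)
  tsu <- titrationSeries(tpu$apo, tpu$holo, tpu$concentrations, tpu$Ptotal)
  fitu <- fitTitration(tsu, residues = tpu$site)
  expect_false(fitu$saturated)

  ## all-zero series: no-binding status
  flat <- new("TitrationSeries", concentrations = c(1e-4, 2e-4, 4e-4),
              Ptotal = 1e-4,
              delta = matrix(0, 2, 3, dimnames = list(c("1", "2"), NULL)))
  expect_equal(fitTitration(flat)$status, "no binding detected")
})

test_that("the binding equation halves at L = Kd in the dilute limit", {
  ## P << Kd, L = Kd: bound fraction 1/2, so delta = ddMax / 2; a fit to
  ## exact points reproduces the closed-form limit
  P <- 1e-7; Kd <- 1e-3; ddMax <- 0.2
  L <- c(0.25, 0.5, 1, 2, 4) * Kd
  delta <- matrix(ddMax * cartwheel:::bound_fraction(L, P, Kd), 1,
                  dimnames = list("7", NULL))
  ts <- new("TitrationSeries", concentrations = L, Ptotal = P, delta = delta)
  fit <- fitTitration(ts)
  pred_at_kd <- unname(fit$ddMax[1]) * cartwheel:::bound_fraction(Kd, P, fit$Kd)
  expect_equal(pred_at_kd, ddMax / 2, tolerance = 1e-3)
})

test_that("saturation limit of the generator reaches ddMax", {
  spec <- syntheticSpec(seed = 5, cspNoise = 0,
                        concentrations = c(1e-3, 1e-2, 2))  # up to 1000 Kd
  tp <- makeTitrationPeaks(spec)
  p <- cspProfile(tp$apo, tp$holo[[3]])
  d <- cspData(p)
  site_delta <- d$delta[d$resno %in% tp$site]
  expect_equal(site_delta, rep(spec@ddMax, length(tp$site)),
               tolerance = 2e-3)
})

test_that("structure mapping reports fractions and enrichment correctly", {
  ## synthetic chain of 100 CA residues on a line, site = first 20; notable
  ## residues planted 8 inside / 2 outside the site neighborhood
  mk <- cartwheel:::atom_row
  a <- do.call(rbind, lapply(1:100, function(i)
    mk(i, "CA", "C", "ALA", "A", i, c(10 * i, 0, 0))))
  s <- new("PDBStructure", atoms = a, modelId = 1L)
  site <- 1:20
  apo <- peakList(paste0("A", 1:100), rep(8, 100), rep(115, 100))
  holo <- apo
  planted <- c(2, 4, 6, 8, 10, 12, 14, 16, 60, 80)
  holo$dH[planted] <- holo$dH[planted] + 0.3
  p <- cspProfile(apo, holo)
  expect_setequal(notableResidues(p), planted)
  res <- mapToStructure(p, s, site, siteRadius = 8)
  expect_equal(res$fraction, 0.8)
  expect_equal(res$pvalue, oracle_hyper_tail(8, 20, 100, 10),
               tolerance = 1e-12)

  ## notable set fully inside the site
  holo2 <- apo
  holo2$dH[site[1:5]] <- holo2$dH[site[1:5]] + 0.3
  res2 <- mapToStructure(cspProfile(apo, holo2), s, site)
  expect_equal(res2$fraction, 1.0)
  expect_equal(res2$classification, "site")

  ## empty notable set: no-binding classification
  res3 <- mapToStructure(cspProfile(apo, apo), s, site)
  expect_equal(res3$classification, "no binding")
  expect_true(is.na(res3$fraction))

  ## chain without any profile residue
  expect_error(mapToStructure(p, s, site, chain = "Z"), "no profile")
})

test_that("CSP B-factor annotation survives the PDB round-trip", {
  s <- makeToyInterface()
  apo <- peakList(paste0("A", 1:5), rep(8, 5), rep(115, 5))
  holo <- apo; holo$dH[2] <- holo$dH[2] + 0.12
  p <- cspProfile(apo, holo)
  res <- mapToStructure(p, s, site = 2L, siteRadius = 8, chain = "A")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(res$structure, f)
  back <- readStructure(f)
  b <- atoms(back)
  d <- cspData(p)
  for (r in 1:5) {
    expect_equal(unique(b$bfactor[b$chain == "A" & b$resno == r]),
                 round(d$delta[d$resno == r], 2), tolerance = 1e-9)
  }
})

test_that("hetNOE comparison flags only real changes", {
  a <- data.frame(resno = 1:30, noe = rep(0.8, 30), sigma = 0.03)
  expect_equal(compareHetNOE(a, a)$verdict, "no significant change")

  b <- a; b$noe[12] <- a$noe[12] + 10 * sqrt(2) * 0.03
  cmp <- compareHetNOE(a, b)
  expect_equal(cmp$verdict, "changed")
  expect_equal(cmp$table$resno[cmp$table$flagged], 12L)

  expect_error(compareHetNOE(a, data.frame(resno = 99, noe = 1, sigma = 1)),
               "shared")

  ## calibration: identical means with noise matching the stated 0.03
  ## uncertainty. Per residue the 3-sigma rule trips with p ~ 0.0027, so a
  ## 12-residue profile stays "no change" in ~97 percent of draws.
  set.seed(27)
  verdicts <- vapply(1:200, function(i) {
    x <- data.frame(resno = 1:12, noe = 0.8 + rnorm(12, 0, 0.03),
                    sigma = 0.03)
    y <- data.frame(resno = 1:12, noe = 0.8 + rnorm(12, 0, 0.03),
                    sigma = 0.03)
    compareHetNOE(x, y)$verdict
  }, character(1))
  expect_gte(mean(verdicts == "no significant change"), 0.95)
})

test_that("Sparky-style peak lists read and write cleanly", {
  pl <- peakList(c("A5", "LYS6", "7"), c(8.1234, 7.5, 9.01),
                 c(115.2, 120.77, 108.3), condition = "apo")
  expect_equal(pl$resno, 5:7)
  f <- withr::local_tempfile(fileext = ".list")
  writePeakList(pl, f)
  back <- readPeakList(f, "apo")
  expect_equal(back$resno, pl$resno)
  expect_equal(back$dH, pl$dH, tolerance = 1e-4)
  expect_equal(back$dN, pl$dN, tolerance = 1e-3)
  expect_error(peakList("XYZ", 8, 115), "residue number")
})
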