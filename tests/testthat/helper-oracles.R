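## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: the superposition oracle is a grid search over
## rotations, the fitting oracle enumerates correspondences without pruning
## and uses bio3d for the rigid transform, and the enrichment oracle is a
## brute-force hypergeometric tail sum.

## grid search over ZYZ Euler angles: a full coarse grid, then independent
## local refinement around each of the best coarse candidates (the Euler
## parameterization has degenerate valleys, so refining a single candidate
## can stall in a local minimum)
oracle_superpose_rmsd <- function(ref, mov, coarse_deg = 10) {
  cref <- colMeans(ref); cmov <- colMeans(mov)
  P <- sweep(mov, 2L, cmov); Q <- sweep(ref, 2L, cref)
  rmsd_at <- function(a, b, g) {
    R <- cartwheel:::euler_rotation(a, b, g)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  step0 <- coarse_deg * pi / 180
  grid <- expand.grid(a = seq(0, 2 * pi, by = step0),
                      b = seq(0, pi, by = step0),
                      g = seq(0, 2 * pi, by = step0))
  r0 <- vapply(seq_len(nrow(grid)), function(i)
    rmsd_at(grid$a[i], grid$b[i], grid$g[i]), numeric(1))
  cands <- grid[order(r0)[1:20], , drop = FALSE]
  best <- min(r0)
  for (ci in seq_len(nrow(cands))) {
    ctr <- as.numeric(cands[ci, ])
    step <- step0 / 3
    for (lvl in 1:5) {
      local <- expand.grid(a = ctr[1] + step * (-3:3),
                           b = pmin(pi, pmax(0, ctr[2] + step * (-3:3))),
                           g = ctr[3] + step * (-3:3))
      rl <- vapply(seq_len(nrow(local)), function(i)
        rmsd_at(local$a[i], local$b[i], local$g[i]), numeric(1))
      ctr <- as.numeric(local[which.min(rl), ])
      best <- min(best, min(rl))
      step <- step / 3
    }
  }
  best
}

## exhaustive correspondence search; transform via bio3d, no pruning
oracle_fit_score <- function(points, sub) {
  f <- sub@features
  nf <- nrow(f)
  compat <- lapply(seq_len(nf), function(i) {
    which(vapply(points$kind, function(pk) {
      switch(f$kind[i],
             hydrophobic = pk %in% c("hydrophobic", "aromatic"),
             aromatic = pk %in% c("aromatic", "hydrophobic"),
             donor = pk == "donor",
             acceptor = pk == "acceptor")
    }, logical(1)))
  })
  fc <- as.matrix(f[, c("x", "y", "z")])
  pc <- as.matrix(points[, c("x", "y", "z")])
  best <- -Inf
  rec <- function(depth, used) {
    if (depth > nf) {
      mov <- pc[used, , drop = FALSE]
      fitted <- suppressWarnings(
        bio3d::fit.xyz(fixed = as.vector(t(fc)),
                       mobile = as.vector(t(mov))))
      moved <- matrix(fitted, ncol = 3, byrow = TRUE)
      d <- sqrt(rowSums((moved - fc)^2))
      if (all(d <= f$radius)) {
        sc <- sum(exp(-d^2 / (2 * (f$radius / 2)^2)))
        if (sc > best) best <<- sc
      }
      return()
    }
    for (p in compat[[depth]]) {
      if (p %in% used) next
      rec(depth + 1L, c(used, p))
    }
  }
  rec(1L, integer(0))
  if (is.finite(best)) best else NULL
}

## brute-force upper-tail hypergeometric probability P(X >= k)
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## hand simulation of the greedy diversity walk on a similarity matrix
oracle_greedy_pick <- function(sim, threshold) {
  kept <- integer(0)
  for (i in seq_len(nrow(sim))) {
    if (all(sim[i, kept] < threshold)) kept <- c(kept, i)
  }
  kept
}

## random typed feature points/pharmacophores for the fit-equivalence check
random_fit_case <- function(nf, np) {
  kinds <- c("hydrophobic", "aromatic", "donor", "acceptor")
  fk <- sample(kinds, nf, replace = TRUE)
  fc <- matrix(runif(nf * 3, -4, 4), nf, 3)
  feats <- data.frame(kind = fk, x = fc[, 1], y = fc[, 2], z = fc[, 3],
                      radius = runif(nf, 0.8, 1.6),
                      dx = NA_real_, dy = NA_real_, dz = NA_real_,
                      label = "")
  sub <- pharmacophore(feats, mandatory = integer(0), minMatch = nf)
  ## half the points echo the model geometry (rotated), half are noise
  R <- cartwheel:::euler_rotation(runif(1, 0, 2 * pi), runif(1, 0, pi),
                                  runif(1, 0, 2 * pi))
  echo <- sweep(fc %*% t(R), 2L, runif(3, -3, 3), "+") +
    matrix(rnorm(nf * 3, 0, 0.3), nf, 3)
  extra <- matrix(runif((np - nf) * 3, -5, 5), np - nf, 3)
  pts_xyz <- rbind(echo, extra)
  pk <- c(fk, sample(kinds, np - nf, replace = TRUE))
  points <- data.frame(kind = pk, x = pts_xyz[, 1], y = pts_xyz[, 2],
                       z = pts_xyz[, 3], dx = NA_real_, dy = NA_real_,
                       dz = NA_real_, atoms = "")
  list(points = points, sub = sub)
}
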