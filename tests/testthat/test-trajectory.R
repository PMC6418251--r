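refComplex <- makeToyComplex(30, 30)

test_that("rmsdSeries is zero for frames equal to the reference and under rigid motions", {
  m <- refComplex$model
  mask <- caMask(m, c("A", "B"), 0)
  traj <- newTrajectory(m, list(coords(m), coords(m), coords(m)), dt = 1)
  rs <- rmsdSeries(traj, mask, m)
  expect_equal(rs$rmsd_A, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(rs$time_ns, c(0, 1, 2))
  # per-frame random rigid motions are removed by the fit
  set.seed(21)
  frames <- lapply(1:5, function(i)
    sweep(coords(m) %*% randomRotation(), 2, rnorm(3, 0, 5)))
  suppressWarnings(traj2 <- newTrajectory(m, frames, dt = 1))
  expect_lt(max(rmsdSeries(traj2, mask, m)$rmsd_A), 1e-9)
})

test_that("mean RMSD under isotropic Gaussian noise approaches sigma * sqrt(3)", {
  m <- refComplex$model
  mask <- caMask(m, c("A", "B"), 0)
  sigma <- 0.5
  nA <- nAtoms(m)
  set.seed(22)
  frames <- lapply(1:1000, function(i)
    coords(m) + matrix(rnorm(nA * 3, 0, sigma), nA, 3))
  traj <- newTrajectory(m, frames, dt = 0.01)
  meanRmsd <- mean(rmsdSeries(traj, mask, m)$rmsd_A)
  expect_equal(meanRmsd, sigma * sqrt(3), tolerance = 0.05)
})

test_that("L-RMSD is invariant to whole-complex motion and exact under partner translation", {
  m <- refComplex$model
  agMask <- caMask(m, "A", 0)
  abMask <- caMask(m, "B", 0)
  set.seed(23)
  frames <- lapply(1:5, function(i)
    sweep(coords(m) %*% randomRotation(), 2, rnorm(3, 0, 10)))
  suppressWarnings(traj <- newTrajectory(m, frames, dt = 1))
  expect_lt(max(lrmsdSeries(traj, agMask, abMask, m)$series$lrmsd_A), 1e-9)

  # antigen fixed, antibody translated by (3,0,0): L-RMSD exactly 3
  x <- coords(m)
  rowsB <- which(atomTable(m)$chainId == "B")
  x2 <- x; x2[rowsB, 1] <- x2[rowsB, 1] + 3
  traj2 <- newTrajectory(m, list(x2), dt = 1)
  lr <- lrmsdSeries(traj2, agMask, abMask, m)
  expect_equal(lr$series$lrmsd_A, 3.0, tolerance = 1e-9)
  expect_error(lrmsdSeries(traj2, agMask, c(agMask[1], abMask), m),
               "disjoint")
})

test_that("L-RMSD increases on a drifting (dissociating) trajectory", {
  m <- refComplex$model
  st <- makeSyntheticTrajectory(m, nFrames = 101, dt = 1, jitterSd = 0.05,
                                driftChain = "B", driftRate = 0.1, seed = 31)
  agMask <- caMask(m, "A", 5)
  abMask <- caMask(m, "B", 5)
  lr <- lrmsdSeries(st$trajectory, agMask, abMask, m)
  v <- lr$series$lrmsd_A
  burn <- lr$series$time_ns >= 20
  fit <- lm(v[burn] ~ lr$series$time_ns[burn])
  expect_gt(coef(fit)[2], 0.09)            # drift rate recovered
  expect_equal(v[101], 10, tolerance = 0.1) # final offset ~ rate * t
})

test_that("distanceSeries reproduces constructed distances and the crystal value", {
  toy <- makeToyComplex(4, 4, list(list(basic = "LYS", acidic = "ASP",
                                        distance = 4.0)))
  m <- toy$model
  cd <- contactDefinition("K1-D1", "A:1", "NZ", "B:1", "CG", 4.0)
  # static trajectory equals the crystal distance in every frame
  traj <- newTrajectory(m, list(coords(m), coords(m)), dt = 1)
  expect_equal(distanceSeries(traj, cd)$distance_A, c(4, 4), tolerance = 1e-12)
  # oscillation 4 + sin(t) planted along the contact axis
  a <- atomTable(m)
  iNZ <- which(a$name == "NZ"); iCG <- which(a$name == "CG")
  t <- seq(0, 6, by = 0.1)
  x <- coords(m)
  u <- (x[iCG, ] - x[iNZ, ]) / 4
  frames <- lapply(t, function(tt) {
    xf <- x; xf[iCG, ] <- x[iNZ, ] + (4 + sin(tt)) * u; xf
  })
  traj2 <- newTrajectory(m, frames, times = t)
  expect_equal(distanceSeries(traj2, cd)$distance_A, 4 + sin(t),
               tolerance = 1e-9)
  # per-frame agreement with the single-model geometry
  perFrame <- vapply(seq_along(t), function(f)
    representativeDistance(
      new("StructureModel", atoms = a, coords = frames[[f]],
          modelIndex = 1L), "A:1", "B:1"), numeric(1))
  expect_equal(distanceSeries(traj2, cd)$distance_A, perFrame,
               tolerance = 1e-12)
})

test_that("contact occupancy counts post-burn-in frames at or below threshold", {
  s <- data.frame(time_ns = c(30, 50, 70, 90), distance_A = c(3, 5, 3, 5))
  expect_equal(contactOccupancy(s, threshold = 4, burnIn = 20), 0.5)
  expect_equal(contactOccupancy(s, threshold = 6, burnIn = 20), 1.0)
  expect_error(contactOccupancy(s, threshold = 4, burnIn = 200),
               "no frames remain")
  # exact fraction for a planted exceedance pattern
  set.seed(24)
  inside <- sample(c(rep(TRUE, 763), rep(FALSE, 237)))
  s2 <- data.frame(time_ns = seq_len(1000), distance_A = ifelse(inside, 3, 5))
  expect_identical(contactOccupancy(s2, 4, 0), 0.763)
  # invariant to frame order after burn-in; monotone in threshold
  s3 <- s2[sample(nrow(s2)), ]
  expect_identical(contactOccupancy(s3, 4, 0), 0.763)
  o <- vapply(c(2, 3, 4, 5, 6), function(th) contactOccupancy(s2, th, 0),
              numeric(1))
  expect_false(is.unsorted(o))
})

test_that("planted occupancies are recovered within the binomial bound", {
  toy <- makeToyComplex(4, 4, list(list(basic = "LYS", acidic = "ASP",
                                        distance = 3.6)))
  cd <- contactDefinition("K1-D1", "A:1", "NZ", "B:1", "CG", 3.6)
  nFrames <- 1000
  for (p in c(0.1, 0.5, 0.9)) {
    hits <- 0L
    for (seed in 1:20) {
      st <- makeSyntheticTrajectory(toy$model, nFrames = nFrames, dt = 0.1,
        jitterSd = 0.1, contactTargets = list(list(contact = cd,
                                                   occupancy = p)),
        seed = seed)
      occ <- contactOccupancy(distanceSeries(st$trajectory, cd), 3.6, 0)
      # occupancy equals the planted Bernoulli schedule exactly
      expect_identical(occ, mean(st$groundTruth$schedules[["K1-D1"]]))
      if (abs(occ - p) <= 3 * sqrt(p * (1 - p) / nFrames)) hits <- hits + 1L
    }
    expect_gte(hits / 20, 0.95)
  }
})

test_that("replica summary gives mean, sample sd and standard error", {
  s <- replicaSummary(c(0.5, 0.5, 0.5))
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 0)
  # the three wild-type R84-E27 run occupancies: frozen hand computation
  s2 <- replicaSummary(c(0.773, 0.833, 0.267))
  expect_equal(s2$mean, 0.6243333, tolerance = 1e-6)
  expect_equal(s2$sd, 0.3109105, tolerance = 1e-6)
  expect_equal(s2$se, 0.3109105 / sqrt(3), tolerance = 1e-6)
  # permutation invariance
  s3 <- replicaSummary(c(0.267, 0.773, 0.833))
  expect_equal(s3$mean, s2$mean)
  expect_equal(s3$sd, s2$sd)
  # single replica flags undefined spread instead of silent zero
  s4 <- replicaSummary(0.7)
  expect_false(s4$spreadDefined)
  expect_true(is.na(s4$sd))
})

test_that("unwrapped-looking trajectories trigger the jump warning", {
  m <- refComplex$model
  x <- coords(m)
  x2 <- x; x2[1, 1] <- x2[1, 1] + 50
  expect_warning(newTrajectory(m, list(x, x2), dt = 1), "re-imaged")
})
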