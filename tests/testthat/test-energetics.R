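test_that("Coulomb term matches its closed form and sign conventions", {
  expect_equal(coulombEnergy(0, 1, 2.5), 0)
  expect_equal(coulombEnergy(1, -1, 3.0), -1389.35458 / 3, tolerance = 1e-9)
  set.seed(41)
  r <- runif(20, 0.5, 15)
  expect_true(all(coulombEnergy(1, 1, r) > 0))
  expect_true(all(coulombEnergy(-1, -1, r) > 0))
  expect_true(all(coulombEnergy(1, -1, r) < 0))
  # dielectric scales inversely
  expect_equal(coulombEnergy(1, -1, 3, dielectric = 2),
               coulombEnergy(1, -1, 3) / 2)
  expect_error(coulombEnergy(1, 1, 0), "singular")
})

test_that("Lennard-Jones node, minimum and a hand-evaluated point", {
  expect_equal(ljEnergy(3.5, 0.5, 3.5), 0, tolerance = 1e-12)
  expect_equal(ljEnergy(3.5, 0.5, 2^(1 / 6) * 3.5), -0.5, tolerance = 1e-12)
  # 4*0.5*(2^-12 - 2^-6) at r = 2 sigma
  expect_equal(ljEnergy(3.5, 0.5, 7.0), -0.030761719, tolerance = 1e-8)
  expect_error(ljEnergy(3.5, 0.5, 0), "singular")
  lb <- combineLorentzBerthelot(3.0, 4.0, 0.25, 1.0)
  expect_equal(lb$sigma, 3.5)
  expect_equal(lb$epsilon, 0.5)
})

test_that("residue interaction energy matches a brute-force pairwise oracle", {
  toy <- makeToyComplex(5, 5, list(list(basic = "LYS", acidic = "ASP",
                                        distance = 3.0)))
  m <- toy$model
  a <- atomTable(m)
  set.seed(42)
  params <- uniformParams(m)
  params$charge_e <- round(runif(nrow(params), -0.8, 0.8), 3)
  params$sigma_A <- round(runif(nrow(params), 2.5, 4.0), 3)
  params$epsilon_kJmol <- round(runif(nrow(params), 0.05, 1.0), 3)
  frames <- lapply(1:5, function(i)
    coords(m) + matrix(rnorm(nAtoms(m) * 3, 0, 0.2), nAtoms(m), 3))
  traj <- newTrajectory(m, frames, dt = 1)
  cutoff <- 1e4                       # exceeds the system diameter
  en <- residueInteractionEnergy(traj, params, "A:1", "B", cutoff = cutoff)
  # independent O(n^2) double loop, no cutoff
  ri <- which(a$chainId == "A" & a$resSeq == 1)
  pj <- which(a$chainId == "B")
  key <- paste(a$chainId, a$resSeq, a$name, sep = "|")
  pk <- paste(params$chain, params$res_seq, params$atom, sep = "|")
  q <- params$charge_e[match(key, pk)]
  sg <- params$sigma_A[match(key, pk)]
  ep <- params$epsilon_kJmol[match(key, pk)]
  tot <- 0
  for (f in 1:5) {
    x <- frames[[f]]
    for (i in ri) for (j in pj) {
      r <- sqrt(sum((x[i, ] - x[j, ])^2))
      sij <- (sg[i] + sg[j]) / 2
      eij <- sqrt(ep[i] * ep[j])
      tot <- tot + 1389.35458 * q[i] * q[j] / r +
        4 * eij * ((sij / r)^12 - (sij / r)^6)
    }
  }
  expect_equal(en$total, tot / 5, tolerance = 1e-9)
  expect_equal(en$total, en$coulomb + en$lj, tolerance = 1e-9)
})

test_that("zero parameters, cutoff exclusion and unparameterized atoms behave", {
  toy <- makeToyComplex(4, 4, list(list(basic = "LYS", acidic = "ASP",
                                        distance = 3.0)))
  m <- toy$model
  traj <- newTrajectory(m, list(coords(m)), dt = 1)
  p0 <- uniformParams(m, charge = 0, eps = 0)
  en0 <- residueInteractionEnergy(traj, p0, "A:1", "B")
  expect_equal(en0$total, 0)
  # partner moved far beyond cutoff + sigma: exactly zero by truncation
  x <- coords(m)
  rowsB <- which(atomTable(m)$chainId == "B")
  x[rowsB, 1] <- x[rowsB, 1] + 500
  trajFar <- newTrajectory(new("StructureModel", atoms = atomTable(m),
                               coords = x, modelIndex = 1L), list(x), dt = 1)
  enFar <- residueInteractionEnergy(trajFar, uniformParams(m), "A:1", "B",
                                    cutoff = 12)
  expect_identical(enFar$total, 0)
  pMiss <- uniformParams(m)[-3, ]
  expect_error(residueInteractionEnergy(traj, pMiss, "A:1", "B"),
               "unparameterized")
  expect_error(residueInteractionEnergy(traj, uniformParams(m), "A:1", "A"),
               "own chain")
})

test_that("pair energies are symmetric and Coulomb is quadratic in charge", {
  set.seed(43)
  # one residue per chain makes residue-vs-chain equal residue-vs-residue
  toy2 <- makeToyComplex(1, 1, list(list(basic = "ARG", acidic = "GLU",
                                         distance = 4.0)))
  tr2 <- newTrajectory(toy2$model, list(coords(toy2$model)), dt = 1)
  p2 <- uniformParams(toy2$model)
  p2$charge_e <- runif(nrow(p2), -0.5, 0.5)
  e12 <- residueInteractionEnergy(tr2, p2, "A:1", "B", cutoff = 1e4)
  e21 <- residueInteractionEnergy(tr2, p2, "B:1", "A", cutoff = 1e4)
  expect_equal(e12$total, e21$total, tolerance = 1e-9)
  # doubling all charges quadruples Coulomb, leaves LJ unchanged
  p4 <- p2; p4$charge_e <- 2 * p4$charge_e
  e4 <- residueInteractionEnergy(tr2, p4, "A:1", "B", cutoff = 1e4)
  expect_equal(e4$coulomb, 4 * e12$coulomb, tolerance = 1e-9)
  expect_equal(e4$lj, e12$lj, tolerance = 1e-12)
})

test_that("a planted salt bridge dominates a neutral control residue energetically", {
  hits <- 0L
  for (seed in 1:20) {
    toy <- makeToyComplex(5, 5, list(list(basic = "LYS", acidic = "ASP",
                                          distance = 3.0)))
    m <- toy$model
    params <- uniformParams(m, charge = 0)
    chg <- function(ch, rs, at, q)
      params$charge_e[params$chain == ch & params$res_seq == rs &
                      params$atom == at] <<- q
    chg("A", 1, "NZ", 1); chg("B", 1, "OD1", -0.5); chg("B", 1, "OD2", -0.5)
    st <- makeSyntheticTrajectory(m, nFrames = 50, dt = 1, jitterSd = 0.15,
                                  seed = seed)
    en <- residueInteractionEnergy(st$trajectory, params,
                                   list("A:1", "A:2"), "B", cutoff = 12)
    if (abs(en$total[1]) > abs(en$total[2])) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})

test_that("replica aggregation reports mean and standard error over runs", {
  toy <- makeToyComplex(4, 4, list(list(basic = "LYS", acidic = "ASP",
                                        distance = 3.2)))
  m <- toy$model
  params <- uniformParams(m)
  trajs <- lapply(1:3, function(s)
    makeSyntheticTrajectory(m, nFrames = 20, dt = 1, jitterSd = 0.1,
                            seed = s)$trajectory)
  en <- residueInteractionEnergy(trajs, params, "A:1", "B", burnIn = 5)
  expect_equal(en$n_replicas, 3L)
  reps <- attr(en, "replicas")[["A:1"]]
  expect_length(reps, 3)
  expect_equal(en$total, mean(reps), tolerance = 1e-12)
  expect_equal(en$se, sd(reps) / sqrt(3), tolerance = 1e-12)
})

test_that("kJ/mol to kcal/mol conversion uses the thermochemical calorie", {
  expect_equal(kJToKcal(4.184), 1)
})
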