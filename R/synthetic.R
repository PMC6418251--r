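# Seeded generators producing every input the analysis stages consume, with
# exact machine-readable ground truth. Toy complexes use idealized side-chain
# geometry (group atoms + a minimal backbone), which keeps PDB writing simple
# but is deliberately non-physical.

# idealized side-chain templates: atom offsets relative to CA, Angstrom.
# Internal charged-group geometry is correct (C-O 1.25 A, C-N 1.33 A,
# carboxylate angle ~123 deg, planar guanidine); overall side-chain shape is
# a straight idealization.
.residueTemplate <- function(resName) {
  bb <- rbind(N = c(-1.46, 0, 0), CA = c(0, 0, 0), C = c(1.52, 0, 0))
  side <- switch(resName,
    GLY = NULL,
    ALA = rbind(CB = c(0, 0, 1.53)),
    LYS = rbind(NZ = c(0, 0, 5.9)),
    ARG = rbind(CZ = c(0, 0, 5.9), NE = c(1.15, 0, 5.235),
                NH1 = c(0, 0, 7.23), NH2 = c(-1.15, 0, 5.235)),
    ASP = rbind(CG = c(0, 0, 2.4), OD1 = c(0, 1.10, 3.00),
                OD2 = c(0, -1.10, 3.00)),
    GLU = rbind(CD = c(0, 0, 3.8), OE1 = c(0, 1.10, 4.40),
                OE2 = c(0, -1.10, 4.40)),
    .stopf("no idealized template for residue type '%s'", resName))
  rbind(bb, side)
}

# element symbol from an idealized atom name
.elementOf <- function(name) substr(gsub("[0-9]", "", name), 1, 1)

# assemble a StructureModel from a list of residue descriptors:
# list(chain, resSeq, resName, atoms = named 3-col matrix of positions)
.buildModel <- function(resList) {
  rows <- list()
  serial <- 0L
  for (r in resList) {
    nm <- rownames(r$atoms)
    for (k in seq_along(nm)) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = nm[k], altLoc = "", resName = r$resName,
        chainId = r$chain, resSeq = r$resSeq, iCode = "",
        element = .elementOf(nm[k]), occupancy = 1,
        x = r$atoms[k, 1], y = r$atoms[k, 2], z = r$atoms[k, 3],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  new("StructureModel",
      atoms = df[, c("serial", "name", "altLoc", "resName", "chainId",
                     "resSeq", "iCode", "element", "occupancy")],
      coords = as.matrix(df[, c("x", "y", "z")]), modelIndex = 1L)
}

# residue descriptor with template placed at CA position, optional flip
# (template +z inverted) so side chains can point toward each other
.placeResidue <- function(chain, resSeq, resName, caPos, flip = FALSE) {
  tpl <- .residueTemplate(resName)
  if (flip) tpl[, 3] <- -tpl[, 3]
  atoms <- sweep(tpl, 2, -caPos)
  list(chain = chain, resSeq = resSeq, resName = resName, atoms = atoms)
}

#' Generate a two-chain toy complex with planted salt bridges
#'
#' Builds an idealized two-chain model in which each planted (basic, acidic)
#' pair has exactly the requested representative-atom distance; all other
#' charged pairs are at least 8 A apart. Chain A holds the basic partner of
#' every planted pair, chain B the acidic partner; remaining residues are
#' neutral glycines, plus optional far-apart charged decoys.
#'
#' @param nResA,nResB residue counts per chain (each >= number of planted
#'   pairs)
#' @param plantedPairs list of \code{list(basic, acidic, distance)} with
#'   basic in \{"LYS","ARG"\}, acidic in \{"ASP","GLU"\}, distance in
#'   Angstrom (> 1)
#' @param decoys number of additional well-separated charged residues per
#'   chain
#' @param chainA,chainB chain identifiers
#' @return list with \code{model} (a \linkS4class{StructureModel}) and
#'   \code{planted} (data.frame of pair identities and distances)
#' @export
makeToyComplex <- function(nResA = 10, nResB = 10, plantedPairs = list(),
                           decoys = 0, chainA = "A", chainB = "B") {
  m <- length(plantedPairs)
  if (nResA < m || nResB < m)
    .stopf("chain lengths must be >= number of planted pairs (%d)", m)
  res <- list()
  planted <- list()
  for (j in seq_len(m)) {
    p <- plantedPairs[[j]]
    if (p$distance <= 1) .stopf("planted distance must exceed 1 A")
    basic <- .residueTemplate(p$basic); acidic <- .residueTemplate(p$acidic)
    repB <- chargedGroups()[[p$basic]]$rep
    repA <- chargedGroups()[[p$acidic]]$rep
    zb <- basic[repB, 3]; za <- acidic[repA, 3]
    caB <- c(40 * j, 0, 0)
    # flipped acidic template: rep atom sits at CA - (0,0,za)
    caA <- caB + c(0, 0, zb) + c(p$distance, 0, za)
    res[[length(res) + 1L]] <- .placeResidue(chainA, j, p$basic, caB)
    res[[length(res) + 1L]] <- .placeResidue(chainB, j, p$acidic, caA,
                                             flip = TRUE)
    planted[[j]] <- data.frame(
      label = sprintf("%s%d-%s%d", .aa1[[p$basic]], j, .aa1[[p$acidic]], j),
      chain_a = chainA, res_a = j, atom_a = repB,
      chain_b = chainB, res_b = j, atom_b = repA,
      distance_A = p$distance, stringsAsFactors = FALSE)
  }
  # neutral fillers on separate lanes, ~10 A spacing; a gentle helical wobble
  # keeps each chain's CA trace non-collinear (superposition needs rank 2)
  for (k in seq_len(nResA - m))
    res[[length(res) + 1L]] <- .placeResidue(chainA, m + k, "GLY",
      c(10 * k, 30 + 3 * sin(0.8 * k), 2 * cos(0.8 * k)))
  for (k in seq_len(nResB - m))
    res[[length(res) + 1L]] <- .placeResidue(chainB, m + k, "GLY",
      c(10 * k, -30 - 3 * sin(0.8 * k), 2 * cos(0.8 * k)))
  # decoy charged residues, all mutual distances >= 8 A by 12 A spacing
  for (k in seq_len(decoys)) {
    res[[length(res) + 1L]] <- .placeResidue(
      chainA, nResA + k, if (k %% 2) "LYS" else "ASP", c(12 * k, 60, 0))
    res[[length(res) + 1L]] <- .placeResidue(
      chainB, nResB + k, if (k %% 2) "GLU" else "ARG", c(12 * k + 6, 90, 0))
  }
  model <- .buildModel(res)
  planted <- if (m) do.call(rbind, planted) else
    data.frame(label = character(), distance_A = numeric())
  list(model = model, planted = planted)
}

# carboxylate/guanidine orientation helper: place a pair of group atoms
# around center so the nearest one sits at exactly dmin from target.
# center, target: positions in the z = 0 plane; bond: C-O (or C-N) length.
.orientedPair <- function(center, target, dmin, bond, spread = 123) {
  dct <- .euclid(center, target)
  if (dct >= dmin + bond || dct <= dmin - bond)
    .stopf("orientation infeasible: |center-target| = %.2f, dmin = %.2f, bond = %.2f",
           dct, dmin, bond)
  u <- (target - center) / dct
  v <- c(-u[2], u[1], 0)                      # in-plane perpendicular
  theta <- acos((dct^2 + bond^2 - dmin^2) / (2 * dct * bond))
  a1 <- center + bond * (cos(theta) * u + sin(theta) * v)
  a2 <- center + bond * (cos(theta + spread * pi / 180) * u +
                         sin(theta + spread * pi / 180) * v)
  rbind(a1, a2)
}

#' Synthetic interface reference model (1JRH-like geometry)
#'
#' A synthetic stand-in for the crystal structure of the
#' antigen-antibody interface, built from idealized charged-residue geometry
#' so that the published crystal contact distances hold by construction:
#' K52(NZ)-D54(CG) 3.6 A, K52(NZ)-D56(CG) 3.5 A, R84(CZ)-E45(CD) 4.3 A,
#' E27(CD)-K98(NZ) 8.0 A, R84-E45 group minimum 2.9 A, K52-D54 and K52-D56
#' carboxylate-O minima 2.8 A, R84-E27 group minimum 3.7 A and K98-D28
#' group minimum 4.3 A. Chains follow the crystal convention: I = antigen,
#' H = heavy-chain variable domain, L = light-chain variable domain. This
#' is NOT the deposited structure; it is a geometric emulation for testing
#' the distance machinery offline.
#'
#' @return a \linkS4class{StructureModel}
#' @export
makeReferenceInterface <- function() {
  res <- list()
  addRes <- function(chain, resSeq, resName, atoms) {
    res[[length(res) + 1L]] <<- list(chain = chain, resSeq = resSeq,
                                     resName = resName, atoms = atoms)
  }
  bbFor <- function(anchor, sgn, stem) {
    ca <- anchor + c(0, 0, sgn * stem)
    rbind(N = ca + c(-1.46, 0, 0), CA = ca, C = ca + c(1.52, 0, 0))
  }

  # --- K52 (antigen) cluster, near the origin -------------------------
  nz52 <- c(0, 0, 0)
  addRes("I", 52L, "LYS", rbind(bbFor(nz52, -1, 5.9), NZ = nz52))

  cg54 <- nz52 + c(3.6, 0, 0)                 # rep distance 3.6 A
  od54 <- .orientedPair(cg54, nz52, 2.8, 1.25) # carboxyl-O minimum 2.8 A
  addRes("H", 54L, "ASP", rbind(bbFor(cg54, 1, 2.4), CG = cg54,
                                OD1 = od54[1, ], OD2 = od54[2, ]))

  cg56 <- nz52 + c(0, 3.5, 0)                 # rep distance 3.5 A
  od56 <- .orientedPair(cg56, nz52, 2.8, 1.25)
  addRes("H", 56L, "ASP", rbind(bbFor(cg56, 1, 2.4), CG = cg56,
                                OD1 = od56[1, ], OD2 = od56[2, ]))

  # --- R84 (antigen) cluster at x = 20 --------------------------------
  cz84 <- c(20, 0, 0)
  cd45 <- cz84 + c(4.3, 0, 0)                 # rep distance 4.3 A
  nh1 <- cz84 + 1.33 * (cd45 - cz84) / 4.3    # guanidine N toward E45
  ne  <- cz84 + 1.33 * c(cos(2 * pi / 3), -sin(2 * pi / 3), 0)
  nh2 <- cz84 + 1.33 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
  addRes("I", 84L, "ARG", rbind(bbFor(cz84, -1, 5.9), CZ = cz84,
                                NE = ne, NH1 = nh1, NH2 = nh2))

  oe45 <- .orientedPair(cd45, nh1, 2.9, 1.25)  # group minimum 2.9 A
  addRes("I", 45L, "GLU", rbind(bbFor(cd45, 1, 3.8), CD = cd45,
                                OE1 = oe45[1, ], OE2 = oe45[2, ]))

  # --- E27 (light chain) between R84 and K98 --------------------------
  cd27 <- cz84 + c(0, 5, 0)
  guan <- rbind(ne, nh1, nh2)
  nearest <- guan[which.min(apply(guan, 1, function(p) .euclid(p, cd27))), ]
  oe27 <- .orientedPair(cd27, nearest, 3.7, 1.25) # guanidine-carboxyl 3.7 A
  addRes("L", 27L, "GLU", rbind(bbFor(cd27, 1, 3.8), CD = cd27,
                                OE1 = oe27[1, ], OE2 = oe27[2, ]))

  nz98 <- cd27 + c(0, 8, 0)                   # E27(CD)-K98(NZ) 8.0 A
  addRes("I", 98L, "LYS", rbind(bbFor(nz98, -1, 5.9), NZ = nz98))

  cg28 <- nz98 + c(0, 5, 0)
  od28 <- .orientedPair(cg28, nz98, 4.3, 1.25) # K98-D28 group minimum 4.3 A
  addRes("L", 28L, "ASP", rbind(bbFor(cg28, 1, 2.4), CG = cg28,
                                OD1 = od28[1, ], OD2 = od28[2, ]))

  model <- .buildModel(res)

  # construction invariants: the planted distances must hold exactly
  stopifnot(
    abs(representativeDistance(model, "I:52", "H:54") - 3.6) < 1e-9,
    abs(representativeDistance(model, "I:52", "H:56") - 3.5) < 1e-9,
    abs(representativeDistance(model, "I:84", "I:45") - 4.3) < 1e-9,
    abs(.euclid(cd27, nz98) - 8.0) < 1e-9,
    abs(groupMinDistance(model, "I:84", "I:45") - 2.9) < 1e-9,
    abs(groupMinDistance(model, "I:52", "H:54") - 2.8) < 1e-9,
    abs(groupMinDistance(model, "I:52", "H:56") - 2.8) < 1e-9,
    abs(groupMinDistance(model, "I:84", "L:27") - 3.7) < 1e-9,
    abs(groupMinDistance(model, "I:98", "L:28") - 4.3) < 1e-9)
  model
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Frames are the reference plus iid Gaussian jitter. For each contact
#' target, a Bernoulli(p) schedule decides per frame whether the contact's
#' measurement atoms are placed inside (distance < threshold) or outside
#' (distance > threshold) along their reference axis, so the planted
#' occupancy schedule is exact by construction rather than emergent.
#' Optional linear drift displaces every atom of one chain by
#' \code{t * rate}, emulating a dissociating complex. Contact atom
#' positions are planted after drift, so planted schedules stay exact.
#'
#' @param reference \linkS4class{StructureModel} reference structure
#' @param nFrames number of frames (>= 1)
#' @param dt frame spacing, ns
#' @param jitterSd isotropic Gaussian jitter per coordinate, Angstrom
#' @param contactTargets list of \code{list(contact = ContactDefinition,
#'   occupancy = p)} with p in [0, 1]
#' @param driftChain chain id to drift (NULL = stable complex)
#' @param driftRate drift speed, Angstrom/ns, applied along +x
#' @param seed RNG seed (generators are pure functions of their seed)
#' @return list with \code{trajectory} (a \linkS4class{Trajectory}) and
#'   \code{groundTruth} (per-contact logical schedules, drift description)
#' @export
makeSyntheticTrajectory <- function(reference, nFrames = 1000, dt = 0.1,
                                    jitterSd = 0, contactTargets = list(),
                                    driftChain = NULL, driftRate = 0,
                                    seed = 1) {
  if (nFrames < 1) .stopf("nFrames must be >= 1")
  for (ct in contactTargets)
    if (ct$occupancy < 0 || ct$occupancy > 1)
      .stopf("target occupancy must lie in [0, 1]")
  top <- reference
  nA <- nAtoms(top)
  ref <- top@coords
  times <- (seq_len(nFrames) - 1) * dt
  a <- top@atoms

  # resolve contact atom rows; shared atoms across targets are contradictory
  ctRows <- lapply(contactTargets, function(ct) {
    cd <- ct$contact
    c(.atomRow(top, list(chain = cd@chainA, resSeq = cd@resA,
                         iCode = cd@iCodeA), cd@atomA),
      .atomRow(top, list(chain = cd@chainB, resSeq = cd@resB,
                         iCode = cd@iCodeB), cd@atomB))
  })
  allRows <- unlist(ctRows)
  if (anyDuplicated(allRows))
    .stopf("contradictory contact targets: atoms shared between targets")

  driftRows <- if (!is.null(driftChain)) which(a$chainId == driftChain)
               else integer()
  if (!is.null(driftChain) && !length(driftRows))
    .stopf("drift chain '%s' has no atoms", driftChain)

  withSeed(seed, function() {
    arr <- array(0, dim = c(nFrames, nA, 3))
    schedules <- vector("list", length(contactTargets))
    for (f in seq_len(nFrames)) {
      fr <- ref
      if (jitterSd > 0)
        fr <- fr + matrix(stats::rnorm(nA * 3, 0, jitterSd), nA, 3)
      if (length(driftRows) && driftRate != 0)
        fr[driftRows, 1] <- fr[driftRows, 1] + times[f] * driftRate
      arr[f, , ] <- fr
    }
    for (j in seq_along(contactTargets)) {
      ct <- contactTargets[[j]]
      thr <- ct$contact@threshold
      ia <- ctRows[[j]][1]; ib <- ctRows[[j]][2]
      u <- ref[ib, ] - ref[ia, ]
      u <- u / sqrt(sum(u^2))
      inside <- stats::runif(nFrames) < ct$occupancy
      dIn <- thr * stats::runif(nFrames, 0.70, 0.95)
      dOut <- thr * stats::runif(nFrames, 1.20, 1.80)
      dist <- ifelse(inside, dIn, dOut)
      for (f in seq_len(nFrames)) {
        arr[f, ia, ] <- ref[ia, ]
        arr[f, ib, ] <- ref[ia, ] + dist[f] * u
      }
      schedules[[j]] <- inside
    }
    names(schedules) <- vapply(contactTargets,
                               function(ct) ct$contact@label, character(1))
    traj <- newTrajectory(top, arr, times = times)
    list(trajectory = traj,
         groundTruth = list(schedules = schedules,
                            drift = list(chain = driftChain,
                                         rate_A_per_ns = driftRate),
                            jitterSd = jitterSd, seed = seed))
  })
}

#' Six-concentration dilution series used in the SPR panels
#'
#' The standard two-fold dilution series 1000, 500, 250, 125, 62.5,
#' 31.25 nM, in molar units.
#'
#' @return numeric vector of concentrations, M
#' @export
standardDilutionSeries <- function() {
  c(1000, 500, 250, 125, 62.5, 31.25) * 1e-9
}

#' Generate a multi-concentration sensorgram panel
#'
#' Simulates one 1:1 Langmuir sensorgram per concentration with shared
#' (kon, koff, rmax) and iid Gaussian noise; the default concentration grid
#' is the standard six-point two-fold dilution series.
#'
#' @inheritParams simulateSensorgram
#' @param concentrations analyte concentrations, M
#' @return stacked data.frame(time_s, response_RU, conc_M, phase)
#' @export
makeSensorgramPanel <- function(kon, koff, rmax,
                                concentrations = standardDilutionSeries(),
                                tAssoc = 60, tDissoc = 300, dt = 0.5,
                                noiseSd = 0, seed = NULL) {
  withSeed(seed, function() {
    do.call(rbind, lapply(concentrations, function(C)
      simulateSensorgram(kon, koff, rmax, C, tAssoc = tAssoc,
                         tDissoc = tDissoc, dt = dt, noiseSd = noiseSd,
                         seed = NULL)))
  })
}

#' Generate a KD(T) series from known thermodynamic parameters
#'
#' \code{ln KD = dH/(R T) - dS/R}, with optional multiplicative log-normal
#' noise.
#'
#' @param dH binding enthalpy, kJ/mol
#' @param dS binding entropy, kJ/(mol K)
#' @param temperatures temperatures, K
#' @param noiseFrac multiplicative noise scale (sd of log KD)
#' @param seed RNG seed
#' @return data.frame(T_K, KD_M)
#' @export
makeKdSeries <- function(dH, dS, temperatures = seq(288, 310, length.out = 6),
                         noiseFrac = 0, seed = NULL) {
  lnKd <- dH / (R_GAS_KJ * temperatures) - dS / R_GAS_KJ
  kd <- exp(lnKd)
  if (noiseFrac > 0)
    kd <- withSeed(seed, function()
      kd * exp(stats::rnorm(length(kd), 0, noiseFrac)))
  data.frame(T_K = temperatures, KD_M = kd)
}

#' Generate a single- or double-peak DSC thermogram
#'
#' Gaussian transition peak(s) on a flat baseline with optional noise.
#'
#' @param tm peak center, degrees C
#' @param width Gaussian sd, degrees C
#' @param height peak height, arbitrary units
#' @param baseline constant baseline level
#' @param tRange scan range, degrees C
#' @param dt grid step, degrees C
#' @param secondPeak optional \code{list(tm, width, height)} for a second
#'   transition
#' @param noiseSd Gaussian noise sd
#' @param seed RNG seed
#' @return data.frame(T_C, Cp)
#' @export
makeThermogram <- function(tm = 70, width = 4, height = 1, baseline = 0.05,
                           tRange = c(30, 95), dt = 0.1, secondPeak = NULL,
                           noiseSd = 0, seed = NULL) {
  t <- seq(tRange[1], tRange[2], by = dt)
  cp <- baseline + height * exp(-(t - tm)^2 / (2 * width^2))
  if (!is.null(secondPeak))
    cp <- cp + secondPeak$height *
      exp(-(t - secondPeak$tm)^2 / (2 * secondPeak$width^2))
  if (noiseSd > 0)
    cp <- cp + withSeed(seed, function() stats::rnorm(length(t), 0, noiseSd))
  data.frame(T_C = t, Cp = cp)
}
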