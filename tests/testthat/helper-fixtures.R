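# shared fixtures and independent oracles, built in code at test time

# minimal hand-written PDB text: two atoms, one chain
twoAtomPDB <- function() {
  paste(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "END", sep = "\n")
}

# quaternion-method (Horn) minimum RMSD: independent of the SVD route
quatRMSD <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(sum(P^2) + sum(Q^2) - 2 * lam, 0) / nrow(P))
}

# random proper rotation matrix
randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

# apply one rigid motion to a StructureModel
rigidMove <- function(model, R, t) {
  new("StructureModel", atoms = atomTable(model),
      coords = sweep(coords(model) %*% R, 2, -t),
      modelIndex = model@modelIndex)
}

# uniform nonbonded parameter table covering every atom of a model
uniformParams <- function(model, charge = 0.1, sigma = 3.2, eps = 0.3) {
  a <- atomTable(model)
  data.frame(chain = a$chainId, res_seq = a$resSeq, res_name = a$resName,
             atom = a$name, charge_e = charge, sigma_A = sigma,
             epsilon_kJmol = eps, stringsAsFactors = FALSE)
}

# Table-1-style kinetic ground truth used for simulate-and-refit checks:
# rates in 1/(M s) and 1/s, published KD in nM
kineticTruthTable <- function() {
  data.frame(
    complex = c("WT-WT", "R84A-WT", "K98A-WT", "R84E-E27R", "K98D-D28K"),
    kon = c(2.7e5, 0.74e5, 0.90e5, 2.4e5, 2.1e5),
    koff = c(2.3e-2, 2.1e-2, 3.9e-2, 1.7e-2, 2.0e-2),
    kd_nM = c(87, 280, 440, 73, 95),
    stringsAsFactors = FALSE)
}

# write a complete set of pipeline input fixtures into dir; returns config
makePipelineFixtures <- function(dir, nFrames = 100) {
  m <- makeReferenceInterface()
  writePDB(m, file.path(dir, "ref.pdb"))
  cd <- contactDefinition("K52-D54", "I:52", "NZ", "H:54", "CG", 3.6)
  for (i in 1:3) {
    st <- makeSyntheticTrajectory(m, nFrames = nFrames, dt = 0.5,
      jitterSd = 0.05,
      contactTargets = list(list(contact = cd, occupancy = 0.8)), seed = i)
    writePDB(lapply(seq_len(nFrames), function(f)
      new("StructureModel", atoms = atomTable(m),
          coords = frameCoords(st$trajectory, f), modelIndex = as.integer(f))),
      file.path(dir, sprintf("rep%d.pdb", i)))
  }
  write.csv(uniformParams(m), file.path(dir, "params.csv"), row.names = FALSE)
  write.csv(makeSensorgramPanel(2.7e5, 2.3e-2, 100, noiseSd = 1, seed = 3),
            file.path(dir, "spr.csv"), row.names = FALSE)
  write.csv(makeKdSeries(-50, -0.03, noiseFrac = 0.02, seed = 4),
            file.path(dir, "kd.csv"), row.names = FALSE)
  write.csv(makeThermogram(tm = 70, noiseSd = 0.01, seed = 5),
            file.path(dir, "dsc.csv"), row.names = FALSE)
  list(
    seed = 1, output_dir = file.path(dir, "out"),
    structure = list(file = file.path(dir, "ref.pdb")),
    chain_roles = list(antigen = "I", heavy = "H", light = "L"),
    contacts = list(list(label = "K52-D54", res_a = "I:52", atom_a = "NZ",
                         res_b = "H:54", atom_b = "CG", threshold = 3.6)),
    trajectories = list(dt_ns = 0.5, burn_in_ns = 10, terminal_exclude = 0,
                        replicas = as.list(file.path(dir,
                                                     sprintf("rep%d.pdb", 1:3)))),
    energetics = list(params = file.path(dir, "params.csv"),
                      residues = list("I:52"),
                      partner_chains = list("H", "L")),
    spr = list(file = file.path(dir, "spr.csv")),
    vant_hoff = list(file = file.path(dir, "kd.csv")),
    dsc = list(file = file.path(dir, "dsc.csv")))
}
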