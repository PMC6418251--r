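# Coulomb conversion factor: e^2/(4 pi eps0) in kJ A / (mol e^2)
COULOMB_KJ_A <- 1389.35458

#' Coulomb pair energy
#'
#' \code{f * q1 * q2 / (dielectric * r)} with
#' f = 1389.35458 kJ A mol^-1 e^-2.
#'
#' @param q1,q2 partial charges, e
#' @param r separation, Angstrom (> 0)
#' @param dielectric relative dielectric constant (1 = vacuum-style
#'   decomposition)
#' @return energy in kJ/mol
#' @export
coulombEnergy <- function(q1, q2, r, dielectric = 1) {
  if (any(r <= 0)) .stopf("Coulomb energy is singular at r <= 0")
  COULOMB_KJ_A * q1 * q2 / (dielectric * r)
}

#' Lennard-Jones 12-6 pair energy
#'
#' \code{4 eps ((sigma/r)^12 - (sigma/r)^6)} for pair parameters
#' \code{sigma_ij}, \code{eps_ij}.
#'
#' @param sigma pair sigma, Angstrom
#' @param epsilon pair epsilon (well depth), kJ/mol
#' @param r separation, Angstrom (> 0)
#' @return energy in kJ/mol
#' @export
ljEnergy <- function(sigma, epsilon, r) {
  if (any(r <= 0)) .stopf("Lennard-Jones energy is singular at r <= 0")
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6 * sr6 - sr6)
}

#' Lorentz-Berthelot combining rules
#'
#' Arithmetic mean for sigma, geometric mean for epsilon.
#'
#' @param sigmaI,sigmaJ per-atom sigmas, Angstrom
#' @param epsI,epsJ per-atom epsilons, kJ/mol
#' @return list(sigma, epsilon)
#' @export
combineLorentzBerthelot <- function(sigmaI, sigmaJ, epsI, epsJ) {
  list(sigma = (sigmaI + sigmaJ) / 2, epsilon = sqrt(epsI * epsJ))
}

#' Read a per-atom nonbonded parameter table
#'
#' CSV/TSV with columns chain, res_seq, res_name, atom, charge_e, sigma_A,
#' epsilon_kJmol (force-field parameters are always supplied by file, never
#' hard-coded).
#'
#' @param file path to the parameter table
#' @return data.frame of parameters
#' @export
readNonbondedParams <- function(file) {
  sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  p <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("chain", "res_seq", "res_name", "atom", "charge_e", "sigma_A",
            "epsilon_kJmol")
  miss <- setdiff(need, names(p))
  if (length(miss))
    .stopf("parameter table lacks columns: %s", paste(miss, collapse = ", "))
  if (any(p$sigma_A <= 0)) .stopf("lj sigma must be positive")
  if (any(p$epsilon_kJmol < 0)) .stopf("lj epsilon must be non-negative")
  p
}

# align a parameter table to the topology atoms; refuse on missing entries
.matchParams <- function(topology, params) {
  a <- topology@atoms
  keyT <- paste(a$chainId, a$resSeq, a$name, sep = "\r")
  keyP <- paste(params$chain, params$res_seq, params$atom, sep = "\r")
  idx <- match(keyT, keyP)
  if (anyNA(idx)) {
    missing <- unique(paste0(a$chainId[is.na(idx)], ":", a$resSeq[is.na(idx)],
                             "[", a$name[is.na(idx)], "]"))
    .stopf("unparameterized atoms: %s",
           paste(utils::head(missing, 10), collapse = ", "))
  }
  data.frame(charge = params$charge_e[idx], sigma = params$sigma_A[idx],
             epsilon = params$epsilon_kJmol[idx])
}

# pairwise short-range energy between two atom sets in one frame
.pairEnergy <- function(pa, pb, qa, qb, sa, sb, ea, eb, cutoff, dielectric,
                        pairTable = NULL, namesA = NULL, namesB = NULL) {
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  d <- sqrt(pmax(d2, 0))
  if (any(d == 0)) .stopf("coincident atoms (r = 0) in energy evaluation")
  within <- d <= cutoff
  if (!any(within)) return(c(coulomb = 0, lj = 0))
  sig <- outer(sa, sb, "+") / 2
  eps <- sqrt(outer(ea, eb))
  if (!is.null(pairTable)) {
    # pair-specific overrides take precedence over Lorentz-Berthelot
    keyM <- outer(namesA, namesB, paste, sep = "\r")
    hit <- match(keyM, paste(pairTable$atom_i, pairTable$atom_j, sep = "\r"))
    hit2 <- match(keyM, paste(pairTable$atom_j, pairTable$atom_i, sep = "\r"))
    hit[is.na(hit)] <- hit2[is.na(hit)]
    use <- !is.na(hit)
    sig[use] <- pairTable$sigma_A[hit[use]]
    eps[use] <- pairTable$epsilon_kJmol[hit[use]]
  }
  qq <- outer(qa, qb)
  ec <- COULOMB_KJ_A * qq / (dielectric * d)
  sr6 <- (sig / d)^6
  el <- 4 * eps * (sr6 * sr6 - sr6)
  c(coulomb = sum(ec[within]), lj = sum(el[within]))
}

#' Per-residue interaction energy against partner chains
#'
#' For every post-burn-in frame, sums Coulomb plus Lennard-Jones energies
#' over all (residue atom, partner-chain atom) pairs within the cutoff,
#' then averages over time per replica and reports the replica mean with
#' its standard error. Plain truncation is used at the cutoff (no switching
#' function and no reciprocal-space long-range term, which cannot be
#' assigned to individual residue pairs).
#'
#' @param trajs a \linkS4class{Trajectory} or list of replica trajectories
#'   sharing one topology
#' @param params parameter table (see \code{\link{readNonbondedParams}})
#' @param residues residue selector or list of selectors (e.g.
#'   \code{c("I:52", "I:84")})
#' @param partnerChains chain ids of the partner molecule; must exclude the
#'   residue's own chain
#' @param cutoff interaction cutoff, Angstrom
#' @param burnIn initial ns excluded from the time average
#' @param dielectric relative dielectric constant
#' @param pairParams optional pair-specific table with columns atom_i,
#'   atom_j, sigma_A, epsilon_kJmol, overriding Lorentz-Berthelot
#' @return data.frame, one row per residue: chain, res_seq, res_name,
#'   coulomb, lj, total (kJ/mol, replica means), sd, se, n_replicas; the
#'   per-replica totals are attached as attribute "replicas"
#' @export
residueInteractionEnergy <- function(trajs, params, residues, partnerChains,
                                     cutoff = 12, burnIn = 0, dielectric = 1,
                                     pairParams = NULL) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  if (!length(partnerChains)) .stopf("empty partner-chain selection")
  top <- trajs[[1]]@topology
  par <- .matchParams(top, params)
  if (!is.list(residues) || !is.null(residues$chain))
    residues <- if (is.character(residues)) as.list(residues) else list(residues)
  a <- top@atoms
  rows <- list()
  repTotals <- list()
  for (res in residues) {
    r <- .parseRes(res)
    ri <- .residueRows(top, r)
    if (!length(ri)) .stopf("residue %s not found in topology", .resLabel(r))
    if (r$chain %in% partnerChains)
      .stopf("partner chains must exclude the residue's own chain (%s)",
             r$chain)
    pi_ <- which(a$chainId %in% partnerChains)
    if (!length(pi_)) .stopf("no atoms in partner chains %s",
                             paste(partnerChains, collapse = ","))
    perRep <- vapply(trajs, function(tr) {
      keep <- which(tr@times >= burnIn)
      if (!length(keep))
        .stopf("no frames remain after burn-in of %g ns", burnIn)
      acc <- c(coulomb = 0, lj = 0)
      for (f in keep) {
        fr <- frameCoords(tr, f)
        acc <- acc + .pairEnergy(fr[ri, , drop = FALSE],
                                 fr[pi_, , drop = FALSE],
                                 par$charge[ri], par$charge[pi_],
                                 par$sigma[ri], par$sigma[pi_],
                                 par$epsilon[ri], par$epsilon[pi_],
                                 cutoff, dielectric, pairParams,
                                 a$name[ri], a$name[pi_])
      }
      acc / length(keep)
    }, c(coulomb = 0, lj = 0))
    tot <- colSums(perRep)
    summ <- replicaSummary(tot)
    rows[[length(rows) + 1L]] <- data.frame(
      chain = r$chain, res_seq = r$resSeq,
      res_name = a$resName[ri[1]],
      coulomb = mean(perRep["coulomb", ]), lj = mean(perRep["lj", ]),
      total = summ$mean, sd = summ$sd, se = summ$se,
      n_replicas = summ$n, stringsAsFactors = FALSE)
    repTotals[[.resLabel(r)]] <- tot
  }
  out <- do.call(rbind, rows)
  attr(out, "replicas") <- repTotals
  out
}

#' Convert energies from kJ/mol to kcal/mol
#'
#' @param x energy in kJ/mol
#' @return energy in kcal/mol
#' @export
kJToKcal <- function(x) x / 4.184
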