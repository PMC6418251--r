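#' Construct a Trajectory
#'
#' @param topology \linkS4class{StructureModel} giving atom identities
#' @param coords nFrames x nAtoms x 3 array, or a list of nAtoms x 3
#'   matrices, Angstrom
#' @param times frame times in ns (strictly increasing); default
#'   \code{(0:(nFrames-1)) * dt}
#' @param dt frame spacing in ns used when \code{times} is NULL (MD
#'   snapshots are commonly saved every 10 ps = 0.01 ns)
#' @return a \linkS4class{Trajectory}
#' @export
newTrajectory <- function(topology, coords, times = NULL, dt = 0.01) {
  if (is.list(coords)) {
    arr <- array(0, dim = c(length(coords), nrow(coords[[1]]), 3))
    for (i in seq_along(coords)) arr[i, , ] <- coords[[i]]
    coords <- arr
  }
  if (is.null(times)) times <- (seq_len(dim(coords)[1]) - 1) * dt
  traj <- new("Trajectory", topology = topology, coords = coords,
              times = as.numeric(times))
  .warnOnJumps(traj)
  traj
}

# trajectories are assumed pre-imaged with the complex whole; a large
# inter-frame displacement is the signature of an unwrapped periodic box
.warnOnJumps <- function(traj, jump = 20) {
  n <- dim(traj@coords)[1]
  if (n < 2) return(invisible())
  d <- traj@coords[-1, , , drop = FALSE] - traj@coords[-n, , , drop = FALSE]
  maxJump <- sqrt(max(apply(d^2, c(1, 2), sum)))
  if (maxJump > jump)
    warning(sprintf(
      "inter-frame atom jump of %.1f A exceeds %g A: trajectory may not be re-imaged/whole",
      maxJump, jump), call. = FALSE)
  invisible()
}

#' Build a Trajectory from parsed multi-model PDB structures
#'
#' @param models list of \linkS4class{StructureModel} (equal atom counts)
#' @inheritParams newTrajectory
#' @return a \linkS4class{Trajectory}
#' @export
trajectoryFromModels <- function(models, times = NULL, dt = 0.01) {
  n <- vapply(models, nAtoms, integer(1))
  if (length(unique(n)) != 1)
    .stopf("models have differing atom counts: %s",
           paste(unique(n), collapse = ", "))
  newTrajectory(models[[1]], lapply(models, coords), times = times, dt = dt)
}

#' Read a trajectory file
#'
#' Multi-model PDB is read natively; DCD is read via \code{bio3d::read.dcd}
#' against a supplied topology. XTC is not supported by the installed
#' readers and raises a capability error.
#'
#' @param file trajectory path
#' @param format "pdb", "dcd" or "xtc" (guessed from the extension)
#' @param topology \linkS4class{StructureModel}, required for DCD
#' @inheritParams newTrajectory
#' @return a \linkS4class{Trajectory}
#' @export
readTrajectory <- function(file, format = c("auto", "pdb", "dcd", "xtc"),
                           topology = NULL, times = NULL, dt = 0.01) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(file)),
                     dcd = "dcd", xtc = "xtc", "pdb")
  if (format == "xtc")
    .stopf("no XTC reader is available; convert to multi-model PDB or DCD")
  if (format == "dcd") {
    if (is.null(topology))
      .stopf("reading DCD requires a topology StructureModel")
    xyz <- bio3d::read.dcd(file, verbose = FALSE)
    coords <- lapply(seq_len(nrow(xyz)), function(i)
      matrix(xyz[i, ], ncol = 3, byrow = TRUE))
    return(newTrajectory(topology, coords, times = times, dt = dt))
  }
  trajectoryFromModels(parsePDB(file), times = times, dt = dt)
}

.checkMask <- function(mask, nAtomsTotal, what = "mask") {
  mask <- as.integer(mask)
  if (!length(mask) || any(mask < 1) || any(mask > nAtomsTotal))
    .stopf("%s indexes atoms outside 1..%d", what, nAtomsTotal)
  mask
}

#' Per-frame C-alpha RMSD against a reference structure
#'
#' Each frame is superposed onto the reference over \code{fitMask}
#' (default: the measurement mask itself), then the RMSD is computed over
#' \code{measureMask}.
#'
#' @param traj a \linkS4class{Trajectory}
#' @param measureMask integer atom indices to measure (e.g. from
#'   \code{\link{caMask}})
#' @param reference \linkS4class{StructureModel} with the same atom layout
#'   as the trajectory topology
#' @param fitMask atom indices used for the superposition fit
#' @return data.frame(time_ns, rmsd_A)
#' @export
rmsdSeries <- function(traj, measureMask, reference, fitMask = NULL) {
  nA <- nAtoms(traj)
  if (nAtoms(reference) != nA)
    .stopf("reference has %d atoms but trajectory topology has %d",
           nAtoms(reference), nA)
  measureMask <- .checkMask(measureMask, nA, "measureMask")
  fitMask <- if (is.null(fitMask)) measureMask
             else .checkMask(fitMask, nA, "fitMask")
  refFit <- reference@coords[fitMask, , drop = FALSE]
  refMeas <- reference@coords[measureMask, , drop = FALSE]
  n <- nFrames(traj)
  vals <- vapply(seq_len(n), function(f) {
    fr <- frameCoords(traj, f)
    sp <- kabschSuperpose(fr[fitMask, , drop = FALSE], refFit)
    fitted <- applySuperposition(fr[measureMask, , drop = FALSE], sp)
    sqrt(mean(rowSums((fitted - refMeas)^2)))
  }, numeric(1))
  data.frame(time_ns = traj@times, rmsd_A = vals)
}

#' Ligand-RMSD series: antibody RMSD after superposing on the antigen
#'
#' Per frame, the superposition is fitted on the antigen C-alpha atoms only
#' and the RMSD is then measured over the antibody C-alpha atoms without
#' re-fitting. This captures changes in the relative orientation of the two
#' binding partners: a stable complex keeps a flat, low L-RMSD; a
#' dissociating complex shows a growing one.
#'
#' @param traj a \linkS4class{Trajectory}
#' @param antigenFitMask atom indices of the antigen fit selection (>= 3,
#'   non-collinear)
#' @param antibodyMeasureMask atom indices of the antibody measurement
#'   selection; must not overlap the fit selection
#' @param reference \linkS4class{StructureModel} reference (crystal)
#'   structure
#' @return list with \code{series} (data.frame time_ns, lrmsd_A),
#'   \code{mean} and \code{sd} over the whole series
#' @export
lrmsdSeries <- function(traj, antigenFitMask, antibodyMeasureMask, reference) {
  nA <- nAtoms(traj)
  antigenFitMask <- .checkMask(antigenFitMask, nA, "antigenFitMask")
  antibodyMeasureMask <- .checkMask(antibodyMeasureMask, nA,
                                    "antibodyMeasureMask")
  if (length(intersect(antigenFitMask, antibodyMeasureMask)))
    .stopf("fit and measurement masks must be disjoint")
  if (nAtoms(reference) != nA)
    .stopf("reference has %d atoms but trajectory topology has %d",
           nAtoms(reference), nA)
  refFit <- reference@coords[antigenFitMask, , drop = FALSE]
  refMeas <- reference@coords[antibodyMeasureMask, , drop = FALSE]
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    fr <- frameCoords(traj, f)
    sp <- kabschSuperpose(fr[antigenFitMask, , drop = FALSE], refFit)
    fitted <- applySuperposition(fr[antibodyMeasureMask, , drop = FALSE], sp)
    sqrt(mean(rowSums((fitted - refMeas)^2)))
  }, numeric(1))
  list(series = data.frame(time_ns = traj@times, lrmsd_A = vals),
       mean = mean(vals), sd = stats::sd(vals))
}

#' Per-frame distance between the two measurement atoms of a contact
#'
#' @param traj a \linkS4class{Trajectory}
#' @param contact a \linkS4class{ContactDefinition}
#' @return data.frame(time_ns, distance_A)
#' @export
distanceSeries <- function(traj, contact) {
  top <- traj@topology
  ia <- .atomRow(top, list(chain = contact@chainA, resSeq = contact@resA,
                           iCode = contact@iCodeA), contact@atomA)
  ib <- .atomRow(top, list(chain = contact@chainB, resSeq = contact@resB,
                           iCode = contact@iCodeB), contact@atomB)
  d <- sqrt(rowSums((traj@coords[, ia, , drop = FALSE] -
                     traj@coords[, ib, , drop = FALSE])^2, dims = 1))
  data.frame(time_ns = traj@times, distance_A = as.numeric(d))
}

#' Contact occupancy: fraction of post-burn-in frames within threshold
#'
#' @param series data.frame(time_ns, distance_A) as returned by
#'   \code{\link{distanceSeries}}
#' @param threshold distance threshold, Angstrom (conventionally the
#'   crystal-structure distance of the same contact; 4.0 A is the common
#'   generic preset, see \code{\link{occupancyThresholdPreset}})
#' @param burnIn initial time span in ns excluded from the statistic
#' @return fraction in [0, 1]
#' @export
contactOccupancy <- function(series, threshold, burnIn = 0) {
  if (threshold <= 0) .stopf("threshold must be positive")
  keep <- series$time_ns >= burnIn
  if (!any(keep))
    .stopf("no frames remain after burn-in of %g ns", burnIn)
  mean(series$distance_A[keep] <= threshold)
}

#' Generic salt-bridge occupancy threshold preset
#'
#' The generic 4.0 A charged-group distance threshold commonly applied when
#' no contact-specific crystal distance is available (e.g. for contacts
#' created by mutation).
#'
#' @return 4.0 (Angstrom)
#' @export
occupancyThresholdPreset <- function() 4.0

#' Replica summary statistics
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and
#' standard error over replicate simulations. Occupancy tables
#' conventionally report mean and sd; energy tables report mean and se.
#' A single replica returns NA spread with a flag rather than a silent 0.
#'
#' @param fractions numeric vector, one value per replica
#' @return list(mean, sd, se, n, spreadDefined)
#' @export
replicaSummary <- function(fractions) {
  n <- length(fractions)
  if (!n) .stopf("no replica values supplied")
  if (n == 1) {
    return(list(mean = fractions, sd = NA_real_, se = NA_real_, n = 1L,
                spreadDefined = FALSE))
  }
  s <- stats::sd(fractions)
  list(mean = mean(fractions), sd = s, se = s / sqrt(n), n = as.integer(n),
       spreadDefined = TRUE)
}
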