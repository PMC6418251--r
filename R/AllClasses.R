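#' @import methods
NULL

#' StructureModel: one set of coordinates with atom metadata
#'
#' A single structural model (one crystal model or one trajectory frame
#' template): an atom table in PDB order plus an n x 3 coordinate matrix in
#' Angstrom. Residues are identified by (chainId, resSeq, iCode) in author
#' numbering.
#'
#' @slot atoms data.frame with columns serial, name, altLoc, resName,
#'   chainId, resSeq, iCode, element, occupancy
#' @slot coords numeric matrix, nrow(atoms) x 3, Angstrom
#' @slot modelIndex integer model number (1-based)
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", coords = "matrix",
                 modelIndex = "integer"),
  prototype(modelIndex = 1L))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  x <- object@coords
  msgs <- character()
  need <- c("serial", "name", "altLoc", "resName", "chainId", "resSeq",
            "iCode", "element", "occupancy")
  if (!all(need %in% names(a)))
    msgs <- c(msgs, paste("atoms must have columns:",
                          paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) != nrow(x) || ncol(x) != 3)
    msgs <- c(msgs, "coords must be nrow(atoms) x 3")
  if (nrow(x) && !all(is.finite(x)))
    msgs <- c(msgs, "coordinates must be finite")
  if (nrow(a) && any(!nzchar(a$name)))
    msgs <- c(msgs, "atom names must be non-empty")
  if (nrow(a)) {
    key <- paste(a$chainId, a$resSeq, a$iCode, a$name)
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate atom name within a residue after alt-loc resolution")
  }
  if (length(msgs)) msgs else TRUE
})

#' Trajectory: time-ordered frames bound to one topology
#'
#' @slot topology StructureModel giving atom identities (frame-0 reference)
#' @slot coords numeric array nFrames x nAtoms x 3, Angstrom
#' @slot times numeric, frame times in ns, strictly increasing
#' @export
setClass("Trajectory",
  representation(topology = "StructureModel", coords = "array",
                 times = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  msgs <- character()
  if (length(d) != 3 || d[3] != 3)
    msgs <- c(msgs, "coords must be an nFrames x nAtoms x 3 array")
  else {
    if (d[2] != nrow(object@topology@atoms))
      msgs <- c(msgs, "frame atom count differs from topology")
    if (d[1] != length(object@times))
      msgs <- c(msgs, "length(times) must equal number of frames")
  }
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' ContactDefinition: a named charged-residue pair with measurement atoms
#'
#' @slot label character label, e.g. "K52-D54"
#' @slot chainA,chainB chain identifiers
#' @slot resA,resB residue sequence numbers (author numbering)
#' @slot iCodeA,iCodeB insertion codes ("" if none)
#' @slot atomA,atomB measurement atom names (e.g. "NZ", "CG")
#' @slot threshold distance threshold in Angstrom (> 0), typically the
#'   crystal-structure distance of the same contact
#' @export
setClass("ContactDefinition",
  representation(label = "character",
                 chainA = "character", resA = "integer", iCodeA = "character",
                 atomA = "character",
                 chainB = "character", resB = "integer", iCodeB = "character",
                 atomB = "character",
                 threshold = "numeric"))

setValidity("ContactDefinition", function(object) {
  if (length(object@threshold) != 1 || !is.finite(object@threshold) ||
      object@threshold <= 0)
    return("threshold must be a single positive number")
  if (!nzchar(object@atomA) || !nzchar(object@atomB))
    return("measurement atom names must be non-empty")
  TRUE
})

#' SuperpositionResult: optimal rigid-body fit of one point set onto another
#'
#' The transform maps mobile coordinates (rows) as
#' \code{fitted = mobile \%*\% rotation + translation}.
#'
#' @slot rotation 3 x 3 proper rotation matrix (det = +1)
#' @slot translation length-3 numeric, Angstrom
#' @slot rmsd minimized root-mean-square deviation, Angstrom
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal to 1e-9")
  if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det = +1)")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' KineticFit: globally fitted 1:1 Langmuir kinetics
#'
#' @slot kon association rate constant, 1/(M s)
#' @slot koff dissociation rate constant, 1/s
#' @slot rmax maximal response, RU
#' @slot kd equilibrium dissociation constant koff/kon, M
#' @slot sd named numeric standard deviations for kon, koff, rmax, kd
#' @slot rss residual sum of squares, RU^2
#' @slot nObs number of fitted response points
#' @slot warnings character vector of fit diagnostics (e.g. identifiability)
#' @export
setClass("KineticFit",
  representation(kon = "numeric", koff = "numeric", rmax = "numeric",
                 kd = "numeric", sd = "numeric", rss = "numeric",
                 nObs = "integer", warnings = "character"))

setValidity("KineticFit", function(object) {
  if (any(c(object@kon, object@koff, object@rmax) <= 0))
    return("all rates and rmax must be positive")
  if (abs(object@kd - object@koff / object@kon) >
      1e-12 * max(object@kd, .Machine$double.eps))
    return("kd must equal koff/kon")
  TRUE
})

#' VantHoffFit: binding enthalpy/entropy from ln KD vs 1/T regression
#'
#' @slot dH binding enthalpy, kJ/mol
#' @slot dS binding entropy, kJ/(mol K)
#' @slot refT reference temperature, K
#' @slot dG free energy dH - refT * dS at refT, kJ/mol
#' @slot sd named numeric standard deviations for dH, dS, dG
#' @slot cov 2 x 2 covariance matrix of (dH, dS)
#' @slot nT number of temperatures fitted
#' @export
setClass("VantHoffFit",
  representation(dH = "numeric", dS = "numeric", refT = "numeric",
                 dG = "numeric", sd = "numeric", cov = "matrix",
                 nT = "integer"))

setValidity("VantHoffFit", function(object) {
  if (abs(object@dG - (object@dH - object@refT * object@dS)) > 1e-9)
    return("dG must equal dH - refT * dS to 1e-9")
  if (!all(dim(object@cov) == c(2, 2)))
    return("cov must be 2 x 2")
  TRUE
})

#' TmResult: apparent melting temperature from a thermogram
#'
#' @slot tmApp temperature of maximum heat capacity, degrees C
#' @slot multiPeak TRUE if more than one prominent peak was detected
#' @slot nPeaks number of prominent local maxima
#' @slot smoothWindow moving-average window used (0 = none)
#' @export
setClass("TmResult",
  representation(tmApp = "numeric", multiPeak = "logical",
                 nPeaks = "integer", smoothWindow = "integer"))
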