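#' @rdname StructureModel-class
#' @param object,x a StructureModel, Trajectory or fit object
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname StructureModel-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname StructureModel-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Trajectory-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname Trajectory-class
#' @param i frame index
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname Trajectory-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

setMethod("atomTable", "StructureModel", function(x) x@atoms)
setMethod("coords", "StructureModel", function(x) x@coords)
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))
setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel (model", object@modelIndex, "):", nrow(a), "atoms,",
      length(unique(paste(a$chainId, a$resSeq, a$iCode))), "residues,",
      "chains:", paste(unique(a$chainId), collapse = " "), "\n")
})

setMethod("topology", "Trajectory", function(x) x@topology)
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2])
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])
setMethod("frameTimes", "Trajectory", function(x) x@times)
setMethod("frameCoords", "Trajectory", function(x, i) {
  stopifnot(length(i) == 1, i >= 1, i <= dim(x@coords)[1])
  m <- x@coords[i, , , drop = FALSE]
  dim(m) <- dim(x@coords)[2:3]
  m
})
setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nFrames(object), "frames x", nAtoms(object), "atoms,",
      "t =", min(object@times), "-", max(object@times), "ns\n")
})

setMethod("show", "ContactDefinition", function(object) {
  cat(sprintf("Contact %s: %s:%d%s[%s] -- %s:%d%s[%s], threshold %.2f A\n",
              object@label, object@chainA, object@resA, object@iCodeA,
              object@atomA, object@chainB, object@resB, object@iCodeB,
              object@atomB, object@threshold))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat("SuperpositionResult: rmsd =", format(object@rmsd, digits = 6), "A\n")
})

#' @rdname SuperpositionResult-class
#' @param x a SuperpositionResult
#' @export
setGeneric("rotationMatrix", function(x) standardGeneric("rotationMatrix"))
setMethod("rotationMatrix", "SuperpositionResult", function(x) x@rotation)

#' @rdname SuperpositionResult-class
#' @export
setGeneric("translationVector", function(x) standardGeneric("translationVector"))
setMethod("translationVector", "SuperpositionResult", function(x) x@translation)

#' @rdname SuperpositionResult-class
#' @export
setGeneric("rmsdValue", function(x) standardGeneric("rmsdValue"))
setMethod("rmsdValue", "SuperpositionResult", function(x) x@rmsd)

#' @rdname KineticFit-class
#' @param x a KineticFit
#' @export
setGeneric("konRate", function(x) standardGeneric("konRate"))
setMethod("konRate", "KineticFit", function(x) x@kon)

#' @rdname KineticFit-class
#' @export
setGeneric("koffRate", function(x) standardGeneric("koffRate"))
setMethod("koffRate", "KineticFit", function(x) x@koff)

#' @rdname KineticFit-class
#' @export
setGeneric("kdValue", function(x) standardGeneric("kdValue"))
setMethod("kdValue", "KineticFit", function(x) x@kd)

#' @rdname KineticFit-class
#' @export
setGeneric("rmaxValue", function(x) standardGeneric("rmaxValue"))
setMethod("rmaxValue", "KineticFit", function(x) x@rmax)

#' @rdname KineticFit-class
#' @export
setGeneric("fitSD", function(x) standardGeneric("fitSD"))
setMethod("fitSD", "KineticFit", function(x) x@sd)
setMethod("fitSD", "VantHoffFit", function(x) x@sd)

setMethod("show", "KineticFit", function(object) {
  cat(sprintf(paste0("KineticFit (1:1 Langmuir, global):\n",
      "  kon  = %.4g +/- %.2g 1/(M s)\n  koff = %.4g +/- %.2g 1/s\n",
      "  Rmax = %.4g +/- %.2g RU\n  KD   = %.4g +/- %.2g M (%.1f nM)\n",
      "  RSS  = %.4g over %d points\n"),
      object@kon, object@sd["kon"], object@koff, object@sd["koff"],
      object@rmax, object@sd["rmax"], object@kd, object@sd["kd"],
      object@kd * 1e9, object@rss, object@nObs))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

#' @rdname VantHoffFit-class
#' @param x a VantHoffFit
#' @export
setGeneric("enthalpy", function(x) standardGeneric("enthalpy"))
setMethod("enthalpy", "VantHoffFit", function(x) x@dH)

#' @rdname VantHoffFit-class
#' @export
setGeneric("entropy", function(x) standardGeneric("entropy"))
setMethod("entropy", "VantHoffFit", function(x) x@dS)

#' @rdname VantHoffFit-class
#' @export
setGeneric("freeEnergy", function(x) standardGeneric("freeEnergy"))
setMethod("freeEnergy", "VantHoffFit", function(x) x@dG)

setMethod("show", "VantHoffFit", function(object) {
  cat(sprintf(paste0("VantHoffFit (ln KD = dH/RT - dS/R, %d temperatures):\n",
      "  dH = %.3f +/- %.3f kJ/mol\n  dS = %.5f +/- %.5f kJ/(mol K)\n",
      "  dG(%.1f K) = %.3f +/- %.3f kJ/mol\n"),
      object@nT, object@dH, object@sd["dH"], object@dS, object@sd["dS"],
      object@refT, object@dG, object@sd["dG"]))
})

#' @rdname TmResult-class
#' @param x a TmResult
#' @export
setGeneric("tmValue", function(x) standardGeneric("tmValue"))
setMethod("tmValue", "TmResult", function(x) x@tmApp)

setMethod("show", "TmResult", function(object) {
  cat(sprintf("TmResult: Tm,app = %.2f C (%d peak%s%s)\n", object@tmApp,
              object@nPeaks, if (object@nPeaks == 1) "" else "s",
              if (object@multiPeak) ", multi-peak flagged" else ""))
})
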