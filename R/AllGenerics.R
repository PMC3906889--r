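# Accessor generics and show methods. Slots are never reached into by user
# code; every documented field has an accessor.

#' @rdname CultureSeries-class
#' @param object a package object.
#' @export
setGeneric("cultureId", function(object) standardGeneric("cultureId"))
#' @rdname CultureSeries-class
#' @export
setGeneric("obsTimes", function(object) standardGeneric("obsTimes"))
#' @rdname CultureSeries-class
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

setMethod("cultureId", "CultureSeries", function(object) object@cultureId)
setMethod("obsTimes", "CultureSeries", function(object) object@times)
setMethod("intensities", "CultureSeries", function(object) object@intensities)

setMethod("show", "CultureSeries", function(object) {
  cat(sprintf(
    "CultureSeries '%s': %d points, t = [%g, %g] h, intensity range [%g, %g]\n",
    object@cultureId, length(object@times),
    min(object@times), max(object@times),
    min(object@intensities), max(object@intensities)
  ))
})

#' @rdname GrowthFit-class
#' @param object a package object.
#' @export
setGeneric("capacity", function(object) standardGeneric("capacity"))
#' @rdname GrowthFit-class
#' @export
setGeneric("rate", function(object) standardGeneric("rate"))
#' @rdname GrowthFit-class
#' @export
setGeneric("halfTime", function(object) standardGeneric("halfTime"))
#' @rdname GrowthFit-class
#' @export
setGeneric("baseline", function(object) standardGeneric("baseline"))
#' @rdname GrowthFit-class
#' @export
setGeneric("aucValue", function(object) standardGeneric("aucValue"))
#' @rdname GrowthFit-class
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname GrowthFit-class
#' @export
setGeneric("grew", function(object) standardGeneric("grew"))
#' @rdname GrowthFit-class
#' @export
setGeneric("confint95", function(object) standardGeneric("confint95"))

setMethod("capacity", "GrowthFit", function(object) object@K)
setMethod("rate", "GrowthFit", function(object) object@r)
setMethod("halfTime", "GrowthFit", function(object) object@L)
setMethod("baseline", "GrowthFit", function(object) object@baseline)
setMethod("aucValue", "GrowthFit", function(object) object@auc)
setMethod("rSquared", "GrowthFit", function(object) object@rSquared)
setMethod("grew", "GrowthFit", function(object) object@grew)
setMethod("confint95", "GrowthFit", function(object) {
  rbind(lower = object@ciLower, upper = object@ciUpper)
})
setMethod("cultureId", "GrowthFit", function(object) object@cultureId)

setMethod("show", "GrowthFit", function(object) {
  if (object@grew) {
    cat(sprintf(
      "GrowthFit '%s': K = %.4g, r = %.4g /h, L = %.4g h, AUC = %.5g, R2 = %.4f\n",
      object@cultureId, object@K, object@r, object@L, object@auc, object@rSquared
    ))
  } else {
    cat(sprintf("GrowthFit '%s': no growth (converged = %s)\n",
      object@cultureId, object@converged))
  }
})

#' @rdname DoseResponse-class
#' @param object a package object.
#' @export
setGeneric("doses", function(object) standardGeneric("doses"))
#' @rdname DoseResponse-class
#' @export
setGeneric("lValues", function(object) standardGeneric("lValues"))
#' @rdname DoseResponse-class
#' @export
setGeneric("strainId", function(object) standardGeneric("strainId"))

setMethod("strainId", "DoseResponse", function(object) object@strainId)
setMethod("doses", "DoseResponse", function(object) object@doses)
setMethod("lValues", "DoseResponse", function(object) object@L)
setMethod("grew", "DoseResponse", function(object) object@grew)

setMethod("show", "DoseResponse", function(object) {
  cat(sprintf("DoseResponse '%s' over %d doses (%d grown)\n",
    object@strainId, length(object@doses), sum(object@grew)))
})

#' @rdname ReferenceModel-class
#' @param object a package object.
#' @export
setGeneric("centralL", function(object) standardGeneric("centralL"))
#' @rdname ReferenceModel-class
#' @export
setGeneric("referenceBand", function(object) standardGeneric("referenceBand"))
#' @rdname ReferenceModel-class
#' @export
setGeneric("nReplicates", function(object) standardGeneric("nReplicates"))

setMethod("doses", "ReferenceModel", function(object) object@doses)
setMethod("centralL", "ReferenceModel", function(object) object@central)
setMethod("referenceBand", "ReferenceModel", function(object) {
  rbind(low = object@bandLow, high = object@bandHigh)
})
setMethod("nReplicates", "ReferenceModel", function(object) object@nReplicates)

setMethod("show", "ReferenceModel", function(object) {
  cat(sprintf(
    "ReferenceModel (%s of reference L) over doses %s; n = %s\n",
    object@center, paste(object@doses, collapse = ", "),
    paste(object@nReplicates, collapse = ", ")
  ))
})

#' @rdname InteractionResult-class
#' @param object a package object.
#' @export
setGeneric("orfEffect", function(object) standardGeneric("orfEffect"))
#' @rdname InteractionResult-class
#' @export
setGeneric("interactionValue", function(object) standardGeneric("interactionValue"))
#' @rdname InteractionResult-class
#' @export
setGeneric("quadCoef", function(object) standardGeneric("quadCoef"))
#' @rdname InteractionResult-class
#' @export
setGeneric("tier", function(object) standardGeneric("tier"))
#' @rdname InteractionResult-class
#' @export
setGeneric("interactionClass", function(object) standardGeneric("interactionClass"))
#' @rdname InteractionResult-class
#' @export
setGeneric("adjustedResponse", function(object) standardGeneric("adjustedResponse"))
#' @rdname InteractionResult-class
#' @export
setGeneric("dMaxScored", function(object) standardGeneric("dMaxScored"))
#' @rdname InteractionResult-class
#' @export
setGeneric("flags", function(object) standardGeneric("flags"))

setMethod("strainId", "InteractionResult", function(object) object@strainId)
setMethod("orfEffect", "InteractionResult", function(object) object@K0)
setMethod("interactionValue", "InteractionResult", function(object) object@INT)
setMethod("quadCoef", "InteractionResult", function(object) object@coef)
setMethod("tier", "InteractionResult", function(object) object@tier)
setMethod("interactionClass", "InteractionResult", function(object) object@intClass)
setMethod("dMaxScored", "InteractionResult", function(object) object@dMaxScored)
setMethod("flags", "InteractionResult", function(object) object@qcFlags)
setMethod("adjustedResponse", "InteractionResult", function(object) {
  data.frame(dose = object@adjustedDoses, L = object@adjustedL)
})

setMethod("show", "InteractionResult", function(object) {
  cat(sprintf(
    "InteractionResult '%s': K0 = %.3g h, INT = %.3g h at D = %g, tier = %d%s\n",
    object@strainId, object@K0, object@INT, object@dMaxScored, object@tier,
    if (!is.na(object@intClass)) sprintf(", class = %s", object@intClass) else ""
  ))
})

setMethod("show", "Thresholds", function(object) {
  cat(sprintf("Thresholds: enhancer INT > %g, suppressor INT < %g\n",
    object@enhancerCut, object@suppressorCut))
})

#' @rdname InteractionProfiles-class
#' @param object a package object.
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))
#' @rdname InteractionProfiles-class
#' @export
setGeneric("profileMask", function(object) standardGeneric("profileMask"))
#' @rdname InteractionProfiles-class
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

setMethod("profileValues", "InteractionProfiles", function(object) object@values)
setMethod("profileMask", "InteractionProfiles", function(object) object@mask)
setMethod("geneIds", "InteractionProfiles", function(object) rownames(object@values))

setMethod("show", "InteractionProfiles", function(object) {
  cat(sprintf("InteractionProfiles: %d genes x %d columns (%d masked values)\n",
    nrow(object@values), ncol(object@values), sum(!object@mask)))
})

#' @rdname ClusterNode-class
#' @param object a package object.
#' @export
setGeneric("clusterName", function(object) standardGeneric("clusterName"))
#' @rdname ClusterNode-class
#' @export
setGeneric("members", function(object) standardGeneric("members"))
#' @rdname ClusterNode-class
#' @export
setGeneric("children", function(object) standardGeneric("children"))
#' @rdname ClusterNode-class
#' @export
setGeneric("clusterLogLik", function(object) standardGeneric("clusterLogLik"))
#' @rdname ClusterNode-class
#' @export
setGeneric("leaves", function(object) standardGeneric("leaves"))

setMethod("clusterName", "ClusterNode", function(object) object@name)
setMethod("members", "ClusterNode", function(object) object@members)
setMethod("children", "ClusterNode", function(object) object@children)
setMethod("clusterLogLik", "ClusterNode", function(object) object@logLik)
setMethod("leaves", "ClusterNode", function(object) {
  if (!length(object@children)) return(list(object))
  do.call(c, lapply(object@children, leaves))
})

setMethod("show", "ClusterNode", function(object) {
  nl <- length(leaves(object))
  cat(sprintf("ClusterNode '%s': %d genes, logLik = %.3f, %d leaf cluster%s\n",
    object@name, length(object@members), object@logLik, nl,
    if (nl == 1L) "" else "s"))
})

#' @rdname PlateStack-class
#' @param object a package object.
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname PlateStack-class
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

setMethod("frames", "PlateStack", function(object) object@frames)
setMethod("frameTimes", "PlateStack", function(object) object@frameTimes)

setMethod("show", "PlateStack", function(object) {
  d <- if (length(object@frames)) dim(object@frames[[1L]]) else c(0L, 0L)
  cat(sprintf("PlateStack: %d frames of %d x %d px, grid %d x %d, pitch %g px\n",
    length(object@frames), d[1L], d[2L],
    object@gridRows, object@gridCols, object@pitch))
})
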