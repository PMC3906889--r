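#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Single-culture growth time series
#'
#' Holds one spot culture's background-subtracted pixel-density trajectory.
#' Times are in hours and must be strictly increasing; intensities are in
#' arbitrary image units and may contain small noise-driven negatives.
#'
#' @slot cultureId character scalar identifying the culture.
#' @slot times numeric vector of observation times (hours).
#' @slot intensities numeric vector, same length as `times`.
#'
#' @examples
#' cs <- CultureSeries("orf1", 0:10 * 4, 100 / (1 + exp(-0.4 * (0:10 * 4 - 24))))
#' obsTimes(cs)
#' @export
setClass("CultureSeries",
  representation(
    cultureId = "character",
    times = "numeric",
    intensities = "numeric"
  )
)

setValidity("CultureSeries", function(object) {
  msg <- character()
  if (length(object@cultureId) != 1L) msg <- c(msg, "cultureId must be a single string")
  if (length(object@times) != length(object@intensities))
    msg <- c(msg, "times and intensities must have equal length")
  if (length(object@times) < 4L)
    msg <- c(msg, "at least 4 time points are required")
  if (anyNA(object@times) || any(object@times < 0))
    msg <- c(msg, "times must be non-negative and non-missing")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname CultureSeries-class
#' @param cultureId culture identifier.
#' @param times observation times (hours), strictly increasing.
#' @param intensities background-subtracted spot densities.
#' @export
CultureSeries <- function(cultureId, times, intensities) {
  new("CultureSeries",
    cultureId = as.character(cultureId),
    times = as.numeric(times),
    intensities = as.numeric(intensities)
  )
}

#' Logistic growth-curve fit
#'
#' Result of fitting `G(t) = baseline + K / (1 + exp(-r * (t - L)))` to one
#' [CultureSeries]. When `grew` is `FALSE` the parameters `K`, `r`, `L`, the
#' AUC and the confidence bounds are `NA`.
#'
#' @slot cultureId culture identifier.
#' @slot K carrying capacity above baseline (intensity units).
#' @slot r maximum specific rate (1/hour).
#' @slot L time to half carrying capacity (hours).
#' @slot baseline additive offset (intensity units).
#' @slot auc area under the fitted curve, baseline excluded, over the
#'   observation window (intensity x hours).
#' @slot rSquared coefficient of determination of the fit.
#' @slot ciLower,ciUpper named numeric vectors (`K`, `r`, `L`) with symmetric
#'   95% bounds from the curvature of the objective at the optimum.
#' @slot grew logical growth flag (see [detectNoGrowth]).
#' @slot converged logical; `FALSE` when the optimizer failed.
#' @export
setClass("GrowthFit",
  representation(
    cultureId = "character",
    K = "numeric", r = "numeric", L = "numeric",
    baseline = "numeric", auc = "numeric", rSquared = "numeric",
    ciLower = "numeric", ciUpper = "numeric",
    grew = "logical", converged = "logical"
  )
)

setValidity("GrowthFit", function(object) {
  msg <- character()
  for (s in c("K", "r", "L", "baseline", "auc", "rSquared", "grew", "converged"))
    if (length(slot(object, s)) != 1L) msg <- c(msg, sprintf("%s must be scalar", s))
  if (isTRUE(object@grew)) {
    if (!is.na(object@K) && object@K < 0) msg <- c(msg, "K must be >= 0")
    if (!is.na(object@auc) && object@auc < 0) msg <- c(msg, "auc must be >= 0 when grew")
  }
  if (!is.na(object@rSquared) && object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Per-strain dose response
#'
#' The fitted `L` value of one strain across the oligomycin ladder, with a
#' growth flag per dose. `L` is `NA` exactly where `grew` is `FALSE`.
#'
#' @slot strainId strain identifier.
#' @slot doses oligomycin concentrations (ug/mL), strictly increasing, first 0.
#' @slot L fitted time-to-half-capacity per dose (hours), `NA` where censored.
#' @slot grew logical vector per dose.
#' @export
setClass("DoseResponse",
  representation(
    strainId = "character",
    doses = "numeric",
    L = "numeric",
    grew = "logical"
  )
)

setValidity("DoseResponse", function(object) {
  msg <- character()
  n <- length(object@doses)
  if (length(object@L) != n || length(object@grew) != n)
    msg <- c(msg, "doses, L, grew must have equal length")
  if (n == 0L || object@doses[1L] != 0)
    msg <- c(msg, "dose ladder must start at 0")
  if (n > 1L && any(diff(object@doses) <= 0))
    msg <- c(msg, "doses must be strictly increasing")
  if (!all(is.na(object@L) == !object@grew))
    msg <- c(msg, "L must be present exactly where grew is TRUE")
  if (length(msg)) msg else TRUE
})

#' @rdname DoseResponse-class
#' @param strainId strain identifier.
#' @param doses oligomycin ladder (ug/mL), starting at 0.
#' @param L fitted L per dose; `NA` marks no growth.
#' @param grew optional logical per dose; defaults to `!is.na(L)`.
#' @export
DoseResponse <- function(strainId, doses, L, grew = !is.na(L)) {
  new("DoseResponse",
    strainId = as.character(strainId), doses = as.numeric(doses),
    L = as.numeric(L), grew = as.logical(grew)
  )
}

#' Reference-strain dose-response model
#'
#' Central tendency and central-95% band of the replicated single-mutant
#' reference at each dose, computed over grown replicates only.
#'
#' @slot doses oligomycin ladder (ug/mL).
#' @slot central per-dose central tendency of reference L (hours).
#' @slot bandLow,bandHigh per-dose empirical 2.5 and 97.5 percentiles.
#' @slot nReplicates grown replicates used per dose.
#' @slot center `"median"` or `"mean"`.
#' @export
setClass("ReferenceModel",
  representation(
    doses = "numeric", central = "numeric",
    bandLow = "numeric", bandHigh = "numeric",
    nReplicates = "integer", center = "character"
  )
)

setValidity("ReferenceModel", function(object) {
  msg <- character()
  n <- length(object@doses)
  for (s in c("central", "bandLow", "bandHigh"))
    if (length(slot(object, s)) != n) msg <- c(msg, sprintf("%s length mismatch", s))
  if (!length(msg) && n &&
      !all(object@bandLow <= object@central & object@central <= object@bandHigh))
    msg <- c(msg, "band must bracket the central tendency at every dose")
  if (length(msg)) msg else TRUE
})

#' Gene-interaction score for one strain
#'
#' Output of the five-step dose-response scoring: knockout effect at zero
#' dose (`K0`, the "ORF effect"), quadratic coefficients of the adjusted
#' response, the interaction value `INT` evaluated at the highest dose with
#' measurable growth, the no-growth tier, class and quality flags.
#'
#' @slot strainId strain identifier.
#' @slot K0 knockout effect at zero dose (hours).
#' @slot coef named numeric `(A, B, C)` of the quadratic fit (hours,
#'   hours*mL/ug, hours*mL^2/ug^2); `NA` when fewer than 3 doses grew.
#' @slot INT interaction value at `dMaxScored` (hours).
#' @slot dMaxScored highest dose with measurable growth (ug/mL).
#' @slot tier number of doses with no growth (deletion-enhancer strength).
#' @slot quadR2 coefficient of determination of the quadratic fit.
#' @slot class one of `"deletion_enhancer"`, `"deletion_suppressor"`, `"none"`,
#'   or `NA` before classification.
#' @slot qcFlags character vector of named quality flags (see [qcFlags]).
#' @slot adjustedL adjusted response `L_i` at each grown dose (hours); exactly
#'   0 at dose 0.
#' @slot adjustedDoses doses corresponding to `adjustedL`.
#' @export
setClass("InteractionResult",
  representation(
    strainId = "character",
    K0 = "numeric", coef = "numeric", INT = "numeric",
    dMaxScored = "numeric", tier = "integer", quadR2 = "numeric",
    intClass = "character", qcFlags = "character",
    adjustedL = "numeric", adjustedDoses = "numeric"
  )
)

setValidity("InteractionResult", function(object) {
  msg <- character()
  if (length(object@tier) != 1L || object@tier < 0L)
    msg <- c(msg, "tier must be a single non-negative integer")
  if (length(object@adjustedL) != length(object@adjustedDoses))
    msg <- c(msg, "adjustedL and adjustedDoses length mismatch")
  if (!is.na(object@INT) && !is.na(object@intClass)) {
    if (object@INT > 0 && object@intClass == "deletion_suppressor")
      msg <- c(msg, "positive INT cannot be a deletion_suppressor")
    if (object@INT < 0 && object@intClass == "deletion_enhancer")
      msg <- c(msg, "negative INT cannot be a deletion_enhancer")
  }
  if (length(msg)) msg else TRUE
})

#' Interaction classification thresholds
#'
#' Strict-inequality cutoffs on the interaction value: `INT > enhancerCut`
#' calls a deletion enhancer, `INT < suppressorCut` a deletion suppressor.
#' The screen of the misfolded-allele background used `(>10, <-16)`; the
#' wild-type background screen used `(>10, <-12)`.
#'
#' @slot enhancerCut positive cutoff (hours).
#' @slot suppressorCut negative cutoff (hours).
#' @export
setClass("Thresholds",
  representation(enhancerCut = "numeric", suppressorCut = "numeric")
)

setValidity("Thresholds", function(object) {
  if (length(object@enhancerCut) != 1L || length(object@suppressorCut) != 1L)
    return("cuts must be scalar")
  if (!(object@enhancerCut > 0 && object@suppressorCut < 0))
    return("enhancerCut must be > 0 and suppressorCut < 0")
  TRUE
})

#' @rdname Thresholds-class
#' @param enhancerCut minimum INT (exclusive) for an enhancer call.
#' @param suppressorCut maximum INT (exclusive) for a suppressor call.
#' @export
Thresholds <- function(enhancerCut = 10, suppressorCut = -16) {
  new("Thresholds", enhancerCut = enhancerCut, suppressorCut = suppressorCut)
}

#' Gene interaction profiles over perturbation columns
#'
#' A genes x conditions matrix of interaction values over the fixed 15-column
#' schema (see [profileSchema]): the misfolded-allele screen (A), the
#' wild-type screen (B), control growth (C), and twelve gene-drug conditions
#' (D-O). `mask` is `TRUE` where a value was observed; masked entries are
#' imputed to column medians before clustering.
#'
#' @slot values numeric matrix, rownames = gene ids, colnames = schema labels.
#' @slot mask logical matrix, same shape; `TRUE` = observed.
#' @export
setClass("InteractionProfiles",
  representation(values = "matrix", mask = "matrix")
)

setValidity("InteractionProfiles", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must have identical dimensions")
  if (is.null(rownames(object@values)))
    msg <- c(msg, "values must have gene ids as rownames")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "values must have schema labels as colnames")
  obs <- object@values[object@mask]
  if (length(obs) && any(!is.finite(obs)))
    msg <- c(msg, "unmasked values must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname InteractionProfiles-class
#' @param values genes x columns numeric matrix.
#' @param mask logical matrix marking observed entries; defaults to
#'   `is.finite(values)`.
#' @export
InteractionProfiles <- function(values, mask = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- is.finite(values)
  new("InteractionProfiles", values = values, mask = mask)
}

#' Node of a recursive clustering tree
#'
#' One cluster produced by recursive EM clustering. `name` encodes round and
#' lineage (root `"1-0"`, its children `"2-0.<j>"`, and so on); children
#' partition the parent's members; leaves are the final clusters.
#'
#' @slot name hierarchical cluster label.
#' @slot members gene ids in this cluster.
#' @slot logLik sum of member log mixture densities under the fit that
#'   produced this cluster (cluster-quality indicator).
#' @slot children list of child `ClusterNode`s (empty at leaves).
#' @export
setClass("ClusterNode",
  representation(
    name = "character", members = "character",
    logLik = "numeric", children = "list"
  )
)

setValidity("ClusterNode", function(object) {
  msg <- character()
  if (length(object@members) == 0L) msg <- c(msg, "node must have members")
  if (length(object@children)) {
    kids <- unlist(lapply(object@children, function(ch) ch@members))
    if (!setequal(kids, object@members) || length(kids) != length(object@members))
      msg <- c(msg, "children must partition the parent's members")
  }
  if (length(msg)) msg else TRUE
})

#' Time-lapse plate image stack
#'
#' Ordered grayscale frames of a spotted plate with the grid geometry needed
#' to quantify each spot: `grid` rows x cols (default 16 x 24 = 384 spots),
#' spot pitch and the pixel position of the first spot's center.
#'
#' @slot frames list of numeric matrices (one per time point), equal shapes.
#' @slot frameTimes hours per frame, strictly increasing.
#' @slot gridRows,gridCols spot layout.
#' @slot pitch nominal spot pitch in pixels.
#' @slot originRow,originCol pixel coordinates (row, col) of spot (0, 0).
#' @export
setClass("PlateStack",
  representation(
    frames = "list", frameTimes = "numeric",
    gridRows = "integer", gridCols = "integer",
    pitch = "numeric", originRow = "numeric", originCol = "numeric"
  )
)

setValidity("PlateStack", function(object) {
  msg <- character()
  if (length(object@frames) != length(object@frameTimes))
    msg <- c(msg, "one frame time per frame required")
  if (length(object@frameTimes) > 1L && any(diff(object@frameTimes) <= 0))
    msg <- c(msg, "frameTimes must be strictly increasing")
  dims <- unique(lapply(object@frames, dim))
  if (length(dims) > 1L) msg <- c(msg, "all frames must share one shape")
  if (length(object@frames) && !length(msg)) {
    d <- dims[[1L]]
    maxR <- object@originRow + (object@gridRows - 1L) * object@pitch
    maxC <- object@originCol + (object@gridCols - 1L) * object@pitch
    if (maxR > d[1L] || maxC > d[2L] ||
        object@originRow < 1 || object@originCol < 1)
      msg <- c(msg, "grid does not fit within the frame bounds")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname PlateStack-class
#' @param frames list of grayscale matrices.
#' @param frameTimes acquisition times (hours).
#' @param gridRows,gridCols spot grid (default 16 x 24).
#' @param pitch spot pitch in pixels.
#' @param originRow,originCol pixel center of spot (0, 0).
#' @export
PlateStack <- function(frames, frameTimes, gridRows = 16L, gridCols = 24L,
                       pitch, originRow, originCol) {
  new("PlateStack",
    frames = frames, frameTimes = as.numeric(frameTimes),
    gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
    pitch = as.numeric(pitch),
    originRow = as.numeric(originRow), originCol = as.numeric(originCol)
  )
}
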