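# Dose-response gene-interaction scoring. For each double-mutant strain the
# observed growth parameter Y_i (the logistic L, hours) at oligomycin dose
# D_i is compared to a replicated single-mutant reference:
#   1. reference central tendency per dose: RD_i
#   2. remove the reference dose effect:    K_i = Y_i - RD_i
#   3. remove the knockout main effect:     L_i = K_i - K_0   (so L_0 = 0)
#   4. quadratic fit:                       L_i = A + B*D_i + C*D_i^2
#   5. interaction value at the highest grown dose:
#                                           INT = A + B*Dmax + C*Dmax^2
# Doses with no measurable growth are excluded from the fit; their count is
# the strain's tier (stronger deletion enhancers have higher tiers).

#' Build the reference dose-response model
#'
#' Summarizes the replicated single-mutant reference per dose: the central
#' tendency (median by default, robust to censoring and outliers; mean
#' available) and the empirical central-95% band, computed over grown
#' replicates only.
#'
#' @param replicates data.frame with columns `dose` and `L` (`NA` where the
#'   replicate did not grow), one row per replicate culture and dose.
#' @param center `"median"` (default) or `"mean"`.
#' @return a [ReferenceModel].
#' @export
buildReference <- function(replicates, center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(all(c("dose", "L") %in% names(replicates)))
  ds <- sort(unique(replicates$dose))
  centralFun <- if (center == "median") stats::median else mean
  central <- bandLow <- bandHigh <- numeric(length(ds))
  n <- integer(length(ds))
  for (i in seq_along(ds)) {
    x <- replicates$L[replicates$dose == ds[i]]
    x <- x[!is.na(x)]
    if (length(x) < 2L)
      stop("fewer than 2 grown reference replicates at dose ", ds[i])
    central[i] <- centralFun(x)
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    bandLow[i] <- q[1L]; bandHigh[i] <- q[2L]
    n[i] <- length(x)
  }
  new("ReferenceModel",
    doses = ds, central = central, bandLow = bandLow, bandHigh = bandHigh,
    nReplicates = n, center = center)
}

#' Score one strain's gene interaction over the dose ladder
#'
#' Applies the five-step scoring (see the package vignette): subtracts the
#' reference dose effect and the strain's zero-dose knockout effect from its
#' `L` response, fits a free-intercept quadratic in dose over the grown
#' doses (the dose-0 point, exactly 0 by construction, included), and
#' evaluates it at the highest dose with measurable growth. Doses without
#' growth are excluded, never imputed; their count is the tier.
#'
#' @param dr a [DoseResponse]; dose 0 must have grown.
#' @param ref a [ReferenceModel] on the same dose ladder.
#' @return an [InteractionResult] (unclassified; see [classifyInteraction]).
#'   With fewer than 3 grown doses `INT` and the coefficients are `NA` but
#'   the tier is still set, so the strain remains rankable.
#' @examples
#' ref <- buildReference(data.frame(
#'   dose = rep(c(0, 0.1, 0.2), each = 5),
#'   L = rep(c(30, 33, 38), each = 5)))
#' dr <- DoseResponse("ex", c(0, 0.1, 0.2), c(32, 37, 44))
#' interactionValue(scoreInteraction(dr, ref))
#' @export
scoreInteraction <- function(dr, ref) {
  stopifnot(is(dr, "DoseResponse"), is(ref, "ReferenceModel"))
  validObject(dr)
  if (!isTRUE(all.equal(dr@doses, ref@doses)))
    stop("strain '", dr@strainId, "' and reference use different dose ladders")
  if (!dr@grew[1L])
    stop("strain '", dr@strainId,
         "': no growth at dose 0; interaction undefined")

  gi <- dr@grew
  Ki <- dr@L[gi] - ref@central[gi]      # dose effect removed
  K0 <- Ki[1L]                          # knockout main effect (dose 0 grew)
  Li <- Ki - K0                         # L_0 = 0 exactly
  Di <- dr@doses[gi]
  tier <- sum(!gi)
  dMax <- max(Di)

  if (sum(gi) < 3L) {
    return(new("InteractionResult",
      strainId = dr@strainId, K0 = K0,
      coef = c(A = NA_real_, B = NA_real_, C = NA_real_),
      INT = NA_real_, dMaxScored = dMax, tier = as.integer(tier),
      quadR2 = NA_real_, intClass = NA_character_, qcFlags = character(),
      adjustedL = Li, adjustedDoses = Di))
  }

  fit <- stats::lm(Li ~ Di + I(Di^2))
  cf <- stats::setNames(unname(stats::coef(fit)), c("A", "B", "C"))
  INT <- unname(cf["A"] + cf["B"] * dMax + cf["C"] * dMax^2)
  sst <- sum((Li - mean(Li))^2)
  quadR2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1

  new("InteractionResult",
    strainId = dr@strainId, K0 = K0, coef = cf, INT = INT,
    dMaxScored = dMax, tier = as.integer(tier), quadR2 = quadR2,
    intClass = NA_character_, qcFlags = character(),
    adjustedL = Li, adjustedDoses = Di)
}

#' Classify an interaction as enhancer, suppressor or neither
#'
#' Strict-inequality calls: deletion enhancer when `INT > enhancerCut`, or
#' when `INT` could not be computed but the strain failed to grow at one or
#' more doses (tiered enhancer); deletion suppressor when
#' `INT < suppressorCut`; otherwise `"none"`.
#'
#' @param res an [InteractionResult].
#' @param th a [Thresholds].
#' @return the input with its `class` filled in.
#' @export
classifyInteraction <- function(res, th = Thresholds()) {
  stopifnot(is(res, "InteractionResult"), is(th, "Thresholds"))
  cls <- if (is.na(res@INT)) {
    if (res@tier > 0L) "deletion_enhancer" else "none"
  } else if (res@INT > th@enhancerCut) {
    "deletion_enhancer"
  } else if (res@INT < th@suppressorCut) {
    "deletion_suppressor"
  } else "none"
  res@intClass <- cls
  res
}

#' Collect interaction results into a table
#'
#' @param results list of [InteractionResult].
#' @return data.frame with one row per strain: `strain`, `K0`, `A`, `B`,
#'   `C`, `INT`, `d_max`, `tier`, `quad_r2`, `class`, `qc_flags`
#'   (comma-joined), `high_confidence`.
#' @export
interactionTable <- function(results) {
  out <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      strain = r@strainId, K0 = r@K0,
      A = r@coef[["A"]], B = r@coef[["B"]], C = r@coef[["C"]],
      INT = r@INT, d_max = r@dMaxScored, tier = r@tier,
      quad_r2 = r@quadR2, class = r@intClass,
      qc_flags = paste(r@qcFlags, collapse = ","),
      high_confidence = length(r@qcFlags) == 0L &&
        !is.na(r@intClass) && r@intClass != "none"
    )
  }))
  rownames(out) <- NULL
  out
}

#' Rank interactions from strongest enhancer to strongest suppressor
#'
#' Primary key: tier, descending (strains failing to grow at more doses are
#' the stronger deletion enhancers). Secondary key: `INT`, descending, with
#' non-computable `INT` (fewer than 3 grown doses) treated as larger than
#' any scored value within its tier. Ties broken by strain id, so the order
#' is deterministic.
#'
#' @param tbl data.frame from [interactionTable] (needs `tier`, `INT`,
#'   `strain`).
#' @return the table, reordered.
#' @export
rankInteractions <- function(tbl) {
  key <- ifelse(is.na(tbl$INT), Inf, tbl$INT)
  tbl[order(-tbl$tier, -key, tbl$strain), , drop = FALSE]
}

#' Single-condition gene-drug interaction score
#'
#' For perturbations tested at too few concentrations to fit a quadratic,
#' the interaction is the difference in `L` between the deletion and the
#' reference strain on the drug, adjusted for the drug's dose effect on the
#' reference and for the deletion's effect on growth in the control media:
#' `(deletionL - referenceL) - (deletionControlL - referenceControlL)`.
#' All arguments are vectorized.
#'
#' @param deletionL,referenceL fitted `L` on the drug media (hours).
#' @param deletionControlL,referenceControlL fitted `L` on the control
#'   media (hours).
#' @return score in hours; `NA` where any input culture did not grow
#'   (input `NA`).
#' @export
geneDrugScore <- function(deletionL, deletionControlL,
                          referenceL, referenceControlL) {
  (deletionL - referenceL) - (deletionControlL - referenceControlL)
}

#' Interaction-score correlation across overlapping-ORF pairs
#'
#' Deletions of overlapping open reading frames disrupt the same genomic
#' region, so their interaction scores should agree; their correlation is a
#' reproducibility diagnostic for the screen.
#'
#' @param intA,intB interaction values (`INT`) of the two members of each
#'   pair, aligned.
#' @param ids optional pair identifiers.
#' @return list with `correlation` (Pearson, complete pairs) and `table`
#'   (the paired scatter table with an `complete` flag).
#' @export
overlapOrfCorrelation <- function(intA, intB, ids = seq_along(intA)) {
  stopifnot(length(intA) == length(intB))
  complete <- !is.na(intA) & !is.na(intB)
  if (sum(complete) < 3L)
    stop("need at least 3 pairs with defined interaction values; got ",
         sum(complete))
  list(
    correlation = stats::cor(intA[complete], intB[complete]),
    table = data.frame(pair = ids, int_orf = intA, int_overlap = intB,
                       complete = complete)
  )
}

#' Quality-control configuration for interaction calls
#'
#' @param k0Max flag `large_zero_dose_effect` when `|K0|` exceeds this (hours).
#' @param quadR2Min flag `poor_quadratic_fit` when the quadratic R-squared
#'   falls below this.
#' @param plateauSlopeMin flag `plateau_response` when the fitted slope at
#'   the top scored dose, `B + 2*C*d_max`, has magnitude below this
#'   (hours x mL/ug) while `|INT|` exceeds `plateauIntMin`.
#' @param plateauIntMin see `plateauSlopeMin` (hours).
#' @param weakIntMax flag `weak_effect` when `|INT|` falls below this (hours).
#' @return a list of class `qcConfig`.
#' @export
qcConfig <- function(k0Max = 10, quadR2Min = 0.8,
                     plateauSlopeMin = 5, plateauIntMin = 10,
                     weakIntMax = 5) {
  structure(
    list(k0Max = k0Max, quadR2Min = quadR2Min,
         plateauSlopeMin = plateauSlopeMin, plateauIntMin = plateauIntMin,
         weakIntMax = weakIntMax),
    class = "qcConfig"
  )
}

#' Quality flags for an interaction call
#'
#' Automates the screen's low-confidence exclusion criteria: a large effect
#' of the deletion on growth without drug, an interaction already present in
#' the companion wild-type-context screen, a dose response poorly fit by the
#' quadratic, an uncharacteristic plateauing dose response, and weak
#' effects. A call is high-confidence when it carries no flags and its class
#' is not `"none"`.
#'
#' @param res a scored [InteractionResult].
#' @param companion optional [InteractionResult] for the same deletion in
#'   the companion (wild-type-context) screen.
#' @param companionTh [Thresholds] applied to the companion screen.
#' @param cuts a [qcConfig].
#' @return the input with `qcFlags` filled in.
#' @export
qcFlags <- function(res, companion = NULL,
                    companionTh = Thresholds(10, -12), cuts = qcConfig()) {
  stopifnot(is(res, "InteractionResult"))
  fl <- character()
  if (!is.na(res@K0) && abs(res@K0) > cuts$k0Max)
    fl <- c(fl, "large_zero_dose_effect")
  if (!is.null(companion) && !is.na(companion@INT) &&
      (companion@INT > companionTh@enhancerCut ||
       companion@INT < companionTh@suppressorCut))
    fl <- c(fl, "wildtype_context_interaction")
  if (!is.na(res@quadR2) && res@quadR2 < cuts$quadR2Min)
    fl <- c(fl, "poor_quadratic_fit")
  if (!is.na(res@INT)) {
    slopeAtMax <- res@coef[["B"]] + 2 * res@coef[["C"]] * res@dMaxScored
    if (!is.na(slopeAtMax) && abs(slopeAtMax) < cuts$plateauSlopeMin &&
        abs(res@INT) > cuts$plateauIntMin)
      fl <- c(fl, "plateau_response")
    if (abs(res@INT) < cuts$weakIntMax)
      fl <- c(fl, "weak_effect")
  }
  res@qcFlags <- fl
  res
}

#' Score, classify and QC-flag a whole screen
#'
#' Convenience wrapper: runs [scoreInteraction], [classifyInteraction] and
#' [qcFlags] over a list of dose responses against one reference model.
#'
#' @param doseResponses list of [DoseResponse].
#' @param ref a [ReferenceModel].
#' @param th a [Thresholds] for this screen.
#' @param companions optional named list of companion-screen
#'   [InteractionResult]s, indexed by strain id.
#' @param companionTh [Thresholds] for the companion screen.
#' @param cuts a [qcConfig].
#' @return named list of [InteractionResult]s.
#' @export
scoreScreen <- function(doseResponses, ref, th = Thresholds(),
                        companions = NULL, companionTh = Thresholds(10, -12),
                        cuts = qcConfig()) {
  res <- lapply(doseResponses, function(dr) {
    r <- classifyInteraction(scoreInteraction(dr, ref), th)
    qcFlags(r, companion = companions[[dr@strainId]],
            companionTh = companionTh, cuts = cuts)
  })
  stats::setNames(res, vapply(res, strainId, character(1)))
}
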