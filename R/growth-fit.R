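#' Fitting configuration for logistic growth curves
#'
#' @param kMin no-growth carrying-capacity threshold (intensity units):
#'   a fit with `K < kMin` (strictly) is flagged as no growth.
#' @param kMinFrac when fitting a whole screen, `kMin` is replaced by
#'   `kMinFrac` times the plate-wide median fitted `K` (see [fitScreen]).
#' @param r2Min no-growth goodness-of-fit threshold: `rSquared < r2Min`
#'   flags no growth.
#' @param tol optimizer convergence tolerance.
#' @param maxIter maximum optimizer iterations.
#' @param fitBaseline logical; fit the additive background offset (default)
#'   or fix it at the first observed intensity.
#' @return a list of class `fitConfig`.
#' @export
fitConfig <- function(kMin = 5, kMinFrac = 0.05, r2Min = 0.7,
                      tol = 1e-10, maxIter = 200L, fitBaseline = TRUE) {
  stopifnot(kMin > 0, kMinFrac > 0, r2Min > 0, tol > 0, maxIter >= 1L)
  structure(
    list(kMin = kMin, kMinFrac = kMinFrac, r2Min = r2Min,
         tol = tol, maxIter = as.integer(maxIter), fitBaseline = fitBaseline),
    class = "fitConfig"
  )
}

#' Logistic growth curve
#'
#' Evaluates `G(t) = baseline + K / (1 + exp(-r * (t - L)))`: `K` is the
#' carrying capacity above baseline, `r` the maximum specific rate and `L`
#' the time at which half of `K` is reached.
#'
#' @param t times (hours).
#' @param K carrying capacity.
#' @param r maximum specific rate (1/hour).
#' @param L time to half capacity (hours).
#' @param baseline additive offset.
#' @return intensities at `t`.
#' @export
logisticCurve <- function(t, K, r, L, baseline = 0) {
  baseline + K / (1 + exp(-r * (t - L)))
}

# numerically stable log(1 + exp(x))
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# deterministic starting values: range-based K, half-range crossing for L,
# local slope for r
.logisticStart <- function(t, y, fitBaseline) {
  b0 <- if (fitBaseline) min(y) else y[1L]
  K0 <- max(y) - b0
  if (K0 <= 0) K0 <- max(abs(y - b0), 1e-6)
  half <- b0 + K0 / 2
  above <- which(y >= half)
  L0 <- if (length(above)) {
    i <- above[1L]
    if (i == 1L) t[1L]
    else t[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
  } else mean(range(t))
  i <- which.min(abs(t - L0))
  lo <- max(1L, i - 1L); hi <- min(length(t), i + 1L)
  slope <- (y[hi] - y[lo]) / (t[hi] - t[lo])
  r0 <- 4 * slope / K0
  if (!is.finite(r0) || r0 <= 0) r0 <- 4 / diff(range(t))
  list(K = K0, r = r0, L = L0, baseline = b0)
}

#' Fit a logistic growth curve to one culture
#'
#' Least-squares fit of [logisticCurve] to a [CultureSeries]. Parameters are
#' initialized from the data (range-based `K`, half-range crossing for `L`,
#' local slope for `r`) and refined by Levenberg-Marquardt. 95% confidence
#' bounds come from the curvature of the objective at the optimum. The `grew`
#' flag follows the [detectNoGrowth] contract; optimizer failure never
#' raises, it returns a non-grown fit with `converged = FALSE`.
#'
#' @param ts a [CultureSeries].
#' @param cfg a [fitConfig].
#' @return a [GrowthFit].
#' @examples
#' t <- seq(0, 48, by = 2)
#' fit <- fitLogistic(CultureSeries("ex", t, logisticCurve(t, 100, 0.4, 24)))
#' capacity(fit); rate(fit); halfTime(fit)
#' @export
fitLogistic <- function(ts, cfg = fitConfig()) {
  stopifnot(is(ts, "CultureSeries"))
  validObject(ts)
  t <- ts@times
  y <- ts@intensities
  start <- .logisticStart(t, y, cfg$fitBaseline)

  # residuals and analytic Jacobian for Levenberg-Marquardt
  resid <- function(p) {
    b <- if (cfg$fitBaseline) p[["baseline"]] else start$baseline
    y - logisticCurve(t, p[["K"]], p[["r"]], p[["L"]], b)
  }
  jac <- function(p) {
    s <- 1 / (1 + exp(-p[["r"]] * (t - p[["L"]])))
    dsdr <- p[["K"]] * s * (1 - s) * (t - p[["L"]])
    dsdL <- -p[["K"]] * p[["r"]] * s * (1 - s)
    J <- cbind(K = s, r = dsdr, L = dsdL)
    if (cfg$fitBaseline) J <- cbind(J, baseline = rep(1, length(t)))
    -J
  }
  naCI <- c(K = NA_real_, r = NA_real_, L = NA_real_)
  par0 <- if (cfg$fitBaseline) unlist(start) else unlist(start[c("K", "r", "L")])
  lowerB <- c(K = 0, r = 0, L = min(t) - diff(range(t)), baseline = -Inf)
  lowerB <- lowerB[names(par0)]
  fitted <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = par0, fn = resid, jac = jac, lower = lowerB,
                         control = minpack.lm::nls.lm.control(
                           maxiter = cfg$maxIter, ftol = cfg$tol,
                           ptol = cfg$tol))),
    error = function(e) NULL)
  # info 0 = improper input, 5 = function-evaluation cap, 9 = iteration cap
  if (!is.null(fitted) && (anyNA(fitted$par) || fitted$info %in% c(0L, 5L, 9L)))
    fitted <- NULL

  if (is.null(fitted)) {
    return(new("GrowthFit",
      cultureId = ts@cultureId, K = NA_real_, r = NA_real_, L = NA_real_,
      baseline = if (cfg$fitBaseline) NA_real_ else start$baseline,
      auc = NA_real_, rSquared = NA_real_,
      ciLower = naCI, ciUpper = naCI, grew = FALSE, converged = FALSE))
  }

  cf <- fitted$par
  K <- unname(cf[["K"]]); r <- unname(cf[["r"]]); L <- unname(cf[["L"]])
  b <- if (cfg$fitBaseline) unname(cf[["baseline"]]) else start$baseline
  res <- y - logisticCurve(t, K, r, L, b)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else if (sum(res^2) == 0) 1 else -Inf

  # symmetric 95% bounds from the curvature (J'J) at the optimum
  se <- tryCatch({
    J <- jac(cf)
    dfree <- max(length(t) - length(cf), 1L)
    sigma2 <- sum(res^2) / dfree
    v <- sigma2 * diag(solve(crossprod(J)))
    sqrt(pmax(v[match(c("K", "r", "L"), names(cf))], 0))
  }, error = function(e) naCI)
  crit <- stats::qt(0.975, df = max(length(t) - length(cf), 1L))
  ciLower <- stats::setNames(c(K, r, L) - crit * unname(se), c("K", "r", "L"))
  ciUpper <- stats::setNames(c(K, r, L) + crit * unname(se), c("K", "r", "L"))

  isGrown <- is.finite(r2) && r2 >= cfg$r2Min && K >= cfg$kMin
  if (!isGrown) {
    return(new("GrowthFit",
      cultureId = ts@cultureId, K = NA_real_, r = NA_real_, L = NA_real_,
      baseline = b, auc = NA_real_, rSquared = r2,
      ciLower = naCI, ciUpper = naCI, grew = FALSE, converged = TRUE))
  }

  auc <- .aucClosedForm(K, r, L, min(t), max(t))
  new("GrowthFit",
    cultureId = ts@cultureId, K = K, r = r, L = L, baseline = b,
    auc = auc, rSquared = r2,
    ciLower = ciLower, ciUpper = ciUpper, grew = TRUE, converged = TRUE)
}

.aucClosedForm <- function(K, r, L, t0, t1) {
  (K / r) * (.softplus(r * (t1 - L)) - .softplus(r * (t0 - L)))
}

#' Area under the fitted logistic curve
#'
#' Integrates the fitted curve (baseline excluded) over `[tStart, tEnd]`
#' using the closed form
#' `(K/r) * log((1 + exp(r*(tEnd - L))) / (1 + exp(r*(tStart - L))))`.
#'
#' @param fit a [GrowthFit] with `grew = TRUE`.
#' @param tStart,tEnd integration window (hours), `tEnd > tStart`.
#' @return the integral (intensity x hours), or `NA` when the culture did
#'   not grow.
#' @export
aucLogistic <- function(fit, tStart, tEnd) {
  stopifnot(is(fit, "GrowthFit"), tEnd > tStart)
  if (!fit@grew) return(NA_real_)
  if (fit@K == 0) return(0)
  .aucClosedForm(fit@K, fit@r, fit@L, tStart, tEnd)
}

#' Decide whether a culture grew
#'
#' Fits the series and flags no growth when the fitted carrying capacity
#' falls strictly below `cfg$kMin` or the fit's R-squared falls strictly
#' below `cfg$r2Min`. Deterministic for fixed input and configuration; a
#' series the optimizer cannot fit at all is also no growth.
#'
#' @param ts a [CultureSeries].
#' @param cfg a [fitConfig].
#' @return logical growth flag.
#' @export
detectNoGrowth <- function(ts, cfg = fitConfig()) {
  fitLogistic(ts, cfg)@grew
}

#' Standardize parameter values against the untreated group
#'
#' Transforms every value by `(x - mean0) / sd0`, where `mean0` and `sd0`
#' are taken from the zero-dose (untreated) group, so dose trends of
#' different growth parameters become directly comparable; the untreated
#' group itself ends up with mean 0 and standard deviation 1.
#'
#' @param values numeric vector of parameter values.
#' @param doses vector of doses, same length; the untreated group is
#'   `doses == zeroDose`.
#' @param zeroDose dose identifying the untreated group (default 0).
#' @return numeric vector of standardized values, same order as `values`.
#' @export
standardizeByUntreated <- function(values, doses, zeroDose = 0) {
  stopifnot(length(values) == length(doses))
  untreated <- values[doses == zeroDose]
  if (length(untreated) < 2L)
    stop("untreated group (dose = ", zeroDose, ") needs at least 2 values")
  s0 <- stats::sd(untreated)
  if (!is.finite(s0) || s0 == 0)
    stop("untreated group (dose = ", zeroDose, ") has zero standard deviation")
  (values - mean(untreated)) / s0
}

#' Fit every culture of a screen
#'
#' Applies [fitLogistic] to a collection of [CultureSeries] and assembles
#' the screen-layout table (see [writeScreenTable]). The no-growth capacity
#' threshold is taken as `cfg$kMinFrac` times the plate-wide median fitted
#' `K` (over first-pass grown fits), so the detector adapts to the plate's
#' intensity scale; fits are then re-flagged against that threshold.
#'
#' @param seriesList list of [CultureSeries].
#' @param cfg a [fitConfig].
#' @param meta optional data.frame with columns `culture_id`, `oligomycin`,
#'   `orf`, `gene` merged into the output.
#' @return data.frame in screen layout, one row per culture, plus a
#'   `grew` column.
#' @export
fitScreen <- function(seriesList, cfg = fitConfig(), meta = NULL) {
  fits <- lapply(seriesList, fitLogistic, cfg = cfg)
  ks <- vapply(fits, function(f) f@K, numeric(1))
  medK <- stats::median(ks, na.rm = TRUE)
  kCut <- if (is.finite(medK)) cfg$kMinFrac * medK else cfg$kMin
  rows <- lapply(fits, function(f) {
    grewHere <- isTRUE(f@grew) && !is.na(f@K) && f@K >= kCut
    data.frame(
      culture_id = f@cultureId,
      auc = if (grewHere) f@auc else NA_real_,
      K = if (grewHere) f@K else NA_real_,
      r = if (grewHere) f@r else NA_real_,
      L = if (grewHere) f@L else NA_real_,
      r_squared = f@rSquared,
      K_lower = f@ciLower[["K"]], K_upper = f@ciUpper[["K"]],
      r_lower = f@ciLower[["r"]], r_upper = f@ciUpper[["r"]],
      L_lower = f@ciLower[["L"]], L_upper = f@ciUpper[["L"]],
      grew = grewHere
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(meta)) out <- merge(meta, out, by = "culture_id", sort = FALSE)
  out
}
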