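# Seeded synthetic screens with ground truth. The generator composes each
# strain's L response as
#   L(D) = RD(D) + K0 + B*D + C*D^2 + noise,
# with RD(D) the reference dose response, plants enhancer / suppressor /
# null effects at configurable rates, censors cultures whose deterministic
# L exceeds a growth horizon (monotone in dose), and can render full
# logistic time series and plate images so the fitting and image front ends
# are exercised end to end.

#' Synthetic-screen configuration
#'
#' Defaults emulate the screen's stated conditions: a six-step oligomycin
#' ladder from 0 to 0.25 ug/mL, 768 reference replicates, and planted
#' interaction effects clearly beyond the classification thresholds
#' (`|INT|` at the top dose at least 1.5x the 10 / -16 cuts).
#'
#' @param nGenes number of deletion strains.
#' @param doses oligomycin ladder (ug/mL), starting at 0.
#' @param nRefReplicates reference replicate cultures per dose.
#' @param fracEnhancer,fracSuppressor planted class fractions (rest null).
#' @param enhancerIntRange,suppressorIntRange uniform ranges for the planted
#'   interaction value at the top dose (hours).
#' @param k0Sd standard deviation of planted knockout main effects (hours).
#' @param refL0,refSlope,refQuad reference dose response
#'   `RD(D) = refL0 + refSlope*D + refQuad*D^2` (monotone growth delay).
#' @param refNoiseSd replicate-to-replicate sd of reference L (hours).
#' @param lNoiseSd strain L measurement noise (hours).
#' @param kRange,rRange per-strain logistic capacity and rate ranges used
#'   when rendering time series.
#' @param intensityNoiseSd pixel-density noise added to rendered series.
#' @param times observation times for rendered series (hours).
#' @param baselineLevel additive background of rendered series.
#' @param horizon censoring horizon (hours): a culture whose deterministic
#'   composed L exceeds it is emitted as a flat no-growth series.
#' @param nOverlapPairs number of overlapping-ORF strain pairs sharing a
#'   planted effect.
#' @param drugEffect magnitude of class-linked gene-drug profile centers.
#' @param drugNoiseSd noise sd of gene-drug interaction values.
#' @param seed integer seed (mandatory; every draw flows from it).
#' @return a list of class `screenConfig`.
#' @export
screenConfig <- function(nGenes = 500L,
                         doses = c(0, 0.05, 0.1, 0.15, 0.2, 0.25),
                         nRefReplicates = 768L,
                         fracEnhancer = 0.1, fracSuppressor = 0.1,
                         enhancerIntRange = c(15, 40),
                         suppressorIntRange = c(-40, -24),
                         k0Sd = 2,
                         refL0 = 30, refSlope = 30, refQuad = 80,
                         refNoiseSd = 1.5, lNoiseSd = 0.5,
                         kRange = c(80, 120), rRange = c(0.3, 0.5),
                         intensityNoiseSd = 2,
                         times = seq(0, 96, by = 4),
                         baselineLevel = 10,
                         horizon = 72,
                         nOverlapPairs = 0L,
                         drugEffect = 6, drugNoiseSd = 1.5,
                         seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(doses[1L] == 0, all(diff(doses) > 0),
            fracEnhancer + fracSuppressor <= 1,
            refSlope > 0, refQuad > 0)
  refAtMax <- refL0 + refSlope * max(doses) + refQuad * max(doses)^2
  if (horizon <= refL0)
    stop("infeasible config: horizon (", horizon,
         " h) is below the reference L at dose 0 (", refL0, " h)")
  cfg <- as.list(environment())
  cfg$refAtMax <- refAtMax
  class(cfg) <- "screenConfig"
  cfg
}

.referenceShape <- function(cfg, D) {
  cfg$refL0 + cfg$refSlope * D + cfg$refQuad * D^2
}

# draw (B, C) realizing a target INT at dMax with a random linear/quadratic mix
.drawQuadratic <- function(intTarget, dMax) {
  phi <- stats::runif(length(intTarget))
  list(B = (1 - phi) * intTarget / dMax,
       C = phi * intTarget / dMax^2)
}

#' Generate a synthetic screen with ground truth
#'
#' Draws planted effects per gene, composes noisy per-dose L values for each
#' strain and for the replicated reference, applies the monotone censoring
#' rule, and (optionally) renders every culture as a logistic intensity
#' time series so the full quantify-fit-score path can be run. All output
#' is reproducible bit for bit from `cfg$seed`.
#'
#' @param cfg a [screenConfig].
#' @param emitSeries render [CultureSeries] for every culture (slower).
#' @return list with elements:
#' \describe{
#'   \item{truth}{per-gene ground truth: `gene`, `class`, `K0`, `B`, `C`,
#'     `int_planted` (at the top dose), `tier` (implied by censoring),
#'     `pair` (overlap-pair id or `NA`).}
#'   \item{strains}{long data.frame `gene`, `dose`, `L`, `grew`.}
#'   \item{reference}{long data.frame `replicate`, `dose`, `L`.}
#'   \item{geneDrug}{genes x 12 matrix of gene-drug interaction values
#'     (profile columns D-O), with class-linked structure.}
#'   \item{geneSets}{synthetic annotation terms (list term -> genes).}
#'   \item{overlapPairs}{data.frame `pair`, `gene_orf`, `gene_overlap`.}
#'   \item{series, seriesMeta}{only when `emitSeries`: list of
#'     [CultureSeries] and its metadata (`culture_id`, `strain`, `dose`,
#'     `type`).}
#' }
#' @export
generateScreen <- function(cfg, emitSeries = FALSE) {
  stopifnot(inherits(cfg, "screenConfig"))
  set.seed(cfg$seed)
  D <- cfg$doses
  dMax <- max(D)
  nD <- length(D)

  nE <- round(cfg$nGenes * cfg$fracEnhancer)
  nS <- round(cfg$nGenes * cfg$fracSuppressor)
  nN <- cfg$nGenes - nE - nS
  classes <- c(rep("deletion_enhancer", nE), rep("deletion_suppressor", nS),
               rep("none", nN))
  genes <- sprintf("gene%04d", seq_len(cfg$nGenes))

  intPlanted <- numeric(cfg$nGenes)
  intPlanted[classes == "deletion_enhancer"] <-
    stats::runif(nE, cfg$enhancerIntRange[1L], cfg$enhancerIntRange[2L])
  intPlanted[classes == "deletion_suppressor"] <-
    stats::runif(nS, cfg$suppressorIntRange[1L], cfg$suppressorIntRange[2L])
  qc <- .drawQuadratic(intPlanted, dMax)
  B <- ifelse(classes == "none", 0, qc$B)
  C <- ifelse(classes == "none", 0, qc$C)
  K0 <- stats::rnorm(cfg$nGenes, 0, cfg$k0Sd)
  pair <- rep(NA_character_, cfg$nGenes)

  # overlapping-ORF pairs: appended strains sharing one planted effect
  if (cfg$nOverlapPairs > 0L) {
    np <- cfg$nOverlapPairs
    pairInt <- stats::rnorm(np, 0, 15)
    pairQ <- .drawQuadratic(pairInt, dMax)
    pairK0 <- stats::rnorm(np, 0, cfg$k0Sd)
    pairIds <- sprintf("pair%03d", seq_len(np))
    for (side in c("orf", "ovl")) {
      genes <- c(genes, sprintf("%s_%s", side, pairIds))
      classes <- c(classes, ifelse(pairInt > 10, "deletion_enhancer",
                            ifelse(pairInt < -16, "deletion_suppressor",
                                   "none")))
      intPlanted <- c(intPlanted, pairInt)
      B <- c(B, pairQ$B); C <- c(C, pairQ$C)
      K0 <- c(K0, pairK0)
      pair <- c(pair, pairIds)
    }
  }
  nAll <- length(genes)

  refShape <- .referenceShape(cfg, D)
  Ldet <- outer(K0, rep(1, nD)) +
    outer(B, D) + outer(C, D^2) +
    matrix(refShape, nAll, nD, byrow = TRUE)
  censored <- t(apply(Ldet > cfg$horizon, 1L, cummax)) > 0
  grew <- !censored
  tierTrue <- rowSums(censored)

  Lobs <- Ldet + matrix(stats::rnorm(nAll * nD, 0, cfg$lNoiseSd), nAll, nD)
  Lobs[!grew] <- NA_real_

  strains <- data.frame(
    gene = rep(genes, each = nD),
    dose = rep(D, nAll),
    L = as.vector(t(Lobs)),
    grew = as.vector(t(grew))
  )

  reference <- data.frame(
    replicate = rep(seq_len(cfg$nRefReplicates), each = nD),
    dose = rep(D, cfg$nRefReplicates),
    L = as.vector(t(
      matrix(refShape, cfg$nRefReplicates, nD, byrow = TRUE) +
        matrix(stats::rnorm(cfg$nRefReplicates * nD, 0, cfg$refNoiseSd),
               cfg$nRefReplicates, nD)))
  )

  # class-linked gene-drug structure over profile columns D-O
  drugCols <- profileSchema()$label[4:15]
  centers <- matrix(0, nAll, length(drugCols))
  centers[classes == "deletion_enhancer", 1:6] <- cfg$drugEffect
  centers[classes == "deletion_suppressor", 7:12] <- -cfg$drugEffect
  geneDrug <- centers +
    matrix(stats::rnorm(nAll * length(drugCols), 0, cfg$drugNoiseSd),
           nAll, length(drugCols))
  dimnames(geneDrug) <- list(genes, drugCols)

  geneSets <- list(
    enhancer_module = genes[classes == "deletion_enhancer"],
    suppressor_module = genes[classes == "deletion_suppressor"]
  )

  truth <- data.frame(
    gene = genes, class = classes, K0 = K0, B = B, C = C,
    int_planted = intPlanted, tier = as.integer(tierTrue), pair = pair
  )
  overlapPairs <- if (cfg$nOverlapPairs > 0L) {
    data.frame(pair = pairIds,
               gene_orf = sprintf("orf_%s", pairIds),
               gene_overlap = sprintf("ovl_%s", pairIds))
  } else {
    data.frame(pair = character(), gene_orf = character(),
               gene_overlap = character())
  }

  out <- list(truth = truth, strains = strains, reference = reference,
              geneDrug = geneDrug, geneSets = geneSets,
              overlapPairs = overlapPairs, doses = D, config = cfg)

  if (emitSeries) {
    Kg <- stats::runif(nAll, cfg$kRange[1L], cfg$kRange[2L])
    rg <- stats::runif(nAll, cfg$rRange[1L], cfg$rRange[2L])
    series <- list()
    meta <- list()
    renderOne <- function(id, strain, dose, type, L, K, r) {
      y <- if (is.na(L)) rep(0, length(cfg$times))
      else logisticCurve(cfg$times, K, r, L, 0)
      y <- y + cfg$baselineLevel +
        stats::rnorm(length(cfg$times), 0, cfg$intensityNoiseSd)
      series[[id]] <<- CultureSeries(id, cfg$times, y)
      meta[[id]] <<- data.frame(culture_id = id, strain = strain,
                                dose = dose, type = type)
    }
    for (i in seq_len(nAll)) {
      for (j in seq_len(nD)) {
        id <- sprintf("%s_d%02d", genes[i], j)
        renderOne(id, genes[i], D[j], "mutant",
                  if (grew[i, j]) Lobs[i, j] else NA_real_, Kg[i], rg[i])
      }
    }
    refL <- matrix(reference$L, nrow = nD)
    refK <- stats::runif(cfg$nRefReplicates, cfg$kRange[1L], cfg$kRange[2L])
    refR <- stats::runif(cfg$nRefReplicates, cfg$rRange[1L], cfg$rRange[2L])
    for (i in seq_len(cfg$nRefReplicates)) {
      for (j in seq_len(nD)) {
        id <- sprintf("ref%04d_d%02d", i, j)
        renderOne(id, sprintf("ref%04d", i), D[j], "reference",
                  refL[j, i], refK[i], refR[i])
      }
    }
    out$series <- series
    out$seriesMeta <- do.call(rbind, meta)
    rownames(out$seriesMeta) <- NULL
  }
  out
}

#' Dose-response objects from a synthetic screen
#'
#' @param screen output of [generateScreen].
#' @return named list of [DoseResponse], one per strain.
#' @export
screenDoseResponses <- function(screen) {
  genes <- unique(screen$strains$gene)
  stats::setNames(lapply(genes, function(g) {
    sub <- screen$strains[screen$strains$gene == g, , drop = FALSE]
    sub <- sub[order(sub$dose), , drop = FALSE]
    DoseResponse(g, sub$dose, sub$L, sub$grew)
  }), genes)
}

#' Generate planted Gaussian interaction profiles
#'
#' Draws `nPerCluster[k]` profiles around each center in the 15-column
#' profile space, for clustering-recovery checks.
#'
#' @param nPerCluster integer vector, profiles per cluster.
#' @param centers k x 15 matrix of cluster centers (rows recycled to the
#'   schema width if needed).
#' @param sd within-cluster standard deviation (isotropic).
#' @param seed integer seed.
#' @return list with `profiles` (an [InteractionProfiles]) and `labels`
#'   (integer planted cluster per gene).
#' @export
generateProfiles <- function(nPerCluster, centers, sd = 1, seed = 1L) {
  stopifnot(sd > 0)
  centers <- as.matrix(centers)
  k <- nrow(centers)
  stopifnot(length(nPerCluster) == k,
            nrow(unique(centers)) == k)
  d <- nrow(profileSchema())
  if (ncol(centers) != d)
    stop("centers must have ", d, " columns (the A-O schema)")
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(stats::rnorm(nPerCluster[j] * d, mean = centers[j, ], sd = sd),
           nPerCluster[j], d, byrow = TRUE)
  }))
  labels <- rep(seq_len(k), nPerCluster)
  rownames(X) <- sprintf("g%d_%03d", labels,
                         unlist(lapply(nPerCluster, seq_len)))
  colnames(X) <- profileSchema()$label
  list(profiles = InteractionProfiles(X), labels = labels)
}

#' Render synthetic plate images for a set of cultures
#'
#' Produces time-lapse frames with a flat background plus one Gaussian spot
#' per culture whose integrated amplitude follows that culture's logistic
#' trajectory, with seeded pixel noise — a controlled front-end test for
#' [quantifyStack].
#'
#' @param cultures data.frame with columns `row`, `col` (0-based grid
#'   positions), `K`, `r`, `L` (logistic parameters; `L = NA` renders a
#'   blank, no-growth spot).
#' @param times frame times (hours).
#' @param gridRows,gridCols plate layout (default 16 x 24).
#' @param pitch spot pitch in pixels.
#' @param spotSigma Gaussian spot width (pixels).
#' @param bgLevel flat background intensity.
#' @param noiseSd pixel noise sd.
#' @param seed integer seed for the pixel noise.
#' @return a [PlateStack].
#' @export
renderPlateImages <- function(cultures, times, gridRows = 16L, gridCols = 24L,
                              pitch = 20, spotSigma = pitch / 6,
                              bgLevel = 10, noiseSd = 0, seed = 1L) {
  if (nrow(cultures) > gridRows * gridCols)
    stop("more cultures than grid positions")
  if (nrow(cultures) &&
      (any(cultures$row < 0 | cultures$row >= gridRows) ||
       any(cultures$col < 0 | cultures$col >= gridCols)))
    stop("culture grid positions outside the plate layout")
  set.seed(seed)
  nr <- gridRows * pitch
  nc <- gridCols * pitch
  origin <- pitch / 2
  halo <- ceiling(4 * spotSigma)
  frames <- lapply(times, function(t) {
    frame <- matrix(bgLevel, nr, nc)
    for (i in seq_len(nrow(cultures))) {
      if (is.na(cultures$L[i])) next
      amp <- logisticCurve(t, cultures$K[i], cultures$r[i], cultures$L[i], 0)
      if (amp <= 0) next
      cr <- origin + cultures$row[i] * pitch
      cc <- origin + cultures$col[i] * pitch
      rows <- max(1L, floor(cr - halo)):min(nr, ceiling(cr + halo))
      cols <- max(1L, floor(cc - halo)):min(nc, ceiling(cc + halo))
      g <- amp / (2 * pi * spotSigma^2) *
        outer(exp(-(rows - cr)^2 / (2 * spotSigma^2)),
              exp(-(cols - cc)^2 / (2 * spotSigma^2)))
      frame[rows, cols] <- frame[rows, cols] + g
    }
    if (noiseSd > 0)
      frame <- frame + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
    frame
  })
  PlateStack(frames, times, gridRows, gridCols, pitch, origin, origin)
}
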