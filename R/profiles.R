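# Interaction-profile assembly, recursive model-based clustering, and
# gene-set enrichment. Profiles live over a fixed 15-column schema; the
# clustering is a recursive diagonal-covariance Gaussian mixture with the
# number of components chosen by BIC at every round.

#' The fixed perturbation-column schema for interaction profiles
#'
#' Fifteen columns, labeled A-O: the primary screen in the misfolded-allele
#' background (A), the same library in the wild-type background (B), the
#' deletion's growth defect on control media (C), and twelve gene-drug
#' interaction conditions (D-O).
#'
#' @return data.frame with columns `label` and `condition`.
#' @export
profileSchema <- function() {
  data.frame(
    label = LETTERS[1:15],
    condition = c(
      "misfolded-allele screen interaction",
      "wild-type screen interaction",
      "control media growth defect",
      "SC -thr", "SC -thr + beta-chloro-alanine",
      "rapamycin low", "rapamycin high", "FK-506",
      "rapamycin + FK-506", "hydroxyurea low", "hydroxyurea high",
      "cycloheximide low", "cycloheximide high",
      "miconazole low", "miconazole high"
    )
  )
}

#' Select genes for profile clustering
#'
#' Takes the union of genes passing either screen's strict-inequality
#' interaction thresholds (the tails of the interaction-strength
#' distributions), plus tiered no-growth enhancers.
#'
#' @param deltaFTbl,wildtypeTbl data.frames from [interactionTable] for the
#'   misfolded-allele and wild-type screens.
#' @param thDeltaF,thWT per-screen [Thresholds].
#' @return sorted character vector of selected strain/gene ids.
#' @export
selectGenes <- function(deltaFTbl, wildtypeTbl,
                        thDeltaF = Thresholds(10, -16),
                        thWT = Thresholds(10, -12)) {
  pass <- function(tbl, th) {
    hit <- (!is.na(tbl$INT) &
              (tbl$INT > th@enhancerCut | tbl$INT < th@suppressorCut)) |
      tbl$tier > 0L
    tbl$strain[hit]
  }
  sort(union(pass(deltaFTbl, thDeltaF), pass(wildtypeTbl, thWT)))
}

## ---- diagonal-covariance Gaussian mixture EM -------------------------------

# one EM run from given initial centers; returns loglik trace for the
# monotonicity guarantee
.emRun <- function(X, centers, maxIter, tol, varFloor) {
  n <- nrow(X); d <- ncol(X); k <- nrow(centers)
  mu <- centers
  sigma2 <- matrix(rep(pmax(apply(X, 2, stats::var), varFloor), each = k),
                   k, d, byrow = FALSE)
  w <- rep(1 / k, k)
  trace <- numeric(0)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    logDens <- vapply(seq_len(k), function(j) {
      -0.5 * colSums((t(X) - mu[j, ])^2 / sigma2[j, ]) -
        0.5 * sum(log(2 * pi * sigma2[j, ])) + log(w[j])
    }, numeric(n))
    logDens <- matrix(logDens, nrow = n)
    m <- apply(logDens, 1L, max)
    lse <- m + log(rowSums(exp(logDens - m)))
    newLL <- sum(lse)
    resp <- exp(logDens - lse)
    nk <- colSums(resp)
    w <- nk / n
    for (j in seq_len(k)) {
      if (nk[j] < 1e-10) next  # collapsed component; keep parameters
      mu[j, ] <- colSums(resp[, j] * X) / nk[j]
      sigma2[j, ] <- pmax(
        colSums(resp[, j] * (X - matrix(mu[j, ], n, d, byrow = TRUE))^2) / nk[j],
        varFloor)
    }
    trace <- c(trace, newLL)
    if (is.finite(ll) && newLL - ll < tol) { ll <- newLL; break }
    ll <- newLL
  }
  list(logLik = ll, trace = trace, mean = mu, sigma2 = sigma2, w = w,
       logDens = logDens, assign = max.col(logDens), rowLogLik = lse,
       degenerate = min(nk) < 2)
}

# fit a k-component diagonal Gaussian mixture with seeded restarts;
# k = 1 is closed-form
.gmmFit <- function(X, k, nRestarts, maxIter, tol, varFloor) {
  n <- nrow(X); d <- ncol(X)
  if (k == 1L) {
    mu <- matrix(colMeans(X), 1L, d)
    s2 <- pmax(colMeans((X - matrix(mu, n, d, byrow = TRUE))^2), varFloor)
    ll <- sum(vapply(seq_len(n), function(i)
      sum(stats::dnorm(X[i, ], mu[1L, ], sqrt(s2), log = TRUE)), numeric(1)))
    return(list(logLik = ll, trace = ll, mean = mu,
                sigma2 = matrix(s2, 1L, d), w = 1,
                assign = rep(1L, n),
                rowLogLik = vapply(seq_len(n), function(i)
                  sum(stats::dnorm(X[i, ], mu[1L, ], sqrt(s2), log = TRUE)),
                  numeric(1)),
                degenerate = FALSE))
  }
  best <- NULL
  for (rs in seq_len(nRestarts)) {
    centers <- X[sample.int(n, k), , drop = FALSE]
    fit <- .emRun(X, centers, maxIter, tol, varFloor)
    if (fit$degenerate) next  # a component collapsed onto < 2 points
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  best
}

.gmmBIC <- function(fit, n, d, k) {
  p <- (k - 1) + 2 * k * d
  -2 * fit$logLik + p * log(n)
}

#' Configuration for recursive EM clustering
#'
#' @param kMax largest number of components tried at each round.
#' @param nRestarts seeded EM restarts per candidate k.
#' @param minSize clusters smaller than this are not re-clustered.
#' @param maxIter,tol EM iteration cap and log-likelihood tolerance.
#' @param varFloor absolute lower bound on per-dimension variances.
#' @param varFloorFrac per-dimension variance floor as a fraction of the
#'   full data's variance in that dimension, held fixed through the
#'   recursion; guards against near-singular components inflating the
#'   likelihood.
#' @param seed integer seed driving all restarts (mandatory for
#'   reproducibility).
#' @return a list of class `remcConfig`.
#' @export
remcConfig <- function(kMax = 6L, nRestarts = 10L, minSize = 9L,
                       maxIter = 300L, tol = 1e-8, varFloor = 1e-6,
                       varFloorFrac = 0.05, seed = 1L) {
  stopifnot(kMax >= 1L, nRestarts >= 1L, minSize >= 2L, tol > 0,
            varFloorFrac >= 0)
  structure(
    list(kMax = as.integer(kMax), nRestarts = as.integer(nRestarts),
         minSize = as.integer(minSize), maxIter = as.integer(maxIter),
         tol = tol, varFloor = varFloor, varFloorFrac = varFloorFrac,
         seed = as.integer(seed)),
    class = "remcConfig"
  )
}

# median-impute masked entries, keeping gene/column names
.imputedMatrix <- function(profiles) {
  X <- profileValues(profiles)
  M <- profileMask(profiles)
  for (j in seq_len(ncol(X))) {
    bad <- !M[, j]
    if (any(bad)) X[bad, j] <- stats::median(X[M[, j], j])
  }
  X
}

#' Recursive EM clustering of interaction profiles
#'
#' Round 1 fits diagonal-covariance Gaussian mixtures for `k = 1..kMax`
#' (each with seeded restarts) to all profiles and keeps the k with the best
#' (lowest) BIC; each resulting cluster is then re-clustered the same way
#' until BIC prefers a single component or the cluster falls below
#' `minSize`. The number of clusters is thus chosen by the algorithm, not
#' the user. Node names encode round and lineage (root `"1-0"`, its j-th
#' child `"1-0.<j>"`, grandchildren `"2-0.<j>.<i>"`, ...); each node carries
#' the summed log mixture density of its members as a quality indicator.
#' Missing profile values are imputed to column medians first. The whole
#' tree is reproducible from `cfg$seed`.
#'
#' @param profiles an [InteractionProfiles].
#' @param cfg a [remcConfig].
#' @return the root [ClusterNode]; [leaves] gives the final clusters.
#' @export
remc <- function(profiles, cfg = remcConfig()) {
  stopifnot(is(profiles, "InteractionProfiles"))
  X <- .imputedMatrix(profiles)
  if (nrow(X) < 2L)
    return(new("ClusterNode", name = "1-0", members = rownames(X),
               logLik = 0, children = list()))
  set.seed(cfg$seed)
  floorVec <- pmax(cfg$varFloor, cfg$varFloorFrac * apply(X, 2, stats::var))
  root <- .remcNode(X, lineage = "0", round = 1L, cfg = cfg,
                    floorVec = floorVec)
  root
}

.remcNode <- function(X, lineage, round, cfg, floorVec) {
  n <- nrow(X); d <- ncol(X)
  name <- paste0(round, "-", lineage)
  if (n < cfg$minSize) {
    fit1 <- .gmmFit(X, 1L, cfg$nRestarts, cfg$maxIter, cfg$tol, floorVec)
    return(new("ClusterNode", name = name, members = rownames(X),
               logLik = fit1$logLik, children = list()))
  }
  kCand <- seq_len(min(cfg$kMax, n - 1L))
  fits <- lapply(kCand, function(k)
    .gmmFit(X, k, cfg$nRestarts, cfg$maxIter, cfg$tol, floorVec))
  ok <- !vapply(fits, is.null, logical(1))
  kCand <- kCand[ok]; fits <- fits[ok]
  bics <- vapply(seq_along(kCand), function(i)
    .gmmBIC(fits[[i]], n, d, kCand[i]), numeric(1))
  bestI <- which.min(bics)
  bestK <- kCand[bestI]
  fit <- fits[[bestI]]
  nodeLL <- fit$logLik
  if (bestK == 1L)
    return(new("ClusterNode", name = name, members = rownames(X),
               logLik = nodeLL, children = list()))
  kept <- sort(unique(fit$assign))
  children <- vector("list", length(kept))
  for (idx in seq_along(kept)) {
    j <- kept[idx]
    sel <- fit$assign == j
    childLineage <- paste0(lineage, ".", idx)
    sub <- X[sel, , drop = FALSE]
    child <- .remcNode(sub, childLineage, round + 1L, cfg, floorVec)
    # child quality under the parent mixture
    child@logLik <- sum(fit$rowLogLik[sel])
    child@name <- paste0(round, "-", childLineage)
    children[[idx]] <- child
  }
  new("ClusterNode", name = name, members = rownames(X),
      logLik = nodeLL, children = children)
}

#' Flatten a clustering tree to a membership table
#'
#' @param node a [ClusterNode] (typically the [remc] root).
#' @return data.frame with columns `cluster` (leaf name), `gene`,
#'   `log_lik` (the leaf's quality score).
#' @export
clusterTable <- function(node) {
  lv <- leaves(node)
  out <- do.call(rbind, lapply(lv, function(l)
    data.frame(cluster = l@name, gene = l@members, log_lik = l@logLik)))
  rownames(out) <- NULL
  out
}

#' Hierarchically order a cluster's members for display
#'
#' Agglomerative clustering of the node's member profiles with Euclidean
#' distance and complete linkage; the dendrogram's leaf order keeps similar
#' profiles adjacent in heat maps.
#'
#' @param node a [ClusterNode].
#' @param profiles the [InteractionProfiles] the node was built from.
#' @return list with `order` (member ids in display order) and `hclust`
#'   (the `stats::hclust` object, or `NULL` for a single member).
#' @export
hclustOrder <- function(node, profiles) {
  stopifnot(is(node, "ClusterNode"))
  ids <- node@members
  if (length(ids) < 2L) return(list(order = ids, hclust = NULL))
  X <- .imputedMatrix(profiles)[ids, , drop = FALSE]
  hc <- stats::hclust(stats::dist(X, method = "euclidean"),
                      method = "complete")
  list(order = ids[hc$order], hclust = hc)
}

#' Gene-set enrichment of a cluster
#'
#' Per term: the upper-tail hypergeometric p-value of the overlap between
#' the cluster and the term's genes within the universe, adjusted across
#' terms by Benjamini-Hochberg. The cluster-level aggregate is a
#' permutation z-score of the summed `-log(p)` mass against random gene
#' sets of the cluster's size drawn from the universe (a GOid_z-style
#' overall-enrichment statistic).
#'
#' @param members cluster gene ids (must lie in `universe`).
#' @param geneSets named list mapping term id to gene ids.
#' @param universe all scored gene ids.
#' @param nPerm permutations for the aggregate z (default 200).
#' @param seed optional integer; when given, the permutation draws are
#'   seeded for reproducibility.
#' @return list with `terms` (data.frame: `term`, `term_size`, `overlap`,
#'   `p`, `p_adj`) and `z` (aggregate enrichment z-score).
#' @export
enrichment <- function(members, geneSets, universe, nPerm = 200L,
                       seed = NULL) {
  if (!length(universe)) stop("empty universe")
  if (!length(members)) stop("empty cluster")
  if (!all(members %in% universe))
    stop("cluster members must be a subset of the universe")
  N <- length(universe)
  n <- length(members)
  termGenes <- lapply(geneSets, intersect, universe)
  stat <- function(set) {
    ps <- vapply(termGenes, function(g) {
      m <- length(g)
      k <- length(intersect(g, set))
      stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    }, numeric(1))
    ps
  }
  p <- stat(members)
  terms <- data.frame(
    term = names(geneSets),
    term_size = vapply(termGenes, length, integer(1)),
    overlap = vapply(termGenes, function(g)
      length(intersect(g, members)), integer(1)),
    p = p,
    p_adj = stats::p.adjust(p, method = "BH")
  )
  rownames(terms) <- NULL
  S <- sum(-log(p))
  if (!is.null(seed)) set.seed(seed)
  permS <- vapply(seq_len(nPerm), function(i)
    sum(-log(stat(sample(universe, n)))), numeric(1))
  sdS <- stats::sd(permS)
  z <- if (is.finite(sdS) && sdS > 0) (S - mean(permS)) / sdS else NA_real_
  list(terms = terms, z = z)
}
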