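suppressPackageStartupMessages(library(mclust))

# Independent oracles used to check package computations. These deliberately
# avoid the code paths they verify: brute-force grids, quadrature,
# combinatorial enumeration, comparison sorts.

# exhaustive grid search minimizing the sum of squared residuals of
# K / (1 + exp(-r (t - L))) over a (K, r, L) grid
gridSearchLogistic <- function(t, y,
                               Kgrid = seq(50, 150, by = 1),
                               rgrid = seq(0.1, 1, by = 0.01),
                               Lgrid = seq(10, 40, by = 0.25)) {
  best <- list(ssr = Inf)
  for (r in rgrid) {
    for (L in Lgrid) {
      s <- 1 / (1 + exp(-r * (t - L)))
      # SSR over all K on the grid, vectorized
      ssrs <- vapply(Kgrid, function(K) sum((y - K * s)^2), numeric(1))
      i <- which.min(ssrs)
      if (ssrs[i] < best$ssr)
        best <- list(K = Kgrid[i], r = r, L = L, ssr = ssrs[i])
    }
  }
  best
}

# fine trapezoidal quadrature of the logistic curve (baseline excluded)
trapezoidAUC <- function(K, r, L, t0, t1, n = 200000L) {
  t <- seq(t0, t1, length.out = n)
  y <- K / (1 + exp(-r * (t - L)))
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

# exact upper-tail hypergeometric probability by enumeration:
# P(overlap >= k) drawing n from a universe of N containing m term genes
hyperEnumeration <- function(N, m, n, k) {
  js <- k:min(m, n)
  js <- js[js >= max(0L, n - (N - m))]
  if (!length(js)) return(0)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# brute-force interaction ranking: tier desc, INT desc (NA treated as +Inf
# within a tier), id asc — written as an explicit pairwise comparison sort
bruteRank <- function(tbl) {
  key <- ifelse(is.na(tbl$INT), Inf, tbl$INT)
  n <- nrow(tbl)
  idx <- seq_len(n)
  lessThan <- function(i, j) {
    if (tbl$tier[i] != tbl$tier[j]) return(tbl$tier[i] > tbl$tier[j])
    if (key[i] != key[j]) return(key[i] > key[j])
    tbl$strain[i] < tbl$strain[j]
  }
  for (a in seq_len(n - 1L)) {             # selection sort
    best <- a
    for (b in (a + 1L):n) if (lessThan(idx[b], idx[best])) best <- b
    tmp <- idx[a]; idx[a] <- idx[best]; idx[best] <- tmp
  }
  tbl[idx, , drop = FALSE]
}

# reference dose-response shape used by the generator, recomputed directly
refShapeOracle <- function(cfg, D) cfg$refL0 + cfg$refSlope * D + cfg$refQuad * D^2

# build an exactly-quadratic dose response over a reference model:
# Y_i = RD_i + K0 + B*D + C*D^2, optionally censoring the given dose indices
plantedDoseResponse <- function(id, ref, K0, B, C, censorIdx = integer()) {
  D <- doses(ref)
  Y <- centralL(ref) + K0 + B * D + C * D^2
  grew <- rep(TRUE, length(D))
  grew[censorIdx] <- FALSE
  Y[!grew] <- NA_real_
  DoseResponse(id, D, Y, grew)
}

# a constant-valued reference model over the standard ladder
flatReference <- function(doses = c(0, 0.05, 0.1, 0.15, 0.2, 0.25),
                          level = 30, nRep = 5) {
  buildReference(data.frame(dose = rep(doses, each = nRep),
                            L = rep(level, length(doses) * nRep) +
                              rep(c(-0.2, -0.1, 0, 0.1, 0.2), length(doses))))
}

# leaf labelling of a cluster tree as an integer vector over gene ids
leafLabels <- function(tree) {
  lv <- leaves(tree)
  lab <- integer(0)
  for (i in seq_along(lv))
    lab[members(lv[[i]])] <- i
  lab
}
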