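test_that("gene selection is the union of per-screen tail passers", {
  mkTbl <- function(strain, INT, tier = 0L)
    data.frame(strain = strain, INT = INT, tier = tier)
  df <- mkTbl(c("a", "b", "c", "d", "e"), c(10, 10.1, -16, -17, 0))
  wt <- mkTbl(c("a", "b", "c", "d", "e"), c(0, 0, 0, 0, -12.5))
  sel <- selectGenes(df, wt)
  expect_identical(sel, c("b", "d", "e"))  # 10 and -16 are excluded (strict)

  # tiered no-growth enhancers pass regardless of INT
  dfT <- mkTbl(c("a", "b"), c(NA, 0), tier = c(2L, 0L))
  expect_identical(selectGenes(dfT, mkTbl(c("a", "b"), c(0, 0))), "a")

  # on a larger synthetic table, selection equals a brute-force row filter
  set.seed(51)
  big <- data.frame(strain = sprintf("g%03d", 1:200),
                    INT = rnorm(200, 0, 12),
                    tier = sample(c(0L, 0L, 0L, 1L), 200, replace = TRUE))
  bigWT <- data.frame(strain = big$strain, INT = rnorm(200, 0, 8), tier = 0L)
  want <- sort(unique(c(
    big$strain[(big$INT > 10 | big$INT < -16) | big$tier > 0],
    bigWT$strain[bigWT$INT > 10 | bigWT$INT < -12])))
  expect_identical(selectGenes(big, bigWT), want)
})

test_that("recursive EM recovers planted clusters and is deterministic", {
  gp <- generateProfiles(c(50, 50), rbind(rep(0, 15), rep(5, 15)),
                         sd = 1, seed = 7)
  tree <- remc(gp$profiles, remcConfig(seed = 2))
  lv <- leaves(tree)
  expect_equal(length(lv), 2L)
  lab <- leafLabels(tree)[geneIds(gp$profiles)]
  expect_equal(mclust::adjustedRandIndex(lab, gp$labels), 1)

  # every gene lands in exactly one leaf
  allMembers <- unlist(lapply(lv, members))
  expect_identical(sort(allMembers), sort(geneIds(gp$profiles)))
  expect_equal(anyDuplicated(allMembers), 0L)

  # identical seed reproduces the identical tree
  tree2 <- remc(gp$profiles, remcConfig(seed = 2))
  expect_identical(clusterTable(tree), clusterTable(tree2))

  # a single tight blob stays one leaf
  one <- generateProfiles(60, matrix(0, 1, 15), sd = 0.1, seed = 3)
  expect_equal(length(leaves(remc(one$profiles, remcConfig(seed = 2)))), 1L)

  # node names encode round and lineage
  expect_equal(clusterName(tree), "1-0")
  expect_true(all(grepl("^1-0\\.[0-9]+$",
                        vapply(children(tree), clusterName, character(1)))))
})

test_that("EM log-likelihood is non-decreasing within a fit and matches an independent mixture fit", {
  gp <- generateProfiles(c(40, 40), rbind(rep(0, 15), rep(4, 15)),
                         sd = 1, seed = 13)
  X <- profileValues(gp$profiles)
  set.seed(5)
  run <- qhtcp:::.emRun(X, X[sample.int(nrow(X), 2), ],
                        maxIter = 200, tol = 1e-10,
                        varFloor = rep(1e-4, ncol(X)))
  expect_true(all(diff(run$trace) > -1e-6))

  # cross-check partition against an independently implemented GMM
  mc <- mclust::Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  lab <- leafLabels(remc(gp$profiles, remcConfig(seed = 2)))[rownames(X)]
  expect_equal(mclust::adjustedRandIndex(lab, mc$classification), 1)
  expect_equal(mclust::adjustedRandIndex(lab, gp$labels), 1)
})

test_that("profiles with missing values are median-imputed before clustering", {
  gp <- generateProfiles(c(20, 20), rbind(rep(0, 15), rep(6, 15)),
                         sd = 0.5, seed = 9)
  X <- profileValues(gp$profiles)
  X[1, 3] <- NA; X[25, 10] <- NA
  pr <- InteractionProfiles(X)
  expect_equal(sum(!profileMask(pr)), 2L)
  tree <- remc(pr, remcConfig(seed = 4))
  expect_equal(length(leaves(tree)), 2L)
  expect_equal(mclust::adjustedRandIndex(leafLabels(tree)[rownames(X)],
                                         gp$labels), 1)
})

test_that("hierarchical ordering uses Euclidean distance with complete linkage", {
  # three profiles with pairwise distances 1, 2, 3 along one axis
  X <- matrix(0, 3, 15, dimnames = list(c("p1", "p2", "p3"), LETTERS[1:15]))
  X[2, 1] <- 1; X[3, 1] <- 3
  node <- new("ClusterNode", name = "1-0", members = rownames(X),
              logLik = 0, children = list())
  ho <- hclustOrder(node, InteractionProfiles(X))
  expect_equal(ho$hclust$height, c(1, 3))  # complete linkage takes the max
  # the closest pair merges first and sits adjacent in the leaf order
  pos <- match(c("p1", "p2"), ho$order)
  expect_equal(abs(diff(pos)), 1L)

  # identical profiles merge at height zero
  Y <- matrix(1, 2, 15, dimnames = list(c("q1", "q2"), LETTERS[1:15]))
  ho2 <- hclustOrder(new("ClusterNode", name = "n", members = rownames(Y),
                         logLik = 0, children = list()),
                     InteractionProfiles(Y))
  expect_equal(ho2$hclust$height, 0)

  # members of a tight planted pair stay adjacent among scattered profiles
  set.seed(17)
  Z <- matrix(rnorm(6 * 15, 0, 5), 6, 15,
              dimnames = list(sprintf("z%d", 1:6), LETTERS[1:15]))
  Z[5, ] <- Z[6, ] + rnorm(15, 0, 0.01)
  ho3 <- hclustOrder(new("ClusterNode", name = "n", members = rownames(Z),
                         logLik = 0, children = list()),
                     InteractionProfiles(Z))
  expect_equal(abs(diff(match(c("z5", "z6"), ho3$order))), 1L)

  # single member: trivial order, no dendrogram
  ho1 <- hclustOrder(new("ClusterNode", name = "n", members = "p1",
                         logLik = 0, children = list()),
                     InteractionProfiles(X))
  expect_identical(ho1$order, "p1")
  expect_null(ho1$hclust)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- sprintf("g%02d", 1:20)
  en <- enrichment(universe[1:5], list(term = universe[1:5]), universe,
                   nPerm = 50, seed = 1)
  expect_equal(en$terms$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(en$terms$p, 6.449948e-05, tolerance = 1e-6)

  # zero overlap has upper-tail probability 1
  en0 <- enrichment(universe[6:10], list(term = universe[1:5]), universe,
                    nPerm = 50, seed = 1)
  expect_equal(en0$terms$p, 1)
  expect_equal(en0$terms$overlap, 0L)

  # exhaustive agreement with enumeration for every small configuration
  for (N in 5:25) {
    uni <- sprintf("u%02d", seq_len(N))
    for (m in c(1L, N %/% 3L, N %/% 2L)) {
      if (m < 1) next
      for (n in c(2L, N %/% 2L)) {
        cl <- uni[seq_len(n)]
        term <- uni[seq_len(m)]
        e <- enrichment(cl, list(t = term), uni, nPerm = 2, seed = 1)
        k <- length(intersect(cl, term))
        expect_equal(e$terms$p, hyperEnumeration(N, m, n, k),
                     tolerance = 1e-12)
      }
    }
  }

  # adjusted p-values follow Benjamini-Hochberg across terms
  sets <- list(a = universe[1:5], b = universe[6:9], c = universe[1:10])
  e3 <- enrichment(universe[1:5], sets, universe, nPerm = 10, seed = 2)
  expect_equal(e3$terms$p_adj, p.adjust(e3$terms$p, "BH"))

  expect_error(enrichment(character(), sets, universe), "empty cluster")
  expect_error(enrichment("zz", sets, universe), "subset")
})

test_that("aggregate enrichment z is calibrated near zero for random clusters", {
  set.seed(61)
  universe <- sprintf("g%03d", 1:60)
  sets <- list(t1 = universe[1:12], t2 = universe[13:30], t3 = universe[31:40])
  zs <- vapply(1:50, function(i)
    enrichment(sample(universe, 10), sets, universe, nPerm = 100)$z,
    numeric(1))
  expect_lt(abs(mean(zs)), 0.3)
  # a genuinely enriched cluster scores well above the null spread
  zHit <- enrichment(universe[1:10], sets, universe, nPerm = 100, seed = 3)$z
  expect_gt(zHit, 2)
})
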