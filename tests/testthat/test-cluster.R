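twoBlobs <- function(n = 200, sep = 20, sd = 1, seed = 41) {
  set.seed(seed)
  list(S = rbind(matrix(rnorm(n * 2, 0, sd), ncol = 2),
                 matrix(rnorm(n * 2, sep, sd), ncol = 2)),
       labels = rep(1:2, each = n))
}

test_that("a single-component fit recovers the sample moments", {
  set.seed(43)
  S <- matrix(rnorm(400 * 3, sd = 2), ncol = 3)
  f <- fitGMM(S, 1, seed = 1, nInit = 2)
  expect_equal(gmmWeights(f), 1)
  expect_equal(gmmMeans(f)[1, ], colMeans(S), tolerance = 1e-8)
  # EM maximum likelihood covariance has the 1/n normalization (+ floor)
  mle <- crossprod(sweep(S, 2, colMeans(S))) / nrow(S)
  expect_equal(gmmCovariances(f)[, , 1], mle + diag(1e-6, 3),
               tolerance = 1e-6)
})

test_that("well-separated blobs are recovered exactly (ARI 1)", {
  d <- twoBlobs(sep = 20)
  f <- fitGMM(d$S, 2, seed = 7)
  lab <- assignFrames(f, d$S)
  expect_equal(mclust::adjustedRandIndex(lab, d$labels), 1.0)
  expect_equal(sort(gmmWeights(f)), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("the EM log-likelihood never decreases", {
  # overlapping components stress many EM iterations
  set.seed(47)
  S <- rbind(matrix(rnorm(300 * 2), ncol = 2),
             matrix(rnorm(300 * 2, 1.5), ncol = 2))
  for (K in 2:4) {
    f <- fitGMM(S, K, seed = K, nInit = 3)
    expect_true(all(diff(logLikTrace(f)) >= -1e-9))
  }
})

test_that("the EM likelihood matches an independent mixture fitter", {
  d <- twoBlobs(n = 150, sep = 12, seed = 53)
  f <- fitGMM(d$S, 2, seed = 3)
  mc <- mclust::Mclust(d$S, G = 2, modelNames = "VVV", verbose = FALSE)
  # same global optimum on well-separated data
  expect_equal(logLik(f), as.numeric(mc$loglik), tolerance = 1e-3)
  expect_equal(mclust::adjustedRandIndex(assignFrames(f, d$S),
                                         mc$classification), 1.0)
})

test_that("degenerate inputs are rejected", {
  expect_error(fitGMM(matrix(rnorm(10), 5, 2), 6), "exceeds")
  expect_error(fitGMM(matrix(1, 20, 2), 2), "identical")
})

test_that("silhouette matches the textbook formula on a hand instance", {
  # two pairs: (0), (1) | (10), (11)
  S <- matrix(c(0, 1, 10, 11, 0, 0, 0, 0), ncol = 2)
  lab <- c(1L, 1L, 2L, 2L)
  sil <- silhouetteScore(S, lab)
  # oracle: a(i) and b(i) by hand for point 1: a = 1, b = (10 + 11)/2
  a <- c(1, 1, 1, 1)
  b <- c((10 + 11) / 2, (9 + 10) / 2, (10 + 9) / 2, (11 + 10) / 2)
  oracle <- (b - a) / pmax(a, b)
  expect_equal(as.numeric(sil$widths), oracle, tolerance = 1e-12)
  expect_equal(sil$mean, mean(oracle), tolerance = 1e-12)
})

test_that("silhouette limits: far separation scores ~1, singletons 0", {
  d <- twoBlobs(n = 50, sep = 100, sd = 0.5, seed = 59)
  expect_gte(silhouetteScore(d$S, d$labels)$mean, 0.99)
  S <- matrix(rnorm(12), ncol = 2)
  allSingle <- silhouetteScore(S, seq_len(6))
  expect_true(all(allSingle$widths == 0))
  expect_error(silhouetteScore(d$S, rep(1L, 200)), "2 clusters")
})

test_that("assignment picks the maximum posterior with low-index ties", {
  means <- rbind(c(-2, 0), c(2, 0))
  covs <- array(diag(2), dim = c(2, 2, 2))
  f <- new("GMMFit", K = 2L, weights = c(0.5, 0.5), means = means,
           covariances = covs, logLik = 0, logLikTrace = 0,
           seed = 1L, converged = TRUE)
  expect_equal(assignFrames(f, means), c(1L, 2L))
  # the midpoint is an exact tie -> lowest component index
  expect_equal(assignFrames(f, rbind(c(0, 0))), 1L)
  R <- posteriorResponsibilities(f, matrix(rnorm(40), ncol = 2))
  expect_equal(rowSums(R), rep(1, 20), tolerance = 1e-10)
  expect_error(assignFrames(f, matrix(0, 2, 3)), "dimension")
})

test_that("cluster weights are frame fractions", {
  expect_equal(as.numeric(clusterWeights(c(1L, 1L, 2L, 2L))), c(0.5, 0.5))
  expect_equal(as.numeric(clusterWeights(rep(3L, 7))), 1)
  expect_error(clusterWeights(integer(0)), "empty")
})

test_that("per-condition populations are row-normalized and validated", {
  lab <- c(1L, 1L, 2L, 1L, 2L, 2L)
  meta <- S4Vectors::DataFrame(condition = rep(c("apo", "RNA"), each = 3))
  P <- populationsByCondition(lab, meta)
  expect_equal(rowSums(P), c(apo = 1, RNA = 1))
  expect_equal(P["apo", ], c("1" = 2 / 3, "2" = 1 / 3))
  # single condition reduces to the cluster weights
  one <- populationsByCondition(lab, S4Vectors::DataFrame(
    condition = rep("apo", 6)))
  expect_equal(as.numeric(one), as.numeric(clusterWeights(lab)))
  expect_error(populationsByCondition(lab, S4Vectors::DataFrame(
    condition = c(rep("apo", 5), ""))), "condition")
})

test_that("representative frames are closest-to-center with low-index ties", {
  means <- rbind(c(0, 0), c(10, 0))
  f <- new("GMMFit", K = 2L, weights = c(0.5, 0.5), means = means,
           covariances = array(diag(2), dim = c(2, 2, 2)), logLik = 0,
           logLikTrace = 0, seed = 1L, converged = TRUE)
  S <- rbind(c(0.5, 0), c(0, 0), c(10, 1), c(10, -1))
  rep1 <- representativeFrames(f, S, labels = c(1L, 1L, 2L, 2L))
  expect_equal(as.integer(rep1), c(2L, 3L))  # frame 2 hits the mean; 3-4 tie
  expect_error(representativeFrames(f, S, labels = rep(1L, 4)), "empty")
})

test_that("scanK reports a silhouette-ranked single-row table for K range [2,2]", {
  d <- twoBlobs(n = 60, seed = 61)
  sel <- scanK(d$S, 2, 2, seed = 1, nInit = 3)
  expect_equal(nrow(selectionTable(sel)), 1L)
  expect_true(is.na(elbowK(sel)))
  expect_equal(bestSilhouetteK(sel), 2L)
  expect_error(scanK(d$S, 4, 3), "empty")
})

test_that("two far basins put the best silhouette at K = 2", {
  d <- twoBlobs(n = 150, sep = 40, seed = 67)
  sel <- scanK(d$S, 2, 5, seed = 2, nInit = 4)
  expect_equal(bestSilhouetteK(sel), 2L)
})

test_that("relabeling components leaves the partition metrics unchanged", {
  d <- twoBlobs(n = 100, sep = 15, seed = 71)
  f <- fitGMM(d$S, 2, seed = 5)
  lab <- assignFrames(f, d$S)
  perm <- 3L - lab  # swap 1 <-> 2
  expect_equal(sort(as.numeric(clusterWeights(lab))),
               sort(as.numeric(clusterWeights(perm))))
  expect_equal(silhouetteScore(d$S, lab)$mean,
               silhouetteScore(d$S, perm)$mean, tolerance = 1e-12)
  expect_equal(mclust::adjustedRandIndex(lab, d$labels),
               mclust::adjustedRandIndex(perm, d$labels))
})
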