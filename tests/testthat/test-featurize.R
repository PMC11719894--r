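test_that("strided CA picking reproduces the published atom counts", {
  chain <- caChain(1275)
  expect_length(pickFeatureAtoms(chain, 25), 51L)
  expect_length(pickFeatureAtoms(chain, 1), 1275L)
  small <- caChain(10)
  expect_equal(pickFeatureAtoms(small, 3), c(1L, 4L, 7L, 10L))
  expect_error(pickFeatureAtoms(chain, 0), "stride")
})

test_that("picking counts positions among CA-bearing residues", {
  # residue 2 has no CA: stride positions skip it entirely
  a <- data.frame(residue_index = c(1L, 2L, 3L, 4L, 5L),
                  residue_name = "ALA",
                  atom_name = c("CA", "N", "CA", "CA", "CA"))
  s <- ProteinStructure(a, cbind(1:5, 0, 0))
  expect_equal(pickFeatureAtoms(s, 2), c(1L, 4L))  # CA positions 1 and 3
})

test_that("feature counts follow n(n-1)/2", {
  expect_identical(featureCount(51), 1275L)
  expect_identical(featureCount(1275), 812175L)
  expect_identical(featureCount(2), 1L)
  expect_identical(featureCount(1), 0L)
  expect_identical(featureCount(0), 0L)
})

test_that("single-pair distances and degenerate frames are exact", {
  topo <- caChain(2)
  tr <- trajFromFrames(topo, list(rbind(c(0, 0, 0), c(3, 4, 0))))
  fm <- distanceFeatures(tr, 1:2)
  expect_equal(featureValues(fm), matrix(5), ignore_attr = TRUE)
  tr0 <- trajFromFrames(caChain(4), list(matrix(1, 4, 3)))
  expect_true(all(featureValues(distanceFeatures(tr0, 1:4)) == 0))
})

test_that("distance features match a brute-force double loop", {
  set.seed(13)
  topo <- caChain(6)
  frames <- replicate(4, matrix(rnorm(18, sd = 5), 6, 3), simplify = FALSE)
  tr <- trajFromFrames(topo, frames)
  fm <- distanceFeatures(tr, 1:6)
  V <- featureValues(fm)
  pi <- pairIndex(fm)
  expect_equal(ncol(V), featureCount(6))
  # oracle: explicit loops over frames and lexicographic pairs
  col <- 0L
  for (i in 1:5) for (j in (i + 1):6) {
    col <- col + 1L
    expect_equal(pi$i[col], i)
    expect_equal(pi$j[col], j)
    for (f in 1:4)
      expect_equal(V[f, col], sqrt(sum((frames[[f]][i, ] - frames[[f]][j, ])^2)),
                   tolerance = 1e-10)
  }
})

test_that("features are invariant under global rigid motion", {
  set.seed(17)
  topo <- caChain(8)
  frames <- replicate(3, matrix(rnorm(24, sd = 8), 8, 3), simplify = FALSE)
  R <- randomRotation()
  t <- c(12, -7, 3)
  moved <- lapply(frames, function(X) sweep(X %*% t(R), 2, t, "+"))
  f1 <- featureValues(distanceFeatures(trajFromFrames(topo, frames), 1:8))
  f2 <- featureValues(distanceFeatures(trajFromFrames(topo, moved), 1:8))
  expect_lt(max(abs(f1 - f2)), 1e-8)
})

test_that("frame order is preserved, not sorted", {
  set.seed(19)
  topo <- caChain(5)
  frames <- replicate(6, matrix(rnorm(15), 5, 3), simplify = FALSE)
  perm <- c(4, 1, 6, 2, 5, 3)
  f1 <- featureValues(distanceFeatures(trajFromFrames(topo, frames), 1:5))
  f2 <- featureValues(distanceFeatures(trajFromFrames(topo, frames[perm]), 1:5))
  expect_equal(f2, f1[perm, ], tolerance = 1e-12)
})

test_that("pooling keeps run order and metadata; mismatches error", {
  spec <- twoDomainSpec(sigma = 0.1, framesPerRun = 3L)
  spec2 <- twoDomainSpec(sigma = 0.1, framesPerRun = 3L, seed = 2L)
  t1 <- trajectories(generateTrajectory(spec))[[1]]
  t2 <- trajectories(generateTrajectory(spec2))[[1]]
  fm <- distanceFeatures(list(t1, t2), 1:5)
  expect_equal(nFrames(fm), 6L)
  expect_equal(frameMeta(fm)$frame, rep(1:3, 2))
  expect_error(distanceFeatures(list(t1, trajFromFrames(caChain(3),
    list(coords(caChain(3))))), 1:3), "topology")
  expect_error(distanceFeatures(t1, c(1L, 99L)), "out of range")
})
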