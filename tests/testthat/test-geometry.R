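test_that("kabsch is exact on identical and rigidly moved point sets", {
  set.seed(73)
  P <- matrix(rnorm(30, sd = 5), ncol = 3)
  same <- kabsch(P, P)
  expect_equal(same@rmsd, 0, tolerance = 1e-10)
  expect_equal(same@rotation, diag(3), tolerance = 1e-8)
  R <- randomRotation()
  Q <- sweep(P %*% t(R), 2, c(5, -3, 8), "+")
  fit <- kabsch(P, Q)
  expect_lt(fit@rmsd, 1e-8)
  expect_equal(applySuperposition(fit, P), Q, tolerance = 1e-8)
  expect_equal(det(fit@rotation), 1, tolerance = 1e-10)
})

test_that("kabsch matches a numerical optimization oracle", {
  # 4-point set with one displaced vertex: nonzero residual RMSD
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Q <- P
  Q[4, ] <- c(0.3, 0.2, 1.4)
  fit <- kabsch(P, Q)
  # oracle: minimize RMSD over rotations (Euler angles; centroids aligned)
  obj <- function(ang) {
    Rz <- rotationMatrix(c(0, 0, 1), ang[1])
    Ry <- rotationMatrix(c(0, 1, 0), ang[2])
    Rx <- rotationMatrix(c(1, 0, 0), ang[3])
    R <- Rz %*% Ry %*% Rx
    Pc <- sweep(P, 2, colMeans(P))
    Qc <- sweep(Q, 2, colMeans(Q))
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    o <- stats::optim(runif(3, -pi, pi), obj,
                      control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, o$value)
  }
  expect_equal(fit@rmsd, best, tolerance = 1e-6)
})

test_that("kabsch agrees with the bio3d least-squares fit", {
  set.seed(79)
  P <- matrix(rnorm(45, sd = 4), ncol = 3)
  Q <- P + matrix(rnorm(45, sd = 0.8), ncol = 3)
  fit <- kabsch(P, Q)
  oracle <- bio3d::rmsd(as.vector(t(Q)), as.vector(t(P)), fit = TRUE)
  expect_equal(fit@rmsd, oracle, tolerance = 1e-3)
})

test_that("kabsch rejects or flags degenerate geometry", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_warning(kabsch(line, line + 1), "collinear")
})

test_that("core superposition undoes global rigid motion", {
  set.seed(83)
  topo <- buildToyTopology(c(A = 12L, B = 8L))
  ref <- coords(topo)
  frames <- lapply(1:5, function(i) {
    sweep(ref %*% t(randomRotation()), 2, rnorm(3, sd = 10), "+")
  })
  tr <- trajFromFrames(topo, frames)
  al <- superposeOnCore(tr, 1:12, topo)
  for (f in 1:5)
    expect_equal(coords(al, frame = f), ref, tolerance = 1e-8)
})

test_that("aligned core RMSD never exceeds the unaligned core RMSD", {
  set.seed(89)
  topo <- buildToyTopology(c(A = 10L, B = 10L))
  ref <- coords(topo)
  frames <- lapply(1:6, function(i) ref + matrix(rnorm(60, sd = 1.5), 20, 3))
  tr <- trajFromFrames(topo, frames)
  al <- superposeOnCore(tr, 1:10, topo)
  for (f in 1:6) {
    before <- sqrt(mean(rowSums((coords(tr, frame = f)[1:10, ] - ref[1:10, ])^2)))
    after <- sqrt(mean(rowSums((coords(al, frame = f)[1:10, ] - ref[1:10, ])^2)))
    expect_lte(after, before + 1e-12)
  }
})

test_that("the iterated average structure solves simple cases exactly", {
  topo <- buildToyTopology(c(A = 8L))
  ref <- coords(topo)
  # all frames identical -> that frame
  same <- trajFromFrames(topo, list(ref, ref, ref))
  expect_equal(coords(averageStructure(same, 1:8)), ref, tolerance = 1e-10)
  # two frames mirror-displaced about the reference with a static core
  d <- matrix(0, 8, 3); d[7:8, 1] <- 2.5
  tr <- trajFromFrames(topo, list(ref + d, ref - d))
  expect_equal(coords(averageStructure(tr, 1:4)), ref, tolerance = 1e-6)
})

test_that("the average reference gives smaller mean RMSD than the initial", {
  # drifting mobile domain: frames spread around a mean away from frame 1
  for (s in 1:5) {
    set.seed(s)
    topo <- buildToyTopology(c(A = 10L, B = 6L))
    ref <- coords(topo)
    frames <- lapply(1:20, function(i) {
      X <- ref
      X[11:16, ] <- X[11:16, ] + matrix(rep(c(6, 0, 0), each = 6), 6, 3) +
        matrix(rnorm(18, sd = 1), 6, 3)
      X
    })
    tr <- trajFromFrames(topo, frames)
    al <- superposeOnCore(tr, 1:10, topo)
    avg <- averageStructure(al, 1:10)
    alAvg <- superposeOnCore(tr, 1:10, avg)
    mInit <- seriesMean(domainRMSD(al, topo, 11:16))
    mAvg <- seriesMean(domainRMSD(alAvg, avg, 11:16))
    expect_lt(mAvg, mInit)
  }
})

test_that("domain RMSD is analytic for pure translations", {
  topo <- buildToyTopology(c(A = 10L, B = 5L))
  ref <- coords(topo)
  X <- ref
  X[11:15, ] <- sweep(X[11:15, ], 2, c(3, 4, 0), "+")
  tr <- trajFromFrames(topo, list(ref, X))
  r <- domainRMSD(tr, topo, 11:15)
  expect_equal(seriesValues(r), c(0, 5), tolerance = 1e-12)
  expect_error(domainRMSD(tr, topo, integer(0)), "empty")
})

test_that("domain RMSD matches the per-atom sum formula", {
  set.seed(97)
  topo <- buildToyTopology(c(A = 6L))
  ref <- coords(topo)
  frames <- lapply(1:4, function(i) ref + matrix(rnorm(18), 6, 3))
  tr <- trajFromFrames(topo, frames)
  r <- seriesValues(domainRMSD(tr, topo, 2:5))
  oracle <- vapply(frames, function(X) {
    s <- 0
    for (i in 2:5) s <- s + sum((X[i, ] - ref[i, ])^2)
    sqrt(s / 4)
  }, numeric(1))
  expect_equal(r, oracle, tolerance = 1e-10)
})

test_that("internal RMSD removes rigid-body motion and bounds domain RMSD", {
  set.seed(101)
  topo <- buildToyTopology(c(A = 10L, B = 8L))
  ref <- coords(topo)
  # B rigidly moved, zero jitter: internal RMSD must vanish
  frames <- lapply(1:4, function(i) {
    X <- ref
    Xb <- X[11:18, ]
    cen <- colMeans(Xb)
    X[11:18, ] <- sweep(sweep(Xb, 2, cen) %*% t(randomRotation()), 2,
                        cen + rnorm(3, sd = 6), "+")
    X
  })
  tr <- trajFromFrames(topo, frames)
  expect_lt(max(seriesValues(internalRMSD(tr, 11:18, topo))), 1e-8)
  # with jitter: internal <= core-aligned domain RMSD, frame-wise
  frames <- lapply(frames, function(X) X + matrix(rnorm(54, sd = 0.5), 18, 3))
  tr <- trajFromFrames(topo, frames)
  al <- superposeOnCore(tr, 1:10, topo)
  expect_true(all(seriesValues(internalRMSD(al, 11:18, topo)) <=
                  seriesValues(domainRMSD(al, topo, 11:18)) + 1e-12))
})

test_that("internal RMSD grows monotonically with planted jitter", {
  means <- vapply(c(0.5, 1, 2), function(sig) {
    spec <- twoDomainSpec(sigma = sig, framesPerRun = 60L, seed = 31L)
    tr <- trajectories(generateTrajectory(spec))[[1]]
    seriesMean(internalRMSD(tr, 11:20, spec@topology))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("minimum interdomain distance is exact and validated", {
  topo <- caChain(2)
  tr <- trajFromFrames(topo, list(rbind(c(0, 0, 0), c(3, 4, 0))))
  expect_equal(seriesValues(minInterdomainDistance(tr, 1L, 2L)), 5)
  tr0 <- trajFromFrames(topo, list(matrix(2, 2, 3)))
  expect_equal(seriesValues(minInterdomainDistance(tr0, 1L, 2L)), 0)
  expect_error(minInterdomainDistance(tr, 1:2, 2L), "overlap")
  expect_error(minInterdomainDistance(tr, integer(0), 2L), "non-empty")
})

test_that("minimum distance matches a brute-force double loop, symmetrically", {
  set.seed(103)
  topo <- caChain(9)
  frames <- replicate(5, matrix(rnorm(27, sd = 6), 9, 3), simplify = FALSE)
  tr <- trajFromFrames(topo, frames)
  a <- 1:4; b <- 5:9
  got <- seriesValues(minInterdomainDistance(tr, a, b))
  oracle <- vapply(frames, function(X) {
    best <- Inf
    for (i in a) for (j in b)
      best <- min(best, sqrt(sum((X[i, ] - X[j, ])^2)))
    best
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_equal(seriesValues(minInterdomainDistance(tr, b, a)), got)
})

test_that("threshold fractions use a strict inequality", {
  expect_equal(fractionBelow(c(7, 9, 7, 9), 8), 0.5)
  expect_equal(fractionBelow(c(8, 9, 10), 8), 0)   # 8 is not < 8
  expect_error(fractionBelow(numeric(0), 8), "empty")
  expect_error(fractionBelow(c(1, 2), 0), "threshold")
})

test_that("open/closed classification agrees with the fraction", {
  v <- c(7.9, 8.0, 16, 5, 9.99)
  cls <- classifyOpenClosed(v, 8)
  expect_equal(as.character(cls[1]), "closed-contact")
  expect_equal(as.character(cls[2]), "open")  # boundary is open
  expect_equal(mean(cls == "closed-contact"), fractionBelow(v, 8))
  cls10 <- classifyOpenClosed(v, 10)
  expect_equal(mean(cls10 == "closed-contact"), fractionBelow(v, 10))
})

test_that("RMSD and distances are invariant under pre-alignment rigid motion", {
  set.seed(107)
  topo <- buildToyTopology(c(A = 10L, B = 6L))
  ref <- coords(topo)
  frames <- lapply(1:4, function(i) ref + matrix(rnorm(48, sd = 1), 16, 3))
  R <- randomRotation(); t <- c(20, -5, 11)
  moved <- lapply(frames, function(X) sweep(X %*% t(R), 2, t, "+"))
  tr1 <- trajFromFrames(topo, frames)
  tr2 <- trajFromFrames(topo, moved)
  r1 <- seriesValues(domainRMSD(superposeOnCore(tr1, 1:10, topo), topo, 11:16))
  r2 <- seriesValues(domainRMSD(superposeOnCore(tr2, 1:10, topo), topo, 11:16))
  expect_equal(r1, r2, tolerance = 1e-8)
  d1 <- seriesValues(minInterdomainDistance(tr1, 1:10, 11:16))
  d2 <- seriesValues(minInterdomainDistance(tr2, 1:10, 11:16))
  expect_equal(d1, d2, tolerance = 1e-8)
})
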