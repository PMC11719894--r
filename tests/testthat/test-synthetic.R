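test_that("toy topologies have contiguous numbering matching their map", {
  s <- buildToyTopology(c(A = 10L, B = 10L))
  expect_equal(nAtoms(s), 20L)
  expect_equal(atomData(s)$residue_index, 1:20)
  expect_equal(nAtoms(buildToyTopology(c(solo = 1L))), 1L)
  sizes <- c(EN = 12L, tower = 10L, fingers = 6L, palm = 10L, thumb = 4L,
             wrist = 10L, CTD = 10L)
  s7 <- buildToyTopology(sizes)
  map <- toyDomainMap(sizes)
  for (d in names(sizes)) {
    r <- domainRange(map, d)
    expect_equal(length(domainAtomIndices(s7, map, d)), sizes[[d]])
    expect_equal(r[2] - r[1] + 1L, sizes[[d]])
  }
  expect_equal(domainRange(map, "CTD")[2], sum(sizes))
  expect_error(buildToyTopology(c(A = 0L)), ">= 1")
})

test_that("the miniature system plants a 16 A tower-CTD reference gap", {
  mt <- miniatureTopology()
  expect_equal(nAtoms(mt$topology), 255L)
  iT <- domainAtomIndices(mt$topology, mt$map, "tower")
  iC <- domainAtomIndices(mt$topology, mt$map, "CTD")
  tr <- trajFromFrames(mt$topology, list(coords(mt$topology)))
  d0 <- seriesValues(minInterdomainDistance(tr, iT, iC))
  expect_equal(d0, 16, tolerance = 1e-6)
  # the contact shift brings the domains into sub-8 A contact
  X <- coords(mt$topology)
  X[iC, ] <- sweep(X[iC, , drop = FALSE], 2, mt$contactShift, "+")
  trC <- trajFromFrames(mt$topology, list(X))
  expect_lt(seriesValues(minInterdomainDistance(trC, iT, iC)), 8)
})

test_that("state sequences follow the chain and its stationary law", {
  # degenerate identity chain never leaves the initial state
  s <- sampleStateSequence(diag(2), 200, c(1, 0), seed = 3)
  expect_true(all(s == 1L))
  # reproducibility
  P <- rbind(c(0.9, 0.1), c(0.3, 0.7))
  expect_identical(sampleStateSequence(P, 500, seed = 11),
                   sampleStateSequence(P, 500, seed = 11))
  # stationary occupancy of state 1 is 0.75 for this chain (solve pi P = pi)
  expect_equal(stationaryDistribution(P), c(0.75, 0.25), tolerance = 1e-12)
  s <- sampleStateSequence(P, 200000, seed = 5)
  expect_equal(mean(s == 1L), 0.75, tolerance = 0.01)
  # symmetric memoryless chain is uniform
  Q <- matrix(0.5, 2, 2)
  s <- sampleStateSequence(Q, 100000, seed = 7)
  expect_equal(mean(s == 1L), 0.5, tolerance = 0.01)
  expect_error(sampleStateSequence(rbind(c(0.5, 0.4), c(0.3, 0.7)), 10),
               "sum to 1")
})

test_that("identity transforms with zero jitter reproduce the reference", {
  spec <- twoDomainSpec(sigma = 0, framesPerRun = 8L,
                        transition = diag(2))  # stays in state 1
  ens <- generateTrajectory(spec)
  tr <- trajectories(ens)[[1]]
  ref <- coords(spec@topology)
  for (f in seq_len(nFrames(tr)))
    expect_identical(coords(tr, frame = f), ref)
  expect_true(all(stateLabels(ens) == 1L))
})

test_that("a pure domain translation yields exactly its norm as RMSD", {
  spec <- twoDomainSpec(K2translation = c(10, 0, 0), sigma = 0,
                        framesPerRun = 40L, seed = 4)
  ens <- generateTrajectory(spec)
  tr <- trajectories(ens)[[1]]
  gt <- stateLabels(ens)
  topo <- spec@topology
  coreIdx <- domainAtomIndices(topo, spec@domainMap, "A")
  bIdx <- domainAtomIndices(topo, spec@domainMap, "B")
  aligned <- superposeOnCore(tr, coreIdx, topo)
  r <- seriesValues(domainRMSD(aligned, topo, bIdx))
  expect_equal(r[gt == 2L], rep(10, sum(gt == 2L)), tolerance = 1e-8)
  expect_equal(r[gt == 1L], rep(0, sum(gt == 1L)), tolerance = 1e-8)
})

test_that("generation is bit-reproducible under a fixed seed", {
  spec <- twoDomainSpec(sigma = 0.5, framesPerRun = 20L, seed = 9)
  e1 <- generateTrajectory(spec)
  e2 <- generateTrajectory(spec)
  expect_identical(coords(trajectories(e1)[[1]]),
                   coords(trajectories(e2)[[1]]))
  expect_identical(stateLabels(e1), stateLabels(e2))
})

test_that("transforms must reference known domains", {
  sizes <- c(A = 5L, B = 5L)
  topo <- buildToyTopology(sizes)
  st <- StateSpec(list(Z = domainTransform(0, c(0, 0, 1), c(1, 0, 0))))
  expect_error(
    EnsembleSpec(topo, toyDomainMap(sizes), list(st), matrix(1, 1, 1)),
    "unknown domain")
})

test_that("planted jitter ordering shows up as the domain RMSD ordering", {
  sizes <- miniatureDomainSizes()
  mt <- miniatureTopology()
  sig <- c(EN = 2.0, CTD = 1.5, tower = 1.0, wrist = 0.6,
           fingers = 0.2, palm = 0.2, thumb = 0.2)
  spec <- EnsembleSpec(mt$topology, mt$map,
                       list(StateSpec(jitter = sig)), matrix(1, 1, 1),
                       framesPerRun = 150L, runsPerCondition = c(apo = 1L),
                       seed = 21L)
  tr <- trajectories(generateTrajectory(spec))[[1]]
  core <- domainAtomIndices(mt$topology, mt$map, "FPT")
  aligned <- superposeOnCore(tr, core, mt$topology)
  m <- vapply(c("EN", "CTD", "tower", "wrist", "FPT"), function(d)
    seriesMean(domainRMSD(aligned, mt$topology,
                          domainAtomIndices(mt$topology, mt$map, d), d)),
    numeric(1))
  expect_true(all(diff(m) < 0))  # EN > CTD > tower > wrist > core
})

test_that("ensembles are written with labels and provenance", {
  spec <- twoDomainSpec(sigma = 0.2, framesPerRun = 4L)
  ens <- generateTrajectory(spec)
  d <- withr::local_tempdir()
  writeSyntheticEnsemble(ens, d)
  expect_true(file.exists(file.path(d, "apo-1.pdb")))
  gt <- read.csv(file.path(d, "ground_truth.csv"))
  expect_equal(nrow(gt), 4L)
  expect_equal(gt$state, stateLabels(ens))
  expect_true(file.exists(file.path(d, "ensemble_spec.yaml")))
})
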