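test_that("a hand-written PDB reads back with coordinates to 0.001 A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPDB(f)
  s <- readPDB(f)
  expect_s4_class(s, "ProteinStructure")
  expect_equal(nAtoms(s), 3L)
  expect_equal(atomData(s)$atom_name, c("N", "CA", "CA"))
  expect_equal(atomData(s)$residue_index, c(1L, 1L, 2L))
  expect_equal(coords(s)[2, ], c(2.5, 2.0, 3.0), tolerance = 1e-3)
  expect_equal(coords(s)[3, ], c(4.125, 3.25, 3.0), tolerance = 1e-3)
})

test_that("structure write/read round trip preserves atoms and coordinates", {
  s <- buildToyTopology(c(A = 7L, B = 5L))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(s, f)
  s2 <- readPDB(f)
  expect_equal(atomData(s2)$residue_index, atomData(s)$residue_index)
  expect_equal(atomData(s2)$atom_name, atomData(s)$atom_name)
  # PDB stores 3 decimals
  expect_equal(coords(s2), coords(s), tolerance = 1e-3)
})

test_that("degenerate PDB inputs are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(readPDB(f))
  expect_error(readPDB(file.path(tempdir(), "does-not-exist.pdb")),
               "no such file")
})

test_that("multi-model files go through readTrajectory, not readPDB", {
  topo <- caChain(4)
  tr <- trajFromFrames(topo, list(coords(topo), coords(topo) + 1))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(tr, f)
  expect_error(readPDB(f), "multi-model")
  tr2 <- readTrajectory(f)
  expect_equal(nFrames(tr2), 2L)
  expect_equal(coords(tr2), coords(tr), tolerance = 1e-3)
})

test_that("trajectory round trip preserves frame order and coordinates", {
  spec <- twoDomainSpec(sigma = 0.3, framesPerRun = 5L)
  tr <- trajectories(generateTrajectory(spec))[[1]]
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(tr, f)
  tr2 <- readTrajectory(f, runId = runId(tr))
  expect_equal(nFrames(tr2), nFrames(tr))
  expect_equal(coords(tr2), coords(tr), tolerance = 1e-3)
})

test_that("atom-count mismatch between topology and frames errors", {
  topo5 <- caChain(5)
  topo4 <- caChain(4)
  f5 <- withr::local_tempfile(fileext = ".pdb")
  f4 <- withr::local_tempfile(fileext = ".pdb")
  writePDB(topo5, f5)
  writeTrajectory(trajFromFrames(topo4, list(coords(topo4))), f4)
  expect_error(readTrajectory(f5, f4), "mismatch")
})

test_that("selectAtoms filters by name and residue interval", {
  s <- caChain(10)
  expect_equal(selectAtoms(s, "CA", c(3, 5)), 3:5)
  expect_length(selectAtoms(s, "CA", c(11, 20)), 0L)
  expect_error(selectAtoms(s, "CA", c(11, 20), requireNonEmpty = TRUE),
               "empty")
  expect_error(selectAtoms(s, "CA", c(5, 3)), "start <= end")
  # strictly increasing always
  expect_true(all(diff(selectAtoms(s, "CA")) > 0))
})

test_that("FPT composite on a full-length chain selects 423 CA atoms", {
  s <- caChain(1275)
  map <- orf2pDomainMap()
  idx <- domainAtomIndices(s, map, "FPT")
  expect_equal(length(idx), (557 - 440 + 1) + (775 - 558 + 1) + (862 - 776 + 1))
  expect_equal(length(idx), 423L)
})

test_that("the default domain map covers 1-1275 with only the printed overlap", {
  map <- orf2pDomainMap()
  membership <- residueDomains(map, 1:1275)
  expect_true(all(lengths(membership) >= 1L))
  shared <- which(lengths(membership) > 1L)
  expect_equal(shared, 1061L, ignore_attr = TRUE)
  expect_setequal(membership[["1061"]], c("wrist", "CTD"))
  expect_error(residueDomains(map, 1276), "outside")
})

test_that("adjusted contact intervals trim the wrist and CTD", {
  map <- orf2pDomainMap(adjusted = TRUE)
  expect_equal(domainRange(map, "CTD"), c(1068, 1275))
  expect_equal(domainRange(map, "wrist"), c(877, 1056))
})

test_that("domain maps round trip through YAML", {
  map <- orf2pDomainMap()
  f <- withr::local_tempfile(fileext = ".yaml")
  writeDomainMap(map, f)
  map2 <- readDomainMap(f)
  expect_equal(domainNames(map2), domainNames(map))
  for (d in domainNames(map))
    expect_equal(domainRange(map2, d), domainRange(map, d))
})
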