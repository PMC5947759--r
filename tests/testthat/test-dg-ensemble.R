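helixFixture <- makeHelix(12, tailRes = 4)
helixCS <- extractConstraints(helixFixture)

test_that("an unperturbed start converges in zero sweeps to the input", {
  conf <- sampleConformation(helixCS, helixFixture, seed = 3, sigma = 0)
  expect_true(conf$converged)
  expect_equal(conf$nSweeps, 0L)
  expect_identical(conf$xyz, unname(coords(helixFixture)))
})

test_that("accepted conformations satisfy every bound and keep chirality", {
  ele <- atomData(helixFixture)$elesy
  n_acc <- 0L
  for (seed in 1:25) {
    conf <- sampleConformation(helixCS, helixFixture, seed = seed)
    if (!conf$converged) next
    n_acc <- n_acc + 1L
    # independent R-side check of all bounds incl. the exclusion floor
    expect_lte(constraintViolation(helixCS, conf$xyz, ele), 0.05)
    expect_gte(chiralityPreserved(helixFixture, conf$xyz), 0.95)
  }
  expect_gte(n_acc, 5L)
})

test_that("unsatisfiable bounds are a signalled failure, not an error", {
  a <- do.call(rbind, lapply(1:3, function(i)
    mrforge:::atomRow("CA", "C", "ALA", "A", i)))
  s <- mrforge:::newStructure(a, rbind(c(0, 0, 0), c(10, 0, 0), c(5, 1, 0)))
  # triangle-impossible: d12 ~ 10 required, but both atoms pinned within
  # ~1.1 A of atom 3
  cs <- new("ConstraintSet",
            constraints = data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                                     lower = c(10, 1, 1),
                                     upper = c(10.1, 1.1, 1.1),
                                     tier = c(5L, 5L, 5L)),
            radii = c(C = 1.7), nAtoms = 3L)
  conf <- sampleConformation(cs, s, seed = 1, maxSweeps = 200L)
  expect_false(conf$converged)
  expect_gt(conf$maxViolation, 0.05)
})

test_that("generateEnsemble returns exactly n members, deterministically", {
  e <- generateEnsemble(helixFixture, n = 3, seed = 11, cs = helixCS)
  expect_s4_class(e, "ConformationEnsemble")
  expect_equal(nModels(e), 3L)
  expect_equal(e@nRequested, 3L)
  e2 <- generateEnsemble(helixFixture, n = 3, seed = 11, cs = helixCS)
  expect_identical(e@xyz, e2@xyz)
  expect_identical(e@seeds, e2@seeds)
  # child seeds are root + attempt index, so widely separated roots give
  # distinct member streams
  e3 <- generateEnsemble(helixFixture, n = 3, seed = 500, cs = helixCS)
  expect_false(identical(e@xyz, e3@xyz))
})

test_that("loosely constrained tail residues fluctuate more than the helix", {
  e <- generateEnsemble(helixFixture, n = 30, seed = 5, cs = helixCS)
  vp <- varianceProfile(e)
  expect_true(all(vp$variance > 0))
  lab <- assignSecondaryStructure(helixFixture)
  helix_res <- which(lab == "H")
  tail_res <- (nResidues(helixFixture) - 2):nResidues(helixFixture)
  expect_gt(mean(vp$variance[tail_res]), mean(vp$variance[helix_res]))
})

test_that("ensemble members can be written as numbered files", {
  e <- generateEnsemble(helixFixture, n = 2, seed = 2, cs = helixCS)
  d <- withr::local_tempdir()
  paths <- writeEnsembleFiles(e, d, stem = "fix")
  expect_true(all(file.exists(paths)))
  expect_match(basename(paths[2]), "fix_disco2\\.pdb")
  expect_equal(coords(readPDB(paths[1])), coords(e, 1), tolerance = 1e-3)
})
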