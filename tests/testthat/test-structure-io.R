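test_that("hand-written PDB text parses into the expected hierarchy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(tinyPdbLines(), "END"), f)
  s <- readPDB(f)
  expect_s4_class(s, "ProteinStructure")
  expect_equal(length(unique(atomData(s)$chain)), 1L)
  expect_equal(nResidues(s), 3L)
  expect_equal(nModels(s), 1L)
  # the hydrogen was dropped on read
  expect_false("H" %in% atomData(s)$elety)
  expect_equal(nAtoms(s), 12L)
  expect_equal(unname(coords(s)[2, ]), c(1.458, 0, 0))
})

test_that("MODEL blocks become coordinate sets; broken topology errors", {
  block <- tinyPdbLines()
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- unlist(lapply(1:5, function(m)
    c(sprintf("MODEL     %4d", m), block, "ENDMDL")))
  writeLines(c(lines, "END"), f)
  s <- readPDB(f)
  expect_equal(nModels(s), 5L)
  expect_equal(nAtoms(s), 12L)

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", block, "ENDMDL",
               "MODEL     2", block[-3], "ENDMDL", "END"), f2)
  expect_error(readPDB(f2), "topology")

  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), f3)
  expect_error(readPDB(f3), "ATOM")
})

test_that("prepareInput reverts MSE, prunes altlocs and strips waters", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdbLine(1, "N",  "MSE", "A", 1, 0, 0, 0, ele = "N"),
    pdbLine(2, "CA", "MSE", "A", 1, 1.5, 0, 0, ele = "C"),
    pdbLine(3, "SE", "MSE", "A", 1, 2.5, 1, 0, ele = "SE"),
    pdbLine(4, "N",  "SER", "A", 2, 3, 2, 0, ele = "N"),
    pdbLine(5, "CA", "SER", "A", 2, 4.4, 2.2, 0, ele = "C"),
    pdbLine(6, "OG", "SER", "A", 2, 5.0, 3.0, 1.0, occ = 0.6, alt = "A",
            ele = "O"),
    pdbLine(7, "OG", "SER", "A", 2, 5.0, 3.2, -1.0, occ = 0.4, alt = "B",
            ele = "O"),
    pdbLine(90, "N",  "ALA", "A", 3, 6, 2, 0, ele = "N"),
    pdbLine(91, "CA", "ALA", "A", 3, 7.4, 2.2, 0, occ = 0.3, alt = "A",
            ele = "C"),
    pdbLine(92, "CA", "ALA", "A", 3, 7.4, 2.2, 0.8, occ = 0.7, alt = "B",
            ele = "C"),
    pdbLine(8, "O",  "HOH", "A", 90, 9, 9, 9, ele = "O", record = "HETATM"),
    "END"), f)
  s <- prepareInput(readPDB(f), "A")
  a <- atomData(s)
  expect_false(any(a$resid == "MSE"))
  expect_true("SD" %in% a$elety[a$resid == "MET"])
  expect_equal(a$elesy[a$elety == "SD"], "S")
  # highest-occupancy conformer kept (A here, B there), tag cleared
  expect_equal(sum(a$elety == "OG"), 1L)
  expect_equal(a$occ[a$elety == "OG"], 0.6)
  expect_equal(a$occ[a$elety == "CA" & a$resno == 3], 0.7)
  expect_equal(unname(coords(s)[a$elety == "CA" & a$resno == 3, 3]), 0.8)
  expect_true(all(a$alt == ""))
  # waters gone
  expect_false(any(a$resid == "HOH"))
  # idempotent
  expect_equal(prepareInput(s), s)
  expect_error(prepareInput(s, "Z"), "chain")
})

test_that("write/read round-trips coordinates at PDB precision", {
  h <- makeHelix(5)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeModels(h, f)
  s <- readPDB(f)
  expect_equal(nAtoms(s), nAtoms(h))
  expect_equal(coords(s), coords(h), tolerance = 1e-3)
  expect_lte(max(abs(coords(s) - round(coords(h), 3))), 1e-9)

  # another write/read cycle is exact (idempotence at 3 decimals)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeModels(s, f2)
  expect_identical(coords(readPDB(f2)), coords(s))

  # 30-model ensemble file
  e <- makePerturbedEnsemble(h, 30, 0.5, seed = 3)
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeModels(e, f3)
  s3 <- readPDB(f3)
  expect_equal(nModels(s3), 30L)
  expect_equal(coords(s3, 17), coords(e, 17), tolerance = 1e-3)
})

test_that("writeModels enforces its contract", {
  h <- makeHelix(4)
  expect_error(writeModels(list(), tempfile()), "empty")
  e <- makePerturbedEnsemble(h, 2, 0.1, seed = 1)
  expect_error(writeModels(e, tempfile(), multiModel = FALSE), "single")
  # single model, multiModel = FALSE -> no MODEL records
  f <- withr::local_tempfile(fileext = ".pdb")
  writeModels(h, f, multiModel = FALSE)
  expect_false(any(grepl("^MODEL", readLines(f))))
})
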