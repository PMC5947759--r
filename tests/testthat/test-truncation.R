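test_that("the truncation ladder reproduces printed size series", {
  expect_equal(truncationLadder(100)$nKeep, seq(100L, 5L, by = -5L))
  l259 <- truncationLadder(259)$nKeep
  expect_true(all(c(25L, 38L, 51L, 64L, 77L, 90L, 103L, 116L, 129L,
                    142L) %in% l259))
  expect_equal(truncationLadder(20)$nKeep, 20:1)
  # duplicate counts are merged; the clamp keeps at least one residue
  l3 <- truncationLadder(3)
  expect_equal(l3$nKeep, c(3L, 2L, 1L))
  expect_false(anyDuplicated(l3$nKeep) > 0)
  expect_equal(min(truncationLadder(1)$nKeep), 1L)
})

test_that("residue selection keeps the lowest scores, ties by number", {
  expect_equal(selectResidues(data.frame(r = 1:3, s = c(3, 1, 2)), 2), c(2L, 3L))
  expect_equal(selectResidues(data.frame(r = 1:3, s = c(1, 1, 2)), 1), 1L)
  expect_error(selectResidues(data.frame(r = 1:3, s = 1:3), 4), "exceeds")

  # brute-force full-sort oracle on a random profile
  set.seed(7)
  prof <- data.frame(resno = sample(1:50), score = rnorm(50))
  for (k in c(1, 7, 25, 50)) {
    got <- selectResidues(prof, k)
    ord <- prof[order(prof$score, prof$resno), ]
    expect_equal(got, sort(ord$resno[seq_len(k)]))
  }
  # nestedness across the ladder: a fixed ranking means smaller levels are
  # subsets of larger ones
  lad <- truncationLadder(50)
  kept <- lapply(lad$nKeep, function(k) selectResidues(prof, k))
  for (i in seq_along(kept)[-1])
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
})

test_that("side-chain treatments obey the atom laws", {
  h <- makeHelix(9)            # all-ALA: 5 heavy atoms per residue
  pa <- applySideChains(h, "polyala")
  expect_equal(nAtoms(pa), 5L * 9L)
  expect_true(all(atomData(pa)$resid == "ALA"))
  expect_identical(applySideChains(h, "allatom"), h)

  # glycine keeps its name and loses nothing (no CB to start with)
  g <- mrforge:::subsetAtoms(h, atomData(h)$elety != "CB")
  g@atoms$resid <- "GLY"
  pg <- applySideChains(g, "polyala")
  expect_equal(nAtoms(pg), 4L * 9L)
  expect_true(all(atomData(pg)$resid == "GLY"))

  # reliable mode: MET side chain survives, LYS is stripped
  am <- rbind(
    do.call(rbind, lapply(c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
      function(e) mrforge:::atomRow(e, ifelse(e == "SD", "S", "C"), "MET", "A", 1))),
    do.call(rbind, lapply(c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
      function(e) mrforge:::atomRow(e, substr(e, 1, 1), "LYS", "A", 2))))
  sm <- mrforge:::newStructure(am, matrix(seq_len(3 * nrow(am)), ncol = 3))
  rel <- applySideChains(sm, "reliable")
  a <- atomData(rel)
  expect_equal(sum(a$resno == 1), 8L)       # MET intact
  expect_equal(sum(a$resno == 2), 5L)       # LYS -> polyala atoms
  expect_equal(unique(a$resid[a$resno == 2]), "ALA")
})

test_that("the ensemble-mode pool obeys the pool-size law", {
  e <- twoBasinEnsemble(makeHelix(20), nA = 7, nB = 3)
  cl <- clusterEnsemble(e)
  pool <- buildSearchModels(e, cl, nClustersUsed = 1L)
  expect_length(pool, 180L)

  man <- searchModelManifest(pool)
  expect_equal(nrow(man), 180L)
  expect_equal(sort(unique(man$radius)), c(1, 2, 3))
  expect_setequal(unique(man$mode), c("allatom", "reliable", "polyala"))
  # residue counts match the ladder at every level
  lad <- truncationLadder(20)
  expect_setequal(unique(man$n_residues), lad$nKeep)
  # every model's stored residue count matches its structure
  for (k in c(1, 60, 180))
    expect_equal(nResidues(pool[[k]]@model), pool[[k]]@nResidues)

  # reduced configuration: one radius, one mode -> one model per level
  p1 <- buildSearchModels(e, cl, 1L, radii = 2, modes = "polyala")
  expect_length(p1, 20L)
  # polyala atom-count law (all-ALA fixture: 5 atoms per kept residue)
  expect_equal(nAtoms(p1[[1]]@model), 5L * p1[[1]]@nResidues)
})

test_that("clusters multiply the pool and tiny clusters still emit", {
  e <- twoBasinEnsemble(makeHelix(20), nA = 7, nB = 3)
  cl <- clusterEnsemble(e)
  expect_gte(length(cl@members), 2L)
  pool2 <- buildSearchModels(e, cl, nClustersUsed = 2L)
  expect_length(pool2, 360L)
  # cluster index recorded in provenance
  expect_setequal(unique(searchModelManifest(pool2)$cluster), c(1L, 2L))
})
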