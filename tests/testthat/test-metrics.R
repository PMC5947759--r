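caOnly <- function(positions) {
  n <- nrow(positions)
  a <- do.call(rbind, lapply(seq_len(n), function(i)
    mrforge:::atomRow("CA", "C", "ALA", "A", i)))
  mrforge:::newStructure(a, positions)
}

test_that("weighted contact number matches hand enumeration", {
  s2 <- caOnly(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(wcnProfile(s2, raw = TRUE)$wcn, c(0.25, 0.25))

  s3 <- caOnly(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  expect_equal(wcnProfile(s3, raw = TRUE)$wcn,
               c(1 / 9 + 1 / 36, 2 / 9, 1 / 9 + 1 / 36))

  s1 <- caOnly(matrix(c(1, 2, 3), 1))
  expect_equal(wcnProfile(s1, raw = TRUE)$wcn, 0)

  # emitted score is the negated raw value (higher = removed earlier)
  expect_equal(wcnProfile(s3)$wcn, -wcnProfile(s3, raw = TRUE)$wcn)
})

test_that("WCN is rigid-motion invariant and matches the brute-force oracle", {
  h <- makeHelix(14, tailRes = 4)
  raw <- wcnProfile(h, raw = TRUE)$wcn
  expect_equal(raw, bruteWcn(caCoordinates(h)), tolerance = 1e-12)

  R <- randomRotation()
  hr <- h
  hr@xyz[, , 1] <- sweep(coords(h) %*% t(R), 2, c(11, -4, 2), "+")
  expect_equal(wcnProfile(hr, raw = TRUE)$wcn, raw, tolerance = 1e-9)

  # strictly decreasing when one pair distance grows
  s3 <- caOnly(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)))
  s3far <- caOnly(rbind(c(0, 0, 0), c(4, 0, 0), c(9, 0, 0)))
  w0 <- wcnProfile(s3, raw = TRUE)$wcn
  w1 <- wcnProfile(s3far, raw = TRUE)$wcn
  expect_lt(w1[3], w0[3])
  expect_lt(w1[1], w0[1])
  expect_equal(w1[2] < w0[2], TRUE)
})

test_that("solvent-accessible areas match analytic and quadrature oracles", {
  # isolated carbon: full expanded sphere, 4*pi*(1.7+1.4)^2
  s1 <- caOnly(matrix(0, 1, 3))
  expect_equal(sasaProfile(s1)$asa, 4 * pi * 3.1^2, tolerance = 1e-6)

  # two atoms far apart: both full spheres
  s2 <- caOnly(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(sasaProfile(s2)$asa, rep(4 * pi * 3.1^2, 2), tolerance = 1e-6)

  # two overlapping spheres: analytic cap formula, convergence in nPoints
  s2b <- caOnly(rbind(c(0, 0, 0), c(2.5, 0, 0)))
  truth <- twoSphereAsa(3.1, 3.1, 2.5)
  a240 <- sasaProfile(s2b, nPoints = 240L)$asa
  a960 <- sasaProfile(s2b, nPoints = 960L)$asa
  expect_lte(max(abs(a960 - truth) / truth), max(abs(a240 - truth) / truth))
  expect_lte(max(abs(a960 - truth) / truth), 0.01)

  # random cluster vs an independent Monte-Carlo quadrature, within 2%
  set.seed(11)
  pos <- matrix(rnorm(15, sd = 2), ncol = 3)
  s5 <- caOnly(pos)
  got <- sasaProfile(s5, nPoints = 960L)$asa
  ref <- mcSasa(pos, rep(1.7, 5))
  expect_lt(max(abs(got - ref) / (4 * pi * 3.1^2)), 0.02)

  # adding atoms can only bury surface
  s4 <- caOnly(pos[1:4, , drop = FALSE])
  got4 <- sasaProfile(s4, nPoints = 960L)$asa
  expect_true(all(got[1:4] <= got4 + 1e-9))
  expect_lte(sum(got), 5 * 4 * pi * 3.1^2)
})

test_that("unknown elements fall back to the default radius with warning", {
  a <- mrforge:::atomRow("X1", "XX", "ALA", "A", 1)
  s <- mrforge:::newStructure(a, matrix(0, 1, 3))
  expect_warning(asa <- sasaProfile(s)$asa, "unknown element")
  expect_equal(asa, 4 * pi * (1.8 + 1.4)^2, tolerance = 1e-6)
})

test_that("B-factor profiles average heavy atoms per residue", {
  h <- makeHelix(3)
  h@atoms$b <- c(10, 20, 30, 20, 20,   # residue 1: mean 20
                 20, 20, 20, 20, 20,   # residue 2: uniform control
                 5, 5, 5, 5, 5)
  bp <- bfactorProfile(h)
  expect_equal(bp$bfac, c(20, 20, 5))
  # single-atom residue: that atom's B
  s1 <- caOnly(matrix(0, 1, 3))
  s1@atoms$b <- 37
  expect_equal(bfactorProfile(s1)$bfac, 37)
})

test_that("packing and exposure rank core above tail in opposite senses", {
  h <- makeHelix(16, tailRes = 6)
  lab <- assignSecondaryStructure(h)
  core <- which(lab == "H")
  tail <- (nResidues(h) - 3):nResidues(h)
  wcn <- wcnProfile(h, raw = TRUE)$wcn
  asa <- sasaProfile(h)$asa
  expect_gt(mean(wcn[core]), mean(wcn[tail]))   # core better packed
  expect_lt(mean(asa[core]), mean(asa[tail]))   # core less exposed
})

test_that("metric profiles round-trip through the score-file format", {
  h <- makeHelix(6)
  for (prof in list(wcnProfile(h), sasaProfile(h, nPoints = 240L),
                    bfactorProfile(h))) {
    f <- withr::local_tempfile(fileext = ".txt")
    writeScoreFile(prof, f)
    back <- parseScoreFile(f)
    expect_equal(back[[2]], prof[[2]], tolerance = 1e-10)
  }
})
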