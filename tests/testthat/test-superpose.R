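test_that("superposition handles identity, translation and rotation", {
  set.seed(1)
  a <- matrix(rnorm(30, sd = 4), ncol = 3)

  sp <- superpose(a, a)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)

  b <- sweep(a, 2, c(-5, 0, 0))         # b = a + (5,0,0)
  sp <- superpose(a, b)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  # mapping b back onto a undoes the shift
  expect_equal(sp$translation, c(-5, 0, 0), tolerance = 1e-9)

  for (k in 1:5) {
    R <- randomRotation()
    b <- a %*% t(R)
    sp <- superpose(a, b)
    expect_equal(sp$rmsd, 0, tolerance = 1e-8)
    expect_equal(sp$rotation %*% R, diag(3), tolerance = 1e-6)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  }
})

test_that("weighted fits and degenerate point sets behave", {
  set.seed(2)
  a <- matrix(rnorm(24, sd = 3), ncol = 3)
  b <- a; b[1, ] <- b[1, ] + 10       # one outlier point
  w <- c(0, rep(1, 7))                # zero weight kills the outlier
  sp <- superpose(a, b, w)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)

  line <- cbind(seq_len(6), 0, 0)      # collinear
  sp2 <- superpose(line, sweep(line, 2, c(-1, -2, -3)))
  expect_true(sp2$degenerate)
  expect_equal(sp2$rotation, diag(3))
  expect_equal(sp2$translation, c(-1, -2, -3), tolerance = 1e-9)
})

test_that("superposition RMSD agrees with an established implementation", {
  set.seed(3)
  a <- matrix(rnorm(45, sd = 5), ncol = 3)
  b <- a %*% t(randomRotation()) + matrix(rnorm(45, sd = 1), ncol = 3)
  ours <- superpose(a, b)$rmsd
  fit <- suppressWarnings(bio3d::fit.xyz(as.vector(t(a)), as.vector(t(b))))
  ref <- bio3d::rmsd(as.vector(t(a)), fit)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("pairwise RMSD matrix is symmetric with zero diagonal", {
  e <- makePerturbedEnsemble(makeHelix(8), 6, 0.5, seed = 4)
  dm <- pairwiseRmsd(e)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), rep(0, 6))
  # spot-check one entry against the scalar path
  r12 <- superpose(caCoordinates(e, 1), caCoordinates(e, 2))$rmsd
  expect_equal(dm[1, 2], r12, tolerance = 1e-8)
})
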