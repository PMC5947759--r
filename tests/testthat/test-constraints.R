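test_that("minimal structures yield the forced constraint census", {
  # two bonded atoms: exactly one tier-1 constraint
  a2 <- rbind(mrforge:::atomRow("N", "N", "ALA", "A", 1),
              mrforge:::atomRow("CA", "C", "ALA", "A", 1))
  s2 <- mrforge:::newStructure(a2, rbind(c(0, 0, 0), c(1.458, 0, 0)))
  cs2 <- extractConstraints(s2)
  expect_equal(nrow(cs2@constraints), 1L)
  expect_equal(cs2@constraints$tier, 1L)
  d <- 1.458
  expect_equal(cs2@constraints$lower, d * 0.995)
  expect_equal(cs2@constraints$upper, d * 1.005)

  # 3-atom chain A-B-C: two tier-1 bonds + one tier-2 (1-3) pair
  a3 <- rbind(mrforge:::atomRow("N", "N", "ALA", "A", 1),
              mrforge:::atomRow("CA", "C", "ALA", "A", 1),
              mrforge:::atomRow("C", "C", "ALA", "A", 1))
  s3 <- mrforge:::newStructure(a3, rbind(c(0, 0, 0), c(1.458, 0, 0),
                                         c(2.0, 1.4, 0)))
  cs3 <- extractConstraints(s3)
  expect_equal(sort(cs3@constraints$tier), c(1L, 1L, 2L))
})

test_that("helix constraint census matches the independent enumeration oracle", {
  for (n in c(10L, 15L)) {
    h <- makeHelix(n)
    cs <- extractConstraints(h)
    got <- table(factor(cs@constraints$tier, levels = 1:5))
    core <- 2:(n - 1)   # helical labels by construction
    want <- oracleConstraintCensus(h, helixCore = core)
    expect_equal(as.integer(got), as.integer(want),
                 label = paste("tier census, n =", n))
  }
})

test_that("tier bounds respect the observed geometry", {
  h <- makeHelix(12)
  cs <- extractConstraints(h)
  co <- cs@constraints
  x <- coords(h)
  d <- sqrt(rowSums((x[co$i, ] - x[co$j, ])^2))
  # the generating structure satisfies every bound it induced
  expect_true(all(d >= co$lower - 1e-9 & d <= co$upper + 1e-9))
  # tighter tiers have narrower relative widths
  width <- (co$upper - co$lower) / d
  mw <- tapply(width, co$tier, mean)
  expect_true(all(diff(mw[as.character(sort(unique(co$tier)))]) > 0))
  expect_equal(constraintViolation(cs, x, atomData(h)$elesy), 0)
})

test_that("clashing inputs are rejected with a diagnostic", {
  a <- rbind(mrforge:::atomRow("CA", "C", "ALA", "A", 1),
             mrforge:::atomRow("CA", "C", "ALA", "A", 2))
  s <- mrforge:::newStructure(a, rbind(c(0, 0, 0), c(1.0, 0, 0)))
  expect_error(extractConstraints(s), "clash")
})
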