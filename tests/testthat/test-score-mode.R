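writeScoreLines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("score files parse with auto-detected delimiters", {
  f <- writeScoreLines(c("res score", "1 0.5", "2 1.5", "3 0.1"))
  tab <- parseScoreFile(f)
  expect_equal(tab$resno, 1:3)
  expect_equal(names(tab), c("resno", "score"))
  expect_equal(tab$score, c(0.5, 1.5, 0.1))

  # two score columns, comma-delimited
  f2 <- writeScoreLines(c("res,wcn,bfac", "1,0.2,30", "2,0.4,10"))
  tab2 <- parseScoreFile(f2)
  expect_equal(names(tab2), c("resno", "wcn", "bfac"))
  expect_equal(tab2$bfac, c(30, 10))
})

test_that("malformed score files fail with line-level diagnostics", {
  expect_error(parseScoreFile(writeScoreLines(c("res score", "1 0.5", "2 oops"))),
               "line 3")
  expect_error(parseScoreFile(writeScoreLines(c("res score", "1 0.5 9"))),
               "fields")
  expect_error(parseScoreFile(writeScoreLines(c("res score", "1 0.5", "1 0.7"))),
               "duplicate")
  expect_error(parseScoreFile(writeScoreLines("res score")), "at least one row")
  expect_error(parseScoreFile(tempfile()), "not found")
})

test_that("single-model truncation yields 60 models per score column", {
  s <- makeHelix(20)
  tab <- data.frame(resno = 1:20, flex = rev(seq_len(20)))
  pool <- truncateSingleModel(s, tab)
  expect_length(pool, 60L)
  man <- searchModelManifest(pool)
  expect_true(all(is.na(man$radius)))
  expect_equal(unique(man$score_column), "flex")

  # two columns pool to 120 models
  tab2 <- cbind(tab, rigid = seq_len(20))
  expect_length(truncateSingleModel(s, tab2), 120L)

  # highest scores are removed first
  s4 <- makeHelix(4)
  t4 <- data.frame(resno = 1:4, s = c(9, 1, 5, 2))
  p4 <- truncateSingleModel(s4, t4, modes = "allatom")
  m50 <- p4[[which(vapply(p4, function(m) m@nResidues, integer(1)) == 2L)]]
  expect_equal(residueIds(m50@model), c(2L, 4L))
})

test_that("score/structure residue mismatches are errors, not imputations", {
  s <- makeHelix(5)
  expect_error(truncateSingleModel(s, data.frame(resno = 1:6, x = 1:6)),
               "absent from the structure")
  expect_error(truncateSingleModel(s, data.frame(resno = 1:4, x = 1:4)),
               "without a score")
})

test_that("truncation depends only on score ranks", {
  s <- makeHelix(15)
  set.seed(8)
  base <- data.frame(resno = 1:15, s = rnorm(15))
  ref <- truncateSingleModel(s, base, modes = "polyala")
  for (tr in list(function(x) 10 * x, function(x) x + 100,
                  function(x) 0.5 * x - 3)) {
    alt <- truncateSingleModel(s, transform(base, s = tr(s)),
                               modes = "polyala")
    for (k in seq_along(ref))
      expect_identical(ref[[k]]@model@xyz, alt[[k]]@model@xyz)
  }
})
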