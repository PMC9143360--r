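test_that("pdcp of a region against itself sits exactly on the diagonal", {
  x <- random_msa(6L, 200L, seed = 4)
  r <- region(1, 200)
  p <- pdcp(x, r, r)
  expect_equal(p$rmse, 0)
  expect_equal(p$slope, 1)
  expect_equal(p$intercept, 0)
  expect_equal(nrow(p$points), 15L)
  expect_false(p$degenerate)
})

test_that("pdcp regression matches an independent OLS fit on a toy mosaic", {
  # two 2-sequence clades; in region_b one sequence is replaced by a copy of
  # the other clade's member, creating incongruent distances
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, 120, replace = TRUE)
  a2 <- a1; a2[sample(120, 6)] <- sample(bases, 6, replace = TRUE)
  b1 <- a1; b1[sample(120, 25)] <- sample(bases, 25, replace = TRUE)
  b2 <- b1; b2[sample(120, 6)] <- sample(bases, 6, replace = TRUE)
  left <- list(a1, a2, b1, b2)
  right <- list(a1, a2, b1, a2)  # last sequence's right half donated by a2
  seqs <- vapply(1:4, function(i) paste(c(left[[i]], right[[i]]), collapse = ""),
                 character(1))
  x <- msa(seqs, ids = c("a1", "a2", "b1", "b2"))
  p <- pdcp(x, region(1, 120), region(121, 240))
  fit <- lm(d_b ~ d_a, data = p$points)
  expect_equal(p$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(p$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
  expect_equal(p$rmse, sqrt(mean(resid(fit)^2)), tolerance = 1e-12)
  expect_gt(p$rmse, 0.01)

  # removing the mosaic sequence strictly decreases the incongruence
  x3 <- msa(seqs[1:3], ids = c("a1", "a2", "b1"))
  p3 <- pdcp(x3, region(1, 120), region(121, 240))
  expect_lt(p3$rmse, p$rmse)
})

test_that("degenerate regressions are flagged, not zeroed", {
  x <- msa(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  p <- suppressWarnings(pdcp(x, region(1, 4), region(5, 8)))
  expect_true(p$degenerate)
  expect_equal(p$slope, 0)
  x2 <- msa(c(a = "ACGT", b = "ACGA"))
  expect_error(pdcp(x2, region(1, 2), region(3, 4)), "insufficient")
})

test_that("pddm window layout covers the alignment with full windows", {
  x <- random_msa(4L, 1700L, seed = 8)
  g <- pddm(x, window = 500, step = 250)
  starts <- vapply(g$windows, `[[`, integer(1), "start")
  expect_equal(starts, c(1L, 251L, 501L, 751L, 1001L, 1201L))
  expect_true(all(vapply(g$windows, region_length, integer(1)) == 500L))
  expect_identical(g$rmse, t(g$rmse))
  expect_equal(unname(diag(g$rmse)), rep(0, 6))
})

test_that("pddm on identical sequences is a flagged degenerate grid", {
  x <- msa(setNames(rep(strrep("ACGT", 50), 3), c("a", "b", "c")))
  expect_message(g <- pddm(x, window = 100, step = 50), "degenerate")
  expect_true(all(is.na(g$rmse[upper.tri(g$rmse)])))
  expect_gt(g$n_degenerate, 0)
})

test_that("low_recombination_span merges the longest run of quiet windows", {
  fake_grid <- function(row_vals, width = 100L) {
    k <- length(row_vals)
    rmse <- outer(row_vals, row_vals, function(a, b) (a + b) / 2)
    diag(rmse) <- 0
    windows <- lapply(seq_len(k), function(i) region((i - 1L) * width + 1L, i * width))
    structure(list(window = width, step = width, windows = windows,
                   rmse = rmse, n_degenerate = 0L), class = "pddm_grid")
  }
  g <- fake_grid(c(0.001, 0.001, 0.001, 0.05, 0.05, 0.05))
  span <- low_recombination_span(g, quantile = 0.5)
  expect_equal(c(span$start, span$end), c(1L, 300L))
  # uniform grid: nothing strictly below the quantile
  expect_warning(expect_null(low_recombination_span(fake_grid(rep(0.02, 5)))),
                 "no window")
  # a single low window yields that window alone
  g1 <- fake_grid(c(0.05, 0.001, 0.05, 0.05))
  span1 <- low_recombination_span(g1, quantile = 0.5)
  expect_equal(c(span1$start, span1$end), c(101L, 200L))
  # tie between equal-length runs resolves to the earliest
  g2 <- fake_grid(c(0.001, 0.05, 0.001, 0.05, 0.05, 0.05))
  span2 <- low_recombination_span(g2, quantile = 0.5)
  expect_equal(c(span2$start, span2$end), c(1L, 100L))
})

test_that("similarity scan window count and identity track behave as defined", {
  x <- random_msa(3L, 4400L, seed = 10)
  twin <- msa(c(x$seq, x$seq[1]), ids = c(x$ids, "twin"))
  s <- similarity_scan(twin, "twin", window = 1000, step = 40)
  expect_equal(length(s$centers), 86L)
  expect_equal(sort(s$panel_ids), sort(x$ids))
  expect_true(all(s$similarity[, "s01"] == 1))
  expect_true(all(s$similarity >= 0 & s$similarity <= 1, na.rm = TRUE))
})

test_that("a mosaic query crosses tracks at its breakpoint", {
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  donorA <- sample(bases, 2000, replace = TRUE)
  donorB <- donorA
  flip <- sample(2000, 400)  # ~20% divergence
  donorB[flip] <- vapply(donorB[flip], function(b) sample(setdiff(bases, b), 1), "")
  mosaic <- c(donorA[1:1000], donorB[1001:2000])
  x <- msa(c(A = paste(donorA, collapse = ""), B = paste(donorB, collapse = ""),
             Q = paste(mosaic, collapse = "")))
  s <- similarity_scan(x, "Q", window = 400, step = 100)
  first <- s$centers <= 800
  last <- s$centers >= 1400
  expect_true(all(s$similarity[first, "A"] == 1))
  expect_true(all(s$similarity[last, "B"] == 1))
  expect_true(mean(s$similarity[last, "A"]) < 0.85)
  expect_true(mean(s$similarity[first, "B"]) < 0.85)
})

test_that("similarity track TSV export has one row per window", {
  x <- random_msa(3L, 500L, seed = 12)
  s <- similarity_scan(x, "s01", window = 100, step = 50)
  path <- tempfile(fileext = ".tsv")
  write_similarity_tsv(s, path)
  df <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(df), length(s$centers))
  expect_equal(colnames(df), c("center", s$panel_ids))
})
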