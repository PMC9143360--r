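toy_dm <- function(vals, labels) {
  d <- matrix(0, length(labels), length(labels), dimnames = list(labels, labels))
  for (v in vals) {
    d[v[[1]], v[[2]]] <- d[v[[2]], v[[1]]] <- as.numeric(v[[3]])
  }
  p_dist_matrix(d)
}

test_that("threshold clustering uses strict d < threshold connected components", {
  dm <- toy_dm(list(list("A", "B", 0.05), list("B", "C", 0.05),
                    list("A", "C", 0.12)), c("A", "B", "C"))
  cl <- cluster_by_threshold(dm, 0.10)
  expect_length(cl$clusters, 1L)
  # chaining violation is surfaced, not hidden
  expect_equal(nrow(cl$violations), 1L)
  expect_setequal(unlist(cl$violations[1, c("id1", "id2")]), c("A", "C"))
  # a pair exactly at the threshold is between-genotype
  dm2 <- toy_dm(list(list("A", "B", 0.10)), c("A", "B"))
  expect_length(cluster_by_threshold(dm2, 0.10)$clusters, 2L)
  # all-zero matrix: a single cluster
  expect_length(cluster_by_threshold(toy_dm(list(), c("x", "y", "z")))$clusters, 1L)
  expect_error(cluster_by_threshold(dm, 0), "threshold")
  expect_error(cluster_by_threshold(dm, 1.5), "threshold")
})

test_that("clustering agrees with a transitive-closure brute force", {
  for (seed in 1:200) {
    set.seed(seed)
    n <- sample(3:12, 1)
    d <- matrix(0, n, n)
    vals <- round(runif(n * (n - 1) / 2, 0, 0.3), 2)
    d[upper.tri(d)] <- vals
    d <- d + t(d)
    labels <- sprintf("t%02d", 1:n)
    dimnames(d) <- list(labels, labels)
    thr <- sample(c(0.05, 0.1, 0.15, 0.2), 1)
    cl <- cluster_by_threshold(p_dist_matrix(d), thr)
    oracle <- closure_components(d, thr)
    expect_equal(canonical_partition(unname(cl$membership)),
                 canonical_partition(oracle))
  }
})

test_that("clustering is invariant to label order, and monotone in threshold", {
  set.seed(101)
  n <- 10
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- round(runif(n * (n - 1) / 2, 0, 0.25), 2)
  d <- d + t(d)
  labels <- sprintf("v%02d", 1:n)
  dimnames(d) <- list(labels, labels)
  cl <- cluster_by_threshold(p_dist_matrix(d), 0.10)
  perm <- sample(n)
  cl_p <- cluster_by_threshold(p_dist_matrix(d[perm, perm]), 0.10)
  expect_equal(lapply(cl$clusters, sort)[order(sapply(cl$clusters, min))],
               lapply(cl_p$clusters, sort)[order(sapply(cl_p$clusters, min))])
  # every cluster at t is inside some cluster at t' > t
  cl_hi <- cluster_by_threshold(p_dist_matrix(d), 0.20)
  for (grp in cl$clusters) {
    host <- cl_hi$membership[grp]
    expect_length(unique(host), 1L)
  }
})

test_that("missing distances contribute no edge", {
  d <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  dm <- p_dist_matrix(d)
  expect_message(cl <- cluster_by_threshold(dm, 0.1), "missing")
  expect_length(cl$clusters, 2L)
})

test_that("between-cluster ranges bracket every cross-cluster pair", {
  dm <- table1_fixture("nt")
  cl <- cluster_by_threshold(dm, 0.10)
  rng <- between_cluster_ranges(dm, cl)
  expect_true(all(rng$min <= rng$max))
  # singleton-vs-singleton pairs collapse to a point range
  singletons <- which(vapply(cl$clusters, length, integer(1)) == 1L)
  ss <- rng$cluster_i %in% singletons & rng$cluster_j %in% singletons
  expect_true(all(rng$min[ss] == rng$max[ss]))
  bad <- cluster_by_threshold(toy_dm(list(), c("A", "B")), 0.1)
  expect_error(between_cluster_ranges(dm, bad), "labels")
})

test_that("cloud partition is disjoint and exhaustive", {
  dm_nt <- table1_fixture("nt")
  dm_aa <- table1_fixture("aa")
  cp <- cloud_partition(dm_nt, dm_aa)
  expect_equal(sum(cp$counts), 55L)  # 11 * 10 / 2
  expect_gt(cp$counts[["low"]], 0L)
  expect_gt(cp$counts[["high"]], 0L)
  # every within-genotype pair of the known classification is in the low cloud
  cl <- cluster_by_threshold(dm_nt, 0.10)
  same <- cl$membership[cp$pairs$id1] == cl$membership[cp$pairs$id2]
  expect_true(all(cp$pairs$cloud[same] == "low"))
  expect_true(all(cp$pairs$cloud[!same] != "low"))
  # bounds that no pair can satisfy leave everything unassigned
  cp0 <- cloud_partition(dm_nt, dm_aa,
                         bounds = list(nt_low_max = 0, aa_low_max = 0,
                                       nt_high_min = 1, aa_high_min = 1))
  expect_equal(unname(cp0$counts[["unassigned"]]), 55L)
  # identical sequences: every pair in the low cloud
  x <- msa(setNames(rep("ACGTACGTACGT", 4), letters[1:4]))
  dm0 <- pairwise_matrix(x)
  cp1 <- cloud_partition(dm0, dm0)
  expect_equal(unname(cp1$counts[["low"]]), 6L)
  expect_error(cloud_partition(dm_nt, dm0), "labels")
})

test_that("query assignment picks the unique sub-threshold cluster", {
  # two clades of three: members a few substitutions from their clade base,
  # clade bases ~25% apart
  set.seed(33)
  bases <- c("A", "C", "G", "T")
  base_a <- sample(bases, 300, TRUE)
  base_b <- base_a
  flip <- sample(300, 75)
  base_b[flip] <- vapply(base_a[flip], function(ch) sample(setdiff(bases, ch), 1), "")
  jitter <- function(s) {
    i <- sample(300, 5)
    s[i] <- vapply(s[i], function(ch) sample(setdiff(bases, ch), 1), "")
    paste(s, collapse = "")
  }
  refs <- msa(c(vapply(1:3, function(i) jitter(base_a), ""),
                vapply(1:3, function(i) jitter(base_b), "")),
              ids = sprintf("r%d", 1:6))
  dm <- pairwise_matrix(refs)
  cl <- cluster_by_threshold(dm, 0.10)
  expect_length(cl$clusters, 2L)

  hit <- assign_genotype(refs$seq[1], refs, cl)
  expect_equal(unname(hit$label), 1L)
  expect_equal(unname(hit$distances[["1"]]), 0)

  novel <- assign_genotype(paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                                 collapse = ""), refs, cl)
  expect_equal(novel$label, "novel")

  expect_error(assign_genotype("ACGT", refs, cl), "alignment error")
  expect_error(assign_genotype(strrep("N", 300), refs, cl), "undefined")
})

test_that("a query equidistant below threshold from two clusters is ambiguous", {
  # references 60 nt apart in 300 (d = 0.2); query 30 from each (d = 0.1 > thr?)
  set.seed(55)
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, 300, TRUE)
  flip <- sample(300, 60)
  b <- a
  b[flip] <- vapply(a[flip], function(ch) sample(setdiff(bases, ch), 1), "")
  q <- a
  q[flip[1:30]] <- b[flip[1:30]]  # 0.1 from a, 0.1 from b
  refs <- msa(c(A = paste(a, collapse = ""), B = paste(b, collapse = "")))
  cl <- cluster_by_threshold(pairwise_matrix(refs), 0.10)
  res <- assign_genotype(paste(q, collapse = ""), refs, cl, threshold = 0.15)
  expect_true("ambiguous" %in% res$flags)
  expect_true(is.na(res$label))
})
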