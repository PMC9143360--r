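# programmatic fixtures shared across test files

random_msa <- function(n = 6L, L = 60L, seed = 1L, gap_frac = 0,
                       amb_frac = 0) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(bases, L, replace = TRUE)
    k <- round(gap_frac * L)
    if (k > 0) s[sample.int(L, k)] <- "-"
    k <- round(amb_frac * L)
    if (k > 0) s[sample.int(L, k)] <- "N"
    paste(s, collapse = "")
  }, character(1L))
  msa(seqs, ids = sprintf("s%02d", seq_len(n)))
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# independent oracle: connected components at a distance threshold via
# boolean transitive closure of the adjacency matrix
closure_components <- function(d, threshold) {
  adj <- !is.na(d) & d < threshold
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(nrow(d))
  k <- 0L
  for (i in seq_len(nrow(d))) {
    if (comp[i] == 0L) {
      k <- k + 1L
      comp[reach[i, ]] <- k
    }
  }
  comp
}

# canonical form of a partition (relabel by first appearance) so two
# partitions can be compared up to label permutation
canonical_partition <- function(m) {
  match(m, unique(m))
}

# independent oracle for 4-taxon NJ: least-squares branch lengths for each
# of the three unrooted quartet topologies; returns the split of the best
# fit plus its residual sum of squares
quartet_ls <- function(D) {
  taxa <- rownames(D)
  splits <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  fit_one <- function(pair) {
    other <- setdiff(1:4, pair)
    a <- pair[1L]; b <- pair[2L]; c <- other[1L]; d <- other[2L]
    # unknowns: ea, eb, ec, ed, em (internal edge)
    X <- rbind(
      c(1, 1, 0, 0, 0),  # d(a,b)
      c(1, 0, 1, 0, 1),  # d(a,c)
      c(1, 0, 0, 1, 1),  # d(a,d)
      c(0, 1, 1, 0, 1),  # d(b,c)
      c(0, 1, 0, 1, 1),  # d(b,d)
      c(0, 0, 1, 1, 0))  # d(c,d)
    y <- c(D[a, b], D[a, c], D[a, d], D[b, c], D[b, d], D[c, d])
    beta <- qr.solve(X, y)
    list(split = sort(taxa[pair]), rss = sum((y - X %*% beta)^2),
         lengths = beta)
  }
  fits <- lapply(splits, fit_one)
  best <- which.min(vapply(fits, `[[`, numeric(1L), "rss"))
  out <- fits[[best]]
  out$split <- canonical_split(out$split, taxa)
  out
}

# a quartet split named by the side holding the alphabetically first taxon
canonical_split <- function(side, taxa) {
  side <- sort(side)
  if (min(taxa) %in% side) side else sort(setdiff(taxa, side))
}

# the split {t1,t2} vs rest implied by an unrooted 4-taxon phylo tree
quartet_split <- function(tree) {
  stopifnot(length(tree$tip.label) == 4L)
  internal <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  # partition tips by which side of the internal edge they fall on
  ie <- which(tree$edge[, 2L] > length(tree$tip.label))
  if (length(ie) == 0L) return(sort(tree$tip.label)[1:2])  # star fallback
  sub <- ape::extract.clade(ape::root(tree, node = tree$edge[ie[1L], 1L],
                                      resolve.root = FALSE),
                            tree$edge[ie[1L], 2L])$tip.label
  side <- if (length(sub) == 2L) sub else setdiff(tree$tip.label, sub)
  canonical_split(side, tree$tip.label)
}

# additive distance matrix from a random quartet tree with positive lengths
random_additive_quartet <- function(seed) {
  set.seed(seed)
  lens <- round(stats::runif(5L, 0.05, 1), 3)
  nwk <- sprintf("((A:%g,B:%g):%g,C:%g,D:%g);",
                 lens[1L], lens[2L], lens[5L], lens[3L], lens[4L])
  tr <- ape::read.tree(text = nwk)
  D <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  list(D = D, split = c("A", "B"), tree = tr)
}
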