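#' Threshold clustering of a distance matrix into genotypes
#'
#' Builds a graph over sequence ids with an edge wherever the pairwise
#' distance is strictly below `threshold`, and reports its connected
#' components (single linkage). Under the rep-gene genotype definition two
#' sequences in the same genotype differ by less than 10% of nucleotides, so
#' a pair at exactly the threshold is between-genotype. Missing distances
#' contribute no edge.
#'
#' Because single linkage can chain, any same-cluster pair at or above the
#' threshold is surfaced in `violations` rather than hidden; a clustering
#' with empty `violations` has max within-cluster distance strictly below
#' the threshold.
#'
#' @param dm a `p_dist_matrix`.
#' @param threshold proportion in `(0, 1]`; default 0.10.
#' @return An object of class `genotype_clustering`: `threshold`;
#'   `clusters` (list of label vectors, numbered by first appearance in
#'   `dm$labels`); `membership` (named integer vector); `within_max`
#'   (per-cluster max distance, `NA` for singletons); `between` (data frame
#'   `cluster_i`, `cluster_j`, `min`, `max`); `violations` (data frame of
#'   same-cluster pairs with distance >= threshold).
#' @export
cluster_by_threshold <- function(dm, threshold = 0.10) {
  stopifnot(inherits(dm, "p_dist_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  n <- length(dm$labels)
  adj <- !is.na(dm$d) & dm$d < threshold
  diag(adj) <- TRUE
  n_missing <- sum(is.na(dm$d[upper.tri(dm$d)]))
  if (n_missing > 0L)
    message(n_missing, " missing distance(s) treated as no edge")
  # connected components by breadth-first search, numbered by first member
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  clusters <- lapply(seq_len(k), function(g) dm$labels[comp == g])
  membership <- stats::setNames(comp, dm$labels)

  within_max <- vapply(seq_len(k), function(g) {
    idx <- which(comp == g)
    if (length(idx) < 2L) return(NA_real_)
    sub <- dm$d[idx, idx]
    v <- sub[upper.tri(sub)]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1L))

  between <- between_ranges_from_membership(dm, comp, k)

  viol <- which(outer(comp, comp, "==") & !is.na(dm$d) & dm$d >= threshold &
                  upper.tri(dm$d), arr.ind = TRUE)
  violations <- data.frame(id1 = dm$labels[viol[, 1L]],
                           id2 = dm$labels[viol[, 2L]],
                           distance = dm$d[viol], stringsAsFactors = FALSE)

  structure(list(threshold = threshold, clusters = clusters,
                 membership = membership, within_max = within_max,
                 between = between, violations = violations),
            class = "genotype_clustering")
}

between_ranges_from_membership <- function(dm, comp, k) {
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      vals <- dm$d[comp == i, comp == j, drop = FALSE]
      vals <- vals[!is.na(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_i = i, cluster_j = j,
        min = if (length(vals)) min(vals) else NA_real_,
        max = if (length(vals)) max(vals) else NA_real_)
    }
  }
  if (!length(rows))
    return(data.frame(cluster_i = integer(), cluster_j = integer(),
                      min = numeric(), max = numeric()))
  do.call(rbind, rows)
}

#' @export
print.genotype_clustering <- function(x, ...) {
  cat(sprintf("genotype_clustering: %d cluster(s) at threshold %.3g\n",
              length(x$clusters), x$threshold))
  for (g in seq_along(x$clusters)) {
    cat(sprintf("  %d: {%s}%s\n", g, paste(x$clusters[[g]], collapse = ", "),
                if (!is.na(x$within_max[g]))
                  sprintf("  within-max %.3g", x$within_max[g]) else ""))
  }
  if (nrow(x$violations))
    cat(" ", nrow(x$violations), "within-cluster pair(s) at/above threshold\n")
  invisible(x)
}

#' Between-cluster distance ranges
#'
#' The min/max pairwise distance over every cross-cluster pair of sequences,
#' the quantity tabulated when reporting genotype-to-genotype divergence.
#' Singleton-vs-singleton cluster pairs have `min == max`.
#'
#' @param dm a `p_dist_matrix`.
#' @param clustering a `genotype_clustering` over exactly `dm`'s label set.
#' @return Data frame with columns `cluster_i`, `cluster_j`, `min`, `max`.
#' @export
between_cluster_ranges <- function(dm, clustering) {
  stopifnot(inherits(dm, "p_dist_matrix"), inherits(clustering, "genotype_clustering"))
  if (!setequal(names(clustering$membership), dm$labels))
    stop("clustering labels do not match the distance matrix")
  comp <- unname(clustering$membership[dm$labels])
  between_ranges_from_membership(dm, comp, length(clustering$clusters))
}

#' Default nucleotide/amino-acid cloud bounds
#'
#' Bounds of the two clouds observed in the rep-region distance scatter:
#' the within-genotype cloud reaches 7.5% nt and 8% aa divergence, the
#' between-genotype cloud starts above 11% nt and 6% aa.
#'
#' @return Named list `nt_low_max`, `aa_low_max`, `nt_high_min`, `aa_high_min`.
#' @export
default_cloud_bounds <- function() {
  list(nt_low_max = 0.075, aa_low_max = 0.08,
       nt_high_min = 0.11, aa_high_min = 0.06)
}

#' Partition sequence pairs into nt/aa distance clouds
#'
#' Assigns every unordered pair of sequences to the low cloud (nt and aa
#' distances both at or below the low bounds), the high cloud (both strictly
#' above the high bounds) or neither. The three bins are disjoint and
#' exhaustive: their sizes sum to `n(n-1)/2`. Pairs with a missing distance
#' cannot satisfy either cloud and fall in `unassigned`.
#'
#' @param dm_nt,dm_aa `p_dist_matrix` objects over the same labels in the
#'   same order (nucleotide and inferred amino-acid distances).
#' @param bounds list as returned by [default_cloud_bounds()].
#' @return An object of class `cloud_partition`: `counts` (named integer
#'   vector `low`, `high`, `unassigned`), `pairs` (data frame `id1`, `id2`,
#'   `nt`, `aa`, `cloud`) and `bounds`.
#' @export
cloud_partition <- function(dm_nt, dm_aa, bounds = default_cloud_bounds()) {
  stopifnot(inherits(dm_nt, "p_dist_matrix"), inherits(dm_aa, "p_dist_matrix"))
  if (!identical(dm_nt$labels, dm_aa$labels))
    stop("nt and aa matrices must share the same labels in the same order")
  pn <- dist_pairs(dm_nt)
  pa <- dist_pairs(dm_aa)
  low <- !is.na(pn$distance) & !is.na(pa$distance) &
    pn$distance <= bounds$nt_low_max & pa$distance <= bounds$aa_low_max
  high <- !is.na(pn$distance) & !is.na(pa$distance) &
    pn$distance > bounds$nt_high_min & pa$distance > bounds$aa_high_min
  cloud <- ifelse(low, "low", ifelse(high, "high", "unassigned"))
  pairs <- data.frame(id1 = pn$id1, id2 = pn$id2, nt = pn$distance,
                      aa = pa$distance, cloud = cloud, stringsAsFactors = FALSE)
  counts <- c(low = sum(low), high = sum(high),
              unassigned = sum(!low & !high))
  structure(list(counts = counts, pairs = pairs, bounds = bounds),
            class = "cloud_partition")
}

#' @export
print.cloud_partition <- function(x, ...) {
  cat(sprintf("cloud_partition: %d low / %d high / %d unassigned (of %d pairs)\n",
              x$counts[["low"]], x$counts[["high"]], x$counts[["unassigned"]],
              sum(x$counts)))
  invisible(x)
}

#' Assign a query sequence to a genotype
#'
#' Computes the query's p-distance to every reference, takes the minimum per
#' cluster, and assigns the unique cluster whose minimum is strictly below
#' the threshold. A query below the threshold against two or more clusters
#' is flagged ambiguous and left unassigned; a query below it against none
#' is reported `"novel"`.
#'
#' @param query an aligned sequence (character string) on the same column
#'   coordinates as `refs`.
#' @param refs an [msa] of reference sequences.
#' @param clustering a `genotype_clustering` over `refs`' ids.
#' @param threshold proportion; default 0.10.
#' @param alphabet `"nt"` or `"aa"`.
#' @return List with `label` (cluster index, `"novel"`, or `NA` when
#'   ambiguous), `distances` (per-cluster minimum distance) and `flags`
#'   (character vector; may contain `"ambiguous"`).
#' @export
assign_genotype <- function(query, refs, clustering, threshold = 0.10,
                            alphabet = "nt") {
  stopifnot(inherits(refs, "msa"), inherits(clustering, "genotype_clustering"))
  query <- toupper(as.character(query))
  if (nchar(query) != alignment_length(refs))
    stop("alignment error: query length ", nchar(query),
         " does not match reference alignment length ", alignment_length(refs))
  d <- vapply(refs$seq, function(s) p_distance(query, s, alphabet)$distance,
              numeric(1L), USE.NAMES = FALSE)
  names(d) <- refs$ids
  if (all(is.na(d))) stop("all query-to-reference distances are undefined")
  k <- length(clustering$clusters)
  cluster_min <- vapply(seq_len(k), function(g) {
    v <- d[clustering$clusters[[g]]]
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  }, numeric(1L))
  names(cluster_min) <- as.character(seq_len(k))
  hits <- which(!is.na(cluster_min) & cluster_min < threshold)
  flags <- character(0)
  if (length(hits) == 0L) {
    label <- "novel"
  } else if (length(hits) == 1L) {
    label <- hits
  } else {
    label <- NA_integer_
    flags <- "ambiguous"
  }
  list(label = label, distances = cluster_min, flags = flags)
}
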