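NT_RESIDUES <- c("A", "C", "G", "T")
AA_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

residue_set <- function(alphabet = c("nt", "aa")) {
  switch(match.arg(alphabet), nt = NT_RESIDUES, aa = AA_RESIDUES)
}

#' Pairwise p-distance between two aligned sequences
#'
#' The p-distance is the proportion of differing sites among comparable
#' sites. A column is comparable only when both sequences carry an
#' unambiguous residue (`A`/`C`/`G`/`T` for nucleotides, the 20 standard
#' amino acids for proteins); gaps, `N`/`X` and IUPAC ambiguity codes are
#' excluded per pair (pairwise deletion).
#'
#' @param a,b aligned sequences of equal length (character strings).
#' @param alphabet `"nt"` or `"aa"`.
#' @return A list with `distance` (proportion in `[0, 1]`, `NA` if no column
#'   is comparable) and `comparable_sites` (integer).
#' @export
p_distance <- function(a, b, alphabet = c("nt", "aa")) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  res <- residue_set(alphabet)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  ok <- (ca %in% res) & (cb %in% res)
  n <- sum(ok)
  d <- if (n == 0L) NA_real_ else sum(ca[ok] != cb[ok]) / n
  list(distance = d, comparable_sites = n)
}

#' Full pairwise p-distance matrix
#'
#' Computes all `n(n-1)/2` pairwise p-distances of an alignment under
#' pairwise deletion. Pairs with no comparable site are stored as `NA`
#' (never silently 0) and flagged with a warning.
#'
#' No evolutionary-model correction is applied: values are raw proportions
#' of differing sites, the metric under which the rep-gene genotype
#' threshold is defined.
#'
#' @param x an [msa] with at least 2 records.
#' @param alphabet `"nt"` or `"aa"`.
#' @return An object of class `p_dist_matrix`: list with `labels`, `d`
#'   (symmetric numeric matrix, zero diagonal, `NA` where undefined) and
#'   `comparable_sites` (symmetric integer matrix).
#' @export
pairwise_matrix <- function(x, alphabet = c("nt", "aa")) {
  stopifnot(inherits(x, "msa"))
  if (length(x$ids) < 2L) stop("need at least 2 records for pairwise distances")
  res <- residue_set(alphabet)
  m <- msa_char_matrix(x)
  valid <- matrix(m %in% res, nrow = nrow(m))
  # matches and comparable-site counts via indicator cross-products
  comp <- tcrossprod(valid * 1)
  match_ct <- matrix(0, nrow(m), nrow(m))
  for (ch in res) match_ct <- match_ct + tcrossprod((m == ch & valid) * 1)
  d <- (comp - match_ct) / comp
  d[comp == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(x$ids, x$ids)
  storage.mode(comp) <- "integer"
  dimnames(comp) <- dimnames(d)
  n_undef <- sum(is.na(d[upper.tri(d)]))
  if (n_undef > 0L)
    warning(n_undef, " pair(s) share no comparable site; distances stored as NA")
  new_p_dist_matrix(x$ids, d, comp)
}

new_p_dist_matrix <- function(labels, d, comparable_sites = NULL) {
  if (is.null(comparable_sites)) {
    comparable_sites <- matrix(NA_integer_, nrow(d), ncol(d), dimnames = dimnames(d))
  }
  structure(list(labels = labels, d = d, comparable_sites = comparable_sites),
            class = "p_dist_matrix")
}

#' Construct a p-distance matrix from a plain matrix
#'
#' Wraps an existing symmetric matrix of proportions (for example a
#' published distance table) in the container used by the clustering and
#' tree functions. Comparable-site counts may be unknown (`NA`).
#'
#' @param d symmetric numeric matrix with zero diagonal; dimnames used as
#'   labels unless `labels` is given.
#' @param labels optional character vector of sequence ids.
#' @param comparable_sites optional symmetric integer matrix.
#' @return A `p_dist_matrix` object.
#' @export
p_dist_matrix <- function(d, labels = rownames(d), comparable_sites = NULL) {
  d <- as.matrix(d)
  if (is.null(labels)) stop("labels are required")
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (length(labels) != nrow(d)) stop("labels length does not match matrix")
  if (any(abs(d - t(d)) > 1e-12, na.rm = TRUE)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0, na.rm = TRUE)) stop("diagonal must be zero")
  if (any(d < 0 | d > 1, na.rm = TRUE)) stop("distances must lie in [0, 1]")
  dimnames(d) <- list(labels, labels)
  new_p_dist_matrix(as.character(labels), d, comparable_sites)
}

#' @export
print.p_dist_matrix <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("p_dist_matrix: %d labels, %d pairs (%d undefined)\n",
              n, n * (n - 1L) / 2L, sum(is.na(x$d[upper.tri(x$d)]))))
  print(utils::head(round(x$d, 3), 8L))
  invisible(x)
}

#' @export
as.matrix.p_dist_matrix <- function(x, ...) x$d

#' @export
as.dist.p_dist_matrix <- function(m, ...) stats::as.dist(m$d)

# lower-triangle pair table: id1, id2, distance (row order fixed by labels)
dist_pairs <- function(dm) {
  n <- length(dm$labels)
  idx <- which(lower.tri(dm$d), arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  data.frame(id1 = dm$labels[idx[, 2L]], id2 = dm$labels[idx[, 1L]],
             distance = dm$d[idx], stringsAsFactors = FALSE)
}

#' Write / read a distance matrix as TSV
#'
#' Square tab-separated layout: a header row of labels, a label column, and
#' a numeric body with missing values as `NA`. The reader accepts the same
#' dialect, which is also how printed distance tables are supplied.
#'
#' @param x a `p_dist_matrix`.
#' @param path file path.
#' @return `write_distance_tsv`: `path` invisibly. `read_distance_tsv`: a
#'   `p_dist_matrix`.
#' @export
write_distance_tsv <- function(x, path) {
  stopifnot(inherits(x, "p_dist_matrix"))
  df <- data.frame(id = x$labels, x$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1L)
  m <- as.matrix(df)
  p_dist_matrix(m, labels = rownames(m))
}

#' Split an alignment into odd and even columns
#'
#' The two interleaved halves of an alignment carry the same phylogenetic
#' signal, so a distance-congruence comparison between them is a negative
#' control for recombination scanning: only sampling noise separates them.
#'
#' @param x an [msa] with at least 2 columns.
#' @return A list with elements `odd` (columns 1, 3, 5, ...) and `even`
#'   (columns 2, 4, 6, ...), both [msa] objects.
#' @export
even_odd_split <- function(x) {
  stopifnot(inherits(x, "msa"))
  L <- alignment_length(x)
  if (L < 2L) stop("alignment must have at least 2 columns")
  m <- msa_char_matrix(x)
  odd_i <- seq(1L, L, by = 2L)
  even_i <- seq(2L, L, by = 2L)
  collapse <- function(cols) apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
  list(odd = msa(collapse(odd_i), ids = x$ids, desc = x$desc,
                 alphabet = attr(x, "alphabet")),
       even = msa(collapse(even_i), ids = x$ids, desc = x$desc,
                  alphabet = attr(x, "alphabet")))
}
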