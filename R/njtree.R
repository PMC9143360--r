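newick_label <- function(x) {
  if (grepl("[][ ():;,']", x)) {
    paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  } else x
}

fmt_len <- function(l) sprintf("%.12g", l)

#' Neighbor-joining tree from a p-distance matrix
#'
#' Standard agglomerative neighbor joining: at each step the pair minimizing
#' the Q criterion is joined, with branch lengths from the usual rate-
#' corrected formulas; the last three lineages are joined at a central
#' vertex by the closed three-point formulas. The result is an unrooted
#' `ape::phylo` tree whose leaf labels are the matrix labels. For an
#' additive distance matrix the leaf-to-leaf path lengths reproduce the
#' input exactly.
#'
#' Ties in the Q minimization are broken deterministically by the lowest
#' (row, column) index pair, so the output depends only on the input order.
#' Negative branch lengths are clamped to zero; the number clamped is
#' attached as attribute `negative_clamped`.
#'
#' @param dm a `p_dist_matrix` with at least 2 labels and no missing entry.
#' @return An `ape::phylo` object (unrooted for `n >= 3`).
#' @export
neighbor_joining <- function(dm) {
  stopifnot(inherits(dm, "p_dist_matrix"))
  n <- length(dm$labels)
  if (n < 2L) stop("need at least 2 sequences to build a tree")
  D <- unname(dm$d)
  if (anyNA(D))
    stop("distance matrix has missing entries; impute or remove those taxa first")
  n_clamped <- 0L
  clamp <- function(l) {
    if (l < 0) { n_clamped <<- n_clamped + 1L; 0 } else l
  }
  # build with placeholder leaf names, restore real labels on the phylo
  nodes <- sprintf("t%d", seq_len(n))

  finish <- function(nwk) {
    tree <- ape::read.tree(text = nwk)
    tree$tip.label <- dm$labels[as.integer(sub("^t", "", tree$tip.label))]
    attr(tree, "negative_clamped") <- n_clamped
    tree
  }

  if (n == 2L) {
    h <- D[1L, 2L] / 2
    return(finish(sprintf("(%s:%s,%s:%s);", nodes[1L], fmt_len(h),
                          nodes[2L], fmt_len(h))))
  }

  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    # lowest (row, col) index pair among the minima, scanning i < j row-major
    best <- c(1L, 2L); qmin <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        if (Q[i, j] < qmin) { qmin <- Q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    li_raw <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    li <- clamp(li_raw)
    lj <- clamp(D[i, j] - li_raw)
    merged <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt_len(li), nodes[j], fmt_len(lj))
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]), c(newd[keep], 0))
    nodes <- c(nodes[keep], merged)
  }

  la <- clamp((D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2)
  lb <- clamp((D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2)
  lc <- clamp((D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2)
  finish(sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1L], fmt_len(la),
                 nodes[2L], fmt_len(lb), nodes[3L], fmt_len(lc)))
}

#' Serialize a tree to Newick
#'
#' Writes a `phylo` tree as a Newick string with branch lengths. Labels
#' containing Newick-reserved characters (parentheses, commas, colons,
#' semicolons, brackets, spaces or quotes) are single-quoted, with embedded
#' quotes doubled.
#'
#' @param tree an `ape::phylo` object.
#' @param decimals digits after the decimal point for branch lengths.
#' @return A single Newick string terminated by `;`.
#' @seealso [read_newick()] for the inverse.
#' @export
to_newick <- function(tree, decimals = 6L) {
  stopifnot(inherits(tree, "phylo"))
  decimals <- as.integer(decimals)
  nt <- length(tree$tip.label)
  root <- nt + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  lens <- tree$edge.length
  edge_of <- integer(max(tree$edge))
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  fmt <- function(node) {
    lab <- if (node <= nt) newick_label(tree$tip.label[node]) else ""
    sub <- kids[[as.character(node)]]
    core <- if (is.null(sub)) lab else {
      paste0("(", paste(vapply(sub, fmt, character(1L)), collapse = ","), ")", lab)
    }
    if (node == root || is.null(lens)) return(core)
    paste0(core, ":", formatC(lens[edge_of[node]], format = "f", digits = decimals))
  }
  paste0(fmt(root), ";")
}

#' Read a Newick string or file
#'
#' Thin wrapper over `ape::read.tree` that additionally strips the single
#' quotes `ape` retains around quoted labels, so [to_newick()] round-trips
#' to an isomorphic tree with identical labels.
#'
#' @param text Newick string (use `file` for a path).
#' @param file optional path to a Newick file.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", substr(x[q], 2L, nchar(x[q]) - 1L), fixed = TRUE)
    x
  }
  tree$tip.label <- unquote(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- unquote(tree$node.label)
  tree
}
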