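# OLS of y on x plus root-mean-square error of the residuals.
# Zero variance in x cannot support a regression: slope 0, intercept mean(y),
# flagged degenerate rather than silently zeroed.
ols_rmse <- function(x, y) {
  if (length(x) < 3L) stop("insufficient data: need >= 3 points for regression")
  vx <- stats::var(x)
  if (vx == 0) {
    slope <- 0
    intercept <- mean(y)
    degenerate <- TRUE
  } else {
    slope <- stats::cov(x, y) / vx
    intercept <- mean(y) - slope * mean(x)
    degenerate <- FALSE
  }
  resid <- y - (slope * x + intercept)
  list(slope = slope, intercept = intercept,
       rmse = sqrt(mean(resid^2)), degenerate = degenerate)
}

#' Pairwise distance correspondence plot (PDCP)
#'
#' For every pair of sequences, plots (conceptually) its p-distance in one
#' genome region against its p-distance in another. When the two regions
#' share a phylogenetic history the points fall on a line; recombination
#' between the regions scatters them. The deviation is summarized as the
#' root-mean-square error (RMSE) of the points around the ordinary
#' least-squares regression of `d_b` on `d_a`.
#'
#' @param x a nucleotide [msa].
#' @param region_a,region_b [region]s within the alignment.
#' @param alphabet passed to [pairwise_matrix()].
#' @return An object of class `pdcp_result`: regions, a `points` data frame
#'   (`id1`, `id2`, `d_a`, `d_b`), `slope`, `intercept`, `rmse`,
#'   `n_omitted` (pairs undefined in either region) and a `degenerate` flag
#'   (zero variance in `d_a`).
#' @export
pdcp <- function(x, region_a, region_b, alphabet = "nt") {
  stopifnot(inherits(x, "msa"))
  dm_a <- suppressWarnings(pairwise_matrix(extract_region(x, region_a), alphabet))
  dm_b <- suppressWarnings(pairwise_matrix(extract_region(x, region_b), alphabet))
  pdcp_from_matrices(dm_a, dm_b, region_a, region_b)
}

pdcp_from_matrices <- function(dm_a, dm_b, region_a, region_b) {
  pa <- dist_pairs(dm_a)
  pb <- dist_pairs(dm_b)
  ok <- !is.na(pa$distance) & !is.na(pb$distance)
  pts <- data.frame(id1 = pa$id1[ok], id2 = pa$id2[ok],
                    d_a = pa$distance[ok], d_b = pb$distance[ok],
                    stringsAsFactors = FALSE)
  fit <- ols_rmse(pts$d_a, pts$d_b)
  structure(list(region_a = region_a, region_b = region_b, points = pts,
                 slope = fit$slope, intercept = fit$intercept, rmse = fit$rmse,
                 n_omitted = sum(!ok), degenerate = fit$degenerate),
            class = "pdcp_result")
}

#' @export
print.pdcp_result <- function(x, ...) {
  cat(sprintf("pdcp: [%d-%d] vs [%d-%d], %d pairs (%d omitted)\n",
              x$region_a$start, x$region_a$end, x$region_b$start, x$region_b$end,
              nrow(x$points), x$n_omitted))
  cat(sprintf("  slope %.4f, intercept %.4f, rmse %.5f%s\n", x$slope, x$intercept,
              x$rmse, if (x$degenerate) " [degenerate regression]" else ""))
  invisible(x)
}

#' @export
plot.pdcp_result <- function(x, ...) {
  graphics::plot(x$points$d_a, x$points$d_b,
                 xlab = sprintf("p-distance %d-%d", x$region_a$start, x$region_a$end),
                 ylab = sprintf("p-distance %d-%d", x$region_b$start, x$region_b$end),
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.5), ...)
  graphics::abline(x$intercept, x$slope, col = "firebrick")
  invisible(x)
}

# full sliding windows: starts 1, 1+step, ...; trailing partials discarded.
# With snap_tail, a final full window anchored at the alignment end is added
# when the stride does not reach it, so the scan covers every column.
sliding_windows <- function(L, window, step, snap_tail = FALSE) {
  if (window > L) stop("window larger than alignment")
  if (step < 1L) stop("step must be >= 1")
  last <- L - window + 1L
  starts <- seq.int(1L, last, by = step)
  if (snap_tail && starts[length(starts)] < last) starts <- c(starts, last)
  lapply(starts, function(s) region(s, s + window - 1L))
}

#' Pairwise distance deviation matrix (PDDM)
#'
#' Slides a window along the alignment and, for every unordered pair of
#' windows, records the PDCP regression RMSE between them. Because OLS is
#' not symmetric in its two variables, each cell stores the mean of the two
#' directed RMSEs, making the grid symmetric by construction (the directed
#' values are recoverable by calling [pdcp()] on the window pair). High
#' cells mark region pairs whose distance structure is incongruent, i.e.
#' recombination-prone.
#'
#' Windows start at columns 1, 1+step, 2·step, ...; trailing partial windows
#' are discarded, but a final full window anchored at the last column is
#' added when the stride would otherwise leave the alignment tail uncovered.
#'
#' @param x a nucleotide [msa].
#' @param window window width in alignment columns (500 by default).
#' @param step window start increment; defaults to half-overlapping windows.
#' @param alphabet passed to [pairwise_matrix()].
#' @return An object of class `pddm_grid`: `window`, `step`, `windows`
#'   (list of [region]s), `rmse` (symmetric matrix, zero diagonal, `NA`
#'   where a window pair was degenerate or underpowered) and `n_degenerate`.
#' @export
pddm <- function(x, window = 500L, step = window %/% 2L, alphabet = "nt") {
  stopifnot(inherits(x, "msa"))
  windows <- sliding_windows(alignment_length(x), as.integer(window),
                             as.integer(step), snap_tail = TRUE)
  k <- length(windows)
  # one distance matrix per window, reused across all window pairs
  vecs <- lapply(windows, function(w) {
    dist_pairs(suppressWarnings(pairwise_matrix(extract_region(x, w), alphabet)))$distance
  })
  rmse <- matrix(0, k, k)
  n_degenerate <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      a <- vecs[[i]]; b <- vecs[[j]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3L || stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) {
        rmse[i, j] <- rmse[j, i] <- NA_real_
        n_degenerate <- n_degenerate + 1L
        next
      }
      f1 <- ols_rmse(a[ok], b[ok])
      f2 <- ols_rmse(b[ok], a[ok])
      rmse[i, j] <- rmse[j, i] <- (f1$rmse + f2$rmse) / 2
    }
  }
  lab <- vapply(windows, function(w) sprintf("%d-%d", w$start, w$end), character(1L))
  dimnames(rmse) <- list(lab, lab)
  if (n_degenerate > 0L)
    message(n_degenerate, " window pair(s) degenerate or underpowered; stored as NA")
  structure(list(window = as.integer(window), step = as.integer(step),
                 windows = windows, rmse = rmse, n_degenerate = n_degenerate),
            class = "pddm_grid")
}

#' @export
print.pddm_grid <- function(x, ...) {
  cat(sprintf("pddm_grid: %d windows of %d nt (step %d), %d degenerate cells\n",
              length(x$windows), x$window, x$step, x$n_degenerate))
  print(round(x$rmse, 4))
  invisible(x)
}

#' @export
plot.pddm_grid <- function(x, ...) {
  k <- length(x$windows)
  starts <- vapply(x$windows, `[[`, integer(1L), "start")
  graphics::image(starts, starts, x$rmse, col = grDevices::hcl.colors(50, "YlOrRd", rev = TRUE),
                  xlab = "window start", ylab = "window start",
                  main = "PDDM (mean directed regression RMSE)", ...)
  invisible(x)
}

#' Write a PDDM grid as TSV
#'
#' Square layout with `start-end` window coordinates as row and column
#' headers, mirroring [write_distance_tsv()].
#'
#' @param x a `pddm_grid`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pddm_tsv <- function(x, path) {
  stopifnot(inherits(x, "pddm_grid"))
  df <- data.frame(window = rownames(x$rmse), x$rmse, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Longest low-recombination span of a PDDM grid
#'
#' Ranks windows by their mean RMSE against all other windows and merges the
#' longest contiguous run of windows below the given quantile of those means
#' into a single region — an explicit, reproducible stand-in for reading the
#' quiet block off a PDDM heatmap by eye.
#'
#' @param grid a `pddm_grid` with at least 2 windows with defined RMSE.
#' @param quantile proportion; windows with mean RMSE strictly below this
#'   quantile of all window means count as low-recombination.
#' @return A [region] spanning the merged run, or `NULL` (with a warning)
#'   when no window falls below the cutoff. Ties between equal-length runs
#'   are broken in favor of the earliest.
#' @export
low_recombination_span <- function(grid, quantile = 0.25) {
  stopifnot(inherits(grid, "pddm_grid"))
  k <- length(grid$windows)
  row_mean <- vapply(seq_len(k), function(i) {
    v <- grid$rmse[i, -i]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1L))
  if (sum(!is.na(row_mean)) < 2L) stop("need >= 2 windows with defined RMSE")
  cutoff <- stats::quantile(row_mean, quantile, na.rm = TRUE, names = FALSE)
  low <- !is.na(row_mean) & row_mean < cutoff
  if (!any(low)) {
    warning("no window below the ", quantile, " quantile of window means")
    return(NULL)
  }
  runs <- rle(low)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]  # earliest longest run
  region(grid$windows[[starts[best]]]$start, grid$windows[[ends[best]]]$end)
}

#' Sliding-window similarity scan
#'
#' Simplot-style scan: the similarity of a query to each other sequence in
#' the alignment, computed per full window as `1 - p-distance` over the
#' window's comparable sites. Mosaic (recombinant) queries show crossing
#' tracks at breakpoints.
#'
#' @param x a nucleotide [msa].
#' @param query_id id of the query sequence.
#' @param window window width in columns.
#' @param step window start increment.
#' @param alphabet `"nt"` or `"aa"`.
#' @return An object of class `similarity_track`: `query_id`, `panel_ids`,
#'   `window`, `step`, `centers` (window midpoints in alignment columns) and
#'   `similarity` (windows x panel matrix, `NA` where no site is comparable).
#' @export
similarity_scan <- function(x, query_id, window = 1000L, step = 40L,
                            alphabet = "nt") {
  stopifnot(inherits(x, "msa"))
  qi <- match(query_id, x$ids)
  if (is.na(qi)) stop("unknown query id: ", query_id)
  if (length(x$ids) < 2L) stop("need at least one non-query sequence")
  windows <- sliding_windows(alignment_length(x), as.integer(window), as.integer(step))
  res <- residue_set(alphabet)
  m <- msa_char_matrix(x)
  valid <- matrix(m %in% res, nrow = nrow(m))
  panel <- setdiff(x$ids, query_id)
  sim <- matrix(NA_real_, length(windows), length(panel),
                dimnames = list(NULL, panel))
  q <- m[qi, ]; qv <- valid[qi, ]
  for (p in panel) {
    pi <- match(p, x$ids)
    ok <- qv & valid[pi, ]
    mm <- ok & (q != m[pi, ])
    for (w in seq_along(windows)) {
      cols <- windows[[w]]$start:windows[[w]]$end
      n <- sum(ok[cols])
      if (n > 0L) sim[w, p] <- 1 - sum(mm[cols]) / n
    }
  }
  centers <- vapply(windows, function(w) (w$start + w$end) / 2, numeric(1L))
  structure(list(query_id = query_id, panel_ids = panel,
                 window = as.integer(window), step = as.integer(step),
                 centers = centers, similarity = sim),
            class = "similarity_track")
}

#' @export
print.similarity_track <- function(x, ...) {
  cat(sprintf("similarity_track: query '%s' vs %d sequences, %d windows (%d/%d nt)\n",
              x$query_id, length(x$panel_ids), length(x$centers), x$window, x$step))
  invisible(x)
}

#' @export
plot.similarity_track <- function(x, ...) {
  graphics::matplot(x$centers, x$similarity, type = "l", lty = 1,
                    xlab = "alignment position (window center)",
                    ylab = "similarity", main = paste("query:", x$query_id), ...)
  graphics::legend("bottomleft", legend = x$panel_ids, lty = 1,
                   col = seq_along(x$panel_ids), cex = 0.7, bty = "n")
  invisible(x)
}

#' Write a similarity track as TSV
#'
#' One row per window (`center` column) and one similarity column per panel
#' sequence.
#'
#' @param x a `similarity_track`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(x, path) {
  stopifnot(inherits(x, "similarity_track"))
  df <- data.frame(center = x$centers, x$similarity, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
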