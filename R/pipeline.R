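#' Configuration for an end-to-end analysis run
#'
#' Bundles all tunable parameters of the pipeline with their standard
#' values: the rep classification region 453-1700 and cap region 2250-4400
#' (alignment coordinates), the 10% genotype threshold, 500/250 nt
#' PDDM windows and 1000/40 nt similarity-scan windows.
#'
#' @param input path to an aligned FASTA file, or an [msa] object.
#' @param rep_region,cap_region [region]s analysed and used for trees.
#' @param threshold genotype clustering threshold (proportion).
#' @param pddm_window,pddm_step PDDM sliding-window width and step (nt).
#' @param simscan_window,simscan_step similarity-scan width and step (nt).
#' @param frame_offset reading-frame offset for translating the rep region.
#' @param outdir output directory (created if absent).
#' @param seed integer seed for any stochastic stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, rep_region = region(453L, 1700L),
                       cap_region = region(2250L, 4400L), threshold = 0.10,
                       pddm_window = 500L, pddm_step = 250L,
                       simscan_window = 1000L, simscan_step = 40L,
                       frame_offset = 0L, outdir = "aavgenotyper_out",
                       seed = 1L) {
  structure(list(input = input, rep_region = rep_region,
                 cap_region = cap_region, threshold = threshold,
                 pddm_window = as.integer(pddm_window),
                 pddm_step = as.integer(pddm_step),
                 simscan_window = as.integer(simscan_window),
                 simscan_step = as.integer(simscan_step),
                 frame_offset = as.integer(frame_offset),
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full genotyping analysis
#'
#' Composes the pipeline end-to-end on one alignment: nucleotide and
#' amino-acid rep-region distance matrices, the PDDM recombination grid,
#' PDCP tables for rep-vs-cap and the even/odd negative control,
#' the nt/aa cloud partition, threshold clustering with between-genotype
#' ranges, and neighbor-joining trees for the rep and cap regions. All
#' results are written as diffable TSV/Newick files plus a machine-readable
#' `summary.json`; the result objects are also returned invisibly.
#'
#' @param config a [run_config].
#' @return Invisibly, a named list of the computed objects.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  x <- if (inherits(config$input, "msa")) config$input else
    read_fasta_alignment(config$input)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  rep_msa <- extract_region(x, config$rep_region)
  dm_nt <- pairwise_matrix(rep_msa, "nt")
  dm_aa <- pairwise_matrix(translate_region(x, config$rep_region,
                                            config$frame_offset), "aa")
  write_distance_tsv(dm_nt, out("rep_nt_distances.tsv"))
  write_distance_tsv(dm_aa, out("rep_aa_distances.tsv"))

  grid <- pddm(x, config$pddm_window, config$pddm_step)
  write_pddm_tsv(grid, out("pddm.tsv"))

  write_pdcp <- function(p, f) {
    utils::write.table(p$points, out(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }
  pdcp_rep_cap <- write_pdcp(pdcp(x, config$rep_region, config$cap_region),
                             "pdcp_rep_vs_cap.tsv")
  halves <- even_odd_split(rep_msa)
  ctrl_dm <- list(suppressWarnings(pairwise_matrix(halves$odd)),
                  suppressWarnings(pairwise_matrix(halves$even)))
  pdcp_control <- write_pdcp(
    pdcp_from_matrices(ctrl_dm[[1L]], ctrl_dm[[2L]],
                       region(1L, alignment_length(halves$odd)),
                       region(1L, alignment_length(halves$even))),
    "pdcp_even_odd_control.tsv")

  clouds <- cloud_partition(dm_nt, dm_aa)
  clustering <- cluster_by_threshold(dm_nt, config$threshold)
  ranges <- between_cluster_ranges(dm_nt, clustering)
  utils::write.table(ranges, out("between_genotype_ranges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  memb <- data.frame(id = names(clustering$membership),
                     genotype = unname(clustering$membership))
  utils::write.table(memb, out("genotype_assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  trees <- list(rep = neighbor_joining(dm_nt),
                cap = neighbor_joining(pairwise_matrix(
                  extract_region(x, config$cap_region), "nt")))
  writeLines(to_newick(trees$rep), out("tree_rep.nwk"))
  writeLines(to_newick(trees$cap), out("tree_cap.nwk"))

  summary <- list(
    n_sequences = length(x$ids),
    alignment_length = alignment_length(x),
    threshold = config$threshold,
    n_clusters = length(clustering$clusters),
    cluster_sizes = vapply(clustering$clusters, length, integer(1L)),
    n_violations = nrow(clustering$violations),
    cloud_counts = as.list(clouds$counts),
    pdcp_rep_vs_cap_rmse = pdcp_rep_cap$rmse,
    pdcp_even_odd_rmse = pdcp_control$rmse,
    max_within_cluster = if (all(is.na(clustering$within_max))) NA else
      max(clustering$within_max, na.rm = TRUE),
    min_between_cluster = if (nrow(ranges)) min(ranges$min, na.rm = TRUE) else NA)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  invisible(list(dm_nt = dm_nt, dm_aa = dm_aa, pddm = grid,
                 pdcp_rep_vs_cap = pdcp_rep_cap, pdcp_control = pdcp_control,
                 clouds = clouds, clustering = clustering, ranges = ranges,
                 trees = trees, summary = summary))
}
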