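#' Configuration for the synthetic population simulator
#'
#' Defines a genotype-structured recombinant virus population: a set of
#' divergent genotype ancestors, members radiating from each ancestor, and
#' segment-copy recombination that is confined within genotypes in the
#' rep-analog region but crosses genotypes in the cap-analog region. The
#' defaults mirror the statistical structure of the natural AAV A
#' population the analysis is designed for: four genotypes totalling 103
#' genomes, between-genotype rep p-distances around 0.13 against
#' within-genotype distances below ~0.05.
#'
#' @param genome_length alignment length in nt.
#' @param rep_region,cap_region non-overlapping [region]s within the genome
#'   (rep-analog and cap-analog).
#' @param n_genotypes number of genotype clades.
#' @param seqs_per_genotype integer vector of clade sizes (length
#'   `n_genotypes`).
#' @param between_divergence target p-distance between genotype ancestors.
#' @param within_divergence approximate maximum expected within-genotype
#'   p-distance; each member mutates away from its ancestor at per-site
#'   rate `within_divergence / 2`.
#' @param rep_recomb_rate expected number of within-genotype recombination
#'   events per sequence in the rep region.
#' @param cap_recomb_rate expected number of (possibly between-genotype)
#'   recombination events per sequence in the cap region.
#' @param seed integer seed; the same seed reproduces the population
#'   byte-for-byte.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 4400L,
                       rep_region = region(453L, 1700L),
                       cap_region = region(2250L, 4400L),
                       n_genotypes = 4L,
                       seqs_per_genotype = c(30L, 40L, 20L, 13L),
                       between_divergence = 0.13,
                       within_divergence = 0.05,
                       rep_recomb_rate = 1.0,
                       cap_recomb_rate = 0.5,
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              rep_region = rep_region, cap_region = cap_region,
              n_genotypes = as.integer(n_genotypes),
              seqs_per_genotype = as.integer(seqs_per_genotype),
              between_divergence = between_divergence,
              within_divergence = within_divergence,
              rep_recomb_rate = rep_recomb_rate,
              cap_recomb_rate = cap_recomb_rate,
              seed = as.integer(seed))
  stopifnot(inherits(rep_region, "region"), inherits(cap_region, "region"))
  if (cfg$genome_length < 1L) stop("genome_length must be positive")
  if (rep_region$end > cfg$genome_length || cap_region$end > cfg$genome_length)
    stop("regions must lie within the genome")
  if (max(rep_region$start, cap_region$start) <= min(rep_region$end, cap_region$end))
    stop("rep and cap regions must not overlap")
  if (!(cfg$within_divergence > 0 && cfg$within_divergence < cfg$between_divergence &&
        cfg$between_divergence < 0.75))
    stop("need 0 < within_divergence < between_divergence < 0.75")
  if (length(cfg$seqs_per_genotype) != cfg$n_genotypes)
    stop("seqs_per_genotype must have one entry per genotype")
  if (any(cfg$seqs_per_genotype < 1L) || cfg$n_genotypes < 1L)
    stop("all counts must be positive")
  if (cfg$rep_recomb_rate < 0 || cfg$cap_recomb_rate < 0)
    stop("recombination rates must be non-negative")
  structure(cfg, class = "sim_config")
}

DNA_BASES <- c("A", "C", "G", "T")

# per-lineage substitution probability q so that two lineages mutated
# independently from a common ancestor show expected p-distance D:
# D = 2q(1-q) + (2/3)q^2  =>  q = (3/4) (1 - sqrt(1 - 4D/3))
ancestor_mut_rate <- function(D) 0.75 * (1 - sqrt(1 - 4 * D / 3))

mutate_seq <- function(s, p) {
  hit <- which(stats::runif(length(s)) < p)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    s[hit] <- DNA_BASES[(match(s[hit], DNA_BASES) - 1L + shift) %% 4L + 1L]
  }
  s
}

#' Simulate a genotype-structured recombinant population
#'
#' Generates a gap-free nucleotide alignment with known genotype labels and
#' a complete recombination log. Procedure: (1) draw a uniform-random root
#' genome; (2) derive each genotype ancestor by independent per-site
#' substitution calibrated (with the expected-overlap correction for
#' substitutions on both lineages) so that ancestor pairs sit at
#' `between_divergence`; (3) derive members from their ancestor at per-site
#' rate `within_divergence / 2`; (4) apply Poisson-count segment-copy
#' recombination: in the rep region the donor is always a member of the
#' same genotype, in the cap region the donor may be any other member;
#' breakpoints are uniform within the region. All randomness derives from
#' `config$seed`, so equal configurations give byte-identical output.
#'
#' @param config a [sim_config].
#' @return A list with `msa` (the simulated [msa]) and `truth`, itself a
#'   list with `genotype` (named integer vector of true labels) and
#'   `events` (data frame: `recipient`, `donor`, `start`, `end`, `region`
#'   (`"rep"`/`"cap"`), `recipient_genotype`, `donor_genotype`).
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  L <- config$genome_length
  root <- sample(DNA_BASES, L, replace = TRUE)
  q <- ancestor_mut_rate(config$between_divergence)
  ancestors <- lapply(seq_len(config$n_genotypes), function(g) mutate_seq(root, q))

  ids <- character(0); genotype <- integer(0)
  seqs <- list()
  for (g in seq_len(config$n_genotypes)) {
    for (k in seq_len(config$seqs_per_genotype[g])) {
      id <- sprintf("g%d_s%02d", g, k)
      ids <- c(ids, id); genotype <- c(genotype, g)
      seqs[[id]] <- mutate_seq(ancestors[[g]], config$within_divergence / 2)
    }
  }
  names(genotype) <- ids

  events <- list()
  do_events <- function(recipient, rate, reg, donors, region_name) {
    n_ev <- stats::rpois(1L, rate)
    for (e in seq_len(n_ev)) {
      if (length(donors) == 0L) next
      donor <- if (length(donors) == 1L) donors else sample(donors, 1L)
      bp <- sort(sample(reg$start:reg$end, 2L, replace = FALSE))
      idx <- bp[1L]:bp[2L]
      seqs[[recipient]][idx] <<- seqs[[donor]][idx]
      events[[length(events) + 1L]] <<- data.frame(
        recipient = recipient, donor = donor, start = bp[1L], end = bp[2L],
        region = region_name,
        recipient_genotype = genotype[[recipient]],
        donor_genotype = genotype[[donor]],
        stringsAsFactors = FALSE)
    }
  }
  for (id in ids) {
    g <- genotype[[id]]
    same <- setdiff(ids[genotype == g], id)
    do_events(id, config$rep_recomb_rate, config$rep_region, same, "rep")
    do_events(id, config$cap_recomb_rate, config$cap_region, setdiff(ids, id), "cap")
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(recipient = character(), donor = character(), start = integer(),
               end = integer(), region = character(),
               recipient_genotype = integer(), donor_genotype = integer(),
               stringsAsFactors = FALSE)
  rownames(events) <- NULL

  pop <- msa(vapply(seqs, paste, character(1L), collapse = ""), ids = ids)
  list(msa = pop, truth = list(genotype = genotype, events = events))
}

#' Published 11-serotype rep-region distance matrix
#'
#' The printed pairwise distance table among the reference genomes of the
#' 11 classical AAV serotypes over alignment positions 453-1700:
#' nucleotide proportions (`"nt"`) or inferred amino-acid proportions
#' (`"aa"`), symmetrized from the published triangle and rounded as printed
#' (2 decimals). Packaged as a plain-text fixture and used by the
#' acceptance checks; comparable-site counts are unknown (`NA`).
#'
#' @param type `"nt"` (default) or `"aa"`.
#' @return A `p_dist_matrix` with labels `AAV1, AAV2, AAV3, AAV4, AAV6,
#'   AAV7, AAV8, AAV10, AAV11, AAV12, AAV13`.
#' @export
table1_fixture <- function(type = c("nt", "aa")) {
  type <- match.arg(type)
  path <- system.file("extdata", sprintf("serotype_rep_%s_distances.tsv", type),
                      package = "aavgenotyper", mustWork = TRUE)
  read_distance_tsv(path)
}
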