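#' Aligned sequence set
#'
#' Lightweight container for a multiple sequence alignment. Sequences are
#' stored as upper-case character strings of identical length over the
#' nucleotide alphabet (`A`, `C`, `G`, `T`, IUPAC ambiguity codes, `-`) or,
#' after [translate_region()], the amino-acid alphabet.
#'
#' @param seqs character vector of aligned sequences, all the same length.
#' @param ids character vector of unique, non-empty record identifiers. If
#'   `seqs` is named and `ids` is missing, the names are used.
#' @param desc optional full header lines (defaults to `ids`).
#' @param alphabet `"nt"` or `"aa"`; stored as an attribute, not enforced
#'   beyond what individual operations require.
#'
#' @return An object of class `msa`: a list with elements `ids`, `desc`,
#'   `seq` (unnamed character vector parallel to `ids`) and attribute
#'   `alphabet`.
#' @export
msa <- function(seqs, ids = names(seqs), desc = NULL, alphabet = "nt") {
  if (is.null(ids)) stop("sequence ids are required")
  ids <- as.character(ids)
  seqs <- toupper(unname(as.character(seqs)))
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  if (any(!nzchar(ids)) || anyNA(ids)) stop("ids must be non-empty")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1L]])
  lens <- nchar(seqs)
  if (length(seqs) == 0L) stop("alignment has no records")
  if (any(lens != lens[[1L]])) {
    bad <- ids[which(lens != lens[[1L]])[1L]]
    stop("alignment error: record '", bad, "' has length ", nchar(seqs[ids == bad]),
         ", expected ", lens[[1L]])
  }
  if (lens[[1L]] < 1L) stop("alignment length must be >= 1")
  if (is.null(desc)) desc <- ids
  structure(list(ids = ids, desc = as.character(desc), seq = seqs),
            alphabet = match.arg(alphabet, c("nt", "aa")), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (%s)\n",
              length(x$ids), alignment_length(x), attr(x, "alphabet")))
  show <- utils::head(x$ids, 6L)
  for (id in show) {
    s <- x$seq[match(id, x$ids)]
    cat(sprintf("  %-20s %s%s\n", id, substr(s, 1L, 50L),
                if (nchar(s) > 50L) "..." else ""))
  }
  if (length(x$ids) > 6L) cat("  ...\n")
  invisible(x)
}

#' Number of alignment columns
#' @param x an [msa] object.
#' @return integer column count.
#' @export
alignment_length <- function(x) {
  stopifnot(inherits(x, "msa"))
  nchar(x$seq[[1L]])
}

#' @export
length.msa <- function(x) length(x$ids)

# alignment as a character matrix (rows = records), used by distance code
msa_char_matrix <- function(x) {
  stopifnot(inherits(x, "msa"))
  m <- matrix(unlist(strsplit(x$seq, "", fixed = TRUE), use.names = FALSE),
              nrow = length(x$ids), byrow = TRUE)
  rownames(m) <- x$ids
  m
}

#' Alignment region
#'
#' A 1-based inclusive span of alignment columns, the coordinate convention
#' used throughout (e.g. the rep classification region `region(453, 1700)`).
#'
#' @param start,end integer columns, `1 <= start <= end`.
#' @return An object of class `region` with fields `start`, `end`.
#' @export
region <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (anyNA(c(start, end)) || length(start) != 1L || length(end) != 1L)
    stop("start and end must be single integers")
  if (start < 1L || end < start)
    stop("invalid region: need 1 <= start <= end, got [", start, ", ", end, "]")
  structure(list(start = start, end = end), class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region [%d, %d] (%d columns)\n", x$start, x$end, region_length(x)))
  invisible(x)
}

#' Length of a region in columns
#' @param r a [region] object.
#' @return integer, `end - start + 1`.
#' @export
region_length <- function(r) {
  stopifnot(inherits(r, "region"))
  r$end - r$start + 1L
}

#' Read a FASTA alignment
#'
#' Parses a FASTA file into an [msa]. Record ids are the first
#' whitespace-delimited token of each header (the full header is retained as
#' the description); sequences are upper-cased and `U` is normalized to `T`.
#' All records must have the same aligned length.
#'
#' @param path path to a FASTA file.
#' @return An [msa] object.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: no records in '", path, "'")
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1L), 1L)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  msa(seqs, ids = ids, desc = headers)
}

#' Write an alignment to FASTA
#'
#' Writes sequences wrapped at 70 columns; headers are the stored
#' descriptions (which begin with the record id).
#'
#' @param x an [msa] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- x$desc
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Extract a column region from an alignment
#'
#' @param x an [msa] object.
#' @param r a [region]; `r$end` must not exceed the alignment length.
#' @return An [msa] restricted to columns `r$start..r$end`.
#' @export
extract_region <- function(x, r) {
  stopifnot(inherits(x, "msa"), inherits(r, "region"))
  if (r$end > alignment_length(x))
    stop("region end ", r$end, " exceeds alignment length ", alignment_length(x))
  out <- msa(substr(x$seq, r$start, r$end), ids = x$ids, desc = x$desc,
             alphabet = attr(x, "alphabet"))
  out
}

IUPAC_NT <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H",
              "V", "N", "-")

#' Translate an alignment region
#'
#' Translates columns `r$start + frame_offset` onward with the standard
#' genetic code, discarding any trailing partial codon. A codon containing a
#' gap or any ambiguity code translates to `X`; stop codons translate to `*`.
#'
#' @param x a nucleotide [msa].
#' @param r a [region] to translate.
#' @param frame_offset 0, 1 or 2 columns skipped before the first codon. The
#'   reading-frame phase of a region is alignment-specific and must be
#'   supplied by the user (default 0).
#' @return An amino-acid [msa].
#' @export
translate_region <- function(x, r, frame_offset = 0L) {
  stopifnot(inherits(x, "msa"))
  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  if (attr(x, "alphabet") != "nt") stop("translate_region requires a nucleotide alignment")
  sub <- extract_region(x, r)
  bad <- !grepl(paste0("^[", paste(sub("-", "\\\\-", IUPAC_NT), collapse = ""), "]*$"),
                sub$seq)
  if (any(bad))
    stop("non-nucleotide characters in record '", sub$ids[which(bad)[1L]], "'")
  if (region_length(r) - frame_offset < 3L)
    stop("region too short to contain a codon at this frame offset")
  n_codons <- (region_length(r) - frame_offset) %/% 3L
  code <- Biostrings::GENETIC_CODE
  aa <- vapply(sub$seq, function(s) {
    s <- substr(s, frame_offset + 1L, frame_offset + 3L * n_codons)
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    out <- unname(code[codons])
    out[is.na(out)] <- "X"
    paste(out, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  msa(aa, ids = x$ids, desc = x$desc, alphabet = "aa")
}

#' Map alignment columns to ungapped reference coordinates
#'
#' For a chosen reference record, gives the 1-based ungapped position of each
#' alignment column in that reference, or `NA` at columns where the reference
#' is gapped. The column holding the reference's k-th non-gap character maps
#' to k.
#'
#' @param x an [msa] object.
#' @param ref_id id of the reference record.
#' @return Integer vector of length `alignment_length(x)` with `NA` at
#'   reference gaps.
#' @export
ref_coordinate_map <- function(x, ref_id) {
  stopifnot(inherits(x, "msa"))
  i <- match(ref_id, x$ids)
  if (is.na(i)) stop("unknown reference id: ", ref_id)
  chars <- strsplit(x$seq[[i]], "", fixed = TRUE)[[1L]]
  nongap <- chars != "-"
  map <- rep(NA_integer_, length(chars))
  map[nongap] <- seq_len(sum(nongap))
  map
}
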