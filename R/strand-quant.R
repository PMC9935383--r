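#' Strandedness convention for a run
#'
#' In a stranded paired-end library the orientation of the first mate relative
#' to the reference determines whether the fragment came from the sense
#' (cassette) or antisense strand of the construct. Under the `"reverse"`
#' convention (dUTP-style chemistry, the default) a reverse-aligned first mate
#' means sense; under `"forward"` the two classes swap. Exactly one convention
#' is active per run; library chemistry, not the software, determines which is
#' correct.
#'
#' @param convention `"reverse"` or `"forward"`.
#' @return A `strand_rule` object.
#' @export
strand_rule <- function(convention = c("reverse", "forward")) {
  convention <- match.arg(convention)
  structure(list(convention = convention), class = "strand_rule")
}

#' Classify one aligned segment as sense, antisense, or skip
#'
#' Implements the per-read decision: a first mate is classified by its own
#' orientation; a second mate receives the class its first mate would receive
#' (so both mates of a fragment always land on the same strand). Unpaired
#' segments, and second mates whose first mate is unknown (unmapped, or its
#' primary record absent from the file), cannot be classified and return
#' `"skip"`.
#'
#' @param mate_index 1 or 2 (`NA` for unpaired).
#' @param is_reverse Is this segment reverse-aligned?
#' @param first_mate_is_reverse For a second mate: orientation of its first
#'   mate, or `NA` when unknown. Ignored for first mates.
#' @param rule A [strand_rule()].
#' @return `"sense"`, `"antisense"`, or `"skip"`.
#' @export
classify_segment <- function(mate_index, is_reverse,
                             first_mate_is_reverse = NA,
                             rule = strand_rule("reverse")) {
  stopifnot(inherits(rule, "strand_rule"))
  if (is.na(mate_index)) return("skip")
  fm_rev <- if (mate_index == 1L) is_reverse else first_mate_is_reverse
  if (is.na(fm_rev)) return("skip")
  sense_when_reverse <- identical(rule$convention, "reverse")
  if (fm_rev == sense_when_reverse) "sense" else "antisense"
}

# Vectorised classification over an aligned_segments table.
classify_segments <- function(segments, fm_lookup, rule) {
  n <- nrow(segments)
  fm_rev <- rep(NA, n)
  m1 <- !is.na(segments$mate_index) & segments$mate_index == 1L
  m2 <- !is.na(segments$mate_index) & segments$mate_index == 2L
  fm_rev[m1] <- segments$is_reverse[m1]
  fm_rev[m2] <- unname(fm_lookup[segments$read_name[m2]])
  cls <- rep("skip", n)
  sense_when_reverse <- identical(rule$convention, "reverse")
  known <- !is.na(fm_rev)
  cls[known & (fm_rev == sense_when_reverse)] <- "sense"
  cls[known & (fm_rev != sense_when_reverse)] <- "antisense"
  cls
}

#' Record the first-mate orientation of every pair
#'
#' Builds the name-keyed map that lets a second mate be classified by its
#' first mate's orientation without requiring name-sorted input. Memory is
#' proportional to the number of pairs on the construct references only, so
#' the input must already be restricted to constructs (decoy-aligned reads
#' never enter).
#'
#' @param segments An `aligned_segments` table restricted to construct
#'   references.
#' @return Named logical vector: `read_name -> is_reverse` of its primary
#'   first-mate segment.
#' @export
first_mate_lookup <- function(segments) {
  m1 <- !is.na(segments$mate_index) & segments$mate_index == 1L
  nm <- segments$read_name[m1]
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0L) {
    stop("multiple primary first-mate records for read(s): ",
         paste(utils::head(dup, 3L), collapse = ", "),
         if (length(dup) > 3L) ", ..." else "", call. = FALSE)
  }
  stats::setNames(segments$is_reverse[m1], nm)
}

#' Per-nucleotide sense/antisense counts for one sample
#'
#' The central quantification: every aligned base of every classified segment
#' increments the classified strand's array at that position. Both mates of a
#' pair are counted independently (overlapping mate bases count twice), and a
#' base covers a position only through an aligned (M/=/X) CIGAR operation —
#' deletion- and intron-spanned positions are not counted.
#'
#' Two passes are made over the construct-restricted segments: the first
#' builds the first-mate orientation map ([first_mate_lookup()]), the second
#' accumulates counts. Segments that cannot be classified (unpaired, or
#' second mates with no first-mate record) contribute to neither array but
#' are retained in `total_aligned_reads` — the normalisation denominator is
#' the number of aligned reads, classified or not — and tallied in
#' `n_skipped_segments`.
#'
#' @param segments An `aligned_segments` table (see [read_alignments()]).
#' @param constructs [Biostrings::DNAStringSet] of construct references.
#'   Every construct gets a track, aligned to or not.
#' @param rule A [strand_rule()].
#' @param sample_id Sample label carried into the tracks.
#' @return Named list of `stranded_count_track` objects, one per construct:
#'   fields `construct_id`, `sample_id`, `sense`, `antisense` (integer
#'   arrays, length = construct length), `total_aligned_reads` (primary
#'   mapped segments on that construct, each mate counted as one read),
#'   `n_skipped_segments`.
#' @export
count_sample <- function(segments, constructs, rule = strand_rule("reverse"),
                         sample_id = "sample") {
  unknown <- setdiff(unique(segments$ref_id), names(constructs))
  if (length(unknown) > 0L) {
    stop("alignments reference construct(s) absent from the reference set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  fm <- first_mate_lookup(segments)
  cls <- classify_segments(segments, fm, rule)
  tracks <- vector("list", length(constructs))
  names(tracks) <- names(constructs)
  for (cid in names(constructs)) {
    len <- Biostrings::width(constructs)[match(cid, names(constructs))]
    on_c <- segments$ref_id == cid
    track <- list(
      construct_id = cid,
      sample_id = sample_id,
      sense = accumulate_blocks(segments$blocks[on_c & cls == "sense"], len),
      antisense = accumulate_blocks(segments$blocks[on_c & cls == "antisense"], len),
      total_aligned_reads = sum(on_c),
      n_skipped_segments = sum(on_c & cls == "skip")
    )
    class(track) <- "stranded_count_track"
    tracks[[cid]] <- track
  }
  tracks
}

# Sum +1 over every position of every block; returns integer vector of length len.
accumulate_blocks <- function(block_list, len) {
  if (length(block_list) == 0L) return(integer(len))
  starts <- unlist(lapply(block_list, function(b) b[, "start"]),
                   use.names = FALSE)
  ends <- unlist(lapply(block_list, function(b) b[, "end"]),
                 use.names = FALSE)
  if (any(starts < 0L) || any(ends > len)) {
    stop("aligned block outside construct bounds", call. = FALSE)
  }
  # 1-based position indices of every covered base
  pos <- sequence(ends - starts, from = starts + 1L)
  tabulate(pos, nbins = len)
}

#' @export
print.stranded_count_track <- function(x, ...) {
  cat("stranded_count_track:", x$construct_id, "/", x$sample_id, "\n")
  cat("  length:", length(x$sense), "positions\n")
  cat("  sense bases:", sum(x$sense), " antisense bases:", sum(x$antisense), "\n")
  cat("  aligned reads:", x$total_aligned_reads,
      " unclassified:", x$n_skipped_segments, "\n")
  invisible(x)
}

#' Export a count track as TSV
#'
#' Columns: `construct_id`, `position` (0-based), `sense_count`,
#' `antisense_count`.
#' @param track A `stranded_count_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(track, path) {
  utils::write.table(
    data.frame(
      construct_id = track$construct_id,
      position = seq_along(track$sense) - 1L,
      sense_count = track$sense,
      antisense_count = track$antisense
    ),
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Export one strand of a count track as bedGraph
#' @param track A `stranded_count_track`.
#' @param strand `"sense"` or `"antisense"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, strand = c("sense", "antisense"), path) {
  strand <- match.arg(strand)
  v <- track[[strand]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  utils::write.table(
    data.frame(track$construct_id, starts, ends, r$values),
    file = path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
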