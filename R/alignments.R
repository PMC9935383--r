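#' Read paired-end alignments for the construct references
#'
#' Streams primary, mapped alignment records from a SAM or BAM file and keeps
#' only those on the requested construct references; records on decoy (host)
#' sequences are dropped here and never enter downstream memory. Secondary
#' (0x100) and supplementary (0x800) records are excluded. Duplicate-marked
#' records (0x400) are kept by default because the upstream alignment applies
#' no duplicate marking; a switch is exposed. No mapping-quality filter is
#' applied by default, matching default aligner settings; `min_mapq` is
#' exposed for sensitivity analysis.
#'
#' Aligned reference blocks are derived from the CIGAR string: M/=/X operators
#' contribute covered positions; D and N consume reference without
#' contributing; S/I/H contribute nothing. Blocks are reported 0-based
#' half-open (SAM's 1-based POS is converted at this boundary and nowhere
#' else).
#'
#' Paired records whose FLAG carries both or neither of the first-/second-mate
#' bits (0x40/0x80) are malformed; they are skipped with a warning and tallied
#' in the `n_flag_skipped` attribute of the result.
#'
#' @param path SAM or BAM file with a header. SAM input is converted in a
#'   temporary directory via [Rsamtools::asBam].
#' @param ref_ids Character vector of construct ids to retain.
#' @param include_duplicates Keep duplicate-marked (0x400) records
#'   (default `TRUE`).
#' @param min_mapq Minimum mapping quality; `0` (default) disables the filter.
#' @return An `aligned_segments` data.frame with columns `read_name`,
#'   `mate_index` (1, 2, or `NA` for unpaired), `ref_id`, `is_reverse`,
#'   `is_paired`, `mate_mapped`, and a list column `blocks` of two-column
#'   integer matrices (`start`, `end`; 0-based half-open). Attribute
#'   `n_flag_skipped` counts malformed-flag records.
#' @export
read_alignments <- function(path, ref_ids, include_duplicates = TRUE,
                            min_mapq = 0L) {
  if (!file.exists(path)) {
    stop("alignment file does not exist: ", path, call. = FALSE)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) {
        stop("failed to parse SAM (missing or invalid header?): ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "pos", "cigar"),
    mapqFilter = if (min_mapq > 0L) as.integer(min_mapq) else NA_integer_
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  if (length(res$qname) == 0L) {
    return(empty_segments())
  }
  keep <- !is.na(res$rname) & as.character(res$rname) %in% ref_ids
  qname <- res$qname[keep]
  fl <- res$flag[keep]
  rname <- as.character(res$rname[keep])
  pos <- res$pos[keep]
  cigar <- res$cigar[keep]

  is_paired <- bitwAnd(fl, 0x1L) != 0L
  first <- bitwAnd(fl, 0x40L) != 0L
  second <- bitwAnd(fl, 0x80L) != 0L
  bad_flags <- is_paired & (first == second)
  if (any(bad_flags)) {
    warning(sum(bad_flags),
            " paired record(s) with malformed mate flags skipped",
            call. = FALSE)
  }
  ok <- !bad_flags
  mate_index <- rep(NA_integer_, length(fl))
  mate_index[is_paired & first] <- 1L
  mate_index[is_paired & second] <- 2L

  blocks <- cigar_blocks(cigar[ok], pos[ok])
  seg <- data.frame(
    read_name = qname[ok],
    mate_index = mate_index[ok],
    ref_id = rname[ok],
    is_reverse = bitwAnd(fl[ok], 0x10L) != 0L,
    is_paired = is_paired[ok],
    mate_mapped = bitwAnd(fl[ok], 0x8L) == 0L,
    stringsAsFactors = FALSE
  )
  seg$blocks <- blocks
  attr(seg, "n_flag_skipped") <- sum(bad_flags)
  class(seg) <- c("aligned_segments", "data.frame")
  seg
}

# Reference blocks (0-based half-open) from 1-based POS + CIGAR.
# Works on the flattened ranges: element-wise extraction from the S4
# range lists is far too slow at typical alignment counts.
cigar_blocks <- function(cigar, pos) {
  ir <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X"), reduce.ranges = TRUE
  )
  n <- S4Vectors::elementNROWS(ir)
  flat <- unlist(ir, use.names = FALSE)
  m <- cbind(start = IRanges::start(flat) - 1L, end = IRanges::end(flat))
  idx <- unname(split.default(seq_len(nrow(m)), rep.int(seq_along(n), n)))
  blocks <- rep(list(m[0L, , drop = FALSE]), length(n))
  blocks[n > 0L] <- lapply(idx, function(i) m[i, , drop = FALSE])
  blocks
}

empty_segments <- function() {
  seg <- data.frame(
    read_name = character(0), mate_index = integer(0), ref_id = character(0),
    is_reverse = logical(0), is_paired = logical(0), mate_mapped = logical(0),
    stringsAsFactors = FALSE
  )
  seg$blocks <- list()
  attr(seg, "n_flag_skipped") <- 0L
  class(seg) <- c("aligned_segments", "data.frame")
  seg
}
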