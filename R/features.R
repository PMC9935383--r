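#' Construct a feature annotation table
#'
#' Features are intervals on a construct reference in 0-based half-open
#' coordinates (the BED convention, used for every interval in this package).
#'
#' @param construct_id Character vector of construct ids.
#' @param name Feature names (e.g. `"3LTR"`, `"SV40_pA"`).
#' @param start,end Integer 0-based half-open bounds, `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."` per feature.
#' @return A `feature_table` data.frame.
#' @export
feature_table <- function(construct_id, name, start, end, strand = ".") {
  ft <- data.frame(
    construct_id = as.character(construct_id),
    name = as.character(name),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(construct_id)),
    stringsAsFactors = FALSE
  )
  bad <- which(!(ft$start >= 0L & ft$start < ft$end))
  if (length(bad) > 0L) {
    stop("invalid feature interval (need 0 <= start < end) at row ",
         bad[1L], ": ", ft$name[bad[1L]], call. = FALSE)
  }
  if (!all(ft$strand %in% c("+", "-", "."))) {
    stop("feature strand must be one of '+', '-', '.'", call. = FALSE)
  }
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Read construct feature annotations from a BED file
#'
#' Accepts BED4 (chrom, start, end, name) or BED6 (plus score and strand).
#' BED's native 0-based half-open coordinates are kept unchanged; a missing
#' strand column becomes `"."`.
#'
#' @param path Path to a BED file.
#' @param references Optional [Biostrings::DNAStringSet]; when supplied every
#'   feature must name a known construct and lie within its bounds.
#' @return A `feature_table` data.frame with columns `construct_id`, `name`,
#'   `start`, `end`, `strand`.
#' @export
read_features <- function(path, references = NULL) {
  if (!file.exists(path)) {
    stop("BED file does not exist: ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) {
    stop("BED file contains no features: ", path, call. = FALSE)
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  zero <- which(start0 >= end0)
  if (length(zero) > 0L) {
    stop("feature with start >= end at line ", zero[1L], " of ", path,
         call. = FALSE)
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  nm <- gr$name
  if (is.null(nm)) nm <- paste0("feature_", seq_along(gr))
  ft <- feature_table(
    construct_id = as.character(GenomicRanges::seqnames(gr)),
    name = nm, start = start0, end = end0, strand = strand
  )
  if (!is.null(references)) {
    unknown <- setdiff(unique(ft$construct_id), names(references))
    if (length(unknown) > 0L) {
      stop("feature(s) reference unknown construct id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    len <- Biostrings::width(references)[match(ft$construct_id, names(references))]
    out <- which(ft$end > len)
    if (length(out) > 0L) {
      stop("feature '", ft$name[out[1L]], "' extends past the end of construct ",
           ft$construct_id[out[1L]], call. = FALSE)
    }
  }
  ft
}

#' Write a feature table as BED6
#' @param features A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  strand <- ifelse(features$strand == ".", ".", features$strand)
  utils::write.table(
    data.frame(features$construct_id, features$start, features$end,
               features$name, 0L, strand),
    file = path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
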