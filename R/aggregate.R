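#' Normalise a count track by its aligned-read denominator
#'
#' Divides the sense and antisense counts at each nucleotide position by the
#' total number of reads that aligned to the construct, yielding counts per
#' position per aligned read. The integer counts are exactly recoverable as
#' `sense_norm * total_aligned_reads`. A track with zero aligned reads
#' normalises to all-zero arrays with a warning.
#'
#' @param track A `stranded_count_track` from [count_sample()].
#' @return A `normalized_track` with fields `construct_id`, `sample_id`,
#'   `sense_norm`, `antisense_norm`, `total_aligned_reads`.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "stranded_count_track"))
  d <- track$total_aligned_reads
  if (d == 0L) {
    warning("track ", track$construct_id, "/", track$sample_id,
            " has zero aligned reads; normalised track is all zero",
            call. = FALSE)
    sense <- numeric(length(track$sense))
    anti <- numeric(length(track$antisense))
  } else {
    sense <- track$sense / d
    anti <- track$antisense / d
  }
  structure(
    list(construct_id = track$construct_id, sample_id = track$sample_id,
         sense_norm = sense, antisense_norm = anti,
         total_aligned_reads = d),
    class = "normalized_track"
  )
}

#' Recover the integer counts from a normalised track
#'
#' Exact inverse of [normalize_track()]: multiplying by the stored
#' denominator and rounding to the nearest integer recovers the original
#' count arrays bit-exactly (the division/multiplication round trip is
#' within a fraction of an ulp, far below 0.5).
#'
#' @param ntrack A `normalized_track`.
#' @return List with integer `sense` and `antisense` arrays.
#' @export
denormalize_track <- function(ntrack) {
  stopifnot(inherits(ntrack, "normalized_track"))
  d <- ntrack$total_aligned_reads
  list(sense = as.integer(round(ntrack$sense_norm * d)),
       antisense = as.integer(round(ntrack$antisense_norm * d)))
}

#' Integrate normalised tracks across a sample group
#'
#' Positionwise arithmetic mean of the normalised sense and antisense values
#' over all samples in the group, plus the across-sample minimum and maximum
#' at every position (the envelope used to visualise count variability).
#'
#' @param tracks Non-empty list of `normalized_track` objects sharing one
#'   construct.
#' @param group_id Group label.
#' @return A `group_profile` with per-position `mean_sense`, `min_sense`,
#'   `max_sense`, `mean_antisense`, `min_antisense`, `max_antisense` and
#'   `n_samples`.
#' @export
integrate_group <- function(tracks, group_id) {
  if (length(tracks) == 0L) {
    stop("cannot integrate an empty sample list", call. = FALSE)
  }
  cids <- vapply(tracks, `[[`, "", "construct_id")
  if (length(unique(cids)) != 1L) {
    stop("tracks span multiple constructs: ",
         paste(unique(cids), collapse = ", "), call. = FALSE)
  }
  lens <- vapply(tracks, function(t) length(t$sense_norm), 0L)
  if (length(unique(lens)) != 1L) {
    stop("tracks have mismatched array lengths", call. = FALSE)
  }
  sm <- do.call(rbind, lapply(tracks, `[[`, "sense_norm"))
  am <- do.call(rbind, lapply(tracks, `[[`, "antisense_norm"))
  structure(
    list(
      construct_id = cids[[1L]], group_id = group_id,
      n_samples = length(tracks),
      mean_sense = colMeans(sm), min_sense = apply(sm, 2L, min),
      max_sense = apply(sm, 2L, max),
      mean_antisense = colMeans(am), min_antisense = apply(am, 2L, min),
      max_antisense = apply(am, 2L, max)
    ),
    class = "group_profile"
  )
}

#' @export
print.group_profile <- function(x, ...) {
  cat("group_profile:", x$construct_id, "/", x$group_id,
      "(", x$n_samples, "samples,", length(x$mean_sense), "positions )\n")
  invisible(x)
}

#' Region-level coverage metrics on a group profile
#'
#' Quantifies the two phenomena of interest on an annotated interval:
#' the *antisense fraction* (summed mean antisense over the interval divided
#' by summed sense + antisense; summed counts rather than per-position
#' fractions, which are unstable at zero-coverage positions) and, when a
#' baseline interval is given, the *retention ratio* — mean sense coverage
#' over the query divided by mean sense coverage over the baseline. A
#' retention ratio well below 1 across a termination anchor is the read
#' drop-off signature; an antisense fraction of 0 is complete absence of
#' antisense transcription.
#'
#' Undefined metrics are reported as `NA` with a reason, never coerced to 0.
#'
#' @param profile A `group_profile`.
#' @param query A single-row `feature_table` (or list with `construct_id`,
#'   `name`, `start`, `end`) on the profile's construct.
#' @param baseline Optional interval for the retention-ratio denominator.
#' @return One-row data.frame: `construct_id`, `group_id`, `name`, `start`,
#'   `end`, `sense_mean_cov`, `antisense_mean_cov`, `antisense_fraction`,
#'   `retention_ratio`, `note`.
#' @export
region_metrics <- function(profile, query, baseline = NULL) {
  stopifnot(inherits(profile, "group_profile"))
  q <- as_interval(query, profile)
  idx <- (q$start + 1L):q$end
  sense_sum <- sum(profile$mean_sense[idx])
  anti_sum <- sum(profile$mean_antisense[idx])
  width <- q$end - q$start
  note <- ""

  if (sense_sum + anti_sum > 0) {
    anti_frac <- anti_sum / (sense_sum + anti_sum)
  } else {
    anti_frac <- NA_real_
    note <- "antisense_fraction undefined: no coverage in interval"
  }

  retention <- NA_real_
  if (!is.null(baseline)) {
    b <- as_interval(baseline, profile)
    bidx <- (b$start + 1L):b$end
    base_mean <- mean(profile$mean_sense[bidx])
    if (base_mean > 0) {
      retention <- (sense_sum / width) / base_mean
    } else {
      note <- paste0(note, if (nzchar(note)) "; ",
                     "retention_ratio undefined: zero baseline sense coverage")
    }
  }

  data.frame(
    construct_id = profile$construct_id, group_id = profile$group_id,
    name = q$name, start = q$start, end = q$end,
    sense_mean_cov = sense_sum / width,
    antisense_mean_cov = anti_sum / width,
    antisense_fraction = anti_frac,
    retention_ratio = retention,
    note = note,
    stringsAsFactors = FALSE
  )
}

as_interval <- function(x, profile) {
  x <- as.list(x)
  if (!is.null(x$construct_id) && x$construct_id != profile$construct_id) {
    stop("interval '", x$name, "' is on construct ", x$construct_id,
         ", not ", profile$construct_id, call. = FALSE)
  }
  len <- length(profile$mean_sense)
  if (x$start < 0L || x$end > len || x$start >= x$end) {
    stop("interval '", x$name, "' [", x$start, ",", x$end,
         ") outside construct bounds [0,", len, ")", call. = FALSE)
  }
  list(name = if (is.null(x$name)) "interval" else x$name,
       start = as.integer(x$start), end = as.integer(x$end))
}

#' Transcript abundance per delivered DNA copy
#'
#' Normalises a transcript abundance measurement to the vector copy number
#' delivered per cell, giving transcripts per template copy — the quantity
#' that separates transcription efficiency from delivery.
#'
#' @param transcript_abundance Non-negative abundance (any consistent unit).
#' @param copies_per_cell Positive vector copies per cell
#'   (see [copies_per_cell()]).
#' @return Transcripts per DNA copy.
#' @export
transcripts_per_copy <- function(transcript_abundance, copies_per_cell) {
  if (any(copies_per_cell <= 0)) {
    stop("copies_per_cell must be > 0", call. = FALSE)
  }
  transcript_abundance / copies_per_cell
}

#' Export a group profile as TSV
#'
#' Columns: `construct_id`, `group_id`, `position` (0-based), then mean, min
#' and max per strand.
#' @param profile A `group_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(
      construct_id = profile$construct_id, group_id = profile$group_id,
      position = seq_along(profile$mean_sense) - 1L,
      mean_sense = profile$mean_sense, min_sense = profile$min_sense,
      max_sense = profile$max_sense,
      mean_antisense = profile$mean_antisense,
      min_antisense = profile$min_antisense,
      max_antisense = profile$max_antisense
    ),
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
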