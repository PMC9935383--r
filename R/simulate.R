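#' Transcription program over a toy construct
#'
#' Describes where transcripts initiate on a construct and at what relative
#' rate, separately for the sense (cassette) and antisense orientations, plus
#' the fraction of fragments arising from background (host decoy)
#' transcription. Segment rates are relative weights: the probability that a
#' construct fragment comes from a given segment is proportional to
#' `rate * (end - start)`, so per-base fragment density is proportional to
#' the rate. Fragments are drawn entirely within their source segment.
#'
#' @param construct_id Construct the program runs on.
#' @param sense_segments data.frame with columns `start`, `end` (0-based
#'   half-open) and `rate` (relative, >= 0).
#' @param antisense_segments Same layout, for antisense initiation; may be
#'   `NULL` or empty.
#' @param background_decoy_fraction Fraction of all fragments drawn from the
#'   decoy sequence instead of the construct, in `[0, 1]`.
#' @return A `transcription_program`.
#' @export
transcription_program <- function(construct_id, sense_segments,
                                  antisense_segments = NULL,
                                  background_decoy_fraction = 0) {
  norm_seg <- function(x) {
    if (is.null(x) || nrow(x) == 0L) {
      return(data.frame(start = integer(0), end = integer(0),
                        rate = numeric(0)))
    }
    stopifnot(all(c("start", "end", "rate") %in% names(x)))
    x <- x[, c("start", "end", "rate")]
    if (any(x$start < 0L | x$start >= x$end) || any(x$rate < 0)) {
      stop("invalid program segment (need 0 <= start < end, rate >= 0)",
           call. = FALSE)
    }
    x
  }
  sense <- norm_seg(sense_segments)
  anti <- norm_seg(antisense_segments)
  if (sum(sense$rate) + sum(anti$rate) <= 0) {
    stop("program needs at least one segment with rate > 0", call. = FALSE)
  }
  if (background_decoy_fraction < 0 || background_decoy_fraction > 1) {
    stop("background_decoy_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(construct_id = construct_id, sense_segments = sense,
         antisense_segments = anti,
         background_decoy_fraction = background_decoy_fraction),
    class = "transcription_program"
  )
}

#' Fragment model for the read simulator
#'
#' @param n_fragments Number of fragments (pairs) to draw.
#' @param fragment_length_mean,fragment_length_sd Fragment length
#'   distribution in bases (normal, truncated below at `read_length` and
#'   above at the source segment length).
#' @param read_length Bases per mate.
#' @param seed Integer seed; mandatory — there is no silent default.
#' @return A `fragment_model`.
#' @export
fragment_model <- function(n_fragments, fragment_length_mean = 300,
                           fragment_length_sd = 30, read_length = 100L,
                           seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(n_fragments >= 1, fragment_length_mean > 0,
            fragment_length_sd > 0, read_length >= 1,
            read_length <= fragment_length_mean)
  structure(
    list(n_fragments = as.integer(n_fragments),
         fragment_length_mean = fragment_length_mean,
         fragment_length_sd = fragment_length_sd,
         read_length = as.integer(read_length),
         seed = as.integer(seed)),
    class = "fragment_model"
  )
}

#' Toy transfer-vector reference set
#'
#' A ~5 kb random-sequence stand-in for a lentiviral transfer vector plus a
#' 2 kb random "host" decoy that absorbs background reads. The feature layout
#' mirrors a SIN lentiviral cassette: 5' LTR, payload, 3' LTR carrying the
#' weak poly(A) at its midpoint (`LTR_pA`, position 3500), a strong poly(A)
#' site immediately downstream of the 3' LTR (`SV40_pA`), and a 3' stuffer.
#' Two analysis intervals bracket the weak poly(A) anchor (`upstream_pA`,
#' `downstream_pA`) for retention-ratio calculations. Sequence content is
#' random (seeded); only the coordinates carry meaning.
#'
#' @param seed Seed for the random sequences.
#' @param construct_length,decoy_length Lengths in bases.
#' @return List with `references` ([Biostrings::DNAStringSet]: construct then
#'   decoy), `features` (a `feature_table`), `construct_id`, `decoy_id`,
#'   `pa_anchor` (the weak poly(A) position).
#' @export
toy_references <- function(seed = 1L, construct_length = 5000L,
                           decoy_length = 2000L) {
  stopifnot(construct_length >= 5000L * 0L + 4000L)  # layout needs >= 4 kb
  seqs <- with_seed(seed, {
    vapply(c(construct_length, decoy_length), function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, "")
  })
  refs <- Biostrings::DNAStringSet(seqs)
  names(refs) <- c("transfer_vector", "host_decoy")
  features <- feature_table(
    construct_id = "transfer_vector",
    name = c("5LTR", "payload", "3LTR", "LTR_pA", "SV40_pA", "stuffer",
             "upstream_pA", "downstream_pA"),
    start = c(0L, 600L, 3200L, 3490L, 3800L, 3850L, 0L, 3500L),
    end = c(600L, 3200L, 3800L, 3510L, 3850L, construct_length,
            3500L, construct_length),
    strand = c("+", "+", "+", "+", "+", ".", ".", ".")
  )
  list(references = refs, features = features,
       construct_id = "transfer_vector", decoy_id = "host_decoy",
       pa_anchor = 3500L)
}

#' Preset transcription programs for the vector architectures of interest
#'
#' Three scenarios over the [toy_references()] layout, emulating the
#' RNA-seq phenotypes of linear covalently closed transfer vectors:
#'
#' * `dropoff` — weak termination at the 3' LTR poly(A): full-rate sense
#'   transcription upstream of the anchor (position 3500), falling to
#'   `residual_rate` downstream, with antisense initiation across the 3'
#'   stuffer. The classic read drop-off plus antisense signature.
#' * `strong_pA` — a strong poly(A) placed downstream of the 3' LTR restores
#'   full sense coverage through the LTR (drop only past `SV40_pA`), but
#'   residual antisense persists through the poly(A).
#' * `spacer` — a 1 kb spacer downstream of the strong poly(A): same sense
#'   profile as `strong_pA` with antisense transcription abolished entirely.
#'
#' @param residual_rate Sense rate downstream of the active poly(A), relative
#'   to the upstream rate (default 0.1).
#' @param antisense_rate Relative antisense initiation rate for the `dropoff`
#'   scenario (default 0.05).
#' @param decoy_fraction Background fraction routed to the decoy
#'   (default 0.05).
#' @param construct_length Construct length; must match [toy_references()].
#' @return Named list of `transcription_program` presets.
#' @export
scenario_library <- function(residual_rate = 0.1, antisense_rate = 0.05,
                             decoy_fraction = 0.05,
                             construct_length = 5000L) {
  seg <- function(start, end, rate) data.frame(start = start, end = end,
                                               rate = rate)
  list(
    dropoff = transcription_program(
      "transfer_vector",
      sense_segments = seg(c(0L, 3500L), c(3500L, construct_length),
                           c(1, residual_rate)),
      antisense_segments = seg(3850L, construct_length, antisense_rate),
      background_decoy_fraction = decoy_fraction
    ),
    strong_pA = transcription_program(
      "transfer_vector",
      sense_segments = seg(c(0L, 3850L), c(3850L, construct_length),
                           c(1, residual_rate / 2)),
      antisense_segments = seg(3850L, construct_length, antisense_rate / 2),
      background_decoy_fraction = decoy_fraction
    ),
    spacer = transcription_program(
      "transfer_vector",
      sense_segments = seg(c(0L, 3850L), c(3850L, construct_length),
                           c(1, residual_rate / 2)),
      antisense_segments = NULL,
      background_decoy_fraction = decoy_fraction
    )
  )
}

#' Simulate one stranded paired-end sample as aligned reads
#'
#' Draws fragments from a [transcription_program()] and writes them directly
#' as a coordinate-sorted SAM file — the simulator produces alignments, not
#' raw reads, because the quantification under test begins downstream of the
#' aligner. Each fragment emits a proper pair: one forward and one reverse
#' mate at the fragment ends, error-free, all-M CIGAR, with mate-1
#' orientation set by the fragment's source strand under the given
#' [strand_rule()] (a sense fragment has a reverse first mate under the
#' `"reverse"` convention). Fragment counts per segment are multinomial with
#' probability proportional to `rate * length` (and
#' `background_decoy_fraction` for the decoy); fragment length is normal,
#' truncated to `[read_length, segment length]`; fragments lie entirely
#' within their source segment. A fixed seed gives byte-identical output.
#'
#' @param program A [transcription_program()].
#' @param model A [fragment_model()].
#' @param rule A [strand_rule()].
#' @param references Reference set containing the program's construct and the
#'   decoy (first non-construct sequence is used as decoy).
#' @param dir Output directory.
#' @param sample_id Sample label; also the SAM file stem.
#' @param deletion_rate Fraction of forward mates given a 5-base deletion
#'   mid-read (CIGAR `kM5DmM`), solely to exercise block handling. Default 0.
#' @param fastq Also emit the read pairs as `_R1`/`_R2` FASTQ files.
#' @return List: `sam` (path), `truth` (data.frame, one row per fragment:
#'   `fragment`, `target`, `strand` — `sense`/`antisense`/`background` —
#'   `start`, `end`, `length`, `segment_start`, `segment_end`), `program`,
#'   `model`, `rule`.
#' @export
simulate_sample <- function(program, model, rule = strand_rule("reverse"),
                            references, dir = tempdir(),
                            sample_id = "sim", deletion_rate = 0,
                            fastq = FALSE) {
  stopifnot(inherits(program, "transcription_program"),
            inherits(model, "fragment_model"),
            inherits(rule, "strand_rule"))
  cid <- program$construct_id
  if (!cid %in% names(references)) {
    stop("program construct '", cid, "' absent from reference set",
         call. = FALSE)
  }
  decoy_id <- setdiff(names(references), cid)[1L]
  clen <- Biostrings::width(references)[match(cid, names(references))]

  segs <- rbind(
    cbind(program$sense_segments,
          strand = rep("sense", nrow(program$sense_segments))),
    cbind(program$antisense_segments,
          strand = rep("antisense", nrow(program$antisense_segments)))
  )
  segs <- segs[segs$rate > 0, , drop = FALSE]
  if (any(segs$end > clen)) {
    stop("program segment extends past construct end", call. = FALSE)
  }
  if (any(segs$end - segs$start < model$read_length)) {
    stop("infeasible geometry: program segment shorter than read length",
         call. = FALSE)
  }
  L <- model$read_length
  N <- model$n_fragments
  decoy_p <- program$background_decoy_fraction
  w <- segs$rate * (segs$end - segs$start)
  p <- c(w / sum(w) * (1 - decoy_p), decoy_p)

  truth <- with_seed(model$seed, {
    pick <- sample.int(nrow(segs) + 1L, N, replace = TRUE, prob = p)
    on_decoy <- pick > nrow(segs)
    seg_start <- ifelse(on_decoy, 0L, segs$start[pick])
    seg_end <- ifelse(on_decoy,
                      Biostrings::width(references)[match(decoy_id, names(references))],
                      segs$end[pick])
    seg_len <- seg_end - seg_start
    len <- round(stats::rnorm(N, model$fragment_length_mean,
                              model$fragment_length_sd))
    len <- pmax(L, pmin(len, seg_len))
    start <- seg_start + floor(stats::runif(N) * (seg_len - len + 1))
    strand <- ifelse(on_decoy, "background", as.character(segs$strand[pick]))
    del <- if (deletion_rate > 0) stats::runif(N) < deletion_rate else
      logical(N)
    data.frame(
      fragment = sprintf("%s_f%06d", sample_id, seq_len(N)),
      target = ifelse(on_decoy, decoy_id, cid),
      strand = strand,
      start = as.integer(start), end = as.integer(start + len),
      length = as.integer(len),
      segment_start = as.integer(seg_start), segment_end = as.integer(seg_end),
      has_deletion = del,
      stringsAsFactors = FALSE
    )
  })

  sam_path <- file.path(dir, paste0(sample_id, ".sam"))
  write_simulated_sam(truth, references, rule, L, sam_path)
  out <- list(sam = sam_path, truth = truth, program = program,
              model = model, rule = rule)
  if (fastq) {
    out$fastq <- write_simulated_fastq(truth, references, L, dir, sample_id)
  }
  out
}

# Emit the pairs of a truth table as a coordinate-sorted SAM file.
write_simulated_sam <- function(truth, references, rule, read_length,
                                path) {
  L <- read_length
  # sense fragments lie on the construct plus strand; under the reverse
  # convention their first mate aligns reverse
  plus_strand <- truth$strand != "antisense"
  mate1_rev <- plus_strand == identical(rule$convention, "reverse")

  left_pos <- truth$start            # 0-based leftmost of forward mate
  right_pos <- truth$end - L         # 0-based leftmost of reverse mate

  # forward mate may carry an injected 5-base deletion when there is room
  del <- truth$has_deletion & (truth$end - truth$start >= L + 5L)
  fwd_cigar <- ifelse(del, sprintf("%dM5D%dM", L %/% 2L, L - L %/% 2L),
                      sprintf("%dM", L))
  fwd_ref_span <- ifelse(del, L + 5L, L)
  rev_cigar <- sprintf("%dM", L)

  # FLAGs: 83/163 when mate1 is the reverse mate, 99/147 otherwise
  m1_flag <- ifelse(mate1_rev, 83L, 99L)
  m2_flag <- ifelse(mate1_rev, 163L, 147L)
  m1_pos <- ifelse(mate1_rev, right_pos, left_pos)
  m2_pos <- ifelse(mate1_rev, left_pos, right_pos)
  m1_cigar <- ifelse(mate1_rev, rev_cigar, fwd_cigar)
  m2_cigar <- ifelse(mate1_rev, fwd_cigar, rev_cigar)
  tlen <- truth$end - truth$start
  m1_tlen <- ifelse(mate1_rev, -tlen, tlen)

  refstr <- stats::setNames(as.character(references), names(references))
  seq_at <- function(pos, span) {
    substring(refstr[truth$target], pos + 1L, pos + span)
  }
  fwd_seq <- read_through_deletion(seq_at(left_pos, fwd_ref_span), del, L)
  rev_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq_at(right_pos, L))))
  m1_seq <- ifelse(mate1_rev, rev_seq, fwd_seq)
  m2_seq <- ifelse(mate1_rev, fwd_seq, rev_seq)
  qual <- strrep("I", L)

  rec <- function(flag, pos, cigar, mpos, tl, sq) {
    paste(truth$fragment, flag, truth$target, pos + 1L, 255L, cigar, "=",
          mpos + 1L, tl, sq, qual, sep = "\t")
  }
  lines <- c(rec(m1_flag, m1_pos, m1_cigar, m2_pos, m1_tlen, m1_seq),
             rec(m2_flag, m2_pos, m2_cigar, m1_pos, -m1_tlen, m2_seq))
  ref_ord <- match(rep(truth$target, 2L), names(references))
  lines <- lines[order(ref_ord, c(m1_pos, m2_pos))]

  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(references),
            Biostrings::width(references)),
    "@PG\tID:strandquant_sim\tPN:strandquant"
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

# A read spanning a reference deletion carries the flanking bases only.
read_through_deletion <- function(ref_seq, del, read_length) {
  if (!any(del)) return(ref_seq)
  k <- read_length %/% 2L
  ifelse(del,
         paste0(substring(ref_seq, 1L, k),
                substring(ref_seq, k + 6L, read_length + 5L)),
         substring(ref_seq, 1L, read_length))
}

write_simulated_fastq <- function(truth, references, read_length, dir,
                                  sample_id) {
  refstr <- stats::setNames(as.character(references), names(references))
  fwd <- substring(refstr[truth$target], truth$start + 1L,
                   truth$start + read_length)
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substring(refstr[truth$target], truth$end - read_length + 1L, truth$end))))
  qual <- strrep("I", read_length)
  emit <- function(seqs, path) {
    writeLines(as.vector(rbind(paste0("@", truth$fragment), seqs,
                               "+", qual)), path)
    path
  }
  r1 <- emit(fwd, file.path(dir, paste0(sample_id, "_R1.fastq")))
  r2 <- emit(rev, file.path(dir, paste0(sample_id, "_R2.fastq")))
  c(R1 = r1, R2 = r2)
}

#' Fragment tallies from a simulation truth table
#'
#' @param truth The `truth` data.frame from [simulate_sample()].
#' @return data.frame of fragment counts by `target` and `strand`.
#' @export
truth_summary <- function(truth) {
  as.data.frame(table(target = truth$target, strand = truth$strand),
                responseName = "n_fragments")
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
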