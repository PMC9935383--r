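# Independent oracle: a deliberately naive position-major transcription of
# the per-nucleotide counting rule. For every nucleotide position it
# re-tests, over all segments, whether an aligned block covers that position
# and what class the segment's pair orientation implies. Kept separate from
# the production read-major accumulator so the two can disagree.

naive_count_sample <- function(segments, constructs,
                               rule = strandquant::strand_rule("reverse"),
                               sample_id = "sample") {
  m1 <- !is.na(segments$mate_index) & segments$mate_index == 1L
  fm <- stats::setNames(segments$is_reverse[m1], segments$read_name[m1])
  if (anyDuplicated(segments$read_name[m1])) stop("duplicate first mates")

  cls <- vapply(seq_len(nrow(segments)), function(i) {
    strandquant::classify_segment(
      segments$mate_index[i], segments$is_reverse[i],
      first_mate_is_reverse = unname(fm[segments$read_name[i]]),
      rule = rule)
  }, "")

  out <- list()
  for (cid in names(constructs)) {
    len <- Biostrings::width(constructs)[match(cid, names(constructs))]
    on_c <- segments$ref_id == cid
    idx <- which(on_c)
    # flatten blocks, remembering which segment each block belongs to
    nb <- vapply(segments$blocks[idx], nrow, 0L)
    seg_of_block <- rep(idx, nb)
    bm <- do.call(rbind, segments$blocks[idx])
    sense <- integer(len)
    anti <- integer(len)
    if (!is.null(bm)) {
      for (p in seq_len(len)) {
        p0 <- p - 1L
        covering <- seg_of_block[bm[, "start"] <= p0 & p0 < bm[, "end"]]
        sense[p] <- sum(cls[covering] == "sense")
        anti[p] <- sum(cls[covering] == "antisense")
      }
    }
    track <- list(construct_id = cid, sample_id = sample_id,
                  sense = sense, antisense = anti,
                  total_aligned_reads = sum(on_c),
                  n_skipped_segments = sum(on_c & cls == "skip"))
    class(track) <- "stranded_count_track"
    out[[cid]] <- track
  }
  out
}
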