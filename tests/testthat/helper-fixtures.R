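# Shared in-code fixtures: tiny references, hand-built segment tables, and
# temp-file writers. Everything is generated at test time; nothing binary.

tiny_refs <- function(lens = c(tv = 30L)) {
  seqs <- vapply(lens, function(n) strrep("ACGT", ceiling(n / 4)), "")
  seqs <- substr(seqs, 1L, lens)
  refs <- Biostrings::DNAStringSet(seqs)
  names(refs) <- names(lens)
  refs
}

# Build an aligned_segments table directly (the count_sample input contract)
# without going through a SAM file.
make_segments <- function(read_name, mate_index, ref_id, is_reverse,
                          blocks, is_paired = TRUE, mate_mapped = TRUE) {
  seg <- data.frame(
    read_name = read_name,
    mate_index = as.integer(mate_index),
    ref_id = ref_id,
    is_reverse = is_reverse,
    is_paired = rep_len(is_paired, length(read_name)),
    mate_mapped = rep_len(mate_mapped, length(read_name)),
    stringsAsFactors = FALSE
  )
  seg$blocks <- lapply(blocks, function(b) {
    m <- matrix(as.integer(b), ncol = 2L, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  })
  attr(seg, "n_flag_skipped") <- 0L
  class(seg) <- c("aligned_segments", "data.frame")
  seg
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

write_tmp_bed <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# A minimal valid SAM file over the given references.
write_tmp_sam <- function(records, refs = tiny_refs(c(tv = 500L)),
                          header = TRUE) {
  path <- tempfile(fileext = ".sam")
  hdr <- if (header) {
    c("@HD\tVN:1.6\tSO:coordinate",
      sprintf("@SQ\tSN:%s\tLN:%d", names(refs), Biostrings::width(refs)))
  } else character(0)
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, rname, pos1, cigar, seq = "*",
                       mapq = 60L) {
  paste(qname, flag, rname, pos1, mapq, cigar, "=", pos1, 0L, seq, "*",
        sep = "\t")
}

# Total aligned (M/=/X) bases over a segment table, computed independently
# of the counter, for conservation checks.
total_block_bases <- function(segments, keep = rep(TRUE, nrow(segments))) {
  sum(vapply(segments$blocks[keep],
             function(b) sum(b[, "end"] - b[, "start"]), 0L))
}
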