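test_that("classify_segment follows first-mate orientation under both conventions", {
  rev_rule <- strand_rule("reverse")
  fwd_rule <- strand_rule("forward")
  # first mate classified by its own orientation
  expect_equal(classify_segment(1L, TRUE, rule = rev_rule), "sense")
  expect_equal(classify_segment(1L, FALSE, rule = rev_rule), "antisense")
  # second mate inherits the class its first mate would receive
  expect_equal(classify_segment(2L, FALSE, first_mate_is_reverse = TRUE,
                                rule = rev_rule), "sense")
  expect_equal(classify_segment(2L, TRUE, first_mate_is_reverse = FALSE,
                                rule = rev_rule), "antisense")
  # unknown first mate or unpaired: skip
  expect_equal(classify_segment(2L, FALSE, first_mate_is_reverse = NA,
                                rule = rev_rule), "skip")
  expect_equal(classify_segment(NA_integer_, TRUE, rule = rev_rule), "skip")
  # convention flip swaps the classes
  expect_equal(classify_segment(1L, TRUE, rule = fwd_rule), "antisense")
  expect_equal(classify_segment(2L, TRUE, first_mate_is_reverse = TRUE,
                                rule = fwd_rule), "antisense")
})

test_that("first_mate_lookup maps read names to first-mate orientation", {
  seg <- make_segments(
    read_name = c("r1", "r1"), mate_index = c(1L, 2L), ref_id = "tv",
    is_reverse = c(TRUE, FALSE), blocks = list(c(0, 5), c(10, 15)))
  expect_equal(first_mate_lookup(seg), c(r1 = TRUE))

  only2 <- make_segments("r9", 2L, "tv", FALSE, list(c(0, 5)))
  expect_length(first_mate_lookup(only2), 0L)

  dup <- make_segments(c("r1", "r1"), c(1L, 1L), "tv", c(TRUE, TRUE),
                       list(c(0, 5), c(6, 9)))
  expect_error(first_mate_lookup(dup), "multiple primary first-mate")
})

test_that("count_sample counts every aligned base on the classified strand", {
  refs <- tiny_refs(c(tv = 30L))
  # one proper pair: mate1 reverse [10,15), mate2 forward [20,25)
  seg <- make_segments(
    read_name = c("p1", "p1"), mate_index = c(1L, 2L), ref_id = "tv",
    is_reverse = c(TRUE, FALSE), blocks = list(c(10, 15), c(20, 25)))
  tr <- count_sample(seg, refs)$tv
  expected <- integer(30)
  expected[c(11:15, 21:25)] <- 1L
  expect_equal(tr$sense, expected)
  expect_equal(tr$antisense, integer(30))
  expect_equal(tr$total_aligned_reads, 2L)
  expect_equal(tr$n_skipped_segments, 0L)
})

test_that("count_sample handles empty streams and mixed orientations", {
  refs <- tiny_refs(c(tv = 30L))
  empty <- make_segments(character(0), integer(0), character(0), logical(0),
                         list())
  tr0 <- count_sample(empty, refs)$tv
  expect_equal(tr0$sense, integer(30))
  expect_equal(tr0$antisense, integer(30))
  expect_equal(tr0$total_aligned_reads, 0L)

  both <- make_segments(c("a", "b"), c(1L, 1L), "tv", c(TRUE, FALSE),
                        list(c(0, 5), c(0, 5)))
  tr <- count_sample(both, refs)$tv
  expect_equal(tr$sense[1:5], rep(1L, 5))
  expect_equal(tr$antisense[1:5], rep(1L, 5))
  expect_equal(sum(tr$sense) + sum(tr$antisense), 10L)
})

test_that("unclassifiable segments feed the denominator but not the arrays", {
  refs <- tiny_refs(c(tv = 30L))
  seg <- make_segments(
    read_name = c("p1", "orphan2"), mate_index = c(1L, 2L), ref_id = "tv",
    is_reverse = c(TRUE, FALSE), blocks = list(c(0, 5), c(10, 15)))
  tr <- count_sample(seg, refs)$tv
  expect_equal(tr$total_aligned_reads, 2L)
  expect_equal(tr$n_skipped_segments, 1L)
  expect_equal(sum(tr$sense) + sum(tr$antisense), 5L)
})

test_that("counting matches the naive position-major oracle on random inputs", {
  refs <- tiny_refs(c(tv = 80L, tv2 = 60L))
  set.seed(11)
  n_pairs <- 120L
  ref_of <- sample(c("tv", "tv2"), n_pairs, replace = TRUE)
  len_of <- c(tv = 80L, tv2 = 60L)[ref_of]
  s1 <- floor(runif(n_pairs) * (len_of - 10L))
  s2 <- floor(runif(n_pairs) * (len_of - 10L))
  rev1 <- runif(n_pairs) < 0.5
  seg <- make_segments(
    read_name = rep(sprintf("r%03d", seq_len(n_pairs)), each = 2L),
    mate_index = rep(c(1L, 2L), n_pairs),
    ref_id = rep(ref_of, each = 2L),
    is_reverse = as.vector(rbind(rev1, !rev1)),
    blocks = lapply(as.vector(rbind(s1, s2)), function(s) c(s, s + 10L)))
  for (conv in c("reverse", "forward")) {
    rule <- strand_rule(conv)
    prod <- count_sample(seg, refs, rule)
    oracle <- naive_count_sample(seg, refs, rule)
    for (cid in names(refs)) {
      expect_identical(prod[[cid]]$sense, oracle[[cid]]$sense)
      expect_identical(prod[[cid]]$antisense, oracle[[cid]]$antisense)
      expect_identical(prod[[cid]]$total_aligned_reads,
                       oracle[[cid]]$total_aligned_reads)
    }
  }
})

test_that("counts conserve aligned bases, flip with the convention, and ignore order", {
  refs <- tiny_refs(c(tv = 80L))
  set.seed(22)
  n_pairs <- 60L
  starts <- floor(runif(2L * n_pairs) * 70L)
  rev1 <- runif(n_pairs) < 0.5
  seg <- make_segments(
    read_name = rep(sprintf("r%03d", seq_len(n_pairs)), each = 2L),
    mate_index = rep(c(1L, 2L), n_pairs),
    ref_id = "tv",
    is_reverse = as.vector(rbind(rev1, !rev1)),
    blocks = lapply(starts, function(s) c(s, s + 10L)))
  tr <- count_sample(seg, refs)$tv
  expect_equal(sum(tr$sense) + sum(tr$antisense), total_block_bases(seg))

  flipped <- count_sample(seg, refs, strand_rule("forward"))$tv
  expect_identical(flipped$sense, tr$antisense)
  expect_identical(flipped$antisense, tr$sense)

  perm <- seg[sample(nrow(seg)), ]
  attr(perm, "n_flag_skipped") <- 0L
  class(perm) <- class(seg)
  shuffled <- count_sample(perm, refs)$tv
  expect_identical(shuffled$sense, tr$sense)
  expect_identical(shuffled$antisense, tr$antisense)
})

test_that("count TSV and bedGraph exports round-trip the arrays", {
  refs <- tiny_refs(c(tv = 30L))
  seg <- make_segments(c("p1", "p1"), c(1L, 2L), "tv", c(TRUE, FALSE),
                       list(c(10, 15), c(20, 25)))
  tr <- count_sample(seg, refs)$tv
  tsv <- tempfile(fileext = ".tsv")
  write_counts_tsv(tr, tsv)
  back <- read.delim(tsv)
  expect_equal(back$sense_count, tr$sense)
  expect_equal(back$position, 0:29)

  bg <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, "sense", bg)
  bed <- read.delim(bg, header = FALSE)
  reconstructed <- integer(30)
  for (i in seq_len(nrow(bed))) {
    reconstructed[(bed$V2[i] + 1L):bed$V3[i]] <- bed$V4[i]
  }
  expect_equal(reconstructed, tr$sense)
})
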