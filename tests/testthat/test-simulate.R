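toy <- toy_references(seed = 3)

test_that("scenario presets encode the three vector architectures", {
  sc <- scenario_library()
  expect_setequal(names(sc), c("dropoff", "strong_pA", "spacer"))
  # spacer construct: no antisense source at all
  expect_equal(nrow(sc$spacer$antisense_segments), 0L)
  # dropoff: downstream/upstream programmed sense rate ratio is the residual
  rs <- sc$dropoff$sense_segments
  expect_equal(rs$rate[rs$start == 3500] / rs$rate[rs$start == 0], 0.1)
  # dropoff antisense sits over the 3' stuffer
  expect_true(all(sc$dropoff$antisense_segments$start >= 3850))
})

test_that("simulation is deterministic under a fixed seed", {
  mod <- fragment_model(n_fragments = 300, seed = 77)
  s1 <- simulate_sample(scenario_library()$dropoff, mod,
                        references = toy$references,
                        dir = tempdir(), sample_id = "det_a")
  s2 <- simulate_sample(scenario_library()$dropoff, mod,
                        references = toy$references,
                        dir = tempdir(), sample_id = "det_a")
  expect_identical(s1$truth, s2$truth)
  expect_identical(readLines(s1$sam), readLines(s2$sam))

  s3 <- simulate_sample(scenario_library()$dropoff,
                        fragment_model(n_fragments = 300, seed = 78),
                        references = toy$references,
                        dir = tempdir(), sample_id = "det_b")
  expect_false(identical(s1$truth$start, s3$truth$start))
})

test_that("a sense-only program produces zero antisense counts downstream", {
  prog <- transcription_program(
    "transfer_vector",
    sense_segments = data.frame(start = 0L, end = 5000L, rate = 1))
  sim <- simulate_sample(prog, fragment_model(1000, seed = 5),
                         references = toy$references,
                         dir = tempdir(), sample_id = "sense_only")
  segs <- read_alignments(sim$sam, ref_ids = "transfer_vector")
  tr <- count_sample(segs, toy$references["transfer_vector"])$transfer_vector
  expect_true(all(tr$antisense == 0L))
  expect_equal(sum(tr$sense), 2L * 100L * 1000L)
})

test_that("truth fragment tallies match classification-level pair counts", {
  sim <- simulate_sample(scenario_library()$dropoff,
                         fragment_model(2000, seed = 13),
                         references = toy$references,
                         dir = tempdir(), sample_id = "tally")
  segs <- read_alignments(sim$sam, ref_ids = "transfer_vector")
  fm <- first_mate_lookup(segs)
  m1 <- segs[segs$mate_index == 1L, ]
  cls <- vapply(seq_len(nrow(m1)), function(i) {
    classify_segment(1L, m1$is_reverse[i], rule = strand_rule("reverse"))
  }, "")
  truth_construct <- sim$truth[sim$truth$target == "transfer_vector", ]
  expect_equal(sum(cls == "sense"),
               sum(truth_construct$strand == "sense"))
  expect_equal(sum(cls == "antisense"),
               sum(truth_construct$strand == "antisense"))
  # decoy fragments never reach the construct stream
  expect_equal(nrow(segs), 2L * nrow(truth_construct))
})

test_that("the strand rule controls simulated mate orientation coherently", {
  prog <- transcription_program(
    "transfer_vector",
    sense_segments = data.frame(start = 0L, end = 5000L, rate = 1))
  for (conv in c("reverse", "forward")) {
    rule <- strand_rule(conv)
    sim <- simulate_sample(prog, fragment_model(200, seed = 31), rule = rule,
                           references = toy$references,
                           dir = tempdir(),
                           sample_id = paste0("conv_", conv))
    segs <- read_alignments(sim$sam, ref_ids = "transfer_vector")
    tr <- count_sample(segs, toy$references["transfer_vector"],
                       rule = rule)$transfer_vector
    # all fragments are sense under the rule they were simulated with
    expect_true(all(tr$antisense == 0L))
    expect_equal(sum(tr$sense), 2L * 100L * 200L)
  }
})

test_that("infeasible geometry is rejected", {
  prog <- transcription_program(
    "transfer_vector",
    sense_segments = data.frame(start = 0L, end = 50L, rate = 1))
  expect_error(
    simulate_sample(prog, fragment_model(10, seed = 1, read_length = 100L),
                    references = toy$references, dir = tempdir()),
    "infeasible geometry")
})

test_that("injected deletions produce split blocks yet conserve counted bases", {
  prog <- transcription_program(
    "transfer_vector",
    sense_segments = data.frame(start = 0L, end = 5000L, rate = 1))
  sim <- simulate_sample(prog, fragment_model(300, seed = 19),
                         references = toy$references, dir = tempdir(),
                         sample_id = "dels", deletion_rate = 0.5)
  segs <- read_alignments(sim$sam, ref_ids = "transfer_vector")
  n_blocks <- vapply(segs$blocks, nrow, 0L)
  expect_true(any(n_blocks == 2L))
  tr <- count_sample(segs, toy$references["transfer_vector"])$transfer_vector
  # every read still contributes exactly read_length aligned bases
  expect_equal(sum(tr$sense) + sum(tr$antisense), total_block_bases(segs))
  expect_equal(total_block_bases(segs), 2L * 100L * 300L)
})

test_that("the FASTQ emitter writes one record per mate", {
  prog <- transcription_program(
    "transfer_vector",
    sense_segments = data.frame(start = 0L, end = 5000L, rate = 1))
  sim <- simulate_sample(prog, fragment_model(50, seed = 2),
                         references = toy$references, dir = tempdir(),
                         sample_id = "fq", fastq = TRUE)
  r1 <- readLines(sim$fastq[["R1"]])
  expect_length(r1, 4L * 50L)
  expect_match(r1[1L], "^@fq_f")
  expect_equal(nchar(r1[2L]), 100L)
})
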