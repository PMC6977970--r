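test_that("error-free amplicon reads all contain the junction signature with an identical prefix", {
  ref <- build_reference(seed = 1, n_ref = 600, cassette_start = 201)
  cfg <- sim_config(n_reads = 10, seed = 2, error_rate = 0, dup_skew = 1,
                    sites = data.frame(pos = 201, weight = 1))
  sim <- simulate_reads(ref, cfg)
  expect_length(sim$reads, 10)
  expect_true(all(grepl("GAGTTACCTATATCCC", sim$reads, fixed = TRUE)))
  expect_true(all(startsWith(sim$reads, "GAGTTACCTATATCCC")))
  # within each strand the downstream sequence is identical
  for (s in c("+", "-")) {
    rs <- sim$reads[sim$truth$strand == s]
    if (length(rs) > 1) expect_length(unique(rs), 1)
  }
})

test_that("simulation is byte-identical for a fixed configuration", {
  ref <- build_reference(seed = 3, n_ref = 600, cassette_start = 201)
  cfg <- sim_config(n_reads = 500, seed = 9)
  s1 <- simulate_reads(ref, cfg)
  s2 <- simulate_reads(ref, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(s1, f1); write_fastq(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("read counts are conserved and PCR duplication collapses below n_reads", {
  ref <- build_reference(seed = 4, n_ref = 600, cassette_start = 201)
  cfg <- sim_config(n_reads = 5000, seed = 11, dup_skew = 2, error_rate = 0)
  sim <- simulate_reads(ref, cfg)
  expect_equal(nrow(sim$truth), 5000)
  expect_identical(sim$truth$read_id, names(sim$reads))
  uniques <- collapse_reads(sim$reads)
  expect_equal(sum(uniques$abundance), 5000)
  expect_lt(length(unique(sim$truth$molecule_id)), 5000)
})

test_that("junction-spanning flags agree with string containment of the end sequence at zero error", {
  ref <- build_reference(seed = 5, n_ref = 400, cassette_start = 101)
  cfg <- sim_config(n_reads = 2000, seed = 12, mode = "fragmentation",
                    error_rate = 0, dup_skew = 1)
  sim <- simulate_reads(ref, cfg)
  contains <- grepl(cfg$end_sequence, sim$reads, fixed = TRUE)
  expect_identical(unname(contains), sim$truth$junction_spanning)
})

test_that("no wrong-end junction appears unless configured, and FASTQ round trips", {
  ref <- build_reference(seed = 6, n_ref = 600, cassette_start = 201)
  cfg <- sim_config(n_reads = 1000, seed = 13, error_rate = 0, dup_skew = 1)
  sim <- simulate_reads(ref, cfg)
  remote <- revcomp(cfg$end_sequence)
  expect_false(any(grepl(remote, sim$reads, fixed = TRUE)))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim, path)
  back <- read_fastq(path)
  expect_identical(back, sim$reads)
})

test_that("junction geometry: clipped suffixes align at p on plus and end at q on minus", {
  ref <- build_reference(seed = 7, n_ref = 400, cassette_start = 101)
  p <- 101L
  L <- ref$tsd_len
  q <- p + L - 1L
  cfg <- sim_config(n_reads = 400, seed = 14, mode = "fragmentation",
                    error_rate = 0, dup_skew = 1, product_downstream = 80)
  sim <- simulate_reads(ref, cfg)
  jr <- sim$truth$junction_spanning
  uniques <- collapse_reads(sim$reads[jr])
  clip <- clip_downstream(filter_junction(uniques))$retained
  hits <- align_reads(clip, ref)
  expect_true(all(hits$aligned & hits$unique & hits$mismatches == 0))
  ev <- call_events(hits, ref$n_ref)
  expect_setequal(ev$site[ev$strand == "+"], p)
  expect_setequal(ev$site[ev$strand == "-"], q)
})

test_that("invalid simulation configurations error distinctly", {
  ref <- build_reference(seed = 1, n_ref = 600, cassette_start = 201)
  expect_error(sim_config(n_reads = 10, seed = 1, error_rate = 0.5),
               class = "caspomap_invalid_config")
  expect_error(sim_config(n_reads = 10, seed = 1,
                          sites = data.frame(pos = integer(0),
                                             weight = numeric(0))),
               class = "caspomap_invalid_config")
  cfg <- sim_config(n_reads = 10, seed = 1,
                    sites = data.frame(pos = 9999, weight = 1))
  expect_error(simulate_reads(ref, cfg), class = "caspomap_invalid_config")
})
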