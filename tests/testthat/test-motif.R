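test_that("single sequences give one-hot columns and weights average correctly", {
  m1 <- build_freq_matrix(paste0("CGCA", strrep("T", 26)))
  expect_equal(m1$values["C", 1], 1)
  expect_equal(m1$values["G", 2], 1)
  expect_equal(m1$values["C", 3], 1)
  expect_equal(m1$values["A", 4], 1)
  expect_equal(colSums(m1$values), rep(1, 30), ignore_attr = TRUE)

  m2 <- build_freq_matrix(data.frame(
    clipped = c(strrep("A", 30), strrep("C", 30)),
    abundance = c(3L, 1L)))
  expect_equal(unname(m2$values["A", ]), rep(0.75, 30))
  expect_equal(unname(m2$values["C", ]), rep(0.25, 30))
  expect_equal(m2$n_effective, 4)
})

test_that("short sequences contribute only to covered columns, with per-column renormalisation", {
  m <- build_freq_matrix(data.frame(
    clipped = c(strrep("A", 30), strrep("C", 10)),
    abundance = c(1L, 1L)), W = 30)
  expect_equal(m$values["A", 5], 0.5)
  expect_equal(m$values["A", 15], 1)
  expect_equal(m$coverage[5], 2)
  expect_equal(m$coverage[15], 1)
})

test_that("an empty input yields a flagged zero matrix, never NaN", {
  m <- build_freq_matrix(data.frame(clipped = character(0),
                                    abundance = integer(0)))
  expect_equal(m$n_effective, 0)
  expect_false(anyNA(m$values))
  expect_true(all(m$values == 0))
})

test_that("the matrix equals brute-force counting on the abundance-expanded list", {
  set.seed(51)
  seqs <- replicate(25, random_dna(sample(14:30, 1)))
  ab <- sample(1:9, 25, replace = TRUE)
  m <- build_freq_matrix(data.frame(clipped = seqs, abundance = ab), W = 30)
  expect_equal(m$values, oracle_freq_matrix(seqs, ab, 30))
})

test_that("complement flipping reverses columns, swaps complementary rows, and is an involution", {
  m <- build_freq_matrix(paste0("A", strrep("G", 29)))
  f <- flip_negative_matrix(m)
  expect_equal(f$values["T", 30], 1)   # one-hot A at +1 -> T at +W
  expect_equal(f$values["C", 1], 1)    # G columns complement to C
  expect_equal(flip_negative_matrix(f)$values, m$values)
})

test_that("information content has the closed-form values and [0, 2] bounds", {
  uniform <- build_freq_matrix(data.frame(
    clipped = c("A", "C", "G", "T"), abundance = rep(1L, 4)), W = 1)
  expect_equal(information_content(uniform), 0, ignore_attr = TRUE)
  onehot <- build_freq_matrix("A", W = 1)
  expect_equal(information_content(onehot), 2, ignore_attr = TRUE)
  half <- build_freq_matrix(data.frame(clipped = c("A", "C"),
                                       abundance = c(1L, 1L)), W = 1)
  expect_equal(information_content(half), 1, ignore_attr = TRUE)

  set.seed(52)
  m <- build_freq_matrix(data.frame(
    clipped = replicate(40, random_dna(30)),
    abundance = sample(1:5, 40, replace = TRUE)))
  ic <- information_content(m)
  expect_true(all(ic >= 0 & ic <= 2))
})

test_that("flanking context indexes the reference around the junction, wrapping circularly", {
  ref <- build_reference(seed = 21, n_ref = 600, cassette_start = 201)
  fc <- flank_context(201, ref, c(-2, -1, 1, 2))
  expect_equal(unname(fc["+1"]), "C")  # first TSD base
  expect_equal(unname(fc["+2"]), "G")
  expect_equal(unname(fc["-1"]), substr(ref$sequence, 200, 200))
  expect_equal(unname(fc["-2"]), "C")  # upstream stub places C at -2
  # circular wrap at the origin
  ref2 <- build_reference(seed = 21, n_ref = 600, cassette_start = 1)
  expect_equal(unname(flank_context(1, ref2, -1)),
               substr(ref2$sequence, 600, 600))
  expect_error(flank_context(201, ref, c(0, 1)),
               class = "caspomap_invalid_input")
})

test_that("simulated plus and flipped minus matrices agree over the duplicated target", {
  ref <- build_reference(seed = 22, n_ref = 600, cassette_start = 201)
  cfg <- sim_config(n_reads = 4000, seed = 40, error_rate = 0, dup_skew = 1)
  sim <- simulate_reads(ref, cfg)
  run <- run_pipeline(list(sim$reads), ref, W = 14)
  # plus-strand matrix over the TSD is one-hot on the reference bases
  tsd <- strsplit(substr(ref$sequence, 201, 214), "")[[1]]
  for (j in 1:14)
    expect_equal(run$motif$plus$values[tsd[j], j], 1)
  # the flipped minus matrix reproduces the same duplicated-target columns
  expect_equal(run$motif$minus_flipped$values, run$motif$plus$values)
})
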