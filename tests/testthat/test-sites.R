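mk_hits <- function(...) {
  df <- data.frame(...)
  df$aligned <- TRUE
  if (is.null(df$unique)) df$unique <- TRUE
  if (is.null(df$mismatches)) df$mismatches <- 0L
  df
}

test_that("events carry the junction coordinate convention per strand", {
  h <- mk_hits(query = c(strrep("A", 25), strrep("C", 25)),
               abundance = c(10L, 5L),
               ref_start = c(601L, 590L), strand = c("+", "-"))
  ev <- call_events(h, n_ref = 2700)
  expect_equal(ev$site[ev$strand == "+"], 601L)
  expect_equal(ev$abundance[ev$strand == "+"], 10L)
  expect_equal(ev$site[ev$strand == "-"], 590L + 25L - 1L)  # 614
})

test_that("identical (site, strand) events merge and non-unique hits are refused", {
  h <- mk_hits(query = c(strrep("A", 20), strrep("G", 30)),
               abundance = c(3L, 4L),
               ref_start = c(100L, 100L), strand = c("+", "+"))
  ev <- call_events(h, n_ref = 500)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$abundance, 7L)

  h$unique <- c(TRUE, FALSE)
  expect_error(call_events(h, n_ref = 500),
               class = "caspomap_contract_violation")
})

test_that("an error-free single-site simulation yields exactly the strand pair (p, q)", {
  ref <- build_reference(seed = 16, n_ref = 600, cassette_start = 201)
  cfg <- sim_config(n_reads = 500, seed = 30, error_rate = 0, dup_skew = 1)
  sim <- simulate_reads(ref, cfg)
  clip <- clip_downstream(filter_junction(collapse_reads(sim$reads)))
  hits <- align_reads(clip$retained, ref)
  ev <- call_events(hits, ref$n_ref)
  expect_equal(nrow(ev), 2)
  expect_setequal(paste(ev$site, ev$strand), c("201 +", "214 -"))
  # event abundance conservation
  expect_equal(sum(ev$abundance), sum(hits$abundance[hits$unique]))
})

test_that("strand pairing recovers the 14 bp offset and labels by frequency", {
  ev <- data.frame(site = c(601L, 614L), strand = c("+", "-"),
                   abundance = c(990L, 985L))
  sc <- pair_sites(ev, n_ref = 2700)
  expect_equal(nrow(sc$calls), 1)
  expect_equal(sc$calls$label, "TS1")
  expect_equal(sc$calls$tsd_len, 14L)
  expect_equal(sc$calls$frequency, 1)
  expect_equal(infer_tsd(sc), 14L)

  lone <- data.frame(site = 601L, strand = "+", abundance = 100L)
  sc2 <- pair_sites(lone, n_ref = 2700)
  expect_equal(nrow(sc2$calls), 0)
  expect_equal(nrow(sc2$unpaired), 1)
  expect_true(is.na(infer_tsd(sc2)))
})

test_that("a coincident strand pair gives the degenerate single-base duplication", {
  ev <- data.frame(site = c(50L, 50L), strand = c("+", "-"),
                   abundance = c(10L, 10L))
  sc <- pair_sites(ev, n_ref = 500)
  expect_equal(sc$calls$tsd_len, 1L)
})

test_that("pairing wraps across the origin", {
  ev <- data.frame(site = c(495L, 8L), strand = c("+", "-"),
                   abundance = c(10L, 9L))
  sc <- pair_sites(ev, n_ref = 500)
  expect_equal(sc$calls$tsd_len, 14L)
})

test_that("simulated TSD lengths are recovered exactly across L in {5, 10, 14, 20}", {
  ref <- build_reference(seed = 17, n_ref = 800, cassette_start = 301)
  for (L in c(5L, 10L, 14L, 20L)) {
    cfg <- sim_config(n_reads = 1200, seed = 100 + L, tsd_len = L,
                      sites = data.frame(pos = 301, weight = 1))
    sim <- simulate_reads(ref, cfg)
    run <- run_pipeline(list(sim$reads), ref)
    expect_equal(run$tsd_len, L, info = paste("L =", L))
  }
})

test_that("site mixture weights are recovered within 3 binomial SE", {
  ref <- build_reference(seed = 18, n_ref = 2000, cassette_start = 501)
  w <- c(0.90, 0.07, 0.03)
  sites <- data.frame(pos = c(501L, 1101L, 1601L), weight = w)
  cfg <- sim_config(n_reads = 20000, seed = 31, sites = sites,
                    dup_skew = 1)
  sim <- simulate_reads(ref, cfg)
  run <- run_pipeline(list(sim$reads), ref)
  expect_equal(nrow(run$sites), 3)
  expect_equal(run$sites$plus_site, sites$pos[order(-w)])
  for (i in seq_len(3)) {
    se <- sqrt(w[i] * (1 - w[i]) / 20000)
    expect_lt(abs(run$sites$frequency[i] - sort(w, decreasing = TRUE)[i]),
              3 * se + 1e-12)
  }
})

test_that("mirrored references give mirrored coordinates and the same TSD length", {
  ref <- build_reference(seed = 19, n_ref = 600, cassette_start = 201)
  n <- ref$n_ref
  cfg <- sim_config(n_reads = 600, seed = 32, error_rate = 0, dup_skew = 1)
  sim <- simulate_reads(ref, cfg)
  clip <- clip_downstream(filter_junction(collapse_reads(sim$reads)))
  ev1 <- call_events(align_reads(clip$retained, ref), n)
  ref2 <- ref
  ref2$sequence <- revcomp(ref$sequence)
  ev2 <- call_events(align_reads(clip$retained, ref2), n)
  mirror <- data.frame(site = n - ev1$site + 1L,
                       strand = chartr("+-", "-+", ev1$strand),
                       abundance = ev1$abundance)
  expect_setequal(paste(ev2$site, ev2$strand, ev2$abundance),
                  paste(mirror$site, mirror$strand, mirror$abundance))
  L1 <- infer_tsd(pair_sites(ev1, n))
  L2 <- infer_tsd(pair_sites(ev2, n))
  expect_equal(L1, L2)
})

test_that("the directionality audit counts wrong-end junctions and recovers a spiked fraction", {
  expect_equal(audit_directionality(collapse_reads(character(0))), 0L)

  ref <- build_reference(seed = 20, n_ref = 600, cassette_start = 201)
  cfg0 <- sim_config(n_reads = 2000, seed = 33, error_rate = 0, dup_skew = 1)
  sim0 <- simulate_reads(ref, cfg0)
  remote <- revcomp(cfg0$end_sequence)
  expect_equal(audit_directionality(collapse_reads(sim0$reads), remote), 0L)

  cfg1 <- sim_config(n_reads = 5000, seed = 34, error_rate = 0, dup_skew = 1,
                     opposite_end_fraction = 0.1)
  sim1 <- simulate_reads(ref, cfg1)
  count <- audit_directionality(collapse_reads(sim1$reads), remote)
  se <- sqrt(0.1 * 0.9 / 5000)
  expect_lt(abs(count / 5000 - 0.1), 3 * se)
})
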