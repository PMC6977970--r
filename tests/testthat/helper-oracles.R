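# Independent oracles and fixture builders. These deliberately avoid the
# package's internal helpers (encoding, profile scan, string surgery) so the
# dual-route checks stay independent.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "")[[1]])
    paste(ifelse(ch %in% names(comp), comp[ch], "N"), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force both-strand Hamming scan over the doubled linear reference.
# Returns all minimal placements with mismatches <= max_mm, as a data frame
# sorted for comparison.
oracle_align <- function(query, refseq, max_mm = 2) {
  n <- nchar(refseq)
  ref2 <- paste0(refseq, refseq)
  m <- nchar(query)
  rch2 <- strsplit(ref2, "")[[1]]
  scan_one <- function(q) {
    qch <- strsplit(q, "")[[1]]
    vapply(seq_len(n), function(s) {
      sum(rch2[s:(s + m - 1)] != qch)
    }, numeric(1))
  }
  mm_f <- scan_one(query)
  mm_r <- scan_one(oracle_revcomp(query))
  best <- min(mm_f, mm_r)
  if (best > max_mm)
    return(data.frame(ref_start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  fpos <- which(mm_f == best)
  rpos <- which(mm_r == best)
  out <- data.frame(ref_start = c(fpos, rpos),
                    strand = rep(c("+", "-"), c(length(fpos), length(rpos))),
                    mismatches = best)
  out[order(out$strand, out$ref_start), , drop = FALSE]
}

# Position counting on the abundance-expanded sequence list: the direct
# definition of the weighted frequency matrix.
oracle_freq_matrix <- function(seqs, abundance, W) {
  expanded <- rep(seqs, abundance)
  vals <- matrix(0, 4, W, dimnames = list(c("A", "C", "G", "T"),
                                          paste0("+", seq_len(W))))
  for (j in seq_len(W)) {
    b <- substr(expanded[nchar(expanded) >= j], j, j)
    if (length(b) == 0) next
    cnt <- table(factor(b, levels = c("A", "C", "G", "T")))
    vals[, j] <- as.numeric(cnt) / length(b)
  }
  vals
}

# Build the four product strands of full-site integration by explicit string
# surgery on literal sequences, and measure their lengths.
oracle_products <- function(target_len, end_len, top_cut, tsd_len) {
  top <- random_dna(target_len)
  bottom <- oracle_revcomp(top)            # 5'->3' from the target right end
  end <- random_dna(end_len)
  released_top <- substr(top, 1, top_cut)
  joined_top <- paste0(end, substr(top, top_cut + 1, target_len))
  bot_cut <- target_len - (top_cut + tsd_len)  # bottom 5' fragment length
  released_bottom <- substr(bottom, 1, bot_cut)
  joined_bottom <- paste0(end, substr(bottom, bot_cut + 1, target_len))
  list(top = c(released = nchar(released_top), joined = nchar(joined_top)),
       bottom = c(released = nchar(released_bottom),
                  joined = nchar(joined_bottom)))
}

# Small simulated data set used by several files.
small_sim <- function(seed = 7, n_reads = 2000, ...) {
  ref <- build_reference(seed = seed, n_ref = 600, cassette_start = 201)
  cfg <- sim_config(n_reads = n_reads, seed = seed + 1, ...)
  list(ref = ref, sim = simulate_reads(ref, cfg))
}
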