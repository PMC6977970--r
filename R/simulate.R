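# Simulation of stranded junction reads from in vitro double-end integration
# products, with per-read ground truth. The geometry: an event at plus-strand
# coordinate p with TSD length L joins the casposon end's 3'-OH to the plus
# strand at p, and (on the other target strand) to the minus strand at plus
# coordinate q = p + L - 1. Each junction therefore yields a product strand
# reading end-sequence then target-derived sequence, which is what a stranded
# read 1 observes.

#' Simulation configuration for junction reads
#'
#' @param n_reads Number of reads to emit.
#' @param seed Integer seed (required; the simulation is deterministic given
#'   the full configuration).
#' @param sites Data frame with columns \code{pos} (plus-strand coordinate of
#'   the first TSD base) and \code{weight} (event weights summing to 1), or
#'   \code{NULL} to use the reference's cassette start with weight 1.
#' @param end_sequence DNA string joined at the junction (the 3' terminal
#'   segment of the transferred casposon-end strand). Default is the 16-nt
#'   casposon left-end terminus 5'-GAGTTACCTATATCCC used as the junction
#'   signature downstream.
#' @param tsd_len TSD length L; \code{NULL} takes it from the reference.
#' @param read_len Read length in nt (default 75, a MiSeq 75-base run).
#' @param error_rate Per-base substitution probability (default 0.001).
#' @param dup_skew Mean PCR duplicates per template molecule; duplicate
#'   counts are drawn as 1 + geometric so the mean equals \code{dup_skew}.
#'   Values <= 1 disable duplication. Default 3, a moderately amplified
#'   library.
#' @param mode \code{"amplicon"} (every read starts at a fixed primer offset
#'   inside the end sequence, mirroring libraries amplified with an end
#'   primer) or \code{"fragmentation"} (uniform breakpoints over the product
#'   molecule, mirroring tagmentation).
#' @param primer_offset 0-based offset of the read start within the end
#'   sequence in amplicon mode (default 0: reads begin at its first base).
#' @param product_downstream Target-derived bases carried downstream of the
#'   junction in each product molecule; default \code{n_ref - tsd_len}, the
#'   full linearised plasmid, in fragmentation mode and \code{read_len} in
#'   amplicon mode.
#' @param opposite_end_fraction Fraction of events simulated with the wrong
#'   (remote) 3'-OH as nucleophile; their junction carries the reverse
#'   complement of \code{end_sequence}. Default 0, as observed.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_reads, seed, sites = NULL,
                       end_sequence = "GAGTTACCTATATCCC",
                       tsd_len = NULL, read_len = 75, error_rate = 0.001,
                       dup_skew = 3, mode = c("amplicon", "fragmentation"),
                       primer_offset = 0, product_downstream = NULL,
                       opposite_end_fraction = 0) {
  mode <- match.arg(mode)
  if (missing(seed)) stop_invalid_config("sim_config requires a seed")
  end_sequence <- toupper(end_sequence)
  if (!is_dna(end_sequence)) stop_invalid_config("end_sequence must be A/C/G/T")
  if (error_rate < 0 || error_rate >= 0.25)
    stop_invalid_config("error_rate must be in [0, 0.25)")
  if (n_reads < 0) stop_invalid_config("n_reads must be >= 0")
  if (!is.null(sites)) {
    if (nrow(sites) == 0 && n_reads > 0)
      stop_invalid_config("empty sites list with n_reads > 0")
    if (nrow(sites) > 0 && abs(sum(sites$weight) - 1) > 1e-9)
      stop_invalid_config("site weights must sum to 1")
  }
  if (read_len < nchar(end_sequence) - primer_offset + 1)
    stop_invalid_config("read_len too short to span the end sequence")
  structure(list(n_reads = as.integer(n_reads), seed = as.integer(seed),
                 sites = sites, end_sequence = end_sequence,
                 tsd_len = tsd_len, read_len = as.integer(read_len),
                 error_rate = error_rate, dup_skew = dup_skew, mode = mode,
                 primer_offset = as.integer(primer_offset),
                 product_downstream = product_downstream,
                 opposite_end_fraction = opposite_end_fraction),
            class = "sim_config")
}

# Build the product-molecule template for one (site, strand, wrong-end)
# combination: joined end segment followed by D target-derived bases.
junction_template <- function(ref_chars, n, p, L, strand, end_seq, D, wrong) {
  joined <- if (wrong) revcomp(end_seq) else end_seq
  target <- if (strand == "+") {
    circ_substr(ref_chars, p, D, n)
  } else {
    q <- wrap_coord(p + L - 1L, n)
    # minus strand 5'->3' walks plus coordinates downwards from q
    revcomp(circ_substr(ref_chars, q - D + 1L, D, n))
  }
  paste0(joined, target)
}

#' Simulate stranded junction reads with ground truth
#'
#' Draws template molecules from the configured integration sites (each
#' event contributes a plus-strand and a minus-strand junction product with
#' equal probability), duplicates them per the PCR skew, fragments or
#' primer-anchors them into reads, and injects i.i.d. substitution errors.
#' Deterministic given \code{(ref, cfg)} including the seed.
#'
#' @param ref A \code{ref_assembly}.
#' @param cfg A \code{sim_config}.
#' @return A list of class \code{sim_reads}: \code{reads} (named character
#'   vector of read sequences), \code{truth} (data frame with one row per
#'   read: \code{read_id}, \code{molecule_id}, \code{site}, \code{strand},
#'   \code{junction_spanning}, \code{wrong_end}), and the \code{ref} and
#'   \code{cfg} used.
#' @export
simulate_reads <- function(ref, cfg) {
  stopifnot(inherits(ref, "ref_assembly"), inherits(cfg, "sim_config"))
  n <- ref$n_ref
  L <- if (!is.null(cfg$tsd_len)) as.integer(cfg$tsd_len) else ref$tsd_len
  sites <- cfg$sites
  if (is.null(sites))
    sites <- data.frame(pos = ref$cassette_start, weight = 1)
  if (nrow(sites) == 0 && cfg$n_reads > 0)
    stop_invalid_config("empty sites list with n_reads > 0")
  if (any(sites$pos < 1 | sites$pos > n))
    stop_invalid_config("site coordinate outside reference")
  end_len <- nchar(cfg$end_sequence)
  D <- cfg$product_downstream
  if (is.null(D))
    D <- if (cfg$mode == "amplicon") cfg$read_len else n - L
  D <- max(D, cfg$read_len)  # molecules must accommodate a full read

  ref_chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  out <- with_seed(cfg$seed, {
    nr <- cfg$n_reads
    if (nr == 0L) {
      list(reads = stats::setNames(character(0), character(0)),
           truth = data.frame(read_id = character(0),
                              molecule_id = integer(0), site = integer(0),
                              strand = character(0),
                              junction_spanning = logical(0),
                              wrong_end = logical(0)))
    } else {
      # template molecules with PCR duplicate counts summing to exactly nr
      counts <- integer(0)
      while (sum(counts) < nr) {
        k <- max(64L, ceiling((nr - sum(counts)) / max(cfg$dup_skew, 1)))
        extra <- if (cfg$dup_skew > 1)
          1L + stats::rgeom(k, prob = 1 / cfg$dup_skew) else rep(1L, k)
        counts <- c(counts, extra)
      }
      nm <- which(cumsum(counts) >= nr)[1]
      counts <- counts[seq_len(nm)]
      counts[nm] <- counts[nm] - (sum(counts) - nr)

      site_idx <- sample.int(nrow(sites), nm, replace = TRUE,
                             prob = sites$weight)
      strand <- sample(c("+", "-"), nm, replace = TRUE)
      wrong <- stats::runif(nm) < cfg$opposite_end_fraction
      mol_len <- end_len + D
      start <- if (cfg$mode == "amplicon")
        rep(cfg$primer_offset + 1L, nm)
      else
        sample.int(mol_len - cfg$read_len + 1L, nm, replace = TRUE)

      # template cache keyed by (site, strand, wrong)
      key <- paste(site_idx, strand, wrong)
      tmpl <- vapply(unique(key), function(k) {
        i <- match(k, key)
        junction_template(ref_chars, n, as.integer(sites$pos[site_idx[i]]),
                          L, strand[i], cfg$end_sequence, D, wrong[i])
      }, character(1))

      mol_id <- rep.int(seq_len(nm), counts)
      rd_start <- start[mol_id]
      seqs <- substr(tmpl[key][mol_id], rd_start,
                     rd_start + cfg$read_len - 1L)

      if (cfg$error_rate > 0) {
        nerr <- stats::rbinom(nr, cfg$read_len, cfg$error_rate)
        for (i in which(nerr > 0)) {
          pos <- sample.int(cfg$read_len, nerr[i])
          s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
          for (p2 in pos)
            s[p2] <- sample(setdiff(c("A", "C", "G", "T"), s[p2]), 1)
          seqs[i] <- paste(s, collapse = "")
        }
      }

      ids <- sprintf("read_%06d", seq_len(nr))
      names(seqs) <- ids
      jspan <- rd_start == 1L & cfg$read_len > end_len
      list(reads = seqs,
           truth = data.frame(read_id = ids, molecule_id = mol_id,
                              site = as.integer(sites$pos[site_idx[mol_id]]),
                              strand = strand[mol_id],
                              junction_spanning = jspan,
                              wrong_end = wrong[mol_id]))
    }
  })
  structure(list(reads = out$reads, truth = out$truth, ref = ref, cfg = cfg),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("<sim_reads>", length(x$reads), "reads of", x$cfg$read_len, "nt;",
      length(unique(x$truth$molecule_id)), "template molecules\n")
  cat("  mode:", x$cfg$mode, " error rate:", x$cfg$error_rate, "\n")
  invisible(x)
}

#' Write simulated reads and ground truth
#'
#' \code{write_fastq} emits standard 4-line FASTQ (Phred+33, constant Q30
#' qualities; the pipeline ignores qualities). \code{write_truth_table}
#' writes the per-read ground truth as TSV with header.
#'
#' @param sim A \code{sim_reads} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(sim, path) {
  reads <- if (inherits(sim, "sim_reads")) sim$reads else sim
  if (length(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- vapply(nchar(reads), function(w) strrep("?", w), character(1))
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_truth_table <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a FASTQ file (read 1)
#'
#' Loads a Phred+33 FASTQ via \pkg{Biostrings} and returns the sequences as
#' an id-named character vector; qualities are discarded.
#'
#' @param path FASTQ file path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0)
    return(stats::setNames(character(0), character(0)))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
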