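# End-to-end pipeline: FASTQ (read 1) -> collapse -> junction filter -> clip
# -> ungapped align -> strand-paired site calls, motif matrices, and a
# directionality audit, with per-sample stage counts. Multiple samples are
# processed independently, events pooled for site calling, and per-sample
# frequencies summarised as mean +/- standard error.

process_sample <- function(reads, ref, signature, max_mismatch, min_clip_len,
                           max_mm) {
  uniques <- collapse_reads(reads)
  junction <- filter_junction(uniques, signature, max_mismatch)
  clip <- clip_downstream(junction, signature, min_clip_len)
  hits <- align_reads(clip$retained, ref, max_mm)
  uhits <- hits[hits$aligned & hits$unique, , drop = FALSE]
  list(uniques = uniques, junction = junction, clip = clip, hits = hits,
       uhits = uhits,
       counts = c(raw = length(reads),
                  unique = nrow(uniques),
                  junction_positive = nrow(junction),
                  clipped_retained = nrow(clip$retained),
                  uniquely_aligned = nrow(uhits)),
       abundance = c(raw = length(reads),
                     junction_positive = sum(junction$abundance),
                     clipped_retained = sum(clip$retained$abundance),
                     uniquely_aligned = sum(uhits$abundance)))
}

#' Run the integration-site mapping pipeline
#'
#' Processes one or more read-1 FASTQ samples against a circular target
#' reference: collapse to unique sequences, select junction-signature
#' reads, clip to the target-derived suffix, align without gaps, call
#' strand-resolved insertion events, pair them into sites with TSD lengths
#' and frequencies, build per-strand target-motif matrices, and audit for
#' wrong-end junctions.
#'
#' @param samples FASTQ file path(s), or a (optionally named) list of
#'   character vectors of read sequences.
#' @param reference A \code{ref_assembly} or path to a single-sequence
#'   FASTA.
#' @param signature Junction signature (default 5'-GAGTTACCTATATCCC).
#' @param remote_signature Wrong-end junction string for the directionality
#'   audit; default the reverse complement of \code{signature}. \code{NA}
#'   disables the audit.
#' @param max_mismatch Substitutions tolerated in the signature (default 0).
#' @param min_clip_len Minimum clipped suffix length (default 14).
#' @param max_mm Maximum alignment mismatches (default 2).
#' @param merge_window Event coordinate merge window (default 0).
#' @param max_offset Maximum plus-to-minus pairing offset (default 50).
#' @param min_frequency Minimum event frequency seeding a site call
#'   (default 0.001).
#' @param W Motif matrix width (default 30).
#' @return An object of class \code{caspomap_run}; see
#'   \code{\link{print.caspomap_run}}. Key elements: \code{sites} (the site
#'   table with per-sample mean frequency and standard error),
#'   \code{tsd_len} (consensus TSD length), \code{events}, \code{motif}
#'   (plus/minus/minus-flipped \code{freq_matrix} objects),
#'   \code{wrong_end_count}, \code{stage_counts}.
#' @export
run_pipeline <- function(samples, reference,
                         signature = "GAGTTACCTATATCCC",
                         remote_signature = NULL,
                         max_mismatch = 0, min_clip_len = 14, max_mm = 2,
                         merge_window = 0, max_offset = 50,
                         min_frequency = 0.001, W = 30) {
  signature <- toupper(signature)
  if (is.null(remote_signature)) remote_signature <- revcomp(signature)
  ref <- if (inherits(reference, "ref_assembly")) reference
         else read_reference(reference)

  if (is.character(samples)) {
    paths <- samples
    samples <- lapply(paths, read_fastq)
    names(samples) <- if (!is.null(names(paths)) && all(nzchar(names(paths))))
      names(paths) else sub("\\.(fastq|fq)(\\.gz)?$", "", basename(paths))
  }
  if (!is.list(samples))
    stop_invalid_input("samples must be FASTQ paths or a list of read vectors")
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- paste0("S", seq_along(samples))

  per <- lapply(samples, process_sample, ref = ref, signature = signature,
                max_mismatch = max_mismatch, min_clip_len = min_clip_len,
                max_mm = max_mm)

  # per-sample events, then pooled events for site calling
  ev_list <- lapply(per, function(x)
    call_events(x$uhits, ref$n_ref, merge_window))
  pooled <- do.call(rbind, ev_list)
  if (is.null(pooled) || nrow(pooled) == 0) {
    warning("no junction-positive uniquely aligned reads; empty site table")
    pooled <- data.frame(site = integer(0), strand = character(0),
                         abundance = integer(0))
  }
  events <- if (nrow(pooled))
    stats::aggregate(abundance ~ site + strand, data = pooled, FUN = sum)
  else pooled
  events <- events[order(-events$abundance, events$site), , drop = FALSE]
  rownames(events) <- NULL
  calls <- pair_sites(events, ref$n_ref, max_offset, min_frequency)

  # per-sample frequency of each called site -> mean +/- SE across samples
  freq_mat <- sapply(seq_len(nrow(calls$calls)), function(i) {
    p <- calls$calls$plus_site[i]; q <- calls$calls$minus_site[i]
    vapply(ev_list, function(ev) {
      tot <- sum(ev$abundance)
      if (tot == 0) return(NA_real_)
      sum(ev$abundance[(ev$strand == "+" & ev$site == p) |
                       (ev$strand == "-" & ev$site == q)]) / tot
    }, numeric(1))
  })
  if (nrow(calls$calls)) {
    freq_mat <- matrix(freq_mat, nrow = length(per))
    calls$calls$freq_mean <- colMeans(freq_mat, na.rm = TRUE)
    calls$calls$freq_se <- apply(freq_mat, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
    })
  } else {
    calls$calls$freq_mean <- numeric(0)
    calls$calls$freq_se <- numeric(0)
  }

  # motif matrices over uniquely aligned clipped reads, by strand
  clip_all <- do.call(rbind, lapply(per, function(x) {
    h <- x$uhits
    if (nrow(h) == 0)
      return(data.frame(clipped = character(0), abundance = integer(0),
                        strand = character(0)))
    data.frame(clipped = h$query, abundance = h$abundance,
               strand = h$strand)
  }))
  motif_plus <- build_freq_matrix(
    clip_all[clip_all$strand == "+", , drop = FALSE], W)
  motif_minus <- build_freq_matrix(
    clip_all[clip_all$strand == "-", , drop = FALSE], W)

  wrong_end <- if (is.na(remote_signature[1])) NA_integer_ else
    sum(vapply(per, function(x)
      audit_directionality(x$uniques, remote_signature), integer(1)))

  stage_counts <- t(vapply(per, function(x) x$counts,
                           numeric(length(per[[1]]$counts))))
  structure(
    list(sites = calls$calls, unpaired = calls$unpaired,
         tsd_len = infer_tsd(calls), events = events,
         motif = list(plus = motif_plus, minus = motif_minus,
                      minus_flipped = flip_negative_matrix(motif_minus)),
         wrong_end_count = wrong_end,
         stage_counts = stage_counts,
         stage_abundance = t(vapply(per, function(x) x$abundance,
                                    numeric(length(per[[1]]$abundance)))),
         per_sample_events = ev_list,
         reference = ref,
         params = list(signature = signature,
                       remote_signature = remote_signature,
                       max_mismatch = max_mismatch,
                       min_clip_len = min_clip_len, max_mm = max_mm,
                       merge_window = merge_window, max_offset = max_offset,
                       min_frequency = min_frequency, W = W)),
    class = "caspomap_run")
}

#' Print and summarise a pipeline run
#'
#' @param x,object A \code{caspomap_run}.
#' @param ... Unused.
#' @return The object, invisibly.
#' @export
print.caspomap_run <- function(x, ...) {
  cat("<caspomap_run>", nrow(x$stage_counts), "sample(s) against",
      x$reference$name, sprintf("(%d bp, circular)\n", x$reference$n_ref))
  cat("  consensus TSD length:",
      if (is.na(x$tsd_len)) "NA" else paste0(x$tsd_len, " bp"), "\n")
  cat("  sites called:", nrow(x$sites), " wrong-end junction reads:",
      x$wrong_end_count, "\n")
  if (nrow(x$sites)) {
    cat("\n")
    print(x$sites, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @rdname print.caspomap_run
#' @export
summary.caspomap_run <- function(object, ...) {
  print(object)
  cat("\nStage counts (unique sequences):\n")
  print(object$stage_counts)
  cat("\nStage counts (read abundance):\n")
  print(object$stage_abundance)
  if (nrow(object$unpaired)) {
    cat("\nUnpaired events:\n")
    print(object$unpaired, row.names = FALSE)
  }
  invisible(object)
}

#' Plot strand-resolved insertion events
#'
#' Positive-strand event abundances are drawn upward, negative-strand
#' abundances downward, along the reference coordinate.
#'
#' @param x A \code{caspomap_run}.
#' @param ... Passed to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @export
plot.caspomap_run <- function(x, ...) {
  ev <- x$events
  if (nrow(ev) == 0) {
    graphics::plot.new()
    graphics::title(main = "No insertion events")
    return(invisible(x))
  }
  y <- ifelse(ev$strand == "+", ev$abundance, -ev$abundance)
  graphics::plot(ev$site, y, type = "h",
                 col = ifelse(ev$strand == "+", "blue", "red"),
                 xlab = "reference coordinate (bp)",
                 ylab = "read abundance (+ up, - down)",
                 main = "Strand-resolved insertion events", ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Write the site table as TSV
#'
#' @param run A \code{caspomap_run}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_site_table <- function(run, path) {
  utils::write.table(run$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
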