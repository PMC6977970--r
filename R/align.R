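# Transparent ungapped (substitution-only) alignment to the circular
# reference. The clipped target-derived fragments are short and the product
# molecules contain no indels relative to the reference, so an exhaustive
# Hamming scan over both strands of the doubled reference is exact, fast at
# plasmid scale, and directly testable against a naive oracle.

# Precompute the scanning index for a reference: the plus strand doubled so
# that placements wrapping past the origin are ordinary substrings.
ref_index <- function(ref) {
  seq2 <- paste0(ref$sequence, ref$sequence)
  code <- match(strsplit(seq2, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  code[is.na(code)] <- 0L
  list(n = ref$n_ref, fwd2 = as.integer(code))
}

# Mismatch count of an encoded query at every canonical start 1..n of the
# doubled reference.
mismatch_profile <- function(q, idx) {
  n <- idx$n
  mm <- integer(n)
  for (j in seq_along(q)) {
    mm <- mm + (idx$fwd2[j:(j + n - 1L)] != q[j])
  }
  mm
}

#' Ungapped alignment of a query to the circular reference
#'
#' Scans all placements of the query on both strands of the circularised
#' reference (positions wrap modulo the reference length) and returns every
#' placement achieving the minimal Hamming distance, provided it does not
#' exceed \code{max_mm}. Non-A/C/G/T query characters count as mismatches at
#' every position. A minus-strand hit is reported by the plus-strand
#' coordinate of its leftmost aligned reference base.
#'
#' @param query DNA string (at least 10 nt).
#' @param ref A \code{ref_assembly}, or a prebuilt index from the internal
#'   indexer (used by the batch interface).
#' @param max_mm Maximum mismatches tolerated (default 2).
#' @return Data frame with columns \code{ref_start} (1-based plus-strand
#'   coordinate), \code{strand} (\code{"+"}/\code{"-"}), \code{mismatches},
#'   and \code{unique} (TRUE iff exactly one minimal placement exists).
#'   Zero rows when no placement is within \code{max_mm}.
#' @examples
#' ref <- build_reference(seed = 1, n_ref = 500, cassette_start = 101)
#' align_ungapped(substr(ref$sequence, 50, 80), ref)
#' @export
align_ungapped <- function(query, ref, max_mm = 2) {
  query <- toupper(query)
  if (nchar(query) < 10)
    stop_invalid_input("query must be at least 10 nt")
  idx <- if (inherits(ref, "ref_assembly")) ref_index(ref) else ref
  mm_fwd <- mismatch_profile(encode_dna(query), idx)
  mm_rev <- mismatch_profile(encode_dna(revcomp(query)), idx)
  best <- min(mm_fwd, mm_rev)
  if (best > max_mm)
    return(data.frame(ref_start = integer(0), strand = character(0),
                      mismatches = integer(0), unique = logical(0)))
  fpos <- which(mm_fwd == best)
  rpos <- which(mm_rev == best)
  hits <- data.frame(
    ref_start = c(fpos, rpos),
    strand = rep(c("+", "-"), c(length(fpos), length(rpos))),
    mismatches = best)
  hits$unique <- nrow(hits) == 1L
  hits
}

#' Align a batch of clipped unique reads
#'
#' Aligns every clipped sequence with \code{\link{align_ungapped}} and
#' returns one row per query summarising its best placement. Queries whose
#' minimal placement is ambiguous are flagged \code{unique = FALSE} (their
#' reported coordinate is the first minimal placement); queries with no
#' placement within \code{max_mm} get \code{aligned = FALSE}.
#'
#' @param clipped Data frame with columns \code{clipped} (query sequences)
#'   and \code{abundance}.
#' @param ref A \code{ref_assembly}.
#' @param max_mm Maximum mismatches (default 2).
#' @return Data frame: \code{query}, \code{abundance}, \code{aligned},
#'   \code{ref_start}, \code{strand}, \code{mismatches}, \code{unique},
#'   \code{n_hits}.
#' @export
align_reads <- function(clipped, ref, max_mm = 2) {
  idx <- ref_index(ref)
  res <- lapply(clipped$clipped, function(q) {
    h <- align_ungapped(q, idx, max_mm = max_mm)
    if (nrow(h) == 0)
      data.frame(aligned = FALSE, ref_start = NA_integer_,
                 strand = NA_character_, mismatches = NA_integer_,
                 unique = FALSE, n_hits = 0L)
    else
      data.frame(aligned = TRUE, ref_start = h$ref_start[1],
                 strand = h$strand[1], mismatches = h$mismatches[1],
                 unique = h$unique[1], n_hits = nrow(h))
  })
  out <- cbind(data.frame(query = clipped$clipped,
                          abundance = clipped$abundance),
               do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Write an alignment hit table as TSV
#'
#' @param hits Data frame from \code{\link{align_reads}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
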