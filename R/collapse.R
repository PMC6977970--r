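# Read collapsing and junction extraction: raw reads are collapsed to unique
# sequences with recorded abundances, filtered for the casposon-end junction
# signature, and clipped to the target-derived suffix downstream of it.

#' Collapse reads to unique sequences with abundances
#'
#' @param reads Character vector of read sequences (a whole FASTQ's read 1
#'   sequences).
#' @return Data frame with columns \code{sequence} and \code{abundance},
#'   sorted by descending abundance, ties broken lexicographically by
#'   sequence. Abundances sum to \code{length(reads)}.
#' @examples
#' collapse_reads(c("ACGT", "ACGT", "TTTT"))
#' @export
collapse_reads <- function(reads) {
  if (length(reads) == 0)
    return(data.frame(sequence = character(0), abundance = integer(0)))
  tab <- table(reads)
  out <- data.frame(sequence = names(tab),
                    abundance = as.integer(tab))
  out <- out[order(-out$abundance, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Leftmost 0-based offset of `signature` within each sequence allowing up to
# max_mismatch substitutions; NA where absent. Exact matching uses fixed
# regexpr; the mismatch-tolerant path is a per-position Hamming scan.
signature_offsets <- function(seqs, signature, max_mismatch = 0) {
  if (max_mismatch == 0) {
    off <- regexpr(signature, seqs, fixed = TRUE)
    return(ifelse(off < 0, NA_integer_, as.integer(off) - 1L))
  }
  sig <- encode_dna(signature)
  m <- length(sig)
  vapply(seqs, function(s) {
    q <- encode_dna(s)
    n <- length(q)
    if (n < m) return(NA_integer_)
    for (st in seq_len(n - m + 1L)) {
      if (sum(q[st:(st + m - 1L)] != sig) <= max_mismatch)
        return(st - 1L)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Select unique reads containing the junction signature
#'
#' Retains collapsed reads whose forward sequence contains the casposon-end
#' junction signature with at most \code{max_mismatch} substitutions,
#' recording the leftmost occurrence. Reads are stranded, so no
#' reverse-complement search is performed.
#'
#' @param uniques Data frame from \code{\link{collapse_reads}}.
#' @param signature Junction signature (the 3' terminus of the transferred
#'   casposon-end strand); default 5'-GAGTTACCTATATCCC. Must be at least
#'   8 nt.
#' @param max_mismatch Substitutions tolerated inside the signature
#'   (default 0: exact containment).
#' @return The retained rows with an added integer column
#'   \code{signature_offset} (0-based start of the signature).
#' @export
filter_junction <- function(uniques, signature = "GAGTTACCTATATCCC",
                            max_mismatch = 0) {
  signature <- toupper(signature)
  if (nchar(signature) < 8)
    stop_invalid_config("junction signature must be at least 8 nt")
  if (nrow(uniques) == 0) {
    uniques$signature_offset <- integer(0)
    return(uniques)
  }
  off <- signature_offsets(uniques$sequence, signature, max_mismatch)
  out <- uniques[!is.na(off), , drop = FALSE]
  out$signature_offset <- off[!is.na(off)]
  rownames(out) <- NULL
  out
}

#' Clip junction reads to the target-derived downstream region
#'
#' Removes the casposon-end fragment (everything through the matched
#' signature) and retains the downstream target-derived suffix. Suffixes
#' shorter than \code{min_clip_len} are rejected with a reason.
#'
#' @param entries Data frame from \code{\link{filter_junction}} (must carry
#'   \code{signature_offset}).
#' @param signature The signature used for filtering.
#' @param min_clip_len Minimum retained suffix length (default 14 nt, one
#'   full TSD).
#' @return A list with \code{retained} (data frame: \code{source_sequence},
#'   \code{signature_offset}, \code{clipped}, \code{abundance}) and
#'   \code{rejected} (data frame: \code{source_sequence}, \code{abundance},
#'   \code{reason}).
#' @export
clip_downstream <- function(entries, signature = "GAGTTACCTATATCCC",
                            min_clip_len = 14) {
  signature <- toupper(signature)
  empty_ret <- data.frame(source_sequence = character(0),
                          signature_offset = integer(0),
                          clipped = character(0), abundance = integer(0))
  empty_rej <- data.frame(source_sequence = character(0),
                          abundance = integer(0), reason = character(0))
  if (nrow(entries) == 0)
    return(list(retained = empty_ret, rejected = empty_rej))
  if (is.null(entries$signature_offset) || anyNA(entries$signature_offset))
    stop_contract("clip_downstream requires entries that passed filter_junction")
  clipped <- substr(entries$sequence,
                    entries$signature_offset + nchar(signature) + 1L,
                    nchar(entries$sequence))
  keep <- nchar(clipped) >= min_clip_len
  retained <- data.frame(source_sequence = entries$sequence[keep],
                         signature_offset = entries$signature_offset[keep],
                         clipped = clipped[keep],
                         abundance = entries$abundance[keep])
  rejected <- data.frame(source_sequence = entries$sequence[!keep],
                         abundance = entries$abundance[!keep],
                         reason = rep("too-short", sum(!keep)))
  rownames(retained) <- rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected)
}

#' Write collapsed unique sequences as FASTA
#'
#' Headers are \code{id_count}, carrying the recorded abundance (the
#' convention of storing collapsed reads in FASTA with abundance in the
#' header).
#'
#' @param uniques Data frame from \code{\link{collapse_reads}}.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_unique_fasta <- function(uniques, path) {
  x <- Biostrings::DNAStringSet(uniques$sequence)
  names(x) <- sprintf("u%06d_%d", seq_len(nrow(uniques)), uniques$abundance)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Abundance-weighted count of wrong-end junction reads
#'
#' Audits directionality: counts (weighted by abundance) the unique reads
#' containing the junction string expected if the opposite 3'-OH of the
#' casposon end had been used as the nucleophile.
#'
#' @param uniques Data frame from \code{\link{collapse_reads}}.
#' @param remote_signature Junction string expected from wrong-end use
#'   (for a duplex end, the reverse complement of the end sequence).
#' @return Abundance-weighted integer count.
#' @export
audit_directionality <- function(uniques,
                                 remote_signature = revcomp("GAGTTACCTATATCCC")) {
  if (nrow(uniques) == 0) return(0L)
  hit <- grepl(toupper(remote_signature), uniques$sequence, fixed = TRUE)
  as.integer(sum(uniques$abundance[hit]))
}
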