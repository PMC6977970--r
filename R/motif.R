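# Target-motif matrices: abundance-weighted nucleotide frequencies over
# positions +1..+W downstream of the integration junction, per strand, with
# the negative-strand matrix complement-flipped for comparison.

DNA_BASES <- c("A", "C", "G", "T")

#' Build an abundance-weighted nucleotide frequency matrix
#'
#' Clipped target-derived sequences are aligned at their 5' ends (position
#' +1 is the first base 3' of the junction) and per-position base
#' frequencies are computed with each sequence weighted by its abundance.
#' Sequences shorter than \code{W} contribute only to the columns they
#' cover; each column is normalised by the weight covering it.
#'
#' @param clipped Data frame with a sequence column (\code{clipped} or
#'   \code{sequence}) and an \code{abundance} column; plain character
#'   vectors are accepted with abundance 1.
#' @param W Number of downstream positions (default 30).
#' @return An object of class \code{freq_matrix}: list with \code{values}
#'   (4 x W matrix, rows A,C,G,T, columns +1..+W), \code{n_effective}
#'   (total weight), and \code{coverage} (per-column weight). An empty
#'   input yields an all-zero matrix with \code{n_effective = 0}.
#' @export
build_freq_matrix <- function(clipped, W = 30) {
  if (is.character(clipped))
    clipped <- data.frame(clipped = clipped,
                          abundance = rep(1L, length(clipped)))
  seqs <- toupper(if (!is.null(clipped$clipped)) clipped$clipped
                  else clipped$sequence)
  ab <- clipped$abundance
  values <- matrix(0, nrow = 4, ncol = W,
                   dimnames = list(DNA_BASES, paste0("+", seq_len(W))))
  coverage <- numeric(W)
  if (length(seqs) > 0) {
    len <- nchar(seqs)
    for (j in seq_len(W)) {
      cov <- len >= j
      if (!any(cov)) next
      b <- substr(seqs[cov], j, j)
      w <- tapply(ab[cov], factor(b, levels = DNA_BASES), sum,
                  default = 0)
      coverage[j] <- sum(ab[cov])
      values[, j] <- w / coverage[j]
    }
  }
  structure(list(values = values,
                 n_effective = if (length(seqs)) sum(ab) else 0,
                 coverage = coverage),
            class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, digits = 3, ...) {
  cat("<freq_matrix>", ncol(x$values), "positions, effective weight",
      x$n_effective, "\n")
  print(round(x$values[, seq_len(min(8, ncol(x$values))), drop = FALSE],
              digits))
  if (ncol(x$values) > 8) cat("  ...\n")
  invisible(x)
}

#' Complement-flip a negative-strand frequency matrix
#'
#' Reverses the column order and swaps the A/T and C/G rows, so a
#' negative-strand matrix can be laid over the positive-strand one to
#' visualise the complementarity across the duplicated target. The
#' operation is an involution.
#'
#' @param m A \code{freq_matrix}.
#' @return A \code{freq_matrix}.
#' @export
flip_negative_matrix <- function(m) {
  v <- m$values[c("T", "G", "C", "A"), rev(seq_len(ncol(m$values))),
                drop = FALSE]
  dimnames(v) <- dimnames(m$values)
  structure(list(values = v, n_effective = m$n_effective,
                 coverage = rev(m$coverage)),
            class = "freq_matrix")
}

#' Per-column information content in bits
#'
#' \code{IC_j = 2 + sum_b F[b,j] log2 F[b,j]} with \code{0 log 0 = 0};
#' a uniform column carries 0 bits and a one-hot column 2 bits.
#'
#' @param m A \code{freq_matrix}.
#' @return Numeric vector of per-column bits in [0, 2].
#' @export
information_content <- function(m) {
  f <- m$values
  term <- ifelse(f > 0, f * log2(f), 0)
  ic <- 2 + colSums(term)
  # zero-coverage columns carry no information
  ic[colSums(f) == 0] <- 0
  pmin(pmax(ic, 0), 2)
}

#' Reference bases flanking an insertion site
#'
#' Returns reference bases at the given offsets relative to the plus-strand
#' insertion site, with circular wrap. Offset +1 is the first TSD base
#' (the site itself); offset -1 is the base immediately 5' of the junction.
#'
#' @param site A plus-strand coordinate, or a \code{site_calls} object /
#'   call row whose \code{plus_site} is used.
#' @param ref A \code{ref_assembly}.
#' @param offsets Nonzero integer offsets (negative = upstream).
#' @return Named character vector of bases.
#' @export
flank_context <- function(site, ref, offsets) {
  if (inherits(site, "site_calls")) site <- site$calls$plus_site[1]
  if (is.list(site) || is.data.frame(site)) site <- site$plus_site[1]
  if (any(offsets == 0)) stop_invalid_input("offsets must be nonzero")
  pos <- ifelse(offsets > 0, site + offsets - 1L, site + offsets)
  pos <- wrap_coord(as.integer(pos), ref$n_ref)
  out <- substring(ref$sequence, pos, pos)
  names(out) <- ifelse(offsets > 0, paste0("+", offsets),
                       as.character(offsets))
  out
}

#' Write a frequency matrix as TSV
#'
#' @param m A \code{freq_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_freq_matrix <- function(m, path) {
  df <- data.frame(base = rownames(m$values), m$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
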