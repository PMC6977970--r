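# Synthetic target references: a circular plasmid backbone carrying the
# casposase target cassette (an upstream region required for integration
# followed by the sequence that is duplicated as the TSD).

# Fixed default cassette. The duplicated target begins with the conserved
# 5'-CGCA motif followed by an AT-rich stretch; the 30-bp upstream stub ends
# with a C at the -2 flanking position, the one conserved flanking base
# observed across target sites. Both are fixed literals so that the cassette
# is identical across simulation seeds.
DEFAULT_UPSTREAM <- "GGTTCGAGTCCAACACGGGACAACCTTTCA"
DEFAULT_TSD <- "CGCAATTTAATTGA"

#' Build a synthetic circular target reference
#'
#' Constructs a circular plasmid-like reference: a seeded random backbone
#' (uniform A/C/G/T) into which a target cassette is written. The cassette is
#' the concatenation of an upstream region (required in cis for integration)
#' and the target sequence whose duplication upon double-end integration
#' produces the TSD. \code{cassette_start} is the 1-based coordinate of the
#' first TSD base; the upstream region occupies the \code{nchar(upstream)}
#' bases immediately 5' of it (wrapping past the origin if needed).
#'
#' @param seed Integer seed; the backbone is deterministic given the seed.
#' @param n_ref Reference length in bp (default 2700, the scale of a pUC19
#'   derivative).
#' @param cassette_template Either \code{"default"} (a 14-bp CGCA-initiated
#'   AT-rich target) or a DNA string giving the target/TSD sequence directly.
#' @param cassette_start 1-based coordinate at which the first TSD base is
#'   placed.
#' @param upstream Either \code{"default"} (a fixed 30-bp stub with C at the
#'   -2 flank) or a DNA string placed immediately 5' of the TSD.
#' @param name Reference name used in FASTA headers.
#' @return An object of class \code{ref_assembly}: a list with elements
#'   \code{name}, \code{sequence}, \code{n_ref}, \code{cassette_start},
#'   \code{tsd_len}, \code{upstream_len}, \code{topology}.
#' @examples
#' ref <- build_reference(seed = 1, n_ref = 2700, cassette_start = 600)
#' substr(ref$sequence, 600, 603)  # "CGCA"
#' @export
build_reference <- function(seed, n_ref = 2700, cassette_template = "default",
                            cassette_start = 601, upstream = "default",
                            name = "synthetic_target") {
  tsd <- if (identical(cassette_template, "default")) DEFAULT_TSD
         else toupper(cassette_template)
  ups <- if (identical(upstream, "default")) DEFAULT_UPSTREAM
         else toupper(upstream)
  if (!is_dna(tsd) || !is_dna(ups))
    stop_invalid_config("cassette and upstream sequences must be A/C/G/T only")
  cassette_len <- nchar(tsd) + nchar(ups)
  if (n_ref <= cassette_len + 100)
    stop_invalid_config("reference length must exceed cassette length + 100")
  if (cassette_start < 1 || cassette_start > n_ref)
    stop_invalid_config("cassette_start outside reference")

  chars <- with_seed(seed,
    sample(c("A", "C", "G", "T"), n_ref, replace = TRUE))
  cassette <- strsplit(paste0(ups, tsd), "", fixed = TRUE)[[1]]
  idx <- wrap_coord(cassette_start - nchar(ups) - 1L + seq_along(cassette), n_ref)
  chars[idx] <- cassette

  structure(
    list(name = name,
         sequence = paste(chars, collapse = ""),
         n_ref = as.integer(n_ref),
         cassette_start = as.integer(cassette_start),
         tsd_len = nchar(tsd),
         upstream_len = nchar(ups),
         topology = "circular"),
    class = "ref_assembly")
}

#' @export
print.ref_assembly <- function(x, ...) {
  cat("<ref_assembly>", x$name, "\n")
  cat("  length:", x$n_ref, "bp,", x$topology, "\n")
  cat(sprintf("  target cassette: TSD %d bp at %d..%d (starts %s), %d bp upstream region\n",
              x$tsd_len, x$cassette_start,
              wrap_coord(x$cassette_start + x$tsd_len - 1L, x$n_ref),
              substr(x$sequence, x$cassette_start,
                     min(x$cassette_start + 3L, x$n_ref)),
              x$upstream_len))
  invisible(x)
}

#' Read or write a reference as FASTA
#'
#' Thin wrappers around \pkg{Biostrings} FASTA I/O. \code{read_reference}
#' annotates the loaded sequence with cassette coordinates supplied by the
#' caller (a plain FASTA carries no annotation).
#'
#' @param ref A \code{ref_assembly}.
#' @param path File path.
#' @param cassette_start,tsd_len,upstream_len Cassette annotation for a
#'   reference loaded from FASTA.
#' @return \code{write_reference} returns \code{path} invisibly;
#'   \code{read_reference} returns a \code{ref_assembly}.
#' @export
write_reference <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- ref$name
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path, cassette_start = NA_integer_,
                           tsd_len = NA_integer_, upstream_len = NA_integer_) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L)
    stop_invalid_input("reference FASTA must contain exactly one sequence")
  structure(
    list(name = sub("\\s.*$", "", names(x)[1]),
         sequence = as.character(x[[1]]),
         n_ref = Biostrings::width(x)[1],
         cassette_start = as.integer(cassette_start),
         tsd_len = as.integer(tsd_len),
         upstream_len = as.integer(upstream_len),
         topology = "circular"),
    class = "ref_assembly")
}
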