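# Internal helpers shared across the pipeline stages.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_invalid_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("caspomap_invalid_config", "error")))
}

stop_contract <- function(...) {
  stop(errorCondition(paste0(...), class = c("caspomap_contract_violation", "error")))
}

stop_invalid_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("caspomap_invalid_input", "error")))
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement. Characters outside A/C/G/T/N are mapped to
#' N before complementing, so degenerate input never errors.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  x <- gsub("[^ACGTN]", "N", x)
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

# Map DNA characters to integers 1..4 (A,C,G,T); anything else becomes 0 and
# therefore mismatches every reference base.
encode_dna <- function(x) {
  code <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]],
                c("A", "C", "G", "T"))
  code[is.na(code)] <- 0L
  as.integer(code)
}

# 1-based circular coordinate normalisation.
wrap_coord <- function(pos, n) ((pos - 1L) %% n) + 1L

# Substring of a circular sequence, wrapping past the origin.
circ_substr <- function(chars, start, len, n) {
  idx <- wrap_coord(start - 1L + seq_len(len), n)
  paste(chars[idx], collapse = "")
}

is_dna <- function(x) {
  all(grepl("^[ACGT]+$", toupper(x)))
}
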