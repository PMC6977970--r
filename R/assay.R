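# Closed-form models of the biochemical readouts: denaturing-gel product
# lengths for integration of an end oligonucleotide into a duplex target,
# plasmid topology outcomes, and oligonucleotide / protein-complex masses.

#' Specify an oligonucleotide-target integration geometry
#'
#' @param target_len Duplex target length in bp.
#' @param end_len Length (nt) of the transferred (nucleophile) strand.
#' @param top_cut Bases of the target top strand 5' of the top-strand
#'   junction.
#' @param tsd_len Target-site-duplication length L.
#' @return A validated list of class \code{product_spec}.
#' @export
product_spec <- function(target_len, end_len, top_cut, tsd_len) {
  vals <- c(target_len = target_len, end_len = end_len,
            top_cut = top_cut, tsd_len = tsd_len)
  if (any(vals != round(vals)) || any(vals <= 0))
    stop_invalid_config("all product geometry fields must be positive integers")
  if (top_cut + tsd_len > target_len)
    stop_invalid_config("top_cut + tsd_len must not exceed target_len")
  out <- as.list(vapply(vals, as.integer, integer(1)))
  structure(out, class = "product_spec")
}

#' Predict denaturing-gel product lengths for full-site integration
#'
#' Double-end integration into a linear duplex target cuts each target
#' strand once, the two cuts offset by the TSD. Each strand yields a
#' released 5' (or 3') fragment and a covalent joint of the transferred
#' end with the remaining target fragment:
#' top released = \code{top_cut}; top joined = \code{end_len + target_len -
#' top_cut}; bottom released = \code{target_len - top_cut - tsd_len};
#' bottom joined = \code{end_len + top_cut + tsd_len}. Total nucleotides
#' are conserved: the four lengths sum to \code{2*target_len + 2*end_len}.
#'
#' @param spec A \code{product_spec} (or arguments passed to it).
#' @param ... Passed to \code{product_spec} when \code{spec} is numeric.
#' @return List with elements \code{top} and \code{bottom}, each a named
#'   integer vector \code{c(released=, joined=)}.
#' @examples
#' predict_products(product_spec(40, 17, 22, 14))  # top 22/35, bottom 4/53
#' @export
predict_products <- function(spec, ...) {
  if (!inherits(spec, "product_spec")) spec <- product_spec(spec, ...)
  list(top = c(released = spec$top_cut,
               joined = spec$end_len + spec$target_len - spec$top_cut),
       bottom = c(released = spec$target_len - spec$top_cut - spec$tsd_len,
                  joined = spec$end_len + spec$top_cut + spec$tsd_len))
}

#' Plasmid topology outcome of integration
#'
#' @param n_joined_strands Number of target strands joined: 0 (unreacted),
#'   1 (single-end integration) or 2 (coordinated double-end integration
#'   into opposite strands of one site).
#' @return \code{"supercoiled"}, \code{"relaxed"} or \code{"linear"}.
#' @export
plasmid_outcome <- function(n_joined_strands) {
  if (!n_joined_strands %in% c(0L, 1L, 2L))
    stop_invalid_config("n_joined_strands must be 0, 1 or 2")
  c("supercoiled", "relaxed", "linear")[n_joined_strands + 1L]
}

# Average residue masses (Da) of DNA nucleotide monophosphates within a
# chain, and the correction for a 5'-hydroxyl terminus (loss of HPO3 less
# the water regained: 79.98 - 18.02).
RESIDUE_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
FIVE_PRIME_OH_CORRECTION <- 61.96

#' Average molecular mass of a DNA oligonucleotide
#'
#' Sums average residue masses (A 313.21, C 289.18, G 329.21, T 304.20 Da)
#' and, for a 5'-hydroxyl terminus, subtracts 61.96 Da for the missing
#' terminal phosphate. Synthetic oligos without phosphorylation are 5'-OH,
#' the default.
#'
#' @param seq DNA string (A/C/G/T, non-empty).
#' @param five_prime \code{"OH"} (default) or \code{"monophosphate"}.
#' @return Mass in daltons.
#' @examples
#' oligo_mass("T")                       # 242.24 Da (thymidine)
#' 2 * oligo_mass("TATATCCCCGCACTTAAGCGTG") / 1000  # 13.3 kDa duplex
#' @export
oligo_mass <- function(seq, five_prime = c("OH", "monophosphate")) {
  five_prime <- match.arg(five_prime)
  seq <- toupper(seq)
  if (!nzchar(seq) || !is_dna(seq))
    stop_invalid_input("sequence must be a non-empty A/C/G/T string")
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- sum(RESIDUE_MASS[bases])
  if (five_prime == "OH") m <- m - FIVE_PRIME_OH_CORRECTION
  unname(m)
}

#' Mass of a protein-DNA complex
#'
#' Additive mass stoichiometry as read out by mass photometry:
#' \code{protein_count * protein_monomer_kda + dna_kda}.
#'
#' @param protein_monomer_kda Protein monomer mass in kDa.
#' @param protein_count Number of protein monomers (>= 0).
#' @param dna_kda Total DNA mass in kDa (default 0).
#' @return Complex mass in kDa.
#' @examples
#' complex_mass(49.4, 4, 13.3)  # 210.9 kDa tetramer + integration product
#' complex_mass(49.4, 2)        # 98.8 kDa dimer
#' @export
complex_mass <- function(protein_monomer_kda, protein_count, dna_kda = 0) {
  if (protein_count < 0 || protein_count != round(protein_count))
    stop_invalid_config("protein_count must be a non-negative integer")
  protein_count * protein_monomer_kda + dna_kda
}
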