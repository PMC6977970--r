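---
title: "Mapping casposase integration sites from junction reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping casposase integration sites from junction reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Casposons are mobile genetic elements whose Cas1-homolog integrase (the
casposase) is the leading candidate ancestor of the CRISPR-Cas
spacer-acquisition machinery. In vitro, a casposase joins the 3'-OH terminus
of a casposon-end oligonucleotide into a circular target plasmid. A
coordinated pair of strand-transfer events — one into each target strand,
offset by a fixed number of base pairs — linearises the plasmid and, after
repair, would duplicate the intervening target bases as a target-site
duplication (TSD). Sequencing the linear products with a stranded library
places junction reads at base precision: each read starts in the casposon
end and runs into target DNA, so the first target-derived base identifies
the insertion coordinate on that strand.

`caspomap` turns read-1 FASTQ files from such an experiment into
strand-resolved insertion sites, the inferred TSD length, per-site
frequencies, and nucleotide frequency matrices of the target motif. Because
the deposited raw data are not required, the package also ships a simulator
that generates junction reads with per-read ground truth, which is how the
whole pipeline is tested.

## The pipeline model

1. **Collapse.** Raw reads are collapsed to unique sequences and the
   abundance of each recorded; all downstream statistics are
   abundance-weighted so the collapse loses nothing.
2. **Junction filter.** Unique sequences are kept if their forward strand
   contains the casposon-end junction signature
   (default 5'-GAGTTACCTATATCCC, the 3' terminus of the transferred
   strand). Reads are stranded, so no reverse-complement search is done —
   which is also what makes the wrong-end audit below meaningful.
3. **Clip.** The casposon-end fragment through the signature is removed,
   retaining the target-derived suffix (minimum 14 nt, one full TSD, so
   every retained fragment can span a duplication).
4. **Align.** Clipped fragments are aligned ungapped to both strands of the
   circularised reference by an exhaustive Hamming scan over the doubled
   sequence (positions wrap modulo the reference length). Only placements
   achieving the minimal mismatch count (≤ `max_mm`, default 2) are
   reported, and only unambiguous (`unique`) placements are used for site
   calling. Gapped alignment is deliberately out of scope: the fragments
   are short (≤ ~59 nt at 75-nt reads) and strand-transfer chemistry
   introduces no indels relative to the reference, so substitution-only
   alignment is exact and directly testable against a brute-force oracle.
5. **Events and sites.** Each uniquely aligned fragment becomes an
   insertion event at the plus-strand coordinate of the first target base
   3' of the junction: `ref_start` for plus-strand hits,
   `ref_start + length - 1` for minus-strand hits. Events at identical
   (site, strand) merge by abundance. For every sufficiently frequent
   plus-strand event, the minus-strand event within the downstream pairing
   window maximising joint abundance is selected; the pair's offset gives
   the TSD length `L = q − p + 1`, counting both junction bases, so a
   14-base duplicated target yields L = 14. Calls are labelled TS1, TS2, …
   by descending abundance-weighted frequency; the consensus L across
   calls is the abundance-weighted mode.
6. **Motif.** Per strand, clipped fragments are aligned at their 5' ends
   and an abundance-weighted nucleotide frequency matrix over positions
   +1..+30 downstream of the junction is computed. The negative-strand
   matrix can be complement-flipped (reverse columns, swap A/T and C/G) to
   overlay the positive-strand matrix across the duplicated target.
   Information content per column (`2 + Σ f log2 f` bits) is provided for
   logo-style scaling; the primary object is the frequency matrix.
7. **Directionality audit.** Reads containing the junction string expected
   if the *other* 3'-OH of the end oligonucleotide had been the nucleophile
   are counted (abundance-weighted). For a duplex end this remote junction
   is modelled as the reverse complement of the end sequence — the sequence
   read off the remote 3' terminus — and the expected count in a clean
   experiment is zero.

Multiple samples are processed independently; events are pooled for site
calling, and each call additionally reports the mean and standard error of
its per-sample frequency.

## Parameters that matter

| parameter | default | rationale |
|---|---|---|
| `signature` | GAGTTACCTATATCCC | 3' terminus of the transferred casposon-end strand; ≥ 8 nt enforced so random 75-mers essentially never match |
| `max_mismatch` (filter) | 0 | grep-style exact containment; errors inside the signature drop the read rather than risking false junctions |
| `min_clip_len` | 14 nt | a retained fragment can span one full TSD |
| `max_mm` (aligner) | 2 | ~3% of a 75-nt read; substitution errors at rate 0.001 almost never exceed it on a ≤ 59-nt fragment |
| `merge_window` | 0 bp | junction chemistry is base-precise and an ungapped unique hit cannot shift its start under substitutions, so exact-coordinate aggregation is correct; a window is available for degraded inputs |
| `max_offset` | 50 bp | upper bound on plausible TSD lengths when pairing strands |
| `min_frequency` | 0.001 | reporting threshold for minor sites; lower it for deep PCR-free libraries where rarer sites are resolvable |
| `W` | 30 | motif window +1..+30 downstream of the junction |

## What the simulator emulates

`build_reference()` makes a ~2.7-kb circular plasmid-scale reference with a
uniform random backbone and a fixed cassette: a 30-bp upstream region
(required in cis for integration; its fixed literal ends with C at the −2
flank, the one conserved flanking base) followed by a TSD whose default is
CGCA plus ten AT-rich bases, matching the consensus of an initial CGCA
motif followed by AT-rich sequence. The cassette literals are fixed rather
than seed-drawn so that references differing only in seed share an
identical cassette — only the backbone varies. The real target plasmid's
full sequence is not needed: the pipeline's claims are about junction
geometry, not about plasmid identity.

`simulate_reads()` draws template molecules from configured sites (each
event contributes plus- and minus-junction products with equal
probability), duplicates molecules with geometric PCR-duplicate counts
(mean `dup_skew`, default 3, a moderately amplified library; duplicates are
made before error injection so collapsing is meaningful), then emits 75-nt
stranded reads with i.i.d. substitution errors (default 0.001). Two
library geometries are modelled: `amplicon` (default), where every read
starts at a fixed primer offset inside the end sequence, mirroring
libraries amplified with an end primer; and `fragmentation`, with uniform
breakpoints over the product molecule, mirroring tagmentation. A
configurable fraction of events can be spiked with wrong-end joining for
the directionality audit. Ground truth (site, strand, molecule,
junction-spanning flag) is recorded per read.

Features of real data that are *not* modelled: indels, quality decay and
quality-dependent errors, insert-size distributions, adapter read-through,
chimeric PCR artefacts, and strand bias in library preparation. Passing
tests therefore demonstrate correctness of the coordinate bookkeeping,
pairing logic and statistics under the stated error model, not robustness
to every artefact of a real sequencer.

## Numerical and design choices

- **TSD convention.** `L = q − p + 1` counts both junction bases, so the
  duplication of a 14-base target reads as L = 14. A coincident strand
  pair (p = q) is the degenerate single-base duplication, L = 1.
- **Tie-breaks.** Collapsed sequences sort by descending abundance with
  lexicographic ties; the leftmost signature occurrence wins on repeated
  signatures; ambiguous (multi-mapping) alignments are flagged and
  excluded from site calling so attribution is never arbitrary.
- **Ragged motif columns.** Fragments shorter than W contribute to the
  columns they cover; each column is normalised by the weight covering it.
  An empty input yields a flagged zero matrix, never NaN.
- **Masses.** Average (not monoisotopic) residue masses (A 313.21,
  C 289.18, G 329.21, T 304.20 Da) with a −61.96 Da correction for a
  5'-OH terminus; synthetic oligonucleotides without phosphorylation are
  5'-OH, the default. This reproduces, e.g., 242.24 Da for thymidine and
  13.3 kDa for the two-stranded 22-nt integration-product mimic.
- **Product lengths.** The denaturing-gel model assumes full-site
  (double-end) insertion defined by one top-strand cut and one TSD length;
  the four product lengths conserve nucleotides
  (`Σ = 2·target + 2·end`). Half-site outcomes are covered only by the
  plasmid topology map (0 → supercoiled, 1 → relaxed, 2 → linear).
- **Seeding.** Every stochastic function takes an explicit seed and
  restores the caller's RNG state, so identical configurations give
  byte-identical FASTQ, truth tables and site tables.

## Problem sizes used in the shipped checks

The test suite exercises the pipeline at 400–5,000 reads on 300–2,700-bp
references, plus one 100,000-read mixture-recovery experiment at weights
(0.994, 0.004, 0.002) run PCR-free (`dup_skew = 1`, emulating a library
prepared without amplification) so that recovered frequencies can be judged
against plain binomial sampling error; with duplicate skew the effective
sample size shrinks and a binomial band would be the wrong yardstick. The
aligner is validated against a brute-force doubled-reference Hamming scan
on 1,000 random queries over a 300-bp reference; exhaustive equivalence,
not spot checks.

## Limitations

- Ungapped alignment is exact for this assay but unsuitable for references
  with repeats longer than the clipped fragments (such queries are flagged
  non-unique and dropped) or for data with indel errors.
- Site significance is not tested statistically; frequencies are reported
  with per-sample standard errors only.
- The directionality audit is a containment count, not an alignment; a
  remote-junction string that happens to occur in the target backbone
  would inflate it (no such occurrence exists for the default 16-nt
  signature at plasmid scale).
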