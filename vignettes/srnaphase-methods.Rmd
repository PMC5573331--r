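---
title: "Methods: small RNA locus discovery, phasing statistics and degradome validation"
author: "srnaphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA locus discovery, phasing statistics and degradome validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaphase)
```

## Scope and model

`srnaphase` re-implements, on assembled transcripts, the analysis chain used
in plant root small-RNA studies: collapsing sequenced reads into unique tags,
annotating conserved and novel miRNA loci from fold-back precursor structure,
detecting 21-nt phased siRNA (phasiRNA) loci with a hypergeometric register
test and a phase score, locating TAS3 loci from dual miR390 complementary
sites around conserved tasiARF sequences, validating small RNA targets with
degradome (PARE) 5'-end profiles, and testing miRNA abundance differences
between biomass groups defined from a phenotype table. A synthetic-data
generator produces all of these inputs with known ground truth, so every
stage is testable without sequencing archives.

Coordinates are 0-based half-open internally and 1-based inclusive in every
report and GFF3 file. Sequences are held in the RNA alphabet; DNA input is
converted on read and restored on write.

## The register statistics

For a window of `m` phases of 21 nt (window length 210 nt, `m = 10` by
default), let `n` be the number of distinct occupied 21-nt sRNA positions in
the window and `k` the number of occupied register positions. If reads were
placed at random, the number of occupied register positions follows a
hypergeometric distribution over the `21 m` window positions, `m` of which
are in register. The window P-value is the upper tail

$$P = \sum_{X=k}^{\min(n,m)} \frac{\binom{m}{X}\binom{20m}{n-X}}{\binom{21m}{n}},$$

evaluated in log space (exact to ~1e-12 up to `n = 210`). Two reading notes,
both config-free: the sum's upper limit is `min(n, m)` so every term is
defined when `n < m`, and the summation index runs through the binomials
(the tail does not normalize otherwise). The invariant `k <= m` forces
cycle-level counting: `n` counts distinct occupied effective positions and
`k` distinct occupied phase cycles, while the phase score's \(P_i\) and
\(U_i\) hold raw read counts.

The phase score of a window with `k >= 3` phased unique sRNAs is

$$\mathrm{score} = (k-2)\,\ln\!\left(1 + 10 \frac{\sum_i P_i}{1 + \sum_i U_i}\right),$$

with \(P_i\) the phased and \(U_i\) the non-phased reads of cycle `i`; the
score is 0 for `k <= 2`. Loci are called when some window has
`p_value <= 0.001` **and** `phase_score >= 5` (both thresholds exposed in
`run_config()`; the score threshold follows the convention that phased
transcripts score above 5). Windows slide 1 nt at a time — the slide step is
unstated in most descriptions of the scan, and a 1-nt slide finds every
register at negligible cost on transcripts.

Antisense reads of a phased duplex carry the 2-nt 3' overhang signature, so
an antisense alignment's left coordinate sits 2 nt upstream of its sense
partner; `map_effective_positions()` adds `+2` to antisense positions and
drops non-21-nt tags.

```{r}
window_pvalue(5, 5, 10)
phase_score(c(10, rep(0, 9)), rep(0, 10), k = 3)  # = ln(101)
```

## Hairpin discovery

`find_homolog_loci()` searches known mature miRNAs against transcripts on
both strands, ungapped, keeping hits with at most 2 substitutions (the
"no more than two mismatches" rule implies substitution-only alignment).
Antisense hits are kept and flagged. 150-nt flanks are extracted around each
hit and folded.

The internal folder is a maximum base-pair (Nussinov-style) fold over nested
structures, minimum hairpin loop 3 nt, with a deliberately simple non-Turner
energy model: −3 kcal/mol per G:C, −2 per A:U, −1 per G:U wobble. The −40
kcal/mol precursor threshold is calibrated for this model; when the
ViennaRNA `RNAfold` binary is available it can be selected as a backend with
thermodynamic energies, but nothing depends on it. The traceback prefers the
largest co-optimal partner, which keeps helices stacked against the
enclosing pair; a smallest-partner traceback converts symmetric internal
loops into spurious bulges. The folder is verified in the test suite against
brute-force enumeration of nested pairings on random strings up to 30 nt.

`hairpin_filter()` requires at least 18 paired nucleotides **within the
mature region** and folding energy strictly below −40 kcal/mol. Reading the
18-nt bound over the mature region (not the whole 321-nt window, where it
would be vacuous) is the only interpretation that makes the filter
discriminative; both the location and the thresholds are configurable.

`mircheck_filter()` evaluates the mature against its dominant duplex — the
longest chain of paired mature positions with strictly decreasing partners,
so stray long-range pairs into the flanks are ignored. Per interior gap,
`min(gap_mature, gap_partner)` nucleotides count as mismatches and
`max(0, gap_mature − gap_partner)` as bulged/asymmetric; the three bounds
(≤6 mismatches, ≤2 bulged nucleotides, ≤3 continuous mismatches) are taken
within the mature miRNA, so partner-side-only gaps and dangling mature ends
do not count.

`call_novel()` demands miRNA* evidence: tags mapping to both arms whose
duplex shows ~2-nt 3' overhangs under the candidate's structure, with ±1 nt
tolerance (standard annotation-criteria practice; the exact tolerance is
rarely stated). The overhang is measured as the modal implied offset over
all paired tag positions, which is robust to 1–2 shifted pairs at duplex
ends in co-optimal folds. `merge_members()` merges isomiR-style calls
differing by at most two terminal nucleotides, and never merges calls whose
recorded precursors differ — including transitively through precursor-free
calls.

## Degradome validation and TAS3

`build_profile()` anchors each degradome tag's exact sense matches at the
tag's 5' position; multi-mapping tags count at every locus (the simplest
auditable rule; fractional assignment would need an arbitrary model).
`find_sites()` scores reverse complementarity over all ungapped alignments;
G:U wobbles count 0.5 mismatch (rounded down on the total), switchable to 1.
The cleavage position is the transcript position opposite small-RNA position
10. A "valid read" is a degradome 5' end opposite positions 9–11 — the
canonical slicer position with 1-nt tolerance; the window is config-exposed
since the construct's published definition is informal.

`validate_targets()` applies the retention rules: conserved-family sites
with fewer than 4 mismatches are kept as predictions; family sites with 4–5
mismatches are kept only when the family has no retained lower-mismatch
site; novel-miRNA sites need fewer than 4 mismatches **and** at least one
valid read. The 4–5-mismatch fallback does not additionally require
degradome support (it mirrors the stated rule only).

`find_tas3()` reports transcripts carrying a tasiARF homolog (≤3
substitutions against packaged canonical Arabidopsis tasiARF 21-mers,
user-replaceable) with miR390 complementary sites (≤5 mismatches) both 5'
and 3' of the match, and computes the phase register between the 3' site's
cleavage position and the tasiARF start modulo 21 — register 0 means the
tasiARFs sit in frame with miR390-guided cleavage, the canonical two-hit
configuration.

## Differential abundance and phenotypes

Tag abundances are normalized to reads per ten million (RPTM),
`raw × 10^7 / library size`, using the library's total qualified reads
(depth) rather than the post-filter total — RPTM normalizes sequencing
depth, and blocklist filtering therefore leaves `library_size` unchanged.
Samples are grouped by total root mass: Small below `mean − 0.5 sd`, Large
above `mean + 0.5 sd`, Medium the inclusive interval between (sample sd,
n−1; the factor is configurable). Thresholds may be computed from a larger
reference table than the samples being labeled. Only miRNAs with mean RPTM
≥ 10 in either Small or Large enter testing, and the comparison uses only
those two groups.

`test_differential()` is the package's own count test (numeric equivalence
to any external tool is a non-goal): counts are scaled to a common library
size, a common negative-binomial dispersion (variance `mu + phi mu^2`) is
estimated by moments — the mean of per-miRNA excess-variance ratios over
well-expressed rows, which is markedly more stable than either a median (biased
low by the skew of small-sample variances) or a depth-weighted sum
(dominated by a few extreme rows) — and each miRNA gets a Wald z statistic
on the difference of group means with the null standard error evaluated at
the pooled mean. Evaluating the SE at the pooled mean (score-test style)
removes an artifactual correlation between the effect and its SE that makes
the two-group-mean version conservative. Null simulations show uniform raw
P-values (type-I ≈ 0.05) and ≥ 95% power at 3-fold spikes with 6 vs 6
libraries and dispersion 0.05. Multiple testing uses Benjamini–Hochberg
(the conventional default of count-based differential tools; Bonferroni
available via `p.adjust`).

Trait correlations are pairwise-complete Pearson with two-sided t-tests;
qPCR fold changes use `2^(−ΔΔCt)` with the calibrator sample at exactly 1.

## The synthetic-data generator

`sim_design()` fixes the study conditions; all randomness flows from its
single seed and identical designs give byte-identical output. The generator
emulates:

- **Transcripts**: i.i.d. uniform A/C/G/U background, default 30 transcripts
  of 600–1200 nt (long enough for 150-nt flanks and a 210-nt scan window
  plus trigger site).
- **Hairpins**: `gen_hairpin()` builds `mature + loop + star` with the
  canonical 2-nt 3' overhang geometry (star = reverse complement of mature
  1–19 plus a 2-nt tail); planted duplex mismatches are self-base
  oppositions, which can never Watson–Crick- or wobble-pair, so the planted
  mismatch count is exact. When the loop is ≥5 nt its last two bases
  complement mature 20–21, so a maximum-pairing fold pairs ≥ `21 − mm`
  mature positions. In `gen_transcriptome()` each hairpin is embedded in a
  10-nt lower stem (as in real fold-backs) and re-sampled until the flanked
  window passes the precursor filters: the generator plants only bona fide
  precursors, which is the closure property the discovery stage is tested
  against. Hairpin windows are guarded so no later feature lands within
  flank range.
- **Phased loci**: a trigger complementary site whose cleavage position
  (opposite trigger position 10) starts a 10-cycle register; a fraction
  `1 − offtarget_frac` of reads start exactly on register, `antisense_frac`
  of them on the antisense strand at the duplex-partner position, and
  off-target reads fall uniformly on non-register positions. One locus per
  transcript, since calling keeps the best window per transcript.
- **Decoys**: transcripts carrying only the background read stream (pure
  noise; `decoy_read_rate` can add more). Background and decoy reads draw
  lengths from a bimodal 20–24 nt distribution with peaks at 21 and 24 nt,
  as real plant libraries show; only the 21-mers are phasing-eligible.
- **Counts**: negative binomial with `variance = mu + phi mu^2`, per-sample
  library sizes, 6/5/6 Small/Medium/Large libraries (a 17-library design).
  Spiked miRNAs scale smoothly with the per-sample TRM so that the
  Large/Small mean ratio equals the design fold change and spiked abundance
  correlates positively with TRM.
- **Degradome**: 20-nt 5'-anchored fragments; every true site receives
  `degradome_peak_depth` reads at its cleavage position over Poisson
  background. Tags are generated first and the profile is built from them
  through `build_profile()`, so the two are consistent by construction.
- **Phenotypes**: multivariate normal with a one-factor (plant size)
  correlation structure over TRM, RM, HT, MLL, MLW, TLA and LN
  (`r(TRM, TLA) ≈ 0.78`, leaf number nearly independent), truncated at a
  small positive floor only at output so mild truncation barely disturbs
  the target correlations.

What the generator does **not** emulate: sequencing errors, adapters and
quality scores (upstream of everything implemented here), genome-scale
multi-mapping ambiguity, expression-coupled secondary structure, or
ncRNA/repeat contamination beyond what a user supplies as blocklist FASTA.
Passing closure tests on this generator therefore demonstrates correctness
of the statistics and the discovery logic, not robustness to every artifact
of real libraries.

## Numerical and design choices

- Binomial coefficients in log space; tail sums rescaled by their maximum
  term; P-values clamped to [0, 1]; `k = 0` returns exactly 1.
- Ties in locus calling resolve by smallest P-value, then largest score;
  the deterministic folder traceback is described above.
- `dinucleotide_shuffle()` is an Altschul–Erickson shuffle (random Eulerian
  walk preserving exact dinucleotide counts), used to build decoys for
  hairpin discovery.
- Degenerate inputs: empty tag libraries, read-free windows, transcripts
  shorter than one window, zero-variance TRM and constant traits all return
  well-defined empty/neutral results rather than errors; genuinely invalid
  input (non-positive counts, bad correlation matrices, missing
  calibrators) errors early with the offending record named.
- Test problem sizes: 50 planted hairpins on 60 transcripts, 20 phased loci
  with 20 decoys, 10^4 null windows, 10^5 Monte-Carlo placements, 100 power
  simulations of 200 miRNAs — sizes at which every stochastic check is
  stable across seeds while the whole suite runs in well under a minute per
  module.

## Known limitations

- The internal energy model is not a thermodynamic nearest-neighbor model;
  energies are comparable only within this package (the `RNAfold` backend
  restores thermodynamic semantics).
- The homolog search and site scan are ungapped; 1-nt bulged target sites
  are out of scope by default.
- Blocklist filtering is exact full-tag containment (optionally with
  mismatches), not a spliced or gapped aligner.
- The differential test estimates one common dispersion; strong per-miRNA
  dispersion heterogeneity would call for tagwise shrinkage, which is
  deliberately not re-implemented here.
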