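---
title: "Screening mercury-cycling genes in marine metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening mercury-cycling genes in marine metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgscreen)
```

## The problem

Methylmercury (MeHg) is a bioaccumulative neurotoxin whose marine budget is
largely set by microbial gene systems: `hgcAB` (Hg(II) methylation — HgcA is
a corrinoid methyl-carrier protein, HgcB its ferredoxin electron donor),
`merB` (organomercury lyase, demethylation) and `merA` (mercuric reductase,
Hg(II) → volatile Hg(0)). Surveys of these genes in open-ocean metagenomes
follow a common analysis pattern:

1. **Detect** candidate proteins per family with profile hidden Markov
   models and family-specific E-value cutoffs (1e-5 for hgcA/hgcB/merB,
   1e-10 for merA).
2. **Curate** hits by requiring the experimentally validated catalytic and
   metal-binding residues (see below); sequences missing any of them —
   including fragments whose alignment leaves a gap at a required
   position — are excluded.
3. **Quantify** validated counts per sample as a percentage of the
   single-copy marker gene *rpoB*.
4. **Dereplicate** at 90% amino-acid identity and assign lineages for
   composition summaries.
5. **Correlate** gene abundances and mercury species against hydrographic
   depth profiles (Spearman's rank correlation, n = stations × depths).

`hgscreen` implements this pipeline as a tested, reusable package, and
ships seeded synthetic-data generators with known ground truth so that the
whole chain — detection calibration, residue curation, normalization,
lineage assignment, correlation — can be verified end to end without any
external downloads.

## Curation rules

Rules are data, anchored to the ungapped 1-based coordinates of a named
reference sequence and editable as a TSV (`write_rules()` /
`read_rules()`):

| family | requirement |
|--------|-------------|
| hgcA | Cys at position 93 (cap-helix cysteine) |
| hgcB | two `CX2CX2CX3C` ferredoxin-type cysteine clusters (count on the candidate itself) |
| merA | Cys-207 + Cys-212 (catalytic pair), Tyr-264, Tyr-or-Phe-605 (bacterial vs archaeal variants), vicinal Cys-628 + Cys-629 — mercuric-reductase numbering of the *Bacillus* sp. RC607 anchor |
| merB | Cys-96, Asp-99, Cys-117, Cys-159 (R831b organomercury-lyase numbering) |
| rpoB | none — it is the normalization marker, not a curated family |

A candidate is mapped onto the anchor with one global alignment and each
rule position is read off in anchor coordinates, which makes the check
invariant to insertions in the candidate; a gap at a rule position fails
the rule, so partial genes cannot pass. The shipped anchors are synthetic
(generated with the rule residues planted); real anchor sequences can be
substituted through the rule TSV and reference FASTA without code changes.

## Alignment conventions

Pairwise alignment is global Needleman–Wunsch with affine gaps, BLOSUM62,
`gap_open = -11`, `gap_extend = -1` (a gap of length *k* costs
`open + (k-1)*extend`; end gaps are penalized). Identity uses the CD-HIT
convention — identical columns divided by the length of the shorter
unaligned sequence — because the 90% dereplication cutoff cites that tool.
Traceback ties are broken diagonal → gap-in-candidate → gap-in-reference,
fixed for determinism. `X` scores 0 against everything and never counts as
identical. Dereplication is greedy-incremental: records sorted by
descending length (ties by id) join the first representative they match at
the threshold, so representatives are always the longest member.

## Profile models and E-values

Profiles are small Plan7-style models (match/insert/delete states, global
in the model, no local envelopes or multi-hit scoring) built from a
reference alignment: columns with <50% gaps become match states; emissions
are Laplace-smoothed counts `(n+1)/(N+20)`; transitions come from the gap
structure with +1 pseudocounts; the background is the overall smoothed MSA
residue frequency. Scores are log-odds in bits (Viterbi and forward; the
forward score is always ≥ Viterbi, a property the tests check along with
an exhaustive path-enumeration oracle on tiny profiles).

E-values are calibrated empirically per profile: `n_null = 500` i.i.d.
background sequences are drawn with lengths resampled from the searched
catalog, scored with Viterbi, and a Gumbel law is fitted by maximum
likelihood; `E(s | N) = N · (1 − F(s))` with N = catalog size. Two
numerical choices matter here and were forced by measurement rather than
taste:

* **Length trend.** A global-in-model score depends strongly on sequence
  length, with a kink at the profile length L (sequences shorter than L
  force deletions; longer ones force inserts). The calibration removes
  this trend by least squares on the hinge features `max(L−len, 0)` and
  `max(len−L, 0)` (linear + quadratic). With a single pooled Gumbel and no
  trend removal, a *perfect* reference copy only reached E ≈ 1e-6 — the
  merA 1e-10 threshold would have rejected every true merA.
* **Length-dependent spread.** Null-score fluctuations also grow with
  length, so the residual variance is modeled as linear in length and the
  Gumbel is fitted to standardized residuals. Without this, the pooled
  spread (dominated by long decoys) made every planted hgcB hit — a
  100-residue family — undetectable at 1e-5.

The Gumbel right tail is heavier than the roughly Gaussian truth for these
global scores, so E-values are conservative: decoy false positives are
over-protected, and genuine hits (hundreds of bits above the null) are
unaffected. The calibration seed, coefficients and null scores are kept in
the calibration object; profiles serialize to a versioned plain-text
format that round-trips byte-exactly.

## Quantification and lineages

rpoB abundance uses HMM hits only (no residue curation — the curation
rules concern the mercury genes). Relative abundance is
`100 · validated / rpoB` with an explicit error (never a silent NaN) if a
sample's rpoB count is zero. Dereplication is applied **before lineage
tabulation but not before abundance counting**: normalization concerns raw
gene counts, while composition summaries should not be inflated by
near-identical sequences.

Lineage assignment replaces tree placement with best-labeled-reference
search: the candidate's global-alignment score against every labeled
reference of its family; ties break to the lexicographically smaller
reference id; the margin to the second-best reference is reported and
assignments with margin < 5 bits are flagged `ambiguous` (the lineage is
still the argmax). This is deliberately simpler than MAFFT + FastTree
(out of scope) but testable: on the synthetic benchmark, ≥95% of records
mutated at 10% of sites recover their source lineage.

## Statistics

`spearman()` re-implements the rank correlation rather than calling
`cor.test()`: average ranks for ties, rho as the Pearson correlation of
rank vectors, two-sided asymptotic p via the t transform with n−2 degrees
of freedom (`cor.test` serves as an independent oracle in the tests). A
permutation companion enumerates all n! permutations exactly for n ≤ 7
(p = count/n!) and uses the add-one Monte-Carlo estimator otherwise. The
correlation matrix computes every unordered variable pair on pairwise
complete samples and reports the effective n; a pair involving a constant
vector (which arises by design here — see below) yields `NA` rather than
aborting. No multiple-testing correction is applied by default, matching
the reporting convention of depth-profile studies; a Benjamini–Hochberg
column is available behind `adjust = TRUE`.

## The synthetic world

The generators encode one fixed benchmark, not a tunable dial:

* **Sampling design**: 3 stations × 4 depths — 200, 500, ~1,000 (1,000 /
  967 / 1,175 m per station) and 1,500 m — i.e. the n = 12 layout of
  subtropical-gyre depth-profile studies.
* **Families**: template lengths 330 (hgcA), 100 (hgcB), 640 (merA, which
  must host rule positions up to 629), 220 (merB), 300 (rpoB — the real
  gene is ~1,340 codons; it is scaled down so the ~10⁴-sequence benchmark
  searches in seconds on one CPU). References carry lineage-specific
  marker substitutions plus random point mutations; rule sites are never
  touched; deletions planted in every third reference count against the
  divergence budget so pairwise reference identity stays ≥ 1 − 2·0.08.
  For hgcB the background is kept cysteine-free outside the planted
  motifs, so cluster counts are exact by construction.
* **Catalogs**: per sample, planted-valid counts rising into the
  mesopelagic for hgcA (5→20), merA and merB (4→12) and flat for hgcB
  (8), mirroring the depth trends such surveys report; 5 rule-ablated
  records per mercury family (one named rule broken per record, with
  chemically conservative substitutions C→S, D→N, Y→H so they still score
  well under the HMM — isolating the curation step); 200 uniform-random
  decoys; 500 rpoB records; default mutation rate 0.05. Roughly 9,000
  records in total.
* **Environment tables**: strictly monotone depth profiles built from
  cumulative positive random increments — dMeHg (≈0.005→0.04 pM), AOU,
  NO₃, PO₄, SiO₂ increasing; temperature, O₂, cell counts decreasing;
  dTHg flat noise in 0.42–0.66 pM. The dMeHg/dTHg ratio column is exact.

What a green test establishes — and what it does not: the synthetic world
verifies the *machinery* (detection calibration, residue mapping,
normalization arithmetic, lineage recovery, correlation behavior) under
known truth. It does not emulate real hgcA sequence diversity, real
lineage imbalance, chimeric assemblies, or real abundance scales: planted
counts are 1–4% of rpoB, an order of magnitude above the ~0.1–0.25%
reported at sea, because single-digit true counts would make recall
statistics meaningless at desk scale. Flat hgcB counts with a constant
rpoB denominator produce a constant abundance profile, which is why the
correlation matrix has an explicit NA policy for degenerate pairs.

## Determinism and limitations

All randomness flows from config seeds (simulation, calibration,
permutation); running the pipeline twice with the same config reproduces
every output table byte for byte, which is itself an acceptance test. The
command-line interface (`simulate`, `build-profiles`, `search`,
`validate`, `dereplicate`, `quantify`, `correlate`, `run-all`) exchanges
documented TSV/FASTA/plain-text formats so stages are independently
testable; exit codes are 0 (success), 2 (input error), 3 (internal error).

Known limitations: no local alignment or domain envelopes (a distant
homolog embedded in a long fusion protein would score poorly against the
global-in-model profile); no paralog discrimination beyond the residue
rules; best-reference lineage assignment cannot discover novel lineages;
the E-value model extrapolates a fitted Gumbel tail far beyond the 500
observed nulls and should be read as conservative screening, not exact
tail probability; AOU is consumed as a given column, never computed from
oxygen solubility.
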