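---
title: "duoprobe: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{duoprobe: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duoprobe)
```

`duoprobe` covers the computational spine of building and validating a
60-mer oligonucleotide microarray that serves two divergent genomes at
once — the motivating system is the *japonica*/*indica* rice subspecies
pair — and of analysing the one-channel expression data such a platform
produces. This vignette explains each stage's model and assumptions, the
parameters that matter, the numerical conventions, and what the
synthetic-data module does and does not emulate.

## Probe design

Probes are windows of the mRNA-sense transcript, never
reverse-complemented (synthesis chemistry is out of scope). Candidates
are enumerated at stride `step` (default 1, exhaustive) under four
intrinsic filters, applied in the fixed order N-content, 3′ window, GC,
simple repeats, self-complementarity. The order only determines which
failure is *reported*; pass/fail is the conjunction of the individual
filters, and the test suite checks that property on 10,000 random
60-mers.

* **3′ window** (`window`, default 1200 nt). One-channel labeling
  produces 3′-biased aRNA, so coverage is best near the transcript end.
  The window rule is interpreted as: the probe's *last* base must lie
  within the final `window` nucleotides — equivalently
  `dist_3prime <= window - 1`. Measuring to the probe 3′ end (rather
  than its 5′ start) was a genuinely open choice; the 3′ convention was
  picked because it is the labeled end of the molecule that matters for
  signal. Coordinates are 1-based inclusive throughout.
* **GC bounds** (`gc_min`/`gc_max`, defaults 0.40/0.60, both
  *inclusive*). GC fraction is computed exactly as (#G + #C)/60; a
  candidate at exactly 0.40 or 0.60 passes.
* **Simple repeats** (`max_repeat`, default 5 nt). "Fewer than 6 simple
  nucleotide repeats" admits several readings; the implemented rule
  rejects a candidate when any homopolymer or tandem dinucleotide run
  (period 2, distinct letters) reaches 6 nt. This is the standard
  low-complexity rule for long oligos; the threshold is exposed so a
  stricter or looser reading is one argument away.
* **Self-complementarity** (`selfcomp_max`, default 15 nt). Full RNA
  folding is out of scope; the proxy is the length of the longest
  segment whose reverse complement occurs anywhere in the probe — the
  longest perfect hairpin stem the probe could form. A palindromic
  segment counts against the probe (it pairs with itself across its
  midpoint), while homopolymers score 0 since their complement run
  never occurs. The score is computed by binary search on the longest
  common substring between the probe and its reverse complement
  (monotone in length); the unit tests verify it against an independent
  O(n²) dynamic program. The 15-nt default is deliberately permissive —
  random 60-mers essentially never reach it, so it acts as a guard
  against pathological inputs rather than a routine filter.
* **N handling.** N is legal in input sequences, but any candidate
  window containing N is discarded (`fail_N`) before any metric is
  computed.

One probe per gene is selected deterministically among passing
candidates: smallest `dist_3prime`, then GC closest to 0.50, then
smallest start. Determinism under input permutation is tested.

## Cross-genome specificity

Each probe is searched against both genomes by an internal ungapped
seed-and-extend matcher. Windows of the genome that share at least one
exact `seed_len`-mer (default 16) with the probe are compared
end-to-end; windows with at least `min_matches` identical bases
(default 47 of 60, ≈ 78% identity, in the spirit of the usual
cross-hybridization rule for 60-mers) are accepted; accepted windows on
the same contig and strand within 59 nt of one another are merged,
keeping the best-matching position, so a single genomic locus is never
double-counted. Minus-strand hits are reported in forward-contig
coordinates.

Two properties of this design are worth stating plainly:

* **The seed stage is a heuristic.** A window with 47/60 matches need
  not contain any intact 16-mer (13 substitutions can be spaced to
  break every seed), so seeded search can miss borderline hits.
  `seed_len = 1` evaluates every offset and is exact; the acceptance
  suite verifies exact mode against an independently coded all-offsets
  scorer on a 50-kb genome.
* **Orientation does not affect status**: searching both strands is the
  default, and hit counting is strand-agnostic.

Hit counts map to a status — 0 none, 1 unique, ≥ 2 multiple — and the
status pair maps to the seven groups A–G (see the README table). The
two pairs with no group, (none, none) and (none, multiple), return
`UNASSIGNED`: a probe that hits neither genome cannot be on the array,
and a probe whose only hits are multiple in the second genome has no
defined home among the seven groups, so inventing one was rejected.
`classify_group` is total over all nine pairs and exhaustively tested.

The identity and seed thresholds are conventions, not published values
— the original screening pipeline's cutoffs are not recoverable — and
are therefore exposed in `match_params()` and recorded in every output
header.

## Expression analysis

The pipeline assumes single-label hybridization: each array measures one
sample, and ratios are formed *between* arrays.

* **Detection**: flag `good` and SNR = foreground/background ≥
  `snr_min` (default 2; zero background with a good flag counts as
  detected).
* **Background and floor**: working value is
  max(foreground − background, `floor`) with floor 1, so log2 values
  are bounded below by 0.
* **Median scaling**: each array is multiplied by (reference median /
  its detected-spot median), the reference being the median of
  per-array medians. After scaling, all detected-spot medians agree to
  ~1e-16 relative; the invariant is tested at 1e-9.
* **Ratios and tests**: log2(A/B) is the inverse-variance-weighted mean
  of all pairwise log2 differences, which with equal per-pair weights
  — the only case the data support, as spot-level variances are not
  modeled — reduces to mean(log2 A) − mean(log2 B). That reduction is
  exact and is what the code computes. The p-value is a Welch
  two-sample t-test on the log2 replicate intensities. This pair of
  choices is the package's documented stand-in for the proprietary
  error model of the commercial software that accompanied the original
  platform; only the thresholding semantics below are treated as fixed.
* **Degenerate inputs**: when a Welch test is impossible (fewer than 2
  replicates on a side) the p-value is NA; when the test degenerates
  because replicate values are (numerically) constant, the p-value is 0
  if the means differ and 1 otherwise. Probes detected in only one
  tissue get a ratio against the floor's log2 value, a one-sample
  t-test against that floor, and a `one_sided` flag.
* **DE calls**: up iff log2 ratio ≥ 1 (inclusive) and p < 0.05
  (strict); down symmetrically. No multiple-testing correction is
  applied by default, matching the platform-validation convention of
  thresholding raw p-values; Benjamini–Hochberg is available via
  `adjust = "BH"`.
* **Tissue specificity** is not a published definition; the toolkit's
  convention is: significantly up, detected in ≥ ⌈n/2⌉ arrays of the
  called tissue, detected in 0 arrays of the other. Outputs label the
  rule in their provenance header.

When several probes map to one gene, the probe with the largest
|log2 ratio| represents the gene — a documented convention, applied by
the caller since probe→gene maps are design-table specific.

## Enrichment reporting

`enrich()` performs a one-sided Fisher exact test per term
(hypergeometric upper tail via `phyper`, verified in tests against
explicit enumeration) and reports count, cluster percentage and p-value
per row. Percentages are rounded *half-up* to 2 decimals because that is
how such tables are conventionally printed (base R's `round` is
half-even and disagrees on ties). The hosted annotation services often
used for such tables apply a modified Fisher variant and
version-dependent backgrounds, so external p-values are comparable only
in rank; the count/percentage arithmetic, however, is exactly
reproducible, and the acceptance checks exercise it at published
cluster sizes (3138, 438, 3845). One published table block labels a
438-gene cluster where the accompanying text says 463 root-specific
genes; `enrich()` computes against whatever cluster size the caller
supplies, so both readings can be checked.

## qPCR concordance

`delta_delta_ct()` implements 2^−ΔΔCt with replicate-mean Cts:
ΔCt = mean Ct(target) − mean Ct(reference) per tissue, ΔΔCt = ΔCt_A −
ΔCt_B, returned as log2 fold = −ΔΔCt. Amplification-efficiency
correction and standard curves are out of scope. `concordance()` gives
Pearson r and the t-transform p on n − 2 df; it refuses fewer than 3
pairs or a zero-variance column. The bundled 66-gene validation table
(`qpcr_validation_pairs()`) stores log2 ratios printed to 2 decimals,
so the recomputed r (0.9467) is expected to sit within ±0.01 of the
value computed from unrounded instrument data.

## Synthetic data: what it emulates, and what it does not

`simulate_genomes()` mutates ancestor genes independently into two
genomes (default divergence 1% per copy, a realistic order for the two
rice subspecies' diverged regions), then duplicates a fraction of genes
verbatim within one genome and deletes a fraction from one genome,
alternating which genome is affected so that both single-genome groups
(B and C) and both asymmetric multi-hit groups (D and E) arise. Applying
divergence before duplication makes paralogs identical — a deliberate
simplification that guarantees multi-hit status at any identity
threshold, at the cost of not modeling paralog divergence. Genes sit on
one contig per genome with random 100-nt spacers.

`simulate_arrays()` draws per-probe baseline log2 intensity from
Normal(10, 1.5), plants ±`effect_log2` shifts in tissue A on a
`de_fraction` of probes, adds Normal(0, `noise_sd`) per replicate on the
log2 scale, and reports foreground = 2^(log2 value) + background with
background ~ Normal(100, 10) truncated at 0 and all flags good.
Foreground *includes* the background draw — that is what a scanner
reports — so background subtraction in the analysis recovers the
simulated signal without bias. Defaults (5 arrays per tissue, effect
2.0 log2 units, noise 0.3, 10% planted DE) mirror the two-tissue,
five-replicate validation design the toolkit targets; at these settings
planted effects are recovered at ≥ 90% with the null type-I proportion
near 0.05, and those two rates are what the acceptance run reports.

The simulator does **not** emulate: realistic base composition or codon
structure, scanner saturation, spatial artifacts, bad/empty flags, or
probe-sequence-dependent intensity. Passing tests on synthetic data
therefore demonstrate the correctness of the computations, not the
platform's behavior on real hybridizations.

## Problem sizes and runtime choices

The shipped checks use sizes chosen to exercise every code path while
staying desk-scale: 2,000 probes × 10 arrays for the expression
end-to-end run, a 50-kb genome × 100 probes for matcher/brute-force
equivalence, 60 genes for genome-truth classification, and 10,000
random 60-mers for the filter-order property. The published
platform-scale figures (21,179 probes; 20,806 and 13,683 genes covered;
thousands of DE genes; replicate correlations ≥ 0.983) depend on the
original genome databases and deposited raw data and are context, not
reproduction targets, for this package.

## Known limitations

* The matcher is ungapped; indel-containing cross-hybridization is
  invisible to it (and to the identity-count acceptance rule).
* The seed stage can miss borderline hits at default parameters; exact
  mode exists but is slower.
* The Welch-on-log2 model treats replicate noise as Gaussian per probe;
  heavy-tailed spot artifacts are not down-weighted.
* Tissue-specificity and detection rules are toolkit conventions,
  clearly labeled, not community standards.
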