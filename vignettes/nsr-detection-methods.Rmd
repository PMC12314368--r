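---
title: "Calling non-syntenic regions between haplotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling non-syntenic regions between haplotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nsrscan)
```

## The problem

A haplotype-phased diploid assembly gives two complete copies of every
chromosome from one individual. Most of their length is collinear: the same
genes in the same order, with coding divergence at the heterozygosity scale
(Ka < 0.02, Ks < 0.05). Interspersed are multi-hundred-kb tracts where
collinearity collapses — copy numbers differ between haplotypes, gene order
is scrambled, tandem duplicates and transposons pile up, and divergence
between copies is an order of magnitude higher (Ks approaching 0.3–0.35).
`nsrscan` calls these tracts — non-syntenic regions, nSRs — from gene
annotations, protein homology and coding sequences, and quantifies what
distinguishes them: single-copy-ortholog depletion, transposon and domain
enrichment, tandem-duplicate content, and loss of expression correlation
between homologous copies.

## The statistic

A gene pair is *homologous* when it satisfies two conditions jointly:

1. **Order conservation** — the pair is an anchor of a collinear block.
   Blocks are chains of anchors, strictly monotone in rank on both
   scaffolds (increasing, or decreasing for inversions), with consecutive
   rank gaps of at most `max_gaps = 25`, scored
   `m * match_score + gap_penalty * (skipped ranks)` with
   `match_score = 50`, `gap_penalty = -1`, at least `match_size = 10`
   anchors, block E-value at most `1e-5`.
2. **Low divergence** — NG86 Ks of the codon-aligned pair is strictly
   below 0.3.

Windows of 500 kb, stepped every 100 kb, are then labelled: a window
holding **more than 14 genes** (i.e. at least 15) of which **strictly less
than 15%** are homologous is non-syntenic; flagged windows are unioned into
disjoint nSR intervals. Both inequalities follow the published rule
verbatim; the boundary cases (exactly 14 genes; exactly 15%) are syntenic.

Tunable parameters, with units and defaults:

| parameter | default | meaning |
|---|---|---|
| `window`, `step` | 500,000 / 100,000 bp | scan geometry |
| `min_genes` | 15 | genes required before a window can be judged |
| `max_homolog_frac` | 0.15 | strict upper bound for the nSR label |
| `kaks_threshold`, `kaks_metric` | 0.3, `"ks"` | homolog divergence rule |
| `collinear_params()` | MCScanX set | chaining parameters |
| `max_hits_per_query` | 5 | hit-table pre-filter |

## Numerical and convention choices

* **Coordinates** are 0-based half-open everywhere internally; GFF3 and
  RepeatMasker (1-based inclusive) are converted at the file boundary
  only. A gene belongs to a window (or an nSR) iff its midpoint
  `(start + end) %/% 2` lies inside the half-open interval; a midpoint
  exactly at an interval end is outside. Midpoint assignment keeps every
  gene in a bounded number of windows and is unambiguous at boundaries.
* **Window tails**: window starts run 0, step, … while `start + window <=
  L`, plus one extra right-aligned window `[L - window, L)` so chromosome
  ends are evaluable; it is flagged `is_tail` in the output. Scaffolds
  shorter than one window become a single flagged whole-scaffold window.
  Zero-gene windows are `undetermined` and never contribute nSR span.
* **One representative isoform per gene** (largest summed CDS, ties by
  transcript ID) — isoform handling is not specified upstream; one-per-gene
  keeps ranks well defined.
* **NG86**: site counts are per-codon fractions of synonymous single-base
  changes (changes to stops count as nonsynonymous, so S + N = 3 × codons
  exactly); multiply substituted codons average over all minimal pathways,
  excluding pathways through stop codons unless all are blocked; p ≥ 3/4
  is flagged *saturated* (Ks/Ka undefined, never homologous) rather than
  an error. The estimator was fixed to NG86 + Jukes–Cantor because the
  upstream description names only a wrapper script, not a method; NG86 is
  what that wrapper family computes and is fully testable against
  enumeration.
* **The 0.3 cutoff** is applied to Ks by default. The published phrase
  ("KaKs value below 0.3") does not say whether Ks, Ka or the ratio is
  meant; between-haplotype orthologs show Ks < 0.05 while diverged
  paralogs show Ks ≈ 0.35, so Ks < 0.3 is the reading that separates the
  two populations. All three metrics are selectable (`kaks_metric`).
* **Protein alignment** uses Needleman–Wunsch via
  `Biostrings::pairwiseAlignment` (BLOSUM62, gap open 10, extend 1) —
  standard practice; tie-breaking among co-optimal traces follows
  Biostrings' deterministic traceback.
* **Block E-value**: MCScanX's exact formula is not published; we use a
  Poisson model — the upper tail of the expected anchor count in the
  block's rank rectangle under uniform scatter, divided by m! (the
  probability that m uniformly placed anchors are jointly monotone). It is
  monotone decreasing in anchor count, validated against Monte-Carlo
  permutation, and swappable: native `.collinearity` files can be imported
  bit-for-bit (`read_mcscanx_collinearity`).
* **Tandem collapse**: consecutive same-scaffold genes hitting one partner
  gene collapse to the best anchor before chaining, so tandem arrays do
  not simulate synteny. `overlap_window = 5` suppresses shadow blocks:
  anchors within 5 ranks (both axes) of an accepted block are removed.
* **Hypergeometric tails** are exact log-space sums over the support
  (`lchoose` + log-sum-exp); depletion uses the lower tail (SCOs),
  enrichment the upper (TEs, domains). Features carried by fewer than 5
  items are not tested; the tested universe is a caller decision — the
  pipeline tests TE families against a universe of gene models plus TE
  copies. BH adjustment is the step-up rule, validated against
  `p.adjust`.
* **Ref/Alt assignment** applies rules in order: (i) only one scaffold
  telomere-capped at both ends → it is Ref; (ii) both capped → fewer gaps;
  (iii) otherwise → fewer gaps; an exact tie goes to the longer scaffold
  (recorded as `tiebreak` — no published rule exists for ties). Telomere
  detection merges exact TTAGGG/CCCTAA matches separated by ≤ 2 motif
  lengths, requiring ≥ 25 copies and ≤ 10% of array bases outside exact
  copies, with a 10 kb end window; thresholds are exposed because no
  detection thresholds are published (arrays up to ~20 kb are reported).

## The simulator: a stated world

`simulate_nahr_dataset()` is a gene-resolution forward model of the
duplication mechanism: transposon copies in intergenic spacers misalign
between haplotypes; unequal crossing over between two copies of one family
duplicates the TE-bounded tract tandemly in one haplotype and deletes the
homologous loci in the other. Recurrent events concentrate in hotspot
tracts, both because eligibility is restricted to them and because
duplicated tracts carry their TEs along, supplying new substrates.

Defaults (the world every recovery test runs in):

* 2 scaffolds × 1,000 genes (~4 Mb each; CDS 240–720 bp of random sense
  codons, intergenic spacers 2–5 kb) — about 2,000 genes total.
* 3 hotspots covering 30% of the gene space (~200 genes ≈ 0.8–1 Mb each),
  placed in the inner 12–88% of each scaffold, matching the observation
  that nSRs sit away from chromosome ends.
* 150 unequal-crossover events, round-robin over hotspots (50 each), tract
  sizes 3–15 genes, gaining haplotype random per event. The event count
  comes from a coverage argument made before any testing: a hotspot locus
  escapes all events with probability ≈ exp(−E·L/H) (E events of mean
  tract L over H genes); 50 × 9 / 200 ≈ 2.25 leaves ~10% of loci
  untouched, which is what drives window homolog fractions below the 15%
  bound throughout the tract.
* Substitution rates per branch: synonymous 0.01 / nonsynonymous 0.004 for
  untouched orthologs, 0.15 / 0.05 for event-affected genes, so pair-level
  targets are Ks ≈ 0.02 / 0.30 and Ka ≈ 0.008 / 0.10 — the published
  divergence scales for syntenic orthologs and nSR paralogs. Mutations are
  codon-aware single-base events (Poisson counts proportional to NG86 site
  counts), never creating stops; `kaks_targets()` returns the implied
  pair-level expectations.
* Expression: 7 developmental stages (egg → adult); conserved ortholog
  pairs share a log-normal latent profile with multiplicative noise
  (SD 0.25 on the log scale); event-affected copies draw independent
  profiles, the strong form of the observed decorrelation (a configurable
  intermediate is deliberately omitted — one stated world).
* Telomere arrays (50 × TTAGGG) at both scaffold ends and 1–12 N-gaps per
  scaffold, so the QC/assignment stage is exercised by the same datasets.

Ground truth: one tract per (haplotype, hotspot) — the span from the first
to the last event-affected gene of that hotspot. An important consequence
of the mechanism: one event makes copies of a lineage *mutually exclusive*
between haplotypes (duplicated in one, deleted in the other), so paralog
pairs for divergence and expression contrasts are predominantly
within-haplotype tandem copies; the pipeline therefore contrasts all hit
pairs by region, not only cross-haplotype block anchors.

**What a green test does and does not establish.** The simulator emulates
gene order, copy number, TE placement, coding divergence and expression
correlation — the quantities the pipeline consumes. It does not emulate
real intergenic sequence composition (spacers are uniform random DNA, TEs
are synthetic labelled motifs, not Repbase sequences), alignment noise in
the hit table (hits are derived from true lineage identity), isoform
structure, or assembly error. Recovery results therefore validate the
statistics and their implementation, not upstream annotation or alignment
tools.

## Validation layout

Every operation has an independent oracle in the test suite: NG86 against
a from-scratch pathway-enumeration oracle on all 61 × 61 codon pairs and
random two-codon alignments (≤ 1e−9); hypergeometric tails against
exhaustive subset enumeration for N ≤ 12; the chaining DP against
exhaustive search on ≤ 25-anchor instances (both orientations); TDG
detection against an O(n²) scan; orthogroup fallback against graph
components; interval logic against per-base lookups. End-to-end, the
default simulated world must be recovered: every truth tract with
per-tract Jaccard ≥ 0.7 under default thresholds, background homolog
fraction ≥ 0.9, divergence targets within ±30% at n ≥ 200 pairs, TE
enrichment q < 0.05 inside called nSRs, a zero-event control reporting
0.0% nSR, and byte-identical outputs under one seed. Determinism-style
controls (zero-event, byte-identity) run at reduced genome size in the
suite — the properties are scale-free — while the recovery runs use the
full default world.

## Known limitations

* The chaining is pairwise (two scaffolds); k-way synteny and
  inter-chromosomal translocations are out of scope.
* Greedy best-first block extraction can, in principle, let a short
  high-score chain consume anchors of a longer overlapping chain; on
  realistic anchor sets the effect is suppressed by the match_size floor
  and was never observed in the oracle comparisons.
* The block E-value is an approximation of an unpublished formula; users
  reproducing a native MCScanX run exactly should import its
  `.collinearity` output instead.
* NG86 assumes equal base frequencies and no transition/transversion bias;
  codon-model estimators (GY94) are out of scope by design.
* Simulated paralog divergence is homogeneous within a tract; real nSRs
  mix copies of different ages.
* The SSTDG copy-number pattern is fixed to 1:1 vs 2:2 across haplotypes
  (the published definition); higher-order expansions are reported only
  through TDG pairs. Whether the published orthogroup count requires
  tandem arrangement as part of the definition or as a separate annotation
  is ambiguous; both the copy-number candidates and the tandem subset are
  returned (`call_sstdg()`'s `tandem` column).
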