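# nsrscan

Detection of **non-syntenic regions (nSRs)** between the two haplotypes of a
phased diploid genome assembly — or between two closely related genomes —
from gene order and coding-sequence divergence.

Haplotype-phased, telomere-to-telomere assemblies (e.g. of reef-building
corals) reveal large tracts, hundreds of kb each, where the two haplotypes
of one individual stop being collinear: gene copy numbers differ, order is
scrambled, tandem duplicates and transposons accumulate, and coding
divergence is far above the genome-wide background. `nsrscan` implements
the complete analysis used to characterize such regions, plus a forward
simulator of the mechanism thought to create them (transposon-mediated
unequal crossing over / NAHR), so every stage can be validated on data with
known ground truth.

## What it computes

1. **Collinear blocks** (MCScanX-style): protein hits are mapped to
   gene-rank anchors and chained by a dynamic program under the standard
   parameter set (match_score 50, gap_penalty −1, match_size 10, max_gaps
   25, overlap_window 5, E-value ≤ 1e−5). Native MCScanX `.collinearity`
   output can be imported instead.
2. **Ka/Ks** by Nei–Gojobori (1986) on protein-guided codon alignments:
   fractional site counts (S + N = 3 × codons exactly), all-minimal-pathway
   averaging at multiply substituted codons, Jukes–Cantor correction.
   A gene pair is *homologous* when it sits in a collinear block **and**
   its divergence is below the cutoff (default Ks < 0.3).
3. **nSR calling**: sliding windows (500 kb window, 100 kb step); a window
   with more than 14 genes of which fewer than 15% are homologous is
   non-syntenic; flagged windows are merged into disjoint intervals and
   summarized per scaffold and genome-wide.
4. **Tandem duplications**: TDG pairs (same orthogroup, adjacent or
   separated by one unrelated gene) and species-specific tandem duplicates
   (SSTDGs: one species 1 copy per haplotype, the other 2 per haplotype,
   tandem in at least one haplotype).
5. **Enrichment/depletion** of features (TE families, Pfam domains, SCO
   sets) inside nSRs: exact hypergeometric tails summed in log space,
   Benjamini–Hochberg adjustment.
6. **Expression contrasts**: Pearson *r* of developmental stage profiles
   between homologous gene pairs, compared between nSRs and syntenic
   regions.
7. **Assembly QC**: telomere-array detection (TTAGGG / CCCTAA), assembly
   gap runs, and Ref/Alt haplotype assignment by the three-rule scheme
   (telomeres at both ends → fewer gaps → longer scaffold).
8. **NAHR simulator**: a gene-resolution forward model in which TE-bounded
   tracts are tandemly duplicated in one haplotype and deleted in the
   other, recurrently inside hotspot regions; emits GFF3, FASTA, BLAST
   tabular hits, RepeatMasker-style repeats, orthogroups, expression
   matrices, and the ground-truth tract BED.

All internal coordinates are 0-based half-open; conversion happens only at
file boundaries.

## Worked example

Simulate a one-scaffold haplotype pair (250 ancestral genes, one ~750 kb
hotspot, 30 unequal-crossover events), write it to disk, and run the whole
pipeline:

```r
library(nsrscan)

cfg <- sim_config(seed = 42, n_scaffolds = 1, genes_per_scaffold = 250,
                  n_te_insertions = 150, n_hotspots = 1,
                  hotspot_fraction = 0.3, n_nahr_events = 30)
sim <- simulate_nahr_dataset(cfg)
emit_dataset(sim, "readme_ds")
res <- run_pipeline(pipeline_config("readme_ds", "readme_out"))

sim$truth                                   # ground-truth tracts
#>    scaffold_id  start    end
#> 1:       A_s01 130458 917450
#> 2:       B_s01 130094 761160
res$nsr                                     # called nSRs
#>    scaffold_id start   end
#> 1:       A_s01 1e+05 9e+05
#> 2:       B_s01 1e+05 8e+05
interval_jaccard(sim$truth, res$nsr)        # per-tract recovery
#> [1] 0.94 0.90
mean(res$kaks$Ks[res$kaks$is_homologous])   # ortholog divergence
#> [1] 0.0205
res$expression$means
#>    region      mean_r n_pairs n_undefined
#> 1:     SR 0.926           167           0
#> 2:    nSR 0.008           918           0
head(res$enrichment[feature != "gene_model"], 3)
#>     feature   k   n    K    N        p        q  tail
#> 1:      hAT 123 125 1038 1423 1.21e-15 9.71e-15 upper
#> 2:      BEL 140 145 1038 1423 5.45e-15 2.18e-14 upper
#> 3: Maverick  98  99 1038 1423 2.98e-13 7.94e-13 upper
```

Reading the output: the two simulated hotspot tracts are recovered at
window resolution (Jaccard 0.94 / 0.90); ortholog pairs retained in
collinear blocks show the configured background divergence (mean Ks ≈
0.02, i.e. 2 × the per-branch rate of 0.01); expression profiles of
homologous pairs are strongly correlated in syntenic regions (mean *r* =
0.93) but uncorrelated for the duplicated copies inside nSRs (mean *r* ≈
0.01); and every synthetic TE family is enriched inside the called nSRs
(upper-tail *q* ≪ 0.05), reflecting the hotspot-biased insertions.

The same stages are available as a CLI:

```sh
Rscript -e 'nsrscan::nsr_cli()' simulate --seed 42 --outdir data/
Rscript -e 'nsrscan::nsr_cli()' run-all --input-dir data/ --outdir reports/
```

## Vignette

`vignettes/nsr-detection-methods.Rmd` documents the models, parameter
choices, simulator assumptions, numerical decisions and limitations.
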