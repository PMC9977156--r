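# homeoscan

Homeobox gene discovery and cluster-architecture analysis for genome
assemblies, aimed at the kind of question chromosome-level lepidopteran
genomes raise: where are all the homeodomain-bearing loci, which gene
family is each one, how is the Hox cluster laid out (the *ro*-next-to-*pb*
arrangement, the displaced *lab*, the *ShxA*–*ShxD* block between *pb* and
*zen*), how large are the tandem Shx expansions, and is the Shx region
enriched for transposable elements relative to the rest of the cluster?

The pipeline is the classic translated-search workflow made reproducible
and testable end to end:

1. **Scan** — each reference homeodomain is aligned against all six
   reading frames of every contig (Smith–Waterman, BLOSUM62, affine gaps
   11/1, exact 4-mer seeds gating the DP). Hits are kept at
   E ≤ 10⁻⁵ with E-values from the Karlin–Altschul formula
   (λ = 0.267, K = 0.041, search space = genome length × query length).
   Overlapping hits merge into loci (representative = longest match); a
   second pass re-aligns ±1 kb flanks at E ≤ 10⁻³ to catch weak tandem
   neighbours.
2. **Classify** — reciprocal best match against the reference set; a locus
   is assigned to a family only when the reverse best hit agrees with the
   forward family *and* reverse identity exceeds 70% (strict); everything
   else is exported as divergent for external phylogenetics.
3. **Cluster** — Hox, NK and *hbn*–*Rx*–*otp* architectures: member order
   and orientation, span, intergenic distances, Shx copy counts and tandem
   arrays, and rearrangements as adjacency-set differences against the
   canonical orders.
4. **Enrich** — per-TE-class (LINE/SINE/LTR/DNA) densities in 5-kb windows
   across the cluster; Shx-region windows vs the rest compared by Wilcoxon
   rank-sum (exact when the pooled sample is ≤20 and tie-free) with
   Bonferroni correction over the four classes and a direction gate.
5. **Rates** — pairwise homeodomain identity contrasts between a focal
   clade and the background per family.

A seeded synthetic-genome generator (`sim_config()` / `simulate_genome()`)
plants all of these signals with ground-truth GFF3/BED, so the whole
pipeline is verifiable at desk scale.

## Worked example

Simulate a moth-like genome with a 25-copy tandem *ShxA* expansion,
LINE/CR1 elements interleaved between the copies, and 3× LINE density in
the Shx region; then run the pipeline:

```r
library(homeoscan)
cfg <- sim_config(seed = 1, lab_offset = 5e5, margin = 3e4,
                  shx_copies = c(ShxA = 25), line_period = 6000,
                  shx_repeat_multiplier = c(LINE = 3, SINE = 1, LTR = 1,
                                            DNA = 1))
sim  <- simulate_genome(cfg)
res  <- find_homeobox_loci(sim$genome, sim$refset)
cl   <- classify_loci(res$loci, sim$refset)
arch <- build_cluster(cl, "HOX")
print(arch)
#> HOX cluster on chr_hox : 38 members, span 1019485 bp, 1 external
#> ro - pb - ShxA - ShxA - ... - ShxA - ShxB - ShxC - ShxD - zen - Dfd -
#> Scr - Antp - ftz - Ubx - abd-A - Abd-B
shx_copy_table(arch)
#> Shx copies: ShxA=25 ShxB=1 ShxC=1 ShxD=1
#> Tandem arrays:
#>  family  n  start    end
#>    ShxA 25 288736 437236
paths   <- write_synthetic_genome(sim, tempdir())
rep_ann <- load_repeats(paths[["truth_repeats"]])
shx_enrichment(rep_ann, arch)
#> Shx-region TE enrichment ( 64 Shx vs 140 rest windows )
#>  te_class n_shx n_rest median_shx median_rest    U     p_raw p_bonferroni enriched
#>      LINE    64    140     0.0827      0.0357 6470 2.725e-07    1.090e-06     TRUE
#>      SINE    64    140     0.0000      0.0000 3918 9.551e-02    3.821e-01    FALSE
#>       LTR    64    140     0.0000      0.0000 4267 5.453e-01    1.000e+00    FALSE
#>       DNA    64    140     0.0000      0.0000 4336 6.737e-01    1.000e+00    FALSE
```

All 39 planted genes (the 14-member cluster plus the expansion and the
external *lab*) are recovered and classified; the LINE excess in the Shx
region is called enriched, the other classes are not, and the Bonferroni
column is the raw p × 4 capped at 1. The same run is available stage by
stage from the shell via `inst/cli/homeoscan`
(`simulate`, `scan`, `classify`, `cluster`, `enrich`, `rates`, `all`,
`report`), each stage writing TSV/GFF3/BED outputs plus a JSON manifest of
its inputs and thresholds.

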