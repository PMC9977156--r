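---
title: "Homeobox discovery, cluster architecture, and Shx-region repeat enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeobox discovery, cluster architecture, and Shx-region repeat enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoscan)
```

## The problem

Homeobox genes encode transcription factors whose ~60-residue homeodomain
is conserved enough to be found in raw genome assemblies by translated
similarity search, yet divergent enough across families that classification
needs care. In Lepidoptera the Hox cluster has a distinctive layout: the
non-Hox ANTP-class gene *ro* sits next to *pb* (where *lab* sits in other
insects), *lab* itself is relocated several megabases beyond *Abd-B*, and
four lineage-specific *zen*-derived "special homeobox" genes (*ShxA*-*ShxD*)
lie between *pb* and *zen*. Some moth lineages carry dramatic tandem
expansions of Shx genes, and those expansions co-occur with locally elevated
LINE retrotransposon density — the hypothesis being that LINE-mediated
nonallelic homologous recombination drives the duplications.

`homeoscan` reimplements this discovery-and-description workflow as a
testable pipeline: translated homeodomain scan, reciprocal family
classification, cluster-architecture reconstruction, tandem-array census,
windowed TE-density enrichment, and clade identity contrasts. A seeded
synthetic-genome generator plants all of these signals with known ground
truth, so every stage can be validated end to end without downloading real
assemblies.

## The scan model

Candidate loci are found by aligning every reference homeodomain against
all six reading frames of each contig, emulating a TBLASTN search:

* **Translation.** Six frames under the standard genetic code; codons
  containing `N` translate to `X`, stops to `*`. Each frame keeps an exact
  coordinate map back to forward-strand base positions.
* **Alignment.** Smith–Waterman local alignment under BLOSUM62 with affine
  gaps (open 11, extend 1, a gap of length $L$ costing $11 + L$). The DP
  core is compiled; the test suite checks it against a brute-force
  enumeration oracle and an independent implementation.
* **Seeding.** Full DP is gated by exact 4-mer amino-acid seed matches, with
  a switch (`exhaustive = TRUE`) forcing full DP for validation. A 4-mer is
  a conservative seed for a 60-residue query: even at 20% divergence, runs
  of four unmutated residues are essentially guaranteed.
* **Statistics.** E-values come from the Karlin–Altschul formula with fixed
  gapped-BLOSUM62 constants ($\lambda = 0.267$, $K = 0.041$) and search
  space = total genome length × query length. The reporting threshold is
  $E \le 10^{-5}$, applied as a rank cutoff on the raw score. The constants
  are fixed rather than fitted; the absolute E-values therefore carry the
  usual caveat, but the threshold behaves as intended: planted domains at
  ≤20% divergence score far above it and seeded random sequence never
  reaches it at these genome sizes.

Overlapping hits (≥1 bp, either strand — two-strand overlaps represent one
locus) merge by transitive closure into loci; the representative hit is the
longest aligned span, ties broken by score then query id, making the merge
deterministic and idempotent. A second round re-aligns the reference
against each locus ± 1 kb at a permissive threshold ($E \le 10^{-3}$),
recovering weak tandem neighbours; newly found non-overlapping hits enter a
second merge.

## Classification

Each locus's translated sequence is aligned back against the whole
reference set (the reciprocal search). Assignment requires (i) the best
reverse hit's family to equal the forward query's family and (ii) reverse
identity strictly above 70%, computed over non-gap columns of the reverse
alignment. Everything else is retained as `DIVERGENT_UNCLASSIFIED` and
exported to FASTA for external phylogenetic placement, which is out of
scope here. Two deliberate choices:

* Reciprocity is defined at the *family* level, not the sequence level,
  because the reference holds several species per family; this is the
  weaker and more robust criterion.
* The threshold is strict: a locus at exactly 70.0% stays divergent.

The census counts loci — functional genes, partials and pseudogenes alike —
per family and class, with Shx and zen/Shx totals.

## Cluster architecture

Cluster membership is family identity plus the modal contig (the contig
holding most member loci); no distance gating is imposed, since real
lepidopteran Hox clusters span up to several megabases. For the Hox cluster
the members are the 13 in-cluster Hox/Hox-derived families plus *ro*; *lab*
is reported externally unless it falls inside the cluster interval, and the
span always excludes *lab*. Rearrangement detection collapses each
multi-copy family to one block (anchored at the copy nearest a canonical
neighbour), restricts the canonical order to the families present, and
reports the adjacency-set difference, orientation flips against the
majority strand, and translocated families. No minimal inversion scenario
is computed. The Shx region is strictly the first-to-last Shx coordinate;
where Shx copies interleave with *zen* this is the inclusive envelope.

## Repeat enrichment

Repeat annotations load from BED or RepeatMasker `.out`; the TE class is
the class/family prefix before `/`, and elements under 50 bp are dropped at
load. Densities are merged-coverage fractions in non-overlapping 5-kb
windows tiled from the cluster's *ro*-side edge (the anchoring choice is
exposed since nothing forces it); a terminal window survives only at ≥ half
width, with its actual width as denominator. For each of LINE, SINE, LTR
and DNA, windows inside the Shx region are compared to the remaining
cluster (which already excludes *lab*) with a two-sided Wilcoxon rank-sum
test: exact by full enumeration when the pooled count is ≤20 and tie-free,
otherwise normal approximation with tie and continuity corrections.
Bonferroni multiplicity is $m = 4$ — the four classes within one species,
not across species — and an enriched call additionally requires the Shx
median to exceed the rest median, since the claim of interest is an
*increase*. Density is fraction-of-bases, not element counts.

## Identity contrasts

For one gene family, every focal-clade-vs-background pairwise identity is
compared against every background-vs-background pairwise identity
(two-sided rank-sum, configurable). Identity is counted over columns where
both sequences are non-gap. The alignment is taken as input; for nominal
60-residue homeodomains a gapless equal-length "aligner" ships for
fixtures, and internal MSA construction is out of scope. Because the pair
sets share species, the test's units are dependent; the generator-based
calibration below shows the realized false-positive rate stays near the
nominal level for this design (5 focal, 8 background, weak within-group
noise), which is the regime the analysis uses.

## The synthetic-genome generator

The generator is first-class, tested code; its defaults are the study
conditions the analyses assume:

* background bases i.i.d. at GC 0.37, a typical lepidopteran composition;
* the canonical 14-gene cluster order (*ro*, *pb*, ShxA-D, *zen*, *Dfd*,
  *Scr*, *Antp*, *ftz*, *Ubx*, *abd-A*, *Abd-B*) with lognormal intergenic
  gaps (median 50 kb, `sdlog` 1, floor 2 kb), sized so the realized span is
  of order 1.2 Mb;
* *lab* planted 7 Mb beyond *Abd-B* by default;
* tandem Shx arrays of configurable copy number with intra-array gaps
  (median 5 kb) or, when `line_period` is set, fixed spacing with one
  same-orientation LINE/CR1 element centred between consecutive copies;
* planted homeodomains are reference sequences mutated at the amino-acid
  level (exactly `round(fraction × 60)` substitutions) and
  reverse-translated with synonymous codon choice weighted toward the
  target GC;
* interspersed repeats per class as a homogeneous Poisson process
  (element lengths uniform 80–400 bp) at configurable coverage, with an
  optional Shx-region density multiplier;
* optional NK and *hbn*–*Rx*–*otp* clusters on their own contigs, the trio
  gaps sized to a ~348 kb span.

What it does **not** emulate — and hence what passing tests do not show
about real data: multi-exon gene structure (planted homeodomains are
single-exon, so no splice-aware alignment is exercised), realistic
between-family homeodomain similarity (reference families are independent
random 60-mers, far better separated than real ANTP-class families, so
classification here is easier than on real genomes), assembly gaps and
repeats *as sequence* (repeat annotations are intervals; the underlying
bases stay random), and base-composition heterogeneity. Locus counts and
identity cutoff behaviour on real assemblies can therefore differ; the
pipeline's word size, matrix and gap costs are explicit stand-ins where the
original tool chain left them unstated.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GFF3 output converts to
  1-based closed, and every TSV declares its convention in a header
  comment.
* All tie-breaks (merge representative, reverse best hit) order by score
  then lexicographic id, so results are independent of input order.
* All generator randomness flows from one integer seed; identical
  configurations are byte-identical on disk.
* Degenerate inputs: an empty genome scans to an empty hit table with a
  warning; a cluster with no members builds an empty architecture with a
  warning; a rank-sum test on fully tied data reports $p = 1$; a window
  region shorter than half a window is an error.
* Stages couple through files (TSV/GFF3/BED/JSON manifest) so each is
  independently testable and resumable; the `homeoscan_cli()` dispatcher
  and the thin `inst/cli/homeoscan` Rscript wrap the same functions.

## Problem sizes used in the checks

The shipped verification uses synthetic genomes of 1–5 Mb: recovery runs
use a 1.6 Mb *lab* displacement (total ~2.5–4 Mb per genome, 20 seeds),
copy-number runs plant arrays of 4–51 copies, the architecture check runs
one genome at the full default 7 Mb displacement, and the calibration
studies use 120-window clusters (20 Shx vs 100 rest) with 300–1000
replicates and the 5-vs-8-species contrast design with 200–1000 seeds.
These sizes make the whole suite run in minutes while leaving every
statistical check at the operating point the analyses assume.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, shx_copies = c(ShxA = 25), line_period = 6000,
                  shx_repeat_multiplier = c(LINE = 3, SINE = 1, LTR = 1,
                                            DNA = 1))
sim <- simulate_genome(cfg)
res <- find_homeobox_loci(sim$genome, sim$refset)
cl  <- classify_loci(res$loci, sim$refset)
census(cl)
arch <- build_cluster(cl, "HOX")
shx_copy_table(arch)
rep_ann <- load_repeats(write_synthetic_genome(sim, tempdir())["truth_repeats"])
shx_enrichment(rep_ann, arch)
```

## Known limitations

Splice-aware alignment, HMM-based nucleotide search, de-novo repeat-library
construction, Hi-C/TAD analysis, tree inference for divergent loci, and
minimal rearrangement-scenario reconstruction are all out of scope;
divergent loci and rearrangement reports are exported in forms suitable for
those external analyses.
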