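# panclade

Genus-scale comparative genomics for bacterial genome collections:
delineate *genomic species*, characterise the pangenome, and reconstruct
gene gain/loss histories — with a synthetic-clade simulator that provides
complete ground truth for validating every stage.

## Who this is for

Microbial genomics researchers with a set of assemblies from one genus
(e.g., a few dozen to a few hundred RefSeq genomes of a gut commensal)
who want to answer: *how many species are actually in this collection,
how open is its pangenome, and which ancestors gained or lost which gene
families?*

## The methods at the core

**Genomic species delineation.** For every genome pair the package
computes three standard whole-genome relatedness metrics:

- **ANI** — average nucleotide identity over 1020-nt fragments mapped by
  shared 16-mers and aligned in a 64-column band; a fragment counts if it
  aligns at ≥ 30% identity over ≥ 70% of its length (the classical
  fragment-ANI definition), and the two directional means are averaged.
- **TETRA** — the Pearson correlation of tetranucleotide z-score
  signatures, where each 4-mer count *O(n₁n₂n₃n₄)* is compared against its
  maximal-order Markov expectation
  *E = O(n₁n₂n₃)·O(n₂n₃n₄)/O(n₂n₃)* with the matching variance term.
- **AAI** — mean amino-acid identity over reciprocal-best-hit protein
  pairs (5-mer seeding, banded BLOSUM62 alignment, 30% identity / 70%
  coverage).

Two genomes belong to the same genomic species iff **ANI > 95% and
TETRA > 0.99 and AAI > 95%** simultaneously (strict inequalities);
species are the connected components of that graph.  Pairs passing only
some criteria are reported as *gray zones*, and the share of pairs in the
sparsely populated ANI 83–95% *discontinuity zone* is computed.
Clusters are named by contained type-strain genomes, else by full-length
(> 1400 nt) 16S matches at ≥ 99% identity with ≥ 80% coverages, else as
"unknown group A, B, …".

**Pangenome.** Orthogroups come from deterministic greedy length-sorted
protein clustering (≥ 80% identity over ≥ 80% of the shorter sequence).
The occurrence matrix is partitioned into core (100% of genomes),
soft-core (≥ 95%), shell (≥ 15%) and cloud; rarefaction curves (pan,
core, new-genes) are medians over random genome orderings, and openness
is the power-law fit Δn(N) = κ·N^(−α) to the median new-genes curve —
**α < 1 means an open pangenome**.

**Phylogeny and gene flux.** Single-copy core families give a
length-weighted p-distance matrix, a neighbor-joining tree, and outgroup
rooting.  Ancestral gene content is reconstructed by **Wagner parsimony**
(two-state Sankoff dynamic programming with configurable gain/loss
penalties, equal by default; presence at the root is charged as one
gain), yielding per-branch counts of families gained and lost and the
family set of any last common ancestor.

## Worked example

Simulate a small clade (4 species × 2 strains plus an outgroup) and run
the whole pipeline:

```r
library(panclade)
cfg <- simulation_config(seed = 7, n_species = 4, strains_per_species = 2,
                         root_family_count = 60, include_outgroup = TRUE)
sim <- simulate_clade(cfg)
emit_dataset(sim$records, sim$truth, "demo_data")
run_pipeline(pipeline_config("demo_data/manifest.yaml", "demo_out", seed = 7))
```

or equivalently from a shell:

```sh
Rscript inst/scripts/run_panclade.R simulate --out demo_data --seed 7 \
    --species 4 --strains 2 --families 60 --outgroup
Rscript inst/scripts/run_panclade.R run --manifest demo_data/manifest.yaml \
    --out demo_out --seed 7
```

`demo_out/run_report.md` then contains (actual output):

```
5 clusters over 9 genomes

- C01: unknown group A (2 genomes, evidence: unnamed)
- C02: unknown group B (2 genomes, evidence: unnamed)
- C03: unknown group C (2 genomes, evidence: unnamed)
- C04: unknown group D (2 genomes, evidence: unnamed)
- C05: unknown group E (1 genomes, evidence: unnamed)

ANI discontinuity-zone fraction: 0.1111
gray-zone pairs: 4

families: 205 (core 5, soft-core 0, shell 142, cloud 58)
power-law fit: kappa = 335.3, alpha = 2.6894 -> closed pangenome
```

The four simulated species are recovered exactly (each strain pair forms
one cluster; the outgroup is its own singleton).  The small core and the
α > 1 reflect the tiny 9-genome sample and the deep outgroup: most
families shared with the outgroup have diverged below the 80% clustering
identity, so they no longer count as genus-wide core — append more
ingroup genomes and the openness classification flips.  Alongside the
report the run writes `metrics.tsv`, `clusters.tsv`, `gray_zones.tsv`,
`gene_content.Rtab`, `rarefaction.tsv`, `core_tree.nwk` and
`gain_loss_branches.tsv`.

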