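---
title: "Models and design choices in panclade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in panclade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

panclade implements a genus-scale comparative-genomics workflow: pairwise
genome relatedness metrics, genomic-species delineation, pangenome
structure and openness, a core-genome tree, and Wagner-parsimony
reconstruction of gene gain/loss histories.  This vignette explains the
models behind each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## Pairwise metrics

**ANI.** The established fragment definition: the query is cut into
consecutive 1020-nt fragments (a trailing piece of at least half a
fragment is kept), each fragment is placed on the subject by its
most-supported shared-16-mer diagonal and aligned in a banded
Needleman–Wunsch (band 64; match +1, mismatch −1, gap −2, free end
gaps), and retained when identity ≥ 30% over ≥ 70% of its length.  ANI
is the mean identity of retained fragments, averaged over both
directions, which makes it exactly symmetric.  Identity is always
matches/columns, so the scoring scheme only influences the alignment
path.  Two guards go beyond the bare definition: a placement requires at
least two seed hits on the winning diagonal *and* anchors spanning at
least a quarter of the fragment.  Without them, a single chance ~20-bp
repeat shared between unrelated sequences "maps" a fragment, and a
gapped +1/−1/−2 alignment of random DNA then scores ≈ 50% identity —
formally above the 30% retention bound.  Aligner-based ANI tools impose
the same requirement implicitly through their seeding statistics.
Undefined ANI (no retained fragment in one direction) is reported as "no
homology" and fails every threshold test — conservative for species
grouping.

**TETRA.** Counts of all 2-, 3- and 4-mers are taken over every contig
and its reverse complement; windows never cross contig ends and windows
containing `N` are skipped.  Each 4-mer count is standardised against
its maximal-order Markov expectation
$E(n_1n_2n_3n_4) = O(n_1n_2n_3)\,O(n_2n_3n_4)/O(n_2n_3)$ with variance
$V = E\,(O(n_2n_3)-O(n_1n_2n_3))(O(n_2n_3)-O(n_2n_3n_4))/O(n_2n_3)^2$,
and $z = (O-E)/\sqrt V$ (zero wherever $V=0$).  TETRA is the Pearson
correlation of two 256-long z-score vectors.  Genomes under ~50 kb get a
warning: their z-scores are sampling noise.

**AAI.** Candidate homologs share at least one amino-acid 5-mer;
candidates far below the best-supported one in seed votes are skipped
(they essentially never win).  Alignments are banded affine BLOSUM62
(gap open 11, extend 1, free end gaps; band 48 plus the length
difference), a hit needs ≥ 30% identity over ≥ 70% of the shorter
sequence, and reciprocal best hits define orthologs.  AAI averages the
two directional identities over those pairs, again symmetric by
construction.

**16S identity.** Global alignment with free end gaps; identity is
matches over aligned columns (terminal overhangs excluded, internal gaps
counted), and each sequence's coverage is its aligned span over its
length.  Naming from 16S requires ≥ 99% identity, both coverages ≥ 80%,
and marker length > 1400 nt.

## Species delineation

An edge joins two genomes iff ANI > 95 **and** TETRA > 0.99 **and**
AAI > 95, with strict inequalities (pairs sitting exactly on a boundary
are excluded and flagged).  Genomic species are the connected components
of this graph.  Components are *not* forced to be cliques: near-threshold
intransitivity is real in such data, so member pairs failing the full
criterion are surfaced as `incomplete_pairs` rather than silently merged
or split, and inter-cluster pairs passing some criteria become the
gray-zone report.  The ANI discontinuity-zone statistic is the fraction
of all pairs with ANI in [83, 95].  Where metrics disagree no override
rule is applied — disagreements are reported, never resolved by fiat.
Unknown clusters are lettered in size-then-representative order purely
for determinism.

## Pangenome

Orthogroup clustering is deterministic greedy incremental clustering:
proteins sorted by length (descending, then ID — making the result
independent of input order), each joining the earliest-founded cluster
whose representative it matches at ≥ 80% identity over ≥ 80% of the
shorter sequence.  This is a deliberately simple, reproducible stand-in
for the synteny- and tree-aware production tools, which disagree with
each other substantially on real data anyway; the tests therefore
validate it against simulator ground truth (≥ 99% of presence/absence
cells correct under default divergences) rather than against any
specific external tool.

Categories: core is strictly 100% presence; soft-core ≥ 95%, shell
≥ 15%, cloud below — the conventional Roary-style cutoffs.  Rarefaction
draws random genome orderings and records cumulative pan/core/new
counts; the package default is 1000 permutations, and 200 is used in
tests and the acceptance script (the medians are stable well below
that).  Openness fits
$\log \Delta n(N) = \log\kappa - \alpha\log N$ by least squares over
$N \ge 2$ with positive medians — $\Delta n(1)$ is the first genome's
whole repertoire and does not belong to the decay law, and the log-log
linear fit is deterministic where a nonlinear fit would need starting
values.  The accessory-window statistic (families shared by 50–200
genomes out of 224) is rescaled proportionally for other dataset sizes.

## Core-genome tree

Single-copy core families (count exactly 1 in every genome) are aligned
pairwise per genome pair; distance is 1 − length-weighted mean identity.
These are p-distances — monotone in divergence at the simulated ranges
and parameter-free; no model correction is applied, and triangle
violations are tolerated.  Neighbor joining (with negative branch
lengths clamped to zero, the deficit shifted to the sister edge) and
outgroup rooting at the midpoint of the outgroup's pendant edge complete
the tree.  Maximum-likelihood inference, bootstrap and site-rate models
are out of scope: the gain/loss stage needs a rooted topology, not a
specific inference engine, and any externally built Newick tree is
accepted wherever a tree is needed.

## Gain/loss reconstruction

Per family, a two-state Sankoff dynamic program over the rooted tree
(absent→present costs the gain penalty, present→absent the loss penalty,
both 1 by default) with a root-first traceback.  Presence at the root is
charged one gain — the family's origination — which puts "early gain
plus later losses" and "independent later gains" on the same price
scale.  Cost ties are resolved toward absence, root first (DELTRAN-like,
delaying gains): deterministic and conservative about ancestral content;
the rule is configurable to prefer presence for sensitivity analysis.
One consequence is worth knowing: when a single true loss leaves a
family's remaining presence in two separate clades, the tie rule prices
two later gains equal to root-origination-plus-loss and picks the gains,
so in rare tie cases the reconstruction can contain one more branch
event than the generating history; the guaranteed invariant is that the
total reconstruction *cost* never exceeds the true history's cost.
Occurrence counts are binarized; duplications are not modelled.
Rate-based birth–death optimisation is a non-goal — the reconstruction
here is penalty-based parsimony.

## The synthetic clade generator

The generator produces the statistical structure the analysis assumes,
with complete ground truth:

- **Tree**: a pure-birth species tree of depth 0.2 substitutions/site
  (default), split times uniform on [0, depth − s/2] where *s* is the
  minimum inter-species separation (default 0.06; a nominal 0.05 would
  put the closest species pair exactly on the 95% ANI boundary after
  substitution saturation, so the default keeps every inter-species pair
  clearly below it).  Species tips expand into strain stars at pairwise
  divergence 0.01 (≈ 99% ANI).
- **Gene content**: the root carries `root_family_count` families
  (default 2000 ≈ a 1.8-Mb genome; tests use ~220 ≈ 200 kb to keep run
  times in minutes — the vignette states these sizes as the package's
  validation scale).  Per branch of length *t*, gains ~ Poisson(gain_rate
  · *t*) and losses ~ Poisson(loss_rate · *t*), defaults 150 and 100 per
  unit branch length, giving a realistic accessory fraction on default
  trees.  Gains draw globally unique IDs ("infinite genes", the open
  regime) or, optionally, IDs from a finite accessory pool (the closed
  regime used for openness testing).
- **Sequences**: genes are stop-free codon sequences whose base
  composition follows one clade-level order-3 Markov model (Dirichlet(1)
  transition rows).  This matters: i.i.d.-uniform sequences carry no
  genome-wide tetranucleotide signature, so even 99%-identical strains
  correlate only ~0.95 in TETRA, whereas real same-genus genomes share a
  strong signature — the very premise of the statistic.  Substitution is
  Jukes–Cantor per branch (change probability
  $\tfrac34(1-e^{-4t/3})$, uniform among the three other bases), with
  purifying selection emulated by codon-position structure: positions
  1–2 evolve slowly (rate 0.15), position 3 quickly (rate 3.7), and
  amino-acid-changing third-position mutations are accepted with
  probability 0.1.  The rates are normalised so accepted nucleotide
  divergence equals the branch length in the linear regime; without the
  selection step, deep within-genus orthologs drop below the 80% protein
  clustering identity, which real genus cores do not.  Proteins are
  direct translations, keeping ANI and AAI coherently coupled.  A
  1550-nt rRNA-like marker evolves at 0.05× the branch rate.  Leaf
  repertoires are concatenated into 1–10 contigs.
- **Determinism**: the entire dataset is a pure function of the
  configuration, including its seed.

What the generator does **not** emulate: intergenic DNA and operon
structure, insertions/deletions within genes, rate heterogeneity across
genes, horizontal transfer from outside the clade, assembly artifacts
and contamination.  Passing tests therefore demonstrate correctness of
the statistics and reconstructions under the assumed generative
structure — clean orthology, tree-like evolution, calibrated divergence
— not robustness to the full messiness of real assemblies.

## Degenerate inputs and numerical conventions

Genomes without a quality triple pass the filter with a warning
(complete genomes in practice never went through draft QC); completeness
is inclusive at 95, contamination/heterogeneity strict at 5.  Zero-variance
TETRA profiles are an error for the correlation (not a silent 0).
Undefined ANI/AAI propagate as missing-with-reason and always fail
thresholds.  The openness fit refuses fewer than three positive points.
Self-comparisons are exact identities (ANI = AAI = 100, TETRA = 1) and
are tested to 1e-9.  All internal coordinates are 0-based half-open;
output FASTA wraps at 80 columns; every tabular output carries a
`#`-prefixed header recording the package version and seed.

## Validation scale

The test suite validates species recovery on an 8-species × 3-strain
clade with ~200-kb genomes (all 276 pairs computed in a few minutes on
one CPU), gain/loss recovery on a 16-leaf clade with ~0.23 events per
family, openness classification in both generative regimes at 200
permutations, and the exact oracles (window enumeration for TETRA,
exhaustive labeling enumeration for Wagner parsimony) at small sizes
where brute force is feasible.
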