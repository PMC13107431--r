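---
title: "Structure-based phylogenetics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based phylogenetics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`strucphylo` infers phylogenies from protein structure models. This
vignette explains the statistical and geometric machinery, the tunable
parameters and their defaults, what the synthetic benchmark does and does
not emulate, and the design choices made where more than one reasonable
construction existed.

## Why structure, and what is being estimated

Deep viral lineages — RNA virus polymerases are the canonical case — have
diverged past the point where sequences align reliably, while the fold is
conserved. The estimand is the same as in sequence phylogenetics: a tree
over taxa. The data, however, are C-alpha traces, and the "characters"
are columns of structurally equivalent residues (the *common structural
core*) identified across all models.

## Quality control of predicted models

AlphaFold-style models carry a per-residue confidence (pLDDT, 0–100) in
the B-factor field. Low-confidence regions are not merely uncertain: they
are often modelled as arbitrary coils that would corrupt a structural
alignment. The QC chain applies three positional rules, in order:

* **Terminal trimming** (`trim_termini`): scan with a 15-residue window;
  keep the span from the first window whose residues are all strictly
  above pLDDT 70 through the last such window. Strictness matters at the
  boundary: a residue at exactly 70 does not qualify.
* **Rejection** (`qc_filter`): on the trimmed model, reject when the
  fraction of residues below pLDDT 50 exceeds 5%, or below 70 exceeds
  10%. "Exceeds" is strict, so a model at exactly 5%/10% passes.
* **Removal** (`drop_low_confidence`): delete residues strictly below
  pLDDT 50. Interior removals leave a gapped trace; the aligner is
  sequence-order independent, so gaps only shorten the chain.

Fractions are computed on the terminally trimmed model, matching the
order of operations of the screening procedure the rules encode. Models
shorter than the window are rejected outright (no qualifying window can
exist). Experimental structures without pLDDT (all-zero B-factors) are
assigned confidence 100, making QC a no-op for them.

`trim_to_region` restricts very large models to an annotated domain plus
a 200-residue margin on both sides; discovering the annotation itself is
out of scope — the indices are explicit arguments.

## Pairwise alignment and the similarity score

Two C-alpha traces are aligned purely in space (`align_pair`): gapless
12-residue fragment pairs, sampled on a stride of 8, are superposed by
the Kabsch algorithm; seeds with fragment RMSD below 2 Å are extended by
alternating greedy nearest-neighbour pairing (one-to-one, transformed
distance < 4.5 Å, ties broken by the lower index pair) with
re-superposition, to a fixed point (at most 50 iterations); the seed with
the highest final score wins. Because no step consults residue order,
circularly permuted chains — polymerases with swapped palm subdomains are
the motivating case — align correctly; the test suite exercises exactly
this invariance.

Each matched column contributes

```
score(col) = w_geo * exp(-d^2 / (2 * sigma_s^2)) + w_aa * aa_sim
```

with `d` the inter-C-alpha distance after superposition, `sigma_s = 2` Å,
`w_geo = 1`, `w_aa = 0.5`, and `aa_sim` a BLOSUM62 similarity rescaled
affinely to [0, 1]. This two-term surrogate keeps the geometry dominant
while letting residue identity break near-ties. Two properties are load
bearing:

* **Self-score dominance.** The self-score S(A,A) is the same formula on
  the identity correspondence (d = 0), which is the attainable maximum —
  BLOSUM62 is diagonally dominant, so `aa_sim(a,b) <=
  min(aa_sim(a,a), aa_sim(b,b))` — and therefore
  `S(A,B) <= min(S(A,A), S(B,B))`, which makes all downstream distances
  non-negative.
* **Column additivity.** The total score is the sum of per-column
  contributions, stored explicitly. Jackknife rescoring is then exact
  re-summation over sampled columns, not re-alignment.

The Gaussian geometric term saturates: beyond roughly `2 * sigma_s` the
contribution of a column is near zero regardless of how far the residues
are. Distances derived from the score are therefore close to additive
only while typical core deviations stay within ~2 Å, and compress at
higher divergence. This is a deliberate regime choice, not an accident:
the score rewards the conserved core rather than penalising the
divergent periphery linearly.

## Progressive core construction

`build_core` computes all pairwise alignments, then repeatedly merges the
two most similar groups. Group-to-group similarity is the mean of the
member pairwise alignment scores (computed once, over each pair's own
correspondence); ties break lexicographically on model id, making the
merge order deterministic. Merging intersects correspondences through the
highest-scoring cross pair of member models: a column survives only if
its residues are paired across the two groups. The result is a core in
which every column holds exactly one residue of every model and no
residue appears twice. An alternative — re-scoring groups over currently
shared columns after every merge — was considered and rejected: cross-group
shared columns are undefined before the merge, and a fixed linkage keeps
the agglomeration order independent of intersection side effects.

The final score matrix is computed over the core columns (self-scores
too, so the dominance invariant holds column-for-column), and the core's
`avg_rmsd` is the mean pairwise Kabsch RMSD on those columns. Models that
cannot align to anything (or whose merge would shrink the core below
`min_core_len = 30`) are excluded with a warning, or abort the run under
`strict = TRUE`.

## Distances, neighbor joining, and tree comparison

Distances follow `D(A,B) = min[S(A,A), S(B,B)] − S(A,B)`; a dominance
violation is an error naming the pair, and numerical noise below 1e-9 is
clipped to zero. Trees come from a canonical Saitou–Nei neighbor-joining
implementation with the Studier–Keppler Q-criterion, exact on additive
matrices (the suite verifies exact recovery of topologies and branch
lengths up to 8 taxa, against the four-point condition and an exhaustive
least-squares scan over all unrooted topologies for n ≤ 6). Negative
branch-length estimates are clamped to zero and the clamped deficit
reported — the behaviour of the widely used distance-tree tools this
module replaces.

Robinson–Foulds distances count non-trivial bipartitions present in
exactly one tree; normalization divides by the total number of
non-trivial bipartitions in the two trees (2(n−3) for two binary trees),
so multifurcating trees are penalized only for splits they actually
assert. `map_support` assigns each internal reference edge the rounded
percentage of replicate trees containing its bipartition; it is invariant
to replicate order and rooting. Outgroup rooting requires the outgroup to
be separable by a single edge and keeps supports attached to their
bipartitions by treating node labels as edge labels.

## The jackknife and its calibration

A replicate samples `round(fraction * core_len)` columns — either
independent uniform sites, or contiguous blocks. Block lengths are drawn
uniformly between `min_block = 10` and the remaining quota; if the final
remainder is smaller than `min_block`, one block of exactly that size is
placed so the sampled cardinality is always exact. Placement is uniform
over the legal non-overlapping positions; a dead-ended configuration is
restarted (up to 1000 attempts) before erroring with advice to lower the
fraction. Sampling the full core returns all columns directly. Each
replicate re-sums the stored column contributions, rebuilds distances and
the NJ tree; supports are then mapped onto the reference tree built from
the full core. All resampling derives replicate substreams from one run
seed, so runs are exactly reproducible.

The sampling fraction trades perturbation strength against replicate
informativeness. `fraction_sweep` measures mean normalized RF between
replicate and reference trees across fractions 0.1–0.9: RF falls steeply
at low fractions and flattens once replicates carry enough columns; the
first fraction whose change to the next is below `stable_tol = 0.02` is
reported (advisory only). The default analysis fraction is 0.5 with block
mode — blocks remove spatially contiguous, correlated stretches of the
core and therefore perturb the structural signal more strongly than the
same number of scattered sites, which is the point of reporting both.
Site and block comparisons share replicate seeds (common random numbers)
to reduce the variance of their difference.

## The synthetic benchmark

`simulate_dataset` emulates exactly what the pipeline consumes: a known
tree (`generate_tree`), an idealized self-avoiding C-alpha template of
helix/strand segments in an antiparallel snake (`make_template`,
consecutive spacing 3.8 ± 0.1 Å, non-consecutive clearance > 3 Å), and
leaf structures diverged along the tree (`evolve_structures`) by Gaussian
displacements with per-residue sd `noise_per_unit_branch * branch_length`,
smoothed along the chain by a moving average of width
`spatial_correlation_length` (rescaled to preserve the per-residue sd).
Each leaf receives a random rigid motion; optional indels and
low-confidence terminal tails exercise the aligner and QC respectively;
ground-truth residue correspondences are carried in `meta$truth`.

Default conditions, chosen once for the benchmark and used throughout the
tests: 250-residue template (comparable to real polymerase structural
cores), correlation length 5 (about one secondary-structure element),
0.5 Å noise per unit branch, branch lengths uniform in [0.4, 0.6]. The
branch-length band avoids near-zero internal branches that no distance
method could resolve at finite core size: with correlated noise the core
contains roughly `template_len / correlation_length` independent
stretches, and the sd of a pairwise distance estimate must sit well below
the squared length of the shortest internal branch (noise accumulates
with per-branch sd proportional to branch length, i.e. variance additive
in squared branch lengths). Under these conditions the full pipeline
recovers the generating topology in 20/20 seeded runs; support and
resampling behaviour is studied under a heterogeneous variant
(`branch_length_range = c(0.05, 0.6)`, noise 1.0) whose short deep
branches produce intermediate support values.

What the generator does **not** emulate: real secondary-structure
rearrangements, domain motions, ligand-induced conformational change,
prediction-specific error modes (pLDDT miscalibration, hallucinated
termini with high confidence), or sequence evolution beyond bookkeeping.
Passing benchmarks therefore demonstrate the correctness and internal
consistency of the machinery — QC rule arithmetic, superposition
optimality, score additivity, NJ exactness, jackknife calibration — not
that any particular biological dataset will yield a well-supported tree.

## Numerical choices and degenerate inputs

* Kabsch uses SVD with a reflection guard; near-collinear point sets
  (second singular value below 1e-8 of the first) warn about an unstable
  rotation. Fewer than 3 points is an error.
* Greedy pairing ties (exactly equal distances) break on the lower
  (row, column) index pair; merge-order ties break lexicographically on
  model id — both make results independent of input order.
* Distances within -1e-9 of zero are treated as rounding and clipped.
* Newick parsing validates bracket balance and termination before
  delegating, so malformed files fail with a position rather than a
  misparse.
* PDB coordinates are written at 3 decimals (format convention); the
  mmCIF writer preserves input precision up to 10 significant digits.
* Support percentages are rounded to the nearest integer, the resolution
  at which replicate counts of 100 are meaningful.

## Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run at 6–8 leaves, 250-residue
templates, 100 jackknife replicates and 20-seed recovery experiments —
sizes at which every stage's behaviour is measurable and the complete
analysis reproduces in minutes on one CPU. All sizes are parameters, and
the pipeline has no hard-coded limits; cost grows linearly in replicate
count and roughly quadratically in both model count and model length.

## Known limitations

* The similarity score is a documented surrogate with two terms; it does
  not reproduce any particular published structural aligner's
  parameterization, and its Gaussian term compresses distances once
  typical deviations exceed ~2 Å (deep divergences are reconstructed
  less additively than shallow ones).
* Flexible (hinged) superposition is not attempted; a genuinely hinged
  fold family would fragment the core.
* The jackknife resamples core columns only — alignment uncertainty
  itself is not propagated, mirroring the resampling design the method
  implements.
* Multi-chain assemblies, ligands and modified residues are out of
  scope; non-standard residues map to `X`.
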