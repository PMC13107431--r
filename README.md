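# strucphylo

Structure-based phylogenetics for protein structure models.

When homologous proteins have diverged so far that their sequences no
longer align — the situation for the RNA-dependent RNA polymerases (RdRPs)
shared by all RNA viruses — their three-dimensional folds often still do.
`strucphylo` infers phylogenies directly from C-alpha coordinates of
(typically AlphaFold-predicted) structure models:

1. **Quality control** driven by per-residue pLDDT confidence stored in
   the B-factor column: terminal tails are trimmed with a 15-residue
   sliding window (all residues must exceed pLDDT 70), models are rejected
   when more than 5% of remaining residues fall below pLDDT 50 or more
   than 10% below 70, and residues below 50 are removed before alignment.
2. **Common-core structural alignment**: all pairs of models are aligned
   by seeded iterative closest-residue Kabsch superposition — a purely
   spatial search, so circularly permuted chains align correctly — and
   groups are merged progressively (most similar first), intersecting
   their residue correspondences into a common structural core with one
   residue per model per column.
3. **Distances and trees**: a column-additive similarity score `S` is
   computed over the core; distances follow

   ```
   D(A, B) = min[S(A,A), S(B,B)] − S(A,B)
   ```

   and trees come from a neighbor-joining implementation that is exact on
   additive matrices. Trees can be outgroup-rooted, serialized to Newick,
   and compared by (normalized) Robinson–Foulds distance.
4. **Jackknife branch support**: core columns are resampled — independent
   sites or contiguous blocks of at least 10 columns — scores are re-summed
   per replicate, replicate trees rebuilt, and per-branch support mapped
   onto the reference tree as the percentage of replicates containing each
   bipartition. A sampling-fraction sweep (10%–90%) locates the fraction
   beyond which the topology stabilizes; 50% block resampling is the
   default.

A synthetic-data module generates benchmark datasets with a known
generating tree (structures diverge along branches with spatially
correlated coordinate noise, optional indels and low-confidence tails),
so every stage can be validated against ground truth.

## Worked example

```r
library(strucphylo)

# simulate 6 structures related by a known tree, with low-confidence tails
ds <- simulate_dataset(simulation_spec(n_leaves = 6, tail_len = 25,
                                       tail_plddt = 55, seed = 1))
dir <- tempfile(); write_dataset(ds, dir)

# quality control
models <- read_structure_dir(dir)
qc <- qc_batch(models)
nrow(qc$report)          # 6 reports
#> [1] 6
all(qc$report$passed)    # tails trimmed, every model passes
#> [1] TRUE

# common core + scores
built <- build_core(qc$models)
built$core
#> core_alignment: 250 columns across 6 models (avg RMSD 0.81 A)

# tree and jackknife support
tree <- neighbor_joining(score_to_distance(built$scores))
jk   <- jackknife_support(built$scores, jackknife_config(seed = 1))
jk$tree$node.label       # per-branch support (% of 100 block replicates)
#> [1] ""    "100" "41"  "100"
rf_distance(jk$tree, ds$tree)   # recovers the generating topology
#> [1] 0
```

The core spans the full 250-residue template (no indels were simulated)
and its average pairwise RMSD of ~0.8 Å reflects the low simulated
divergence. The reference topology matches the generating tree exactly,
and block-jackknife support separates the branches: two internal edges
are rock solid (100%), while one — whose signal lives in a removable
stretch of the core — drops to 41%, exactly the kind of instability the
resampling is designed to expose.

A command-line interface over the same functions is installed at
`inst/scripts/strucphylo.R` (subcommands `simulate`, `qc`, `core`, `tree`,
`jackknife`, `sweep`, `compare`, `run`); `run` executes the whole
pipeline from a YAML configuration.

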