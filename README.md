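# frmotif

Network-pharmacology toolkit for bipartite **component–target (C-T)
networks**: given a table of compound descriptors, a compound→target edge
list, a gene-set collection (GMT) and a disease-gene score table, it
answers four questions in sequence:

1. **Which compounds are drug-like?** Lipinski's Rule of Five plus a
   bioavailability window [0.30, 0.55] and a high-GI-absorption
   requirement (`screen_table()`).
2. **Which parts of the network form coherent modules?** Minimization of
   the two-level map-equation codelength of a random walk,

   L(M) = q↷·H(Q) + Σᵢ p↻ᵢ·H(Pᵢ),

   followed by a permutation-significance filter against a
   degree-preserving bipartite null — the significant modules are the
   *SDFMs* (`optimize_partition()`, `module_significance()`).
3. **Which modules carry the disease signal?** A 0/1 knapsack
   (max V = Σ vᵢxᵢ s.t. Σ wᵢxᵢ ≤ C) solved by a genetic algorithm with an
   exact DP oracle for testing — the selected modules are the *FRMs*
   (`build_instance()`, `solve_ga()`, `solve_exact()`). FRMs are
   validated by hypergeometric pathway enrichment (BH-corrected) and
   disease-relevance summaries (`enrich()`, `pathway_coverage()`,
   `frm_disease_summary()`).
4. **Which components drive it?** Components are ranked by target count,
   assigned a marginal-coverage information gain
   ΔZₙ = |(TCₙ \ ∪ᵢ₍ₙ TCᵢ) ∩ T_all| / |T_all|, and scored
   Q = T_nor × ΔZ_nor; the key component group is Q > 0.01
   (`key_components()`).

A synthetic generator (`simulate_bundle()`) produces all four inputs with
planted ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(frmotif)
bundle <- simulate_bundle(seed = 1)           # planted 3-module network
res <- run_pipeline(pipeline_config(list(
  seed = 1,
  frms = list(strategy = "relevance_sum", capacity_frac = 0.7)
)), bundle = bundle)
```

Printed results for this seed:

```
degree_summary: mean component degree 7.33, mean target degree 3.67
screen:         6 of 20 compounds pass the drug-likeness filter
sdfms (all p = 0.005, the floor at n_perm = 199):
  module n_components n_targets      saving p_value
1      4            5         9  0.22679115   0.005
2      3            5        11  0.08192857   0.005
3      1            4         7 -0.05364142   0.005
4      2            1         3 -0.05379827   0.005
validation:     pathway coverage 0.667; FRM mean relevance 7.41
                vs table-wide mean 6.31 (the planted enriched module)
key components:
  component T         dZ T_nor    dZ_nor          Q
1  cmp02_02 9 0.42857143   1.0 1.0000000 1.00000000
2  cmp02_03 9 0.19047619   1.0 0.4444444 0.44444444
3  cmp01_02 8 0.14285714   0.8 0.3333333 0.26666667
...
```

Reading this: the optimizer found four modules, all more internally
cohesive than degree-matched rewirings (p = 0.005); the knapsack kept the
motifs whose targets carry the planted disease relevance, and those
motifs still recover two-thirds of the full network's enriched pathways;
`cmp02_02` tops the key-component ranking because it has both the most
targets (T_nor = 1) and the largest marginal coverage of the motif
target union (ΔZ_nor = 1). A `saving` below zero means splitting that
module out *alone* does not beat the one-module code — only the joint
partition does.

## Command line

```sh
Rscript inst/cli/frmotif.R simulate --seed 3 --outdir sim
Rscript inst/cli/frmotif.R network  --network sim/network.tsv
Rscript inst/cli/frmotif.R pipeline --network sim/network.tsv \
    --disease sim/disease.tsv --genesets sim/genesets.gmt \
    --compounds sim/compounds.tsv --outdir out --seed 3
```

Every JSON artifact embeds the resolved configuration and seed.
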