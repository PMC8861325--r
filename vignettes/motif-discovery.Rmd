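---
title: "Functional response motif discovery in component-target networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional response motif discovery in component-target networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frmotif)
```

## The problem

Herbal prescriptions act through many compounds hitting many protein
targets at once. Given a bipartite component-target (C-T) network, the
practical questions are: which compounds are plausible oral drugs, which
parts of the network form coherent functional units, which of those units
carry the disease-relevant signal, and which individual components drive
that signal. `frmotif` implements this chain as six composable stages.

## Drug-likeness screen

The screen is Lipinski's Rule of Five plus two oral-absorption criteria:
molecular weight strictly below 500 Da; at most 5 hydrogen-bond donors; at
most 10 hydrogen-bond acceptors; logP in $[-2, 5]$; at most 10 rotatable
bonds; a bioavailability score in $[0.30, 0.55]$; and high
gastrointestinal absorption. All descriptors are *inputs* (the shape of a
SwissADME export); the package computes nothing from structure. Two
deliberate choices:

* **Boundary semantics.** "Less than 500" is strict; "does not exceed"
  and the two windows are inclusive. This is the literal reading of the
  standard rule statements.
* **Strict conjunction.** A compound passes only with zero violations.
  The customary relaxation (allow one Lipinski violation) is not applied;
  since the source methodology is silent, the stricter rule was fixed
  once and exposed through `screen_config()` rather than guessed per run.

A useful invariant follows: tightening any single threshold can only
shrink the passed set, which the test suite checks over random
configurations.

## Module detection: the two-level map equation

Modules are found by minimizing the description length of a random walk.
For a partition $M$ of the nodes into $m$ modules,

$$L(M) = q_\curvearrowright H(Q) + \sum_{i=1}^{m} p_\circlearrowright^i H(P_i),$$

where $q_\curvearrowright^i$ is the per-step probability of exiting module
$i$, $q_\curvearrowright = \sum_i q_\curvearrowright^i$, $H(Q)$ is the
entropy of the normalized exit rates (the cost of the index codebook),
$p_\circlearrowright^i = q_\curvearrowright^i + \sum_{\alpha \in i}
p_\alpha$ is module $i$'s codebook usage, and $H(P_i)$ is the entropy of
its within-module codebook (one exit word plus the member nodes). With a
single module $L$ collapses to the entropy of the visit rates — the test
suite uses this identity, and the closed form $p_\alpha =
\mathrm{deg}(\alpha)/2|E|$ for the teleport-free walk, as independent
oracles.

Numerical choices:

* **Teleportation** $\tau = 0.15$ by default (uniform, unrecorded). C-T
  networks are frequently disconnected; teleportation keeps the
  stationary distribution well-defined. $\tau = 0$ is allowed on
  connected networks and reproduces the degree closed form to 1e-10.
  Exit rates include the teleportation flow leaving each module, keeping
  the flow decomposition exactly additive.
* **Bits and conventions.** Logarithms are base 2; $0 \log 0 \equiv 0$.
  Power iteration converges to 1e-10 in L1.
* **Search.** The objective's optimizer is a seeded multi-restart greedy:
  singleton start, sweeps of single-node moves to neighbouring modules,
  interleaved with merges of adjacent modules, ties broken toward the
  lower module id. On every 6-node graph it matches the exhaustive
  minimum over all 203 set partitions; at the package's working scales
  (tens of nodes) 8 restarts have been sufficient in testing.

## Significance: which modules are more than chance

The source methodology filters modules at $p < 0.05$ but never states the
test; the package's null is therefore its own documented choice, not a
reconstruction. Statistic: the codelength *saving* of splitting the
module out of the one-module partition. Null model: degree-preserving
rewiring of the bipartite edge set (double-edge swaps that never create a
duplicate edge). P-values use the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})$ with
$n_\text{perm} = 199$ by default, so the smallest attainable p-value is
0.005. Singleton modules get $p = 1$ by convention. Modules passing the
filter are the significant different functional modes (SDFMs).

## Motif selection: a 0/1 knapsack solved by a GA

SDFMs are pruned to functional response motifs (FRMs) by maximizing
$V = \sum_i v_i x_i$ subject to $\sum_i w_i x_i \le C$, $x_i \in \{0,1\}$.
The mapping of modules onto $(v_i, w_i, C)$ is unstated in the source, so
it is explicit and logged here: value = number of module targets annotated
in the disease table (alternative: sum of their relevance scores), weight
= module node count, capacity = a fraction of the total weight. The
genetic algorithm uses binary chromosomes, roulette-wheel selection,
two-point crossover (p = 0.8), per-bit mutation (1/n), elitism of one.
Two deviations from a literal reading of the source procedure:

* the stated termination "$W = C$" is generally unattainable (no subset
  may hit the capacity exactly), so the stop rule is a generation budget
  (200) plus stagnation (50 unimproved generations);
* infeasible offspring are repaired by randomly removing selected items
  rather than penalized, keeping fitness non-negative as roulette
  selection requires.

An exact dynamic-programming solver ships as the test oracle; on 100
random instances with $n \le 15$ the GA must match it at least 95 times
and never exceed it.

## Validation metrics

Three checks that FRMs stand in for the full network:

1. **Disease relevance.** Mean relevance score and evidence count of FRM
   targets, compared against "high-reliability" gene sets (genes strictly
   above the table-wide mean on each annotation) with a two-sided
   Wilcoxon rank-sum test (the source shows significance stars but names
   no test).
2. **Pathway coverage.** The fraction of the full network's significantly
   enriched pathways (hypergeometric upper tail, BH-adjusted at
   $\alpha = 0.05$) that the FRM genes also enrich. Adjusted p-values are
   used; the source does not say.
3. **Reference-pathway proportion.** Reference = pathways significant for
   both the network targets and the disease genes; the statistic is the
   fraction recovered by the FRM genes.

The enrichment universe defaults to all collection genes plus the query —
the source never defines its universe, and this default is the least
surprising for GMT-only inputs. One caveat worth knowing: BH step-up
adjustment is *not* idempotent as a map on p-values
((0.1, 0.9) adjusts to (0.2, 0.9), which re-adjusts to (0.4, 0.9));
re-application can only inflate values, and the package tests that
property rather than the false fixed-point claim.

## Key components: the information-gain Q score

Within the FRM-restricted network, components are sorted by descending
target count (ties: lexicographic by id — the order matters because gains
are marginal). The n-th component's information gain is the fraction of
the motif target union it newly covers,
$\Delta Z_n = |(TC_n \setminus \bigcup_{i<n} TC_i) \cap T_{all}| /
|T_{all}|$. Target counts and gains are min-max normalized and multiplied:
$Q = T_{nor} \times \Delta Z_{nor}$; components with $Q > 0.01$ form the
key component group. Two formula-inherent facts are documented rather
than "fixed": the last distinct-count component always has $T_{nor} = 0$
hence $Q = 0$ regardless of its gain, and a constant vector would divide
by zero under min-max — the package defines the degenerate normalization
as 1.0 so a constant dimension does not annihilate Q.

## The synthetic world

Every stage is testable offline against generators with planted truth:

* **Network.** A bipartite planted-partition model: 3 modules of 5
  components + 10 targets, within-module edge probability 0.6, across
  0.05; isolated nodes are rewired with one within-module edge. These
  defaults give modules a two-level codelength optimizer recovers with
  adjusted Rand index above 0.9 in the median — dense, clearly separated
  blocks, deliberately easier than real C-T networks.
* **Disease table.** Relevance scores are log-normal (meanlog 1, sdlog
  0.6 — right-skewed like database relevance exports); targets of the
  enriched module are shifted up by 8. Evidence counts are
  negative-binomial with mean tracking relevance (size 2), giving the
  over-dispersion and positive correlation real exports show. Note the
  generator scores *every* target; real disease databases only list
  associated genes.
* **Gene sets.** One pathway per planted module (90% of its targets,
  padded with decoys) plus decoy pathways of random genes.
* **Compounds.** Exactly `round(n * druglike_frac)` records pass the
  default screen; every other record carries one recorded violation.

What a green test does **not** establish: recovery on sparse, skewed,
partially observed real networks; correctness of the significance null
beyond degree preservation; or any of the source study's headline counts,
which depend on proprietary databases and are out of reach by design.

Because the synthetic disease table annotates all targets, the
disease-count knapsack value degenerates (all modules tie), and with
three equal-weight modules a capacity fraction of 0.5 admits exactly one
module by integer granularity. End-to-end runs on the bundle therefore
use the relevance-sum value strategy with capacity fraction 0.7, which
admits two of three modules — roughly the half retention observed when
pruning SDFMs to FRMs in practice. Both knobs are ordinary configuration,
logged in every output's provenance block.

## Reproducibility

One global seed drives everything: stage seeds are derived by a stable
hash of the stage name, so stages are independently reproducible. All
randomness flows through R's RNG; all pipeline outputs embed the resolved
configuration and seed.

```{r example, eval = FALSE}
bundle <- simulate_bundle(seed = 1)
res <- run_pipeline(pipeline_config(list(
  seed = 1,
  frms = list(strategy = "relevance_sum", capacity_frac = 0.7)
)), bundle = bundle)
res$sdfms
res$keycomp$key
```
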