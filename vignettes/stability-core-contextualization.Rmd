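---
title: "Deriving a cell-fate stability core from expression and methylation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a cell-fate stability core from expression and methylation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabilitycore)
```

## The problem

A differentiated cell type is a stable state of a gene regulatory network:
the feedback structure of the network holds expression in a
self-reinforcing configuration. Given (i) genome-scale measurements that
distinguish a target lineage (e.g. cardiomyocytes derived from embryonic
stem cells) from two reference lineages, and (ii) a generic, literature-derived
signed regulatory network, the question this package addresses is: *which
subnetwork of the prior actually maintains the two observed cell states,
and which feedback circuits form its stable core?*

The workflow has three layers:

1. **Omics filters** reduce the measurements to lineage signatures:
   threshold-based differential expression against both references, promoter
   CpG methylation averaged around each TSS, differential methylation calls,
   and their integration (demethylated *and* up-regulated genes).
2. **Boolean network dynamics** turn expression into discrete stable
   states and compute the attractors of candidate networks.
3. **Contextualization** prunes the prior network by an evolutionary
   (estimation-of-distribution) search until its attractors contain the two
   observed states, and reports the **stability core** — the nontrivial
   strongly connected components of the pruned network.

## Boolean model and update rule

A network is a set of genes with signed directed edges (activation `+1`,
inhibition `-1`). A state assigns 0/1 to every gene; all genes update
simultaneously, so the dynamics are a deterministic map on the $2^n$ state
space, and every trajectory ends in an attractor — a fixed point or a
cycle, the model's notion of a stable (or oscillating) phenotype.

A signed edge list does not determine the Boolean function that combines a
gene's regulators, and published network analyses rarely state it. The
default here is the classic rule of synchronous attractor computation on
signed networks:

$$x_g(t+1) = \Big(\bigvee_{a \in A(g)} x_a(t)\Big) \wedge \neg\Big(\bigvee_{i \in I(g)} x_i(t)\Big)$$

with two conventions: a gene with *no* regulators holds its value, and a
gene with inhibitors but no activators treats the activation clause as
vacuously true (inhibition-dominant logic). Because downstream results —
which genes end up in the core — can depend on this choice, the rule is a
parameter (`rule`) throughout: a `"threshold"` (majority) alternative is
provided for sensitivity analysis, under which, e.g., the mutual-activation
pair has only the two fixed points `00` and `11`, whereas the default rule
adds a `01`/`10` swap cycle.

Exhaustive attractor search builds the full successor table (vectorised
over all states) and extracts its terminal cycles with basin sizes; it is
capped at 20 genes (about $10^6$ states, under a minute on one CPU) and
configurable. Beyond the cap, `find_attractors(mode = "sampled")` follows
trajectories from supplied start states. We deliberately use an explicit
successor map rather than symbolic (BDD/SAT) methods: contextualized cores
at the scale this package targets have on the order of ten genes, where
the explicit map is simpler, exactly testable, and fast.

States are encoded as integers (bit $i$ = value of the $i$-th gene in
lexicographic order) and cyclic attractors are rotated to start at their
minimal encoding, which makes attractor identity, hashing and run-to-run
comparisons exact.

## Consistency between attractors and observed states

`consistency_score()` measures how well a candidate network supports two
observed stable states. For each observed state the best-matching attractor
is scored by per-gene agreement and the two state scores are averaged:

* fixed points: each agreeing gene earns credit 1;
* cyclic attractors: each gene is summarised by its time-average over the
  cycle. A gene constant across the cycle is compared directly; an
  oscillating gene is *not reliably in any state*, so it earns at most
  half credit (0.5 when its rounded average — or a 0.5 tie — matches the
  observation, 0 otherwise).

Capping oscillating genes at half credit is a deliberate design choice: a
genuine cycle always oscillates in at least one gene, so the score reaches
1 **exactly** when both observed states are fixed points. Plain rounding
would let a cycle that spends 75% of its time near the observed state
score a perfect 1, blurring the distinction the contextualization step
optimises for. The property tests verify the iff-equivalence directly
against the exhaustive fixed-point enumeration on random networks.

## Evolutionary pruning (EDA)

`prune_network()` searches the lattice of edge subsets of the prior.
Each individual is a keep/drop mask over the prior's edges; generation 0
keeps each edge with probability `init_keep_prob`. Individuals are ranked
by consistency, the top `elite_fraction` is selected, and the next
generation samples each edge with probability

$$p_e = w \cdot \max_{C \ni e} f_C + (1 - w) \cdot f_e$$

where $f_e$ is the edge's inclusion frequency among the elites, $f_C$ the
frequency with which positive circuit $C$ is *intact* among the elites
(every edge present), and $w$ = `circuit_weight`. Taking the max over
positive circuits before mixing preserves intact positive feedback
circuits, the structures that multistationarity theory requires for
multiple stable states. Two boundary decisions the formula leaves open are
resolved as follows: an edge lying on **no** positive circuit falls back to
its edge frequency alone (otherwise its sampling probability would be
dragged to the floor regardless of evidence), and all probabilities are
clamped to `[min_keep_prob, max_keep_prob]` so no edge becomes permanently
fixed in or out.

**Tie-breaking.** Among individuals of equal consistency we prefer the one
retaining *more* prior edges. Under the hold-when-unregulated update rule,
removing edges can never destroy the fixed-point property of a state — in
the limit, the empty network holds every state fixed — so a
fewest-edges preference would collapse the search onto trivially
over-pruned networks with empty cores. Contextualization, as implemented
here, means: *discard as little prior knowledge as the stability constraint
allows*. The result is that, on the planted benchmarks, the optimum is the
full true network rather than any consistent fragment of it, and the
recovered core is the planted one.

The best individual ever seen is tracked across generations (so the
reported best-fitness trace is non-decreasing by construction), and the
whole loop is a pure function of its inputs and `seed` — two runs with the
same configuration are bit-identical.

Defaults (`pruning_config()`): population 100, elite fraction 0.2, 50
generations, `circuit_weight` 0.5, initial keep probability 0.5, clamps
`[0.02, 0.98]`, stop on perfect consistency. These converge in seconds on
priors of up to ~15 genes; all are overridable. For benchmark recovery
runs we set `stop_on_perfect = FALSE`, since stopping at the first perfect
individual returns an arbitrary consistent subnetwork before the
distribution has concentrated on the maximal one.

## Stability core

`stability_core()` decomposes the contextualized network into strongly
connected components (via igraph) and keeps those with at least two genes
or a self-loop. These components are exactly the feedback structures able
to maintain alternative stable states; genes outside them relay signals
but cannot hold state. The package reports the components and their union.

## Omics filters and their conventions

All thresholds follow the conventions of threshold-based lineage
signatures, with boundary semantics implemented exactly and covered by
boundary tests on both sides:

| Quantity | Rule | Boundary |
|---|---|---|
| DE up/down | mean log2 FC vs *each* reference | inclusive (≥ 2-fold) |
| DE significance | two-sided t-test vs each reference | p < 0.05, no correction |
| CpG site filter | total coverage in *every* cell type | inclusive (≥ 10×) |
| Promoter level | mean site frequency within ±1 kb of TSS | inclusive window |
| Differential methylation | delta vs *each* reference | inclusive (≥ 0.05) |
| Promoter class | hypermethylated / low | strict (> 0.70, < 0.10) |

Details and rationale:

* Welch's t-test is the default (`var_equal = FALSE`); with triplicates and
  unequal variances it is the safer reading of an unspecified "t-test".
  Testing against each reference separately (significant only if both pass)
  is the default; a pooled-reference mode exists. No multiple-testing
  correction is applied by default, matching the plain P < 0.05 convention;
  a BH option is provided.
* Fold changes are differences of arithmetic means of log2 values, i.e.
  log2 ratios of geometric means — the natural convention on RMA-scale data.
* "Within 1 kb of the TSS" is read as a symmetric ±1000 bp window,
  inclusive at the boundary, with an upstream-only option. Coordinates are
  0-based; BED annotations are half-open, and the TSS of a minus-strand
  gene is `end - 1`.
* Promoters with no covered CpG in any cell type are *undefined* and are
  excluded from differential calls (and reported), never imputed.
* Inclusive comparisons are performed with a $10^{-9}$ tolerance so that a
  delta of exactly 0.05 computed in floating point (e.g. 0.65 − 0.70) is
  not lost to binary representation.
* Binarization (`binarize_expression()`) bridges expression to Boolean
  states: a gene is ON in a cell type iff its mean exceeds the midpoint of
  its min and max cell-type means; ties (including constant genes) resolve
  to OFF, so an uninformative gene is "absent" rather than arbitrarily on.
  A ≥2-fold-above-minimum alternative is provided.

## What the synthetic generators emulate — and what they do not

`simulate_expression()` reproduces the three-lineage triplicate design on
a normalized log2 scale: per-gene Gaussian baselines, planted
lineage-specific modules (default 30 up / 20 down at ±2 log2 units in the
target type, i.e. four-fold effects), and i.i.d. Gaussian sample noise
(sd 0.25) — a clean microarray experiment with clear signatures. It does
*not* model probe effects, intensity-dependent variance, batch structure
or correlated genes, so passing recovery tests demonstrates threshold and
testing logic, not robustness to array artefacts.

`simulate_methylation()` places promoters ≥3 kb apart on one synthetic
chromosome (so truth labels never share CpGs), draws per-site coverage
from an over-dispersed negative binomial (mean 30, dispersion 5 — bisulfite
capture depth varies strongly between sites, which exercises the joint
coverage filter non-trivially), and methylated counts from a binomial at
the class level. The default classes mirror the observed promoter
dichotomy: "structural-like" genes hypermethylated (0.8) in both
references and demethylated (0.1) in the target, "TF-like" genes low
(0.05) everywhere, and midrange background. An `exact_counts` mode
replaces binomial draws by rounded expectations for noise-free boundary
fixtures. Bisulfite conversion error and read-level structure are out of
scope.

`simulate_prior_network()` plants two disjoint positive activation
circuits (the toy-scale analogue of a two-component stability core),
peripheral activation chains, and spurious inhibitions. The two observed
states set circuit 1 ON / circuit 2 OFF and vice versa — the binarized
profiles of two anti-correlated cell fates. Spurious edges are planted
*within* a circuit, alternating between the two: an inhibition inside a
circuit breaks that circuit's all-ON state, so every spurious edge must be
pruned before both states are fixed points. Inhibitions *between* the two
circuits would be dynamically inert under these anti-correlated states
(the inhibitor and its target are never simultaneously active), which is
why they cannot serve as planted noise here. The generator verifies both
guarantees — planted network consistent, full prior not — with the
package's own attractor machinery and re-draws on failure.

## Problem sizes in the test suite

The shipped tests run the attractor oracle on 50 random networks of up to
12 genes and 30 edges, the circuit oracle on 100 random digraphs of up to
8 nodes plus complete digraphs up to $n=5$, core recovery on the planted
6-gene two-circuit prior over 10 independent pruning seeds (population 50,
30 generations), and DE power at 200 genes × 20 simulation seeds. These
sizes give stable pass/fail behaviour in well under a minute per suite
section while exercising every code path; all generators scale up by
argument if heavier benchmarks are wanted.

## Known limitations

* The Boolean function per gene is a modelling choice, not data; core
  membership can change under a different rule. Both shipped rules should
  be run when the conclusion matters.
* Exhaustive attractor computation is exponential in gene count; priors
  beyond ~20 genes must be reduced (e.g. to their differential subnetwork)
  before contextualization, which is also the scientifically intended use.
* The consistency score compares states to attractors gene-by-gene; it
  does not weight genes by confidence of the binarization, and a cyclic
  attractor's half-credit cap is a convention, not an estimate.
* The EDA offers no optimality guarantee; the recovery benchmark measures
  its practical reliability (≥ 80% of seeds required, 100% observed at the
  shipped sizes).
* Differential calls ignore replicate-level methylation variance; counts
  are aggregated per site before promoter averaging, as is standard for
  threshold-based calls.

## A worked run

```{r example, eval = FALSE}
sp <- simulate_prior_network(seed = 2)
ctx <- prune_network(sp$prior, sp$state_a, sp$state_b,
                     pruning_config(population_size = 50, generations = 30,
                                    seed = 1, stop_on_perfect = FALSE))
glance(ctx)
ctx$core
autoplot(ctx)
```

`glance()` reports the best consistency (1 when both observed states are
fixed points of the pruned network), edges kept versus the prior, and the
core size; `ctx$core` lists the component membership; `autoplot()` draws
the best/mean fitness trace. The README shows the printed output of this
exact run.
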