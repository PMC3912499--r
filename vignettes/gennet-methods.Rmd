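---
title: "Evolving neural-network classifiers over multi-omics data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving neural-network classifiers over multi-omics data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gennet)
```

## The problem

Single-platform molecular signatures of clinical outcome — gene-expression
panels in particular — replicate poorly across cohorts. Two plausible causes
are (i) a focus on features with large marginal effects, which misses
non-linear interactions (epistasis, synthetic-lethality-like patterns) whose
components carry little signal on their own, and (ii) the restriction to one
molecular layer, when an outcome such as short- versus long-term cancer
survival may be driven jointly by copy-number, methylation, miRNA and
transcript-level events.

`gennet` addresses both with one search machinery: grammatical evolution of
small neural-network classifiers that selects input variables, connection
weights and topology *simultaneously*, applied per omics layer and then to a
combined, meta-dimensional feature space.

## Genotype, grammar, phenotype

The heritable material is a variable-length vector of integer codons in
0–255. A fixed BNF grammar (printable via `genn_grammar()`, replaceable via
`read_grammar()`) maps a genome to a network by leftmost derivation: each
non-terminal with *k* ≥ 2 alternatives consumes one codon and expands to
alternative `codon mod k`; single-alternative rules consume nothing. When the
genome is exhausted, reading wraps to its start at most `max_wraps` (default
2) times; a derivation still holding non-terminals after that is *invalid*
and receives fitness 0, so non-functional genomes are selected against
rather than repaired.

The derived phenotype is a tree of activation nodes — `PADD`, `PSUB`,
`PMULT`, `PDIV` — each combining 2 or 3 weighted inputs, where an input is
either an input variable or a nested node. Weights take the form `±d.d`
(−9.9 to 9.9 in 0.1 steps), each digit chosen by one codon. Two design
points deserve mention:

* **Variable indexing uses two codons**, `index = (256·c1 + c2) mod p`.
  A single 8-bit codon can address at most 256 features, while a methylation
  array has tens of thousands; two codons cover any layer up to 65,536
  features with the same modulo semantics.
* **Node semantics are raw arithmetic with a sign threshold.** `PADD` sums
  its weighted inputs, `PSUB` and `PDIV` fold left-to-right, `PDIV` uses
  protected division (denominators below 1e−10 in magnitude yield 1.0), and
  any non-finite intermediate is replaced by 1.0, so evaluation is total.
  Class 1 is predicted when the output is ≥ 0. No squashing function is
  applied; for a sign threshold, a sigmoid centred at 0.5 would decide
  identically, and the raw form keeps `PMULT`/`PDIV` sign patterns — which
  express XOR-type logic directly — undistorted.

Initialization never produces invalid individuals: `random_functional_genome()`
grows a random derivation under a depth budget (alternatives that cannot
terminate within the remaining budget are excluded) and emits, in leftmost
order, codons reproducing exactly that derivation. Mapping the emitted genome
is therefore guaranteed to succeed with zero wraps, and the package tests
verify the round trip codon-for-codon.

## Fitness and the search

Fitness is **balanced accuracy**, (sensitivity + specificity)/2, computed on
training data only. With a 110/148-style class split a constant predictor
scores exactly 0.5, so the fitness cannot be inflated by imbalance.

The search is an island-model genetic algorithm. Each deme evolves
independently — tournament selection (size 2), single-point crossover at
codon boundaries with cut points chosen independently per parent (probability
0.9), per-codon uniform mutation (default 0.01), one elite copied unchanged —
and every `floor(generations/migrations)` generations a copy of each deme's
best replaces the worst individual of the next deme on a ring. Offspring
genomes are truncated at `max_genome_length` (default 250 codons) as bloat
control. Every deme owns a private counter-based random stream derived from
the run seed and its deme index, which makes results bit-identical across
serial and parallel execution and invariant to adding demes.

The published configuration for this class of analysis is cluster-scale
(50 demes × 5,000 individuals, 300 generations, 15 migrations). The package
defaults are a desk-scale analogue — 2 demes × 500, 50 generations — with the
same operator probabilities; all experiments below state their configuration
explicitly.

## The three-stage protocol

1. **Filtering.** A short, wide search (default 10 demes × 500, 20
   generations) is run and the best model of every (generation, deme) pair is
   logged — these are the "intermediate models". Each variable is scored by
   the fraction of intermediate models containing it (set semantics within a
   model), ranked, and the top `ceiling(fraction · p)` retained; candidate
   fractions 10/30/50% can be compared by cross-validated accuracy with
   `select_filter_threshold()`. Filtering is re-run inside each training fold,
   so held-out samples never influence retention. The per-fold choice is the
   conservative reading of the protocol; a global filter would leak test
   information into variable selection.
2. **Modelling.** Stratified 5-fold cross-validation: per fold, a full search
   on the training 4/5, the best-ever network scored on the held-out 1/5.
   The reported model is the one "identified the most": fold-best models are
   grouped by variable set (weights and topology ignored — exact tree
   equality would essentially never repeat), the most frequent group wins,
   ties broken by mean test accuracy then model size. Per-variable
   *consistency* (folds containing the variable, e.g. 4/5) is reported
   alongside. Features are z-scored with training-fold statistics.
3. **Integration.** Variables of each layer's selected model are pooled into
   one dataset (columns copied unchanged, layer-qualified as
   `layer:feature`), searched again, and the integrated model compared
   against each single-layer model by an exact two-sided Wilcoxon signed-rank
   test over the shared folds' test accuracies. One fold assignment, derived
   from the run seed, is shared by all runs so the comparison is paired.

### Pooling modes

`genn_integrate()` offers three pooling modes. `"best"` (the default)
reproduces the published design: only the selected best model of each layer
contributes variables. Its known blind spot is a cross-layer interaction
whose components have no marginal effect within their own layer: a per-layer
search has no signal to find them, so they are pooled only by chance. The
`"folds"` mode widens pooling to all fold-best models; the `"layers"` mode
searches the union of the layers' features jointly and is the mode designed
for marginal-free cross-layer epistasis (at the price of a much larger search
space). The cross-layer XOR experiment below uses `"layers"` for exactly this
reason.

## The exact signed-rank test

With five folds there are only 2^5 sign assignments, so any large-sample
approximation is meaningless. `wilcoxon_exact()` drops zero differences,
assigns average ranks to tied absolute differences, and enumerates all 2^m
sign patterns to obtain the exact null of W (sum of positive ranks); the
two-sided p doubles the smaller tail, capped at 1. A consequence worth
stating: with five informative pairs the smallest attainable two-sided
p-value is 2/32 = 0.0625, and every attainable value is a multiple of 1/16.
The package tests pin this floor.

## The synthetic generator

`simulate_omics()` produces several layers of independent standard-normal
features over a shared sample set, with a binary outcome driven by planted
effects. A *main* effect puts a sample at risk when its planted feature
exceeds 0; an *xor_pair* (within or across layers) when exactly one of its
two features exceeds 0. The class is Bernoulli(penetrance_high) when any
effect is active, else Bernoulli(penetrance_low); defaults are 0.9/0.1, for
which the oracle predicting class 1 exactly on the risk state has balanced
accuracy `bayes_accuracy()` = 0.9 — the performance ceiling of any learner on
such data. Thresholding continuous features at 0 lets both threshold-style
and arithmetic networks express the signal. By symmetry of the XOR, each
component variable alone is marginally independent of the outcome (checked
empirically at n = 10,000 in the tests).

What the generator deliberately does **not** emulate: correlation structure
among features, copy-number segment structure, methylation beta
distributions, batch effects, or missingness patterns of real arrays.
Passing tests on these data demonstrate that the machinery recovers planted
signal of the assumed form through a leakage-safe pipeline — not that it
would attain comparable accuracy on a real cohort.

## Study conditions and the interaction preset

The packaged experiments (test suite and `scripts/acceptance.R`) use these
conditions:

* **Main-effect recovery** — one layer of 100 features, one main effect
  (0.9/0.1), n = 500; filtering at 10 demes × 500 × 20 generations must rank
  the planted variable in the top decile; modelling at 2 demes × 500 × 50
  generations on the top 10% under 5-fold CV is expected to reach a mean test
  balanced accuracy well above 0.75 against the 0.9 ceiling.
* **Cross-layer XOR** — two layers × 100 features, one xor_pair (0.9/0.1),
  n = 500, integration in `"layers"` mode with
  `genn_control_interaction()`; single-layer searches at 2 demes × 500 × 40.
* **Null calibration** — two layers × 50 features, no effects, n = 300, the
  full filter → model → integrate pipeline; mean test balanced accuracy must
  stay near 0.5, confirming that nothing in the pipeline leaks test labels.

`genn_control_interaction()` deserves its rationale. A marginal-free
interaction gives the search no gradient: candidate networks score at chance
until one holds the complete interacting pair inside a product-type node, so
success probability is governed by the *rate of distinct small candidates
tried*, not by selection pressure. The preset therefore (i) caps genomes at
40 codons with initial depth 7, confining networks to a single activation
node over 2–3 variables — the smallest phenotype that can express an XOR via
a `PMULT`/`PDIV` sign pattern — and (ii) raises per-codon mutation to 0.2,
which on ~20-codon genomes resamples roughly one variable reference per
offspring, keeping exploration alive after the population converges on
noise; many demes act as independent restarts. A sizing experiment on the
generator (10 independent datasets per setting) showed discovery rates per
search rising from ~20% at the default mutation rate and 250-codon cap to
75–80% with the preset at the same evaluation budget; at 10 demes × 500 × 60
generations per fold the planted pair is recovered in the large majority of
folds.

## Numerical choices and degenerate inputs

* Protected division constant 1.0 below |den| = 1e−10; the same value
  replaces any non-finite intermediate (overflow guard).
* Network output exactly 0 predicts class 1 (boundary convention).
* Rank ties in the frequency table: stable sort by descending frequency,
  then input-file order — determinism over elegance.
* `ceiling` in threshold retention, so any positive fraction keeps ≥ 1
  variable; retained sets are nested across increasing fractions.
* Stratified folds: per-class remainders rotate across folds, so fold sizes
  differ by at most one overall *and* per class (258 samples split 110/148
  give folds of 52/52/52/51/51 with 22 class-1 samples each).
* Invalid mappings score fitness 0, not 0.5 — functionality is selected for.
* Degenerate inputs fail loudly: one-class training data, a class smaller
  than k, conflicting labels between layers, and empty layer intersections
  are all errors, not warnings.

## Limitations

* Weights come from the grammar's ±d.d lattice; there is no gradient
  refinement, by design — the search optimises variables, weights and
  topology jointly, and a finer weight lattice would lengthen genomes.
* The `"best"` pooling mode inherits the published design's blind spot for
  interactions not represented in any single-layer best model; use
  `"layers"` when such interactions are the target.
* The exact signed-rank enumeration is limited to 20 nonzero differences
  (2^20 sign patterns); cross-validation comparisons here involve five.
* Censored survival outcomes are out of scope; the outcome is a precomputed
  binary class (e.g. the 3-year survival dichotomy applied upstream).
* Search cost scales linearly in population × generations × samples;
  cluster-scale configurations are supported in principle but the packaged
  experiments are desk-scale.
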