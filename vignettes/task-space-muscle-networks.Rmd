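---
title: "Dissecting muscle couplings in the task space: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting muscle couplings in the task space: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskspace)
```

## The problem

Classical muscle-synergy analysis factorises electromyographic (EMG)
envelopes first and interprets the task relevance of the factors afterwards.
`taskspace` reverses that order: it first quantifies, for every pair of
muscle-timepoint activity vectors, how much information the pair carries
about an explicit task variable, and only then extracts low-dimensional
space-time structure from those couplings. Each pairwise coupling is
classified as

* **task-irrelevant** — dependence that survives conditioning on the task
  variable (conditional mutual information, CMI),
* **task-redundant** — both muscles carry the same task information
  (negative co-information), or
* **task-synergistic** — task information that emerges only from the joint
  observation (positive co-information).

The four-observation truth tables returned by `figure2_tables()` are the
minimal worked examples of the last two classes: in the redundancy table
either muscle alone yields the full bit about the left/right task variable;
in the synergy table neither muscle alone is predictive but the pair is.

## Information estimation

Couplings are estimated with the Gaussian-copula family. Margins are
rank-normalised (`copula_normalize()`, average ranks for ties — deterministic
and permutation invariant) to standard normal scores, after which mutual
information is computed from bias-corrected Gaussian entropies
(`gaussian_entropy_bits()`, psi-function small-sample correction). All
entropies are accumulated in nats internally and reported in bits. MI and
CMI estimates are clipped at zero; co-information is computed from the
*unclipped* components `I([x,y];tau) - I(x;tau) - I(y;tau)` so that its sign
is unbiased and the additive identity holds exactly for every call (the
components are returned with the estimate).

Estimator routes:

* continuous-continuous: `mi_gc()` (Gaussian copula MI);
* continuous-discrete: `mi_mixed()`, the Gaussian-mixture form — overall
  copula-normalised entropy minus class-weighted conditional entropies;
* conditioning on a discrete task: class-wise copula re-normalisation
  (conditioning changes the marginals, so ranks are recomputed within each
  class);
* conditioning on a continuous task: closed-form Gaussian conditional MI on
  the copula-normalised triple;
* binary on/off worked examples: `mi_plugin_discrete()`, exact plugin MI
  from joint frequencies (the copula estimators are undefined on
  constant-within-class data).

A property worth knowing: after rank normalisation, *perfectly separated*
classes occupy the two halves of a standard normal, so the class-conditional
Gaussian fit caps `mi_mixed()` at `-log2(1 - 2/pi)/2`, about 0.73 bits, not
at `H(tau) = 1` bit. This is inherent to the copula family (the price of
invariance under monotone transforms), and the tests assert that saturation
limit rather than the naive 1-bit value.

For a continuous task variable and a timepoint pair `(t1, t2)` there is no
single canonical way to pair task samples with the two muscle timepoints;
`build_tensor(tau_pairing = )` exposes two policies: `"own"` conditions on
the task values at both members' own timepoints jointly (marginal MIs are
taken against the same two-dimensional target so the co-information is
coherent; nearly collinear task columns, as in smooth trajectories, fall
back to a single column), and `"mean"` uses the task series averaged over
the two timepoints.

## The coupling tensor

`build_tensor()` evaluates every unordered muscle pair at every unordered
timepoint pair (timepoint pairs include the diagonal — same-time couplings
are where co-activation lives; muscle self-pairs are excluded, since
self-MI is entropy, not coupling) for every layer (task variable x
participant). For an off-diagonal timepoint pair the two orderings of the
muscles over the timepoints are distinct couplings that map to one tensor
cell; the cell stores their mean, which keeps every network view exactly
symmetric. The signed co-information tensor is rectified into two
equally-sized non-negative tensors (redundant = rectified negative part,
synergistic = positive part), which never overlap and reconstruct the
signed tensor exactly.

## Percolation sparsification

Each spatial layer (muscle network per timepoint pair) and each temporal
layer (timepoint network per muscle pair) is sparsified at its percolation
threshold (`percolation_threshold()`): edges are removed in ascending
weight order for as long as the giant component of the *remaining* network
stays at or above the reference level of equivalently sized random networks
— the mean giant-component fraction of networks with the same node and edge
count and uniformly random edge placement. The first removal that would
push the giant component below that reference is not committed; its weight
is the critical threshold `Pc`. The rule is rank-based, hence invariant to
uniform weight scaling, and deterministic given the seed (recorded in the
report). On a path graph, where any removal fragments the network, nothing
is removed and `Pc` is the minimum edge weight; a weak bridge to a pendant
node bounds `Pc` from above.

Because the percolation step sees only weight *ranks* within a layer, it is
blind to absolute magnitude, and a layer of pure estimation noise is
statistically exchangeable with its own null ensemble. A retained entry must
therefore also clear the estimator's **noise floor**: under independence the
bias-corrected information estimate behaves asymptotically like a
chi-squared variable over `2 n ln 2` (in bits), and `sparsify_dual_domain()`
requires every retained entry to exceed the Bonferroni-corrected upper
quantile of that null across all tensor entries (defaults `alpha = 0.05`,
conservative `df = 5`). Finally, the dual-domain heuristic applies: an entry
is kept only if it survives percolation in *both* its spatial and its
temporal layer. With these three conditions, noise-only synthetic tensors at
2000 trials come out empty in essentially all seeds, while planted couplings
a few-fold above the floor are retained with perfect precision and recall
(the test suite measures both).

## Model-rank selection

Spatial and temporal model ranks are chosen by modularity-based community
detection. `modularity_mono()` is the Newman-Girvan Q-statistic
`Q = (1/2m) * sum (A_ij - k_i k_j / 2m) delta(g_i, g_j)`;
`modularity_multi()` adds the multiplex coupling term with resolution
`gamma` and inter-layer coupling `omega` (both default 1, classical
modularity, coupling all-to-all across layers for the same node).
`detect_communities()` optimises the (supra-)modularity matrix with a
generalised Louvain scheme: greedy local moves with lowest-index tie-breaks,
aggregation, best of `n_repeats` seeded restarts, and a guard that never
returns a partition worse than the trivial one. For each participant/task
the spatial slices (and, separately, temporal slices) form a multiplex
network whose joint partition is computed; `consensus_model_rank()` then
stacks the binary co-classification matrices of those partitions as a new
multiplex network and re-runs detection — the number of consensus
communities is the model rank. Both the multilayer variant and the
monolayer variant (on the mean co-classification matrix) are computed; the
multilayer result is the default and disagreement is reported rather than
silently resolved. Self-couplings (diagonal timepoint pairs) are excluded
from the community-detection views: a self-loop inflates a node's expected
degree without informing its community.

## Space-time factorisation

`snm3f_fit()` minimises `sum_l || A_l - V' S_l' W ||_F^2` over non-negative
spatial factors `V` (muscle-pair loadings), temporal factors `W`
(timepoint-pair loadings), shared across layers, and layer-specific
non-negative coefficients `S` — the all-to-all property: any spatial factor
may combine with any temporal factor, with a participant- and task-specific
weight. Updates are multiplicative; each block update is a Lee-Seung step
on a linear non-negative subproblem, so the objective is non-increasing
(asserted per run in the tests). Initialisation is uniform-random and
seeded, with best-of-`n_restarts` (default 10) by residual; convergence is
a relative objective change below `tol` (default 1e-6) or `max_iter`
(default 500). An optional penalty on the off-diagonal factor Gram entries
(`ortho_v`, `ortho_w`, default 0) discourages duplicate factors; the
penalty adds only non-negative terms to the update denominators, and the
monitored objective includes it. The coefficients `S` quantify the
participant- and task-specific scaling of information overlap; they are
*not* variance accounted for.

Two caveats that the tests encode explicitly. First, non-negative
factorisations are only unique under separability-type conditions: the
planted-recovery fixtures use factors with disjoint dominant support and at
least one near-pure layer per factor combination, because with dense random
factors an exact fit with rotated factors exists and factor-wise correlation
is meaningless. Second, multiplicative updates converge sublinearly near
zero entries, so "exact" recoveries stop at relative residuals around 1e-4
rather than machine precision.

`cp_fit()` provides the non-negative canonical polyadic comparator with
one-to-one factor pairing, fitted by the same multiplicative machinery on
the tensor unfoldings.

## Generalisability protocols

`leave_n_out()` removes one participant (or task variable) at a time,
re-runs the coupling + decomposition pipeline, matches factors to the
full-data reference by greedy maximum-correlation assignment (ranks are
small, so greedy equals optimal in practice and is deterministic) and
reports Pearson correlations per orientation. `random_ablation()` removes a
uniformly sized random subset of timepoint-pair columns (at least one, at
most `T - temporal_rank`, so the re-extraction stays defined) jointly from
every layer, re-extracts, and compares: spatial factors on the full support,
temporal factors on the surviving columns. Summaries use Fisher's Z
(`fisher_summary()`): `tanh(mean(atanh(r)))` and the analogous sd, with the
Z-scale sd reported alongside since a back-transformed sd is not itself a
correlation bound. Correlations at exactly one are clipped with a warning.
All decompositions inside one protocol share a fitting seed, so a
perturbation that leaves the couplings unchanged (an empty ablation, a
duplicated participant) reproduces the reference decomposition rather than a
different local optimum.

On tensors whose layers activate different spatial-temporal factor
combinations — the regime that motivates all-to-all pairing — the
tri-factorisation's ablation similarity exceeds the CP comparator's, and the
test suite asserts that direction (the magnitude of the gap depends on the
data and is not asserted).

## Subnetwork analysis

Extracted spatial factors are mapped back to symmetric muscle networks
(`factor_to_network()`; factors live on muscle pairs, so entries are edges).
`communicability()` computes `e^A` (via the `Matrix` package's
scaling-and-squaring exponential) and total node communicability
`C(i) = sum_j [e^A]_ij`. `prune_below_average()` removes existing edges
whose communicability falls below the mean over existing edges — edge-level
pruning, in one pass; node-level pruning would disconnect whole muscles.
`submodules()` delegates to monolayer community detection.

## The synthetic generator

`synthetic_spec()`/`generate()` emulate trial-structured EMG envelope
datasets with planted couplings; they are the package's test bed and define
its study conditions. Defaults: 5 participants, 100 trials each, 9 muscles,
a 10-point envelope, a binary discrete task variable, independent envelope
noise with sd 0.25, and planted redundant pairs in complementary time
windows plus one synergistic and one task-irrelevant pair — dimensions in
the range of a desk-scale reaching study, with trial counts at which the
copula estimators are well out of their small-sample regime. Mechanisms:

* *redundant*: both muscles driven by the same task-determined latent;
  several independent redundant modules use orthogonal class contrasts
  (`group` column), since redundancy about a common task variable is
  transitive and pairwise plants sharing it always form cliques;
* *synergistic*: with a discrete task, random per-trial signs whose product
  encodes the binary-reduced class (parity coding); with a continuous task,
  the task series tracks the *difference* of the two muscles while a strong
  shared latent masks the marginals (differential coding) — a pure
  multiplicative interaction would be invisible to any Gaussian-copula
  estimator, which captures second-order structure only;
* *irrelevant*: a shared latent independent of the task;
* rows with `i == j` drive one muscle directly with the class latent,
  planting graded all-to-all couplings among all driven muscles.

Non-negativity is enforced with a softplus, which is monotone and therefore
invisible to the rank-based estimators. The same seed yields byte-identical
data, and generation does not disturb the caller's RNG stream.

What the generator does *not* emulate: motor-unit dynamics, EMG crosstalk,
nonstationary noise, electrode artifacts, or realistic muscle-specific
envelope shapes. Passing tests therefore demonstrate that the estimators,
the sparsification and the factorisation recover the statistical structure
they target — not that real recordings satisfy those structural assumptions.

## Problem sizes and numerical choices

The test suite runs the full pipeline at 5-9 muscles, 4-10 envelope points,
2-5 participants and 100-2000 trials — sizes chosen so that every stage,
including the 100-null percolation ensembles and multi-restart
factorisations, completes in seconds while staying in the estimators'
asymptotic regime. Degenerate inputs are handled explicitly: constant
envelope columns contribute zero coupling; empty network layers pass
percolation untouched with a warning; an all-zero tensor returns a zero
decomposition. Ties are broken deterministically everywhere (average ranks,
ascending-index edge order, lowest-index community moves), and every source
of randomness flows from a single seed through an internal stream-splitting
scheme, so identical calls are bit-for-bit reproducible.

## Limitations

* The copula estimator family captures rank (second-order) dependence; it
  cannot see purely multiplicative interactions, and saturates below
  `H(tau)` for discrete tasks (see above).
* Percolation significance is topological; magnitude significance comes
  from the asymptotic chi-squared floor, which assumes trial counts large
  enough for the asymptotics (hundreds of trials).
* The noise floor's `df = 5` default is conservative for pairwise estimates
  with few task classes; many-class discrete tasks may warrant a larger
  value.
* Model-rank selection inherits the resolution limit of modularity at
  `gamma = 1`.
* Factor-recovery guarantees require identifiable (separable) structure;
  on non-identifiable tensors the decomposition is still a valid
  approximation, but factor-wise comparisons across fits are only
  meaningful after matching, and similarity below one may reflect
  rotational freedom rather than instability.
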