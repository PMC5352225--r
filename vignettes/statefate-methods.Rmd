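---
title: "Methods: discrete cell states, lineage triplets and threshold-network ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete cell states, lineage triplets and threshold-network ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Single-cell UMI data from a differentiation time course is sparse and
high-dimensional. The package's premise is that cells occupy a small
number of *discrete states* connected by a lineage tree, and that a small
set of transcription factors — *marker* genes (highest in one state of a
local triplet) and *transition* genes (lowest in one state) — both reveal
the states and parameterize a predictive model of the regulatory network.

## Preparation

Wells with fewer than 20,000 total UMIs are discarded (the default
mirrors plate-based quality thresholds). Retained cells are downsampled
to exactly 20,000 UMIs by a multivariate hypergeometric draw — sampling
UMIs *without replacement* is the correct semantics for deduplicated
molecule counts; with-replacement sampling would inflate dispersion.
Normalization is `log2(count + 1)`; base and pseudocount are conventions,
chosen once and used everywhere.

## The triplet likelihood

For one gene and one triplet of clusters, the package pools the gene's
log expression over the triplet's cells and fits a two-component
(low/high) Gaussian mixture by EM (vectorized across genes; sd floor 0.05
to avoid singular components; 30 iterations). Cluster-level posteriors

q_k = P(cluster k is collectively "high")

are the renormalized products of per-cell component posteriors. The eight
joint high/low configurations of the three clusters partition unit mass:
"only k high" is the marker-for-k likelihood, "only k low" the
transition-low-in-k likelihood, and the two uniform configurations carry
the null. Prior odds (default 5e-2 for the transition class; the marker
class reuses that value, since only the transition prior is stated in the
source analysis) reweight the classes into posteriors that sum to one.

Two *evidence gates* make this model honest on UMI data:

* `min_sep` (default 1 log2 unit): a gene whose two mixture components
  are closer than this is not "well separated" and carries null mass
  only. Without the gate, the per-cell product turns tiny compositional
  shifts (library-size renormalization moves every gene a little when
  cluster compositions differ) into spurious certainty.
* `min_high_mean` (default 2.5, i.e. ~5 UMIs at 20,000 depth): a gene
  whose "high" component sits in the low-count quantization regime
  (log2 of 0/1/2 counts) is uninformative; apparent separation there is
  a discreteness artifact.

Both are tunable parameters of `gene_class_posterior()` /
`triplet_result()`.

## Topology votes

A transition gene is, by the lineage logic, expressed in the intermediate
state; its transition-low-in-k mass is therefore incompatible with "k is
intermediate". The topology posterior is

P(T = k | data) ∝ P(T = k) · ∏ᵢ (1 − p_transition,ᵢ(k)),

computed in log space. This product form is exactly the brute-force sum
over all joint gene-class assignments (asserted against an enumeration
oracle in the tests). Posteriors of 0.5 (gene classes) and 0.6 (triplet
topologies) are the defaults used downstream.

## Iteration and convergence

The loop alternates triplet inference over all cluster triplets (clusters
below 5 cells are skipped, not imputed) with re-clustering in the
subspace of genes that are high-probability marker/transition genes in at
least one confident triplet. Convergence is declared when the cluster
assignment is unchanged (ARI = 1) or the gene set's Jaccard change drops
below 0.10. The source analysis parenthetically describes convergence as
"gene count below 10% of all TFs", which contradicts its own final gene
count (889 of 2672 ≈ 33%); assignment stability is the criterion actually
used here, logged per iteration.

Clustering backends: `kmeans_gap` (default) chooses k by the gap
statistic — log within-dispersion against uniform reference draws over
the feature box, smallest k with Gap(k) ≥ Gap(k+1) − s(k+1) — and
`embed_density` (top-10 PCA, a 2-D embedding, density clustering). The
default is k-means because the final configuration is expected to be
method-independent; the embedding backend uses t-SNE when `Rtsne` is
installed and falls back to the first two PCs (the exact embedding of the
original toolchain is not reproduced, a declared non-goal). All k-means
calls are "best-of": random restarts plus one deterministic run seeded
from Ward-linkage hierarchical centers. This matters: a single bad
k-means optimum at the true k inflates W_k, masks the gap maximum, and
can silently merge sibling states.

## Tree assembly

Over spanning trees of the clusters, the package maximizes
Σ [log P(T = median) − log(1/3)] across triplets whose tree-median is one
of the triplet's members. The −log(1/3) reference makes triplets that the
tree leaves undetermined score-neutral; without it, trees would be
rewarded for *avoiding* determined triplets (any log posterior is
negative). Search is exhaustive via Prüfer enumeration for ≤ 7 clusters
and greedy edge-exchange hill climbing from the best chain otherwise;
both routes are compared in the tests.

## Discreteness test

Per cluster, observed PC1 variance is compared with the maximum PC
variance over randomizations in which each gene's values are permuted
independently across the cluster's cells — the standard PCA null that
keeps marginals and breaks gene-gene correlation. A ratio above 1 flags
sub-structure; the merged-pair property (concatenating two planted
clusters scores higher than either alone) is asserted on synthetic data.

## Binarization into modules

Genes supported only by *indirect* triplets (a state skipped along some
pairwise tree path) are removed. Local calls — marker: 1 in its cluster,
0 in the other two; transition: 0 in its lowest cluster, 1 in the other
two — are taken only from direct triplets whose inferred topology agrees
with the assembled tree, because the class labels are defined conditional
on that topology. Genes sharing a local pattern are grouped; remaining
states receive 1 when the group's mean log expression is within 10%
(multiplicatively, on the log scale — the scale is a documented choice,
auditable via the `tolerance` argument) of the lower locally-high level,
inclusive at the boundary. Three-level genes resolve to {medium, high} →
1. Conflicting local calls raise an error by default; the pipeline
instead drops such genes with a warning naming them, since on noisy data
an occasional spurious call should not abort an end-to-end run.
Signalling pathways (LIF/BMP/WNT/FGF) are binarized from their mean
member profile anchored at its maximum (they carry no triplet calls) and
appended as named rows even when the pattern duplicates a TF module; the
duplicate is recorded as an alias and collapsed to a single variable for
modeling, where identical rows would make couplings unidentifiable.

## The threshold network and its ensemble

States are fixed points of mᵢ = H(Σⱼ Jᵢⱼ mⱼ − φ₀), with H(0) = 1, τ = 1,
basal rate 0, and the hard-threshold (μ → ∞) limit. Each module/state
pair yields one inequality — drive ≥ φ₀ for expressed modules, < φ₀
otherwise; strictness is encoded with a slack ε = 1e-6, since linear
programs cannot express strict inequalities. With |Jᵢⱼ| ≤ 1 and φ₀ = 0.1
the system is sampled by: draw aᵢⱼ ~ Bernoulli(0.5), impose the cut
Σ aᵢⱼJᵢⱼ ≤ 0 (a hyperplane through the origin that exposes an interior
face of the polytope), and maximize Σ aᵢⱼJᵢⱼ; infeasible cuts are redrawn
so the ensemble always has the requested size, with retry counts kept.
All returned solutions are treated as equally likely. The LP itself is a
dense two-phase primal simplex written for this package (no LP solver is
otherwise available in the target environment), validated against grid
oracles and hand cases.

One consequence of the model worth stating: because a module's own value
enters its drive, *any* binary state matrix is feasible when
0 < φ₀ ≤ |J|max (the row J = eᵢ separates every on/off split).
Infeasibility therefore only arises for φ₀ outside the reachable drive
range — the diagnostic localizes it per module row, which is possible
because each inequality touches a single row of J.

## Perturbations

Overexpression clamps a module at 1 + Δs (default grid 0–2 by 0.1): the
clamped level feeds the drives but the module is not updated. Each
model's trajectory is iterated until the first repeated state; on a limit
cycle the target counts as "down" only if it is 0 on every cycle state
(the source is silent on limit cycles; this is the documented rule).
Whether to read the outcome at a fixed point or a fixed horizon was open;
cycle detection subsumes both for deterministic maps.

Signal addition clamps modules at 1 and propagates a probability
distribution under the ensemble-averaged kernel 𝒯 (each model contributes
weight 1/n to each support state's image). The full 2^N × 2^N matrix is
never built; the sparse distribution over the reachable support is
propagated lazily (in C++), which is mathematically identical on that
support — asserted against dense 2^N propagation to 1e-9 on small
instances. Mass below `prob_floor` (default 1e-8) is truncated and
reported; propagation stops early once the distribution is exactly
stationary. Support can grow combinatorially for harsh clamps on large
module sets; the `support_cap` guard then asks for a higher floor rather
than thrashing.

## The synthetic world

`lineage_config()` states the world the generator emulates: 9 states on
the bifurcating tree C0–C1–{C2–C4–{C7,C8}, C3–{C5,C6}}, 32 cells per
state (288 total), 300 genes — 12 markers per state, 4 transition genes
per (direct triplet, low state) slot, the rest housekeeping background
spanning moderate-to-high constant expression so that it carries most of
the library mass and per-state composition stays comparable, as in real
transcriptomes. Counts are negative binomial (shared dispersion 10;
`Inf` gives the Poisson limit) scaled to library sizes drawn from
30,000–60,000 UMIs, comfortably above the 20,000 filter. Planted effect
sizes are 5 vs 1 log2 units — strong, clean signals. A green test on this
world establishes that the machinery recovers planted structure under
NB noise and composition effects; it does not establish robustness to
doublets, ambient RNA, batch effects, or continuous (non-discrete)
differentiation, none of which are simulated.

`generate_grn_instance()` draws J uniformly in [−1, 1] until the network
has the requested number of nonzero fixed points (exhaustive enumeration
up to 16 modules, iterated updates above) whose constraints hold with a
margin, so the instance is feasible for the sampler with J itself as a
witness. With few states, distinct modules frequently share state
patterns; such duplicates are accepted by the constraint builder (they
are mathematically benign) while *named* aliases are collapsed in the
pipeline.

## Known limitations

* The triplet likelihood is this package's concrete construction (the
  source defers its exact form to companion work); it is exposed behind
  one interface so alternatives can be swapped.
* Exact reproduction of the published ensemble fractions requires the
  deposited module × state table, which is not redistributable here; the
  drop-in path (`read_state_matrix()`, `pipeline_config(modules_file=)`)
  is implemented and the corresponding acceptance test reports an honest
  failure when the file is absent.
* Uniform (hit-and-run) polytope sampling, finite-μ sigmoidal dynamics
  and asynchronous-update stability are out of scope.
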