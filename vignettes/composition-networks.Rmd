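---
title: "Inferring cell type interaction networks from case-control compositions"
author: "InterCellBN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell type interaction networks from case-control compositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(InterCellBN)
```

# The problem

When two cell populations interact in a tissue, a change in the abundance
of one tends to be accompanied by a change in the abundance of the other.
Case-control single-cell RNA-seq studies measure exactly the right raw
material for this idea: for every biological sample we obtain the fraction
of cells assigned to each annotated cell type. InterCellBN turns those
per-sample compositions into a directed network over cell types, scores
how robustly each directed pair is supported, contrasts the case and
control networks, and then asks *which ligands* could mediate each
inferred interaction, using a sparse regression against a ligand-target
regulatory potential matrix (NicheNet-style prior knowledge).

The pipeline has four stages, each usable on its own:

1. **Composition** (`computeFractions`): per-sample cell type fractions,
   with an abundance filter (types with fewer than `minCells = 100`
   pooled cells are dropped from the columns but still count in each
   sample's denominator).
2. **Discretization** (`discretizeFractions`): each cell type's fraction
   vector is binarized into a low/high abundance state by a
   two-component Gaussian mixture with a type-specific cutoff.
3. **Network** (`learnNetwork` under `bootstrapEdges`): a discrete
   Bayesian network over the binary states, learned by a
   restrict-maximize scheme and scored by repeated learning on cell
   subsamples; `differentialEdges` contrasts conditions.
4. **Ligand-target regression** (`ltrForPair`): for a directed pair
   A → B, a LASSO with one shared activity coefficient per ligand
   predicts the expression changes of target genes in B from the ligand
   expression changes in A folded through the prior matrix.

# Models and estimators

## Discretization

For cell type $i$ with fractions $x^i_1,\dots,x^i_N$ over $N$ samples we
maximize the two-component mixture likelihood

$$\ell^i = \sum_{n=1}^N \log\!\Big(\sum_{k=0}^{1}
  \pi_k\,\mathcal N(x^i_n;\,\mu_k,\sigma_k^2)\Big)$$

by EM (`fitGMM2`; at most 500 iterations, convergence threshold $10^{-4}$,
variance floor $10^{-8}$). The component with the smaller mean is state 0.
Labels are produced by a *single cutoff* placed at the posterior decision
boundary between the two means: with unequal variances the raw posterior
rule can be non-monotone in the fraction (the far tails flip back to the
wide component), while a cutoff matches the intended semantics — every
sample below the type-specific cutoff is 0, every sample above it is 1.
The number of 0s and 1s per type is unconstrained and may be heavily
skewed. Degenerate columns (constant values, vanished component) fall
back to a midpoint split at $(\min + \max)/2$, which is also available
as an explicit strategy.

Two estimator details matter at realistic sample counts (tens of
samples per condition):

* **Log scale.** Fractions share a per-sample renormalizing denominator,
  so their noise is multiplicative; on the raw scale the high-abundance
  cluster is systematically wider than the low one and the maximum
  likelihood fit can genuinely prefer splitting the wide cluster rather
  than the gap between the regimes. `discretizeFractions` therefore fits
  the mixture to log fractions by default (`transform = "identity"`
  restores the raw scale). The decision is still one cutoff on the
  fraction scale.
* **Bounded variance ratio.** With a few dozen points a free
  two-variance mixture can pay for splitting off a tight sub-cluster of
  one regime with an extreme variance ratio. `discretizeFractions`
  bounds $\sigma_{\max}/\sigma_{\min} \le 3$ (`maxSdRatio`); the
  constrained M-step maximizes the expected log-likelihood on the
  boundary, so the EM ascent property is preserved. `fitGMM2` itself
  defaults to free variances.

`looStability` quantifies how much any single sample drives the
binarization: each sample is labeled by a mixture refit without it, and
the per-type agreement with the all-sample labeling is reported.

## Structure learning

Over the binary abundance matrix $D$ ($N$ samples, $Q$ types) we learn a
directed acyclic graph by maximizing the BIC

$$\mathrm{BIC}(G) = \log P(D \mid \hat\Theta, G)
  - \tfrac12\,\mathrm{Dim}(G)\log N,
  \qquad \mathrm{Dim}(G) = \sum_q 2^{|\mathrm{Pa}(q)|},$$

with maximum-likelihood conditional probability tables $\hat\Theta$ (one
free parameter per parent configuration of a binary node). The search is
restrict-maximize:

* **Restrict** (`hitonPC`): per target, other nodes are ranked by
  marginal $G^2$ association and admitted greedily; admitted nodes that
  become conditionally independent of the target given some subset of
  the other admitted nodes (subsets up to `maxCondSize = 3`) are
  removed, and the per-node sets are symmetrized by intersection. Tests
  with any expected cell count below 0.5 are treated as inconclusive:
  they never admit a node and never remove one.
* **Maximize** (`hillClimb`): greedy BIC ascent from the empty graph
  with add / delete / reverse moves, additions restricted to the
  screened skeleton, acyclicity checked per move, ties broken
  lexicographically by (source, target, move type) so the search is
  fully deterministic. When no single move improves the score, one
  composite move is considered — taking in a *pair* of parents for a
  common child, by addition or reversal — which is the v-structure
  escape: two marginally independent parents of a collider offer no
  single-edge foothold, yet the joint move can raise the score. Every
  accepted move, single or composite, strictly increases the BIC.
  Incremental family scores are used; `debug = TRUE` cross-checks every
  accepted move against a full recomputation.

Two thresholds deserve comment. The *admission* level `alpha` is the
false-edge control of the whole pipeline: with $N \approx 30$ samples and
$\binom{Q}{2}$ on the order of 50–100 pairs, a 5% level admits about two
chance associations per network, and because the bootstrap below
resamples *cells* (the per-sample states barely change), a chance
association among the fixed state vectors persists across all bootstrap
iterations and sails past any count threshold. The default is therefore
`alpha = 0.003`, which keeps the expected number of persistent chance
links per network well below one while the direct dependencies of
interest (state agreement around 90%, marginal $G^2 \approx 15$–25) pass
comfortably. The *elimination* level `elimAlpha` plays the opposite
role — an admitted neighbour should be dropped as soon as some
conditioning set renders it plausibly independent — and can usefully be
set above `alpha`.

A structural caveat: strong interactions make cell types near-copies of
one another, which violates the faithfulness assumption behind
conditional-independence screening. Conditioning on a near-copy of the
target can screen off the target's other true neighbours. The screening
is therefore deliberately conservative at small $N$ (inconclusive tests
keep nodes), and the BIC maximization, not the screening, arbitrates
between direct and indirect explanations.

## Bootstrap confidence and differential edges

`bootstrapEdges` repeats the whole composition → discretization →
learning chain `nIter = 100` times on random 80% cell subsamples (drawn
without replacement) of one condition, and counts how often each
*directed* edge is returned. The retained type set is fixed on the full
condition so every iteration scores the same nodes. The mixture-fit seed
is shared across iterations so that the only per-iteration randomness is
the cell subsample (`cellFrac = 1` is exactly reproducible).

`differentialEdges` takes the union of pairs reaching a count of
`threshold = 20` in either condition and scores them as case count minus
control count; `enhancementAnalysis` asks whether adding an independent
dataset preserves the sign and increases the magnitude of those scores,
and `permutationTest` calibrates the enhanced-pair fraction against a
null in which each new-data sample's type labels are permuted across
types (destroying type-type covariation, keeping each sample's value
multiset; permuting within type across samples is available as the
alternative axis). The p-value uses the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$ and is
never exactly zero.

## Ligand-target regression

For a directed pair A → B with ligand expression changes $L(l)$ in the
sender and target expression changes $T(t)$ in the receiver, we solve

$$\min_\alpha \sum_t \Big(\sum_l I(t,l)\,L(l)\,\alpha(l) - T(t)\Big)^2
  + \lambda \lVert\alpha\rVert_1,$$

a standard LASSO in the folded design $A(t,l) = I(t,l)L(l)$
(`buildDesign`), where $I$ is the ligand-target regulatory potential
matrix. One activity $\alpha(l)$ is shared by *all* targets, so held-out
targets are predictable and the model is evaluated by target-wise
five-fold cross-validation (`fitLTR`): per fold, $\lambda$ is selected on
a single 50/50 split of the training targets over a 100-point grid
descending four decades from the smallest all-zero penalty, the model is
refit on the full training fold at the chosen $\lambda$ (solver:
glmnet's coordinate descent), and the held-out Pearson correlation is
recorded. Columns are not standardized — activities stay interpretable
against the regulatory-potential scale — and an intercept is included.
A fold whose coefficients are all zero contributes no correlation; a fit
in which every fold is all-zero is *degenerate* and excluded from all
correlation summaries. Ligands are ranked by the mean over folds of
$L(l)\hat\alpha(l)$ (`rankLigands`).

Both $L$ and $T$ default to log fold changes between the contrasted
conditions, $\log\{(\bar x_{\text{case}} + 1)/(\bar x_{\text{ctrl}} +
1)\}$, computed per cell type (`conditionLFC`); a raw-level mode
(`mode = "levels"`) is available. The target universe is the genes
present in both the prior matrix and the dataset, minus the ligand genes
themselves (no leakage of predictors into the response). Two controls
accompany every fit: the *autocrine* control refits with the receiver's
own ligands (`sender := receiver`), and the *shuffled-matrix* control
permutes all entries of $I$ and refits, which should collapse most fits
to the all-zero solution. `bnLtrAgreement` joins the two evidence
channels per pair — log bootstrap count against mean held-out
correlation (or held-out MSE with `statistic = "mse"`), pairs below the
count threshold and degenerate fits removed.

# The synthetic-data generator

`makeTruth` and `simulateDataset` generate annotated case-control
datasets from a known ground truth so every stage of the pipeline can be
validated end to end. Per sample, a joint binary abundance state is
drawn from the truth network by ancestral sampling; states map to raw
fraction weights ($\mathcal N(0.03, 0.005^2)$ for low,
$\mathcal N(0.12, 0.005^2)$ for high); weights are renormalized to sum
to one; cell counts are multinomial; each cell gets Poisson expression
(rate 2.5 on its type's five private marker genes, 0.15 elsewhere, over
a 200-gene panel); and finally each observed count is zeroed with the
dropout probability. The per-cell `cell_type` annotation handed to the
pipeline is then *re-derived from the observed counts* by a
nearest-marker-score classifier (argmax of summed marker counts), with
the generating type kept in `true_type`. This is the channel through
which expression-level dropout corrupts the composition analysis, as it
does in real data where annotation also works on the observed counts.

Design choices a user should know about:

* **Background anchor.** Compositions are closed — fractions sum to 1 —
  so if every type in the tissue switched between the same low/high
  regimes, the aggregate state would be absorbed into the shared
  denominator: an all-low sample would be indistinguishable from an
  all-high one, and every fraction would carry the aggregate state of
  the others (we observed exactly this as false-positive hubs and up to
  40% discretization error in an unanchored generator). Real tissues
  contain large stable populations, and the generator models them: three
  background cell types (`BG01`…, total raw weight 1, per-type spread
  0.1, outside the truth network) anchor the denominator. The anchor is
  split over several types with independent weights so that no single
  observed column mirrors the residual common mode.
* **Signed interactions.** Each type has a polarity: its abundance
  state switching on either promotes it (state 1 maps to the high
  fraction regime) or suppresses it (state 1 maps to the low regime).
  The default alternates polarity along each cascade. Besides being
  what real interactions look like, this also removes the coherent part
  of the denominator confounder: with all-positive polarity the
  correlated types of a cascade would move together and their aggregate
  state would leak into every other type's fraction.
* **Fixed cascade topology.** The default truth is one fixed network —
  two three-type cascades (CT01→CT02→CT03, CT04→CT05→CT06) and two
  isolated interactions (CT07→CT08, CT09→CT10) — so replicate runs vary
  only the data. Its maximum degree of 2 is deliberate: children of a
  hub are near-copies of each other, and at 30 samples the sampled
  sibling-sibling dependence can genuinely exceed a true hub edge's
  dependence, a structure misidentification no learner can avoid.
  `topology = "random"` draws a random forest (in-degree ≤ 1) instead;
  multi-parent DAGs are possible above `nTypes - 1` edges, but note
  that a single parent behind a two-parent OR/AND gate is marginally
  almost undetectable at realistic sample counts.
* **Heterogeneous interaction strengths.** Each child copies its parent
  with flip probability 0.1, except the last planted interaction
  (CT09→CT10) which uses 0.35 (`weakEdgeFlip`): real interaction
  strengths are heterogeneous, and this places one interaction near the
  detection boundary of composition data at 30 samples per condition.
* **Heterogeneous marker strength.** Marker expression also varies
  between real cell types, and transcriptionally subtle types are the
  first casualties of dropout. The types of the first isolated
  interaction (CT07, CT08) carry subtler markers
  (`subtleMarkerExpr = 0.58` vs 2.5) and their interaction is of
  moderate strength (`subtleEdgeFlip = 0.17`): at full sequencing depth
  they are annotated well and the interaction is usually recovered, but
  at 50% dropout their cells are scrambled and the interaction is lost.
  It is an isolated interaction, so its loss leaves no two-step shadow
  that could surface as a false edge. Together with the strong cascades
  and the weak CT09→CT10 edge this forms a graded difficulty ladder.
* **What the generator does not emulate:** library-size variation, batch
  effects, gene-gene correlation beyond marker structure, doublets, or
  annotation errors other than marker-score confusion. Passing the
  simulation study therefore shows that the chain of estimators works
  under controlled conditions; it does not certify performance on any
  particular real dataset.

The validation experiment (`cmdValidate`, and `scripts/acceptance.R` in
the repository) uses 30 samples per condition, 1000 cells per sample,
100 bootstrap iterations on 80% cell subsamples, count threshold 20, and
five data replicates per dropout rate; recovery is scored undirected by
default (`evaluateRecovery`) because edge directions inside a Markov
equivalence class are not identifiable, with a direction-sensitive mode
available.

# A small worked example

```{r example, eval = FALSE}
truth <- makeTruth()                       # fixed 10-type, 6-edge truth
sce <- simulateDataset(truth, nSamples = 30, cellsPerSample = 1000,
                       seed = 1)
ect <- bootstrapEdges(sce, "case", nIter = 100, seed = 2)
evaluateRecovery(ect, truth, threshold = 20)
```

# Numerical and degenerate-input policy

* EM: k-means++-style two-point initialization under the given seed;
  per-column seeds derived deterministically from the master seed;
  log-space E-step; the log-likelihood trace is exposed and asserted
  non-decreasing in the test suite.
* Cutoff: located by root finding on the posterior log-odds between the
  two means; if one component dominates throughout, the cutoff collapses
  to the nearer mean. The maximum observation is never labeled 0.
* Zero fractions are floored at half the smallest positive value of
  their column before taking logs.
* Hill climbing accepts a move only if it improves the BIC by more than
  1e-9; the accepted-move score sequence is strictly increasing.
* An inconclusive independence test (expected count < 0.5 in a stratum)
  neither admits nor removes a node.
* A bootstrap iteration in which a sample loses all cells is redrawn
  once, then raises an error naming the iteration.
* LASSO designs in which every usable predictor is constant yield the
  all-zero (degenerate) fit rather than an error.

# Limitations

* Composition data carry no information about the common mode of the
  tissue: only relative changes are observable, and denominator-induced
  coupling between unrelated types is a structural confounder of any
  composition-network method. The abundance filter, the screening level
  and the bootstrap threshold control, but cannot eliminate, it.
* Edge directions are reported as learned, but within an equivalence
  class they reflect the deterministic tie-break, not causal evidence.
* At tens of samples, interactions whose marginal association falls at
  the chance level are undetectable in principle; the weak planted edge
  of the simulation makes this visible.
* The ligand-target regression inherits the biases of the prior matrix;
  a ligand absent from the prior cannot be recovered.
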