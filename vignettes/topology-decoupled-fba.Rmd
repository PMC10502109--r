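---
title: "Topology-decoupled constraint-based modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-decoupled constraint-based modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoupleFBA)
```

This vignette documents the mathematical model implemented by
`decoupleFBA`, the parameters and numerical choices it commits to, the
design decisions behind the implementation, and its known limitations.

## 1. The underlying model

A metabolic model is a stoichiometric matrix $S \in \mathbb{R}^{m
\times n}$ with flux bounds $l \le v \le u$ and a linear objective
$c^\top v$. Flux balance analysis (FBA) solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; l \le v \le u.$$

Parsimonious FBA (pFBA) fixes the FBA optimum and minimizes total
absolute flux $\lVert v \rVert_1$ within it, implemented with split
non-negative variables. Flux variability analysis (FVA) minimizes and
maximizes each flux subject to the objective staying above a fraction
of the optimum (default fraction 1).

The central idea of the package is that densely coupled substructures
of the network — reactions that share many directed simple cycles of
the bipartite metabolite–reaction graph — dominate the size and
degeneracy of the flux polytope. Each such cluster is replaced by a
small set of sparse null-space basis vectors, one new "linear basis
reaction" (LBR) per vector, giving a reduced model whose solutions map
linearly back to original-reaction fluxes.

## 2. Topology: cycle similarity and weighted-cut clustering

`coupling_graph()` builds the bipartite digraph with one node per
metabolite and per reaction: each irreversible reaction contributes
arcs substrate → reaction → product; reversible reactions contribute
arcs in both orientations.

`cycle_similarity()` counts, for every reaction pair $(i, j)$, the
number of orientation-consistent simple directed cycles through both
reactions, with cycles capped at 12 reaction nodes by default. Design
choices:

* A cycle may use each reaction once, in one orientation. The trivial
  reversible "back-and-forth" through a single reaction is excluded;
  two antiparallel reactions do form a valid 2-cycle.
* Enumeration is anchored at the minimal metabolite node of each cycle
  so every cycle is counted exactly once.
* The length cap (12 reaction nodes) bounds the exponential
  enumeration; it is a tunable argument. The test suite verifies the
  implementation against an independent oracle built from
  direction-split simple paths in `igraph`.

`wcut()` scores a partition $\{C_1, \dots, C_K\}$ of the coupled
reactions by

$$\mathrm{WCut} = \sum_k \frac{\mathrm{Cut}(C_k, \bar C_k)}{D_k},
\qquad D_k = \sum_{i \in C_k} D_i,$$

where $D_i$ is the total similarity of reaction $i$. Reactions with
$D_i = 0$ participate in no cycle and are classified non-coupled (their
cluster is `NA`); they pass through the reduction untouched.

`best_wcut_cluster()` minimizes WCut by spectral embedding of the
normalized similarity matrix followed by k-means and a greedy
single-move refinement, for each candidate $K$ in `k_range` (default
2–8):

* k-means is seeded deterministically from the `seed` argument and the
  candidate $K$, so results are reproducible.
* The chosen $K$ minimizes WCut; ties are broken toward the **larger**
  $K$ (finer partitions are preferred because smaller clusters give
  cheaper sparse-basis problems).
* Clusters are required to contain at least `min_size = 2` reactions;
  a single reaction participates in no decoupling worth doing.
* A model with no cycles at all yields $K = 0$ with a warning, and
  `decouple_model()` then degenerates to the identity reduction.

## 3. Sparse linear bases

For each cluster $C_k$, `build_cluster_submodel()` extracts the
submatrix $S_k = S[\cdot, C_k]$ restricted to metabolites touched by
the cluster, and augments boundary metabolites (those also produced or
consumed outside the cluster) with artificial exchange columns
(coefficient $-1$, bounds $\pm 1000$) so that internal flux through
the cluster remains feasible in isolation. The basis dimension is
$r_k = |C_k| - \operatorname{rank}(S_k)$, with rank computed by SVD at
tolerance $10^{-9} \sigma_{\max}$.

`sparsify_nullspace()` finds $r_k$ minimal-support null-space vectors
by iterated linear programming: minimize $\sum_i x_i$ with $x \ge |N|$
elementwise, subject to $S_k N = 0$ and a normalization
$|w^\top P v| \ge \zeta$ ($\zeta = 10^{-3}$) that excludes the span of
previously found vectors. Both signs of the normalization are solved
and the sparser solution kept, ties broken toward the positive branch.
Each vector is rescaled to $\max_i |N_i| = 1$ and entries below
$10^{-7}$ truncated to exact zeros. The test suite checks minimal
support against a brute-force combinatorial oracle for $r_k \le 6$.

## 4. The decoupled model

`assemble_decoupled_model()` forms

$$S_{\mathrm{red}} = \left[\, S_{\mathrm{NC}} \;\middle|\; S[\cdot, C_1]
N^*_1 \;\middle|\; \cdots \;\middle|\; S[\cdot, C_K] N^*_K \,\right],$$

with one LBR column per basis vector. LBR bounds are the intersection
over the vector's support of the element-reaction intervals divided by
the basis coefficient (signs swapped for negative coefficients); the
objective maps through $N^{*\top} c$. Clusters with $r_k = 0$ have no
internal degrees of freedom and their reactions pass through
unchanged. `recover_element_fluxes()` maps a reduced solution back via
$v_{C_k} = N^*_k \, v_{\mathrm{LBR},k}$.

Two structural guarantees are enforced by the acceptance tests:
on cluster-free models the reduction is the identity (objectives agree
to $10^{-9}$), and recovered element fluxes always satisfy the original
steady state to $10^{-6}$.

## 5. The LP backend

All LPs are solved by a self-contained dense two-phase tableau simplex
(`R/lp.R`) with Bland's anti-cycling rule. Notable numerical choices:

* Bounds are clamped to $\pm 10^6$ (standing in for $\pm\infty$).
* Variables are shifted by their lower bound ($x = v - l$) so the
  tableau is in standard non-negative form; upper bounds become
  $\le$ rows.
* Linearly dependent equality rows are removed by QR factorization of
  $A_{\mathrm{eq}}^\top$ before solving; dropped rows are re-verified
  on the solution and an inconsistency is reported as infeasible.
* Phase 1 minimizes the sum of artificial variables (only for $=$ and
  $\ge$ rows); a positive phase-1 optimum above $10^{-7}$ means
  infeasible. Residual zero-level artificials are pivoted out before
  phase 2.

A dense tableau is adequate for the toy-to-medium problem sizes the
package targets; see Limitations.

## 6. Regulation and kinetics

**Regulated-gene discovery.** `fit_plsr()` regresses log gene
expression on log biomass-constituent metabolite concentrations by
partial least squares (via `mixOmics::pls`), choosing the number of
components by leave-one-out prediction error when not given.
`select_regulated_genes()` thresholds the per-gene correlation between
observed and fitted expression: total-fit correlation $\ge 0.84$ and
first-component correlation $\ge 0.38$ by default. At least three
predictor metabolites and three strains are required (a hard
requirement of the PLS implementation, surfaced as an informative
error).

**Sampling significance.** `sampling_significance()` compares the
PLSR fit statistic of a candidate metabolite selection against random
same-size selections from the candidate pool, with
$p = (1 + \#\{\text{null} \ge \text{obs}\}) / (n_{\mathrm{draws}} + 1)$.
The optional `genes` argument restricts the fit statistic to a gene
subset (typically the regulated genes); without it, genes driven by
other metabolite blocks dilute the statistic. The acceptance test
checks calibration: p-values for random selections are approximately
uniform.

**Classifying regulator metabolites.** `classify_regulators()`
clusters candidate metabolites by average-linkage hierarchical
clustering of their gene-correlation profiles, cutting at $K = 2$ and
labeling as biomass constituents the group whose members correlate
more strongly with growth rate (or containing `bg_hint`). The distance
between profiles is **Euclidean**, not $1 - \mathrm{cor}$: correlation
distance is invariant to the magnitude of a profile, which is exactly
the signal that separates growth-coupled from non-coupled metabolites,
and it is undefined for near-constant profiles.

**Linearized kinetics.** For a reversible reaction with substrate $S$,
product $P$, equilibrium constant $k_{\mathrm{eq}} =
\exp(-\Delta G^0 / RT)$ (with $RT = 8.314462618 \times 10^{-3} \cdot
298.15$ kJ/mol), `build_kinetic_design()` builds the regression
design

$$\log v \sim \log[\mathrm{BG}_j] + \log\!\big(1 - (P/S)\,
k_{\mathrm{eq}}\big) + (P/S)/k_{\mathrm{eq}} + 1/[\mathrm{A}],$$

with one log-concentration column per biomass constituent, a
saturation term, a mass-action term, and a reciprocal column per
activator. A convention note: the saturation argument is written as
$1 - (P/S) k_{\mathrm{eq}}$, so "at equilibrium" corresponds to
$(P/S) = 1/k_{\mathrm{eq}}$; strains at or beyond that point make the
logarithm undefined and are excluded with a record in the `excluded`
attribute. `fit_linear_kinetics()` uses OLS on an 80/20 train/test
split, falling back to ridge regression with a warning when the number
of training strains is below twice the number of regressors.
`predict_kinetic_flux()` returns fluxes with a default 5% tolerance
band, which `solve_kinetic_fba()` imposes on the decoupled model as a
pair of box constraints per reaction, expressed through the LBR
mapping coefficients.

## 7. Synthetic generators

Problem sizes and distributions in `synth_network()`,
`synth_random_network()`, and `synth_omics()` are the package's own
choices, tuned for fast, well-conditioned property tests rather than
realism at genome scale:

* `synth_network()` plants closed cycles (ground-truth clusters, each
  with the all-ones vector as its one-dimensional sparse basis), a
  linear uptake–biomass chain, and optional acyclic bridges.
* `synth_omics()` draws a strain panel from the package's generative
  laws: log-normal metabolite concentrations, the multiplicative
  biomass growth law $R = \lambda \prod_j (1 + M_{bj}/K_{mj})^{\theta_j}$,
  growth-coupled log-linear expression for regulated genes, and fluxes
  from the full reversible rate law (not its linearization) with
  substrates held above their affinity constants and products clearly
  below equilibrium — the regime in which the log-linearization is
  accurate.

## 8. Limitations

* The dense tableau simplex scales to hundreds of columns, not
  genome-scale models with tens of thousands of reactions; for those a
  sparse industrial LP solver would be needed behind the same
  interface.
* Exhaustive cycle enumeration is exponential in the length cap;
  the default cap of 12 reaction nodes is practical only for networks
  up to a few hundred reactions.
* Minimal-support basis extraction uses an L1 relaxation with a
  normalization side-constraint; it is verified exact on the tested
  problem classes ($r_k \le 6$) but carries no general optimality
  guarantee for L0 support.
* The kinetic regression covers one substrate/product pair per
  reaction plus optional activators; multi-substrate rate laws are out
  of scope.
* `classify_regulators()` assumes the two metabolite groups differ in
  the magnitude of their gene-correlation profiles; panels where both
  groups drive disjoint gene sets with similar strength are not
  separable by this statistic.
* SBML support targets Level 3 with the flux-balance-constraints (FBC)
  package; kinetic laws, compartments beyond identifiers, and
  annotations are not preserved.
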