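---
title: "Regularized simultaneous component analysis of multiblock data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized simultaneous component analysis of multiblock data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Multiblock (linked) data are $K$ matrices $X_k$ ($I \times J_k$) measured
on the *same* $I$ samples but different variable sets — multiple omics
layers on the same subjects, questionnaire batteries filled in by members
of the same family, chemistry and sensory panels on the same food samples.
Simultaneous component analysis (SCA) decomposes all blocks with a single
orthonormal score matrix,

$$X_k = T P_k^\top + E_k, \qquad T^\top T = I_R,$$

so components are directly comparable across sources. The unpenalized
solution is the truncated SVD of the concatenated data $[X_1 \cdots X_K]$.

Plain SCA cannot say *which* variation is shared: every variable loads on
every component. `blocksca` therefore fits the penalized problem

$$\min_{T,P_k}\ \sum_k \lVert X_k - T P_k^\top \rVert^2
  + \lambda_L \sum_k \lVert P_k \rVert_1
  + \lambda_G \sum_k \sqrt{J_k}\, \lVert P_k \rVert_2 ,$$

where the Group Lasso term is taken either over whole blocks
(`method = "block"`) or over each component within each block
(`method = "component"`, the default). A component whose loadings are
entirely zero in some block is *distinctive* (variation specific to the
other sources); a component with at least one nonzero loading in every
block is *common*. The Lasso adds within-component sparsity on top.

Because $T$ is orthonormal, the conditional problem in the loadings is a
sparse Group Lasso with an orthogonal design and has a *closed-form*
solution: soft-threshold the OLS loadings, then multiply the group by the
positive-part factor $[1 - \lambda_G\sqrt{J_k}/(2\lVert S \rVert)]_+$.
Zeros are exact (bit zeros), not rounded approximations — this is what
makes the common/distinctive classification well defined. Given the
loadings, the optimal $T$ is the orthogonal Procrustes solution
$T = VU^\top$ from the SVD of $P_C^\top X_C^\top$. The fitters alternate
these two exact updates; the loss is non-increasing by construction and
every run records its full loss history. The problem is biconvex, so a
multi-start scheme (default 20 starts: the SVD solution plus seeded
Gaussian draws) guards against local minima, and the lowest-loss start is
returned with ties broken toward the lowest start index.

When the common/distinctive structure is known a priori, a $K \times R$
binary *target matrix* pins the zero blocks, the Group Lasso is dropped,
and only the Lasso (on the components listed in `position`) remains
(`fit_structured_sca`).

## Preprocessing

`pre_process` mean-centers every column and scales it to sum of squares
one (`norm_one`), so a block's total sum of squares equals $J_k$ and
block-level variance-accounted-for values are proportions. The
`unit_variance` dialect divides by the standard deviation instead; both
are offered because verbal descriptions of "standardizing" in this
literature are ambiguous between the two. Block weighting
(`block_weight = TRUE`, off by default) additionally divides block $k$ by
$\sqrt{J_k}$ so wide blocks do not dominate. Constant columns cannot be
scaled and become all-zero with a warning rather than an error.

Missing cells are imputed deterministically before preprocessing:
column-mean fill by default, or EM-style iterative truncated-SVD
completion (`iterative_svd`, tolerance 1e-8, at most 500 iterations) when
a low-rank reconstruction is appropriate. The reference implementation in
this area uses stochastic multiple imputation; a deterministic scheme was
chosen deliberately, because the solver mathematics are unaffected and
determinism makes every downstream result reproducible and testable.
Consequently there is no imputation seed.

## Model selection

Three questions must be answered: how many components $R$, which
common/distinctive structure, and how much penalty.

**Choosing $R$** — `compute_vaf` fits plain SCA at a generous $R^*$ and
tabulates, per block, the proportion of the block's sum of squares carried
by each component ($\lVert p_r^k \rVert^2 / \lVert X_k \rVert_F^2$, valid
because $T^\top T = I$); one retains the components that clearly dominate
in any block. `eigen_screen` gives the per-block scree input for the
PCA-GCA route.

**Structure search** — two viewpoints are implemented. `disco_sca`
(explained-variance viewpoint) rotates the SCA loadings toward every
candidate structure (`enumerate_structures`: all $K \times R$ binary
status matrices without empty components, deduplicated up to column
permutation) and measures the squared loading mass left in the cells the
candidate says should be zero. The rotation itself is found by
alternating projections (mask the rotated loadings, Procrustes back),
from the identity plus 10 seeded random restarts, tolerance 1e-9. The
published selection rule for this step is not fully specified, so the
package uses an explicit, documented one: a candidate is **satisfied**
when its intended-zero cells jointly retain at most `floor_frac`
(default 1%) of the total squared loading mass; among satisfied
candidates the one with the *most* zero cells wins. The rationale: any
satisfied structure's nested sub-patterns (fewer zeros) are also
satisfied and would win on noise alone under a naive minimum-leakage
rule — preferring the most constrained satisfied candidate is what makes
the search consistent in simulation. The all-common candidate has an
empty mask (criterion 0 by construction) and only wins when nothing else
is satisfied. This rule recovers generative structures at 0–5% noise in
the test suite; at substantially higher noise the mass bound becomes hard
to meet and the search degrades toward less constrained candidates — a
known limitation.

`pca_gca` (correlation viewpoint) runs PCA per block and counts, per
block pair, canonical correlations between the retained score matrices
that reach a threshold (default 0.7, the conventional choice in this
literature); each one is a common component. For $K = 2$ this implies the
total $R$ and a concrete target matrix. For $K > 2$ the pairwise counts
are reported without forcing a global structure, which the method itself
does not define.

**Penalty tuning** — `max_lambdas` computes, from the closed-form updates
at the SCA scores, the smallest $\lambda_L$ (resp. $\lambda_G$) that
zeroes all loadings; grids run from essentially zero to these maxima
(20 points each for the 2-D search, 50 for the 1-D structured search).
`cv_sparse_sca` / `cv_structured_sca` perform cell-wise K-fold
cross-validation: one random partition of the $I \times \sum J_k$ cells
into near-equal folds per run (so the whole grid is compared on identical
folds), held-out cells replaced by the column mean of the retained cells,
the model fit on the imputed matrix, and the squared error of the
low-rank reconstruction against the true held-out values averaged. The
standard error of a grid point is the **sample standard deviation of the
K fold-level errors** — the definition used by the method's literature;
division by $\sqrt{K}$ is available as `se_scale = "sqrt_k"` but is not
the default, because on well-conditioned data it shrinks the one-SE
threshold to the point where selection collapses to
$\lambda \approx 0$ and no structure can be found. `one_se_select`
implements both reading of the rule: `not_higher` (sparsest model whose
MSPE does not exceed min + SE; the default selection) and `closest`
(nearest to the threshold from either side; reported as the upper end of
the 1-D `region`). Ties break toward the larger penalty; for the 2-D grid
the tie ordering is $\lambda_G$ first, then $\lambda_L$, since the Group
Lasso is the structurally decisive penalty.

## De-shrinkage and comparison utilities

Both penalties bias surviving loadings toward zero. `undo_shrinkage`
re-estimates the nonzero cells by unpenalized least squares at the fixed
zero pattern (read off the fit by exact-zero test), alternating with the
Procrustes score update by default; `refit_scores = FALSE` freezes the
scores instead. Alternating can only improve the fit and reduces to the
frozen answer in one pass when that is already optimal — the literature
is silent on whether scores are re-estimated, so both modes exist. SSE is
non-increasing and fixed zeros are preserved bit-exactly.

Component solutions are identified only up to column permutation and
sign. `match_components` resolves this by maximizing mean Tucker
congruence (exhaustively for $R \le 8$, greedily above);
`recovery_report` builds on it to score structure recovery, cell-level
sparsity recovery, and congruence against a known truth.

## The synthetic world

`simulate_multiblock` generates data *from the model*: a random
orthonormal $T$ (QR of a Gaussian matrix, sign-fixed for cross-platform
determinism), Gaussian loadings zeroed per the designated structure and
optional within-component sparsity (at least one survivor per active
block-component), and Gaussian noise rescaled in closed form so that the
noise fraction of the total sum of squares equals `noise_proportion`
exactly. Defaults state the reference testing world: 5% noise, no
within-sparsity, and the acceptance design uses $I = 50$,
$J = (12, 10)$, $R = 3$ with one common and two distinctive components —
a small, well-conditioned regime typical of the questionnaire and
chemometrics examples this method targets.

What a green test on this generator does establish: the solvers minimize
what they claim, zeros are exact, and the full select-fit-deshrink
pipeline recovers a planted structure under moderate noise. What it does
not establish: behavior under heavy-tailed or correlated noise, grossly
unbalanced block widths, $J \gg I$ regimes, or real measurement artifacts
— none of which the generator emulates. Preprocessing also rescales each
column by its centered norm, so the generative loadings are compared in
the analyzed coordinate system (`loadings_std`); the zero pattern is
scaling-invariant.

Across replicate seeds of the acceptance design, the CV-selected
component-wise fit recovers the planted structure in roughly 5 of 7 runs
(congruence ≥ 0.99 in all of them); the failures are runs where the
one-SE contour touches the $\lambda_G \approx 0$ axis, so all blocks stay
active. This is a property of the one-SE rule on a 2-D grid, not of the
solvers, and is the reason the structured (known-target) route exists.

## Numerical choices

* Convergence: relative loss change below `tol` (1e-9 for fitters, 1e-6
  inside CV where the grid dominates runtime); `max_iter` 10000 (1000 in
  CV). Non-convergence flags the result rather than erroring.
* Knife edge at the penalty maxima: at $\lambda$ *exactly* equal to the
  analytic maximum, rounding can leave a $10^{-16}$-scale survivor that
  the alternating scheme then grows into a spurious nonzero solution. The
  group factor therefore clamps to zero within 1e-12, and `max_lambdas`
  returns its maxima with $10^{-10}$ relative headroom. Refits at 0.99
  times the maxima remain nonzero, so the bound stays sharp.
* Degenerate group update ($\lVert S(\cdot) \rVert = 0$): defined as the
  zero vector (the continuous limit).
* SVD sign ambiguity: every SCA component is flipped so its
  largest-magnitude loading is positive, making output stable across
  LAPACK builds. Singular-value ties keep backend order.
* All randomness flows through explicit seeds; identical seeds give
  bit-identical fits, folds, simulations, and CLI artifacts.

## Known limitations

No inference (standard errors) on loadings; no elastic-net or other
penalties; no joint three-way search over $(R, \lambda_L, \lambda_G)$;
blocks must be linked by rows, not columns; DISCO's search is
combinatorial in $K$ and $R$ (guarded by a candidate cap); structure
detection degrades at high noise as described above.
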