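---
title: "Linking chemical substructures to drug side-effects with sparse CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking chemical substructures to drug side-effects with sparse CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sidefx)
```

## The problem

Adverse drug reactions are a leading cause of attrition in drug development
and of post-market withdrawal. A practical *in silico* question is whether
the side-effect profile of a candidate molecule can be anticipated from its
chemical structure alone, before any clinical data exist. `sidefx` works
with two binary profile matrices over a common set of $n$ drugs:

* $X$ ($n \times p$): presence/absence of $p$ predefined chemical
  substructure keys in each drug's molecular structure (e.g. the 881
  PubChem fingerprint bits);
* $Y$ ($n \times q$): presence/absence of $q$ side-effect keywords
  recorded for each drug (e.g. SIDER terms).

The reference data regime the package targets (see
`sider_benchmark_summary()`) has 888 drugs, 881 substructure bits with
about 121 bits set per drug, and 1385 side-effect keywords with about 69
per drug — both matrices are sparse and binary.

Beyond prediction, the scientific payoff is *interpretability*: the method
extracts small correlated sets — a handful of substructures shared by drugs
that tend to share a handful of side-effects — which is what a chemist can
act on.

## The model

Classical canonical correlation analysis seeks weight vectors
$\alpha \in \mathbb{R}^p$, $\beta \in \mathbb{R}^q$ maximizing the Pearson
correlation of the canonical scores $u_i = \alpha^\top x_i$ and
$v_i = \beta^\top y_i$. With $p, q$ of the order of $n$ or larger, the
within-set covariance matrices are ill-conditioned and the weights are not
unique, so the package adopts the diagonal-covariance approximation:
$X^\top X$ and $Y^\top Y$ are replaced by identities after the columns of
$X$ and $Y$ have been centered and scaled. The problem then reduces to

$$\max_{\alpha, \beta} \; \alpha^\top Z \beta,
  \qquad Z = X_n^\top Y_n,\qquad
  \lVert\alpha\rVert_2 \le 1,\ \lVert\beta\rVert_2 \le 1,$$

whose solution is the leading singular-vector pair of the cross-product
matrix $Z$ — ordinary CCA (`occa()`) is simply a truncated SVD of $Z$.

Sparse CCA (`scca()`) adds L1 constraints
$\lVert\alpha\rVert_1 \le c_1\sqrt{p}$ and
$\lVert\beta\rVert_1 \le c_2\sqrt{q}$ with fractions
$c_1, c_2 \in (0, 1]$. A unit-norm vector of length $p$ has L1 norm between
$1$ and $\sqrt p$, so $c = 1$ leaves the problem unconstrained while small
$c$ forces most weights to exactly zero. Each component solves a penalized
rank-one matrix decomposition by alternating updates: with $\beta$ fixed,
the optimal $\alpha$ is a soft-thresholded, L2-rescaled version of
$Z\beta$, the threshold found by bisection so the L1 bound just holds (and
symmetrically for $\beta$). Successive components are obtained by
deflation,

$$Z^{(k+1)} = Z^{(k)} - d_k\, \alpha_k \beta_k^\top,
  \qquad d_k = \alpha_k^\top Z^{(k)} \beta_k,$$

which makes the reconstruction identity
$\sum_k d_k \alpha_k\beta_k^\top + Z^{(m+1)} = Z^{(1)}$ exact by
construction (the test suite verifies accumulated round-off below $10^{-8}$
in Frobenius norm). For interpretability, signs are adjusted per component
so the largest-magnitude substructure weight is positive; the pair
$(\alpha_k, \beta_k)$ is flipped together, preserving both $d_k$ and the
canonical correlation $\rho_k$ computed on the training rows.

## Prediction for new molecules

A query fingerprint $x$ is normalized with the *training* means and
standard deviations, then projected to canonical space, $u = A^\top
\tilde x$. Two predictors are provided:

* **Profile reconstruction** (`predict_profile_pinv()`): solve
  $B^\top \hat y = u$ in the least-squares sense via the pseudo-inverse of
  $B^\top$ and de-normalize back to the side-effect scale. Singular values
  below $10^{-10}$ of the largest are truncated, since $B$ is routinely
  rank-deficient under strong sparsity.
* **Correlation-weighted score** (`predict_score_weighted()`, the
  default): $s(x) = B \Lambda A^\top \tilde x$ with
  $\Lambda = \mathrm{diag}(\rho_1,\dots,\rho_m)$, i.e. each component's
  contribution is weighted by how reliable it was on the training data.
  These scores are used for ranking and are deliberately *not*
  de-normalized: a per-column affine transform would not change any
  per-side-effect ROC, but it would reshuffle the pooled (global) ranking
  across side-effects by the columns' prevalences rather than by signal.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `c1`, `c2` | sparsity fractions in $(0,1]$ | 0.05 | the reference analysis found 0.05 best for pooled AUC, 0.2 for per-label AUC; `c\sqrt{dim}` must be $\ge 1$ |
| `m` | number of components | 20 | 20 (pooled) to 500 (per-label) in the reference analysis |
| `tol` | convergence threshold on weight change | 1e-7 | max-norm between alternating sweeps |
| `max_iter` | iteration cap per component | 200 | a warning reports non-convergence; the iterate is returned |
| `init` | primary start for the alternating solver | `"svd"` | `"random"` draws a unit Gaussian from `seed` |

Baselines follow the standard conventions: the k-nearest-neighbour scorer
uses Tanimoto (Jaccard) similarity on fingerprint bits — the cheminformatics
default for bit vectors — and scores a side-effect $k'/k$ when $k'$ of the
$k$ neighbours carry it; the SVM baseline fits one classifier per
side-effect with RBF kernel
$\exp(-\lVert x - x'\rVert^2 / 2\sigma^2)$ (note the $\sigma$ convention;
reported widths are only interpretable relative to it); the random
baseline draws a hard 0/1 score per cell at the side-effect's training
prevalence, with a deterministic `"prevalence"` mode for diagnostics.

## Numerical choices

* **Normalization.** Column means and *population* (divisor $n$) standard
  deviations, fitted on training rows only and reused to de-normalize
  predictions. The convention is arbitrary but must match between fit and
  inverse; it is fixed package-wide. Columns constant on the training rows
  get a substituted sd of 1 so the normalized column is identically zero —
  the feature is inert, shapes stay stable across CV folds, and
  de-normalization (which uses the true sd, 0) still returns the training
  constant.
* **Restarts.** The alternating PMD scheme is multimodal once the L1
  constraints bind: a single SVD start occasionally converges to a
  component whose objective is a few percent below the best attainable
  (observed on small integer-valued cross-product matrices against a
  feasible-point search oracle). Whenever $c_1 < 1$ or $c_2 < 1$ the solver
  therefore also restarts from axis vectors on the four strongest columns
  and the four strongest rows of $Z^{(k)}$, screens all starts with a few
  sweeps, polishes the most promising one to full convergence, and keeps
  the best objective. All starts are deterministic.
* **Tied maxima.** If the largest entries of the update direction are
  exactly tied in magnitude (possible with discrete data), no
  soft-threshold level can meet the L1 bound at unit L2 norm. The
  subproblem optimum then has the L1 constraint binding at L2 norm below 1
  — equal mass $c\sqrt{\dim}/k$ on the $k$ tied coordinates — and the
  update returns exactly that point. This is the single situation in which
  a returned weight vector has Euclidean norm less than 1.
* **Sign ties.** When the largest-magnitude weight is tied, the earliest
  index decides the component's sign.
* **Degenerate components.** If $Z^{(k)}$ becomes numerically zero before
  $m$ components are extracted, fitting stops early and returns the
  components found. Canonical correlations with zero-variance scores are
  flagged `NA` and treated as 0 by the weighted predictor, with a warning.
* **AUC.** Computed as the rank (Mann–Whitney) statistic with average ranks,
  so tied score pairs contribute one half — identical to trapezoidal ROC
  integration but with a trivially verifiable pairwise oracle. Per-label
  AUCs for single-class columns are `NA` and excluded (not zero-filled)
  from summaries, avoiding prevalence artifacts.

## Significance of components

The reference analysis reports near-zero p-values for the canonical
correlations of its top components without specifying the procedure. The
package provides a documented stand-in, `permutation_pvalue()`: the rows of
$Y_n$ are permuted, the *first* component refitted each time, and the
add-one estimator $(1 + \#\{\rho^*_1 \ge \rho_{\text{obs}}\})/(1 +
n_{\text{perm}})$ returned. Comparing a later component's observed
$\rho_k$ against the permutation distribution of $\rho^*_1$ is
conservative. This is a design choice of this package, not a claim about
the original procedure.

## What the synthetic generator emulates — and what it does not

`generate_planted_dataset()` plants latent components: each occupies a
small set of substructure columns and a small set of side-effect columns
(disjoint across components within a matrix), carried by a random drug
subset of size `round(drug_frac * n)` drawn without replacement
(components may share drugs, as real drugs share fragments). Planted bits
flip with probability `flip_noise`; all other cells are i.i.d.
Bernoulli(`background_rate`). Bit-flip noise touches only planted cells
and background noise only unplanted cells, keeping the two generative
roles separable for testing. The benchmark configuration used throughout
the tests — $n = 500$, $p = 50$, $q = 40$, two components with size-5
supports, `drug_frac = 0.2`, `flip_noise = 0.05`, `background_rate = 0.05`
— mirrors the small per-component feature sets that make the sparse fit
interpretable on real data; the rates are of the order of the reference
data's bit densities.

The generator does **not** emulate correlated fingerprint bits (real
PubChem keys are strongly nested), the heavy-tailed prevalence
distribution of real side-effect keywords, or drugs' shared protein
targets. Passing the planted-recovery tests therefore shows the estimator
recovers block-structured signal under independent noise — not that it
will attain any particular accuracy on pharmacovigilance data.

One quantitative consequence is worth stating explicitly. Under the
benchmark configuration roughly half of the positive cells of $Y$ are
background noise, statistically independent of $X$. A clairvoyant
predictor that scores exactly the planted carrier cells attains a pooled
cross-validated AUC of about 0.75, and that is an information-theoretic
ceiling for *any* predictor under these conditions. The test suite
therefore checks that the sparse-CCA predictor comes within 0.03 of that
truth-aware oracle ceiling (it does, typically within 0.01), rather than
treating an absolute pooled-AUC figure as attainable; an absolute
threshold of 0.85 would require the planted fraction of positives to be
around 70%, i.e. materially less background noise than the stated
conditions contain.

## Evaluation protocol

`run_cv_experiment()` reproduces the standard protocol: drugs are split
into $K = 5$ folds (random permutation dealt round-robin, so sizes differ
by at most one); the split is computed once and shared across methods;
normalizers and models see training rows only. Reported are the pooled
("global") AUC over all drug × side-effect cells, the per-side-effect AUC
distribution, and per-drug top-$k$ accuracy (ties broken by ascending
column index, stable). Fold processing order cannot affect results because
scores are assembled into a matrix indexed by drug id.

Problem sizes in the tests and in `scripts/acceptance.R` — 50 random
$30 \times 20$ matrices for the SVD-limit check, ten $3 \times 3$ integer
matrices against a $10^5$-sample feasible-point oracle, the
$n = 500$ planted benchmark, and twenty null repetitions at $n = 500$ —
were chosen so the whole suite completes in a few minutes on one CPU while
keeping every Monte-Carlo bound comfortably away from its threshold.

## Known limitations

* The diagonal-covariance approximation discards within-set correlation;
  components are not orthogonalized beyond deflation.
* `c1`, `c2` and `m` interact strongly and the best values depend on the
  objective (pooled vs per-label accuracy); the package deliberately
  offers only the CV harness for choosing them.
* The permutation test refits only the first component per permutation.
* Scores from different methods live on different scales and must never be
  pooled into one ROC.
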