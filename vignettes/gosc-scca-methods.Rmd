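---
title: "Graph-OSCAR sparse CCA: model, solver and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-OSCAR sparse CCA: model, solver and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goscca)
```

## The model

Sparse canonical correlation analysis seeks loading vectors $u \in
\mathbb{R}^p$, $v \in \mathbb{R}^q$ such that the canonical variates $Xu$
and $Yv$ are maximally correlated while most loading entries are zero. In
fields where features are strongly inter-correlated (SNPs in linkage
disequilibrium, neighboring brain regions), a good estimator should also
*group*: highly correlated features should receive loadings of similar
magnitude. Penalties built from signed pairwise differences
$|u_i - \mathrm{sign}(\rho_{ij}) u_j|$ achieve grouping only if the sign of
every sample correlation is estimated correctly first, and noise-driven sign
errors bias the fit. The graph-OSCAR penalty avoids the sign estimate
altogether:

$$\|u\|_{\mathrm{GOSCAR}} = \sum_{(i,j) \in E} \max\{|u_i|, |u_j|\}
  = \tfrac12 \sum_{(i,j) \in E} |u_i - u_j|
  + \tfrac12 \sum_{(i,j) \in E} |u_i + u_j|.$$

Penalizing the difference *and* the sum shrinks the pair toward equal
magnitude whatever the relative sign. $E$ is the edge set of a feature
graph; with no prior network the complete graph is used and the penalty
reduces to classical OSCAR over all pairs ("group-pursuit mode").

The fitted criterion is the Lagrangian

$$\mathcal{L}(u,v) = -u^{\top} X^{\top} Y v
 + \lambda_1 \|u\|_{\mathrm{GOSCAR}} + \lambda_2 \|v\|_{\mathrm{GOSCAR}}
 + \tfrac{\beta_1}{2}\|u\|_1 + \tfrac{\beta_2}{2}\|v\|_1
 + \tfrac{\gamma_1}{2}\|Xu\|_2^2 + \tfrac{\gamma_2}{2}\|Yv\|_2^2,$$

the unconstrained counterpart of maximizing $u^\top X^\top Y v$ subject to
variate-norm caps $\|Xu\|_2^2 \le 1$, $\|Yv\|_2^2 \le 1$ and the sparsity
budgets. Using variate norms (rather than $\|u\|_2 \le 1$) injects the
sample covariance into the constraint, which improves prediction when
features are correlated.

**Assumptions.** Columns of $X$ and $Y$ are mean-centered and scaled to unit
$\ell_2$ norm (`standardize()`), so the diagonal cross-products are
$x_i^\top x_i = 1$ and off-diagonal ones are sample correlations; the
grouping bound below depends on this convention. Inputs must be complete
(no missing entries) and free of constant columns. One canonical component
pair is estimated; deflation for further pairs is out of scope.

## The solver

Each absolute value in the penalties is smoothed as
$\sqrt{x^2 + \zeta}$ with a tiny $\zeta > 0$ and majorized by a quadratic
around the current iterate, giving the pair weights

$$w_{ij} = \frac{1}{2\sqrt{(u_i-u_j)^2+\zeta}}, \qquad
 \hat w_{ij} = \frac{1}{2\sqrt{(u_i+u_j)^2+\zeta}}, \qquad
 \Lambda_{kk} = \frac{1}{2\sqrt{u_k^2+\zeta}}.$$

Collecting the difference weights into a graph Laplacian $L = D - W$ and the
sum weights into the signless analog $\hat L = \hat D + \hat W$ (both
positive semidefinite), the stationarity condition in $u$ for fixed $v$
becomes the linear system

$$\big(\lambda_1 (L + \hat L) + \beta_1 \Lambda + \gamma_1 X^\top X\big)\, u
  = X^\top Y v,$$

solved by Cholesky factorization (never an explicit inverse), and
symmetrically for $v$. One iteration is: reweight from the current $u$,
solve for $u$, reweight from the current $v$, solve for $v$. The smoothing
is applied uniformly to every weight, not only at exact zeros: this keeps
the surrogate differentiable, and as $\zeta \to 0$ the smoothed objective
converges to the exact one (the package asserts a relative difference below
$10^{-4}$ between $\zeta = 10^{-10}$ and $10^{-14}$). Default
$\zeta = 10^{-10}$.

The half-quadratic majorization guarantees that each half-step does not
increase the smoothed objective, hence the objective trace is monotone
non-increasing; the suite verifies this on random instances to within
$10^{-8}$ relative slack. Convergence is declared on the *loadings*:
$\max_k |\Delta u_k| \le \tau$ and $\max_k |\Delta v_k| \le \tau$
simultaneously, with $\tau = 10^{-5}$ and an iteration cap of 100 by
default.

### Rescaling modes, and why there are two

The Lagrangian updates do not enforce $\|Xu\|_2 = 1$ exactly. Left entirely
unnormalized (`rescale = "final"`), the alternating updates contract both
loadings toward the trivial stationary point $u = v = 0$: the bilinear
reward shrinks quadratically while the penalties shrink linearly, so the
objective decreases monotonically to 0 and the stopping rule fires once the
iterates are tiny. That mode exists because the monotonicity guarantee
concerns precisely the unnormalized updates, and the package's
monotone-decrease and fixed-point tests run in it. For actual estimation the
default `rescale = "per_iteration"` scales each updated loading so its
variate has unit norm — re-imposing the constraint the Lagrangian relaxes —
which keeps the iterates on a meaningful scale; correlation, the reported
quantity, is scale-invariant. Reported loadings are always rescaled so
$\|Xu\|_2 = \|Yv\|_2 = 1$.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| $\lambda_1, \lambda_2$ | graph-OSCAR weight per side | 1 | tuned; grid $10^{-3}..10^3$ |
| $\beta_1, \beta_2$ | $\ell_1$ weight per side (enters as $\beta/2$) | 1 | tuned; same grid |
| $\gamma_1, \gamma_2$ | variate-norm weight per side | 1 | tuned over $\{0.1, 1, 10\}$; must be $>0$ |
| $\zeta$ | smoothing of $\sqrt{x^2+\zeta}$ | $10^{-10}$ | dimensionless; fixed |
| $\tau$ | stopping tolerance on $\max|\Delta u|$ | $10^{-5}$ | loadings live on the $\|Xu\|=1$ scale |
| `max_iter` | iteration cap | 100 | |
| `init` | `ones` or seeded `random` | `ones` | scaled so $\|Xu_0\| = 1$ |
| `rescale` | `per_iteration` / `final` | `per_iteration` | see above |

Only the ratios $\lambda/\gamma$ and $\beta/\gamma$ matter for the fitted
direction up to the overall objective scale; the grids cross them anyway
because the tuning protocol treats the axes independently.

## Grouping-effect bound

For an edge $(i,j)$ that is the only edge incident to both endpoints and
whose fitted loadings share a sign, the converged solution satisfies

$$|\tilde u_i - \tilde u_j| \le \frac{2\lambda_1 w_{ij}}{\gamma_1}
 + \frac{1}{\gamma_1}\sqrt{2(1-\rho_{ij})},$$

and the analogous bound with $(\lambda_2, \gamma_2, W_2, \rho')$ on the $v$
side. The bound tightens as $\rho_{ij} \to 1$ (the second term uses the
exact identity $\|x_i - x_j\|_2^2 = 2(1-\rho_{ij})$ for unit-norm centered
columns) and is deliberately slack for weakly related pairs, which should
not be forced together. `grouping_bound_report()` emits one record per edge
with the gap, the bound, and flags for whether the hypotheses hold; the
pass/fail verification counts only hypothesis-satisfying edges, the rest
being informational. Two evaluation choices were open and are fixed here:
$w_{ij}$ is taken from the weights rebuilt at the *converged, rescaled*
loading (the quantity appearing in the stationarity equations), and reports
are produced for non-converged fits too, with a warning.

One caveat deserves emphasis. The bound's derivation keeps only the
diagonal of the $\gamma X^\top X$ term in the row-wise stationarity — it
replaces $\gamma (x_i - x_j)^\top X u$ by $\gamma(\tilde u_i - \tilde u_j)$.
When the fit actually groups the pair the two coincide (with
$x_i \approx x_j$ the cross contribution cancels) and the bound holds in
every simulation this package runs. When the fit *declines* to group —
one loading decays to a numerical zero while the other stays large — the
neglected cross term can dominate and the printed bound can be exceeded;
the package's isolated-pair simulations observe this in roughly 3% of
converged hypothesis-meeting fits. The report is therefore a diagnostic of
the grouping regime, not an unconditional certificate.

## Synthetic data generator

`make_scenario()` / `generate_data()` implement a four-step latent-factor
design: (1) piecewise-constant true loadings — disjoint blocks of features
sharing one nonzero value; (2) a latent score $z_i \sim N(0,1)$ per sample;
(3) rows $x_i \sim N(z_i u, \Sigma_x)$ with the covariance kernel
$(\Sigma_x)_{jk} = \exp(-|u_j - u_k|)$ (unit diagonal; same construction for
$Y$ with $v$); (4) a sign swap: the first $\lfloor \text{size}/2 \rfloor$
members of the first nonzero group have their loading sign *and* their data
column sign flipped, on both sides. Because both flip together,
$X'u' = Xu$ bit-exactly, so the planted association is unchanged while any
method that guesses pairwise correlation signs is stressed. The stored
truths are post-swap. Since the generator's reference truths are known only
as qualitative block patterns, the four shipped scenarios (all $n=80$,
$p=100$, $q=120$; block values between 0.5 and 2, scenario 4 the high-SNR
one at $\pm 2$) *emulate* that design rather than replicate specific
datasets; they were fixed once and are not tuned to test outcomes.

What the generator does **not** emulate: discrete genotype coding (0/1/2
allele counts), linkage-disequilibrium block structure beyond the
exponential kernel, heavy-tailed or heteroskedastic imaging noise, and
covariate effects (age, sex, ...) that real analyses regress out first. A
green recovery test therefore establishes correctness of the estimator on
its stated generative model, not field performance.

Two details are literal readings of the stated design: rows are sampled with
mean $z_i u$ using the *pre-swap* loadings, and equal loadings inside one
block make the kernel correlation exactly 1 there (a singular covariance),
which the sampler handles by an eigen square root when Cholesky fails.

## Cross-validation protocol

`run_nested_cv()` uses seeded, unstratified outer $k$-folds (default 5).
Hyperparameters are tuned by inner $k$-fold CV **on the first outer training
set only** and reused for the remaining folds — a deliberate time-saving
shortcut of the protocol. Standardization statistics always come from
training rows and are applied to held-out rows. Three choices the protocol
leaves open are fixed as: the inner selection criterion is the mean inner
validation correlation with `NaN` scores excluded (an all-`NaN` candidate is
disqualified); ties are broken toward larger penalties (sparser fits);
failed fits propagate `NaN` — reported, excluded from means, and counted,
never raised. Method comparison between per-fold score vectors uses a
two-sided paired t-test (`compare_methods()`), with degenerate cases (zero
variance of the differences) resolved in closed form.

## Numerical choices

- Linear systems: Cholesky solve; on factorization failure, escalating
  diagonal jitter $\varepsilon \cdot \mathrm{mean(diag)}$ with
  $\varepsilon \in \{10^{-10}, 10^{-8}, 10^{-6}\}$, then a hard error. The
  system matrix is PSD by construction and strictly PD whenever $\beta > 0$.
- The recorded `objective_trace` is the exact objective; the smoothed
  surrogate trace (the quantity with the monotonicity guarantee) is kept
  alongside as `objective_trace_smoothed`. At $\zeta = 10^{-10}$ the two
  differ by at most $\sqrt{\zeta}$ per penalty term.
- Degenerate inputs: constant columns are rejected by name before
  standardization; all-zero loadings yield a flagged `NaN` correlation;
  empty graphs make the GOSCAR term exactly zero.
- Dense weight matrices are limited to 5000 features per side, far above
  the intended problem sizes.

## Known limitations

- Single canonical pair; no deflation.
- Near $\beta/\gamma \approx 1$ the reweighted iteration can spend upward of
  100 iterations slowly merging small coefficient clusters (the per-iteration
  change plateaus around $10^{-4}$ before collapsing); such fits converge,
  but not always within the default cap. Tuned configurations usually sit in
  faster regimes; if not, raise `max_iter`.
- The grouping bound is proved only for isolated same-sign pairs; reports
  for other edges are descriptive.
- Tuning cost is the number of grid points times $k$ fits; the tied default
  grid (147 points) is sized for desk-scale runs, and `tune_penalties()`
  exposes `max_iter` to cap tuning fits separately.
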