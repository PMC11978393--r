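---
title: "High-dimensional change testing for multichannel recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-dimensional change testing for multichannel recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdeeg)
```

This package tests two kinds of stimulus-induced change in epoched
multichannel recordings (EEG-style data: rows are time points, columns are
channels): changes in the **mean vector** across epochs, and changes in the
**precision matrix** — the conditional-dependence structure of the channels
— between a pre- and a post-stimulus interval. Both problems are
high-dimensional: the number of channels p is comparable to, or larger
than, the number of time points per epoch, so classical multivariate tests
(Hotelling's T², entrywise Wishart inference) are either undefined or badly
calibrated. This vignette explains the models, the estimators, the tunable
parameters, and the design decisions behind the implementation, and says
precisely what the simulation-based tests do and do not establish.

## 1. The ridge-regularized Hotelling test

Given G groups of p-variate observations with sizes $n_g$
($n = \sum_g n_g$), the hypothesis is $H_0: \mu_1 = \dots = \mu_G$ under a
common covariance $\Sigma$. The classical Hotelling statistic uses
$S_n^{-1}$, the inverse of the pooled covariance with $e_1 = n - G$ degrees
of freedom; when $p > e_1$ that inverse does not exist. The ridge
regularization replaces it:

$$\mathrm{RIHT} = \sum_{g=1}^G n_g (\bar X_g - \hat\mu)' (S_n + \lambda
I)^{-1} (\bar X_g - \hat\mu), \qquad \lambda > 0.$$

Under the null and an independent-component model whose components match
the first four Gaussian moments, a central limit theorem gives

$$T = \frac{\mathrm{RIHT} - e_2\,\mathrm{tr}\{(S_n+\lambda I)^{-1}\Sigma\}}
{\sqrt{2 e_2\, \mathrm{tr}\{((S_n+\lambda I)^{-1}\Sigma)^2\}}}
\;\Rightarrow\; N(0, 1), \qquad e_2 = G - 1.$$

When $\Sigma$ is unknown the two trace terms are estimated from the
spectrum of $S_n$ alone through its Stieltjes transform
$m = p^{-1}\mathrm{tr}(S_n + \lambda I)^{-1}$ and its derivative analogue
$m' = p^{-1}\mathrm{tr}(S_n + \lambda I)^{-2}$:

$$\Theta^{(1)}_n = \frac{1 - \lambda m}{D}, \qquad
\Theta^{(2)}_n = \frac{1 - \lambda m}{D^3} -
\frac{\lambda(m - \lambda m')}{D^4}, \qquad
D = 1 - \gamma_n(1 - \lambda m),$$

with $\mathrm{tr}_1 \approx p\,\Theta^{(1)}_n$ and
$\mathrm{tr}_2 \approx p\,\Theta^{(2)}_n$. These are random-matrix
(Marchenko–Pastur) identities: they are exact in the limit where p and the
sample size grow proportionally.

**Aspect ratio.** The theory states the limit in terms of $\gamma = p/n$.
$S_n$, however, averages $e_1 = n - G$ independent centred contributions,
so at finite sizes its spectrum concentrates at aspect ratio $p/e_1$; the
two are asymptotically identical for fixed G. We use $\gamma_n = p/e_1$.
The choice is not cosmetic: at $p = 63$, $n_1 = n_2 = 20$ the $p/n$ variant
leaves a visible positive bias in the standardized statistic and pushes the
empirical size above the nominal band, while $p/e_1$ calibrates all eight
simulation settings (two component models × two covariances × two
sample-size pairs) into [0.035, 0.065] at the 0.05 level — the acceptance
suite verifies this at 2000 replicates per setting.

**Choice of λ.** Any $\lambda > 0$ yields a valid test — the CLT holds for
every fixed λ — so λ trades off only power. The default is
$\lambda = 1$ (observations are assumed to be on a roughly unit-variance
scale after preprocessing). `riht_test(..., sigma = )` accepts a known
covariance, in which case the trace terms are computed exactly instead of
estimated. $D \le 0$ is reported as an error: it means λ is too small for
the aspect ratio and the plug-in standardization is not usable.

**Change validation.** `validate_changes()` implements the two-step
procedure: a G-interval omnibus test first; only when it rejects (|T| >
1.96 by default) are the adjacent epoch pairs tested, and the boundaries
whose pairwise |T| exceeds the threshold are reported as change points. No
multiple-testing correction is applied across the pairwise tests by
default, matching the original procedure; a Benjamini–Hochberg option is
available (`p_adjust = "BH"`). Equal covariance across epochs is an
assumption, not an enforced constraint; a diagnostic warning fires when
group-wise covariance traces differ by more than a factor of 4.

## 2. Joint sparse precision estimation: the fused graphical lasso

For G populations with empirical covariances $S_{n_g}$ (columns centred by
group means before $S_{n_g} = n_g^{-1} X_g'X_g$ is formed — the Gaussian
likelihood presumes mean-zero data), the joint estimator minimizes

$$\sum_g \left\{ \mathrm{tr}(S_{n_g}\Theta_g) - \log\det\Theta_g \right\}
+ \lambda_1 \sum_g \|(\Theta_g)^-\|_1
+ \lambda_2 \sum_{g<g'} \|(\Theta_g - \Theta_{g'})^-\|_1,$$

where $(\cdot)^-$ zeroes the diagonal. The $\lambda_1$ term induces sparse
conditional-dependence graphs; the $\lambda_2$ term fuses the graphs of
adjacent populations, reflecting the smooth evolution of connectivity over
time. For $G = 2$ — every use in this package's studies — the all-pairs
penalty and the adjacent-chain penalty coincide; for $G \ge 3$ the ADMM
constrains only adjacent pairs while `fgl_objective()` reports the
all-pairs penalty, and the discrepancy is documented rather than silently
resolved.

### The ADMM

The solver introduces slack matrices Z (sparsity) and Δ (fusion) with
scaled duals V, U, and cycles: a closed-form positive-definite update of
each $\Theta_g$, soft-thresholding of the slacks, and dual ascent. The
$\Theta$ update diagonalizes the assembled matrix Y and maps each
eigenvalue d to $(-d + \sqrt{d^2 + 4\rho})/(2\rho)$ — strictly positive, so
**every iterate is positive definite by construction** (asserted
per-iteration in the tests). Three numerical choices matter:

* **Consensus diagonal.** The slack matrices soft-threshold only
  off-diagonal entries and carry the unpenalized diagonal through
  ($Z_{ii} = (\Theta + V)_{ii}$). Zeroing the slack diagonals instead
  leaves a spurious $\rho\,\Theta_{ii}$ term in the Θ-update's fixed point
  and the solver converges to the wrong matrix (the unpenalized
  single-group fit then misses $S^{-1}$ by a large margin). The chosen
  convention is the standard one for joint-graphical-lasso ADMMs and is
  consistent with the initialization $Z^{(0)} = \Theta^{(0)}$, which has a
  nonzero diagonal. Dual diagonals are zeroed each sweep; their residual
  diagonal is identically zero at the fixed point.
* **Initialization.** $\Theta^{(0)}_g = (S_{n_g} + 0.1 I)^{-1}$ with
  all-ones dual matrices (`init = "ones"`, the reference algorithm's
  starting point, kept verbatim); `init = "zeros"` provides the
  conventional zero duals (used internally for warm-started grid cells,
  where an all-ones dual kick would be pure waste).
* **Stopping.** The relative $\ell_1$ change of the precision iterates,
  $\sum_g \|\Theta_g^{(t)} - \Theta_g^{(t-1)}\|_1 / \sum_g
  \|\Theta_g^{(t-1)}\|_1 \le \varepsilon$, with $\varepsilon = 10^{-9}$ and
  a 500-iteration cap by default. Hitting the cap is a warning plus
  `converged = FALSE`, never an exception, so large simulation harnesses
  never abort.

The iteration loop is compiled (RcppArmadillo); an arithmetically identical
pure-R path (`admm_initialize()` / `admm_step()`) is exported for
inspection and is cross-checked against the compiled engine to 1e-10 in
the tests. Correctness is established against an independent convex
oracle — a smoothed-penalty BFGS minimizer over Cholesky factors — to
within 1e-3 in objective value on small instances, and by the analytic
limits: $\lambda_1 = \lambda_2 = 0$ recovers $S^{-1}$; $\lambda_2 \to
\infty$ fuses the off-diagonals to equality.

## 3. De-biased entrywise inference (MPDe)

Penalized estimates are biased, so their entries cannot be plugged into a
z-test directly. The one-step correction

$$\tilde\Theta_g = 2\hat\Theta_g - \hat\Theta_g S_{n_g} \hat\Theta_g$$

removes the first-order penalization bias (an exact inverse is a fixed
point). For known constants $a_1, \dots, a_G$ the null
$H_0: \sum_g a_g \Theta^0_{g;ij} = \Theta^0_{ij}$ is tested entrywise with

$$T_{ij} = \sum_g a_g \tilde\Theta_{g;ij}, \qquad
\hat\sigma^2_{ij} = \sum_g a_g^2 \left( \tilde\Theta_{g;ii}
\tilde\Theta_{g;jj} + \tilde\Theta_{g;ij}^2 \right), \qquad
T^{\mathrm{MPDe}}_{ij} = \frac{\sqrt{n}\,(T_{ij} - \Theta^0_{ij})}
{\hat\sigma_{ij}},$$

compared with N(0, 1). The pre/post comparison uses $a = (1, -1)$, i.e.
"has this conditional dependence changed?", and edges with p-value below
0.01 (configurable; no multiplicity correction by default, BH optional)
form the significant-change network.

**Which n.** The $\sqrt{n}$ factor uses the **total** sample size
$n = \sum_g n_g$, the convention under which n denotes the pooled sample
count throughout the surrounding theory. A per-group reading
($n_{\mathrm{eff}} = \min_g n_g$) is available via the `n_eff` argument.
The two readings differ by $\sqrt{G}$; with the total-n convention the
null statistics at the penalties the tuning methods actually select are
approximately calibrated — the acceptance checks measure per-location
means, sds and a normality fit over 200 null replicates, and most
locations fall inside a [0.85, 1.15] sd band, though entries sitting on
strong edges of a dense truth can run slightly over-dispersed (their
de-biased estimate is nearly unpenalized, so little shrinkage offsets the
$\sqrt{G}$ factor). The per-group reading would instead leave every
location under-dispersed at these penalties. Users combining `n_eff`
overrides with near-zero penalties should be aware the two effects trade
off. No finite-sample (n vs n−1) correction is applied.
Entries with $\hat\sigma_{ij} = 0$ yield NaN statistics with a logged
warning and are deterministically excluded from the network.

## 4. Hyperparameter selection

**AIC grid.** The reference method scores every $(\lambda_1, \lambda_2)$
on a grid — by default 30 equally spaced values from 0.05 to 0.3 per axis
(step 0.0034) — and keeps the minimizer, ties broken toward the sparser
pair. The score is

$$\mathrm{AIC} = \sum_g \left\{ w_g\left[\mathrm{tr}(S_{n_g}\hat\Theta_g) -
\log\det\hat\Theta_g\right] + 2k_g \right\},$$

with $k_g$ = p diagonal entries plus the upper-triangle entries of
$\hat\Theta_g$ exceeding 1e-6 in magnitude. Two weight conventions exist:
$w_g = 1$ (the fitted per-observation objective plus complexity; the
default) and $w_g = n_g$ (total likelihood). The default matters: at
Scenario-I sample sizes the $n_g$-weighted score is dominated by the fit
term and always selects the densest corner of the grid, whereas the
per-observation score selects strongly sparse models (specificity near
100%), which is the operating regime the reference results for AIC tuning
describe. Both are available (`likelihood_weight`). Grid cells are scored
at a relaxed ADMM tolerance (1e-5) with warm starts along the grid; the
winner is refit at 1e-9. The selection was checked to be insensitive to
the relaxed tolerance.

**Data-driven rule.** The alternative replaces the grid by small learned
update rules evaluated *during* a single ADMM trajectory: at each sweep,
$\lambda_1$ is refreshed from the sparsity-consensus residual
$\sum_g \|Z_g - \Theta_g\|_F^2$, $\lambda_2$ from the fusion residual,
and $\rho_1, \rho_2$ from Frobenius-norm summaries of the iterates. Each
rule is a single-layer affine map in log space followed by an exponential,
so outputs are strictly positive for any input, and the identity
initialization returns its input hyperparameter unchanged — making the
untrained procedure exactly a plain fit at the starting values
($\lambda_1 = \lambda_2 = 0.05$, the light end of the grid, a default that
favours the de-biased inference; $\rho_1 = \rho_2 = 1$). One trajectory
costs one ADMM solve versus one per grid cell, which is the method's
selling point.

The original training protocol for these rules is not described in the
source material beyond "single-layer networks trained on synthetic
problems"; the reconstruction here — explicitly flagged experimental —
trains the 15 weights by derivative-free Nelder–Mead search minimizing
(100 − mean support-recovery accuracy) on seeded synthetic problems with
known precision matrices, keeping the best weights seen (so training can
never return something worse than the initialization on the training
loss). Gradient-based unrolling of the ADMM was considered and rejected:
hand-differentiating through repeated symmetric eigendecompositions is
disproportionate for 15 parameters. Trained weights serialize to JSON and
reload bit-exactly.

## 5. The synthetic designs

`simulate`-module generators reproduce the validation designs:

* **Mean tests** (p = 63 channels): observations $x = T\xi + \mu_g$ with
  $TT' = \Sigma$ (symmetric square root — any factor with $TT' = \Sigma$
  is valid, and the symmetric one keeps the component model's
  interpretation). Components ξ are either standard normal
  (`"gaussian"`) or the mixed uniform–Laplace model
  $\tilde m z_1 + \hat m z_2$, $\tilde m = 0.7827$, $\hat m = 0.6224$,
  whose first four moments match the Gaussian ones: variance
  $\tilde m^2 + \hat m^2 = 1.0000$, fourth moment
  $1.8\tilde m^4 + 6\tilde m^2\hat m^2 + 6\hat m^4 \approx 3.00$. For
  those identities to hold, $z_1$ must be uniform on
  $(-\sqrt3, \sqrt3)$ — a wider $(-3, 3)$ interval, sometimes quoted for
  this model, is inconsistent with these constants, and the moment
  computation forces this reading. Covariances: identity, or the spike matrix
  $0.3I + 0.7\,\mathbf{1}\mathbf{1}'$ with one eigenvalue $0.3 + 0.7p$.
  The alternative shifts group 2's jth mean by $(-1)^j \kappa s^* \nu_j$,
  $\nu_j \sim N(0,1)$ fresh each replicate, with step $s^* = 3\times
  10^{-3}$ for $(n_1, n_2) = (100, 20)$ and $3\times 10^{-2}$ for
  $(20, 20)$. At the stated $s^*$, the $(100, 20)$ design's
  noncentrality is small relative to the statistic's null spread for any
  λ, so its power curve rises only modestly; the power-saturation check
  (rate > 0.9 at κ = 20) therefore uses the $(20, 20)$ spike design,
  whose curve saturates well before κ = 20.
* **Precision tests** (p = 50): a symmetric 0/1 adjacency with exactly
  $\mathrm{round}(s\,p(p-1)/2)$ upper-triangle edges (deterministic
  realized sparsity), weights uniform on (0.5, 1), symmetrized, plus
  $\epsilon I$ with $\epsilon$ chosen so the smallest eigenvalue is at
  least 0.1 — the perturbation is unspecified in the source and this rule
  guarantees positive definiteness for every seed. Scenarios I–VI cross
  sparsity $s \in \{0.1, 0.3, 0.5\}$ with per-group sample size
  $\in \{200, 500\}$.
* **Support metrics**: R1 (recall of true edges), R0 (recall of true
  non-edges) and accuracy, over ordered off-diagonal pairs, as
  percentages. The estimated support is read from the penalized
  $\hat\Theta$ at |entry| > 1e-6 — the de-biased matrices are generically
  dense, so "nonzero de-biased entry" is not a usable support definition;
  this thresholded-penalized reading is an interpretation and is recorded
  as such.
* **Null-distribution studies**: the true precision matrix is drawn
  **once** per scenario and held fixed while data are re-drawn each
  replicate — the studied locations are entries of one realized matrix,
  which is only meaningful against a fixed truth.

What the passing simulations establish: calibration and recovery under
independent, identically distributed epochs with the stated covariance
structures. What they do not establish: behaviour under temporal
autocorrelation within epochs, nonstationarity, artifacts, or non-Gaussian
heavy tails beyond the mixed model — real recordings have all of these,
and the epoching/preprocessing upstream of this package is assumed to have
dealt with them.

## 6. Channel analyses

`lasso_select()` regresses the 0/1 pre/post indicator on the channels with
squared-error loss and an $\ell_1$ penalty,
$\hat\beta = \arg\min_\beta n^{-1}\|Y - X\beta\|^2 + \lambda\|\beta\|_1$,
after centring and standardizing both sides; the coordinate-descent path
of glmnet does the optimization (its objective carries $(2n)^{-1}$, so its
penalty is λ/2 — verified against a proximal-gradient oracle to 1e-6). The
squared-error form is the primary — it is the objective the procedure is
defined by, even though the technique is often loosely called "lasso
logistic regression" — and a
logistic-loss variant sits behind `logistic = TRUE`. λ is chosen by
10-fold cross-validation (minimum-error rule, seeded folds) when not
given; "selected" means an exactly nonzero coefficient; λ = 0 with p < n
reduces to least squares. Per-individual selections aggregate by
`selection_frequency()`; how to group individuals is left to the caller.

`degree_centrality()` ranks channels by the number of incident
significant-change edges, ties broken by label order so reports are
deterministic; the top five are highlighted by convention.

## 7. Epoching and scale choices

Millisecond windows convert to row ranges at the sampling rate (floor on
the start, ceiling on the end; 0-based half-open ranges). The defaults are
a 100-row pre-stimulus baseline, P1 at 120–160 ms (20 rows at 500 Hz), and
N170 from 200 ms. The common N170 description "200–220 ms, 20 sample
points" is internally inconsistent at 500 Hz — 20 ms is 10 rows; the row
count is taken as authoritative (200–240 ms) because every test operates
on rows, and the literal 200–220 ms reading is available as
`n170 = "printed"`.

## 8. Problem sizes used in the shipped checks

The acceptance suite runs: size calibration at 2000 replicates per setting
(eight settings); one power curve at 400 replicates per κ; Scenario-I
support recovery over 50 replicates with a 10×10 coarsening of the 30×30
grid (the coarsening was checked to select the same region); the
data-driven-versus-AIC comparison on 8 replicates after a short synthetic
training run; and the null-distribution check at 200 replicates. These
sizes were chosen so the full suite completes on a single CPU in well
under half an hour while keeping Monte-Carlo error comfortably inside the
asserted bands.

## 9. Known limitations

* The fusion penalty in the objective sums over all pairs, the ADMM chains
  only adjacent pairs; identical for G = 2, documented for G ≥ 3.
* De-biased entrywise inference is asymptotic; in dense regimes (edge
  density 0.5) the penalty bias and the $\sqrt{n}$ convention interact as
  described in §3, and calibration at other penalty levels than the tuned
  ones is not guaranteed.
* The data-driven training reconstruction is experimental by design; its
  guarantee is graceful degradation (identity networks = plain fit), not
  optimality.
* Support-recovery metrics depend on the exact-zero threshold reading
  documented in §5; the reference results for AIC tuning report a
  combination of recall metrics that is mutually inconsistent under any
  single support rule, so matching their edge-recall figure is not
  expected, and the discrepancy is left visible rather than tuned away.
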