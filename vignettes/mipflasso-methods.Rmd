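---
title: "Riemannian tangent-space features and MIPF-LASSO selection for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Riemannian tangent-space features and MIPF-LASSO selection for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipflasso)
```

# The problem

Motor imagery (MI) — the mental rehearsal of a movement — modulates
sensorimotor EEG rhythms (mu, 8–13 Hz; beta, 15–30 Hz) through
event-related desynchronization and synchronization. A brain–computer
interface must decode which movement a subject imagined from a short
multichannel epoch. The spatial covariance matrix of an epoch is the
natural carrier of this information, but covariance matrices live on the
manifold of symmetric positive-definite (SPD) matrices, not in a
Euclidean space, and mapping them into one produces far more features
than there are trials. `mipflasso` implements the full chain: filter-bank
preprocessing, Riemannian tangent-space feature extraction, and a
penalized regression — the mutual-information pairwise-fused (MIPF)
LASSO — that selects a small, informative, correlation-aware feature
subset before an RBF-kernel SVM does the classification.

# Preprocessing

Epochs are cut with half-open windows `[t_start, t_end)` (0-based sample
indexing); the default analysis window for the standard MI timing scheme
is 2.5–6 s after trial start. Each windowed trial then passes through a
multi-scale filter bank: for each bandwidth $w \in \{2, 4, 8, 16, 32\}$ Hz
the 4–40 Hz range is tiled into contiguous bands $[4 + kw,\, 4 + (k+1)w]$
truncated at 40 Hz, keeping a truncated final tile iff its width is at
least $w/2$; this gives $18 + 9 + 5 + 2 + 1 = 35$ bands. The tiling rule
itself is this package's design (only the widths and the range are
standard practice for subject-specific MI rhythms); it is exposed in
`filterBankSpec()` so overlapping or alternative tilings can be swapped
in via the explicit `bands` table of `pipelineConfig()`.

Filters are second-order Butterworth band-pass designs applied
forward–backward (zero phase, effective magnitude order 4), with odd
reflective padding of three filter lengths to suppress startup
transients in short epochs. Zero-phase filtering keeps in-band peaks
aligned to within one sample, which matters when features are later
compared across bands.

# Riemannian feature extraction

For each trial and band the channel covariance is estimated with
analytic shrinkage toward the scaled identity (Ledoit–Wolf style convex
combination with data-driven intensity; `shrinkage = "lw"`), so the
matrix is SPD even for short or rank-deficient epochs. A fixed ridge
(`1e-6 * trace / C`) and a no-shrinkage mode are available.

Distances between covariances use the affine-invariant metric
$d(A, B) = \lVert \log(A^{-1/2} B A^{-1/2}) \rVert_F$. The per-band
reference point is the Fréchet (Riemannian) mean of the *training*
covariances, computed by the standard fixed-point iteration
$M \leftarrow M^{1/2} \exp\!\big(\tfrac1n \sum_i \log(M^{-1/2} C_i
M^{-1/2})\big) M^{1/2}$, initialized at the arithmetic mean, with
tolerance $10^{-8}$ on the Frobenius norm of the tangent mean and a cap
of 50 iterations (non-convergence is an error carrying the residual).
The reference is pooled across classes: per-class references are a
plausible alternative, but the pooled mean is the conservative choice
when train/test splits are small, and nothing downstream assumes
class-specific whitening.

Each covariance is mapped to the tangent space at $M$,
$S = \log(M^{-1/2} C M^{-1/2})$, and vectorized with the diagonal
unscaled and off-diagonal entries scaled by $\sqrt2$. That convention
makes the Euclidean norm of the feature vector *equal* to the geodesic
distance $d(M, C)$, so several package tests are exact identities rather
than approximations. With $C$ channels and $B$ bands the design matrix
has $p = B \cdot C(C+1)/2$ columns — e.g. 8855 for 22 channels and 35
bands — which is why selection is indispensable. Distances to class
means are *not* appended as extra features.

# The MIPF-LASSO estimator

Given the $n \times p$ tangent design $X$ (columns standardized to zero
mean, unit Euclidean norm, so $\rho_{ij} = x_i^\top x_j$ is the sample
correlation) and the response $y$ (binary labels coded $\pm 1$, then
centered), the estimator minimizes

$$
\lVert y - X\beta \rVert^2
+ \lambda_1 \sum_{j=1}^p \alpha_j \lvert \beta_j \rvert
+ \lambda_2\, J(\beta),
\qquad
J(\beta) = \sum_{j < i}
\frac{(\beta_i - \beta_j)^2}{1 - \rho_{ij}}
+ \frac{(\beta_i + \beta_j)^2}{1 + \rho_{ij}} .
$$

**Adaptive weights.** $\alpha_j = e^{-r I_j}$, where $I_j$ is the mutual
information (in nats) between feature $j$ and the class label and $r$
(default 5) trades off how sharply informative features escape the
penalty. $I_j$ is a plug-in estimate on an equal-frequency
discretization of the feature (8 bins by default, ties broken by rank
order; features with no more distinct values than bins are binned by
value identity, so already-discrete features keep their exact law). The
plug-in estimator is used without bias correction; at $n = 10^4$ its
bias for an irrelevant feature is well below $0.02$ nats, leaving
$\alpha_j \approx 1$. Weights are floored at $10^{-8}$ so the
back-transformation $\hat\beta_j = \beta^*_j / \alpha_j$ stays bounded.
MI is always computed on training folds only.

**Fusion penalty.** $J(\beta)$ is a quadratic form $\beta^\top W \beta$
with $W_{ii} = \sum_{j \ne i} 2/(1-\rho_{ij}^2)$ and
$W_{ij} = -2\rho_{ij}/(1-\rho_{ij}^2)$; the factor 2 is chosen so the
identity $\beta^\top W \beta = J(\beta)$ holds exactly (a convention a
constant rescaling of $\lambda_2$ absorbs). Correlations are clipped at
$|\rho| \le 0.999$ before forming $W$, because duplicated tangent
features do occur and the denominators $1-\rho^2$ must stay positive.
For strongly positively correlated pairs the difference term dominates
and the coefficients are driven together — the grouping effect that lets
correlated spectral features survive or vanish jointly.

**Reduction to LASSO.** With $R^\top R = W$ (Cholesky when $W$ is
numerically positive definite, a clipped symmetric eigen square root for
the rank-deficient case), stacking $\hat y = [y; 0_p]$ and
$\hat X = [X; \sqrt{\lambda_2} R]$ turns the quadratic penalty into a
residual block: $\lVert \hat y - \hat X \beta \rVert^2 =
\lVert y - X\beta \rVert^2 + \lambda_2 \beta^\top W \beta$ identically.
Dividing column $j$ of $\hat X$ by $\alpha_j$ absorbs the weighted L1
penalty, leaving an ordinary LASSO in $\beta^* = \alpha \odot \beta$.
The augmented design has $n + p$ rows, which is also what makes the
$p > n$ regime well-posed whenever $\lambda_2 > 0$.

**Solver.** Cyclic coordinate descent (C++ core), updates
$\beta^*_j \leftarrow S(x_j^\top r_{(-j)},\, \lambda_1/2) / \lVert x_j
\rVert^2$ — the threshold is $\lambda_1/2$ because the loss carries no
$1/(2n)$ factor. The objective is non-increasing across sweeps (each
update is an exact coordinate minimization); iteration stops when the
largest coefficient change in a sweep falls below `tol` ($10^{-6}$ by
default; inner cross-check tests use $10^{-10}$), with a cap of $10^4$
sweeps that flags `converged = FALSE` rather than erroring. Warm starts
are used along descending $\lambda_1$ paths. With $\lambda_1 = 0$ the
solution coincides with the closed form
$(X^\top X + \lambda_2 W)^{-1} X^\top y$; with $\alpha = 1,
\lambda_2 = 0$ it is a plain LASSO; both reductions (and the full
objective) are verified in the test suite against an independent
accelerated proximal-gradient minimizer that shares no code with the
coordinate-descent path.

**Variants.** `variant = "adaptive_lasso"` forces $\lambda_2 = 0$,
`"lasso"` additionally forces $\alpha = 1$, `"none"` returns the
unpenalized (minimum-norm) fit with every feature kept — the ablation
ladder used to attribute performance to each penalty ingredient.

**Tuning.** No canonical protocol exists for choosing
$(\lambda_1, \lambda_2)$ here, so `tuneMipfLasso()` defines this
package's own: stratified k-fold cross-validation over a grid, scored
either by the accuracy of an RBF-SVM refit on the selected features
(classification) or by the held-out MSE of an ordinary least-squares
refit on the selected features (regression — the direct analogue of the
classification route, and free of the L1 shrinkage bias that otherwise
drags the score toward over-selection). The best mean score wins; ties
break toward larger $\lambda_1$, then larger $\lambda_2$. A
one-standard-error rule (`rule = "1se"`) is available and is what makes
a pure-noise response land on the sparsest grid point. For regression
responses the adaptive weights are built from MI against an
equal-frequency 4-bin discretization of $y$, since the MI formulas
assume a discrete target.

# Classification and evaluation

The classifier is an RBF-kernel SVM; cost and kernel width are chosen by
a small stratified inner cross-validation (3 folds; cost in
$\{1, 10, 100\}$, $\gamma \in \{0.5, 1, 2\}/p$), deterministic given the
seed. Metrics are accuracy, F1 $= 2\,TP/(2\,TP + FP + FN)$ and G-mean
$= \sqrt{\text{sensitivity} \times \text{specificity}}$; degenerate
zero-denominator cases return 0 with a flag. Multi-class problems use
one-vs-rest selection (union of supports), a natively multi-class SVM
and macro-averaged F1/G-mean — the binary formulas are standard, their
multi-class averaging is a package choice.

`runPipeline()` fits everything data-dependent — tangent bases, MI
weights, selection, classifier — strictly inside training folds;
held-out trials are only projected and scored. When an explicit
train/test session split exists in the data it should be honored by
passing the sessions separately; otherwise stratified 5-fold CV with a
fixed seed is the default protocol.

# What the synthetic generators emulate

`genTwoClassTrials()` produces band-limited colored Gaussian noise,
spatially mixed by the square root of a class-specific covariance: class
1 uses a base SPD matrix, class 2 the same eigenvectors with the top
half of the eigenvalues inflated by $1 + \texttt{class\_sep}$. The two
class covariances therefore commute and sit at geodesic distance
$\sqrt{\lceil C/2 \rceil}\, \log(1 + \texttt{class\_sep})$ — a direct,
controllable handle on exactly the contrast the Riemannian stage must
detect, mimicking the band-power redistribution of ERD/ERS. Band
limiting reuses the preprocessing filter, so there is a single filtering
code path. Defaults (8 channels, 40 trials per class, 2 s epochs at
250 Hz, signal content 8–30 Hz, sensor noise sd 0.2) are a realistic
small montage at the standard MI sampling rate. What the generator does
*not* emulate: eye blinks, line noise, channel drift, nonstationarity
across a session, or subject-specific spectral peaks — so a passing
end-to-end test demonstrates the machinery recovers a known manifold
contrast, not that any particular accuracy will transfer to recorded
EEG.

`genSparseRegression()` builds block-equicorrelated Gaussian designs
($x_j = \sqrt\rho f_b + \sqrt{1-\rho}\, z_j$ within block $b$, columns
standardized afterwards so $\rho$ is interpretable) with exactly `k`
nonzero coefficients of alternating sign placed one per block — the
"strongly correlated, multicollinear predictors" regime the fusion
penalty targets.

# Numerical choices and degenerate inputs

- Logarithms are natural throughout (entropy in nats), so
  $\alpha = e^{-rI}$ composes without base conversions; the base is an
  argument where it matters.
- Symmetric eigendecompositions (`eigen(symmetric = TRUE)`) back all
  matrix powers/logs; matrices are re-symmetrized after products to keep
  round-off from accumulating.
- Zero-variance design columns are an error naming the column; constant
  features get MI 0 with a warning (and weight 1).
- An all-constant trial has no covariance and errors under every
  shrinkage mode; a merely rank-deficient trial is rescued by shrinkage.
- `ridgeFusion()` adds a $10^{-10}$-scale jitter only if the penalized
  normal equations are numerically singular; at $\lambda_2 = 0$ with
  $p > n$ it errors instead.
- Empty supports in the pipeline fall back to the 10 highest-MI columns
  so the classifier always has inputs; the tuner scores empty supports
  as majority-class / mean prediction.

# Problem sizes

The test suite and the reproduction script deliberately run at desk
scale: solver-versus-oracle checks use $n \le 60$, $p \le 15$ (and one
$p = 3n$ instance), support recovery uses $n = 100$, $p = 50$, $k = 5$
over 10–20 replicates, and the end-to-end runs use 8 channels, two
bands, 60–80 trials under 4–5-fold CV. These sizes exercise every code
path (including $p > n$) while keeping a full run in tens of seconds;
they are not the scale of a real 22-channel, 35-band analysis, which the
same code handles but with runtimes dominated by the $p \approx 9000$
feature matrix.

# Known limitations

- The MI estimator is plug-in over bins: no Kraskov/k-NN continuous
  estimator, no multivariate redundancy criteria (mRMR, JMI).
- Only the affine-invariant SPD metric is provided (no log-Euclidean or
  Wasserstein alternatives), and no CSP-style spatial filtering.
- Artifact rejection, re-referencing and channel interpolation are out
  of scope; the epoch container assumes clean, epoched input.
- The coordinate-descent solver targets the exact objective above; LARS
  and elastic-net/group variants beyond the ablation reductions are not
  implemented.
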