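---
title: "Global and local kernel association testing with laxkat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global and local kernel association testing with laxkat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laxkat)
```

## The testing problem

Vertex-wise neuroimaging studies ask whether a response (a cognitive
score, a diagnosis, sex) is associated with a high-dimensional predictor
image — thousands of cortical-thickness values per subject — after
adjusting for nuisance covariates, and, when it is, *where* the signal
lives.  The working model is a generalized linear mixed model

$$ g(E[y_i \mid \beta]) = x_i^\top \alpha + z_i^\top W \beta, \qquad
   E[\beta] = 0,\ \mathrm{var}[\beta] = \tau^2 I_p , $$

with a pre-specified diagonal weight matrix $W$.  Testing no predictor
effect is testing $H_0 : \tau^2 = 0$, a variance-component score test.
With $\hat y$ the covariate-only fit, $r = y - \hat y$ and
$\Delta = \mathrm{diag}(\delta)$ the dispersion weights
($\delta_i = 1$ for a Gaussian response,
$\delta_i = \hat y_i(1-\hat y_i)$ for a Bernoulli response), the SKAT
statistic is the quadratic form $Q_{\mathrm{SKAT}} = r^\top Z W^2 Z^\top r$.

SKAT requires committing to one $W$.  In imaging there is rarely a
principled single choice, but there *is* prior structure: an atlas
partitions the vertices into $q$ regions of interest (ROIs).  The LaxKAT
statistic maximizes the scale-invariant form over the whole subspace
$\mathcal{L}$ of diagonal kernels spanned by basis elements
$B_1,\dots,B_q$:

$$ Q_{\mathrm{LaxKAT}} = \max_{W \in \mathcal{L}}
   \frac{r^\top Z W^2 Z^\top r}{\mathrm{tr}(\Delta Z W^2 Z^\top)} . $$

The trace normalisation makes the ratio invariant to rescaling $W$, so
the maximum is over directions in the subspace, not magnitudes.

## Computing the maximum

**Atlas (mutually exclusive supports).**  When the $B_k$ have pairwise
disjoint nonzero coordinates — every atlas has this property, with $B_k$
the 0/1 mask of ROI $k$ — writing $W = \sum_k \phi_k B_k$ turns both the
numerator and the denominator into $\sum_k \phi_k^2 (\cdot)_k$, and the
maximum of a ratio of identically-weighted positive sums is the maximum
of the component-wise ratios.  The statistic decouples exactly into

$$ Q_{\mathrm{LaxKAT}} = \max_k Q_k, \qquad
   Q_k = \frac{r^\top Z B_k^2 Z^\top r}{\mathrm{tr}(\Delta Z B_k^2 Z^\top)}, $$

a maximum of scaled per-ROI SKAT statistics.  `laxkatStatistic()` on an
`AtlasBasis` computes every $Q_k$ by per-feature score accumulation
($u = Z^\top r$, $d_j = \sum_i \delta_i z_{ij}^2$, then sums over each
mask) and never forms the $n \times n$ kernel; ties in the maximum are
broken toward the smallest ROI index so output is deterministic.

**General basis.**  For basis elements with overlapping supports
(e.g. columns of a nonnegative matrix factorisation that are not
orthogonal), substitute $w = B\phi$ with $B$ the $p \times q$ matrix of
basis diagonals.  The ratio becomes a Rayleigh quotient in $\phi$ of the
reduced $q\times q$ pencil $A = B^\top \mathrm{diag}(u \circ u) B$,
$C = B^\top \mathrm{diag}(d) B$, and the maximum is the largest
generalized eigenvalue of $(A, C)$, solved in the symmetric-definite
form via a Cholesky factor of $C$ (`laxkatStatistic()` on a
`GeneralBasis`).  A singular $C$ — a degenerate basis or all-zero
predictors on a support — is an error, not a silent answer.  The suite
validates this route two ways: against the decoupled maximum on
exclusive bases (agreement to 1e-10) and against a staged 1e5-point
random search over $\phi$ on overlapping bases (agreement to 1e-5).

## Inference

**Global.**  No closed form exists for the null distribution of a
maximum of correlated SKAT statistics, so the global p-value is always
permutation-based.  Because the residuals and fitted values absorb the
response-covariate relationship, permuting residuals targets the right
null.  For a Gaussian response only $r$ is permuted ($\Delta = I$ is
fixed); for a Bernoulli response one shared permutation is applied
jointly to the residual and fitted vectors — they remain paired per
subject — and $\delta$ is recomputed from the permuted fitted values, so
the (now random) trace denominator is re-evaluated on every permutation.
We read the pairing as joint rather than independent permutation of the
two vectors: the pair $(r_i, \hat y_i)$ is the subject-level exchangeable
unit under the null, and breaking it would combine residuals with
dispersion weights from different subjects.

One pre-generated permutation table (deterministic in the seed) drives a
single vectorised pass that fills the per-ROI null draws and their
row-maxima at once, so the local p-values are recovered from exactly the
permutations used for the global p-value.  P-values use the add-one
estimator $(1 + \#\{Q^{(b)} \ge Q^{\mathrm{obs}}\})/(1 + B)$, which is
valid and never zero.  The pass processes permutations in column blocks
capped at about 5e6 matrix cells, keeping memory flat at full scale
($p \approx 10^4$, $B \approx 10^4$).

**Local.**  Each ROI is tested by comparing $Q_k$ to its own permutation
column, with Holm step-down correction (`stats::p.adjust`) across the
$q$ ROIs; because the global statistic is the maximum of the ROI
statistics, controlling the familywise error of the local tests is
coherent with the global test.  For Gaussian responses an analytic
alternative (`localMethod = "davies"`) uses the exact null of a scaled
quadratic form: a mixture $\sum_i \lambda_i \chi^2_{1,i}$ with
$\lambda_i$ the eigenvalues of
$\hat\sigma^2 \, Z_k^\top P_0 Z_k$ ($P_0$ the residual-forming
projection) and threshold $c \cdot Q_k^{\mathrm{obs}}$,
$c = \mathrm{tr}(Z_k Z_k^\top)$.  The tail probability is evaluated by
numerical inversion of the characteristic function (Imhof's integral via
`stats::integrate`, relative tolerance 1e-10) with a Liu–Tang–Zhang
four-moment fallback when the integration fails or leaves $[0,1]$; the
route taken is flagged in the `method` attribute.  Eigenvalues below
1e-10 of the trace scale are treated as zero, and a mask lying entirely
in the covariate column space is an error (no variability under the
null).

Two finite-sample facts matter when comparing the analytic and
permutation local p-values.  The analytic null plugs in
$\hat\sigma^2 = \mathrm{RSS}/(n-m)$, and the permutation null conditions
on the observed residual vector; the two distributions agree
asymptotically, with $O(m/n)$ drift at small $n$.  The suite therefore
checks agreement at the study's subject scale ($n = 400$), at
Monte-Carlo precision across the family of comparisons.

## The synthetic-data generator

No public vertex-wise dataset ships with the package, so the simulation
harness emulates the structure of one.  Defaults (desk scale):

* $n = 200$ subjects, $p = 500$ features in $q = 20$ equal ROIs of 25
  features — a scaled-down analogue of ~400 subjects, ~9000 vertices,
  34 ROIs.
* Base matrix `generateBaseMatrix()`: strictly positive, column means
  ~2.5 and sds ~0.3 (a cortical-thickness-like scale), with a
  one-factor-per-ROI Gaussian construction giving within-ROI column
  correlation 0.5 and cross-ROI correlation 0.1.  Entries are floored at
  0.05; the floor is ~8 sds below the mean and exists only to make the
  documented positivity unconditional.
* Covariates: intercept, an age-like N(72, 5²) covariate and a sex-like
  Bernoulli(0.5) covariate, independent of the response by construction
  — they exercise covariate adjustment without inducing confounding.
* Signal: the response $y \sim N(0, I_n)$ (or a latent $y_0$ thresholded
  at 0 for the binary design, since $\mathrm{expit}(t) > 0.5
  \Leftrightarrow t > 0$) perturbs the base matrix by the rank-one
  update $Z = Z_0 + y \otimes (V\gamma)$, confining the association to
  the signal ROIs; $\gamma$ is drawn fresh per replicate and per
  $\tau^2$, either $N(0, \tau^2)$ on the signal ROIs ("normal" shape)
  or the constant $\tau^2$ ("constant" shape).  At $\tau^2 = 0$ the
  update vanishes identically, so null calibration runs on untouched
  base data.

**Effect-size grids.**  The default normal-shape Gaussian grid is
$\tau^2 \in \{0,\ 5\!\times\!10^{-4},\ 10^{-3},\ 2\!\times\!10^{-3},\
4\!\times\!10^{-3}\}$.  The grid is the desk-scale analogue of a
0–0.01 range at full scale: per-ROI aggregate signal scales with the
mask size (25 here versus ~270 at full scale), and the chosen range
spans the operating curve from null to saturation under the generator's
factor-driven noise eigenstructure — a grid an order of magnitude lower
leaves power near the floor, which makes a power curve uninformative.
The binary design uses a 10× wider grid (thresholding the latent
response attenuates the induced association), and the constant-shape
design uses $\{0, 0.01, 0.02, 0.04, 0.08\}$ since there the per-column
signal is $\tau^2$ itself rather than a $N(0,\tau^2)$ draw.

`runExperiment()` evaluates three procedures per replicate — LaxKAT over
the atlas, identity-weight scaled SKAT (computed from the same
permutation pass), and a mass-univariate baseline that regresses the
response on the covariates plus each ROI's mean predictor and Wald-tests
the mean's coefficient — and tabulates global rejections at 0.05,
Holm-corrected local rejections at 0.05, and per-replicate false
discovery proportion (0 when nothing is rejected).  The base matrix and
covariates are generated once per scenario and held fixed across
replicates, mirroring a fixed imaging design; everything is reproducible
from the scenario seed.

**What passing these simulations does and does not show.**  The
generator reproduces the scale, positivity, block correlation and
ROI-confined signal of the motivating data, but real cortical thickness
has spatially smooth, heterogeneous covariance, ROI sizes varying by an
order of magnitude, and signal that need not respect ROI boundaries.
Calibration and relative-power conclusions here are evidence about the
method under a plausible correlation structure, not a reproduction of
any specific dataset's curves.

## Numerical and design choices

* `fitNull()` estimates $\hat\sigma^2$ with denominator $n - m$
  (unbiased residual variance), needed only by the analytic local
  p-values.  Logistic fits use IRLS with relative tolerance 1e-8 and at
  most 50 iterations; non-convergence is an error that reports the
  iteration limit, and perfect separation (fitted probabilities within
  1e-6 of 0/1 across a whole class) is a hard error because the
  dispersion weights would degenerate.
* Rank-deficient covariate matrices are rejected with the pivoted-out
  columns named.  The intercept is the caller's responsibility in the R
  API; the command-line interface prepends one unless `--no-intercept`.
* Predictor columns are used as-is — no internal centering or scaling.
  Residual orthogonality to the covariates (which include the intercept)
  is what the permutation scheme relies on.
* Unassigned features (atlas code `-1` by default) are excluded from all
  tests; their count is recorded on the `AtlasBasis` and logged by the
  CLI.
* Binary responses must be coded 0/1 in files; other codings are
  rejected rather than silently recoded.
* Sequential execution everywhere; the pre-generated permutation table
  makes results independent of any execution order.

## Limitations

A significant global test does not localise signal: the local step can
flag none, one, or several ROIs.  Within-ROI localisation is out of
scope, as are non-linear kernels, minor-allele-frequency-style weight
choices (no neuroimaging analogue), analytic nulls for the global
maximum, and FDR-controlling local procedures (FDR appears only as an
evaluation metric in the simulations).  For general overlapping bases
the package reports the global test only; per-basis-element inference
in that setting would need a different decomposition.

## A small worked run

```{r example, eval = FALSE}
set.seed(42)
atlas <- blockAtlas(p = 500, q = 20)
Z0 <- generateBaseMatrix(n = 200, p = 500, atlas, seed = 1)
X <- syntheticCovariates(200, seed = 2)
y <- rnorm(200)
sig <- unlist(roiMasks(atlas)[1:2])
gamma <- numeric(500)
gamma[sig] <- rnorm(50, 0, sqrt(4e-3))
Z <- perturbMatrix(Z0, y, sig, gamma)
res <- runLaxKAT(y, X, Z, atlas, nPerm = 999, seed = 3)
res
head(roiTable(res)[order(roiTable(res)$p_holm), ])
```

Note the distinct seeds: the data-generating helpers seed their own
temporary RNG streams, so giving `generateBaseMatrix()` the same seed as
the ambient stream that later draws `y` would replay the generator's
global factor into the response and manufacture an association
everywhere.
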