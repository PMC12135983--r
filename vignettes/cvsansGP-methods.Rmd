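---
title: "Estimating partial scattering functions from CV-SANS contrast series"
author: "cvsansGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating partial scattering functions from CV-SANS contrast series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvsansGP)
```

## The inverse problem

Contrast-variation small-angle neutron scattering (CV-SANS) measures the
same specimen at several solvent H/D compositions. For a p-component
incompressible system with p − 1 solutes in a solvent, each measured
intensity curve is a contrast-weighted sum of the partial scattering
functions:

$$I_n(Q) = \sum_{i \le j} A_{n,(i,j)}\, S_{ij}(Q), \qquad
A_{n,(i,i)} = \Delta\rho_{n,i}^2,\quad
A_{n,(i,j)} = 2\,\Delta\rho_{n,i}\Delta\rho_{n,j}\ (i<j),$$

where $\Delta\rho_{n,i}$ is the scattering length density difference
between solute $i$ and the solvent in sample $n$ (carried here in
$10^{-6}\,\mathrm{\AA}^{-2}$, so the design matrix entries are O(1–100)
and the linear algebra is well scaled). The factor 2 lives in the design
matrix, so each cross term is reported once per unordered pair, and pairs
are always ordered lexicographically: $(1,1), (1,2), \dots, (p-1,p-1)$.

The measured errors are modelled as independent Gaussians with known
per-point standard deviations $\sigma_{n,m}$ (heteroscedastic, never
assumed equal). Recovering the $L = p(p-1)/2$ latent curves
$S_\ell(Q_m)$ from the $N$ measured curves on a shared Q grid of $M$
points is then a linear-Gaussian inverse problem. The classical solution
is per-Q weighted least squares (`fitWLS()`), the minimum-variance
unbiased linear estimator; it ignores the one piece of prior knowledge
that is almost always available — $S(Q)$ is a smooth, slowly varying
function of $Q$.

## The Gaussian-process prior and the exact posterior

`fitGPR()` places a zero-mean Gaussian-process prior on each partial
scattering function along Q, independent across the $L$ functions:
stacking the curves ℓ-major / Q-minor gives
$\tilde S \sim \mathcal N(0,\, E_L \otimes D)$ with
$D_{mm'} = k(Q_m, Q_{m'})$. The flattened model is
$\tilde I = B \tilde S + \varepsilon$, $B = A \otimes E_M$,
$\varepsilon \sim \mathcal N(0, \tilde\Sigma)$, and the posterior is the
standard linear-Gaussian update

$$\mu = \tilde K B^\top (B \tilde K B^\top + \tilde\Sigma)^{-1} \tilde I,
\qquad
V^{-1} = \tilde K - \tilde K B^\top
         (B \tilde K B^\top + \tilde\Sigma)^{-1} B \tilde K .$$

The posterior mean is the point estimate; square roots of the diagonal
of $V^{-1}$ are the error bars. Nothing is approximated: the prior's
zero mean is kept exactly (no centering or standardisation — wide
amplitude grids compensate), negative posterior means are reported as-is
(a zero-mean Gaussian prior does not enforce positivity), and two
diagnostics are attached to every fit: the number of points whose mean is
negative with zero outside ±2 standard errors, and the number of points
violating the Cauchy–Schwarz bound $|S_{ij}| \le \sqrt{S_{ii} S_{jj}}$
(reported, never enforced).

### Numerical route

Intensities in this problem span several decades and the per-point
$\sigma$ even more (multiplicative noise), so the factorisation has to
survive extreme scale mixtures. The implementation uses the whitened
weight-space form: with $D = L_o L_o^\top$ (Cholesky, with an escalating
diagonal jitter from $10^{-12}(\alpha+\tau^2)$ up to $10^{-6}$, each
escalation logged, for nearly rank-deficient kernels) and
$W = \tilde\Sigma^{-1/2} (A \otimes L_o)$, the posterior covariance is

$$V^{-1} = \tilde K^{1/2}\,(I + W^\top W)^{-1}\,\tilde K^{1/2\top},$$

computed through the SVD of $W$. This form is positive semidefinite by
construction and remains exact in the two structural limits used as
self-tests: $\alpha \to \infty$ recovers weighted least squares (relative
gap $< 10^{-7}$ at $\alpha = 10^{12}$), and $l \to \infty$ with
$\tau = 0$ yields exactly flat per-function estimates (rank-1 prior). A
direct Cholesky of $B\tilde K B^\top + \tilde\Sigma$ fails in both limits
at this dynamic range. Posterior variances are clamped at zero where
cancellation reaches machine precision.

## Kernels

Three stationary families encode smoothness on the Q axis
(`kernelValue()`, distances on linear Q in $\mathrm{\AA}^{-1}$; an
optional log-Q transform is available but off by default):

* Gaussian: $\alpha \exp(-r^2/2l^2)$ — infinitely differentiable sample
  paths, the smoothest assumption;
* Matérn 3/2: $\alpha (1 + \sqrt3 r/l)\exp(-\sqrt3 r/l)$ — once
  differentiable;
* Matérn 5/2: $\alpha (1 + \sqrt5 r/l + 5r^2/3l^2)\exp(-\sqrt5 r/l)$ —
  twice differentiable.

The amplitude $\alpha$ is the prior variance of $S(Q)$ at every point:
larger $\alpha$ weakens the influence of the prior (the WLS limit above),
smaller $\alpha$ shrinks the estimate towards zero. The length scale $l$
sets how far information travels along Q: larger $l$ gives flatter, more
monotone estimates, and an extreme $l$ gives completely flat ones. A
white kernel $\tau^2 \delta_{PQ}$ is added with $\tau = 10^{-5}$ by
default; it stabilises the Gaussian kernel in particular (the Matérn
fits barely change between $\tau = 0$ and $10^{-5}$, while the Gaussian
kernel without a nugget can be derailed by its own excessive smoothness —
both behaviours are covered by tests). The Matérn 1/2 kernel
(non-differentiable paths) is deliberately not offered; it contradicts
the smoothness assumption that motivates the method. The ν-specific
closed forms are used directly; the general Bessel-function Matérn form
appears only as an independent oracle in the test suite.

One subtlety worth knowing: with $\tau > 0$ the prior grants each point
an independent variance $\tau^2$, so wherever the data's absolute
$\sigma$ is far below $\tau$ the posterior will follow the data rather
than the smooth trend — that is correct inference, not a defect. The
flat-prior limit is therefore exercised with $\tau = 0$ on the low-Q
subset, where $\sigma \gg \tau$ everywhere.

## Selecting kernel parameters

Three routes, in increasing order of automation:

1. **Fixed (subjective) choice** — pass a `KernelSpec` directly,
   justified by prior experience; decided before looking at results.
2. **MAP under a hyper-prior** — `mapObjective()` adds the log
   hyper-prior density over $(\alpha, l)$ to the evidence. Gaussian,
   log-normal and uniform hyper-prior families are supported
   (`HyperPrior()`); the default is log-normal, which respects
   positivity. For the Gaussian family the penalty is the pure quadratic
   $-(\alpha-\alpha_0)^2/2\beta_1^2 - (l-l_0)^2/2\beta_2^2$ (its
   normalizing constant dropped), so as $\beta \to \infty$ MAP reduces
   exactly to empirical Bayes; the log-normal and uniform families use
   their full log-densities. Only θ-independent constants differ between
   the conventions, so the argmax is never affected.
3. **Empirical Bayes** — `gridSearch()` maximises the log marginal
   likelihood $\log \mathcal N(\tilde I;\, 0,\, B\tilde K B^\top +
   \tilde\Sigma)$ over a grid. The log-determinant comes from the same
   whitened factorisation as the fit ($\log\det C = \sum \log(1+d_i^2) +
   \sum \log \sigma^2$), never from a raw determinant.

The default grids are $\alpha, l \in \{10^{-3}, \dots, 10^2\}$, six
log-spaced points each, with $\tau$ fixed at $10^{-5}$ — wide enough to
bracket the O(1) intensity scale of the simulator and the O(0.05–0.4)
$\mathrm{\AA}^{-1}$ extent of typical reduced data. `refine = TRUE` adds
one pass doubling the grid density around the winner (geometric
midpoints towards its neighbours). Ties within $10^{-6}$ are broken
towards the **smaller** length scale, then the smaller amplitude: the
evidence tends to prefer slightly flatter functions than the MSE
optimum, so when indifferent the less flat prior is the safer pick — a
behaviour quantified below. Kernel-family selection is reported
per-family but not automated: evidence differences between families are
typically too small to be meaningful.

## The core–shell validation study

`generateCoreShell()` reproduces a fully controlled benchmark: a
monodisperse sphere with core radius 50 Å and shell thickness 10 Å,
core/shell SLDs 4.0 and 1.0 ($10^{-6}\,\mathrm{\AA}^{-2}$), dispersed in
D₂O/H₂O mixtures at eight D₂O fractions (1.0 down to 0.0). Solvent SLD
mixes linearly between 6.36 and −0.56; the series includes the core
match point ($\phi_D = 0.66$, solvent SLD 4.007) and the shell match
point ($\phi_D = 0.22$, solvent SLD 0.962). With core amplitude
$A_C = V_c f(QR_c)$ and shell amplitude $A_S = V_o f(QR_o) - A_C$
($f$ the sphere amplitude $3(\sin x - x\cos x)/x^3$), the ground truth
is $S_{CC} \propto A_C^2$, $S_{CS} \propto A_C A_S$,
$S_{SS} \propto A_S^2$ — a single-particle model, so
$S_{CS}^2 = S_{CC} S_{SS}$ exactly.

Simulation choices, fixed once:

* **Q grid**: 100 log-spaced points over $[0.004, 0.4]\,
  \mathrm{\AA}^{-1}$, a typical reduced-SANS range; about half the
  points fall below the $Q < 0.05\,\mathrm{\AA}^{-1}$ cut used by
  `subsetLowQ()` (strict inequality). The low-Q subset excludes the
  oscillatory high-Q region where isolated points carry extreme relative
  uncertainty.
* **Noise**: multiplicative, $I = I_0 (1 + \eta)$,
  $\eta \sim \mathcal N(0, \sigma^2)$ with constant relative
  $\sigma = 0.05$ — a mid-range value for well-counted SANS curves; a
  per-(n,m) matrix override exists for heteroscedastic studies. The
  reported uncertainty is the generator's true standard deviation
  $\sigma |I_0|$.
* **Scale**: intensities are normalised by $V_o^2$ so $I(0)$ is O(1–10)
  in arbitrary units; because the noise is multiplicative the absolute
  scale is irrelevant to estimator behaviour.
* **Seeding**: all randomness flows through one seeded draw;
  regeneration with the same seed is bit-identical and the caller's RNG
  state is left untouched.

What the generator deliberately does **not** emulate: polydispersity,
instrumental resolution smearing, incoherent background, inter-particle
structure factors, and Q-dependent counting statistics. Passing the
validation suite therefore demonstrates correctness of the estimator's
mathematics and its comparative behaviour under idealised noise — not
performance on raw instrument output, which must be reduced upstream.

## What the validation quantifies

Run `Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`
to recompute all of the following from scratch (problem sizes: 8 samples,
100 or 55 grid points, 10 simulation seeds for comparative claims, 200
replicates for the unbiasedness study — small enough to finish in a
couple of minutes on one CPU):

* **Analytic worked examples**: solvent SLD at the match compositions;
  the posterior and evidence against brute-force dense-formula oracles
  on small random instances; the WLS and flat limits.
* **Headline comparison**: on the low-Q subset with evidence-selected
  Matérn 5/2 parameters, the GPR mean-squared error against ground truth
  beats per-Q WLS in essentially every seed, typically by an order of
  magnitude.
* **Evidence vs MSE**: the evidence-maximising length scale sits at or
  above the MSE-minimising one (within a grid step) in most seeds — the
  basis for the smaller-l tie-break above.
* **Error misspecification** (fixed reference kernel, Matérn 5/2,
  $\alpha = 10$, $l = 0.1$): halving the *reported* $\sigma$ (data
  unchanged) increases the total variation
  $\sum_m |\hat S(Q_{m+1}) - \hat S(Q_m)|$ of the estimate in most
  seeds; doubling it inflates the mean error bars in every seed.
  Overstating errors is benign; understating them buys spurious
  confidence. A caveat found while building the study: if the kernel
  parameters are *re-selected* by evidence on the misspecified data, the
  selection compensates (a stiffer kernel wins) and the net total
  variation can decrease under this generator's mild 5% noise — the
  waviness statement is a fixed-kernel statement here.
* **Gauss–Markov sanity**: across 200 replicates WLS is unbiased. With
  300 grid points a literal "every point within 3 Monte-Carlo SE" check
  would false-fail more often than not (expected exceedances
  $300 \times 0.0027 \approx 0.8$), so the check is applied familywise
  at the same confidence level: max $|z| \le 4.44$ (Bonferroni) plus a
  bulk condition on the share of points within 3 SE.

## Known limitations

* The prior's zero mean biases estimates towards zero when the amplitude
  is chosen small relative to the signal; the evidence largely guards
  against this, but strongly shrunk fits shed total variation, which is
  why the misspecification study fixes the kernel.
* Error bars shrink as $l$ grows not because the estimate is better but
  because the prior is stronger; error bars must not be used to select
  parameters — use the evidence or a hyper-prior.
* All samples must share one Q grid; curves on different grids must be
  interpolated upstream, since the prior covariance is defined on a
  single grid.
* Non-Gaussian (positivity-enforcing) priors, gradient-based
  hyperparameter optimisation, Q-dependent kernels and cross-function
  correlation kernels are out of scope.

## Session info

```{r}
sessionInfo()
```
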