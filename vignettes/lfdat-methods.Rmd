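---
title: "Methods: penalized function-on-function regression for longitudinal gene-region association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized function-on-function regression for longitudinal gene-region association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfdat)
```

## The model

A gene region spanning $[0, M]$ base pairs contains $L$ SNPs with
additive genotype coding $x_{is} \in \{0, 1, 2\}$ (copies of the minor
allele).  A quantitative trait is measured on a shared grid of $Q+1$
time points.  Treating the genotypes of subject $i$ as a function
$x_i(s)$ of genomic position and the trait as a curve $y_i(t)$, the
function-on-function regression model is

$$y_i(t) = \mu(t) + \int_0^M x_i(s)\,\beta(s,t)\,ds + \varepsilon_i(t),$$

where $\beta(s,t)$ is the time-varying effect surface and the errors are
correlated within a subject over time.  Centering both sides (subtract
the per-time trait mean and the per-SNP genotype mean) removes
$\mu(t)$.  The surface is expanded in a tensor product of marginal
B-spline bases, $\beta(s,t) = \sum_{j=1}^{m_s}\sum_{k=1}^{m_t} b_{jk}
\phi_j(s)\phi_k(t)$, giving $K = m_s m_t$ coefficients, and the model
becomes linear in $b$ with design entries

$$\psi_{i,(j,k)}(t_q) = \Big(\int_0^M x_i(s)\phi_j(s)\,ds\Big)\,
\phi_k(t_q).$$

Estimation minimizes the summed squared errors plus two roughness
penalties — the integrated squared second derivative of the surface in
the position direction (weight $\lambda_1$) and in the time direction
(weight $\lambda_2$) — leading to the penalized normal equations
$\hat b = (\Psi^\top\Psi + \lambda_1 R_1 + \lambda_2 R_2)^{-1}
\Psi^\top y$ with $R_1 = P_s \otimes M_t$ and $R_2 = M_s \otimes P_t$
($P$ = curvature Gram, $M$ = plain Gram of the marginal basis).

The null hypothesis of no association, $\beta(s,t) \equiv 0$
(equivalently all $b_k = 0$), is tested at each time point with

$$F(t_q) = \frac{(RSS_0(t_q) - RSS_1(t_q))/K}
{RSS_1(t_q)/(n - K - 1)} \sim F(K,\; n - K - 1),$$

where $RSS_0$ is the squared centered trait and $RSS_1$ the residual sum
of squares of the fit.  The per-time statistic is the primary output
(this is what the simulation studies tabulate); a whole-grid aggregate
using the summed $RSS$ is reported as a clearly labelled extra.

**What the reference distribution assumes.**  The $F(K, n-K-1)$
reference treats the fit at each time point as a $K$-dimensional
unpenalized projection.  In truth the $K$ coefficients are shared across
all $Q+1$ time points and shrunk by the penalties, so the per-time
$RSS$ reduction is far below $K\sigma^2$ and the test is *conservative*
under the null — deliberately so: the same sharing is what lets the test
report exactly zero evidence at time points where the effect vanishes.
Within-subject error correlation is likewise ignored by the reference
distribution (it affects the joint law across time points, not the
marginal per-time calibration direction); no correction is applied.
The package verifies conservativeness empirically (the type-I rejection
rate never exceeds the nominal level) rather than exactness.  The
single-measurement reduction of the same machinery — the smoothed FLM
comparator below, whose statistic is an honest $F(m_s, n-m_s-1)$ draw
under the null — is checked for exact calibration by a
Kolmogorov–Smirnov uniformity test.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `m_s`, `m_t` | 15, 15 | Marginal B-spline dimensions.  The coefficient count is $K = m_s m_t = 225$.  A two-dimensional basis "of size 15" is not constructible as an order-4 tensor product, so 15 is read as the marginal dimension; both knobs are exposed. |
| `order` | 4 | Cubic splines; the minimum smoothness for which second-derivative penalties exist is order 3. |
| `lambda_grid` | $10^2,\dots,10^6$ | Candidate smoothing weights, applied on the *raw* coordinate scales (positions in bp, time in its native units).  See "Coordinate scales" below. |
| `weights_mode` | `"step"` | Genotype-function convention: $x_i(s)$ is a step function, constant between the midpoints flanking each SNP.  The integrals $\int x_i \phi_j$ are then exact B-spline integrals — deterministic and interpolation-free.  A per-SNP point-mass mode is available. |
| `cv_method` | `"hat"` | Leave-one-**subject**-out cross-validation via the exact block hat-matrix identity; an explicit-refit mode exists as a verification path. |

### Coordinate scales

Both basis domains are kept in their physical units: $[0, M]$ base
pairs for position and the raw measurement interval for time.  On these
scales the curvature Gram entries are tiny (second derivatives scale as
$h^{-3}$ with the knot spacing $h$, which is large in bp), so the
default grid $10^2..10^6$ spans *weak to moderate* regularization — the
regime in which the method has its documented power.  Mapping the
domains to unit intervals would multiply the curvature Grams by factors
of order $10^3$–$10^9$ and turn the same grid into total shrinkage,
silently destroying power.  Keeping raw scales makes the printed grid
meaningful and makes results independent of an arbitrary normalization
choice.  Note that $\lambda_2 > 0$ is required whenever $m_t > Q+1$
(more time-basis functions than measurement times leaves
$\Psi^\top\Psi$ rank-deficient; the time penalty restores a unique
solution).

### Cross-validation unit and tie-breaking

Rows belonging to one subject are correlated, so cross-validation
leaves out whole subjects, not single observations.  Because the
penalized fit is a linear smoother, the deleted-subject residual is
available in closed form, $e_i^{cv} = (I - H_{ii})^{-1} e_i$ with
$H_{ii} = \Psi_i A^{-1} \Psi_i^\top$; `loocv_select(..., method =
"refit")` recomputes it by brute force and the two are required to agree
to $10^{-8}$ in the test suite.  Ties in the CV score go to the
smoother pair (larger $\lambda_1 + \lambda_2$, then larger
$\lambda_2$) — deterministic by construction.

### Numerical choices

* All Gram/penalty/weight integrals are per-knot-span Gauss–Legendre
  quadrature with `order + 2` nodes — exact for the piecewise-polynomial
  integrands, so "quadrature" introduces no approximation error.
* The penalized system is solved by Cholesky; on failure a single jitter
  of $10^{-10}\,\mathrm{tr}(A)/K$ is added, and a persistent failure
  raises an error naming the remedy (increase $\lambda$ or reduce
  $m_s, m_t$).  A monomorphic (all-zero) region therefore returns
  $\hat b = 0$, $F = 0$, $p = 1$ rather than crashing.
* Design rows are ordered subject-major, time-minor, and coefficient
  vectors flatten the surface row-major (position-major); both
  conventions are fixed so fits are bit-reproducible.
* For fitting, $\Psi$ is never materialized: with the tensor basis
  $\Psi^\top\Psi = (Z^\top Z) \otimes (\Phi^\top\Phi)$ and
  $\Psi^\top y$ is a reshaped $Z^\top Y \Phi$, reducing one fit at
  $n = 2000$, $K = 225$ to milliseconds.  `build_design` materializes
  the stacked matrix for small problems and for oracle verification.
* Rejection at level $\alpha$ uses $p \le \alpha$: identical to the
  strict inequality at any interior level, but it keeps the rate at
  $\alpha = 1$ equal to 1 even when a conservative $p$ rounds to
  exactly 1 in floating point.

## The simulation framework

The generators reproduce the study conditions of the simulation
designs:

* **MAF classes**: per SNP, MAF $\sim U(0.0005, 0.01)$ (rare),
  $U(0.01, 0.05)$ (low-frequency), $U(0.05, 0.5)$ (common); mixture
  regions draw per-SNP class membership 20/80 or 80/20
  (common/rare).
* **Linkage equilibrium**: genotypes Binomial(2, MAF) independently
  across SNPs and subjects.
* **Linkage disequilibrium**: each subject carries two independent
  haplotypes; alleles follow a first-order Markov chain whose
  conditional probabilities give adjacent-pair allelic correlation
  exactly $+\sqrt{r^2}$ with $r^2 \sim U(a, b)$ per pair (scenarios
  $(0.01, 0.25)$ and $(0.25, 0.64)$).  Genotypes are haplotype sums, so
  dosage correlations inherit $r$.  (MAF, $r^2$) draws admitting no
  valid chain are resampled and counted.  Only positive-sign LD is
  generated; the chain is adjacent-pair (first-order), not a dense
  block.
* **Phenotypes**: $y_i(t) = 1 + \sum_{s \in A} x_{is}\beta_s(t) +
  \varepsilon_i(t)$ on the raw time labels $t = 1..9$, with
  $\beta_s(t) = \pm\,\eta(s)\,\theta(t)$,
  $\eta(s) = \ln(c)\,|\log_{10}\mathrm{MAF}_s|/2$ (the drawn MAF
  parameter, not the sample MAF, so effect sizes are free of sampling
  noise), and $\theta(t) = 2 + 2\sin(\pi t/12)$ (case one) or
  $2 + 2\sin(\pi t/2)$ (case two — zero at $t = 3, 7$: the
  gene-switching scenario).  Errors are unit-variance with
  compound-symmetry correlation $\rho = 0.5$ (AR(1) available).  The
  causal set has $\max(1, \mathrm{round}(p_c L))$ SNPs and
  $\mathrm{round}(p_- |A|)$ negative signs.

### SNP density

The one quantity the study design leaves genuinely open is how many
SNPs a 1 kb region holds.  The choice interacts with the basis: the
position basis compresses $L$ SNPs into $m_s$ coordinates, and a
random causal SNP's signal survives that compression in proportion to
roughly $m_s/L$.  With the conventional $m_s = 15$ the documented
behaviour of the method — near-saturated power at $c = 7$ from a single
causal variant — requires the basis to resolve (essentially) every SNP,
i.e. $L \lesssim m_s$.  The default is therefore $L = 15$ per 1 kb,
a realistic resequencing-era density, and both $L$ and $m_s$ remain
configurable.  This is an inference from the method's design, not an
external fact; power results at much higher densities than the basis
dimension will be materially lower.

### What the generators do not emulate

Coalescent-realistic haplotype structure (recombination hotspots, dense
LD blocks, allele-frequency spectra), population structure,
covariates, missing data, and measurement-time jitter are all outside
the generators.  Passing simulation tests therefore demonstrates the
statistical machinery under the stated idealized conditions, not
robustness on arbitrary real cohorts.

## Evaluation metrics

For simulation studies the package reports, per replicate:

* **ISE0 / ISE1** — summed squared deviation between the true and
  estimated effect at the SNP-by-time grid cells without/with a true
  effect, divided by $(|\Gamma|-1)(|S_0|-1)$ and
  $(|\Gamma|-1)(|S_1|-1)$.  These $(-1)$ denominators are used verbatim
  (they are the tabulated convention) even though they are not plain
  means; both metrics require at least two sites and two time points,
  so ISE1 is undefined when only one SNP is causal.
* **PMSE** — squared prediction error on held-out subjects divided by
  $N - 1$.  The train/test split is 80/20 by subject, fresh per
  replicate and seeded; the ratio is configurable.

One scale caveat is documented prominently: the tabulated ISE
convention compares the fitted *continuum* surface against the
*discrete* per-SNP effect $\eta(s_l)\theta(t_q)$.  The functional
model's estimand at a SNP is the effect **density** — the discrete
effect divided by its step-interval width ($M/L$) — so the tabulated
ISE1 is dominated by the magnitude of the truth itself and moves only
marginally with estimation quality.  The tabulated convention is kept
for comparability; the *recovery* property (error shrinking with more
subjects and less noise) is verified in the test suite against the
density-scale estimand, on a fixed genotype pool with a fixed smoother
so that only $n$ and $\sigma$ vary.

## The smoothed FLM comparator

`smoothed_flm_test` regresses one time point's centered phenotype on
the same genotype-basis integrals $Z = G_cW$ used by the longitudinal
test, with ridge penalty $\lambda P_s$ and $\lambda$ chosen by ordinary
leave-one-out CV, and reports $F$ with $(m_s, n - m_s - 1)$ degrees of
freedom.  It deliberately reuses this package's genotype-function
convention rather than replicating any particular historical
implementation — a faithful-behaviour, not bit-faithful, baseline.  Its
two roles: it is near-nominal under the null (so it cannot tell a
switched-off gene from no gene — it keeps rejecting at $\approx\alpha$
at gene-off time points, where the longitudinal test drops to zero),
and it is the exactly-calibrated single-measurement reduction used for
the uniformity check above.

## Problem sizes used in the checks

The packaged acceptance studies run the simulation designs at their own
sample sizes ($n = 2000$ for power, $n = 1000$ for type-I error) with
200 and 500 replicates respectively; the Kronecker-factorized solver
makes a full study a matter of seconds.  Unit and property tests use
small instances ($n \le 400$, $m_s, m_t \le 10$) chosen so every oracle
comparison (direct inverse, explicit refit, dense Simpson integration)
is exact to its stated tolerance.

## Known limitations

* No covariates, no random subject effects, no population-structure
  correction.
* The reference distribution is used as stated; the per-time test's
  conservatism is a property, not a bug, but global error control
  across time points is not calibrated.
* Raw p-values only — no multiple-testing correction across regions or
  time points.
* The LD generator is first-order and positive-sign only.
* `ise_nonnull` is undefined for a single causal SNP (the
  $(|S_1|-1)$ denominator); metric studies need $|A| \ge 2$.
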