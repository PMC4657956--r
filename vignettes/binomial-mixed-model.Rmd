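---
title: "Binomial mixed models for differential methylation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binomial mixed models for differential methylation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bsbmm)
```

## The model

Bisulfite sequencing yields, per CpG site and individual, a methylated
read count $y_i$ out of a total $r_i$.  `bsbmm` tests each site for
association with a predictor $x$ under the binomial mixed model

$$y_i \sim \mathrm{Bin}(r_i, \pi_i), \qquad
  \mathrm{logit}(\pi_i) = w_i^\top\alpha + x_i\beta + g_i + e_i,$$
$$g \sim \mathrm{MVN}(0,\ \sigma^2 h^2 K), \qquad
  e \sim \mathrm{MVN}(0,\ \sigma^2 (1-h^2) I),$$

with covariates $w_i$ (an intercept at minimum), a known relatedness
matrix $K$ standardized to $\mathrm{tr}(K)/n = 1$, the heritability
$h^2 \in [0,1]$ of the logit methylation level, and the total
over-dispersion variance $\sigma^2$.  Both random terms model
over-dispersion relative to the binomial: $e$ captures independent
(environmental and technical) noise, as a beta-binomial would, while $g$
captures the component structured by kinship or population
stratification, which a beta-binomial cannot represent.  With $h^2 = 0$
the model is effectively a (logit-normal) beta-binomial; with large
$h^2$ ignoring $g$ either costs power (predictor independent of
structure) or produces false positives (predictor confounded with
structure).

The hypothesis of interest is $H_0: \beta = 0$.  Because the marginal
likelihood is an $n$-dimensional integral, the model is fitted by MCMC
with uninformative priors — $h^2 \sim U(0,1)$ and, by default,
$\sigma^2 \sim U(0, 10)$ — and approximate frequentist inference uses
the asymptotic normality of the posterior: $\hat\beta$ is the posterior
mean, $se(\hat\beta)$ the posterior standard deviation, and
$(\hat\beta/se)^2$ is referred to $\chi^2_1$.  The $\chi^2_1$ upper tail
is identical to a two-sided normal test by construction; it is stated
this way for determinism.

## Auxiliary-variable augmentation

The sampler augments the binomial-logit likelihood with an aggregated
random utility.  Writing $\lambda_i = e^{\psi_i}$ for the odds at the
current linear predictor $\psi_i$, one draws

$$T_i = \Gamma(r_i,\ 1 + \lambda_i) + \Gamma(r_i - y_i,\ \lambda_i)
  \quad\text{(rate parameterization; second term absent if } y_i = r_i),$$

and sets $z_i = -\log T_i$.  This construction arises from an
exponential-race representation of the $r_i$ Bernoulli trials: $T_i$ is
the sum of all success-clock arrival times, so that marginally
$z_i = \psi_i + \varepsilon_i$ with
$\varepsilon_i \sim -\log\Gamma(r_i, 1)$ *exactly* (the package's test
suite verifies this identity by Monte-Carlo KS tests).  The negative
log-gamma residual is then approximated by a finite normal mixture
indexed by $r_i$, standardized by the digamma/trigamma moments
$-\Psi(r)$ and $\Psi'(r)$: drawing a mixture component turns $z_i$ into
a Gaussian pseudo-datum with known heteroscedastic noise, and the model
conditional on the augmentation is an ordinary linear mixed model.

Mixtures are fitted on demand per $r$ (and cached) by
expectation-maximization on a density-weighted grid, with components
added until the Kullback–Leibler divergence from the exact density falls
below $5\times 10^{-4}$ nats; an internal safety factor of 0.9 is
applied so that an independent adaptive-quadrature evaluation of the
divergence also clears the tolerance.  After fitting, components are
affinely corrected so the mixture's mean and variance match
$-\Psi(r)$/$\Psi'(r)$ exactly.  Around $r \gtrsim 170$ a single normal
meets the tolerance (the distribution is asymptotically Gaussian, with
KL against its moment-matched normal decaying like $1/12r$), so the
table is finite in practice: $k$ falls from 6 components at $r = 1$ to 1
in the asymptotic regime.

A Pólya-Gamma backend (`backend = "polya_gamma"`, exact Devroye-type
sampling for trial counts up to 200 per draw, moment-matched normal
beyond) provides an exact augmentation.  It mixes faster per iteration
but costs $O(r_i)$ per individual; the package uses it as the
correctness oracle for the mixture backend, and tests require the two
backends' posterior means of $\beta$ to agree within 0.03 on fixed
fixtures, and the sampler to match a brute-force quadrature posterior
within 0.05 at small $n$.

## Sampler layout and complexity

Each sweep performs: (i) the augmentation above, $O(n)$; (ii) a joint
Gaussian draw of $(\alpha, \beta)$; (iii) coordinate-wise updates of the
genetic effect in the eigenbasis of $K$ ($g = Ua$, restricted to
eigenvectors with positive eigenvalue so the prior stays proper under
rank-deficient $K$), $O(n \cdot \mathrm{rank}(K))$ with a running
residual; (iv) a refresh of $e$ from its Gaussian conditional; and (v) a
random-walk Metropolis update of $(\mathrm{logit}\,h^2, \log\sigma^2)$
(two proposals per sweep, step 0.6).  The independent effect $e$ is
integrated into the observation noise during steps (ii) and (iii) and
redrawn afterwards — a partially collapsed scheme that roughly doubles
the effective sample size of $\beta$ at no extra cost.  The
eigendecomposition of $K$ is computed once per dataset, so per-sweep
cost is quadratic in $n$; an operation counter exposed on the fit
object lets the test suite verify the $O(n^2)$ scaling empirically.
Inner-loop random numbers come from a xoshiro256++ generator seeded from
R's RNG stream, so `set.seed()` fully determines a chain while keeping
the gamma/normal draws fast.

Defaults are 10000 iterations with 1000 burn-in for single-site fits.
Dataset scans in the bundled experiments use 2000 iterations with 200
burn-in, which keeps two independent scans' $-\log_{10} p$ correlated
above 0.95 on thousand-site datasets while keeping a scan of 1000 sites
at $n = 80$ to a few minutes on one CPU.

## Baselines

* **Beta-binomial regression** — logit-mean linear predictor with one
  dispersion $\phi \in [0,1)$ on the intraclass-correlation scale; joint
  ML by BFGS with analytic gradients ($\phi$ on the logit scale,
  restarts over dispersion inits), Wald tests from the observed
  information (LRT available).  A dense grid-search oracle guards the
  optimizer in the tests.
* **Binomial GLM** — `glm` with binomial totals; perfect separation is
  flagged and the p-value set missing.
* **Linear and linear mixed models** — run on per-site transformed
  methylation proportions (quantile-normal by default; logit, M-value
  with offset 0.01, arcsine-square-root available), with missing cells
  imputed by k-nearest-neighbour sites (k = 10, deterministic
  tie-breaks).  The LMM profiles its ML log-likelihood over
  $h^2 \in [0,1]$ in the eigenbasis of $K$ (Brent on the logit scale,
  multi-start, boundary checks).  ML rather than REML is used; we
  checked both on the study conditions and the power and ranking were
  indistinguishable.
* **Fisher's exact test** — two-sided, on counts pooled within the two
  levels of a binarized predictor.

## The generative simulator

`simulate_dataset()` reproduces the study conditions end to end:

* **Kinship.** `baboon_like` builds matrilineal family groups the way a
  wild primate social group is structured: about 50% of individuals have
  no relative in the sample, families of 3–8 share distant relatedness
  ($r = 0.125$), and close dyads (parent–offspring or full sibs
  $r = 0.5$, half sibs $r = 0.25$; about 10% of individuals) are nested
  within families.  `two_pop` derives $K = XX^\top/p$ from a synthetic
  two-subpopulation genotype matrix (Balding–Nichols allele frequencies,
  $F_{st} = 0.15$) — the construction also used for confounding designs,
  where the predictor is PC1 of the genotypes plus Gaussian noise scaled
  so the realized $R^2$(predictor, PC1) hits its target exactly.
* **Predictor.** `age_like` draws ages uniformly on [1.76, 18.01] years,
  the observed span in the motivating baboon sample.
* **Methylation.** Per site, a baseline $a_0 \sim
  U(\mathrm{logit}(0.1), \mathrm{logit}(0.9))$ (so simulated sites
  survive the hyper/hypo-methylation filters); for true-positive sites
  $\beta = \sqrt{pve\,\sigma^2 / ((1-pve)\,\mathrm{Var}(x))}$, which
  makes the per-site variance explained by the predictor, relative to
  the total random variation $g + e$, exactly `pve`; then
  $g$, $e$, and the logit link as in the model.  $\sigma^2$ defaults to
  0.5 — a deliberate choice, since the motivating study estimated it
  from data that are not redistributable; power at fixed PVE is only
  weakly sensitive to it, and the no-structure power levels obtained
  under 0.5 match the published ones closely.
* **Coverage.** Total read counts are negative binomial with per-site
  $(t, p)$ drawn from a coverage pool.  `fit_nb_coverage_pool()` fits
  such a pool from any real count matrix (per-site ML via
  `MASS::fitdistr`); the default synthetic pool draws per-site mean
  coverage log-normally (meanlog 2.43, sdlog 1.3, so site means span
  orders of magnitude and their lowest quartile is ~4.7 reads,
  matching the realized filter cutoff reported for RRBS data) and NB
  size parameters log-normally around 3.

What the simulator does *not* emulate: spatial correlation along the
genome (sites are independent), sequence context, bisulfite conversion
error, and mapping artefacts.  Passing tests therefore demonstrate
statistical behaviour under the stated generative model, not robustness
to those real-data features.

## Evaluation machinery

Empirical FDR follows the permutation recipe (four permutations of the
predictor by default): at candidate threshold $t$,
$\widehat{FDR}(t)$ is the average number of permuted p-values $\le t$
over the number of observed p-values $\le t$, monotonized by a running
minimum from the largest threshold downward (the monotonization is our
addition, needed for a well-defined threshold).  In simulations the same
scan is computed from truth labels.  Storey q-values use the standard
$\lambda$-grid $\pi_0$ estimator with a df-3 smoothing spline (BH
fallback with a warning below 100 sites).  Genomic control is
$\lambda = \mathrm{median}(\chi^2_1\text{-quantiles})/0.4549$.  DMRs
chain consecutive significant CpGs: gaps of at most 1 kb, at least 3
significant sites, at most 3 non-significant sites inside, bounds at the
first/last significant CpG; an exhaustive-window oracle in the tests
pins the greedy implementation down.

## Numerical choices and degenerate inputs

* Individuals with $r_i = 0$ (or missing) are dropped per site by count
  models; the linear-model path instead imputes after transformation.
* Linear predictors are clamped to $\pm 30$ before exponentiation.
* Relatedness matrices are symmetrized, negative eigenvalues clipped at
  zero, and the trace renormalized; inputs that are already standardized
  are kept bit-exact.  Asymmetry beyond $10^{-6}$ (relative) is an
  error.
* The logit transform clamps proportions to
  $[1/(2 r_{\max}), 1 - 1/(2 r_{\max})]$ with $r_{\max}$ the site's
  maximum coverage; quantile normalization maps average-tie ranks
  through $\Phi^{-1}((\mathrm{rank}-0.5)/n_{obs})$.  Both offsets are
  our choices to avoid infinities.
* Site filters run in a fixed order (observation fraction,
  hyper/hypo-methylation, SD quantile, coverage quantile) with the
  quantile cutoffs recomputed on the sites surviving earlier rules;
  computing them on the full input is available via
  `filter_config(quantiles_on = "all")` since published pipelines are
  ambiguous on this point.
* The fixed-effect draw uses a vague N(0, 100) working prior for
  numerical properness.

## Problem sizes used in the bundled checks

The packaged tests run the simulation designs at 1000 sites (100 true
positives) instead of the full 5000 (500), with the BMM at 2000
iterations per site.  The acceptance script uses 2000 sites (200 true
positives) for the shared no-structure design and the full 5000 for the
beta-binomial-only kinship design, because a power estimate at a 10%
empirical FDR is threshold-like: with only ~100 true positives and
~900 nulls the realized detection cutoff hangs on a handful of null
tail p-values, and the estimate can swing tens of percentage points
between dataset realizations.  These sizes keep a full reproduction to
tens of minutes on a single core.  The confounded-null false-call
design runs at its full size (1000 individuals, 5000 sites) for the
beta-binomial arm, and at $n \le 200$ for the BMM arm.

## Known limitations

* Power values for the transformed-proportion baselines depend on the
  spectrum of the relatedness matrix.  With the clean block-structured
  kinship generated here, the linear mixed model retains more power
  than published comparisons that used a noisy microsatellite-estimated
  kinship matrix; see the package tests for the values actually
  obtained.
* The magnitude of beta-binomial miscalibration under confounding
  depends on how much genetic variance the top principal component of
  the kinship carries; with the synthetic two-population structure used
  here the inflation is stronger than with the empirical population
  structure of the original comparison.
* MCMC-based p-values carry Monte-Carlo noise; at 2000 iterations the
  per-site noise is visible (seed-to-seed $-\log_{10}p$ correlation
  ~0.97), and borderline sites can move across a fixed threshold
  between runs.  Use more iterations for final analyses.
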