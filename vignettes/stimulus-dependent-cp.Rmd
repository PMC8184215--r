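---
title: "Stimulus-dependent choice probabilities: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-dependent choice probabilities: models, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpstim)
```

## The problem

In a two-choice perceptual task (the canonical example being coarse motion
discrimination with random-dot stimuli), the *choice probability* (CP) of a
sensory neuron is the probability that a spike count drawn from trials ending
in choice $D=+1$ exceeds a count drawn from $D=-1$ trials — an ROC-area
statistic, with 0.5 meaning no activity–choice covariation. CPs are almost
always reported as a single number per neuron, either from the uninformative
stimulus alone or pooled across stimulus levels. `cpstim` implements a full
toolkit for the richer question: **how does a neuron's CP change with the
stimulus level**, summarized through the *choice rate*
$p_{CR} = p(D = +1)$, which the psychometric function ties to the stimulus.

## The decision-threshold model and its exact CP

The core model assumes a continuous decision variable $d$ (approximately
Gaussian, being a population readout), a threshold $\theta$ with $D = +1$
iff $d > \theta$, and a bivariate-Gaussian joint distribution of a neuron's
response $r$ and $d$ with correlation $\rho$ (the *choice correlation*, CC).
Two numbers then determine the CP exactly:

$$\mathrm{CP} = \tfrac12 +
  \frac{T\!\left(\Phi^{-1}(p_{CR}),\; \rho/\sqrt{2-\rho^2}\right)}
       {p_{CR}(1-p_{CR})},$$

where $T$ is Owen's T function. `cp_exact()` implements this;
`owens_t()` evaluates the kernel by 64-node Gauss–Legendre quadrature after
the standard range reduction, which is exact to well below $10^{-10}$ on
this analytic integrand (the test suite checks it against adaptive
quadrature). At $p_{CR} = 0.5$ the expression reduces to the arctangent
closed form $\tfrac12 + \tfrac{2}{\pi}\arcsin(\rho/\sqrt2)$.

For weak covariations the linear approximation

$$\mathrm{CP}(p_{CR}) \approx \tfrac12 + \frac{\sqrt2}{\pi}\,
  h(p_{CR})\, \mathrm{CC}(p_{CR}), \qquad
  h(p) = \frac{\sqrt{2\pi}\,\phi(\Phi^{-1}(p))}{4p(1-p)}$$

separates a universal, threshold-induced modulation $h$ (equal to 1 at
$p_{CR}=0.5$, symmetric, and growing as one choice dominates) from the
cell-specific CC. A remark on the constant: rendered versions of the linear
formula are typographically ambiguous between $\sqrt{2}/\pi \approx 0.450$
and $\sqrt{2/\pi} \approx 0.798$. We resolved it numerically: only
$\sqrt2/\pi$ is consistent with the exact Owen's-T solution (and with the
arctangent closed form, whose slope in $\rho$ at $p_{CR}=0.5$ is
$\sqrt2/\pi$), so that constant is used throughout, together with
$\mathrm{CP} \approx \tfrac12 + \mathrm{CTA}/(2\sqrt\pi\,\sigma_r)$ for the
choice-triggered-average form and
$\mathrm{CTA} = \tfrac{4h(p_{CR})}{\sqrt{2\pi}}\rho\,\sigma_r$. The
acceptance suite verifies that the linear form stays within 0.01 of the
exact CP for $|\mathrm{CC}| \le 0.3$ and $p_{CR} \in [0.1, 0.9]$, and that
the exact CP matches brute-force Monte-Carlo sampling of the thresholded
bivariate Gaussian on a $5\times5$ parameter grid at $n = 10^6$.

```{r exact-vs-linear}
p_grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
rbind(exact  = sapply(p_grid, function(p) cp_exact(threshold_params(0.2, p))),
      linear = cp_linear(0.2, p_grid))
```

## Gain fluctuations and cell-specific CP profiles

A shared multiplicative gain $g$ (mean 1, variance $\sigma_G^2$) applied to
the tuning curves $f(s)$ adds a rank-one, stimulus-dependent component
$\sigma_G^2 f(s)f(s)^\top$ to the population covariance. With an optimal
linear readout fixed at the uninformative stimulus $s_0$, this perturbs the
choice correlation linearly in the stimulus offset $\Delta s$:

$$\mathrm{CC}_i(p_{CR}) = \mathrm{CC}_i(0.5) +
  \sigma_G \lambda_i \left(1 - \mathrm{CC}_i^2(0.5)\right)
  \frac{\Delta s}{\sigma_d},$$

with $\lambda_i^2$ the fraction of neuron $i$'s variance caused by the gain.
The slope is non-negative for every neuron, so gain fluctuations produce an
*asymmetric* CP profile — rising toward the neuron's preferred direction —
on top of the symmetric $h(p_{CR})$ dip/peak, and they induce a negative
covariation across neurons between $\mathrm{CC}(0.5)$ and asymmetry (high-
$\lambda$ cells have attenuated central CPs,
$\mathrm{CC}(0.5)=\sqrt{1-\lambda^2}\,\mathrm{CC}_0(0.5)$, but steeper
slopes). A neuron with $\mathrm{CC}(0.5)=0$ can even cross from CP < 0.5 to
CP > 0.5 across the stimulus range. `cc_gain_profile()` and
`cp_profile_prediction()` implement these predictions;
`lambda_fraction()` reproduces the worked reference values
$\lambda^2 = 0.5$ and $0.09$ for $\sigma_G^2 = 0.1$ and $0.01$ at rate 10
with non-gain variance equal to the rate.

## Empirical profiles

`estimate_cp()` is the Mann–Whitney estimator with half-credit for ties
(the convention that makes identical distributions give exactly 0.5; tie
handling is otherwise a free choice). Its standard error uses the
flat-CP approximation $1/\sqrt{12 K p_{CR}(1-p_{CR})}$ — e.g. 0.18 at
$K = 30$, $p_{CR} = 0.9$, where only three minority-choice trials are
expected — which motivates everything that follows: single-level CPs at
informative stimuli are noisy, so levels are pooled into five $p_{CR}$ bins
$[0,0.3]$, $[0.3, 0.5-\varepsilon]$, central, $[0.5+\varepsilon, 0.7]$,
$[0.7,1]$ via the subject's psychometric function (`fit_psychometric()`,
binomial ML with a probit link by default, logit as an option), with
$\varepsilon$ set per data set to half the smallest
$|p_{CR}-0.5|$ among informative levels so the central bin contains only
the zero-coherence trials. Within bins and across cells, CPs are combined
with unnormalized weights $K_j p_{CR,j}(1-p_{CR,j})$ (inverse squared SEM),
using psychometric-predicted rather than raw choice fractions (stabler at
high coherence). Only cells with a *complete* five-bin profile enter
cross-cell averages — otherwise the profile shape confounds within-cell
stimulus dependence with which subset of cells contributes at each level —
and averages are computed separately for cells with mean CP above and below
0.5 (ties go to the "above" group), since the threshold modulation inverts
with the CC sign. A cell's "mean CP" for grouping is the bin-level
inverse-error-weighted mean; trial-weighted averaging would be an
alternative, and the choice is configurable in spirit by recomputing from
the per-bin values.

## Surrogate significance testing

The null hypothesis is a $p_{CR}$-independent CP. Because SEMs vary with
$K$ and $p_{CR}$ across bins, apparent profile structure can be a pure
sampling artifact; the test therefore builds surrogates that preserve the
per-level per-choice trial counts exactly. Responses from low-information
levels (default window $\pm1.6\%$ coherence) are pooled after a
*choice-conditioned z-scoring*: each level's location and scale are
estimated as the unweighted average of the two choice-conditional moments
(mean $(m_+ + m_-)/2$; variance $(v_+ + v_-)/2 + (m_+-m_-)^2/4$ with
denominator-$n$ variances), which removes the choice-rate weighting that
makes plain z-scoring underestimate pooled CPs. For exactly balanced
choices it reduces to ordinary z-scoring, and the suite verifies the
no-bias property on a constant-CP construction rather than any particular
printed formula. Surrogate draws are with replacement (keeping level pools
independent). The statistic is built from bin differences
$\Delta CP_k$: averaged as-is (asymmetric variant), sign-flipped on the
$p_{CR}<0.5$ side (symmetric), or additionally inverted for mean CP < 0.5
(threshold variant). The p-value is the plain fraction of surrogates at or
above the observed statistic (no add-one smoothing; a smoothed option
exists). For multi-cell tests the statistic is computed on the
cell-averaged profile — applying the same machinery after averaging — which
is one of two defensible readings of the procedure; computing per-cell
statistics and averaging those would be the other.

Calibration is checked empirically: on constant-CP simulations with
realistic trial counts (one cell per run, seven levels, 30–60 trials per
level), 1000 runs with 200 surrogates each reject at the 5% level at a rate
within $0.05 \pm 0.02$.

## Clustering and the 2-D profile space

Profile shapes are clustered with spherical k-means on the centered
profiles $\mathrm{CP}-0.5$ under cosine dissimilarity (assignment by cosine
similarity, centers renormalized member means), 100 random restarts under a
master seed, best objective kept — initialization and restart counts are
unstated in the source material, so these are package choices. Surrogate
cluster significance re-runs the identical clustering per surrogate and
matches clusters to the originals by CP-sign and center correlation (labels
being arbitrary). Template projections use unit-norm constant and
centered slope-1 templates over the five bins (plain inner products;
normalization again a package choice), and the 2-D embedding takes the
main-cluster center difference as the horizontal axis and, per CP-sign
group, the orthogonalized subcluster-center difference as vertical.
`fit_cp_quadratic()` regresses per-level CPs on the stimulus and reports
the linear coefficient as the empirical asymmetry slope, which the
acceptance suite correlates (r > 0.5 required) with the gain-model
prediction $\beta_{p_{CR}} = \sigma_G\lambda_i(1-\mathrm{CC}_i^2(0.5))$
across a 50-neuron simulated population, alongside recovery of
$\sigma_G^2$ within 20% by the negative-binomial moment estimator
(`estimate_gain_variance()`, least squares on
$\hat v_\ell = \hat\mu_\ell + \sigma_G^2 \hat\mu_\ell^2$, clipped at zero).

## GLMs with stimulus–choice interactions

All models are Poisson with log link:
$\log\mu = \sum_{j=0}^{4} a_j s^j + \sum_{j=1}^{N_c} I_{P_j}(p_{CR})\, b_j D$,
with $D \in \{-1,+1\}$ and the stimulus entering as a fourth-order
polynomial of signed coherence (standardized internally by its maximum
absolute value for conditioning; coefficients reported on the raw scale).
The $N_c$ choice-coefficient subsets come from exact one-dimensional
k-means on the five bin CPs — non-contiguous groupings are the point, since
a symmetric profile wants its two extreme bins to share a coefficient.
Fitting is IRLS (`stats::glm.fit`), unregularized.

Model comparison uses the cross-validated *relative increase in
likelihood*,
$\mathrm{RIL} = (L_{\text{choice,stim}} - L_{\text{stim}}) /
(L_{\text{stim}} - L_0)$. Each of 50 repeats pools trials per
(choice-level, choice), draws 80% of the smaller choice pool from both
pools — so training sets are exactly choice-balanced within every level —
fits **all** competing models on the same training set and evaluates them
on the same held-out set, making the likelihoods directly comparable; the
$N_c \in \{2,3\}$ variant with the better held-out likelihood is reported.
The bin partition is derived once per cell from all data (not re-derived
per fold), which mirrors the described analysis sequence but is a mild
optimism source worth remembering. The RIL denominator requires genuinely
stimulus-driven cells ($L_{\text{stim}} > L_0$ held out); the synthetic GLM
cells therefore carry a realistic tuning slope (0.04 log-units per %
coherence at rate 10), as sensory neurons in this preparation do. On
sign-flipping choice effects ($b > 0$ for $p_{CR} > 0.5$, $b < 0$ below)
the stimulus-dependent model dominates the single-coefficient model in
essentially every run, while the single-coefficient RIL sits near zero —
the sign flip cancels; on constant choice effects the two agree closely.

## The synthetic generator and what passing tests do (and do not) show

`simulate_trials()` draws, per trial, a shared gain
$g \sim \Gamma(\text{mean } 1, \text{var } \sigma_G^2)$ (so counts are
negative-binomial marginally, making the moment estimator exactly
specified), conditionally Poisson counts at rates $g f_i(s)$ with
linearized tuning, a decision variable $d = w^\top r$ with optimal weights
by default, and $D = \mathrm{sign}(d - \theta)$ with the unbiased threshold
$w^\top f(s_0)$. Defaults emulate the classic single-unit archive design:
11 signed coherence levels, 30 trials at high coherence, 45 at weak levels,
60 at zero; default $\sigma_G^2 = 0.1$ (the strong-gain worked value;
$\lambda^2 = 0.5$ at rate 10). The non-gain noise floor is Poisson
(variance equal to the rate, the reference configuration); off-diagonal
base covariance is available through a Gaussian copula, whose marginals are
then only approximately matched — the microstructure of non-gain
correlations is unconstrained by the model and we make no stronger claim.
The generator shares trials across neurons (a simultaneous population), has
no temporal structure within trials, no feedback dynamics, no
serial dependence across trials, and gain that is perfectly global; real
data violate all four, so green tests here validate the estimators'
internal consistency and calibration, not their behavior under, e.g.,
inhomogeneous gain or choice-history effects.

One consequence of the shared-trial design deserves emphasis: the
surrogate test treats cells as independently recorded (as single-unit
archive sessions are), generating surrogates per cell. Applied to a
*simultaneously* simulated population, the observed cell-averaged
statistic has cross-cell correlations — every neuron sees the same gain
draws and choices — so its null spread exceeds the surrogate spread and
group-level p-values are not calibrated in that regime. Group tests should
therefore be read as session-per-cell analyses; the calibration check runs
one cell per session accordingly.

Problem sizes used by the heavier checks (chosen once as realistic study
scales): $10^6$ draws per Monte-Carlo grid point for the exact-CP oracle;
1000 runs × 200 surrogates for test calibration; 50 neurons × 9 levels ×
200 trials for gain-parameter recovery; 15 + 10 runs × 20 CV repeats for
the GLM comparison.

## Numerical and degenerate-input policy

Choice rates are accepted only within $[10^{-6}, 1-10^{-6}]$ (the exact CP
degenerates at the endpoints; empirical rates are clipped to
$[0.01, 0.99]$ by the psychometric predictor). Levels failing the
inclusion rule (≥ 15 trials, ≥ 4 per choice) yield an exclusion sentinel,
never an error; incomplete profiles carry a flag. Zero-variance levels and
single-choice levels inside the surrogate pooling window are skipped with a
warning. Cosine-undefined (zero) profiles are excluded from clustering with
a warning; empty k-means clusters are reseeded at the worst-assigned point.
GLM non-convergence is reported in a flag rather than raised. All
stochastic entry points either take a `seed` argument or respect the
caller's RNG state, and fixed seeds give byte-identical pipeline outputs.
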