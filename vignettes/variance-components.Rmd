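---
title: "Comparing species richness and composition by variance components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing species richness and composition by variance components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Grassland biodiversity experiments manipulate two aspects of diversity at
once: *species richness* (how many species are sown in a plot) and
*species composition* (which particular set of species is sown). Asking
which of the two matters more for aboveground annual net primary
production (ANPP, g m⁻² yr⁻¹) is statistically awkward. In a classical
multi-stratum ANOVA, richness (1 DF when treated as a continuous log₂
regressor) and composition (hundreds of DF) are tested against
*different* error strata, so their F and P values are not comparable; and
the percent of total sums of squares ignores the enormous DF disparity,
so R² is not comparable either. The two familiar summaries can point in
opposite directions on the same data.

`vcanova` implements the estimation-based alternative: put every
explanatory term — fixed or random — on a common scale by computing its
**finite-population standard deviation**, the SD of the realized effects
of the levels actually present in the study, and compare those with
uncertainty intervals ("graphical ANOVA"). The package provides three
mutually cross-checking engines plus a forward simulator:

1. `sequential_ss()` / `assemble_anova()` — least-squares multi-stratum
   ANOVA with Type-I sequential SS and an explicit error-term map;
2. `reml_fit()` — REML crossed-random-effects model (via `lme4`) with
   likelihood-ratio tests and BLUP per-site slopes;
3. `gibbs_sample()` — a purpose-built Gibbs sampler for the Bayesian
   multilevel model that yields posterior finite-population SDs for all
   seven sources of variation.

## The model

For plot $i$ the response is

$$y_i = \beta_0 + e_{site(i)} + b_{block(i)} +
  (\gamma + g_{site(i)})\,\tilde x_i + c_{comp(i)} + d_{site:comp(i)}
  + \varepsilon_i,\qquad \varepsilon_i \sim N(0, \sigma^2),$$

where $\tilde x_i$ is log₂ sown richness centered at its plot-level mean,
and each effect batch is drawn from its own zero-mean normal
distribution: sites $e \sim N(0,\sigma_E^2)$, blocks-in-sites
$b \sim N(0,\sigma_B^2)$, per-site slope deviations
$g \sim N(0,\sigma_{ER}^2)$, composition $c \sim N(0,\sigma_C^2)$ and
site-by-composition $d \sim N(0,\sigma_{EC}^2)$. Compositions are coded
globally — identical species sets sown at different sites share one code
— which makes site and composition *partially crossed* rather than
nested.

Two variance notions coexist. The **super-population** SD $\sigma_m$
describes the hypothetical population a batch's levels were drawn from;
REML estimates these, but only for random terms. The
**finite-population** SD $s_m$ is the SD of the realized effects in this
particular study and is defined for *every* term, including the fixed
richness slope: for categorical batches $s_m$ is the SD over the $J$
level effects (denominator $J-1$); for the two richness-related sources,
which have no levels, it is the SD over the finite population of
plot-level contributions (slope × $\tilde x_i$, denominator $n-1$); the
residual uses the realized plot residuals. A one-coefficient term
therefore still gets a spread: $s_{richness} = |\gamma|\,\mathrm{sd}(\tilde x)$.
Finite-population intervals are systematically narrower than
super-population intervals, markedly so for batches with few levels, and
they cannot contain zero (an SD of strictly positive draws is positive
almost surely).

## The Gibbs sampler

All full conditionals are available in closed form, so the sampler is
pure Gibbs: Gaussian updates for $\beta_0$, $\gamma$ and each effect
block (vectorized over levels), and variance updates from the conjugate
scaled-inverse-χ² **truncated** to the support of the uniform prior on
the SD. Priors are conventional vague choices: uniform$(0, U)$ on every
batch SD and the residual SD with $U = 10\,\mathrm{sd}(y)$ by default
(the slope-deviation batch uses $U/\mathrm{sd}(\tilde x)$, i.e. the same
bound expressed on the slope scale), and $N(0, 10^{12})$ on the two
location parameters. An inverse-gamma(0.001, 0.001) prior on the
variances is available via `prior_spec(family = "invgamma")` for
sensitivity analysis; the exact hyperparameters of the historical
analyses are not recoverable, so ours are declared rather than inferred.

Chains are initialized over-dispersed: effects at zero and all SDs at
$\mathrm{sd}(y) \times \{0.5, 1, 2\}$ cycled over chains. Thinning keeps
every `thin`-th post-burn-in iteration, so the canonical settings
(3 chains × 100,000 iterations, burn-in 5,000, thin 200) retain exactly
475 draws per chain. Convergence is monitored with the
potential-scale-reduction factor
$\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$ for the locations and every
finite-population SD, with the conventional 1.1 threshold; failure sets
a flag on the summary rather than raising.

Two mixing remarks. The additive split between the grand mean and the
(un-sum-constrained) batch means is only softly identified, as in the
original hierarchical formulation; this slows mixing of $\beta_0$ and
$\sigma_E$ but barely affects the finite-population SDs, which are
computed from *centered* effects. Similarly, composition and
site-by-composition effects are collinear for site-local compositions
and are separated only by the shared compositions and the priors — this
is a property of the design, not of the sampler.

## The least-squares and REML engines

`sequential_ss()` computes Type-I SS by projecting the response onto the
incremental column space of each term's design columns after sweeping
out all earlier terms; the incremental rank (the term's DF) is detected
from singular values of the residualized block with a relative tolerance
of 1e-8. This matters because in partially crossed designs the
composition margin is heavily aliased with the site, block and richness
margins: the composition DF *must* emerge from rank, not from
level-count bookkeeping. `assemble_anova()` then applies an explicit
error-term map. The default is the *unconstrained* mixed-model testing
school (random main effects tested against their interaction:
site→block, block→residual, richness→composition,
site×richness→site×composition, composition→site×composition,
site×composition→residual), which is the convention of modern
mixed-effects software; the *constrained* school (random main effects
against the plot residual) is available via
`anova_error_map("constrained")`.

`reml_fit()` wraps `lme4::lmer` — the natural engine for this model
family — behind the package's interface, reporting super-population
variance components with percent shares **on the variance scale over all
six random terms including the residual** (deliberately different from
the SD-scale shares of the Bayesian summary). The fixed-effect F for the
richness slope is the Wald square $(\hat\gamma/SE)^2$; its SS/MS are
reported as F times the residual variance so the row is comparable with
a least-squares table, and no P value is emitted because denominator DF
are not well defined for crossed designs. Likelihood-ratio tests for
random terms refit both models by ML; because the null value lies on the
boundary of the parameter space we report both the naive χ²₁ P value and
the 50:50 χ²₀:χ²₁ mixture P value side by side. BLUP site slopes are the
fixed slope plus the site's predicted deviation and exhibit the usual
shrinkage toward the overall slope.

## The synthetic world

`build_skeleton()` reproduces the combined 12-experiment design: per
site, the blocks, the log₂-spaced richness gradient, the number of
distinct compositions and the plot count, totalling 359 site-local
compositions, 29 blocks and 778 plots. Compositions are abstract species
sets drawn from a 120-species pool; a configurable `sharing_fraction` of
each site's compositions (spread across the whole richness gradient, as
in the real designs) reuses a set introduced earlier, and
`tune_sharing_fraction()` finds the fraction whose deterministic
allocation collapses 359 local labels to exactly 308 global codes
(0.192 with the default seed). The true cross-site sharing incidence was
never published, so the skeleton reproduces the aggregate counts only;
consequently the least-squares strata DF on replayed data resemble but
do not equal the published ones (which depend on that incidence), and no
test asserts them.

`simulate_responses()` draws every batch once per level and adds
residual noise. Default truth is *calibrated* to the published
finite-population magnitudes — SDs 96.5 (site), 26.0 (block), 114.2
(composition), 101.1 (site×composition), 116.5 (residual), with the
richness (111.2) and site×richness (80.3) values divided by
$\mathrm{sd}(\tilde x)$ of the skeleton to express them on the slope
scale — around a grand mean of 420 g m⁻² yr⁻¹, a representative
magnitude for the sites' mean ANPP. This is a calibration, not gospel.
One consequence is stated openly: a Gaussian with total SD ≈ 256 around
420 produces a few negative responses in 778 plots. Real ANPP cannot be
negative, and the loader rejects negative values in measured data; for
simulated data the sign check is relaxed (`nonneg_anpp = FALSE`) rather
than truncating the distribution, which would bias the
parameter-recovery tests. The realized (finite-population) SD of every
source is attached to each simulated dataset, so recovery tests compare
posterior intervals against the *realized* truth of that replicate, the
quantity the finite-population summary actually estimates.

What a green test establishes: that the three engines agree with their
independent oracles and with each other, and that posterior intervals
cover the realized truth at nominal rates *under the model's own
generative world*. The simulator does not emulate species-identity
effects, functional groups, temporal dynamics, heteroscedasticity
between sites, or non-Gaussian tails — agreement here says nothing about
those.

## Numerical and testing choices

* Rank tolerance 1e-8 (relative) for incremental DF; decomposition
  exactness asserted at 1e-8 relative.
* Log₂ richness is centered at the plot-level mean; centering
  decorrelates slope and intercept updates and fixes the population over
  which the richness contribution's SD is taken.
* Truncated variance draws use the inverse-CDF of the gamma on the
  precision scale; the shape $(J-1)/2$ reflects the Jacobian of the
  uniform-on-SD prior.
* Some simulation-based tests are scaled down from their nominal sizes
  to fit the test budget (e.g. 120 rather than 500 boundary-null LRT
  replicates; 20-dataset shrinkage checks); the acceptance-grade
  parameter-recovery study keeps its full 20 replicates at the reduced
  chain settings (3 × 5,000, burn-in 500, thin 10).
* The SEM of a composition mean is the within-composition sample SD over
  √replicates, omitted for singletons.
* Displayed tables round SDs to 1 decimal and percent shares to
  integers; full precision is retained internally.

## Limitations

* The REML engine inherits `lme4`'s boundary behavior: variances
  estimated at exactly zero are reported as zero, with the LRT mixture
  P value as the appropriate test.
* The Gibbs sampler is specific to this model family (six batches, one
  continuous covariate); it is not a general probabilistic-programming
  interface.
* Replaying the published per-stratum DF, F and posterior values exactly
  requires the original plot-level dataset, which is not bundled; the
  pipeline accepts it as a plain CSV in the canonical schema whenever
  the user supplies it.
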