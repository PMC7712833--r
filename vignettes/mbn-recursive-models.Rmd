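---
title: "Recursive multiplicative-binomial models for stillbirth in diallel crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive multiplicative-binomial models for stillbirth in diallel crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbnDiallel)
```

## The scientific problem

The number of stillborn piglets (SB) in a litter is a count bounded by the
litter size (total number born, TNB), dominated by zeros, and empirically
*over-dispersed* relative to a binomial: the deaths within a litter share
causes (farrowing duration, infections, sow condition), so the per-piglet
Bernoulli events are positively dependent.  At the same time mortality rises
with litter size, and in crossbred populations one wants to decompose cross
differences into direct, maternal and heterosis components.  `mbnDiallel`
implements a hierarchical Bayesian model that addresses all three features
at once for a full diallel cross among three varieties (labelled E, R, T,
giving nine sow types EE, ER, ..., TT; the first letter is the sire variety,
the second the dam variety).

## The multiplicative binomial distribution

The stillbirth count $x$ of a litter with $nb$ piglets follows the
multiplicative binomial (MBN) distribution

$$\Pr(x \mid nb, \phi, \theta) \;=\;
  \frac{\binom{nb}{x}\,\phi^x (1-\phi)^{nb-x}\,\theta^{x(nb-x)}}
       {K_{nb}(\phi, \theta)},
\qquad
K_{nb-a} = \sum_{j=0}^{nb-a} \binom{nb-a}{j} \phi^j (1-\phi)^{nb-a-j}
           \theta^{(j+a)(nb-a-j)},$$

with location $\phi \in (0,1)$ and dispersion $\theta > 0$.  At
$\theta = 1$ the distribution is exactly Binomial$(nb, \phi)$; $\theta < 1$
down-weights the extremes less than the middle and produces over-dispersion,
$\theta > 1$ under-dispersion.  The marginal probability that one piglet
dies is not $\phi$ but
$p = \phi\, K_{nb-1}(\phi,\theta) / K_{nb}(\phi,\theta)$ — at the parameter
magnitudes typical of this trait ($\phi \approx 0.1$, $\theta \approx 0.8$,
$nb \approx 8$) the shrinkage is substantial, and all calibrations in the
package go through `mbnSuccessProb()` rather than $\phi$ itself.

All pmf arithmetic is done in log space with log-sum-exp accumulation of
$K$: the factor $\theta^{x(nb-x)}$ under- or overflows double precision
already for moderate litter sizes, while the log-space sums are exact to
about $10^{-14}$ for $nb \le 30$ (verified against direct enumeration in
the tests).  Sampling enumerates all $nb+1$ probabilities and inverts the
CDF — exact, and cheap at litter-size scale.  No closed-form moments exist;
`mbnMoments()` enumerates.

## The two-trait recursive hierarchy

For litter $i$ of sow $s(i)$:

* **Litter size** (Gaussian): $t_i = \mathbf{x}_i' \mathbf{b}_t + u_{t,s(i)}
  + p_{t,s(i)} + e_i$, $e_i \sim N(0, \sigma^2_{et})$.
* **Stillbirth** (MBN): $y_i \sim \mathrm{MBN}(t_i, \phi_i, \theta)$ with
  $\mathrm{logit}\,\phi_i = \mathbf{x}_i' \mathbf{b}_l + u_{l,s(i)} +
  p_{l,s(i)} + r_i$.

The recursion term $r_i$ depends on the deviation $d_i = t_i - \bar t$ of
the *observed* litter size from the average litter size $\bar t$:

| model | $r_i$ |
|-------|------------------------------|
| I     | $0$ |
| II    | $\lambda_1 d_i$ |
| III   | $\lambda_1 d_i + \lambda_2 d_i^2$ |
| IV    | $\lambda_{1k} d_i$ (cross-specific) |
| V     | $\lambda_{1k} d_i + \lambda_{2k} d_i^2$ |

The recursion is phenotypic — the realised integer $t_i$ enters both as the
MBN's number of trials and in $d_i$; litter size is determined around
ovulation/implantation while stillbirth happens at farrowing, which is what
licenses the directed dependence.  $\bar t$ is the unweighted arithmetic
mean of the observed TNB, resolved at fit time and stored in the
`ModelSpec` so a fitted model is reusable on new data.

Fixed effects are cross (9 levels), parity (6 levels) and year-season (up
to 30 levels).  There is no global intercept; all nine cross levels are
kept and the first parity and first year-season levels are dropped, so the
cross effects are directly interpretable (and are additionally reported as
deviations from their nine-level mean, which is invariant to this
convention).  Random effects are bivariate across the two scales: additive
genetic values $(\mathbf{u}_l, \mathbf{u}_t) \sim N(0, \mathbf{A} \otimes
\mathbf{G})$ with $\mathbf{A}$ the pedigree numerator relationship matrix,
and sow permanent environmental values $(\mathbf{p}_l, \mathbf{p}_t) \sim
N(0, \mathbf{I} \otimes \mathbf{P})$.  $\mathbf{G}$ and $\mathbf{P}$ are
unstructured $2 \times 2$ covariance matrices; their correlations $r_a,
r_p$ are derived per draw.

Priors on $\mathbf{b}_t$, $\mathbf{b}_l$, the $\lambda$'s, $\mathbf{G}$,
$\mathbf{P}$, $\sigma^2_{et}$ and $\theta$ are flat within bounds.  The
bounds are deliberately vague relative to the scale of the traits:
variances in $(10^{-6}, 100)$, $\theta \in (10^{-3}, 5]$, effects
unbounded.  They are configurable in `mcmcConfig()`.

## Pedigree machinery

The numerator relationship matrix is built by the tabular method;
inbreeding coefficients use the Meuwissen–Luo algorithm and feed
Henderson's rules for the sparse inverse $\mathbf{A}^{-1}$ — the only
object the sampler needs, so the dense $\mathbf{A}$ is optional for large
pedigrees.  The two constructions are cross-checked against each other (and
against a naive textbook oracle) in the tests.  Unknown parents are treated
as unrelated, non-inbred founders of their declared population; no genetic
groups are fitted, matching the use of a single $\mathbf{A}$ across the
three varieties.

## The sampler

One iteration cycles:

1. **Gaussian side** ($\mathbf{b}_t, \mathbf{u}_t, \mathbf{p}_t$): exact
   scalar Gibbs draws from the conjugate normal full conditionals, using
   the sparse rows of $\mathbf{A}^{-1}$ and the cross-scale couplings
   through $\mathbf{G}^{-1}$ and $\mathbf{P}^{-1}$.
2. **Logit side** ($\mathbf{b}_l, \mathbf{u}_l, \mathbf{p}_l$, the
   $\lambda$'s): single-site Gaussian random-walk Metropolis–Hastings.
   Each site's acceptance uses only the MBN terms of the affected records
   (cached per record) plus the Gaussian prior terms; proposal standard
   deviations are adapted by Robbins–Monro toward an acceptance rate of
   0.44 during burn-in and frozen afterwards, with a floor of $10^{-3}$ so
   a chain can never freeze.
3. **Covariance matrices**: with flat priors,
   $\mathbf{G} \mid \mathbf{u} \sim \mathrm{IW}(q_u - 3,\;
   \mathbf{U}'\mathbf{A}^{-1}\mathbf{U})$ and analogously for $\mathbf{P}$
   (df convention: the IW density carries
   $|\mathbf{G}|^{-(\nu + p + 1)/2}$, so $\nu = q - 3$ reproduces the flat
   prior posterior for $2\times2$ matrices); $\sigma^2_{et}$ is a scaled
   inverse-chi-square with $N - 2$ degrees of freedom.  Draws outside the
   bounds or non-positive-definite are rejected and redrawn (truncation);
   after $10^4$ failures the run stops with advice to widen the bounds.  A
   ridge of $10^{-12}$ on the scale matrix keeps the draw defined when the
   sufficient statistic is singular (e.g. effects pinned at zero in
   diagnostic runs).
4. **Dispersion**: random-walk MH on $\log\theta$ with the flat-on-$\theta$
   Jacobian, touching every litter's normalizer.

Single-site updates were chosen over blocked ones because they are
dimension-agnostic, easy to validate against brute-force oracles (the test
suite compares MH marginals with grid integration and closed-form
conditionals), and fast enough in the compiled core; the whole iteration is
written in C++ with all randomness drawn from R's RNG, so a chain is
bitwise reproducible from its seed.  Whether the logit-side effects are
updated jointly or separately from the $\lambda$'s is immaterial for the
stationary distribution; they are separate blocks here.

Default chain settings (30,000 iterations, 5,000 burn-in, thinning 10) are
desk-scale; the full-scale setting of the motivating analysis (550,000 /
50,000) is reached by raising `n_iter`/`burn_in` in `mcmcConfig()`.  The
per-record MBN log-likelihood is stored at every kept draw, which is what
the CPO machinery consumes.

## Dickerson decomposition

The nine cross effects are mapped per draw to direct ($D_E, D_R, D_T$),
maternal ($M_E, M_R, M_T$) and heterosis ($H_{ER}, H_{ET}, H_{RT}$)
effects.  The $9 \times 9$ coefficient matrix is singular: adding a
constant to every $D$ and subtracting it from every $M$ changes nothing,
so its rank is 8 and only contrasts are identified.  `dickersonSolve()`
returns the minimum-norm least-squares solution together with the numerical
rank and residual, and the reported tables emphasise the estimable
quantities: heterosis effects (which obey closed-form contrasts such as
$H_{ER} = (b_{ER} + b_{RE} - b_{EE} - b_{RR})/2$, asserted to $10^{-10}$ in
the tests) and within-block deviations of $D$ and $M$.  An optional
sum-to-zero mode ($\sum D = 0$, $\sum M = 0$ after absorbing a common
intercept, solved exactly by a KKT system) lets users probe the sensitivity
of the non-estimable components.

## Model comparison by CPO

Models are ranked by the summed log conditional predictive ordinate,
estimated per record by the harmonic mean of the likelihood over
post-burn-in draws, $\hat p(y_i \mid y_{-i}) = N_m \left[\sum_j 1/p(y_i
\mid \theta^{(j)})\right]^{-1}$, accumulated by log-sum-exp so reciprocals
cannot overflow.  The likelihood entering the CPO is the MBN probability of
$y_i$ given $t_i$ and the draw's parameters, conditional on the sampled
random effects; the Gaussian TNB density is excluded because the five
models differ only on the stillbirth side and should be compared on the
same response.  The harmonic-mean estimator converges fast when the
likelihood of the scored outcome stays bounded away from zero under the
posterior (typical stillbirth counts of 0–1); its convergence is provably
slower for rare outcomes, which the tests acknowledge by asserting the
2%-at-$10^5$-draws accuracy on the common outcomes of a conjugate
beta-binomial toy with a closed-form leave-one-out density.

## The synthetic-data generator

Because the motivating survey's records are not publicly deposited, the
package ships a generator that reproduces the *structure* the model
assumes, so every module is testable end to end:

* a three-generation pedigree: purebred founders per variety (default
  sire/dam counts 13/34, 18/62, 38/69 for E, R, T), a purebred intermediate
  generation, and a phenotyped sow cohort whose per-cross counts default to
  the survey's 2110 sows (EE 100, ER 527, ET 177, RE 196, RR 175, RT 488,
  TE 36, TR 343, TT 68), met exactly;
* bivariate additive genetic values by gene dropping (founders $N(0,
  \mathbf{G})$, offspring get the parent average plus Mendelian sampling
  with inbreeding-adjusted variance), which is exactly $N(0, \mathbf{A}
  \otimes \mathbf{G})$ — verified empirically in the tests;
* 3–6 farrowings per sow (uniform), parity running with farrowing number,
  30 year-season levels; litter size $t = \max(1, \mathrm{round}(N(\eta_t,
  \sigma^2_{et})))$ — the rounding/flooring rule is pinned here because the
  Gaussian litter-size model must hand an integer to the MBN;
* stillbirth counts drawn from the MBN at the generating model's logit.

Default generating values sit at the magnitudes where the method operates:
mean TNB 8.46 (sd ≈ 2.3), $\lambda_1 = 0.257$, $\theta = 0.816$,
$\sigma^2_{et} = 4.497$, additive/permanent variances below 0.5 on both
scales.  The baseline logit is calibrated by deterministic quadrature
(discretised Gaussian over litter size × Gauss–Hermite over the remaining
logit-scale variance) so the realised overall death rate is about 0.0296,
i.e. mean SB ≈ 0.25 per litter; naive inversion of the success probability
would miss by nearly a factor of two because the logit-normal mixture and
the litter-size weighting both inflate the realised rate.

Two realism caveats matter for interpreting test results.  First, the
phenotyped cohort descends from a finite founder pool, so the cohort mean
of the genetic values is a random draw with sd ≈ 0.08 litter-size units at
default scale; the calibration checks therefore average over replicates.
Second, the generator draws random matings and ignores selection,
non-random mating by merit and litter-level covariates (birth weights,
farrowing duration), so passing tests demonstrate correct inference *under
the model's own assumptions*, not robustness to the ways real herds violate
them.

## Problem sizes used in the checks

The test suite validates the sampler against brute force where brute force
is exact (two-record toys vs grid integration, Kolmogorov–Smirnov distance
< 0.05 at 50,000 draws), and runs a scaled replicate of the full analysis:
about 500 sows / 2,200 records (a 0.237 scaling of the survey counts)
fitted with a 30,000-iteration chain, recovering $\lambda_1$, $\theta$ and
$\sigma^2_{et}$ within three posterior standard deviations of their
generating values.  Model ranking is checked at about 950 records —
below roughly 600 records the model I/II LogCPO comparison loses power and
single replicates can prefer the simpler model, which is a property of the
criterion at small samples, not of the implementation.  All sizes are the
package's own choices for a desk-scale demonstration; nothing prevents
full-scale runs through the same interfaces.

## Known limitations

* The harmonic-mean CPO estimator is noisy for rare outcomes; refitting
  leave-one-out schemes are out of scope.
* Genetic-group effects, genomic relationship matrices and single-step
  extensions are not implemented.
* Recursions nested within effects other than cross, and change-point
  (non-linear threshold) recursions, are not implemented.
* Flat priors with wide bounds leave weakly-identified components (e.g. the
  genetic vs permanent split of the logit-side variance at small sample
  sizes) with diffuse posteriors; that is visible in the scaled fits and is
  expected behaviour, not a convergence failure.
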