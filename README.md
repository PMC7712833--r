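# mbnDiallel

Bayesian analysis of perinatal piglet mortality in multi-variety diallel
crosses, built around the **multiplicative binomial (MBN) distribution** and
**recursive two-trait animal models**.

Stillbirth counts are bounded by litter size, zero-heavy and over-dispersed
relative to a binomial, because the piglets of one litter share risk factors.
The MBN distribution handles this with a second parameter:

    Pr(x | nb, phi, theta)  ∝  C(nb, x) phi^x (1 - phi)^(nb - x) theta^(x(nb - x))

which is exactly Binomial(nb, phi) at theta = 1, over-dispersed for
theta < 1 and under-dispersed for theta > 1.  The package embeds it in a
hierarchical model for a full diallel cross among three varieties (nine sow
types EE, ER, ..., TT; sire variety first):

* litter size (TNB): Gaussian animal model with cross, parity and
  year-season effects, pedigree-based additive genetic values and sow
  permanent environmental effects;
* stillbirth (SB): MBN likelihood whose logit(phi) carries the analogous
  effects plus one of five **recursive predictors** in the litter-size
  deviation d = t - t̄ — none (I), shared linear λ₁d (II), shared quadratic
  (III), cross-specific linear (IV), cross-specific quadratic (V);
* bivariate priors (u_l, u_t) ~ N(0, A ⊗ G) and (p_l, p_t) ~ N(0, I ⊗ P),
  flat bounded priors on everything else.

Inference is a Gibbs sampler with adaptive Metropolis–Hastings steps for the
logit side and the MBN dispersion (compiled core, bitwise reproducible from a
seed).  Cross effects are reparameterised per draw into Dickerson **direct,
maternal and heterosis** effects, and models are ranked by the conditional
predictive ordinate (**LogCPO**).  A synthetic-data generator reproduces the
diallel structure (pedigree, cross counts, litter-size distribution,
over-dispersion, recursion) so the whole pipeline runs without access to the
original survey records.  Intended users: quantitative geneticists and
biostatisticians working with bounded overdispersed counts in structured
populations.

## Worked example

```r
library(mbnDiallel)

# the MBN distribution itself
dmbn(0:3, size = 3, phi = 0.1, theta = 0.8)
#> [1] 0.807487816 0.172264067 0.019140452 0.001107665
mbnSuccessProb(size = 8, phi = 0.1, theta = 0.8)   # marginal death risk << phi
#> [1] 0.0250806

# a synthetic diallel at 10% of the survey size, generated under model II
# (lambda1 = 0.257, theta = 0.816, sigma2_et = 4.497)
sim <- simulateDiallel(simConfig(scale = 0.1), seed = 7)
sim$data
#> DiallelData: 967 farrowing records, 213 sows
#>   crosses: EE ER ET RE RR RT TE TR TT
#>   mean TNB: 8.55  mean SB: 0.23

chain <- runChain(sim$data, sim$pedigree, modelSpec("II"),
                  mcmcConfig(n_iter = 10000, burn_in = 4000, thin = 5, seed = 8))
chain
#> McmcChain: model II - 1200 stored draws of 95 parameters
#>   MH acceptance: b_l 0.45, u_l 0.49, p_l 0.33, lambda 0.41, theta 0.43

s <- summarizeChain(chain)
s[s$parameter %in% c("lambda1", "theta", "sigma2_et"), ]
#>    parameter   mean     sd hpd_lo hpd_hi
#> 87   lambda1  0.267 0.0390  0.186  0.341
#> 94 sigma2_et  4.636 0.2356  4.141  5.057
#> 95     theta  0.872 0.0258  0.824  0.927
```

The posterior mean of `lambda1` (0.267 ± 0.039 logit units per piglet)
recovers the generating recursion 0.257: mortality rises with litter size.
`theta` < 1 detects the generated over-dispersion, and `sigma2_et` recovers
the residual litter-size variance.  `dickersonChain(chain, trait = "l")`
turns the nine cross-effect posteriors into direct/maternal/heterosis
summaries (with sign probabilities), and

```r
cpoEstimate(chain)        # per-record CPO and summed LogCPO
compareModels(list(...))  # LogCPO ranking across fitted models
```

rank competing recursion structures; on data generated under model II the
recursive model beats model I decisively.

A thin command-line front-end with subcommands `simulate`, `fit`, `cpo`,
`compare`, `dickerson`, `summarize` is installed at
`system.file("cli/mbndiallel", package = "mbnDiallel")`.

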