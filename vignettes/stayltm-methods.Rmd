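---
title: "Joint Bayesian analysis of litter size and sow stayability with a linear-threshold animal model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Bayesian analysis of litter size and sow stayability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sow longevity drives the profitability of commercial pig herds, but a
longevity trait such as *stayability to fourth parity* (STAY14 — did a
sow that farrowed once survive in the herd to farrow a fourth time?) is
binary, expressed late in life, and censored for sows still in
production. Litter size (number born alive, NBA) is recorded at every
parity from early in life. If the two are genetically correlated,
first-parity litter size can serve as an early indirect selection
criterion for longevity. Quantifying that requires estimating genetic
parameters jointly for three continuous traits (NBA at parities 1–3,
treated as distinct traits because their variances are heterogeneous)
and one binary trait, over a livestock pedigree, in the presence of the
very culling process the stayability trait measures.

`stayltm` implements this analysis end to end: pedigree machinery,
data-editing rules, a Gibbs sampler for the four-trait linear-threshold
animal model, posterior summaries, and a synthetic-herd generator that
reproduces the data structure so the whole pipeline can be validated
without access to farm databases.

## Model

For sow $i$ the four-trait observation vector is
$$ y_i = X_i\beta + a_{j(i)} + e_i, $$
where $y_i$ stacks NBA1–NBA3 (continuous) and the *liability* of
STAY14; $\beta$ collects, per trait, the herd–year–season contemporary
group effects and a linear regression on age at first farrowing (AFF,
days, centered); $a_j$ is the 4-vector of additive genetic effects of
animal $j$; and $e_i$ is the residual. Across the pedigree,
$$ a \sim N(0,\, A \otimes G), \qquad e \sim N(0,\, I \otimes R), $$
with $A$ the numerator relationship matrix, and $G$, $R$ the 4×4
additive and residual covariance matrices.

The binary trait follows the threshold (probit) convention: STAY14 = 1
exactly when its latent liability exceeds 0. Because a latent scale has
no units, the threshold is fixed at 0 and the liability residual
variance is pinned to 1; every stored draw of $R$ satisfies
$R_{44} = 1$ exactly.

Heritabilities and correlations are derived per stored draw, before any
averaging: $h^2_t = g_{tt}/(g_{tt}+r_{tt})$ (for STAY14,
$g_{44}/(g_{44}+1)$ by the constraint), $r_{g,ij} =
g_{ij}/\sqrt{g_{ii}g_{jj}}$ and $r_{p,ij} =
(g_{ij}+r_{ij})/\sqrt{\sigma^2_{p,i}\sigma^2_{p,j}}$.

## Gibbs sampling scheme

One cycle updates, in order: liabilities, augmented missing cells,
location effects (contemporary groups, covariate slopes, animal
blocks), $G$, then $R$.

* **Liabilities.** For each sow with observed STAY14, the liability is
  drawn from the normal distribution of the threshold-trait residual
  conditional on the record's other (observed or augmented) residuals
  under the current $R$, shifted by the linear predictor and truncated
  to $(0,\infty)$ for STAY14 = 1 or $(-\infty,0]$ for STAY14 = 0. The
  one-sided truncated-normal generator uses plain rejection when the
  bound is in the bulk, inverse-CDF through the upper tail for moderate
  bounds, and an exponential rejection envelope in the far tail, so it
  is accurate even when the linear predictor sits many standard
  deviations from the threshold.
* **Missing cells.** Litter sizes after culling, and the liability of
  right-censored sows, are data-augmented: drawn from their conditional
  normal given the record's observed residuals under $R$. All
  subsequent conditionals then operate on complete records, which keeps
  every update a closed-form draw. Augmentation of an uninformative
  cell is distributionally equivalent to marginalising it out; it costs
  some mixing speed but no correctness.
* **Location effects.** Single-site draws: each contemporary-group
  level and each covariate slope from its scalar normal conditional,
  and each animal's 4-vector from its multivariate normal conditional
  with precision $n_j R^{-1} + A^{jj} G^{-1}$ and a right-hand side
  combining the animal's records and the $A^{-1}$-weighted effects of
  parents, offspring and mates. Because every animal shares the same
  two precision components up to scalars, the sampler diagonalises
  $(G^{-1}, R^{-1})$ simultaneously once per cycle and each animal's
  draw reduces to two 4×4 matrix–vector products — the step that makes
  desk-scale chains run in tens of seconds.
* **$G$.** Inverse-Wishart conditional with scale
  $a^\top A^{-1} a + S_G$ and degrees of freedom $q + \nu_G$ over the
  $q$ pedigree animals.
* **$R$ with the pinned element.** The full conditional is an
  inverse-Wishart restricted to the slice $R_{44}=1$. The sampler uses
  the conditional decomposition: with the pinned trait as the scalar
  block, the scalar $W_{11}$ of an inverse-Wishart is independent of
  the regression vector $B$ and the conditional block $W_{22\cdot1}$,
  so conditioning on $W_{11}=1$ leaves their joint law unchanged (the
  Jacobian of the reparameterisation is 1 on the slice). The sampler
  draws $W_{22\cdot1} \sim IW(S_{22\cdot1}, \nu)$ and
  $B \mid W_{22\cdot1} \sim N(S_{12}/S_{11},\ W_{22\cdot1}/S_{11})$ and
  reconstructs $R$. Post-hoc rescaling of an unconstrained draw would
  change the stationary distribution and is not used (a
  `rcov_zero` option constrains the residual covariances with the
  binary trait to zero instead, as a simplified fallback).

All randomness flows through R's RNG, so a chain is bitwise
reproducible from its seed. The default chain protocol is a single
chain of 250,000 cycles, 50,000 burn-in, storing every 50th draw —
4,000 stored samples.

## Priors, and two geometry lessons

Fixed effects on continuous traits carry flat priors; only variance
parameters and the derived ratios, which are invariant to the flat
directions, are reported by default. Two prior choices matter more than
they first appear, and both were diagnosed by comparing chains against
the exact marginal likelihood (pedigree effects integrated out
analytically) on small instances:

1. **The inverse-Wishart scale must live at the data's order of
   magnitude.** With $\nu = \dim + 1$ and an arbitrarily small scale
   (say $0.01 I$), the marginal prior on each correlation is uniform —
   but *conditional on variances* that the data pin at order 1–7, the
   density grows without bound as any correlation approaches $\pm 1$,
   and chains get trapped against singular covariance matrices. The
   default scale is therefore the diagonal of the starting values
   (half the observed phenotypic variance per trait; 0.2 and 1 for the
   liability's genetic and residual parts). With thousands of animals
   and records against $\nu = 5$, the posterior remains entirely
   data-dominated.
2. **Fixed effects of the threshold trait need a proper prior.** A
   contemporary group in which every sow has the same stayability
   outcome gives its effect an improper flat-prior conditional (the
   extreme-category problem), and even short of that, several dozen
   free subclass effects on a latent probit scale inflate the liability
   variance components. The binary trait's fixed effects default to
   $N(0, 1)$: group effects of $\pm 1$ liability units already span
   success probabilities of roughly 0.16–0.84 around the mean, far
   beyond plausible herd-year-season differences, so the prior is
   weakly informative in the usual sense for probit scales. It is
   configurable via `ltm_priors(beta_sd_binary = )`.

A `flat = TRUE` option selects the improper flat convention throughout;
it exists for the degenerate single-trait checks where the posterior
has a known closed form.

## Pedigree machinery

Pedigrees are validated (no animal its own parent, no duplicates, no
cycles), renumbered so parents precede offspring, and animals appearing
only as parents are promoted to founders with a warning. Inbreeding
coefficients use the Meuwissen–Luo ancestor-descent algorithm.
$A^{-1}$ is built sparsely by the standard parent–offspring rules with
inbreeding-corrected Mendelian-sampling variances
$d_i = 1 - 0.25(1+F_s) - 0.25(1+F_d)$, each parental term dropped for
an unknown parent; unknown parents are unrelated base-population draws
(no genetic groups). A dense tabular-method $A$ is kept as an oracle,
guarded to 5,000 animals, and the test suite verifies
$A^{-1} A = I$ to $10^{-8}$ on random pedigrees.

## Data editing

The editing rules drop sows with a missing birth date, any farrowing
missing its date or parity, or AFF strictly below 280 d or strictly
above 460 d (the boundaries are retained). Contemporary groups are herd
× calendar year × season of first farrowing, with seasons summer
(March–June), rainy (July–October) and winter (November–February).
STAY14 is 1 with a fourth farrowing, 0 for a sow removed (culled or
died — the records do not distinguish) before the fourth, and missing
for a sow still present at the end of data collection without a
fourth-parity opportunity. Coding such right-censored sows as 0 would
bias liability means downward, and censoring is the only mechanism that
explains stayability counts sitting well below first-parity litter
counts in field data. Parity comes from the recorded parity field;
gaps leave the skipped litter missing, with a warning. AFF is centered
before use as a covariate, decoupling intercepts from slopes.

## The synthetic-herd generator

The generator emulates the data structure this analysis assumes, at a
configurable scale:

* discrete generations from unrelated founders, each dam mated to a
  random sire, `daughters_per_dam` recorded daughters (defaults: 150
  sires, 1,000 dams, 3 daughters — 3,000 sows, chosen to make recovery
  experiments run in minutes on one CPU);
* multivariate breeding values gene-dropped down the pedigree with
  Mendelian-sampling covariance $d_i\,G$;
* AFF from a truncated normal (367 ± 26 d on [280, 460]), birth and
  farrowing dates laid out calendar-consistently (farrowing intervals
  140–165 d), herds and dates inducing realized herd–year–season
  groups whose effects are drawn with SD 0.5 piglets (0.2 liability
  units for stayability) — values chosen once as plausible
  management-level variation;
* default trait architecture on the published scale for tropical
  maternal lines: litter-size means rising 9.4 → 10.5 across parities,
  phenotypic variances near 6.2–6.9 with low heritability, stayability
  intercept 0.72 giving about 76% stayers, strong genetic correlations
  among parities and moderate favourable ones with stayability;
* culling: sows whose liability fell below the threshold receive a
  removal parity in 1–3 (probabilities 0.45/0.30/0.25, matching the
  declining litter counts seen in field data); under the default
  `liability` mode lower liabilities are culled earlier, which makes
  litter-size missingness informative — the situation the joint model
  exists for; a `random` mode isolates the samplers from selection for
  unit testing. A quarter of sows are right-censored by default.

Contemporary groups are realized from simulated herds and dates rather
than drawn as an abstract label count, so that writing the herd to the
record files and running the editing pipeline reproduces the herd's own
analysis table exactly — a round-trip the test suite asserts.

NBA values are simulated Gaussian, matching the model's assumption that
litter size is continuous; a rounding switch exists for realism
experiments. What the generator does *not* emulate: reproductive-cycle
biology (estrus, conception failure), body-condition effects, herd
management trends over time, non-genetic maternal or litter effects,
and culling on observed litter size itself. Passing recovery tests on
these herds therefore validates the estimation machinery under the
model's own assumptions, not the model's adequacy for any particular
real population.

## Numerical choices and degenerate inputs

* Starting values: $G$ and $R$ start diagonal at half the observed
  phenotypic variance per continuous trait (0.2/1.0 for the liability);
  liabilities start at ±0.7 by outcome; missing cells at trait means.
* `(n_cycles - burn_in)` must divide evenly by `thin`, so stored-sample
  counts are exact.
* Cholesky factorisations are applied to symmetrised matrices; a
  non-positive-definite conditional aborts with the cycle index.
* Mendelian-sampling variances $d_i \le 0$ (corrupt inbreeding input)
  raise an error rather than producing an indefinite $A^{-1}$.
* Contemporary groups of size 1 are retained (no minimum is imposed);
  empty levels are rejected at model build.
* Ties in liability-linked culling ranks are broken randomly.

Problem sizes used by the test suite and the acceptance script — 3,000
sows over 4,150 pedigree animals with chains of 20,000 cycles (5,000
burn-in, thinning 10), plus smaller fixtures — were chosen so that the
complete validation cycle runs in a few minutes on a single CPU while
leaving the recovery experiments enough information to be meaningful.

## Known limitations

* Single-site location updates mix slowly along weakly identified
  directions (notably genetic correlations involving traits with heavy
  missingness); the remedy in practice is longer chains, as with any
  sampler in this family. Blocked updates are deliberately out of
  scope.
* Genetic correlations estimated from ~150 sires carry posterior SDs
  of 0.05–0.15 even with correct machinery; single-herd estimates of
  such parameters should be read accordingly.
* One binary trait per analysis; multi-threshold ordinal traits are not
  supported.
* No genetic groups or phantom-parent strategies for unknown parents.
* Posterior dispersion is reported as the posterior SD; no
  highest-posterior-density intervals or formal convergence
  diagnostics beyond the exported trace (the sample store is plain
  text and can be analysed with any MCMC toolkit).

## A worked example

```{r, eval = FALSE}
library(stayltm)

cfg <- sim_config(seed = 42)          # 3,000-sow default herd
herd <- simulate_herd(cfg)
write_herd(herd, "herd")

recs <- read_sow_records("herd/records.csv")
tab <- edit_records(recs)$data
ped <- ped_renumber(read_pedigree("herd/pedigree.csv"))

fit <- ltm_fit(tab, ped, chain = ltm_chain(20000, 5000, 10, seed = 1))
summary(fit)          # component table + correlation matrix
plot(fit)             # heritability traces
write_store(fit$store, "samples.tsv")
```

The same pipeline is available from a shell through the CLI wrapper
(`system.file("cli", "stayltm.R", package = "stayltm")`) with
subcommands `simulate`, `prep`, `fit` and `summarize`.
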