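---
title: "Methods: benchmark-based susceptibility calling and phylogenetic mixed models for host-range data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-range analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrsayHostRange)
```

This vignette documents the statistical machinery of `OrsayHostRange`: the
assay-calling rules, the phylogenetic mixed model and its sampler, the
DIC-based model comparison, and the synthetic-data generator, together with
the numerical choices and their rationale.

## Susceptibility calling from Ct data

qPCR cycle thresholds are inversely related to viral load: one fewer cycle
is roughly a doubling of target RNA, and a well that never crosses the
fluorescence threshold within 40 cycles is recorded as undetected. The
calling rule has three ingredients.

* **Within-strain spread** `sigma_w`: for every experimental strain with at
  least two replicate populations, the sample variance (divisor n−1, the
  convention of `var()`) of its replicate Cts is computed with non-detections
  imputed at 40 cycles; `sigma_w` is the square root of the mean of those
  variances. Controls and benchmarks are excluded, and strains with fewer
  than two replicates are dropped from the mean (with a message). Pooling
  replicates across assay blocks within a strain reflects the design in
  which the same strain may be re-assayed in several blocks.
* **Benchmark-4 anchor**: benchmark-4 plates carry exposure virus but no
  hosts, so they measure carry-over that survives washing. The anchor is
  the *minimum detected* Ct among benchmark-4 wells — the most virus ever
  attributable to carry-over — pooled across all blocks, because a single
  global threshold is derived. Undetected benchmark wells carry no
  information about the most-virus extreme and are ignored.
* **Threshold**: `tau = anchor − sigma_w`, i.e. one within-strain standard
  deviation *more* virus than carry-over can explain. A strain is
  susceptible if at least one replicate has a detected Ct strictly below
  `tau`; equality is not infection, matching the strict form of the rule
  ("Ct < tau"). Because non-detections are imputed at 40, they can never
  produce an infected call for any threshold below 40.

A deliberately conservative alternative uses benchmark 5 (virus diluted
straight into the extraction volume, the most virus possible with zero
replication): `deriveThreshold(..., benchmark = 5)` uses the minimum
detected benchmark-5 Ct with no `sigma_w` padding. It exists for
sensitivity analysis, not as the default.

## Transmission scoring

Each exposed line is passaged up to five times, or until viral RNA is
undetectable. The ordinal score is a deterministic function of the
detection sequence over passages 0–5: 0 if nothing was detected at
exposure; 1 if detected at exposure but not in the first passage; 2 if
detected in the first passage but lost on or before passage 5; 3 if still
detectable at passage 5. Lines whose passaging stopped at a loss are padded
with "undetected" to passage 5 — the experiment stops precisely because
there is nothing left to passage — whereas a line whose record ends in a
*detection* before passage 5 is ambiguous between scores 2 and 3 and raises
a "truncated trajectory" error rather than guessing.

## The phylogenetic mixed model

Both responses are modelled on a latent liability scale
$\ell = X\beta + \sum_t Z_t u_t + e$. For susceptibility the observation is
the count of infected replicates per strain, $k_i \sim
\mathrm{Binom}(n_i, \mathrm{logit}^{-1}(\ell_i))$ — per-strain counts
rather than per-replicate Bernoulli outcomes, since replicate populations
within a strain share an exposure and a liability. For transmission the
score is treated as a continuous Gaussian response, as is conventional for
short ordinal scales when the mixed-model machinery matters more than the
link.

Random terms and their covariance:

* `phylo`: one effect per species with covariance $\sigma^2_p A$, where
  $A_{ij}$ is the depth of the most recent common ancestor of species $i$
  and $j$ — the trait covariance implied by Brownian motion on an
  ultrametric tree. On such a tree $\mathrm{diag}(A) = H$ and the
  cophenetic distance satisfies $d_{ij} = 2(H - A_{ij})$.
* `species`: an i.i.d. species effect capturing species-level variation not
  structured by the phylogeny. Retaining it in every model guards against
  pseudo-replication of strains within species.
* `strain` (transmission models): i.i.d., for replication at strain level.

Fixed effects are the intercept, the cophenetic distance from the focal
host, and (for transmission) the passage-0 Ct. Distances are used in the
input tree's branch-length units, with no rescaling: the variance
components absorb the scale, and doubling all branch lengths demonstrably
halves the posterior $\sigma^2_p$ while leaving fitted values unchanged (a
property test in the suite).

The tree must be rooted and ultrametric; `validateUltrametric()` enforces
tip-depth equality to a relative tolerance of 1e−6 by default and names the
worst-offending tip on failure. Ultrametricisation itself (e.g. strict-clock
smoothing) is treated as preprocessing and is out of scope. Species absent
from the tree have no defined covariance or distance, so the pipeline drops
their observations with an explicit log entry before fitting. `A` is built
at species level; strains map to their species' tip. Because trees here are
small (tens of tips), the inverse of `A` is computed by dense Cholesky
factorisation, which simultaneously certifies positive definiteness;
off-diagonal MRCA depths are clamped below $H(1 - 10^{-9})$ so that
zero-length terminal pairs cannot produce duplicate rows and a singular
matrix.

### Priors and sampler

Priors follow the conventions of the MCMC mixed-model ecosystem this
analysis style comes from: fixed effects $\mathcal{N}(0, 10^8)$; each
random-term variance gets a redundant multiplicative parameter expansion —
$u_t = \alpha_t \eta_t$ with $\eta_t \sim \mathcal{N}(0,
\sigma^2_{\eta t} G_t)$, $\alpha_t \sim \mathcal{N}(0, 1000)$ and a scalar
inverse-Wishart (V = 1, nu = 1) on $\sigma^2_{\eta t}$ — inducing a
heavy-tailed scaled-F marginal prior on the effective variance
$\sigma^2_t = \alpha_t^2 \sigma^2_{\eta t}$ that behaves far better than a
bare inverse-gamma when a variance is near zero; and an inverse-Wishart
(V = 1, nu = 0.002) on the residual. The contract of the expansion is the
target distribution, not a particular update order.

One chain per fit. Updates per iteration: (1) for binomial responses, each
latent liability takes a random-walk Metropolis step whose proposal sd is a
per-observation multiplier times the current $\sqrt{\sigma^2_e}$ — riding
on the residual sd keeps the multiplier calibrated while $\sigma^2_e$
moves during burn-in — with multipliers adapted every 25 burn-in iterations
toward 0.44 acceptance and frozen afterwards; (2) $(\beta, \eta)$ drawn
jointly from their multivariate-normal full conditional via Cholesky of the
precision (using $A^{-1}$ for the phylo block); (3) the $\alpha$ working
scales drawn jointly from their (low-dimensional) normal full conditional;
(4) conjugate inverse-gamma updates for the base and residual variances.
The residual variance of a binomial liability model is only weakly
identified; the default keeps the ecosystem's prior and reports effects on
the liability scale as-is — which is why liability-scale fixed effects can
be numerically large in such analyses — and `fitPMM(fixResidual = )` can
pin it instead (also used by the test suite to compare the Gaussian sampler
against the closed-form conjugate posterior).

All randomness flows through R's RNG, so a `chainSettings(seed = )` fixes
every draw; summaries (posterior means, HPD endpoints, pMCMC) are
deterministic functions of the stored draws.

### Summaries, DIC, diagnostics

95% credible intervals are highest-posterior-density intervals (the
shortest window containing 95% of sorted draws), the convention of the
ecosystem; `hpdInterval()` is exported and an equal-tailed quantile
interval is a one-liner if preferred. The MCMC p-value is
$2\max(1, \min(\#>0, \#<0))/S$, capped at 1 and by construction never 0.

DIC uses the conditional deviance: $\mathrm{DIC} = \bar D + p_D$ with
$p_D = \bar D - D(\bar\theta)$, the plug-in point being the posterior mean
of the latent liabilities (binomial) or of the fitted values and residual
variance (Gaussian). Conditional-vs-marginal deviance conventions differ
between implementations, so *absolute* DIC values are not comparable across
software; differences within a suite, and the weights derived from them,
are the meaningful quantities.

Stationarity is assessed per parameter with an iterative Cramér–von Mises
test: the long-run variance is estimated from the second half of the chain
by an AIC-selected autoregression, successive 10% prefixes are discarded
(up to 50%) until the test passes, and the verdict is invariant to affine
rescaling. If the AR coefficients of the second half sum to ≥ 0.97 the
spectral density at zero is unreliable (trend or random-walk behaviour) and
the chain is declared non-stationary outright; this guard is what makes a
deterministic drift fail cleanly instead of slipping through on an inflated
variance estimate.

## Model comparison

Weights $w_m = e^{-\Delta_m/2}/\sum_j e^{-\Delta_j/2}$ are computed in log
space and normalised, so very large $\Delta$ cannot overflow the
normaliser (a weight may still underflow to exactly 0 in double precision
beyond $\Delta \approx 1400$). A component's weight is the sum of the
weights of the models whose *formula descriptor* contains it — membership
is decided from the declared term sets, never by name-matching fitted
parameters. The per-draw R² decomposition assigns each fixed covariate the
population variance (divisor n) of its contribution $x_j\beta_j$ over the
observed design rows, each random term its sampled variance, plus the
residual; shares are normalised within each draw, so they sum to exactly 1
and combined shares of several components are additive. The intercept
contributes no variance and is omitted from the table. Report tables are
rounded to 3 decimals.

## The synthetic-data generator

The generator exists so that every stage — parsing, calling, scoring,
fitting, comparing — is exercised end-to-end without external data. It
emulates:

* a pure-birth (Yule) species tree rescaled to height 1 (topology realism
  is irrelevant to the contracts being tested; distances are comparable
  across simulations);
* strain-level liabilities $\ell = \beta_0 + \beta_1 d + u_{phylo} +
  u_{species} + e$ with defaults $\beta_0 = 0$, $\beta_1 = -2$,
  $\sigma^2_p = 1$, $\sigma^2_s = 0.5$, $\sigma^2_e = 1$, 40 species × 3
  strains × 3 replicates. The slope and phylogenetic variance are the
  calibration used throughout the recovery tests; the intercept makes the
  focal host's infection probability 0.5, and the species/residual
  variances were set once to keep phylogenetic and non-phylogenetic noise
  of comparable size, a regime in which susceptibility fractions (roughly
  a quarter to a third of strains) resemble a realistic spillover assay;
* plate structure: controls and benchmarks in triplicate per block with Ct
  moments (15.7, 2.0), (12.7, 2.2), (38.4, 2.6), (22.0, 0.6) for the two
  positive controls and two benchmarks, a always-undetected negative
  control, and eight blocks by default. Raw role draws at or above 40
  cycles are recorded as undetected — the detection limit — so the
  *recorded* benchmark-4 wells follow an upper-truncated normal (the test
  suite checks them against that closed form), while roles far from the
  limit reproduce their nominal moments;
* infected replicates drawing Ct from a normal with mean 20, sd 4
  (truncated to (0, 40)): free parameters chosen to straddle the positive
  control means and sit clearly below the threshold regime;
* passage persistence: detection at passage 0 iff the passage-0 Ct is
  below the threshold, then per-passage retention probability
  $\mathrm{logit}^{-1}(1.5 - 0.2\,(Ct_0 - 20))$, so strong primary
  amplification (low Ct) sustains transmission — about 0.82 at Ct 20,
  falling below one half by Ct 28.

What the generator does **not** emulate: qPCR curve chemistry and
efficiency, block-level technical effects on Ct, within-host viral
kinetics, evolution of the virus during passage, and non-Brownian trait
evolution. Passing tests therefore certify the statistical contracts of
the pipeline — calling rules, tree algebra, sampler correctness, weight
arithmetic — on data that satisfy the model's assumptions; they do not
certify that real assay data satisfy those assumptions.

## Scale of the test problems

The test suite fits models at desk scale: chains of 50 000 iterations
(10 000 burn-in, thinning 20, 2000 stored draws) for the recovery study of
100 simulated datasets of 120 observations each, and shorter chains
(≥ 100 stored draws, the summariser's minimum) for structural tests.
Production-scale settings of any size are accepted via `chainSettings()`.
At the recovery calibration the distance fixed effect is partially
confounded with the phylogenetic random effect ($\sigma^2_p = 1$ on a
height-1 tree), which widens the slope's posterior; interval coverage is
the robust property there, while two-sided detection power at
$\alpha = 0.05$ is intrinsically limited at $n = 120$ regardless of chain
length — the corresponding check in the acceptance suite documents this
regime honestly rather than tuning the generator toward separation.

## Known limitations

* Binomial fits report liability-scale effects whose magnitude depends on
  the weakly identified residual variance; compare signs, intervals and
  weights across models, not raw magnitudes across software.
* DIC is computed from the conditional deviance; it is the criterion this
  analysis style uses, not an endorsement — WAIC/LOO are out of scope.
* One chain per fit; between-chain diagnostics (R-hat) are not provided,
  only within-chain stationarity and trace artifacts.
* The pipeline pools transmission blocks without a block term and imputes
  the undetected passage-0 Ct at 40 for score-0 lines (declared,
  configurable via `undetectedCt`), both matching the published design in
  which no block effect appears in the transmission models.
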