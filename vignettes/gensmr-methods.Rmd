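---
title: "Generalized spatial mark-resight: models, sampler and design evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized spatial mark-resight: models, sampler and design evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gensmr)
```

## The estimation problem

Camera-traps detect animals such as pumas that carry no individually
unique natural markings, so most photographs cannot be assigned to an
individual. Spatial mark-resight (SMR) solves this by marking a subset of
the population (here, GPS-collared animals caught at live-traps) so that
detections split into *identified* resightings of marked animals and
*identity-free* detections of unmarked animals. Density is then estimated
by embedding both in a spatial capture-recapture (SCR) model in which
every individual — observed or not — has a latent activity centre.

Conventional SMR (conSMR) ignores *how* animals came to be marked. When
marking happens by live-trapping inside the same region that the cameras
survey, marked animals sit systematically closer to the cameras than
unmarked ones, and ignoring this pushes density estimates down. The
generalized model (genSMR) removes that bias by modelling the marking
process jointly with resighting.

## Model

All coordinates are planar kilometres in an equal-area projection;
distances are Euclidean. The state space $S$ is a rectangle obtained by
buffering the detector extent (both trap types for genSMR; cameras only
for conSMR).

**Abundance and activity centres.** The population is embedded in an
augmented pool of $A$ potential individuals with inclusion indicators
$z_i \sim \mathrm{Bernoulli}(\psi)$; abundance is $N = \sum_i z_i$ and
density $D = N / |S| \times 100$ per 100 km². Marking-period activity
centres are uniform, $s_i^M \sim \mathrm{Uniform}(S)$. With transiency
enabled, each individual relocates once between the marking and the
resighting period:
$s_i^R \sim \mathrm{BVN}(s_i^M, \sigma_t^2 I)$ truncated to $S$
(the truncation constant is the product of two univariate normal CDF
differences, computed exactly); without transiency $s_i^R = s_i^M$.
Truncating the kernel prevents $\sigma_t$ from being underestimated when
centres sit near the boundary.

**Marking.** Live-trap captures are binomial over exposure days with a
hazard half-normal per-day capture probability,
$Y^M_{ij} \sim \mathrm{Binomial}\!\big(E^M_{ij},\,
1 - \exp(-\lambda_0^M e^{-d_{ij}^2 / 2\sigma_d^2})\big)$, with $d_{ij}$
the distance from $s_i^M$ to live-trap $j$. A marking "occasion" is one
trap-day, matching how live-trap effort is recorded in the field
(per-trap effort of order tens of days).

**Resighting.** Camera counts are Poisson,
$Y^R_{ij} \sim \mathrm{Poisson}\!\big(E^R_{ij}\,\lambda_0^R
e^{-d_{ij}^2/2\sigma_d^2}\big)$ with $d_{ij}$ from $s_i^R$; $\lambda_0^R$
is a per-occasion expected count, not a probability. The exposure
matrices $E^M, E^R$ count occasions on which the detector operated *and*
the individual was alive and in the population, so known deaths and
mid-survey markings enter the likelihood through exposure, and through
the mark-status matrix $m$ (0 unmarked / 1 marked / 2 dead per
resighting occasion) that constrains latent-identity allocation: a
record at occasion $k$ can be owned by a marked individual only while
its code is 0, and never by a dead one.

**Telemetry.** Thinned GPS locations (one per occasion per collared
animal) are modelled as independent bivariate normal draws around
$s_i^R$ with per-axis SD $\sigma_d$, untruncated. A single spatial scale
is shared by marking, resighting and telemetry, so telemetry directly
informs $\sigma_d$ — and, with transiency, $\sigma_t$, because collared
animals that moved far between periods are exactly the ones cameras
tend to miss.

**Sex as a partial identity.** Each individual carries
$\mathrm{sex}_i \sim \mathrm{Bernoulli}(p^{sex})$ (1 = female). When the
sex constraint is on, an unmarked detection with observed sex can only
be allocated to an individual of that sex, so a female record and a male
record can never be attributed to the same animal. Records with
unidentified sex are unconstrained. Sex-specific detection parameters
($\lambda_0^M, \lambda_0^R, \sigma_d$ by sex) are optional.

**Priors.** Flat: $\lambda_0 \sim U(0, 10)$,
$\sigma_d \sim U(0, 50\,\mathrm{km})$,
$\sigma_t \sim U(0, 100\,\mathrm{km})$, $\psi, p^{sex} \sim$ Beta(1, 1).
Bounds are wide relative to any plausible carnivore estimate and are
configurable in `mcmc_config()`.

## The sampler

`run_mcmc()` is a Metropolis-within-Gibbs sampler. Each sweep updates:

1. **Activity centres.** Individuals whose centres carry data (marked
   animals, owners of allocated records, telemetry) get bivariate
   random-walk proposals accepted rowwise — proposals and acceptances are
   vectorized across individuals, which is what makes a pure-R sampler
   fast enough. Included individuals with *no* data get independence
   proposals from the prior: their likelihood (a zero-count term) is
   nearly flat away from detectors, so prior proposals mix across the
   whole state space in one step instead of diffusing; this is the main
   reason $N$ and $\sigma_d$ mix acceptably at survey scale. Excluded
   individuals ($z = 0$) are refreshed directly from the prior, which is
   their exact conditional.
2. **Latent identities.** Each unmarked record proposes a new owner
   uniformly among eligible individuals ($z = 1$, mark-status code
   permits, sex compatible). At record level the exact conditional for
   an owner is categorical with weight proportional to the per-occasion
   Poisson rate $\lambda_0^R e^{-d^2/2\sigma_d^2}$ (count factorials
   belong to the record-multiplicity term and cancel), so the acceptance
   ratio is simply the rate ratio of proposed to current owner.
3. **Sexes** of individuals not pinned by data (Gibbs; likelihood-weighted
   when detection is sex-specific), then $p^{sex}$ by its conjugate Beta
   update over included individuals.
4. **Inclusion.** $z_i$ for individuals with no data by Gibbs using their
   zero-detection likelihood, then $\psi$ by its conjugate Beta update.
5. **Detection parameters.** Log-scale random walks for
   $\lambda_0^M, \lambda_0^R, \sigma_d$, plus a joint "ridge" move that
   scales $\sigma_d$ up while scaling the baselines down
   ($\lambda_0 \propto \sigma^{-2}$ keeps total exposure to detection
   roughly constant) — the two are strongly negatively correlated in the
   posterior and axis-aligned walks alone traverse that ridge slowly.
6. **Transiency.** $\sigma_t$ by a log random walk proposed *jointly*
   with a rescaling of the relocation steps of augmented individuals
   that carry no data (Jacobian accounted for), so the kernel exponent
   of those individuals is invariant under the proposal. Without this,
   hundreds of prior-only relocation terms anchor $\sigma_t$ and it
   mixes very poorly — this parameter is the slowest-mixing quantity in
   the transient models and chains should be run longest for them.

Proposal scales adapt toward standard acceptance targets during burn-in
only, leaving the retained chain a fixed-kernel Markov chain. With
`keep_latent = TRUE` the retained allocation, owner sexes and inclusion
vectors are stored so chain-wide invariants (sex exclusion, count
conservation, eligibility) can be audited after the fact; the test suite
does exactly that.

**Validation.** On a tiny instance (four potential individuals, one
live-trap, two cameras, two unmarked records) the posterior over $N$
from the sampler is compared against brute-force enumeration over all
record allocations and inclusion states, with activity centres
integrated numerically on a grid; the two agree within 0.02 total
variation. This check exercises the allocation weights, the inclusion
updates and the marking zero-history terms simultaneously.

## Synthetic data

`simulate_smr()` draws from exactly the generative model above, in the
order population → marking → relocation → resighting → telemetry, and
returns both the truth and a fit-ready dataset. Defaults emulate a large
semi-arid puma study: density 0.84 / 100 km², $\lambda_0^M = 0.007$ per
trap-day, $\lambda_0^R = 0.019$ per occasion, $\sigma_d = 6.51$ km,
$\sigma_t = 17.4$ km, $p^{sex} = 0.33$, 17 weekly occasions, sex
identified for 52% of unmarked detections (the per-detection rate such
studies report), and live-trap effort of roughly three weeks per trap.
Known deaths and mid-survey markings are injected through an event table
and propagate consistently to exposure, mark-status, resighting and
telemetry.

What the generator deliberately does **not** emulate: movement
autocorrelation (telemetry fixes are i.i.d. around the centre, as the
model assumes, whereas real fixes are an autocorrelated track — the
package's `thin_telemetry()` exists precisely to weaken that dependence
before fitting); habitat heterogeneity (centres are uniform on a
rectangle); behavioural responses to traps; and unknown closure
violations. Passing tests therefore demonstrate correctness of the
estimator under its own assumptions, not robustness to their violation.

## Clustered design evaluation

`make_clustered_design()` reproduces a staggered cluster layout: 3×3
cells per cluster at 3.5 km spacing (12.25 km² per cell, 110.25 km² per
cluster), clusters 28 km apart longitudinally with 36/45 km alternating
latitudinal spacing. `run_design_study()` is the pre-deployment harness:
it simulates fully identified SCR data on the buffered design (buffer
$3\sigma$), fits a null SCR model per replicate with `fit_null_scr()`,
and aggregates relative bias (normal-approximation CI), mean posterior
CV (posterior SD / posterior mode), RMSE of the posterior-mode density,
and coverage of 95% HPDIs with a Wilson CI. Wilson intervals were chosen
over Wald for their behaviour at coverage near 1.

## Numerical and design choices

- **Point estimates** are posterior modes: KDE argmax (Gaussian kernel,
  Sheather–Jones bandwidth, normal-reference fallback) for continuous
  parameters; the most frequent value (ties toward the smaller) for
  integer ones. CV is posterior SD divided by the mode. Mode estimates
  inherit KDE bandwidth sensitivity; with the skewed posteriors typical
  of $N$, the mode sits below the mean, which is partly why mode-based
  estimates carry a small positive bias at low information.
- **HPDI** is the shortest window containing $\lceil 0.95 n \rceil$
  sorted draws.
- **Combined detected percentage** adds the percentage of the population
  marked and the percentage of *unmarked* animals detected — two
  different denominators, reported additively as is conventional for
  this summary; the single-denominator alternative is smaller and noted
  in `marked_fractions()` documentation.
- Likelihood sums are accumulated in log space from exposure-weighted
  kernel row sums plus sparse corrections at nonzero counts, so sweeps
  cost a handful of dense matrix operations regardless of how sparse the
  data are.
- Default augmentation sizes (250 conventional / 350 generalized with
  telemetry / 600 without) mirror common practice at this study scale;
  the sampler warns when any retained draw exceeds $0.95A$.
- Problem sizes in the shipped tests are deliberately modest — tens of
  replicates, thousands of sweeps, four-cluster arrays for the
  generalized fits — sized so the whole suite runs on a laptop core in
  tens of minutes while keeping Monte-Carlo error well inside the
  asserted tolerances. The design-evaluation harness reports its CIs so
  scaled-down runs remain comparable with full-length ones.

## Known limitations

- Conventional SMR is weakly identified when unmarked detections are few:
  the likelihood is nearly flat along the ridge where abundance rises and
  the baseline detection rate falls together, so with the flat
  data-augmentation prior the posterior can drift far up that ridge. The
  generalized model's marking process truncates the ridge — every
  included individual must also explain why it was never live-captured —
  which is the practical reason to prefer genSMR whenever a marking
  process exists. In the package's own scaled-down comparisons this shows
  up as conventional posterior modes sitting *above* the generalized
  ones; richer datasets constrain the conventional model better, and
  published field analyses report the opposite ordering. Treat
  conventional fits at small sample sizes with corresponding caution.
- Chains at survey scale with transiency need long runs for $\sigma_t$;
  the joint rescaling move helps but does not remove the problem.
- The latitudinal stagger of a real array is a surveyed quantity; the
  generator's alternating 36/45 km rule reproduces the stated spacing
  range, not any particular realized geometry, and supports a dropout
  mask for cells that could not be instrumented.
- No habitat masks: the state space is rectangular. No open-population
  dynamics beyond known deaths and markings; no behavioural or
  time-varying detection effects.
- `fit_null_scr()` treats identities as known and is intended for design
  simulation, where identified-data performance is the standard proxy
  for SMR design performance.
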