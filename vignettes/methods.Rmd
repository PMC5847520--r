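---
title: "Models and methods in vulturedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in vulturedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vulturedyn)
```

`vulturedyn` links four models of one conservation question: can spatially
variable carcass poisoning explain why two neighbouring populations of
African white-backed vultures show very different survival, and what does
that imply for their persistence? This vignette documents each model, its
assumptions, the tunable parameters and their defaults, the numerical
choices, and what the package's tests do and do not demonstrate.

## Cormack–Jolly–Seber survival estimation

Annualized capture histories (one 0/1 entry per bird per year, conditioned
on first capture) are modelled with apparent survival $\phi$ per bird-year
and resighting probability $p$ per bird-occasion. For a bird released at
occasion $r$ and last seen at occasion $L$ the likelihood contribution is

$$\prod_{t=r}^{L-1}\phi_{it}\,p_{i,t+1}^{y_{i,t+1}}(1-p_{i,t+1})^{1-y_{i,t+1}}
  \;\times\;\chi_{iL},$$

with $\chi$ the probability of never being seen again, computed by the
backward recursion $\chi_{iK}=1$,
$\chi_{it}=(1-\phi_{it})+\phi_{it}(1-p_{i,t+1})\chi_{i,t+1}$.

Structures are additive on the logit scale, in standard mark-recapture
notation: `site` (region of tagging), `age` (current age class) and
`time` for $\phi$; `site` and `time` for $p$. Age classes follow
plumage-based field ageing — juvenile (years 1–2), subadult (3–5), adult
(6+) — and a bird's class advances deterministically with calendar years
since tagging, entering each class at its first year. This treats age as a
time-varying individual covariate, mirroring how age-structured survival is
specified in design-matrix mark-recapture software.

Numerical choices:

* **Optimizer.** Multi-start BFGS on the logit-scale coefficients
  (`reltol` 1e-10, up to 1000 iterations). The default four starts are the
  null vector plus three bounded deterministic spreads, so fitting never
  touches the global RNG. Non-convergence is reported in the fit object,
  never silently.
* **Standard errors** come from the inverse numerical Hessian at the
  optimum; back-transformed estimates use the delta method through the
  logit link.
* **Boundary estimates.** Data in which every bird is seen every year push
  $\hat\phi,\hat p\to 1$; any coefficient beyond $|{\rm logit}|>8$ raises a
  boundary warning and flags the fit.
* **AICc.** $-2\log L + 2k + 2k(k+1)/(n_{\rm ess}-k-1)$. The effective
  sample size is not uniquely defined for CJS data; the package defaults to
  the total number of post-release detection opportunities (summed over
  birds) and exposes `ess = "released"` as an alternative. Within one model
  set the choice shifts all AICc values nearly in lock-step, so rankings
  are robust to it, but absolute AICc values are not comparable across
  conventions. Parameter counts are design-matrix column counts; published
  mark-recapture tables sometimes count confounded terminal parameters
  differently, which is why only a ranking table's *internal* arithmetic
  (deltas and Akaike weights), not absolute AICc, is treated as
  reproducible.
* **Confounding.** With time-dependence in both $\phi$ and $p$, the final
  $\phi p$ product is the only identifiable quantity; requesting that
  structure warns.

`combined_survival()` aggregates a region's age-class estimates with the
region's released-bird age composition (or user weights) and propagates the
uncertainty by the delta method. It is defined only for time-constant
$\phi$ structures.

## Stage-structured matrix models

The life cycle is female-only with a pre-breeding census: the youngest
tracked class is 1-year-olds, and first-year survival is folded into the
fecundity term $f$ (breeding propensity × clutch/2 × hatching × fledging ×
first-year survival). The 5×5 matrix has survival arcs $s_1,s_1,s_2,s_2$ on
the subdiagonal, adult self-loop $s_3$, and a single fecundity arc in the
corner — one reproductive loop, which forces the five loop elasticities
(fecundity and the four pre-adult survival arcs) to share a single value, a
structural identity the tests exploit.

$\lambda$ is the dominant eigenvalue; sensitivities are
$s_{ij}=v_iw_j/\langle v,w\rangle$ from the dominant right (stable stage,
$w$) and left (reproductive value, $v$, scaled to $v_1=1$) eigenvectors,
and elasticities $e_{ij}=(a_{ij}/\lambda)s_{ij}$ sum to 1 over realized
entries. Sensitivities are verified against a central finite-difference
oracle ($h=10^{-6}$, agreement to $10^{-5}$).

**Reconstructed vital rates.** The regional vital rates behind the
published demographic analysis were never printed; what is printed are
$\lambda$, sensitivities and elasticities per rate. Since
$e=(a/\lambda)s$ is invertible entry-wise, `derive_vitals()` recovers
$a = e\lambda/s$; `awbv_demography_table()` carries the printed values.
Two notes: the Kruger adult rate inverts to 1.0045 (>1, a printed-rounding
artefact) and is clipped to 1 with a warning rather than silently adopted;
and the KZN inversion reproduces the empirically unusual pattern of
juvenile survival (0.856) exceeding subadult (0.504) and adult (0.573)
survival. The reconstructed matrices give $\lambda = 1.0357$ (Kruger) and
$0.6517$ (KZN), matching the published 1.04 / 0.65 at their printed
precision, which is the package's evidence that the reconstruction is
faithful.

**Metapopulation.** The 10×10 matrix nests the two regional matrices with
symmetric dispersal: every arc with rate $r$ splits into $r(1-d)$ within
region and $rd$ into the other region's corresponding stage (so column mass
is conserved), with first-year dispersal 5% on fecundity arcs and 2% on
survival arcs by default. The matrix is symmetric by construction — both
regions' arcs split by the same rule — rather than hand-written entry by
entry, which removes any chance of subscript slips. With zero dispersal
the spectrum is the union of the regional spectra, so
$\lambda_{\rm meta} = \max(\lambda_{\rm Kr},\lambda_{\rm KZN})$ — a test
invariant. With the default dispersal the reconstructed rates give
$\lambda = 1.0149$.

**Quasi-extinction.** The only stochastic element is a yearly Bernoulli
catastrophe indicator with probability $1/\text{interval}$; in catastrophe
years the Kruger subadult and adult survival rates are replaced by the KZN
values, reverting afterwards. Projection is otherwise deterministic — no
demographic or environmental noise beyond the catastrophe switch. The
initial vector distributes 1200 (Kruger) and 425 (KZN) females as 9% stage
1, 24% split equally over stages 2–4, and 67% stage 5; this is the chosen
mapping of a three-part published composition onto five single-year
classes. Extinction is first passage below 10 females at any year of the
100-year horizon (an endpoint-only definition is switchable and is
dominated by first passage, a tested invariant). Default 10,000 replicates;
the replicate count of the original analysis was unstated, and at 10,000
the Monte Carlo standard error of a probability is at most 0.005. All
replicates are projected as a single 10×N matrix product per year, so the
simulation runs in seconds.

## The foraging/poisoning agent-based model

The arena is a 200×200 km square of continuous space (1 km patches matter
only through carcass positions). A central circle of 20,000 km² is the
focus region; the exterior has equal area. Habitat identity (protected =
Kruger-like, non-protected = KZN-like) travels with the focus: flipping the
focus swaps labels pointwise, a tested involution. Inside are an 8-km
colony circle and a 50-km foraging circle that confines adults until their
day-240 release from breeding duties.

Carrion: each dawn, expired carcasses are removed (small after one day,
large — over 1000 kg — after two), and each habitat is replenished with
carcasses drawn from its mass distribution until standing mass reaches the
habitat cap (0.15 kg km⁻² × 20,000 km² = 3,000 kg protected; 0.3 kg km⁻²
→ 6,000 kg non-protected; the final draw is kept whole, so a dawn can
exceed the cap by at most one carcass — a tested invariant). Protected
habitat draws Gamma(shape 1.2, rate 0.004) — mean 300 kg and
$P(X>1000)=0.02745$, which pins the rate (not scale) parameterization —
non-protected habitat Normal(500, 100) truncated at zero. A new carcass is
poisoned with probability $1/R$ of its habitat.

Birds: 26 adults (13 birds per 100 km² over the 200 km² colony), 13
subadults, 13 juveniles. Every 10-minute tick a foraging bird turns 15°
left or right at random and flies 4 km (24 km/h), unless it sees a carcass
— detection within 6 km, or 7 km when the carcass is large or already
occupied (local enhancement) — in which case it heads for the nearest one.
Birds that fed yesterday head for that remembered patch first, diverting to
any carcass they detect on the way. Flight is quasi-continuous, so
detection is evaluated against the whole path segment a tick traverses, not
just its endpoints; with 4-km steps this keeps the effective detection
swath at the full stated radius. A bird reaching a carcass feeds until the
9-hour window ends — or dies instantly if the carcass is poisoned, the
model's only mortality source (so with poisoning disabled, survival is 100%
by construction, and alive + logged deaths always equals the initial count).
Multiple birds may die at one poisoned carcass, and a poisoned large
carcass remains lethal on its second day.

Nights: adults return to their colony site until day 240 and to the nearest
roost thereafter; subadults flip a fair coin between their colony site
(prospecting) and the nearest roost; juveniles take the nearest roost.
Because nothing in the model interacts with a homing bird — it cannot feed
or be poisoned en route — the overnight return is implemented as direct
placement at the roost rather than simulating the 48 km/h homing flight;
the two are behaviourally identical at dawn. Memory of a day without
feeding is dropped. Boundaries reflect (the arena edge and, for pre-release
adults, the 50-km circle): a torus would let the "outside" region wrap into
itself and destroy the centre/periphery geometry the model is about.

A year is 365 days; an experiment is 30 replicate years. Between-replicate
variance is substantial (roost placement alone moves stage survival by tens
of percentage points), which is why experiments are summarized as mean ± SD
over replicates and compared with rank statistics rather than replicate by
replicate.

## Rank statistics

`wilcoxon_rank_sum()` and `kruskal_wallis()` wrap the standard base-R
tests (exact small-sample null for tie-free rank-sum data, tie-corrected
normal/χ² approximations otherwise); tied pooled samples of at most 16
values get an exact midrank permutation enumeration, so small-sample
p-values are exact with or without ties. An all-identical sample is
degenerate: it is flagged and returns H = 0, p = 1 rather than NaN.
`dunn_posthoc()` implements Dunn's pairwise mean-rank z tests with
tie-corrected pooled variance; the multiplicity adjustment is selectable
(`holm` default — the adjustment used by the original analysis was
unstated — with `bonferroni` and `BH` available through `p.adjust`).

## The synthetic-data generator

`sim_spec()` describes a tagging study: cohorts (region × age class ×
release occasion), true survival per (region, age class), true resighting
per (region, occasion), and optional annual tag retention (default 1: tag
loss is a known caveat of patagial tags but is excluded from the default
generating model, as it was from the original analysis; dead recoveries are
never emitted). The default design emulates the study scale — 183 birds in
two regions over seven annual occasions, juvenile-heavy staggered cohorts —
with survival and resighting values chosen as field-plausible for *Gyps*
vultures (Kruger-like adult survival 0.90, KZN-like 0.68, resighting
0.4–0.6). Occasions are clean annual pulses; the real study's year-round
resighting window violates the pulse assumption, and no violating mode is
offered — the generator exists to validate the estimator, and a clean pulse
design is what makes truth recovery a meaningful test.

What passing tests show: the likelihood is a proper probability model
(enumerated histories sum to 1), the estimator recovers additive
logit-scale truth at n = 5,000 with bias below 0.02, and the ranking
arithmetic is exact. What they cannot show: that the original field
estimates (e.g. combined survival 0.858 vs 0.683) are reproduced — the
re-sightings data were never deposited, so those numbers are treated as
non-reproducible and excluded as targets; likewise the ABM reproduces the
published *relative* survival patterns (protective effect of the focus
region, KZN juveniles outliving adults) and lands its 30-replicate adult
means near the published ones (Kruger-focus ≈ 54% vs 48.98; KZN-focus
≈ 8–10% vs 7.05), though the KZN-focus mean tends to run one to three
points high. The published means imply that birds fed almost every day,
which independent 6-km-vision search over a 40,000 km² arena at the stated
carrion caps does not quite produce; the residual gap reflects unpublished
implementation detail of the original simulation rather than any stated
parameter, and the package does not paper over it. Individual published
test statistics (W = 6119 and similar) depend on the original simulation
draws and are not asserted.

## Problem sizes

The test suite runs the study-scale conditions end to end: 30-replicate ABM
experiments for both focuses (≈ 8 minutes), 50-seed × 5,000-bird CJS
recovery (≈ 3 minutes), 10,000-replicate extinction scenarios (seconds) and
1,000-simulation type-I calibration of the Kruskal–Wallis wrapper. The
pipeline demo in the tests uses reduced sizes (8-day ABM, 300-replicate
extinction) purely to keep the default run fast; `run_pipeline()` defaults
are the full sizes.
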