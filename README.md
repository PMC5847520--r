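# vulturedyn

Demographic and spatial-risk modelling for African white-backed vultures
(*Gyps africanus*) — or any long-lived scavenger whose survival is driven by
spatially variable carcass poisoning.

African vultures are obligate scavengers in steep decline, and poisoned
carcasses are the dominant mortality source: a single poisoned elephant
carcass can kill hundreds of birds. `vulturedyn` implements the full
computational chain used to ask whether *where* poisoning happens (inside
vs. outside a protected area) can explain regional differences in survival
and what those differences imply for population persistence:

1. **Mark-resighting survival** — a Cormack–Jolly–Seber (CJS) likelihood
   with apparent survival φ and resighting probability p structured
   additively on the logit scale over region (`site`), age class (`age`,
   advancing annually: juvenile → subadult → adult) and occasion (`time`),
   fitted by multi-start quasi-Newton maximum likelihood and ranked by
   AICc with Akaike weights
   `w_i = exp(-Δ_i/2) / Σ_j exp(-Δ_j/2)`.
2. **Matrix population models** — female-only, pre-breeding-census 5×5
   stage matrices per region (survival arcs s1, s1, s2, s2, s3 and a single
   fecundity arc f), with growth rate λ (dominant eigenvalue), sensitivities
   `s_ij = v_i w_j / ⟨v, w⟩`, elasticities `e_ij = (a_ij/λ) s_ij`,
   reproductive values, a 10×10 two-region metapopulation matrix with
   symmetric dispersal, and Monte Carlo quasi-extinction probabilities under
   Bernoulli catastrophe years.
3. **A spatially explicit agent-based model (ABM)** — 26 adults, 13
   subadults and 13 juveniles foraging by correlated random walk over a
   200×200 km arena with a 20,000 km² central region, Gamma- or
   Normal-distributed carcass masses replenished daily to habitat-specific
   carrion caps (3,000 / 6,000 kg), 6 km vision (7 km for occupied or large
   carcasses), one-day carcass memory, colony/roost night returns, and
   per-carcass poisoning probability 1/R by habitat. Death occurs only by
   landing on a poisoned carcass.
4. **Rank statistics** — Wilcoxon rank-sum, Kruskal–Wallis and Dunn's post
   hoc comparisons of simulated survival across areas and life stages.
5. **Synthetic data** — a capture-history generator with known ground truth
   (183 birds, two regions, three age classes, seven annual occasions by
   default), so the entire chain is testable without field data.

## Worked example

```r
library(vulturedyn)

## survival estimation on synthetic data with known truth
ch  <- simulate_capture_histories(sim_spec(), seed = 42)
fit <- fit_cjs(ch, phi = ~ site + age, p = ~ site)
fit
#> CJS model: Phi(site + age), p(site)
#>   logLik -391.0774  k 6  ess 910  AICc 794.2479
combined_survival(fit, "Kruger")
#>   estimate         se
#> 0.77937209 0.03941541

## model ranking (printed AICc values from a candidate set)
rank_models(c("Phi(site+age),p(site+t)" = 619.6521,
              "Phi(site+age),p(t)"      = 630.4739,
              "Phi(site),p(site+t)"     = 633.4523))
#> Model ranking by AICc (3 models)
#>                    model  k     aicc   delta   weight
#>  Phi(site+age),p(site+t) NA 619.6521  0.0000 0.994600
#>       Phi(site+age),p(t) NA 630.4739 10.8218 0.004443
#>      Phi(site),p(site+t) NA 633.4523 13.8002 0.001002

## matrix models from the published sensitivity/elasticity table
v <- awbv_vital_rates()
growth_rate(stage_matrix(v$Kruger))   #> 1.035691   (growing)
growth_rate(stage_matrix(v$KZN))      #> 0.6517109  (declining)
growth_rate(metapop_matrix(v$Kruger, v$KZN))  #> 1.014855

## quasi-extinction risk when catastrophic poisoning hits Kruger
extinction_scenarios(intervals = c(15, 10, 5), seed = 7,
                     replicates = 2000)
#>   interval_years extinction_probability
#> 1             15                 0.0185
#> 2             10                 0.1925
#> 3              5                 0.9720

## the foraging ABM (one year, protected centre)
run_abm_year(abm_config(focus = "Kruger"), seed = 1)
#> ABM run (focus Kruger, rates 1/1000 vs 1/100, seed 1): survival %
#>    adult subadult juvenile
#>    50.00    46.15    23.08
```

A λ above 1 means the region's population grows; the KZN-like parameter set
declines sharply. The extinction probabilities are the fraction of Monte
Carlo replicates in which total females drop below 10 within 100 years. The
ABM survival percentages are per-stage fractions of birds alive at day 365;
with a tenfold lower poisoning rate inside the focal region, adults
(anchored to the central colony) survive far better under a protected focus
than a non-protected one, while wide-ranging juveniles are less affected —
the qualitative fingerprint that spatially variable poisoning leaves on
stage-specific survival.

`run_pipeline()` chains all stages and writes CSV/JSON artifacts plus a
manifest with per-stage seeds and file hashes.

## Vignette

`vignettes/methods.Rmd` documents the models, their assumptions, the
numerical choices and the limits of what the synthetic-data tests show.
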