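# baystmix

Bayesian spatio-temporal mixture modelling for public-health surveillance:
estimate small-area disease risk in space and time **and** detect the areas
— and the time points — whose trends depart from the shared national one.
Written for epidemiologists and biostatisticians analysing area-by-time
count tables (disease registers, hospital admissions, road-traffic
accidents) with an exposure offset.

## The model

Counts follow a Poisson log-linear mixture of two components,

```
Y[i,t] ~ Poisson(mu[i,t] * E[i,t])
log mu[i,t] = z[i,t] * muC[i,t] + (1 - z[i,t]) * muAS[i,t]

muC[i,t]  = alpha0 + eta_i + gamma_t     (Common model: BYM spatial field
                                          + one national RW1 trend)
muAS[i,t] = nu_i + kappa[i,t]            (Area-Specific model: free
                                          per-area RW1 trends)
```

with ICAR priors on the structured fields. Two allocation priors are
provided. The **baseline** model uses one indicator per area,
`z_i ~ Bern(0.95)`, and declares areas unusual with a Bayesian FDR rule on
the posterior allocation probabilities `f_i = P(z_i = 1 | data)`. The
**proposed** model lets the indicator vary per cell,
`z[i,t] ~ Bern(phi[i,t])` with
`logit(phi[i,t]) = pi_i + delta_t + logit(tau)`, `pi` and `delta` ICAR
fields and `tau ~ U(0.9, 1)`, and flags cells with `f[i,t] < 0.05`
directly — the hierarchical prior keeps false positives low without a
multiplicity correction, localises detections in time, and handles long
series. Inference is Metropolis-within-Gibbs with the allocation field
drawn from its exact full conditional, both components fitted to the full
data (the cut factorization of the original method; see the methods
vignette `vignettes/surveillance-mixture-models.Rmd`).

A scenario-based synthetic-data generator with known ground truth, the
sensitivity / specificity / false-positive-proportion / global-error
evaluation criteria, GAL neighbour-list input, a district traffic-volume
exposure aggregator, and a small CLI (`inst/scripts/baystmix`) round out
the toolkit.

## Worked example

Simulate a scenario with 4 unusual areas (isolated in space,
consecutive-variable in time) on a 7×7 lattice, fit both models, detect:

```r
library(baystmix)
g    <- latticeGraph(7, 7)
sim  <- simulateScenario(scenarioSpec("S2", nUnusualAreas = 4, seed = 3), g)
sim
#> SimulatedCounts with 49 areas x 15 time points
#>   counts: total 78587  mean SIR 1.128
#>   scenario: S2  unusual areas: 4
unusualAreas(sim)
#> [1]  1 16 42 46

fit <- runMCMC(sim, g, "proposed",
               mcmcConfig(nIter = 4000, burnIn = 2000, nChains = 1, seed = 5))
det <- fixedThresholdClassify(allocationProb(fit))
det
#> DetectionResult (rule: fixed at level 0.05 -> cutoff 0.05 ): 8 of 735 units declared unusual
head(as.data.frame(det), 3)
#>   area time     f  rule threshold
#> 5    1    7 0.002 fixed      0.05
#> 7    1    9 0.012 fixed      0.05
#> 8    1   10 0.012 fixed      0.05
detectionMetrics(confusionCounts(det, sim, "area_time"))
#>   sensitivity specificity fpProportion globalError
#> 1         0.4           1            0  0.01632653

fitB <- runMCMC(sim, g, "baseline",
                mcmcConfig(nIter = 4000, burnIn = 2000, nChains = 1, seed = 5))
detB <- bayesianFdrClassify(allocationProb(fitB))
truthArea <- apply(trueAllocation(sim) == 0, 1, any)
detectionMetrics(confusionCounts(detB, truthArea, "area"))
#>   sensitivity specificity fpProportion globalError
#> 1           1   0.9777778          0.2  0.02040816
```

The contrast is the method's story in miniature: the proposed model flags
8 of 735 cells, all inside truly unusual areas (false-positive proportion
0) at sensitivity 0.4 on cell level, while the baseline model finds every
unusual area but one declared area in five is a false positive. All cells
the proposed model flags sit in area 1's injected window (`f` well below
the 0.05 threshold).

`scenarioStudy()` runs the replicated pipeline (simulate → fit → detect →
evaluate) for any scenario `S1`–`S10`, and `summarizeReplicates()` /
`noAberrationSummary()` reproduce the study-table summaries.

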