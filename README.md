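# poregate

Quantitative analysis of pH-gated water and glycerol transport through
aquaglyceroporin channels — for transport physiologists and structural
bioinformaticians who need to turn stopped-flow osmotic-shock traces,
channel structures and gate-region trajectory ensembles into permeability
coefficients, pore dimensions and conformational-state populations.

## What it computes

**Transport kinetics.** A vesicle or cell under osmotic shock follows the
coupled flux system

    dV/dt  = Pf  · A · Vw · (osm_in − osm_out)
    dNg/dt = Pgly · A · (c_gly,out − c_gly,in)

with ideal (van 't Hoff) osmometry, constant surface area A, and an
osmotically inactive volume fraction β. `simulateVolumeTrace()` integrates
it; `fitFluxTrace()` estimates the water and glycerol permeability
coefficients Pf and Pgly (cm/s) by nonlinear least squares against a
calibrated relative-volume trace, with standard errors and structural
identifiability flags. The classical shortcut inversions are provided too:
`fitSingleExponential()` for rate constants, `pfFromRate()`
(Pf = k·V0/(ΔC·Vw·A)) and `pglyFromSwelling()` (Pgly = 1/((S/V)·τ)), with
their validity domains spelled out in the methods vignette. On top sit
`calibrateTrace()` (vrel = a·F/F0 + b with bleaching correction),
`tonicity()`/`equalVolumeMix()`/`idealOsmolarity()` for the shock
arithmetic, `hillFit()` for the pH dependence
(p(pH) = pmax/(1 + 10^(n·(pH − pK))), signed n: n > 0 means activated by
acidification) and `arrheniusEa()` (Ea = −slope·R from ln Pgly vs 1/T).

**Pore geometry.** `profileChannel()` computes largest-inscribed-sphere
radius profiles along a channel axis from PDB structures
(`loadStructure()`, `stripForProfile()`), with the HOLE-style "simple" vdW
radius set, deterministic multi-start slice optimization, and termination
at 5 Å. `minInRegion()` reports constriction minima in annotated regions
(ar/R filter, cytoplasmic gate); `compareProfiles()` ranks structures by
minimal dimension. All values are radii.

**Gate conformations.** `superposeFrames()` (Kabsch, proper rotations
only), `pcaFit()` on flattened CA coordinates, `kmeansSieved()` (k-means++
under a fixed seed, trained on every 5th frame), per-condition
`populationHeatmap()` and `clusterPopulations()`,
`representativeStructure()`, pore-width descriptors (`gateDistances()`)
and `rmsdSeries()`.

**Synthetic data.** Seeded generators (`genFluxTrace()`, `genTitration()`,
`genArrhenius()`, `genChannelPdb()`, `genGateTrajectory()`) emulate every
input class with known ground truth, so the entire pipeline is testable
offline.

## Worked example

```r
library(poregate)

## 1. Simulate a yeast glycerol shock and fit (Pf, Pgly) from a noisy trace
cond <- yeastShockDefaults()   # 1.4 M sorbitol inside, 0.7 + 1.05 M glycerol out
times <- seq(0, 20, length.out = 500)
clean <- simulateVolumeTrace(cond$params, cond$geom, cond$shock, times)
set.seed(1)
obs <- vRel(clean) + rnorm(500, sd = 0.01 * diff(range(vRel(clean))))
traj <- new("VolumeTrajectory", times = times, vRel = obs,
            cGlyIn = rep(NA_real_, 500), inactiveFraction = 0)
fitFluxTrace(traj, cond$geom, cond$shock, init = fluxParams(1e-3, 1e-5))
#> FluxFit: Pf = 0.004945 (se 0.00023), Pgly = 2.004e-05 (se 1.1e-07) cm/s; rss = 0.01055
```

The true values were Pf = 5e-3 and Pgly = 2e-5 cm/s: both recovered within
~1% from a trace with 1% noise, with standard errors that cover the truth.

```r
## 2. pH titration and temperature dependence
tit <- genTitration(seed = 1, pK = 6, n = 2, noiseSd = 0.05)
hillFit(tit$ph, tit$pNorm)
#> HillFit: pK = 6.025, n = 2.720 (activated by acidification), pMax = 0.959, rss = 0.00665

arr <- genArrhenius(seed = 1, ea = 20, noiseSd = 0.03)
arrheniusEa(arr$temps, arr$pgly)
#> ArrheniusFit: Ea = 19.992 kJ/mol (se 2.05), ln A = -1.070
```

The midpoint pH is recovered to 0.03 units at 5% noise, and the activation
energy to 0.04% at 3% multiplicative noise over the 283–307 K range.

```r
## 3. Pore profile of a synthetic channel (12-atom rings, radius 5 Å, vdW 1.5 Å)
ch <- genChannelPdb(ringRadius = 5, spacing = 0.5, zRange = c(-6, 6), vdw = 1.5)
prof <- profileChannel(ch$atoms, seedPoint = c(0, 0, 0), axis = c(0, 0, 1))
prof
#> PoreProfile: 69 slices, s in [-8.50, 8.50] A, min radius 3.500 A
minInRegion(prof, poreRegion("mid", c(-2, 2)))$radius
#> [1] 3.5
```

The ring geometry has an exact inscribed radius of 5 − 1.5 = 3.5 Å, which
the profiler reproduces.

```r
## 4. Gate conformations: superpose -> PCA -> sieved k-means
gt <- genGateTrajectory(seed = 1, framesPerCondition = c(mono = 400L, double = 400L))
sup <- superposeFrames(gt$ensemble)
pca <- pcaFit(sup)
cl <- kmeansSieved(pcaScores(pca)[, 1:2], k = 4, sieve = 5,
                   labels = frameLabels(sup))
round(clusterPopulations(cl), 3)
#>       mono double
#> [1,] 0.050  0.298
#> [2,] 0.843  0.105
#> [3,] 0.052  0.298
#> [4,] 0.055  0.300
```

The designed mixture (one condition 85% in a single closed-gate cluster,
the other spread 10/30/30/30 over progressively open clusters) is recovered
within one percentage point per cluster; cluster labels are arbitrary, so
comparisons use the adjusted Rand index and sorted populations.

See `vignettes/poregate-methods.Rmd` for the models, parameter choices and
numerical details.

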