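---
title: "Models and methods behind poregate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poregate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poregate)
```

poregate analyses pH-gated water and glycerol transport through
aquaglyceroporin channels from three directions: transport kinetics measured
by stopped-flow osmotic shocks, pore geometry of channel structures, and
conformational states of the cytoplasmic gate in trajectory ensembles. This
vignette explains the models, the tunable parameters, the numerical choices,
and what the synthetic test bed does and does not establish about real data.

## 1. The osmotic flux model

A vesicle or cell of initial volume $V_0$ (cm^3^) and constant surface area
$A$ (cm^2^) exchanges water and glycerol with an effectively infinite bath.
With ideal (van 't Hoff) osmometry and an osmotically inactive volume
fraction $\beta$, the state is the volume $V$ and the internal glycerol
amount $N_g$:

$$\frac{dV}{dt} = P_f\,A\,V_w\,(\mathrm{osm}_{in}-\mathrm{osm}_{out}),
\qquad
\frac{dN_g}{dt} = P_{gly}\,A\,(c_{g,out}-c_{g,in}),$$

with $\mathrm{osm}_{in} = (N_{imp}+N_g)/(V-\beta V_0)$,
$c_{g,in} = N_g/(V-\beta V_0)$ and
$\mathrm{osm}_{out} = \mathrm{osm}_{out,imp} + c_{g,out}$ constant. $P_f$
and $P_{gly}$ are the water and glycerol permeability coefficients (cm/s),
$V_w = 18$ cm^3^/mol the molar water volume. Under an inward glycerol
gradient the solution is biphasic: fast osmotic shrinkage, then slower
swelling as glycerol equilibrates — the classical aquaglyceroporin
signature. For an impermeant shock the steady state is the closed-form
balance $v_\infty = \beta + (1-\beta)\,\mathrm{osm}_{in,0}/\mathrm{osm}_{out}$,
which the test suite uses as an algebraic oracle.

Assumptions worth keeping in mind: the surface area is frozen at $A(V_0)$
(no membrane tension model), osmotic coefficients are ideal, and there are
no unstirred layers. These are the standard simplifications for
stopped-flow analysis at small relative volume changes.

`simulateVolumeTrace()` integrates the system with `deSolve::lsoda`
(adaptive, stiff-capable) on the non-dimensionalized state $(V/V_0,
N_g/V_0)$, relative tolerance `1e-8`; halving the tolerance moves the
reference solution by less than 10^-6^ in sup-norm, which is the package's
step-size-independence guarantee.

### Rate constants and the permeability formulas

`fitSingleExponential()` fits $y(t)=y_\infty+(y_0-y_\infty)e^{-kt}$.
Because amplitude and offset enter linearly, the implementation profiles the
residual over $k$ (each trial $k$ solved exactly by linear least squares)
before a Levenberg-Marquardt polish — this is robust for both decaying and
rising phases and cannot silently return garbage: flat traces come back
flagged `degenerate`, failed refinements flagged `converged = FALSE`.

The initial-rate inversions are implemented literally:
$P_f = k V_0/(\Delta C\, V_w\, A)$ and $P_{gly} = 1/((S/V)\tau)$. Both are
*conventions with a validity domain*, and the package documents rather than
hides it:

* For the water formula, linearizing the volume equation around equilibrium
  shows that a fitted single-exponential rate corresponds to an effective
  driving gradient $\mathrm{osm}_{out}^2/\mathrm{osm}_{in,0}\,(1-\beta)^{-1}$,
  not to the naive step $\Delta C = \mathrm{osm}_{out}-\mathrm{osm}_{in,0}$.
  `effectiveOsmoticGradient()` supplies that gradient; with it, the
  simulate-fit-invert round trip closes within 10% at tonicity 1.1. With the
  naive step the discrepancy is a factor $\approx\Lambda/(\Lambda-1)$ — large
  for mild shocks — which is why forward-model fitting
  (`fitFluxTrace()`) is the preferred estimator and the formula inversion a
  cross-check.
* The glycerol formula assumes volume relaxation much faster than glycerol
  exchange and a dilute glycerol gradient. In that regime (tracer gradients,
  $P_{gly}(A/V) \ll P_f (A/V) V_w\,\mathrm{osm}$) the round trip closes
  within a few percent; at the 1.05 mol/L preparative gradient the exchange
  rate carries an extra factor
  $(\mathrm{osm}_{out}-c_{g,out})^2/(\mathrm{osm}_{in}\,\mathrm{osm}_{out})$
  and the formula is only an order-of-magnitude tool.

`fitFluxTrace()` estimates $(P_f, P_{gly})$ by Levenberg-Marquardt on the
log scale (positivity built in, good conditioning across the two orders of
magnitude separating the parameters), with delta-method standard errors from
the Jacobian. A shock without any glycerol gradient makes $P_{gly}$
structurally non-identifiable; the fit freezes it, warns, and flags it in
`identifiable` instead of reporting a number.

### Calibration, tonicity, titration, temperature

Fluorescence-quenching traces are calibrated as $v_{rel} = a\,F/F_0 + b$
(`calibrateTrace()`). $F_0$ is the mean signal over a pre-shock baseline
window (first 5% of points by default, or an explicit window). Bleaching is
removed first: when an iso-osmotic control trace is available its
time-dependent drift (anchored at the control's own baseline intercept) is
subtracted; otherwise a line fitted to the baseline window is extrapolated
and its slope term removed. Either route reproduces a drift-free trace
exactly on constructed fixtures.

Tonicity is plain arithmetic, $\Lambda = \mathrm{osm}_\infty/\mathrm{osm}_0$,
with `equalVolumeMix()` for the standard 1:1 stopped-flow mix (mean of the
two osmolarities; buffer contribution ignored by default, available as an
additive term). The 1.4 + 2.1 osmol/L protocol gives $\Lambda = 1.25$.
`idealOsmolarity()` covers dissociating osmolytes — 0.5 M NaCl is
iso-osmotic with 1 M glycerol.

The pH dependence of normalized glycerol permeability
(`normalizePgly()`: $(P_{gly}-P_{gly,control})/P_{gly,max}$) is fitted with
the logistic-in-pH Hill form

$$p(\mathrm{pH}) = \frac{p_{max}}{1+10^{\,n(\mathrm{pH}-pK)}},$$

chosen so that $pK$ is directly the midpoint pH and the *sign* of $n$
encodes direction: $n>0$ for transport activated by acidification
(the AQP10-type response), $n<0$ for the AQP3-type response. Flat titrations
are flagged degenerate rather than fitted.

Activation energy uses ordinary least squares of $\ln P_{gly}$ on $1/T$
(`arrheniusEa()`). The raw slope of an activated process is negative; the
reported value is $E_a = -\mathrm{slope}\cdot R$ in kJ/mol, positive for
thermally activated transport. Two points define the line exactly (no
standard error); three or more give one.

## 2. Pore-radius profiling

`profileChannel()` computes the classical largest-inscribed-sphere profile:
at an axial position the pore radius is
$\min_i(\lVert p - x_i\rVert - r_{vdw,i})$ over heavy atoms, maximized over
the in-plane position $p$. Design choices:

* **Radii.** The "simple" vdW set (C 1.85, N 1.75, O 1.65, S 2.00, P 2.10,
  H 1.00 A) ships as an editable CSV (`inst/extdata/vdw_simple.csv`);
  unknown elements fall back to a configurable radius with a warning.
  Profiling is done on a single chain with waters, heteroatoms and
  hydrogens removed (`stripForProfile()`).
* **Optimizer.** A deterministic multi-start downhill simplex: 9 starts on
  a 1 A grid around the previous slice's optimum, tolerance 0.01 A. The
  in-plane objective is a concave-ish min-of-cones surface that
  Nelder-Mead handles well; determinism makes results reproducible and
  testable. Slices where no restart improves on the start are flagged. The
  test suite holds the optimizer to an exhaustive 0.02 A in-plane grid
  within 0.05 A on random 200-atom systems.
* **Marching.** Axial step 0.25 A by default — several times finer than the
  sub-Angstrom constriction differences of interest. Marching proceeds in
  both directions from a seed point (for gated channels, the CA centroid of
  the gate residues is a natural seed, see `residueCentroid()`), each slice
  warm-started from the last, and terminates once the radius exceeds 5 A
  (the mouth of the channel, recorded in the termination flags) or the path
  leaves the atom bounding box.
* **Axis.** The membrane normal is approximated by the first principal axis
  of the CA trace (`channelAxis()`); profiles are rigid-motion invariant,
  so any consistently transformed axis/seed pair gives the same radii.
* **Convention.** All values are *radii*, the native convention of
  inscribed-sphere profiling; double them for diameters. Region minima
  (`minInRegion()`, `regionFromResidues()`) report the constriction within
  an axial window — by default ±3 A around the CA centroid of the region's
  residues, wide enough to bracket a constriction without bleeding into the
  neighboring one at typical aquaporin dimensions.

`compareProfiles()` orders structures by their minimal dimension (with
per-region columns), ties broken by label for stable output.

## 3. Gate-conformation analysis

`superposeFrames()` removes rigid-body motion with the Kabsch algorithm;
only proper rotations are admitted (determinant +1), so mirror images keep
a positive residual. Collinear selections are rejected. The test suite
cross-checks residuals against Horn's closed-form quaternion method.

PCA (`pcaFit()`) is the eigendecomposition of the covariance of the
flattened, superposed, mean-centered, *unweighted* Cartesian coordinates —
the common trajectory-toolkit default. The superposition reference is the
first frame (crystal-structure frame when one is present), and the
alignment uses the analysis selection itself. The 28-residue gate selection
is a configuration input: per-atom metadata (`chain:resNo:atomName`)
travels with the ensemble, and the default synthetic selection includes the
residues that define the gate (loop B G73-H80 including V76/S77, F85, R94,
plus the facing E27 and L174), so pore-width descriptors
(`gateDistances()`, V76-L174 and V76-H80 CA distances by default) resolve
against it.

Clustering (`kmeansSieved()`) trains k-means on every 5th frame (sieving)
and assigns all frames to the nearest centroid. "k-means with average
linkage" idioms from trajectory toolkits are implemented as standard
k-means; initialization is k-means++ under a fixed seed (default 17) with
five restarts, keeping the lowest-inertia run — deterministic for a given
seed. Populations are tabulated per condition (columns sum to 1), and each
cluster's representative is the frame nearest its centroid, ties broken by
lowest frame index. A k of 10 with post-hoc regrouping by heat-map mode is
one published reading of how "core groups" emerge from a larger k; poregate
keeps regrouping manual — `populationHeatmap()` gives the 50x50 (default)
normalized per-condition histograms on a common grid, and merging decisions
stay with the analyst.

`rmsdSeries()` provides the standard per-frame backbone RMSD monitor
against a reference frame.

## 4. The synthetic test bed

Every analysis stage has a seeded generator producing data with exactly the
statistical structure the stage assumes, plus the ground truth:

* `genFluxTrace()` — forward-model traces mapped to fluorescence (affine in
  $v_{rel}$) or scattering (affine in $1/v_{rel}$) with additive Gaussian
  noise. The default conditions are the yeast shock protocol: 5 µm
  spherical cell, $\beta = 0.55$ (a commonly reported osmotically inactive
  fraction for yeast), 1.4 osmol/L internal sorbitol, equal-volume mix with
  a 2.1 osmol/L glycerol challenge (externally 0.7 impermeant + 1.05 mol/L
  glycerol, $\Lambda = 1.25$), $P_f = 5\times10^{-3}$,
  $P_{gly} = 2\times10^{-5}$ cm/s — aquaporin-expressing-cell scales.
* `genTitration()` / `genArrhenius()` — Hill curves (default $pK=6$,
  $n=\pm2$ over pH 4.5-8) and log-linear series (default $E_a=20$ kJ/mol
  over 283-307 K, the assay's temperature range) with additive /
  multiplicative noise.
* `genChannelPdb()` — stacked-ring cylinders and funnels with a closed-form
  on-axis radius, written as valid PDB text (element-correct columns), used
  as analytic oracles for the profiler.
* `genGateTrajectory()` — frames drawn from k template conformations (a
  designated gate atom displaced progressively, so both pore-width
  distances grow with the cluster index), isotropic jitter $\sigma$, random
  rigid-body motion per frame, and per-condition mixing weights realized by
  largest-remainder allocation so designed populations are exact by
  construction. The default layout concentrates the "mono" condition in
  cluster 1 (85%) and spreads "double" over the open clusters — the
  qualitative protonation-state shift the conformational analysis is meant
  to resolve.

RNG protocol: one user seed; each generator draws from its own substream
(seed + generator-specific offset), so adding a generator never shifts
another's fixtures, and identical configurations are byte-identical.

**What passing tests show — and what they do not.** The generators share
the analyses' own model families (exponential-plus-noise, ideal osmometry,
Gaussian blobs under rigid motion). Recovery at the designed noise levels
therefore demonstrates correctness of the estimators and their numerics —
not robustness to model misspecification in real data: non-ideal osmotic
coefficients, scattering nonlinearity, correlated photobleaching,
anharmonic conformational spread, or force-field artifacts are all outside
the test bed. Real channel structures also differ from ring-stack
pseudo-proteins in having rough, chemically heterogeneous pore walls; the
analytic channels validate the geometry engine, not biological conclusions.

## 5. Problem sizes and runtime posture

The default validation workloads are deliberately desk-scale: 100 random
equilibrium scenarios; 20-seed recovery studies at 500 trace points;
8-point titrations and 7-temperature Arrhenius series; 200-atom random
systems and a few thousand ring atoms for profiling; 800-frame, 28-atom
gate trajectories. These sizes put every estimator well inside its
asymptotic regime while keeping the whole suite in the minutes range on one
CPU. The frame-accounting check (192,036 = 8 cases x 4 monomers x 6,001
frames + 4 crystal frames) exercises ensemble concatenation at full count
with a minimal atom selection.

## 6. Known limitations

* No membrane mechanics, non-ideal osmometry or unstirred-layer
  corrections; no statistical testing of group differences.
* The rate-constant inversions are convention-bound (Section 1); prefer
  `fitFluxTrace()` when the full trace is available.
* The profiler does not compute conductance, water files, electrostatics
  or spherical-probe surfaces; it reports geometry only.
* Which 28 residues define the gate selection, and the superposition
  protocol, materially affect PCA results; both are explicit inputs here,
  with documented defaults, and results should be reported together with
  them.
* pKa estimation of the pH sensor is out of scope; the package
  characterizes pH dependence functionally (Hill), not structurally.
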