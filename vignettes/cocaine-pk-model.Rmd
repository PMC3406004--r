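---
title: "A two-compartment model of cocaine pharmacokinetics with enzymatic elimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-compartment model of cocaine pharmacokinetics with enzymatic elimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocainePK)
```

## The model

cocainePK implements a minimal mechanistic description of intravenous
cocaine disposition in humans: two well-stirred compartments — plasma
(concentration $C_1$, effective volume $V_p$) and brain striatum
($C_2$, effective volume $V_b$) — exchanging free-base cocaine across
the blood–brain barrier by first-order diffusion, with enzymatic
hydrolysis confined to plasma and following Michaelis–Menten kinetics:

$$\frac{dC_1}{dt} = -\frac{V_{max}\,C_1}{K_M + C_1} - K_{pb} C_1 + K_{bp} C_2,$$

$$\frac{dC_2}{dt} = \frac{V_p}{V_b}\left(K_{pb} C_1 - K_{bp} C_2\right),$$

where $V_{max} = k_{cat}\,[E]$ is the maximal hydrolysis velocity of the
plasma enzyme ($k_{cat}$, min⁻¹; active-site concentration $[E]$, µM;
Michaelis constant $K_M$, µM), and $K_{pb}$, $K_{bp}$ (min⁻¹) are the
plasma→brain and brain→plasma diffusion constants. The $V_p/V_b$ factor
makes the exchange conserve amount exactly:
$V_p\,dC_1^{exch} + V_b\,dC_2 = 0$, which `mass_balance_residual()`
verifies on every simulation.

Assumptions worth keeping in mind:

* compartments are homogeneous and exchange is first-order; brain binding
  (e.g. to the dopamine transporter) is not modelled;
* elimination is a single Michaelis–Menten enzyme in plasma. When an
  exogenous hydrolase with ≥1000-fold higher catalytic efficiency is
  present, endogenous butyrylcholinesterase (wtBChE) is neglected, so a
  scenario always carries exactly one `enzyme_kinetics` object;
* administration is an instantaneous i.v. bolus: $C_1(0) = C_{1,0}$,
  $C_2(0) = 0$. A dose $D$ in µg converts through the free-base
  molecular weight, $C_{1,0} = D / (303.35\,V_p)$.

Saturation of the enzyme ($C_1 \gg K_M$) is the scientifically important
nonlinearity: it makes half-lives grow almost linearly with the initial
concentration (slope $\approx 1/(2 V_{max})$ in the fully saturated
regime), which is why a slow endogenous enzyme cannot protect against
high doses, and why a fast hydrolase changes the picture qualitatively.

## Parameters and defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| $V_p$ | effective plasma volume | L | 11.89 |
| $V_b$ | effective brain (striatum) volume | L | 0.3292 |
| $K_{pb}$ | plasma→brain diffusion | min⁻¹ | 0.01898 |
| $K_{bp}$ | brain→plasma diffusion | min⁻¹ | 0.01780 |

`reference_pk_parameters()` returns this calibrated set, obtained by
least-squares fitting of the model to digitized human PET tracer
time courses (plasma and striatum, 0–35 min after a ~11 µg bolus). The
original digitized points are figure-derived and are not shipped;
the fitted values are shipped as reference metadata and every
reproduction in this package recomputes from them. $V_b$ is checked
against the anatomical window 0.00633–1.2538 L (striatum alone up to
whole brain); values outside are flagged, not rejected. The effective
$V_p$ exceeds anatomical plasma volume (~3 L) because cocaine
distributes beyond plasma and brain; it is an effective dilution volume.

The enzyme registry (`reference_enzyme()`) carries the published in
vitro constants of the five cocaine-metabolising enzymes considered
(wtBChE, bacterial cocaine esterase CocE, and the engineered human-BChE
cocaine hydrolases CocH1–CocH3), with two plasma concentrations of
interest: 0.035 µM (physiological wtBChE active-site level) and
0.5 µM (the level achieved by enzyme gene transfer).

## Numerical choices

* **Solver.** `deSolve::ode` with `lsoda` at `rtol = 1e-9`,
  `atol = 1e-12`. High-activity enzymes at high dose are stiff (plasma
  collapses within a minute at 200 µM with CocH3); lsoda switches to a
  BDF method automatically. Tiny negative undershoot is clipped to zero,
  with a warning if it exceeds $10^3\,\mathrm{atol}$.
* **Output grid.** Default spacing `min(0.01, t_end/2000)` min so peak
  refinement and half-life root-finding work on a dense solution.
* **AUC to infinity.** The horizon is extended in doubling chunks until
  the estimated exponential tail of each compartment contributes less
  than $10^{-4}$ of the accumulated trapezoidal integral; the returned
  value adds the tail correction $C(t_{end})/k$ with $k$ the terminal
  log-slope. This makes AUC$_\infty$ grid-independent to about four
  significant figures without a fixed (and dose-dependent) horizon
  choice. A non-decaying system ($V_{max}=0$) raises an error rather
  than extending forever.
* **Peak.** Grid maximum refined by the vertex of the parabola through
  the three bracketing samples; ties break to the earliest time.
* **Half-life.** First post-peak crossing of half the peak value,
  located by inverse linear interpolation on the dense grid. Two
  conventions exist: *absolute* time since injection, and time measured
  *from the peak*. The verbal definition of brain half-life suggests
  absolute time, but the reference lookup-table values are numerically
  consistent only with the from-peak convention (e.g. 27.0 vs 32.1 min
  for wtBChE at 1 µM); both are implemented, from-peak is the default,
  and the reproduction suite reports the selected convention.

## Enzyme-therapy evaluation

`lookup_table()` tabulates brain peak, peak time, brain half-life and
brain AUC$_\infty$ over the enzyme panel and a dose grid
(default 1–200 µM, spanning commonly abused through lethal plasma
concentrations).

`estimate_thresholds()` anchors the threshold of physiological effect to
two human DAT-occupancy calibration doses: 0.32 µM initial plasma
concentration (0.1 mg/kg i.v., perceptible, 47% occupancy) and 0.16 µM
(0.05 mg/kg, imperceptible, 41%). The printed peak plasma concentrations
are treated as $C_{1,0}$ values. Simulating both with endogenous wtBChE
only gives bracketing brain peaks and brain AUCs; the midpoints are the
threshold estimates used downstream, recomputed at run time rather than
hard-coded.

`max_preventable_c0()` finds the largest initial plasma concentration an
enzyme dose keeps sub-threshold in brain. Because published versions of
this quantity are small round numbers, the search brackets on a coarse
integer grid (1 µM steps to 20 µM, 5 µM above), refines the continuous
boundary by bisection to ±0.1 µM, and reports both the refined value and
the largest not-exceeding integer. Whether such results should be
rounded down or to nearest is genuinely ambiguous; we snap down and
expose the refined value so the ambiguity is visible. Boundary cells can
differ by one integer step from other implementations when the brain
peak at the boundary dose sits within ~10⁻⁴ µM of the threshold, which
is the case for CocH3 at 0.5 µM.

## Calibration

`pk_fit()` minimises the unweighted sum of squared residuals over both
compartments jointly (all points equal weight), using
Levenberg–Marquardt (`minpack.lm::nls.lm`) on log-parameters — which
enforces the positivity required for the model to be physically
meaningful — inside a multi-start wrapper (default 25 log-uniform draws
within the bounds; the first start is the geometric midpoint). Bounds
default to the anatomical window for $V_b$ and wide positive boxes
elsewhere. The brain/plasma AUC$_\infty$ ratio at the optimum is
compared with the microdialysis-derived plausibility window 1.02–1.38
and flagged (not rejected) when outside; for this model the long-time
ratio equals $K_{pb}/K_{bp}$ in the linear regime, a property the test
suite checks against closed form.

**Structural identifiability.** The volumes enter the dynamics only
through $V_p/V_b$; $V_p$ is pinned separately by the dose relation
$C_{1,0} = D/(303.35\,V_p)$. Fitting with a known dose and
absolute-units data therefore determines all four parameters, and
`identifiability_probe()` — noise-free data, many random starts,
clustering of the resulting minima — confirms a unique positive-orthant
minimum at the truth for the reference design. With $C_{1,0}$ fixed
instead, or with relative-units tracer data, only $K_{pb}$, $K_{bp}$ and
$V_p/V_b$ are determined; the probe reports the unconstrained directions
rather than failing.

**Practical identifiability.** Scaling $(V_b, K_{pb}, K_{bp})$ by a
common factor $\lambda$ leaves the brain equation exactly invariant and
changes plasma only through the *net* exchange flux, which nearly
vanishes once the compartments equilibrate (a few minutes). Numerically,
$\lambda = 1.2$ changes the noise-free trajectories by only ~0.4% RMS
relative to signal. Consequently, with realistic (≈5%) proportional
observation noise on a 0–35 min schedule, $V_p$ is recovered to a few
percent but the common scale of $(V_b, K_{pb}, K_{bp})$ has order-100%
uncertainty at any dose — the Monte-Carlo recovery study in the test
suite measures exactly this. Two practical consequences: (i) recovery of
all four parameters to better than ~15% requires observation noise well
below 1%, and (ii) predicted brain exposure is nevertheless robust,
because the brain trajectory is invariant along the sloppy direction and
the well-determined quantities ($V_p$, $K_{pb}/K_{bp}$, $V_p/V_b$) are
the ones the exposure metrics depend on.

## Synthetic data

`generate_pk_dataset()` emulates the calibration data type: paired
plasma/brain tracer time courses over 0–35 min (default 36 equally
spaced samples per compartment), optionally rescaled so plasma reads 1
at $t=0$, with seeded observation noise. The default noise model is
multiplicative log-normal with a 5% coefficient of variation — PET count
statistics are roughly proportional-error — parameterised to be
mean-unbiased so the CV equals sigma exactly; additive Gaussian noise is
retained for robustness tests. Negative draws are clipped at zero and
counted. It does **not** simulate radioactive decay correction, scanner
resolution, or metabolite signal contamination, so passing recovery
tests demonstrate estimator correctness under the stated error model,
not robustness to those real-data artefacts. `reference_fixture()` is
the deterministic noise-free instance of the reference truth used to
close the generate→fit loop.

## Problem sizes used by the checks

The test suite and the reproduction script run on sizes chosen to keep
results stable at the asserted tolerances: dense 60-min grids
(dt = 0.01 min, extended automatically for AUC$_\infty$), a dt = 0.001
fixed-step fourth-order Runge–Kutta oracle for solver validation, 20
replicates × 10 starts for the noisy recovery study, and 50 starts for
the identifiability probe.

## Known limitations

* No additional compartments (a cerebellum compartment was deliberately
  excluded from the underlying calibration; differences are absorbed
  into the effective $V_b$), no protein/DAT binding submodels, no
  absorption routes other than i.v. bolus.
* The threshold rests on two calibration doses from a single occupancy
  study; its bracketing interval (not just the midpoint) should be
  carried through any downstream use.
* Relative-units data cannot determine the absolute volume scale
  (see identifiability above).
* Half-life is peak-referenced by default; switch conventions explicitly
  when comparing against sources that measure from injection.
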