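---
title: "A geometric and statistical model of myosin X stepping on actin bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A geometric and statistical model of myosin X stepping on actin bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinstep)
```

## The question

Myosin X transports cargo along the fascin-bundled actin of filopodia,
where it moves roughly twice as fast, and runs more than twice as far,
as on single actin filaments. Its measured step-size distributions are
broad and multimodal: on single filaments a backward population plus a
forward peak near 36 nm; on bundles, additional forward populations near
19, 38–40, 52 and 57 nm. This package implements, as reusable and tested
code, the quantitative ingredients of the explanation: the helical
lattice restricts where a lead head can bind; the dimer's long, partly
compliant lever arms and antiparallel coiled-coil set which of those
sites are mechanically comfortable; and a kinetic gate between the heads,
relieved on bundles, sets the speed.

## The lattice model

F-actin is treated as a helix of binding sites with axial rise
$r = 2.75$ nm and twist $\varphi = -2160/13^\circ \approx -166.154^\circ$
per subunit. The paper-derived quantities we reproduce depend only on
rise and twist, and the exact 13/6 value makes the classical 13-subunit
pseudo-repeat exact: subunit 13 returns to azimuth zero at
$13 r = 35.75$ nm. The commonly quoted $-166.6^\circ$ twist is available
as an alternative; it blurs but does not move the pseudo-repeat.

*Accessibility* is operationalized as a double criterion: the subunit's
axial separation from the rear head must lie in the dimer's reach band,
and its binding-face azimuth must lie within a cone of half-angle
$\tau$ about the motor-facing direction. On the rear head's own filament
the facing direction is the rear head's own azimuth and $\tau = 60^\circ$
by default; toward a bundle neighbour the facing direction is the fixed
inter-filament direction (the neighbour's registry phase, in its own
frame) and $\tau = 30^\circ$, since the lead head must additionally
bridge the inter-filament gap. These two defaults were chosen once, so
that the single-filament accessible set in a 33–57 nm band is exactly
$\{35.75, 41.25, 46.75\}$ nm — matching the observed 36–46 nm
reattachment range — while the 47–57 nm half-turn region is empty. They
are geometric conventions, not fitted quantities; the package exposes
both so users can probe their influence.

The fascin-bundle preset places six hexagonal neighbours at 12 nm axis
spacing. The true subunit-level registry of fascin crosslinked filaments
is not published as numbers, so the preset's registry phases are
calibrated: a quarter-turn class at $90^\circ$ reproduces the 52.25 and
57.75 nm neighbour sites, a $190^\circ$ class contributes 38.5 nm, and
the mirrored $270^\circ$ class (the opposite-side neighbour) contributes
19.25 nm. Two classes alone cannot cover all four observed hot spots —
with phases 90° and 190° the nearest sites to 19 nm are 16.5 and 22 nm —
which is why the preset uses three. With them the accessible-site map
around a bound rear head covers each of the observed ≈19, 38, 52 and
57 nm hot spots to within 0.75 nm.

Distances are reported as axial separations, not 3-D chords, matching
how step sizes are quoted from along-track single-molecule records.

## The dimer model

Each lever arm is a planar two-segment linkage: a stiff converter+3IQ
segment of 9.7 nm and a 10.5 nm single α-helix (SAH), hinged at the
pliant point and at the SAH/coiled-coil junction; the arms are joined by
the antiparallel SAH-CC-SAH coiled-coil of length 24 nm (crystal) or
25.7 nm (relaxed molecular-dynamics average, the default). The 9.7 nm
segment length is calibrated so the per-arm head-to-coiled-coil extent
is 20.2 nm and the flattened span $cc + 2 \times 20.2 = 66.1$ nm matches
the 60–68 nm head-head distances of flattened molecules on EM grids.

Bend limits are not published. They were set once at $110^\circ$ (pliant
point) and $70^\circ$ (SAH junction), which makes the reach envelope
approximately 13.5–66.1 nm: wide enough that the ≈19 nm bundle hot spot
is *just* reachable, at near-maximal bending — consistent with the
observation that 19 nm spacings require strong bending of the region
adjacent to the dimerization domain and are taken less often.

Step preference over a set of candidate separations $d_i$ is modelled as
$w_i \propto \exp(-\beta\, b_i^2)$, where $b_i$ is the minimal total
joint bending (degrees, summed over both joints of both arms, found by a
0.25° grid search over the joint angles under the symmetric-arm
assumption) required to place the heads at $d_i$. The data constrain an
ordering (52–57 nm favoured, 19 nm disfavoured), not a functional form;
the quadratic-exponential form is the simplest smooth choice, and
$\beta = 1.75\times10^{-5}\,\mathrm{deg}^{-2}$ was calibrated once to
give a ≈3:1 weight ratio between the 52 and 19 nm bundle sites:

```{r weights}
w <- preferred_step_weights(dimer_geometry(), c(19.25, 38.5, 52.25, 57.75))
round(rbind(weight = w, bend_deg = attr(w, "bend_deg")), 3)
```

The lever swing is summarized by the chord formula
$d = 2L\sin(\Delta\theta/2)$. The effective lever lengths are obtained by
inverting this formula at the published stroke distances — $L = 21.8$ nm
for the 25 nm / 70° myosin V stroke and $L = 27.7$ nm for the ≈48 nm /
≈120° myosin X stroke — so these two numbers are calibrations that the
code reproduces, not predictions.

## The synthetic-data generator

The generator produces the data the analysis assumes, with known ground
truth, and its defaults are fixed at the study conditions:

* **Step sizes** are drawn from signed Gaussian mixtures whose component
  means and s.d. are the published fit values for each construct/track
  combination (`step_mixture()`), e.g. $-28\pm18$, $17\pm6$, $40\pm9$,
  $57\pm2$ nm for the zippered dimer on bundles ($N = 178$). Component
  *weights* were not published: the defaults use 30% total backward mass
  with the forward mass split equally (two-component sets: 0.3/0.7), and
  equal weights for the four-component bundle set. Tests and acceptance
  quantities therefore target component means and counts, never weights.
* **Traces** are piecewise constant with i.i.d. exponential dwells (rate
  $k$; an Erlang-2 option with the same mean exists for gated-cycle
  dwell shapes), sampled at 50 Hz with 3 nm Gaussian localization noise
  — a typical EM-CCD FIONA regime; neither number is published for the
  original assays and both are stated assumptions here.
* **Run lengths** are $X_0 + \mathrm{Exp}(\lambda)$, the generative
  inverse of the truncated-exponential CDF fit, with per-run velocities
  drawn Gaussian so that length = velocity × duration record by record.
  The published table of $\lambda$ and velocity values per
  construct/track is available as `motility_table()`. The truncation
  point used in the original fits is not printed; $X_0 = 0.4$ µm is this
  package's stated choice.
* **Transients** are sums of decaying exponentials plus Gaussian noise.

Everything is reproducible: each function takes a seed, and the pipeline
derives independent named substreams from one root seed.

What the generator does *not* emulate: tracking artefacts (blinking,
drift, non-Gaussian localization error), load dependence, heterogeneous
motors, and the distinction between centroid and single-head labelling
(steps are generically "observed steps"). Passing tests therefore show
that the analysis recovers truth under the stated statistical model, not
that it is robust to every feature of real movies.

## The analysis pipeline

**Step detection** is a greedy chi-square splitter: starting from one
plateau, repeatedly insert the change point that maximally reduces the
residual sum of squares (minimum dwell 2 frames), then pick the step
count whose *counter-fit* — the same number of steps forced to the
plateau midpoints — is worst relative to the fit (maximal counter-fit /
fit chi-square ratio). On noiseless staircases this recovers the exact
changepoint set; at 3 nm noise and 36 nm steps with ≈20-frame dwells it
detects ≥95% of steps within one frame.

**Mixture fitting** is a hand-rolled univariate Gaussian-mixture EM:
means initialized at data quantiles, uniform weights, pooled s.d.;
10 restarts (later restarts jitter the quantiles); s.d. floor 1 nm
(below the localization noise, preventing spike collapse); convergence
at $10^{-8}$ relative log-likelihood. The log-likelihood is asserted
non-decreasing per iteration, components are reported sorted by mean,
and backward steps are negative-mean components of the same fit. The
component count is selected by 5-fold cross-validation of the mean
held-out log-likelihood per observation, ties resolved toward the
smaller K; folds are reduced with a warning when a fold would hold fewer
points than K. On synthetic data at the published sample sizes the modal
selected K over 25 seeds is 2 for the two-component set ($N = 214$) and
4 for the four-component set ($N = 178$).

**Run lengths** are fitted by least squares between the empirical CDF
(plotting positions $(i - 0.5)/n$, which make the fit exact on exact
exponential quantiles) and $1 - e^{-(X - X_0)/\lambda}$, with bootstrap
standard errors (200 resamples). The estimator agrees with the
closed-form maximum-likelihood value $\overline{X - X_0}$ to within a
few percent and has <1% bias at $n = 10^5$.

**Kinetics.** Transients are fitted by nonlinear least squares
(`minpack.lm`) with log-linear/peeling starts; actin dependence by the
hyperbola $k_{obs} = k_{max}[A]/(K_{1/2} + [A])$. The gate between heads
is modelled at steady state by an alternating-renewal argument: with
gating efficiency $g$ the mean time per head cycle is $(1+g)/k$, so the
per-head rate is $k/(1+g)$ — exactly half the single-headed 19 s⁻¹ at
strict gating, within ~6% of the measured 9.0 s⁻¹ per head. Velocity is
$v = d \cdot k \cdot c$ with coupling $c$ steps per rate-limiting event;
the bundle/filament velocity ratio $34/19 \approx 1.79$ then compares
with the observed ≈2.1×. The coupling needed to reconcile the absolute
velocity (≈0.31 µm/s at ≈36 nm steps implies an effective ≈8.7 s⁻¹
stepping rate, below the 19 s⁻¹ transition) is left as an explicit
parameter rather than resolved.

## Numerical and design choices

* Azimuths are wrapped to $(-180, 180]$ with subunit 0 at zero; the
  accessibility cone comparison includes a $10^{-9}$-degree epsilon so
  exact pseudo-repeat sites survive floating point at zero tolerance.
* Angle grids: 0.25° for bend minimization. The step-finder stops
  inserting steps when the residual drop is below $10^{-10}$ of the
  signal scale, so perfect staircases do not accrete zero-size steps.
* Degenerate EM components (weight below $1/n$, or s.d. at the floor
  with vanishing mass) are flagged and non-degenerate restarts are
  preferred.
* The CLI wrapper is intentionally thin; the package functions are the
  interface of record.
* Problem sizes in the test-suite simulations (25 seeds for recovery
  averages, $10^5$ draws for bias checks, 8–10 seeds for detection
  rates) were chosen as the smallest sizes at which the quoted
  statistical statements are stable.

## Known limitations

The lattice model has no sterics and no 3-D chord geometry; the dimer
model is planar, symmetric and torsion-free; the bundle registry is
calibrated, not measured; mixture component weights are assumptions; and
the kinetic model is a two-state renewal caricature of a multi-state
cycle. Each of these is deliberate: the package reproduces the published
model-level numbers and provides a tested scaffold on which finer
mechanics can be layered.
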