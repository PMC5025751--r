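# actinstep

Target-zone geometry and single-molecule stepping statistics for myosin X
on actin bundles.

Myosin X is the motor that builds and climbs filopodia: a two-headed,
antiparallel-coiled-coil dimer that moves processively along
fascin-bundled F-actin, faster and farther than it does on single
filaments. `actinstep` packages the computational machinery needed to ask
*why* — for structural biologists and single-molecule biophysicists who
want to connect lattice geometry, lever-arm mechanics and kinetics to
measured step-size and run-length distributions.

## What it computes

**Lattice target zones.** F-actin is modelled as a helix with axial rise
`r = 2.75` nm per subunit and twist `φ = −2160/13 ≈ −166.15°` (the exact
13-subunit pseudo-repeat). A subunit `n` is an accessible *target zone*
for the lead head of a bound dimer when its axial separation `n·r` lies
in the dimer's reach band and its binding-face azimuth `wrap(n·φ)` lies
within a cone about the motor-facing direction (default half-angle 60° on
the rear head's own filament, 30° toward a bundle neighbour, whose facing
direction is set by the registry phase). On one filament this yields
sites at 35.75 and 41.25 nm and *none* between 47–57 nm — the half-turn
region faces away. On the hexagonal fascin-bundle preset (12 nm axis
spacing, registry phases 90°/190°/270°) the accessible set covers the
hot spots at ≈19, 38, 52 and 57 nm.

**Dimer mechanics.** Each lever arm is a two-segment planar linkage
(stiff converter+3IQ segment, 9.7 nm; SAH, 10.5 nm) hinged at the pliant
point and at the SAH/coiled-coil junction, joined by the 25.7 nm (relaxed)
or 24 nm (crystal) SAH-CC-SAH coiled-coil. The flattened span is
`cc + 2·(9.7 + 10.5) = 66.1` nm; the lever swing chord is
`2L sin(Δθ/2)` — 25 nm for a 70° swing (myosin V geometry) and ≈48 nm for
the ≈120° myosin X swing. Step preferences over target zones are
`w_i ∝ exp(−β·bend_i²)` with `bend_i` the minimal total joint bending to
reach separation `i`, so flat 52–57 nm spacings beat the heavily bent
≈19 nm one ≈3:1.

**Synthetic single-molecule data.** Signed step sizes from published
Gaussian mixtures (e.g. −28±18 / 17±6 / 40±9 / 57±2 nm for the zippered
dimer on bundles), piecewise-constant traces with exponential or Erlang-2
dwells and Gaussian localization noise, truncated-exponential run lengths
`X0 + Exp(λ)`, and multi-exponential kinetic transients — all with
recorded ground truth and full seed determinism.

**Analysis.** Greedy chi-square step detection with counter-fit model
selection; Gaussian-mixture fits by EM (restarts, quantile
initialization, s.d. floor) with the component count chosen by 5-fold
cross-validated held-out log-likelihood; run-length fits of the empirical
CDF to `1 − exp(−(X − X0)/λ)` with bootstrap standard errors; pooled
velocity statistics; sum-of-exponentials and hyperbolic actin-dependence
kinetic fits; and a gated two-head cycle model in which strict inter-head
gating halves the per-head ATPase (`19 → 9.5 s⁻¹`, cf. the measured
9.0 s⁻¹) and the accelerated rate-limiting step predicts a `34/19 ≈ 1.8×`
bundle speedup (observed ≈2.1×).

## Worked example

```r
library(actinstep)

# Which actin subunits can the lead head reach on its own filament?
accessible_sites_same_filament(helix_params(),
                               accessibility_params(60, 33, 57))
#> Target zones: 3 accessible site(s)
#>  filament_id subunit_index axial_nm azimuth_deg accessible
#>           F0            13    35.75        0.00       TRUE
#>           F0            15    41.25       27.69       TRUE
#>           F0            17    46.75       55.38       TRUE

# End-to-end synthetic pipeline: simulate traces, detect steps, select K
# by cross-validation, fit the mixture and the run lengths.
run_pipeline(demo_config("fl_single", seed = 1))
#> Analysis report 'fl_single' (seed 1)
#>   12 traces, 213 pooled steps; selected K = 2
#>     w=0.35 mean=-23.8 nm sd=17.9 nm
#>     w=0.65 mean=+36.2 nm sd=16.1 nm
#>   run length: mean 0.98 um, lambda 0.57 um (s.e. 0.04, n=283)
#>   velocity: 0.31 +- 0.04 um/s (n=283)
```

The two-component mixture recovers the backward (−26±15 nm) and forward
(36±14 nm) populations the generator drew from, and the run-length fit
recovers the generating λ = 0.60 µm within its bootstrap error. The
`hmm_bundle` demo config selects K = 4 and recovers the 40 and 57 nm
bundle components the same way.

A thin command-line wrapper over these functions is provided at
`inst/scripts/actinstep.R` (subcommands `targets`, `reach`, `simulate`,
`analyze`, `kinetics`, `demo`).

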