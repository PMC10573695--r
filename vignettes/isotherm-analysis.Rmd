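---
title: "Analysing Langmuir monolayer isotherms with langmuir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing Langmuir monolayer isotherms with langmuir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langmuir)
```

## The measurement and its descriptors

A Langmuir trough spreads a known number of amphiphile molecules (lipids,
here azolectin or lecithin as model bacterial membranes) on an aqueous
subphase and compresses the film with movable barriers while a Wilhelmy
sensor records the surface tension. The film's surface pressure is the
tension deficit relative to the clean subphase,

\[ \pi = \gamma_0 - \gamma \quad [\mathrm{mN/m}], \]

and plotting \(\pi\) against the mean molecular area \(A\)
(Å²/molecule) gives the compression isotherm. The package reduces such
traces to the descriptors used throughout the monolayer literature:

* **Lift-off area** \(A_{\mathrm{lift\text{-}off}}\): the largest area at
  which \(\pi\) departs from the zero baseline.
* **Collapse point** \((A_{\mathrm{collapse}}, \pi_{\mathrm{collapse}})\):
  where the film fails, detected as the pressure maximum or as the onset
  of the collapse plateau.
* **Packing ratio** \(\chi = A_{\mathrm{collapse}} / A_{\mathrm{lift\text{-}off}}\).
* **Dynamic-rise slope** \(a_{LE/LC}\): the least-squares slope of
  \(\pi(A)\) in the steeply rising region; smaller magnitude means easier
  molecular rearrangement.
* **Compressibility modulus** \(C_s^{-1}(A) = -A\,d\pi/dA\) and its
  maximum; the maximum diagnoses the phase state (gaseous,
  liquid-expanded, liquid-condensed, solid).
* **Reversibility factor** of a compression–decompression loop,
  \(R_v = 100 \cdot \int \pi\,dA\,(\mathrm{expansion}) / \int \pi\,dA\,(\mathrm{compression})\),
  integrated between the lift-off and collapse areas; 100 % is a fully
  reversible film.

## Wilhelmy wire conversion

For a sensing wire of radius \(r\), length \(l\), density \(\rho_g\),
contact angle \(\theta\) and immersion depth \(h\) in a subphase of
density \(\rho_l\), the net force is taken as

\[ F = \rho_g g \pi r^2 l + 2\gamma\pi r\cos\theta - \rho_l \pi r^2 h , \]

and `tension_from_force()` is its algebraic inverse (the round trip is
exact to better than ten significant digits). The weight and immersion
terms are retained exactly as written here, as the operational
instrument-calibration contract; with the defaults
\(\rho_g = 0, h = 0\) the familiar simplified reading
\(F = 2\gamma\pi r\cos\theta\) remains. \(\gamma_0\) defaults to
72.8 mN/m (water, 25 °C) and is configurable, as are all geometry
parameters — wire length and immersion depth are instrument-specific
inputs, not constants. A blank-compression cleanliness check
(`qc_cleanliness()`, default bound 0.30 mN/m) mirrors standard trough
practice; small negative pressures from baseline drift are retained,
not clamped, unless requested.

## Detection choices and numerical parameters

**Lift-off.** Literal zero-crossing detection is unstable on a noisy
baseline, so the detector requires \(\pi\) to exceed a threshold
(default 0.5 mN/m) for a persistence run (default 5 samples). The
threshold crossing itself is biased below the true lift-off by roughly
threshold/slope — about 1.9 Å²/molecule at the gentle lift-off slopes
of phospholipid films — so by default the initial rise (pressures up to
`max(6 * threshold, 3)` mN/m) is fitted with a quadratic and
extrapolated back to the baseline. This brings the noiseless bias down
to well under 0.1 Å²/molecule and keeps the estimate within
0.5 Å²/molecule at 0.1 mN/m pressure noise. `refine = "crossing"`
returns the raw interpolated crossing instead.

**Collapse.** The default criterion is the global maximum of the
smoothed pressure; a `kink` mode instead locates the plateau onset as
the most negative second derivative, falling back (flagged) to the
pressure maximum when no kink exceeds the curvature threshold. Both are
offered because published isotherms are reduced under either
convention.

**Smoothing and differentiation.** \(-A\,d\pi/dA\) amplifies noise, so
derivatives come from local-polynomial (Savitzky–Golay) fits —
`signal::sgolayfilt` on uniform grids (including proper one-sided end
transients), explicit windowed least-squares fits on irregular grids.
The default window is adaptive: an odd window of about n/32 samples,
clamped to [11, 51]. The rationale is bias–variance: at a realistic
0.1 mN/m pressure noise and 1000 samples per branch, an 11-sample
window leaves a maximum-statistic bias of order +10 % in
\(C_{s,\max}^{-1}\) (the running maximum of a noisy curve), while a
31-sample window keeps the recovered maximum within ±4 % of truth at
the cost of a ~1 Å² blurring of the modulus peak position. Both window
and order are configurable everywhere.

**Slope region.** The "dynamic rise" is not a sharply defined object;
the fit region defaults to pressures between 25 % and 75 % of the
collapse pressure, excluding both the curved lift-off foot and the
collapse plateau, and is configurable.

**Phase bands.** The default threshold table places the boundary
between expanded and condensed liquid at 50 mN/m (gaseous < 12.5,
liquid-expanded < 50, liquid-condensed < 100, condensed < 250, solid
above), with values within ±2 mN/m of 50 additionally flagged as the
LE/LC boundary; the classical Davies–Rideal bands are available as a
preset.

**Integration.** \(R_v\) uses the trapezoid rule on each branch sorted
by increasing area, with interpolated endpoint values at the bounds,
negative pressures clamped to zero for the integration only, and
bounds clipped (flagged) to the area range both branches share.
Per-loop bounds — each loop's own lift-off and collapse — are the
default, matching how per-loop reversibility tables are reported;
fixed caller-supplied bounds are available.

**Cycle splitting.** Direction reversals are detected on the sign of a
running-mean-smoothed area difference with a minimum run length
(default 5 samples), so barrier jitter does not fragment loops.
Trailing or leading unpaired branches are kept and flagged incomplete
rather than dropped.

## The synthetic generator

No public raw traces exist for the systems that motivated this package,
so validation rests on a seeded equation-of-state simulator with
closed-form truth. A compression branch is piecewise:

* \(\pi = 0\) above the lift-off area;
* a Volmer-type liquid-expanded rise
  \(\pi = k_{T,\mathrm{eff}}/(A - A_0) - \pi_{\mathrm{off}}\), anchored
  by \(\pi(A_{\mathrm{lift\text{-}off}}) = 0\) and continuity at the
  LE/LC transition \((A_t, \pi_t)\);
* a linear liquid-condensed branch of slope \(-m_{LC}\) down to the
  collapse pressure \(\pi_c\);
* a flat collapse plateau.

The closed forms are then
\(a_{LE/LC} = -m_{LC}\),
\(C_{s,\max}^{-1} = m_{LC} A_t\) at \((A_t, \pi_t)\),
\(A_{\mathrm{collapse}} = A_t - (\pi_c - \pi_t)/m_{LC}\). Hysteresis
loop \(i\) shifts the branch left by \((i-1)\) times a configurable
step and retraces it on expansion with pressures damped by
\(f_i \in (0,1]\), so \(R_{v,i} = 100 f_i\) exactly.

Defaults emulate a soy-phospholipid film: lift-off 61.6 Å²/molecule,
collapse 45.0 mN/m, \(m_{LC} = 1.79\) mN/(m·Å²) giving
\(C_{s,\max}^{-1} \approx 68.4\) mN/m, loop damping
(0.671, 0.794, 0.824), 1000 samples per branch and 0.1 mN/m Gaussian
pressure noise. The transition pressure \(\pi_t\) defaults to
10.5 mN/m — a realistic LE/LC transition pressure for phospholipids —
deliberately below 25 % of \(\pi_c\), so that the default slope-fit
window samples a single linear regime and the slope truth \(-m_{LC}\)
is recoverable; configurations with \(\pi_t\) inside the fit window
make the fitted "slope" a mixture of the two branches, which is a
property of the descriptor itself, not of the implementation. Noise is
additive i.i.d. Gaussian on pressure only, with an exact area grid,
reflecting that pressure sensing dominates noise in Wilhelmy systems.

What the generator does **not** emulate: drift and autocorrelated
sensor noise, barrier-position noise, evaporation and leakage losses,
film-relaxation kinetics during the plateau, temperature fluctuations,
and genuinely curved LC regions. Tests passing on this family
therefore demonstrate correctness of the numerical reductions under
controlled conditions, not robustness to every instrumental artifact.

## Worked example

```{r example}
params <- synthetic_params(seed = 7)
curve <- generate_isotherm(params)
extract_features(curve)

cycles <- generate_hysteresis(params)
do.call(rbind, lapply(cycles, reversibility_factor))[, c("loop_index", "Rv")]
```

Reference descriptor tables for ten azolectin/lecithin–peptide systems
ship with the package and reproduce exactly under `compute_chi()` and
`classify_phase()`:

```{r reference}
ref <- reference_descriptors()
cbind(ref["system"],
      chi = round_half_up(compute_chi(ref$A_collapse, ref$A_lift_off), 3),
      phase = classify_phase(ref$Cs1_max)$label)
```

## Problem sizes and validation scope

The shipped validation suite runs analytic identities on 500-point
curves, noiseless exactness checks, and a 20-seed recovery study at
1000 samples and 0.1 mN/m noise per isotherm (lift-off within
0.5 Å²/molecule, collapse pressure within 0.3 mN/m, slope within 3 %,
\(C_{s,\max}^{-1}\) within 5 %, \(R_v\) within 0.5 percentage points).
These sizes match one instrument run at a typical 1 Hz sampling and
keep the full suite under half a minute.

## Known limitations

* The collapse area of a plateau-forming film is ambiguous under the
  pressure-maximum criterion (any plateau point has nearly the same
  smoothed pressure); when the collapse *area* matters, use the kink
  mode.
* Reported \(\chi\) values depend on the collapse convention of the
  source; the package computes from the configured mode and does not
  guess the convention behind external tables.
* The Wilhelmy inversion assumes a constant, known contact angle;
  dynamic wetting is out of scope, as are rectangular-plate geometry
  corrections.
* Only delimited-text traces are read; binary vendor formats and
  instrument control are out of scope.
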