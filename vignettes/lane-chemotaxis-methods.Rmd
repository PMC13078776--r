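---
title: "Models and methods: chemotaxis in confined lanes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: chemotaxis in confined lanes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lanetaxis)
```

`lanetaxis` studies a specific phenomenon of *E. coli* motility: on a solid
surface cells swim in chiral circles (radius r ~ 10 µm), and when the surface
is bounded by two sidewalls a few micrometers apart, collisions with the
walls align cells with the wall axis. In an attractant gradient along the
lane this interplay produces strong chemotactic drift that is *maximal at a
lane width of roughly 0.7-0.8 times the circling radius*. The package
implements the three layers of that analysis — an intracellular signaling
model, an agent-based lane simulator, and the trajectory statistics used on
particle-tracking data — plus a closed-form geometric explanation of the
optimum. This vignette documents the models, the tunable parameters, and the
judgment calls made where the problem is genuinely open.

## Signaling pathway

Receptor-kinase activity of a Monod-Wyman-Changeux cluster of `N = 4.6`
receptors with methylation level `m` at attractant concentration `c` (µM):

$$a = \frac{1}{1 + \exp\!\big(N[\alpha(m_0 - m) + L(c)]\big)},
\qquad L(c) = \ln\frac{1 + c/K_{off}}{1 + c/K_{on}},$$

with `K_off = 1.7` µM, `K_on = 12` µM, `α = 1.7`, `m0 = 1`. Methylation
adapts slowly, `dm/dt = k_R(1 - a) - k_B a` with `k_R = 0.005`,
`k_B = 0.010` s⁻¹, so at any steady concentration the activity returns to
`a* = k_R/(k_R + k_B) = 1/3`. Activity maps to CheY-P as `Yp = 7.86 a` µM,
to motor clockwise bias through the steep Hill function
`B = Yp^{10.3}/(Yp^{10.3} + 3.1^{10.3})`, and to the run-to-tumble rate as
`k = B/0.31` s⁻¹. At the fixed point this chain gives `Yp* = 2.62` µM,
`B* ≈ 0.150`, `k* ≈ 0.485` s⁻¹ — a mean run of about 2 s, the measured
near-surface value.

**Sign of the methylation free energy.** The exponent is implemented as
`α(m0 − m)`, so activity increases with methylation. Under the opposite
sign, which occasionally appears in displayed equations, the adaptation
loop is unstable (methylation runs away from any perturbation); every
steady-state number above is identical under both signs, so the stable
convention is the only defensible implementation. The choice is flagged in
the `receptor_activity()` documentation.

**Adapted state in closed form.** Because the activity is logistic in `m`,
`adapted_state()` inverts it analytically instead of root-finding:
`m* = m0 + (L(c) − \ln(1/a^* - 1)/N)/α`, clipped to the configurable
methylation range `[0, 4]` with a warning. Adapted `m*` over the
experimental concentration range (22-30 µM) is 1.85-1.90, far from the
clips. Integration uses explicit Euler at the global step (0.05 s); pathway
timescales (tens of seconds and up) are vastly slower, so no sub-stepping
is needed.

## Lane simulator

Cells are independent self-propelled points in the rectangle
`[0, 160] × [0, w]` µm with concentration `c(x) = 0.05 x + 22` (µM, x in
µm; slope 0 is the control). Per 0.05 s step each cell:

1. **Senses and adapts** (run mode only): one Euler methylation update at
   the local `c(x)`, then switches to tumbling with probability `k·dt`,
   where `k` comes from the pathway chain above.
2. **Tumbles** without translating; the tumble ends at rate 5 s⁻¹ (0.2 s
   mean). At the end a tumble angle is applied: magnitude from a truncated
   exponential on `[0, π]` with characteristic angle `b = 0.25` rad inside
   the 3-µm sidewall bands and `b = 1.35` rad in the middle area (the two
   measured distributions), sign uniform ±.
3. **Runs**: the heading gains the chiral term `+ (v_0/r)\,dt` plus
   rotational diffusion `N(0, 2 D_r dt)` (`v0 = 20` µm/s, `D_r = 0.062`
   rad²/s), then the cell translates at `v0`.
4. **Walls**: crossing a sidewall clamps the cell to it and aligns the
   heading with the wall, preserving the sign of the x-velocity (an exactly
   perpendicular hit goes to +x; the tie has probability zero). While
   aligned, the heading is frozen — no curvature, no rotational diffusion —
   until a tumble; a post-tumble heading pointing into the wall re-aligns
   the cell, otherwise it detaches. A cell aligned longer than
   `wall_max_detention = 7` s is forced to tumble.
5. **x boundary**: cells leaving an end re-enter at the other with a fresh
   uniform y (wall attachment cleared, heading kept), and the stored
   trajectory starts a new track there, as it would in tracking data.

**Chirality convention.** In standard mathematical coordinates the heading
angle *increases* during runs (`chirality = +1`), which is the clockwise
circling seen when imaging through a microscope from above. Under this
convention up-gradient swimmers accumulate on the `y = w` sidewall — the
one the region classification labels RSW — and chemotactic drift is
positive. The `chirality` flag mirrors the lane about its axis; gradient-free
observables are symmetric under the flip (tested).

**Tumble angles by area, not by attachment.** The sidewall tumble-angle
distribution is measured from *tracks in the sidewall bands*, so the
simulator selects the angle model by the cell's current distance to the
nearest wall (`tumble_region_d = 3` µm, the same threshold as the region
classification), not by whether it is attached. The distinction matters: in
lanes narrower than `2 × 3` µm every tumble is a small sidewall
reorientation, direction conversion between up- and down-gradient wall
streams nearly stops, and drift is suppressed — one of the two ingredients
of the optimal-width peak (the other being the dilution of wall streams by
the drift-free circling population as lanes widen). If angles were selected
by attachment state instead, detached cells in narrow lanes would reorient
with the broad middle-area distribution and drift would keep growing as
lanes narrow, with no interior optimum.

**Recycling and pathway memory.** The periodic x boundary moves a cell from
`c = 30` µM to `c = 22` µM instantaneously. Carrying the methylation level
across unchanged would expose the cell to a fictitious 8-µM ligand step;
with adaptation taking tens of seconds, every completed up-gradient
traversal would then be punished by a long burst of elevated tumbling (and
every down-gradient one rewarded), which empirically *inverts* the sign of
the ensemble drift. The simulator therefore shifts the methylation by
`ΔL/α` at the wrap, which keeps the cluster free energy — and hence the
activity and the tumble rate — exactly continuous: the lane behaves as a
periodic window of an extended ramp. The gradient-free control is
unaffected (`ΔL = 0`).

**Detention calibration.** The forced-detachment time is not directly
measurable; it is set to 7 s so that the mean wall-aligned spell,
`E[\min(\mathrm{Exp}(k^*), T)] = (1 - e^{-k^* T})/k^*` at the gradient-free
rate `k* ≈ 0.485` s⁻¹, is about 2 s, the observed wall residence time. The
simulated mean wall residence matches this target (tested to ± 0.3 s).

**Episode statistics under censoring.** Run, tumble, and wall-aligned
spells are right-censored by wall collisions, boundary recycling, and the
end of the simulation; naive averages of completed spells are biased short
(completion selects against long spells). `episode_summary()` therefore
reports the exposure-corrected mean — total time in the state divided by
the number of completed spells — which is the maximum-likelihood mean for
exponential-like spells under independent censoring and recovers `1/k*`
for runs and the capped-exponential mean for wall residence.

**Problem sizes.** The package's study protocol is 100 cells × 150 s ×
50 repeats per condition at dt = 0.05 s; all repeats share one vectorized
state, so a full condition takes a few seconds. The width-radius law uses
20 repeats per grid point over widths `[0.3 r, 1.5 r]` at 1-µm spacing for
radii 5-15 µm — the resolution at which the Gaussian-fitted peak width is
stable — and the test suite uses smaller ensembles where only structure,
not precision, is being checked.

## Trajectory statistics

All statistics consume the same track table (`track_id, frame, time_s,
x_um, y_um`) whether it comes from the simulator or from tracking-software
exports (a TrackMate spots converter is included).

* **Velocity** is the fourth-order central difference (5-point stencil),
  exact for quartic position polynomials; the first/last two frames are
  dropped. Headings are velocity directions; frames slower than 1 µm/s are
  excluded from heading statistics (direction is ill-defined near rest).
* **Drift velocity** regresses the pooled mean displacement
  `⟨x(i+n) − x(i)⟩` on `nΔt` for odd lags 1-39, with an intercept (the
  estimator is insensitive to it at steady state). Tracks contribute to
  every lag they are long enough for, making the estimate robust to early
  track loss.
* **MSOD and rotational exponent**: `⟨(θ(t+τ) − θ(t))²⟩` for `τ < 0.4` s
  with differences wrapped to `(−π, π]`, fitted as `C_R τ^{γ_R}` in log-log
  space. Straight tracks (all MSOD below 1e-12 rad²) return `γ_R = 0` by
  convention; diffusive and circular motion give ≈1 and ≈2.
* **Tumble detection**: a tumble is a maximal run of ≥ 2 consecutive
  below-mean-speed frames that shows a substantial drop — at least one
  successive decrease (including the entry drop) exceeding `⟨v⟩/6`. The
  drop condition is stated ambiguously in the field's descriptions; the
  reading here follows the worked example (a two-frame dip 20,20,3,2,20
  is one tumble) and the plain meaning of "shows a substantial drop from
  the previous time point". Requiring *every* successive decrease to exceed
  the threshold would reject that canonical case.
* **Circle fit**: Savitzky-Golay smoothing (window 5, polynomial order 2 —
  the lowest meaningful order for that window) followed by the algebraic
  Kåsa fit, i.e. least squares on `x² + y² = 2ax + 2by + c` with
  `r = √(c + a² + b²)`. Collinear input raises a degenerate-geometry error.
  For radius distributions, gate tracks with `γ_R > 1.6` as curved.
* **Regions**: tracks are LSW / MA / RSW by mean y with threshold `d = 3`
  µm (≈ one cell body), boundary values to the walls. The RSW up/down split
  uses the sign of the net x displacement; for wall-hugging tracks the mean
  velocity sign gives the same answer.
* **Tumble-angle fits**: either least squares of an 18-bin density
  histogram on `[0, π]` against `a e^{-x/b}` (the form used on binned
  measured distributions) or, preferably, the maximum-likelihood estimate,
  which avoids binning sensitivity.

## First-collision geometry

For a uniformly placed, uniformly oriented cell circling at radius `r` in a
lane of width `w = m r`, `p_up_rsw()` evaluates the probability that its
first sidewall contact is on the RSW moving up-gradient:

$$P(m) = \frac{1}{2\pi m}\Big[-(1-m)\arccos(1-m) + \sqrt{1-(1-m)^2}
 + m\arccos m - \sqrt{1-m^2} + 1\Big], \quad m \le 1,$$

and `P(m) = 1/(π m)` for `m > 1`. The `m ≤ 1` branch is the integral
`\frac{1}{w}\int_0^w (\theta_1+\theta_2)/2\pi\, dy` with
`θ₁ = arccos((r-w+y)/r)`, `θ₂ = arccos(y/r)`; carrying out that integral
gives the closed form exactly as written above (a form easy to mistype —
the square root and the `m arccos m` term are separate summands), and it is
verified independently by continuity and by brute force. Both branches give
`1/π` at `m = 1` (machine-precision continuity is tested), the narrow-lane
limit is `P → 1/4`, and the maximum is `P ≈ 0.3225` at `m* ≈ 0.778` — the
geometric counterpart of the simulated optimum `w ≈ 0.7 r` and of the
fitted width-radius slope. An independent Monte-Carlo oracle
(`mc_first_collision()`) propagates noiseless circles to their first wall
contact in closed form on the circle and agrees with `P(m)` to within
binomial error everywhere, including `m > 2` where some circles touch no
wall (counted as failures). The geometric model deliberately omits
tumbling, sensing, and rotational diffusion; the tumble-modulation
asymmetry that favors the RSW stream over its mirror image is exercised by
the simulator, not here.

## Synthetic fixtures

`make_straight()`, `make_circular()`, `make_run_tumble()`,
`make_drift_ensemble()`, and `make_region_ensemble()` generate 20-fps track
tables with recorded ground truth (speed, radius, drift, tumble log, region
placement) and optional isotropic Gaussian position jitter (0.1 µm is
sub-pixel at the 20×/6.5-µm-pixel optics these data emulate). They exist so
every estimator is tested against known truth without experimental data.
They do not emulate detection dropout, linking errors, or photobleaching —
passing fixtures demonstrates estimator correctness, not robustness to
tracking pathologies.

## Known limitations

* Cells are points: no steric exclusion of the cell body or flagella, so
  very narrow lanes (≲ 6 µm) are idealized; no cell-cell interactions; no
  3-D escape from the surface.
* The chiral circling is imposed as a constant angular velocity, not
  derived from hydrodynamics; wall alignment is instantaneous.
* The x-boundary recycling rule (free-energy continuity) is one defensible
  idealization of an open lane; a fresh-adapted-entrant rule was evaluated
  and yields the same optimal width with smaller drift amplitudes.
* Simulated drift magnitudes at the optimum exceed the measured ones —
  expected for a point-particle model without steric hindrance — while the
  location of the optimum and the width-radius slope are the reproducible
  observables.
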