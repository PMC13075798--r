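---
title: "Methods: the laminar neural mass model and its dynamical analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the laminar neural mass model and its dynamical analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lanmm)
```

## The model

The column couples two canonical circuits.  The deep layer is a
Jansen–Rit loop: pyramidal cells P1 excite spiny stellate cells SS and
slow somatostatin interneurons SST, and receive excitation back from SS
and slow inhibition from SST.  The superficial layer is a PING pair:
pyramidal cells P2 and fast parvalbumin interneurons PV in a reciprocal
loop.  The layers talk through P1→P2, P1→PV and P2→P1 projections, so
the slow deep rhythm can gate the fast superficial one.

Every synapse is a critically damped second-order filter,
$\ddot y + 2a\dot y + a^2 y = A a\,\sigma(v)$, whose impulse response
$h(t) = A a t e^{-at}$ peaks at $A/e$ after $1/a$ seconds and has area
$A/a$.  Three kernels are used (AMPA 3.25 mV/100 s⁻¹, slow GABA
−22 mV/50 s⁻¹, fast GABA −30 mV/220 s⁻¹): inhibitory kernels are larger
and either much slower (SST) or much faster (PV) than excitation, which
is what separates the layers' natural frequencies.  Rates come from
potentials through the logistic $\sigma(v) = 2\varphi_0/(1 +
e^{r(v_0 - v)})$ with $\varphi_0 = 2.5$ s⁻¹, $r = 0.56$ mV⁻¹ and
$v_0 = 6$ mV, except P2 whose threshold of 1 mV makes it far more
excitable — the hinge of the cross-frequency interactions.  Stacking
the five blocks in first-order form gives ten equations; the PV block
is implemented in the same damped form as every other block.

**Input convention.**  The two external drives are *firing rates*
(1/s).  A constant rate $\varphi$ through the AMPA kernel settles at
the potential $(A/a)\varphi$, so the model converts inputs by that
steady gain inside the sigmoid argument: a drive of 200 s⁻¹ enters as
6.5 mV.  All user-facing interfaces use rates; the conversion is
internal.  This convention makes the bifurcation landmarks land on the
published input values (see the acceptance script), which is how it was
validated.

## Numerical integration

Simulations use adaptive lsoda on a C implementation of the vector
field (`rel_tol` 1e−8, `abs_tol` 1e−10), sampled at 1000 s⁻¹ — 25
samples per γ cycle — with a 10 s transient discarded and 50 s
recorded, which gives 0.1 Hz Welch resolution with nine averaged 10 s
Hann segments.  Everything is deterministic: two runs are
bit-identical.  The R-level vector field and analytic Jacobian are
retained and tested against the compiled path; the Jacobian uses
$\sigma'(v) = r\sigma(1 - \sigma/2\varphi_0)$, derived analytically.

The default initial condition is the zero state.  This matters: in
bistable windows the zero state selects one attractor, and experiments
needing a particular branch (hysteresis sweeps, probes near a
subcritical Hopf) should pass an explicit initial state — typically the
final state of the previous run.

## Continuation of equilibria

Branches of fixed points are traced by secant-predictor /
pseudo-arclength Newton-corrector continuation with a *weighted*
arclength: state displacements are weighted 20:1 against the parameter.
The state variables live on a millivolt scale while the parameter spans
hundreds of rate units; with an unweighted norm the S-shaped fold
region is geometrically tiny along the branch, steps overshoot it, and
the corrector silently lands on a different branch.  Two further
safeguards: a corrector solution farther than three step-lengths from
its predictor is rejected (branch-jump guard), and the adaptive step
(initial 0.5, ×1.4 / ÷2 on corrector effort, bounds 1e−4…4) shrinks
into folds.

Folds are flagged where the branch tangent's parameter component
reverses and refined by bisection along the branch.  Hopf points are
flagged *per complex-eigenvalue pair*: the real part of the k-th
ranked pair is tracked separately for every k, because in this model
the γ pair can destabilize while the α pair is already unstable — a
max-real-part test is blind to that crossing.  Refined candidates are
accepted only if the pair lands on the imaginary axis (|Re| < 0.1)
with a genuine frequency (> 0.2 Hz); this rejects the spurious
"crossings" created when two real eigenvalues collide at a fold.
Criticality is decided empirically: simulate just past the point on
the unstable side at offsets δ and δ/4 (δ = 8 rate units, 15 s
settling) and compare saturated amplitudes — supercritical amplitudes
scale like √offset, so the near probe must come out markedly smaller.
A fold is relabeled SNIC when simulation past it finds a
large-amplitude orbit whose period *grows* as the offset shrinks.

Where the upper part of an S-curve is not reachable from below within
the window, detection merges an upward run from the low end with a
downward run seeded at the high end (`equilibrium_bifurcations`).

## Periodic orbits and Floquet analysis

Orbits are found by single shooting: Newton on
$[\phi_T(x_0) - x_0;\ \langle f(x_{\rm ref}), x_0 - x_{\rm ref}\rangle]$
with the monodromy matrix integrated alongside the orbit through the
variational equations (compiled, tolerance 1e−10).  The monodromy's
eigenvalues are the Floquet multipliers; the trivial unit multiplier is
identified as the one closest to 1 and excluded from stability calls.
Single shooting is adequate at this dimension and stiffness; the
Liouville identity $|\det M| = \exp\oint \mathrm{tr}\,J\,dt$ is kept as
a standing consistency test.

Cycle branches are continued in (anchor state, period, parameter) with
the same weighted pseudo-arclength scheme (weights 20 for state, 50
for period); the parameter derivative of the flow is obtained by one
extra orbit integration (forward difference).  This is the only route
to *unstable* cycles — simulation cannot converge to repelling orbits,
and the inner unstable cycle around the torus-bifurcation region is
precisely what makes the bistable α/γ window intelligible.  Detections
along a branch: folds of cycles (FLC) at tangent reversals, located by
a parabolic fit through the three straddling points; torus (TR)
crossings where a genuinely rotating multiplier pair (argument bounded
away from 0 and π, to exclude real-axis collisions) crosses the unit
circle; period doublings where a negative real multiplier crosses −1.
TR and PD are refined by bisection along the branch segment.

## Lyapunov exponents and regime maps

The two largest exponents come from the Benettin procedure: integrate
the flow plus two tangent vectors under the variational equations,
Gram–Schmidt-renormalize every 0.1 s, and average the log stretch
factors.  The per-point default accumulates 200 s after a 20 s state
transient.  Two implementations exist on purpose: a fixed-step RK4 in
C (step 2e−4 s, comfortably inside the stability region of the fastest
220 s⁻¹ kernel) that makes dense maps affordable, and an adaptive
generic R path used for the reference systems; they are tested against
each other on the model itself.

A *tangent warm-up* (default 10 s, renormalized but not accumulated)
precedes accumulation.  Without it the arbitrary initial tangent frame
contaminates the average with an O(1/T) bias of ~0.1–0.2 s⁻¹ — larger
than the 0.05 s⁻¹ tolerance that separates "zero" from "negative"
exponents — and near-periodic cells misclassify.

Classification: chaotic if $\lambda_1 >$ 0.05 s⁻¹, steady if
$\lambda_1 < -0.05$, periodic if only $\lambda_1$ is within tolerance
of zero, quasiperiodic if both are.  Regime maps default to a 48×48
grid with 10 s transient, 15 s warm-up and 30 s accumulation per cell
(~8 minutes on one core); these are the sizes used by the package's
own qualitative map checks, and remaining borderline cells (slow
near-SNIC orbits whose $\lambda_1$ has not fully converged) read as
scattered single-cell "chaos" with small exponents, clearly separated
from the genuine torus-breakdown patches whose exponents are 50×
larger.  The published map resolution (384×384) is available by
passing larger grids.

## Spectra and phase–amplitude coupling

Welch spectra use 10 s Hann segments at 50% overlap on DC-removed
signals, scaled so power integrates to variance.  Dominant frequencies
exclude 12–30 Hz (the model has no material β power; the published
maps omit the band for the same reason) and report "steady" when the
peak is below 1e−6 of total power, so noise-floor argmaxes cannot
label a fixed point as oscillating.  No aperiodic (1/f) correction is
applied: the spectra are line spectra of deterministic dynamics.

Phase and envelope come from a 4th-order Butterworth applied
forward–backward (zero phase) followed by the FFT analytic signal.
Narrow low bands (e.g. δ at 2–4 Hz under a 1000 s⁻¹ rate) are
numerically fragile for transfer-function filters, so the signal is
decimated first until the upper band edge sits at ≥ 1/25 of the
working rate, filtered there, and the unwrapped phase / envelope are
interpolated back.  The modulation index bins phase into 18 bins of
20°, averages the envelope per bin, and normalizes the
Kullback–Leibler divergence of the bin distribution from uniform by
log 18, giving MI ∈ [0, 1], exactly zero for phase-independent
amplitude and exactly one in the single-bin limit; MI is invariant
under positive rescaling of the envelope.  Bin count and filter order
follow the method's original convention; the band definitions are δ
2–4, θ 4–8, α 8–13, γ 30–100 Hz.

## Scenarios

**PV dysfunction.**  `pv_scan` re-derives, for each value of the
PV→P2 contact count C7, the three loci that bound the coexistence of
the slow and fast limit cycles — the SNIC fold, the slow-rhythm Hopf
(eigenfrequency < 20 Hz) and the γ Hopf (> 20 Hz), distinguished by
frequency because the γ locus sweeps *past* the α locus as drive
grows.  The shaded coexistence region is summarized as the fraction of
a 48×48 grid over the input window where the slow-cycle interval and
the region past the γ Hopf overlap; the published figures shade this
region without defining a scalar, and the fraction makes
"enlarges/shrinks" testable.

**Two columns.**  The long-range extension couples two identical
columns: feedforward from the superficial pyramidal of column 1 to
that of column 2, feedback from the deep pyramidal of column 2 onto
the deep pyramidal, superficial pyramidal and SST pool of column 1.
Long-range firing rates enter the target sigmoid arguments scaled by
the steady AMPA gain, exactly as external inputs do, and all four
pyramidal populations share one drive φ.  The canonical long-range
gain constants are not part of the single-column standard set, so the
defaults (g_ff = 50, feedback gains 30) are a documented placeholder
of the same magnitude as the intra-column constants C11–C13 and are
user-overridable; consequently only structural properties are asserted
— exact decoupling at zero gains (bit-exact, tested), agreement of the
decoupled bifurcation values with a single column driven on both
inputs, and multifrequency content in both columns — not numerical
bifurcation positions.

## Synthetic ground truth

Every estimator is validated against generators with known answers,
independent of the model: an amplitude-modulated two-tone family with
closed-form coupling depth for the MI (monotonicity and the d = 0
null); a linear flow, the planar limit-cycle normal form
$\dot r = \kappa r(1 - r^2)$ (λ₁ = 0, λ₂ = −2κ) and an isometric
two-torus flow (both zero) for the Lyapunov estimator; and the direct
kernel convolution as an independent oracle for the second-order
synapse ODE (agreement to 1e−4 mV RMS on band-limited random drive).
All generators are seed-deterministic.

What passing these tests shows — and what it does not: the generators
emulate stationary, noise-free signals with known spectral content.
Real electrophysiology has aperiodic background, nonstationarity and
measurement noise; MI values and dominant frequencies on real data
carry biases (notably from the 1/f background near the α/γ boundary)
that none of these fixtures probe.

## Known limitations

* Hopf criticality and the SNIC label are decided by probe simulation,
  not normal-form coefficients; pathological cases very close to
  codimension-two points could misclassify.
* Two-parameter loci are grids of one-parameter continuations, matching
  the presentation resolution of the underlying diagrams; no
  augmented-system (Moore–Spence) continuation of the loci themselves.
* No continuation of invariant tori; quasiperiodic regimes are
  characterized through simulation, spectra and Lyapunov exponents.
* The two-column supplementary gain constants are placeholders (see
  above); printed two-column bifurcation values are deliberately not
  asserted anywhere.
* Desk-scale regime maps (48×48, 30 s accumulation) leave a small rim
  of borderline λ₁ cells near the SNIC; longer accumulation sharpens
  them at linear cost.
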