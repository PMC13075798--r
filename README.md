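# lanmm — laminar neural mass model analysis

`lanmm` implements and analyzes a five-population *laminar* neural mass
model of a cortical column.  The deep layer is a Jansen–Rit circuit
(pyramidal P1, excitatory spiny stellate SS, slow somatostatin
interneurons SST) that generates slow rhythms (δ/θ/α); the superficial
layer is a PING circuit (pyramidal P2, fast parvalbumin interneurons
PV) that generates γ.  Because the two layers are synaptically coupled,
the column can express *different dominant frequencies in different
layers at the same time* — the substrate of phase–amplitude coupling —
and losing that ability (e.g. when the PV→P2 synapse weakens) is a
candidate mechanism for rhythm disruption in Alzheimer's disease.

The package is for computational neuroscientists who want a tested,
scriptable version of this model and of the complete dynamical-systems
toolbox around it, without external dependencies beyond R.

## Model

Each synapse filters an incoming firing rate through a second-order
kernel `h(t) = A a t e^{-a t}` (AMPA: A = 3.25 mV, a = 100 s⁻¹; slow
GABA: −22 mV, 50 s⁻¹; fast GABA: −30 mV, 220 s⁻¹), equivalent to

    ÿ + 2a ẏ + a² y = A a σ(v),      σ(v) = 2φ₀ / (1 + e^{r(v₀ − v)})

with φ₀ = 2.5 s⁻¹, r = 0.56 mV⁻¹, v₀ = 6 mV (1 mV for P2).  Five such
blocks coupled by the connectivity constants C1…C13 give a
10-dimensional ODE; the observables are the summed postsynaptic
potentials on the two pyramidal populations,
`vP1 = C1 y2 + C2 y3 + C11 y4` and `vP2 = C6 y4 + C7 y5 + C12 y1`.
External input rates φe1, φe2 drive P1 and P2, converted to potentials
by the steady AMPA gain A/a (a rate of 200 s⁻¹ ≡ 6.5 mV).

On top of the model the package provides, all in-package:

* compiled deterministic integration (`simulate_lanmm`, `pulse_response`);
* pseudo-arclength continuation of equilibria with fold/SNIC/Hopf
  detection (`continue_equilibria`, `detect_codim1`, `classify_snic`);
* periodic orbits by single shooting with Floquet multipliers from the
  variational (monodromy) equations, cycle continuation, and
  FLC/torus/period-doubling detection (`find_cycle`, `continue_cycles`,
  `detect_cycle_bifurcations`);
* Welch spectra, dominant-frequency maps, zero-phase band-pass
  filtering, the Tort phase–amplitude modulation index
  (`psd_welch`, `frequency_map`, `pac_mi`);
* two largest Lyapunov exponents (Benettin) with regime classification
  maps (`benettin_les`, `regime_map`);
* the PV-dysfunction scenario (`pv_scan`) and a two-column
  feedforward/feedback coupling extension (`two_column_params`,
  `simulate_two_column`, `two_column_branch`);
* synthetic generators with known ground truth for validating each
  estimator (`synthetic_pac_signal`, `reference_le_system`,
  `convolution_oracle`).

## Worked example

```r
library(lanmm)

## bifurcation skeleton of the deep input at zero superficial drive
br  <- continue_equilibria(lanmm_params(), range = c(0, 600))
detect_codim1(br)
#>         kind    param frequency    diagnostic
#> 1       fold -65.2925        NA  2.259666e+00
#> 2       fold 103.8692        NA  2.356787e-01
#> 3 hopf_super 363.3124  10.82866  3.804749e-09
#> 4 hopf_super 454.6442  40.30102 -1.964445e-09
```

Reading: raising the deep input φe1 destroys the resting state in a
fold at φe1 ≈ 104 (a SNIC — `classify_snic` confirms a large slow cycle
with diverging period is born there), the slow rhythm dies in a
supercritical Hopf at ≈ 363 (10.8 Hz, α), and a small fast cycle
appears at a second Hopf at ≈ 455 (40.3 Hz, γ).

```r
## the standard operating point: alpha deep, gamma superficial
ts <- simulate_lanmm(lanmm_params(phi_e1 = 200, phi_e2 = 90))
dominant_frequency(psd_welch(ts, "vP1"), exclude_band = c(12, 30))
#> [1] 10.1
dominant_frequency(psd_welch(ts, "vP2"), exclude_band = c(12, 30))
#> [1] 39.1

## gamma amplitude locked to the slow phase (Tort modulation index)
ts2 <- remove_dc(simulate_lanmm(lanmm_params(phi_e1 = 110, phi_e2 = 307)))
pac_mi(ts2, phase_band = c(4, 8), amp_band = c(30, 100))$mi
#> [1] 0.05184969
```

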