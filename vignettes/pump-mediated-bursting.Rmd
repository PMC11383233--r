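---
title: "Slow bursting from an electrogenic pump and extracellular potassium: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow bursting from an electrogenic pump and extracellular potassium: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`pumpburst` implements a minimal conductance-based model of a class I
(fast-spiking, interneuron-like) neuron in which the only slow process is
the extracellular potassium concentration, fed by the spike-generating
potassium current and cleared by an electrogenic Na⁺/K⁺-ATPase. The fast
subsystem is the Wang–Buzsáki membrane model with the transient sodium
activation slaved to its voltage steady state, so its state is (V, h, n):

- I_Na = g_Na · h · m∞(V)³ · (V − E_Na), with m∞ = α_m/(α_m + β_m);
- I_K = g_K · n⁴ · (V − E_K), with E_K = 26.71 · ln([K⁺]_out / 140) mV;
- I_L = g_L · (V − E_L);
- dh/dt and dn/dt follow first-order kinetics scaled by a temperature
  factor φ = 5.

The pump current is a sigmoid in extracellular potassium,

  I_P = I_max / (1 + exp((K_half − [K⁺]_out) / 1.1)),   K_half = 11 mM,

saturating at the density-determined ceiling I_max. Because the pump moves
3 Na⁺ out for 2 K⁺ in, it carries net outward charge and appears in the
voltage balance,

  C dV/dt = I_app − I_Na − I_K − I_L − I_P,

and the potassium mass balance closes the loop:

  d[K⁺]_out/dt = (I_K − 2 I_P) · A_cell / (r_v · F · V_cell).

With the cell geometry used here (A_cell = 3.142×10⁻⁶ cm²,
V_cell = 5.23×10⁻¹⁰ cm³, r_v = 0.15) the conversion factor is
4.132×10⁻⁴ mM per ms per μA/cm², which puts the concentration dynamics
three orders of magnitude slower than the spike dynamics — the timescale
separation everything below relies on. An extended variant promotes
intracellular sodium to a state variable (E_Na from its Nernst relation, a
second sigmoid on the pump); an electroneutral control removes I_P from the
voltage equation only, leaving the potassium balance untouched.

### A note on the pump midpoint

The pump sigmoid is implemented with its half-activation at
K_half = 11 mM. Printed renderings of the pump equation are ambiguous
between a midpoint of 10 and 11 mM; the accompanying description of the
activation curve states 11 mM, and only that reading reproduces the
quantitative anchors checked in the test suite (the 11-spike burst at
I_app = 0.5, I_max = 1 μA/cm²; the 11→12 spike-adding transition near
I_max ≈ 0.9945; the placement of tonic, bursting and depolarization-block
regimes). With a 10 mM midpoint the same drive settles into slow tonic
firing instead. Users who want the other convention can set `K_half`
explicitly in `wb_params()`.

## What the package computes

```{r}
library(pumpburst)
p <- wb_params(I_app = 0.5, I_max = 1)

sim <- simulate_neuron(p)        # 12 s, RK4 dt = 0.005 ms, 2 s discarded
sim$regime                       # "bursting"
glance(sim)                      # spikes/burst, cycle period, K range

hys <- assemble_hysteresis(p)    # slow-fast reduction
predict_complete_dynamics(hys)   # "bursting"
autoplot(hys)
```

The analysis layers mirror the slow–fast dissection:

1. **Simulation** (`integrate_system()`, `simulate_neuron()`): fixed-step
   classical RK4 at dt = 0.005 ms (a step small enough that halving it
   moves spike times by well under 0.1 ms, which the tests check against a
   dt-halved run and against an independent integrator). Spikes are upward
   0 mV crossings, linearly interpolated, with a 2 ms refractory gap —
   spikes of this model overshoot 0 mV robustly, so the threshold is not
   delicate. Regimes are classified from the inter-spike-interval (ISI)
   distribution: a two-class split of log-ISIs at their largest gap calls a
   train bimodal (bursting) when the intervals across the gap differ by
   more than 3-fold and both classes have at least two members; silent
   tails classify as rest (V below −60 mV) or depolarization block (V above
   −50 mV), and anything unsettled is reported `undetermined` rather than
   guessed.
2. **Fast-subsystem bifurcations** (`find_equilibria()`,
   `continue_equilibria()`, `find_limit_cycle()`,
   `continue_limit_cycles()`): with [K⁺]_out frozen as a parameter, the
   equilibria reduce to a scalar current balance in V, continued in the
   (V, K) plane by pseudo-arclength with fold (saddle-node, SN) and Hopf
   detection; the spiking limit cycle is found by Newton on the Poincaré
   return map (section V = −20 mV, upward) and continued in K with Floquet
   multipliers from the variational equations. The branch ends either in a
   homoclinic (HOM) — period diverging along the logarithmic law
   τ ≈ a − b·ln(K_hom − K), with K_hom extrapolated from that fit — or in
   a fold of limit cycles (FLC), the nontrivial multiplier approaching +1.
   Because the divergence constant b is of order 20 ms, periods beyond
   ~600 ms are unreachable in double precision near the HOM, so the
   HOM/FLC verdict is not taken from the period alone: once continuation
   steps underflow, the flow is probed just past the branch end and
   classified by where it settles (rest node → HOM, depolarized upstate →
   FLC). A HOM whose terminating point coincides with the SN fold (within
   5×10⁻³ mM) is a SNIC. Two organizing points bound the bursting wedge in
   drive: the saddle-node loop (SNL), located by bisection on the
   SNIC-vs-HOM classification, and the fold of the HOM curve (the point
   beyond which an upward potassium sweep meets the FLC instead), located
   by bisection on that termination type. The latter is the operational
   reading of the "HOM inflection": it is the maximal drive the HOM curve
   reaches, which is what matters for whether a vertical sweep can cross
   it.
3. **Slow reduction** (`averaged_kout_derivative()`,
   `resting_kout_derivative()`, `assemble_hysteresis()`,
   `predict_complete_dynamics()`): on the spiking branch the potassium
   balance is averaged over one period of the frozen-K limit cycle
   (trapezoidal quadrature over at least ~2000 samples per period); on the
   resting branches it is evaluated at the fixed point. A well-formed
   bursting diagram has the spiking branch positive up to the HOM and the
   rest branch negative back down to the SN — the hysteresis loop. A
   stable zero of the spiking-branch average (negative slope) parks the
   slow variable there: tonic firing. The prediction rule is: stable valid
   fixed point on the spiking branch → tonic; SNIC termination → tonic (no
   bistable overlap, the loop cannot close); HOM termination with a
   negative rest branch → bursting; FLC termination → depolarization
   block; no spiking branch → rest.
4. **Regime maps** (`scan_regimes()`, `amplitude_curves()`,
   `refine_regime_boundary()`): one deterministic classified simulation per
   (I_max, I_app) cell, plus potassium-amplitude sweeps along I_max.

## Averaging validity and the breakdown margin

Averaging assumes the fast period is far shorter than the slow drift — an
assumption that must fail close to the HOM/SNIC, where the period diverges.
Spiking-branch samples are therefore flagged invalid when their period
exceeds 500 ms or they lie within 2×10⁻³ mM of the extrapolated homoclinic.
The margin deserves a comment, because the obvious choice of a generous
margin (say 0.05 mM) is wrong at both ends here: the bistable windows of
this model are only 0.2–0.3 mM wide, and the genuine tonic balance point at
strong pumping (I_max = 2, I_app = 1) sits ~6×10⁻³ mM below the HOM — a
wide margin would erase it — while the spurious sign change that averaging
produces as the mean current collapses onto the saddle value appears within
~10⁻⁴ mM of the HOM. Physically, the complete system gains several
hundredths of a mM of potassium per spiking cycle mid-burst, so it cannot
resolve (or park in) structure thinner than that; 2×10⁻³ mM cleanly
separates the two cases and is an order of magnitude above the continuation
resolution at the branch end. Sign structure inside the margin is reported
(`valid = FALSE`) but does not enter the regime prediction.

## Study conditions and problem sizes

The canonical protocol — and the default of `simulate_neuron()` — is 12 s
of simulated time with the first 2 s discarded, at dt = 0.005 ms, from
V = −65 mV, gates at steady state, [K⁺]_out = 4.8 mM (E_K ≈ −90 mV, the
classic resting value for this neuron class) and, when dynamic,
[Na⁺]_in = 18.4 mM (E_Na = 55 mV). Initial conditions are not printed in
the source material; these give roughly ten burst cycles after transients
under the canonical drive, enough for the interior-burst statistics the
summaries report (truncated first and last bursts are excluded).
Continuations use an initial K step of 0.05–0.1 mM (0.08 for hysteresis
assembly), Newton tolerance 10⁻⁸ on the return-map residual, equilibrium
residuals below 10⁻¹², and the spike-adding bisection runs to 10⁻⁴ μA/cm²
— the scale at which an 11-digit printed transition value can honestly be
matched by a fixed-step method.

## What the defaults do and do not show

Everything in the package is deterministic: identical configurations give
bit-identical trajectories, and the test suite asserts as much. The model
itself is intentionally minimal. There is no glial buffering, diffusion,
oxygen or volume dynamics, no chloride or calcium, and the intracellular
potassium and (in the base model) sodium pools are treated as
inexhaustible reservoirs. Consequences worth keeping in mind: the
depolarization-block branch lets [K⁺]_out climb to physiologically absurd
values because nothing clears it; the sodium-extended variant shows a slow
drift of [Na⁺]_in over long runs; and the regime boundaries are those of an
isolated cell in a sealed extracellular pocket. Passing tests certify the
mathematics of the mechanism — the sheared SN/HOM structure, the hysteresis
loop, the regime placements — not the quantitative behaviour of tissue.

Two further caveats. The ISI-bimodality criterion is a pragmatic
classifier; near regime boundaries (period-doubling cascades, chaotic
windows) the modal spikes-per-burst can alternate, which is why summaries
carry the full per-burst counts and a period-doubled flag rather than a
single number. And near-homoclinic Floquet multipliers are intrinsically
ill-conditioned; the package reports them but uses the settling probe, not
the multipliers, to classify branch ends.
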