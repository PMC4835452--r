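---
title: "Modelling transcranial magneto-acoustical stimulation of a Hodgkin-Huxley neuron"
author: "tmas package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transcranial magneto-acoustical stimulation of a Hodgkin-Huxley neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmas)
```

## The physical model

Transcranial magneto-acoustical stimulation (TMAS) combines a focused
ultrasound beam with a static magnetic field. The acoustic wave makes
tissue ions oscillate along the propagation axis with particle speed
amplitude $w$; in a perpendicular magnetostatic field $B_x$ the Lorentz
force separates positive and negative charge carriers, producing an
electric current density perpendicular to both. For a plane wave of
intensity $\Gamma$ in tissue of density $\rho$, sound speed $c_0$, and
electrical conductivity $\sigma$:

$$ w = \sqrt{\frac{2\Gamma}{\rho c_0}}, \qquad
   P = \rho c_0 w, \qquad
   J_0 = \sigma B_x w , $$

so the current-density amplitude scales linearly with $B_x$ and with
$\sqrt{\Gamma}$. At the exact level the acousto-electric coupling carries a
phase angle $\psi$ with $\tan\psi = \omega\tau$, where $\tau$ is an ionic
relaxation time on the order of femtoseconds; at the 200–700 kHz
frequencies of ultrasonic neurostimulation $\omega\tau \sim 10^{-9}$, so
the phase term is dropped throughout. Default tissue constants are
$\sigma = 0.5$ S/m, $\rho = 1120$ kg/m³, $c_0 = 1540$ m/s
(`tissue_constants()`).

Units: users supply $\Gamma$ in W/cm² and receive current densities in
μA/cm² (the native unit of the membrane model); all internal acoustics are
SI. Each conversion (`1 W/cm² = 10⁴ W/m²`, `1 A/m² = 100 μA/cm²`) is a
single named constant applied in exactly one place, because unit slips in
this chain rescale every downstream firing statistic.

### Carrier waveform

A zero-mean carrier $J_0\sin(2\pi f t)$ at hundreds of kHz is three orders
of magnitude faster than the membrane time constant: the membrane averages
it to zero and no sodium current develops. The physiologically effective
drive is the *offset sine*

$$ J(t) = J_0\,[\sin(2\pi f t) + 1], $$

which is non-negative with time average $J_0$. The package keeps pure
`"sine"` and `"cosine"` carriers selectable so the contrast is
demonstrable (`compare_carrier_waveforms()`): at $\Gamma = 3$ W/cm²,
$B = 3$ T, $f = 500$ kHz the sine carrier produces zero spikes and a peak
sodium current three orders of magnitude smaller than the offset carrier,
which fires periodically.

### Pulsed ultrasound

Pulsed mode multiplies the full offset-sine carrier (including its offset)
by a square-wave gate with repetition frequency RF and duty cycle DC. The
gate is 1 on $((n-1)/\mathrm{RF},\, (n-1+\mathrm{DC})/\mathrm{RF}]$ for
$n = 1, 2, \dots$ — open on the left, closed on the right, hence 0 at
$t = 0$. The choice of boundary convention is measure-zero physically, but
fixing it makes every run bit-reproducible.

## The membrane model

The neuron is the classical four-variable Hodgkin–Huxley model in the
shifted voltage frame (resting potential at 0 mV; the absolute frame is
offset by about 65 mV):

$$ C_m \frac{dV}{dt} = I_{ext}
   - \bar g_{Na} m^3 h (V - V_{Na})
   - \bar g_{K} n^4 (V - V_{K})
   - g_L (V - V_L), $$

with each gate following
$dx/dt = \phi\,[\alpha_x(V)(1-x) - \beta_x(V)x]$ and
$\phi = 3^{(T-6.3)/10}$. Defaults (`hh_params()`): $C_m = 1$ μF/cm²,
$\bar g_{Na} = 120$, $\bar g_K = 36$, $g_L = 0.3$ mS/cm², $V_{Na} = 115$,
$V_K = -12$, $V_L = 10.59$ mV, $T = 6.3\,°$C (so $\phi = 1$). All rate
constants are written in this frame; converting the frame would falsify
every constant, so the shifted frame is used everywhere, including in
outputs.

Two rate functions, $\alpha_m$ at $V = 25$ mV and $\alpha_n$ at
$V = 10$ mV, are 0/0 expressions with removable singularities. Within
$10^{-7}$ mV of those points the analytic limits (1.0 and 0.1 ms⁻¹) are
substituted; IEEE cancellation in the raw expression is catastrophic well
before the limit point, and the limit is exact.

The default initial state is the resting state $(V, m, h, n) =
(0, 0.053, 0.596, 0.317)$, which equals the steady-state gating values at
$V = 0$ to the precision shown (`steady_state_gating(0)` gives 0.0529,
0.5961, 0.3177; the third value is conventionally quoted truncated).

## Integration

`simulate_hh()` uses classical fixed-step fourth-order Runge–Kutta,
compiled. Fixed step rather than adaptive: the carrier imposes a hard
resolution floor anyway, and a fixed step makes every run deterministic —
identical inputs give bit-identical trajectories, which the test suite
asserts at the byte level on written CSVs. Specifics:

* The drive is evaluated **analytically** at the substep times $t$,
  $t + dt/2$, $t + dt$, never sampled-and-held, so the carrier is not
  aliased.
* Default $dt = 5\times10^{-5}$ ms = 40 steps per 500 kHz period; the
  integrator refuses any oscillatory run with fewer than 20 steps per
  period. Constant-current runs have no carrier and use $dt = 10^{-3}$ ms.
* Gating variables are clamped to $[0,1]$ after each step. Analytically
  the gating ODE cannot cross those bounds; the clamp only removes
  round-off overshoot (observed $<10^{-9}$).
* Recording keeps at most $10^6$ samples by striding; the stride is
  explicit in the result for convergence comparisons.
* Convergence was verified on the constant-current case: halving $dt$
  reduces the maximum trace difference by a factor ≈16, the RK4 order.

## The firing threshold

For constant drive the model has a subcritical Hopf bifurcation: the
current-adapted equilibrium loses stability near 9.78 μA/cm², and between
roughly 6.26 and 9.78 μA/cm² a stable limit cycle coexists with the stable
fixed point. Consequently there are two distinct "thresholds", and
`find_firing_threshold()` exposes both:

* `method = "stability"` (default) bisects on the sign of the leading
  eigenvalue of the Jacobian at the equilibrium (`hh_equilibrium()`), the
  Hopf point itself (≈9.78 μA/cm²). Near a subcritical Hopf no
  finite-length simulation can make this classification — the growth rate
  and the fixed point's basin both shrink to zero at the bifurcation — so
  the eigenvalue criterion is applied directly. Each classification is a
  root solve plus a 4×4 eigenvalue problem; the bisection is exact
  arithmetic on a deterministic pipeline and bit-reproducible.
* `method = "simulation"` classifies each level by simulating 500 ms from
  the resting state and requiring ≥10 spikes in the 200–500 ms window (a
  definition chosen to reject single onset spikes). Because a current step
  from rest captures onto the coexisting limit cycle, this measures the
  hard-excitation onset at the saddle-node of periodic orbits, ≈6.26
  μA/cm², not the Hopf point. It is retained because it is the
  operationally observable threshold for step stimuli.

## Firing-pattern statistics

`detect_spikes()` defines a spike as a local maximum above 50 mV with ≥2 ms
between accepted peaks (earlier peak wins; flat tops resolve to their
earliest sample). Full-height spikes in this model peak near 90–100 mV, so
50 mV separates them cleanly from subthreshold ripple; near depolarization
block the action-potential amplitude collapses continuously, and
oscillations below 50 mV are deliberately not counted as spikes. Both
settings are arguments.

* **AMP** — mean peak voltage of spikes after a 100 ms transient cutoff
  (the steady-state regime; onset spikes would bias the mean). Undefined
  (`NA`), never zero, when nothing survives the cutoff.
* **ISI** — mean of consecutive spike-time differences, excluding gaps
  longer than a burst-split threshold so silent inter-burst periods of a
  pulsed drive are not averaged in. The default split is half the gate
  off-period, $(1-\mathrm{DC})/(2\,\mathrm{RF})$; for continuous drives
  every gap is kept. At high DC the off-period shrinks below the
  within-burst ISI and the statistic is reported as `NA` rather than
  inventing a burst segmentation.
* **FR** — spikes per complete repetition period of the pulsed gate,
  averaged after skipping the first cycle.

## Sweep experiments

`tmas_preset()` encodes the six standard single-parameter experiments
around the operating point $\Gamma = 3$ W/cm², $B = 3$ T, $f = 500$ kHz
(pulsed: DC = 50%, RF = 10 Hz): magnetostatic field 0.5–7 T, continuous
intensity 1–100 W/cm², carrier frequency 200–700 kHz, pulsed intensity,
duty cycle 5–95%, and repetition frequency 1–100 Hz. Smoke grids (3–5
points, the default) keep a full suite inside a couple of minutes at the
default step; `smoke = FALSE` gives the full grids (14 field values, 19
duty cycles, …). Continuous sweeps run 500 ms; pulsed sweeps run at least
three repetition periods so slow gates are represented. Every summary row
is re-derivable by an independent `simulate_hh()` +
`summarize_firing()` call with identical numbers.

Behaviour worth knowing when reading sweep tables:

* At $B \le 1$ T (with $\Gamma = 3$) the mean drive is below the
  hard-excitation onset; only onset spikes occur and steady-state AMP/ISI
  are `NA`.
* At continuous $\Gamma \gtrsim 40$ W/cm² ($B = 3$ T) the mean drive
  exceeds ~100 μA/cm² and the model approaches depolarization block:
  sustained oscillations persist but peak below the 50 mV spike criterion,
  so spike-based statistics report `NA` (continuous) or count only
  burst-onset spikes (pulsed). This is the model's genuine response to the
  faithful intensity-to-current scaling, not a detection artefact.
* FR grows with duty cycle (more gate-on time per cycle yields more spikes
  per cycle) and falls with repetition frequency (shorter cycles contain
  fewer spikes); both follow directly from FR's per-cycle definition.

## Safety indices

The mechanical and thermal indices of diagnostic ultrasound are provided
as first-class operations: $\mathrm{MI} = p_{r.3}/(\sqrt{f}\,C_{MI})$ with
$C_{MI} = 1$ MPa·MHz^1/2^, and (unscanned soft-tissue mode)
$\mathrm{TI} = W f / C_{TIS}$ with $C_{TIS} = 210$ mW·MHz.
`acoustic_power()` converts a focal-spot diameter and intensity into the
output power $W$. The attenuated peak-rarefactional pressure $p_{r.3}$ is
a *user input*: the package models no propagation, attenuation/derating,
or skull, so $p_{r.3}$ must come from measurement or an external derating
convention. Both indices are below 1 — the accepted no-injury line — at
the reference operating point (3 W/cm², 0.5 MHz, 3 mm spot, $p_{r.3}$ =
0.2275 MPa).

## What the model does and does not capture

The simulated neuron is a single isolated squid-axon-parameter point
membrane at 6.3 °C. Passing tests therefore demonstrate internal
correctness of the forcing → membrane → metrics pipeline, not fidelity to
mammalian cortical tissue: there is no channel noise, no morphology, no
network, no temperature adaptation of conductances, no intramembrane
cavitation mechanism, and no acoustic field modelling (the beam is a
uniform plane wave at the neuron). The intensity-to-current conversion is
the idealised Lorentz-force expression; *in vivo* the effective coupling
depends on local conductivity anisotropy and beam geometry, so absolute
intensities at which regime changes occur (onset, block) should be read as
model statements, not dosimetry.
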