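---
title: "Adaptive exponential time differencing for pulse-coupled Hodgkin-Huxley networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive exponential time differencing for pulse-coupled Hodgkin-Huxley networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etdhh)
```

## The model

Each neuron $i$ of the network obeys the Hodgkin-Huxley equations

$$C \frac{dV_i}{dt} = -(V_i - V_{Na})\,G_{Na} m_i^3 h_i
                      -(V_i - V_K)\,G_K n_i^4
                      -(V_i - V_L)\,G_L + I^{\mathrm{input}}_i,$$
$$\frac{dz_i}{dt} = (1 - z_i)\,\alpha_z(V_i) - z_i\,\beta_z(V_i),
  \qquad z = m, h, n,$$

with the classical squid-axon constants ($C = 1\,\mu F\,cm^{-2}$,
$V_{Na} = 50$, $V_K = -77$, $V_L = -54.387$ mV, $G_{Na} = 120$, $G_K = 36$,
$G_L = 0.3$ mS cm$^{-2}$) exposed as the `"HH"` set of `neuron_params()`.
The synaptic input is conductance-based,

$$I^{\mathrm{input}}_i = -G^E_i(t)\,(V_i - V_{G^E}) - G^I_i(t)\,(V_i - V_{G^I}),
  \qquad V_{G^E} = 0,\; V_{G^I} = -80 \text{ mV},$$

and each conductance follows the double-exponential (alpha-like) kernel: an
auxiliary rise variable $H$ is kicked by Dirac-delta spike events and the
pair $(G, H)$ relaxes with fast rise $\sigma_r$ and slow decay $\sigma_d$
($\sigma^E_r = 0.5$, $\sigma^E_d = 3$, $\sigma^I_r = 0.5$, $\sigma^I_d = 7$
ms). Events are of two kinds: feedforward Poisson input (strength $f$ on the
excitatory receptor, rate $\nu$ per neuron) and recurrent pulse coupling
(weight $S/N$ per edge, routed to the excitatory or inhibitory receptor by
the presynaptic neuron's type). A neuron spikes when $V$ crosses
$V^{th} = -50$ mV from below.

A reduced Traub-Miles (`"RTM"`) variant is included: its sodium activation
is instantaneous, $m = \alpha_m(V) / (\alpha_m(V) + \beta_m(V))$, so the
state reduces to $(V, h, n)$; its threshold is $0$ mV and its constants
($V_K = -100$, $V_L = -67$ mV, $G_{Na} = 100$, $G_K = 80$, $G_L = 0.1$
mS cm$^{-2}$) are the `"RTM"` set.

All rate functions share the form $y / (1 - e^{-y})$ near their removable
singularities (HH: $V = -40, -55$; RTM: $V = -54, -27, -52$ mV). These are
evaluated by a guarded 3-term series when $|y| < 10^{-6}$ and by
`expm1` otherwise, so grid-aligned voltages never hit $0/0$ and the
crossover is continuous to near machine precision.

## Event handling: detection, interpolation, recalibration

Synaptic spike times cannot be known in advance — they are determined by the
trajectories being computed. Every step $[t_k, t_{k+1}]$ therefore proceeds
in four stages:

1. **Spike-free advance.** Each neuron's $(V, m, h, n)$ is advanced by its
   scheme using the *spike-free* conductances, which are known in closed
   form: `decay_step()` is the exact solution of the linear $(G, H)$ system,
   so the stage values at $t_k$ and $t_{k+1}$ cost two table lookups.
2. **Detection.** An upward crossing $V_k < V^{th} \le V_{k+1}$ yields the
   linearly interpolated spike time
   $\tau = t_k + \Delta t\,(V^{th} - V_k)/(V_{k+1} - V_k)$, which carries an
   $O(\Delta t^2)$ error — consistent with the overall order.
3. **Recalibration.** Each spike at time $u$ (feedforward or recurrent) adds
   $w\,e^{-(t_{k+1}-u)/\sigma_d}$ to $H$ and $w\,\mathcal{G}(t_{k+1}-u)$ to
   $G$ of its receptor type, where $\mathcal{G}$ is the kernel. Because the
   synapse dynamics are linear, this superposition is exact; skipping the
   interpolation and assigning spikes to the step end (the `naive-rk2`
   method) degrades the conductance — and hence the whole solution — to
   first order.
4. **Stiff tracking.** Each spiker's stiff period is set to
   $[\tau, \tau + 3.5\,\mathrm{ms}]$.

The neuron states are *not* re-integrated after recalibration; the corrected
conductances act from the next step on. Detection is gated by the same
per-neuron window (no neuron is eligible while $t_k$ precedes its
`stiff_until`), which suppresses double detection on the descending flank of
the action potential; the window is far shorter than any physiological
inter-spike interval at these firing rates.

## The integrators

`rk2` is Heun's explicit trapezoid. `etd2` is the two-stage exponential
integrator ETD2RK: per step and per variable $z$ a linear rate is frozen
from the step-start state,

$$c_V = \frac{-G_{Na} m_k^3 h_k - G_K n_k^4 - G_L}{C}, \qquad
  c_z = -\bigl(\alpha_z(V_k) + \beta_z(V_k)\bigr),$$

the remainder $F_z = f_z - c_z z$ is what is quadratured:

$$a_z = z_k e^{c_z \Delta t} + F_z(t_k)\,\Delta t\,\varphi_1(c_z \Delta t),
\qquad
z_{k+1} = a_z + \bigl[F_z(t_{k+1}, a) - F_z(t_k)\bigr]\,
          \Delta t\,\varphi_2(c_z \Delta t),$$

with $\varphi_1(x) = (e^x - 1)/x$ and $\varphi_2(x) = (e^x - 1 - x)/x^2$.
Setting $c = 0$ recovers Heun exactly — this is why Heun was chosen as the
RK2 flavor: the two branches of the adaptive method are limits of one
formula, and that reduction is tested directly.

`aetd2` switches per neuron and per step: ETD2RK while the neuron is inside
its stiff period, Heun otherwise. The rationale is that outside the spike
the frozen linear and nonlinear parts are individually large but nearly
cancel, so the ETD2 decomposition manufactures stiffness where the flow has
none and loses accuracy at large steps; inside the spike the exponential
propagation of the genuinely stiff linear part is what lets the step stay
large. For the RTM model the upstroke (~0.03 ms) is much faster than the
threshold crossing itself, so a fixed post-spike window anchored at the
crossing would leave the upstroke to the RK2 branch; the stiff region is
instead entered whenever $|dV/dt| \ge 20$ mV/ms, with any step overlapping a
detected spike's 3.5 ms window kept stiff so the criterion cannot chatter at
the two crossings of the threshold.

### Numerical details

* $\varphi_1, \varphi_2$ switch to a 6-term Taylor series for
  $|x| < 10^{-4}$; the direct branch uses `expm1`, keeping the relative
  discontinuity at the crossover below $10^{-10}$.
* The step containing a spike is not recomputed; the ETD2 branch applies
  from the next step whose start precedes `stiff_until`.
* Feedforward events in the half-open interval $(t_k, t_{k+1}]$ belong to
  that step, matching the recalibration sums.
* Non-finite voltages abort with a diagnostic naming the method and step
  size rather than being clamped: plain ETD2 at large steps may *lose
  spikes* but must stay finite, and RK2 at large steps genuinely diverges.
* A run covers $\lceil T/\Delta t \rceil$ full steps; rates are normalized
  by the actual simulated time.

## The synthetic input and what it does (not) emulate

All inputs are synthesized: there are no external datasets. The feedforward
drive is an independent homogeneous Poisson process per neuron with exact
(off-grid) event times; the defaults (`f = 0.06` mS cm$^{-2}$,
$\nu = 300$ Hz, $S = 0.2$ mS cm$^{-2}$, 80 excitatory / 20 inhibitory
neurons, all-to-all with per-edge weight $S/N$) are the study conditions
under which the accuracy results are quoted. One master seed expands into
independent substreams for the trains, the initial-condition jitter and the
random topology, so changing one consumer does not shift another's draws,
and a pre-drawn train can be shared across runs so that method comparisons
see the same realization.

The generator emulates stationary, uncorrelated drive only: no rate
modulation, no input correlations across neurons, no synaptic delays or
plasticity. Passing tests therefore demonstrate the *numerical* claims —
convergence order, stability, firing-rate accuracy at large steps — for
this class of stationary asynchronous network states, not fidelity to any
particular biological recording.

Initial conditions (not part of the published protocol, so chosen here once)
are $V(0) = -65$ mV with gates at steady state and zero conductances; a
seeded uniform jitter on $V(0)$ is available but off by default, since the
independent Poisson drives desynchronize the population within a few tens of
milliseconds. Firing rates are computed over the full run without a
transient discard; at $T = 10$ s the transient contributes well under the
seed-to-seed variability.

## Design choices that were genuinely open

* **All-to-all includes the self-edge** with weight $S/N$ (the literal
  reading of the coupling definition); `include_self = FALSE` removes it.
  At $S/N = 0.002$ mS cm$^{-2}$ the difference is far below seed noise.
* **Error norms.** The final-time voltage error and last-spike-time error
  are reported as Euclidean norms across neurons (the root of the
  sum-of-squares form); the root convention makes the fitted log-log slopes
  line up with the usual first/second-order guide lines. Neurons silent in
  either run are dropped pairwise from the spike-time error with a logged
  count.
* **Benchmark for rate accuracy.** RK2 at $\Delta t = 0.005$ ms: the rate
  table shows the population rate already converged to printed precision
  between 0.005 and 0.02 ms, so a much finer reference would change the
  reported errors only in digits dominated by realization noise.
* **Poisson trains are independent per neuron** (shared-input is the other
  defensible reading); sharing would synchronize the population and change
  the dynamical regime, not just the numerics.

## Problem sizes used by the test suite

The convergence harness fits slopes over $\Delta t = 2^{-5} \dots 2^{-9}$ ms
on a 100 ms run of the study network against an RK2 reference at
$2^{-16}$ ms; the rate-accuracy table uses the full $T = 10$ s run at the
study's step sizes. Unit tests exercise the same operations on closed-form
scalar problems and networks of 1–6 neurons, where the compiled engine is
also cross-checked against the pure-R reference engine step by step.

## Known limitations

* Second order only; the recalibration would need refinement for a
  fourth-order variant.
* At the very largest steps the adaptive method's accuracy is limited by how
  coarsely the ETD2RK branch resolves the action potential itself: with
  $\Delta t = 0.277$ ms the ~2 ms spike is covered by about a dozen nodes,
  and the resulting error in the post-spike gating state leaves a
  measurable bias in the population rate (of order 1–2% on the study
  network, versus $\lesssim 0.1\%$ at $\Delta t \le 0.1$ ms — the
  acceptance script computes these numbers). A sub-stepped stiff window
  would remove this at modest cost, but step-size adaptation is outside
  this package's scope: the adaptation here is scheme switching at fixed
  $\Delta t$.
* In the convergence fits, the largest step sizes sit at the edge of the
  asymptotic regime for plain ETD2 (its error constant in the spike region
  is large), which slightly flattens a log-log slope fitted across a wide
  $\Delta t$ range even though the per-halving error ratios at small steps
  are cleanly fourfold.
* No synaptic delays, conduction latencies or plasticity; single-process
  execution (the per-neuron stepping is embarrassingly parallel in
  principle).
* The adaptive criterion assumes at most one upward crossing per neuron per
  step, valid for $\Delta t$ well below the refractory period (all step
  sizes considered satisfy this by an order of magnitude).
* Wall-clock speedups are hardware-dependent and are deliberately not
  measured; the step-count ratio `efficiency_ratio()` is the portable proxy.
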