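---
title: "Modeling synchronization of delay-coupled pre-Bötzinger complex bursters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling synchronization of delay-coupled pre-Bötzinger complex bursters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pbcsync)
```

## The system

The pre-Bötzinger complex (PBC) is the medullary nucleus believed to
generate the inspiratory respiratory rhythm. A subset of its neurons burst
intrinsically, driven by a persistent sodium current (`I_NaP`) and a
calcium-activated nonspecific cation current (`I_CAN`). `pbcsync`
implements a single-compartment PBC neuron of the Toporikova–Butera /
Park–Rubin family in which the dendritic calcium machinery is replaced by
a prescribed closed path: the calcium concentration `Ca` and the fraction
`l` of non-inactivated IP3 channels rotate on an ellipse centered at
`(Ca_c, l_c) = (0.1, 0.9)` with angular speed `eps = 0.09` per ms and
aspect ratio `d = 0.5`. The five state variables are
`(V, n, h, Ca, l)`:

* `C_m dV/dt = -I_Na - I_NaP - I_CAN - I_K - I_L - I_exc`
* first-order gating for the potassium activation `n` and the NaP
  inactivation `h`, with Boltzmann steady states
  `x_inf(V) = 1/(1 + exp((V - V_half)/s))` and time constants
  `tau(V) = tau_bar / cosh((V - V_half)/(2 s))`
* `dCa/dt = -eps d (l - l_c)`, `dl/dt = (eps/d)(Ca - Ca_c)`.

The currents are `I_Na = g_Na m_inf^3 (1-n)(V - V_Na)` (instantaneous
activation, `1-n` standing in for inactivation),
`I_NaP = g_NaP mp_inf h (V - V_Na)`,
`I_CAN = g_CAN f(Ca)(V - V_Na)` with the Hill activation
`f(Ca) = [1 + (K_CAN/Ca)^n_CAN]^{-1}`, `I_K = g_K n^4 (V - V_K)` and the
leak. `I_exc` is a constant bias current; increasing it hyperpolarizes
the cell, and it is the main bifurcation parameter. Two neurons couple
electrically with optional transmission delays,
`I_ci = g_c (V_j(t - tau_i) - V_i)`, and share one calcium subsystem.

The slow variable that clocks bursting is `h` (`tau_h_bar = 10^4` ms);
`n` is fast (`tau_n_bar = 10` ms). With calcium held at the ellipse
center the model is a classic square-wave burster: at `I_exc = 8.5` it
produces stable period-3 bursting (three spikes per ~2.3 s cycle), the
spikes-per-burst count climbs with `I_exc` through a period-adding
cascade, and firing ceases entirely between 11.0 and 11.5.

## Two parameter conventions, and why the package has `can_scale`

The published description of this model leaves two gaps that this package
had to close, and both decisions are data-driven:

**Gating time-constant assignment.** The source table pairs
`tau_h = 10` ms with `tau_n = 10{,}000` ms — the reverse of the canonical
Butera assignment. The published somatic Jacobian at the Hopf point
settles it: its `(2,2)` entry, `-0.8699 = -1/tau_n(V^*)`, requires
`tau_n_bar = 10` ms, and its `(3,3)` entry `-0.000107` requires
`tau_h_bar = 10^4` ms. The package therefore defaults to the canonical
(fast-`n`, slow-`h`) assignment. Three further independent entries of the
printed Jacobian and the recoverable coefficients of the printed
second-order form agree with our analytic derivatives to all printed
digits under this choice, so the reconstruction of the kinetics is not in
doubt.

**The CAN activation scale.** With the Hill parameters as printed,
`f(0.1) = 0.1255`. That value is inconsistent with the published somatic
fixed-point analysis: the reported Hopf equilibrium
(`V^* = -51.8239` mV at `I_exc^* = 8.073`) balances only if
`g_CAN f(0.1) = 0.0512`, i.e. `f` scaled by `0.5836`, and the reported
`dV`-row Jacobian entry independently demands the same rescaling. Yet the
*simulated* phenomenology (period-3 bursting at 8.5, quiescence onset at
11.5) is reproduced only with the unscaled Hill value, whose own
lower-branch Hopf sits at `I_exc ~ 11.8`, exactly at the firing
boundary. The two halves of the source are mutually inconsistent; no
single parameter set reproduces both. The package resolves this honestly:

* `pbc_params()` defaults to `can_scale = 1` (the plain Hill form).
  Every simulation result in the package uses it.
* `calibrate_can_scale()` solves the reported equilibrium current balance
  in closed form and returns the somatic operating configuration of the
  fixed-point analysis (`can_scale = 0.5836`). The Hopf pipeline
  (`locate_hopf()`, `normal_form_coeffs()`) reproduces the reported
  `I^*`, `V^*`, `omega = 0.0023475` and `lambda = -0.869856` essentially
  exactly in that configuration.

Because calcium stays at the ellipse center in all reference runs,
`can_scale` acts as a single constant conductance factor; it does not
change any functional form.

```{r}
p <- pbc_params()                 # simulation convention
pc <- calibrate_can_scale(p)      # somatic fixed-point convention
normal_form_coeffs(locate_hopf(pc, c(7, 9)), pc)
```

## Hopf criticality: an honest disagreement

At the calibrated Hopf point the package evaluates the complex normal-form
coefficients from exact (hand-differentiated) second- and third-order
tensors of the somatic right-hand side, with `q` scaled to unit first
component and `<p, q> = 1`. Two combinations are reported:
`l1_projection` (the planar formula
`Re(i g20 g11 + omega g21)/(2 omega^2)` with
`g21 = <p, C(q,q,qbar)>`) and `l1_center_manifold`, which adds the
quadratic center-manifold corrections to `g21` — the form that actually
determines criticality in three dimensions. Both come out *positive*
(+0.31 and +0.49), i.e. subcritical, whereas the source reports
`l1 = -1.0025` and calls the bifurcation supercritical.

We believe the computed sign. The machinery recovers the sign of
closed-form planar and three-dimensional oracles (see
`test-stability.R`); the printed first-order data (equilibrium, Jacobian,
eigenvalues, eigenvectors — which we match to five digits) are internally
consistent, but the printed third-order data are not: the published `g11`
differs by a factor of ~12 from what the published `p`, `q` and `B`
themselves give, and the published `g21 = -0.0047` coincides with a
single tensor entry of a `C` matrix whose rows are mutually inconsistent
in scale. Dynamically, the subcritical picture fits what the simulations
show: immediately past the Hopf point trajectories leave the equilibrium
for the large bursting orbit with no intervening small stable cycle, and
the cycle branch born at the Hopf is reported (in the source's own
bifurcation diagram) at parameter values *above* the Hopf point, which is
the subcritical geometry. The acceptance suite keeps the published value
as its reference and therefore flags this single quantity red, by
design.

## Integration

No integrator, step size, run length or transient policy is stated in the
source, so the package fixes its own and applies them uniformly:

* **Scheme.** Classical fixed-step RK4, `dt_integrate = 0.02` ms —
  small enough to resolve the ~1 ms spike upstroke with the fast gate at
  `tau_n ~ 0.5` ms; order-4 convergence is asserted by a Richardson test.
  Delayed voltages use the method of steps with cubic Hermite
  interpolation on the integration-resolution history (values and
  derivatives); with both delays zero the coupled integrator is
  *bitwise* the plain RK4 ODE solution. For delays smaller than one step
  the first step uses a linear Taylor fallback and subsequent stages a
  mild (sub-step) extrapolation of the last Hermite segment.
* **Initial conditions.** `(V, n, h) = (-50, 0, 0.5)`, calcium at the
  ellipse center; a coupled pair starts neuron 2 at `+0.01` mV so
  complete synchronization is demonstrated as convergence. The initial
  history of delayed runs is constant.
* **Run lengths.** Reference metric runs use `2 x 10^5` ms with the
  first 50% discarded (about 40 post-transient burst cycles); metrics are
  computed on `V` sampled at 1 ms. Unit tests use shorter runs
  (3–10 x 10^4 ms) where the property under test stabilizes earlier, and
  the reduced two-parameter maps use 5 x 5 and 3 x 3 grids at
  5 x 10^4 ms per cell; these sizes are the package's chosen balance
  between statistical stability and a test suite that runs in minutes.
* **Conservation check.** The calcium ellipse invariant
  `E = (Ca - Ca_c)^2/d + d (l - l_c)^2` is conserved analytically; the
  integrated drift is held under `1e-6` relative per 1000 ms.

## Synchronization measures

All pairwise measures operate on the post-transient sampled voltages:

* `correlation_coefficient()` — the centered Pearson `R`.
* `max_sync_difference()` — `max_k |V1 - V2|`.
* `poincare_phase()` — piecewise-linear phase from section crossings,
  `phi(t_n) = 2 pi n`. The section is *burst onsets* (first spike of
  each burst, hysteresis spike detector at -30/-40 mV): the source says
  only that trajectories "cross the Poincaré graph", and burst onsets
  make the period/frequency analysis well-defined for bursting signals.
  Phase locking means `max |phi1 - phi2| < 2 pi`.
* `similarity()` — the lag-synchronization diagnostic
  `S^2(tau) = <(x(t) - y(t+tau))^2> / sqrt(<x^2><y^2>)` on
  mean-subtracted signals (the Rosenblum-style convention: the trailing
  signal is shifted forward, so `S(L) = 0` exactly when `y` is `x`
  delayed by `L`; the raw non-centered variant is available via
  `center = FALSE`). `S^2 -> 2` for independent equal-power signals.
* `classify_sync()` — complete (`R > 0.999`, `max_e < 1` mV),
  approximate (`R > 0.95`), phase (`dphi_max < 2 pi`), lag
  (`min S < 0.05` off zero), out-of-phase (best alignment within 15% of
  half the burst period and better than zero lag), else asynchronous.
  The thresholds are package conventions. Of the four labelled no-delay
  reference cases, `g_c = -0.5` (complete) and `g_c = 0.4`
  (out-of-phase) reproduce; `g_c = -0.24` fully synchronizes here (the
  complete-sync band of the reconstructed model extends past -0.3), and
  `g_c = -0.1` classifies as *phase* because its bursts genuinely
  coincide under the burst-onset section even though spike timing inside
  the bursts is unrelated — the source's own description of that regime
  ("bursting at the same time", "no fixed phase" between spike
  sequences) matches both readings.

Delay phenomenology of the coupled pair, all reproduced by the test
suite: complete synchronization for `g_c` in the negative band at zero
delay; persistence of complete synchronization for weak symmetric delays
(`tau < 0.02` ms, the continuous-dependence property); desynchronization
at intermediate delays (`tau ~ 5–8` ms at `g_c = -0.5`) and return to
complete synchronization at large delays (`tau ~ 17`); delay-induced
chaos at `g_c = 0.4`, `tau = 10` with a positive maximal Lyapunov
exponent and `max|V1 - V2|` plateauing near 65 mV.

## Lyapunov exponents

`max_lyapunov()` implements the Benettin two-trajectory method: the twin
starts displaced by `d0 = 1e-6` mV in `V1` and the separation is rescaled
to `d0` every 50 ms; the exponent is the mean log-expansion over the
post-transient renormalizations (first 25% discarded, default duration
`4 x 10^5` ms). For delayed runs a meaningful distance must include the
function segment, so the norm spans the current state plus the voltage
history over the delay window, and renormalization rescales state and
history together. Reference behaviors: negative exponent in the
quiescent regime, zero (to `1e-6`) on the neutral calcium rotation,
positive for the delayed positive-coupling chaos.

## Surrogate ground truth

`surrogate_spec()` / `gen_pair()` generate voltage-like bursty trace
pairs — raised-cosine spikes (2 ms wide) on a -60 mV baseline — with
known lag, phase shift, target correlation (`y = rho x + sqrt(1-rho^2) e`
so the expected Pearson `R` equals `target_R`), anti-phase alignment, or
full independence, plus optional Gaussian white noise, all deterministic
per seed. They emulate exactly the features the metrics consume (burst
timing, lag structure, correlation level); they do not emulate the
neuron model's chaotic attractor statistics, spike-shape variability or
1/f background, so metric tests passing on surrogates validate the
*measures*, not the neuron dynamics — the model-level claims are tested
separately on integrated traces.

## Known limitations

* Continuation of periodic orbits (the fold/homoclinic/period-doubling
  structure of the limit-cycle branches) is out of scope; only
  equilibrium branches and Hopf points are located.
* The quantitative Hopf targets require the calibrated somatic
  configuration, and the first Lyapunov coefficient disagrees in sign
  with the published value for the reasons documented above.
* Networks larger than two neurons, adaptive stepping, and
  analytic-signal (Hilbert) phases are not implemented.
* Full-resolution two-parameter maps are desk-scale reductions
  (coarse grids); they are checked for qualitative contrasts only.
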