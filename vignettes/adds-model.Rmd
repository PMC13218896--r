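---
title: "The ADDS circuit model: agency, dopamine, and decision making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ADDS circuit model: agency, dopamine, and decision making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addsim)
```

## The model

ADDS (Agency Disinhibits the Dopamine System) holds that the sense of
agency — the feeling of control over one's actions and their consequences —
modulates the midbrain dopamine system through a disinhibition chain:
agency-related input drives the ventral subiculum (vSub), which excites
medium spiny neurons (MSNs) of the nucleus accumbens (NAcc); the NAcc
inhibits the ventral pallidum (VP); and the VP tonically inhibits dopamine
(DA) neurons of the ventral tegmental area (VTA). Because VP neurons are
tonically active (about 7 Hz) while MSNs are nearly silent, roughly half of
the VTA DA population is held silent by pallidal tone under control
conditions. Raising agency excites the NAcc, suppresses the VP, and
*recruits* DA neurons into the tonically active pool — without changing the
firing rate of neurons that were already active. Reward-prediction errors
(RPEs) act on the same DA population through an independent channel:
positive RPEs excite the VTA via the pedunculopontine tegmental nucleus
(PPTN) and make tonically active neurons fire phasic bursts; negative RPEs
inhibit it via the rostromedial tegmental nucleus (RMTN) and suppress
firing below baseline.

`addsim` implements this circuit as a spiking network plus two readout
layers:

1. **Circuit** — 100 Izhikevich MSNs (NAcc), 100 quadratic
   integrate-and-fire (QIF) neurons calibrated to 7 Hz (VP), and 100 QIF
   pacemakers calibrated to 4.5 Hz (VTA DA), wired by Bernoulli sampling
   (p = 0.25). vSub, PPTN and RMTN are Poisson drive nodes, not spiking
   populations; the habenular relay onto the RMTN is collapsed into the
   single RMTN drive.
2. **DA concentration** — spike trains are convolved with
   release/clearance kernels to produce extracellular DA traces in the
   accumbens (fast clearance) and frontal cortex (slow clearance).
3. **Decision layer** — agency-dependent prospect-theory utility,
   optional probability weighting, gamble evaluation, and hyperbolic
   temporal discounting with a U-shaped DA coupling.

## Neuron models and units

MSNs follow the two-variable Izhikevich system
$C\dot v = k(v-v_r)(v-v_t) - u + I$, $\dot u = a[b(v-v_r) - u]$, with the
published striatal-MSN parameterization ($C=50$ pF, $k=1$, $v_r=-80$,
$v_t=-25$ mV, $a=0.01$, $b=-20$, $c=-55$, $d=150$, $v_{peak}=40$). An MSN
fires 0 Hz without input and shows up-/down-state behaviour under
fluctuating drive. VP and DA neurons are QIF:
$\tau\dot v = (v-v_r)(v-v_c)/(v_c-v_r) + I$. Input currents are in
pA-equivalents (unit input resistance), so the QIF rheobase is
$(v_c-v_r)/4$. Intrinsic bias currents are not free parameters: they are
solved by `calibrate_bias_current()` (bisection on the simulated 10 s
rate) to hit the tonic-rate contracts — 7 Hz for VP, 4.5 Hz for the DA
pacemaker, a literature-typical intrinsic rate since no value is printed
for it.

Integration is explicit Euler at `dt = 0.5` ms with adaptive substepping:
each substep is capped at a 2 mV membrane change, and a step ends at the
spike with the neuron left at reset. The substepping matters: the
quadratic upswing is much faster than `dt`, and without it coarse steps
fire systematically early (about 9% rate error for a driven MSN at
`dt = 0.5`; with substepping the error against a 100-fold finer reference
is under 1%, and halving `dt` changes a 10 s spike count by at most one
spike). Spike time is the end of the step in which the threshold was
crossed. Membrane noise enters as white current noise scaled by
$\sqrt{dt}$.

## Drive encodings and the calibrated operating point

The agency level $A \in [0,1]$ sets the vSub drive: 50 afferents per MSN,
each at $40A$ Hz. The per-MSN rate is additionally modulated by a slow
log-normal Ornstein–Uhlenbeck process (time constant 200 ms, SD 0.8, mean
1). This models the correlated afferent fluctuations that give MSNs their
characteristic up/down states; mechanically, it converts the MSN
rheobase threshold into a smooth, graded mapping from $A$ to NAcc rate
(with plain Poisson drive the NAcc would be exactly silent below a sharp
agency threshold and the circuit would have no low-agency dynamic range).

Two structural choices shape the DA-population response; both are
documented here because the source material constrains the behaviour, not
the mechanism:

* **Saturating NAcc→VP inhibition** (`vp_inh_max`): the total inhibitory
  current a VP neuron can receive is capped (receptor saturation), so
  high agency floors the VP near 3 Hz instead of silencing it. This keeps
  the agency → percent-active mapping graded up to $A = 1$.
* **Two VP→VTA innervation groups** (`da_deep_fraction`,
  `da_deep_ratio`): half of the DA neurons receive dense pallidal
  innervation (12-fold heavier median weight, log-normal within-group
  spread 0.45) and are deeply hyperpolarized; the rest are sparsely
  innervated and fire near their pacemaker rate. The deeply inhibited
  pool is recruitable by *disinhibition* (which scales inhibition down
  multiplicatively) but not by moderate additive excitation — exactly the
  asymmetry behind the population-activity vs firing-rate double
  dissociation. A single log-normal weight distribution leaves too much
  mass at the silence boundary, and sustained PPTN drive then recruits
  silent neurons, erasing the dissociation.

RPE events map $|\delta|$ linearly onto a 200 ms Poisson drive
(30 Hz at $|\delta| = 1$) of large synaptic kicks (12 pA-equivalents):
large kicks make tonically active pacemakers fire inter-spike intervals
short enough to register as bursts, while remaining below the gap that
separates the deeply inhibited pool from threshold. Sustained activation
(the in-silico NMDA-infusion protocol) instead uses small kicks
(5 pA-equivalents at a few Hz), which raise tonic rates by a steady
depolarization without recruiting silent neurons. A configurable aversive
subpopulation (default 8%, within the reported 3–14% range) receives the
RMTN drive with flipped sign and gain 0.3; it blunts the negative limb of
the DA-vs-RPE curve, producing the gain/loss response asymmetry. Gain 1
would make the negative limb non-monotone (aversive excitation would
overwhelm suppression at large negative RPEs), which is why the default is
lower.

The remaining weights were calibrated once, by simulation, to the stated
operating point: at `A_control = 0.35`, about half of the DA population is
spontaneously active, the VP sits near 6.6 Hz, and NAcc MSNs fire well
under 1 Hz. The calibrated defaults are frozen in `network_config()`;
`run_lodge_grace()` is itself the calibration utility (its control
condition reports the percent-active statistic directly).

## DA neuron states and the concentration readout

`classify_da_states()` labels each DA neuron per analysis window:
*silent* below 0.5 Hz (a rate exactly at threshold counts as tonic),
*phasic* if any burst occurs (burst entry at ISI < 80 ms, exit above
160 ms — the standard DA burst convention), else *tonic*. The default
window is 10 s after a 2 s burn-in.

`spikes_to_concentration()` superposes an exponential release/clearance
kernel over all spikes: each spike adds `release_increment`, cleared with
time constant `clearance_tau` (Michaelis–Menten reuptake is available as
an alternative mode). The accumbens preset uses fast clearance
(`tau = 0.2` s) and no burst facilitation, so every closed form (single
spike, shot-noise mean, linearity) holds exactly. The cortical preset
models slow clearance (`tau = 600` s) with strong release facilitation for
intra-burst spikes (`phasic_gain = 30`, applied to spikes whose preceding
ISI is under 100 ms) — the physiological counterpart of burst-dependent DA
release. With these defaults a single injected 10-spike burst over a
4.5 Hz tonic backdrop keeps the cortical trace more than 1% above its
pre-burst steady state for about 23 minutes, inside the 20–30 minute
window the slow cortical kinetics are meant to capture. The facilitation
is not optional decoration: with uniform per-spike release, no clearance
time constant can hold a realistic burst above a 1% detection threshold
for 20 minutes over the tonic backdrop (the exceedance time
$\tau\ln(k/(0.01\,r\,\tau))$ is maximized at a few minutes), so the
contract pins the facilitation factor rather than the time constant
alone.

`delta_da()` measures the mean concentration in a response window after
an RPE event minus the mean in a pre-onset baseline window;
`rpe_response_curve()` repeats this over an RPE grid and seeds. Raising
agency steepens the positive limb of this curve because more DA neurons
are available to respond; absolute units are arbitrary, so only shape
properties (sign, monotonicity, steepening, gain/loss asymmetry) are
meaningful.

## Protocols and statistics

`run_lodge_grace()` packages the activation experiment: control, vSub
activation (`A_high = 0.85`), sustained PPTN drive (5 Hz per DA neuron),
or both. Each of `n_seeds` replicates rewires and reruns the circuit
(2 s burn-in discarded, 10 s analysis window) and reports the percentage
of tonically active DA neurons and the mean rate of the active ones.
`compare_to_control()` tests differences with a seeded Monte-Carlo
permutation test (10,000 shuffles, add-one corrected, exact at small n;
Welch's t available for speed). At the defaults and 20 seeds, vSub
activation raises percent-active (permutation p < 0.001) without touching
the rate of active neurons (p ≈ 0.5), sustained PPTN drive does the
reverse, and co-application raises percent-active strongly while the rate
shift remains positive but below significance — a consequence of
calibrating the sustained drive weakly enough that PPTN alone does not
recruit silent neurons. Whether co-application should interact beyond
simple superposition is not derivable from the source material; the
drives are simply co-applied.

## The decision layer

Utility is two-part power with the canonical curvature 0.88:
$u(x) = s\,x^{0.88}$ for gains and $-\lambda s\,(-x)^{0.88}$ for losses,
with $s$ and $\lambda$ solved from the control anchors
$u(79) = +50$ and $u(-48) = -50$ (so $s \approx 1.069$,
$\lambda \approx 1.55$). Agency acts through multipliers $g(A)$ on gains
and $l(A)$ on losses, both 1 at `A_control`; the high-agency defaults
$g = 1.38$ and $l = 1.06$ are derived from the printed worked values
(+50 → +69 and −50 → −53), and intermediate levels interpolate linearly
in (multiplier − 1), flooring at 1 below control. The functional family
is a package choice — the theory constrains only that gains shift more
than losses.

With identity weighting and zero delays, the 50/50 win-79/lose-48 gamble
is exactly at indifference under control and worth $0.5(69) + 0.5(-53) =
+8$ under high agency — the risk-reversal witness:

```{r}
g <- gamble(c(79, -48), c(0.5, 0.5))
expected_utility(g, ctx = agency_context(0.35))
expected_utility(g, ctx = agency_context(0.85))
```

Probability weighting ships as the one-parameter inverse-S function
$\pi(p) = p^{\gamma}/(p^{\gamma}+(1-p)^{\gamma})^{1/\gamma}$ with fixed
endpoints, plus a signed DA-modulation coefficient on $\gamma$; the
default mode is *identity* and the coefficient 0, because the evidence on
the direction of the DA effect is unresolved — the mechanism is exposed,
not asserted.

Temporal discounting is hyperbolic, $D(t) = 1/(1+\alpha t)$ with delays
in days and $\alpha = 0.01$/day when uncoupled. Coupled to a circuit (or
an explicit `tonic_da`), the rate follows a convex U-shape in tonic DA:
$\log\alpha = \log\alpha_{\min} + \kappa(\mathrm{DA}-\mathrm{DA}_{opt})^2$
with the optimum at 1.5 times the control DA level and $\kappa = 2$.
Below the optimum, raising agency (hence tonic DA) reduces discounting;
past it — the overdose regime relevant to medicated Parkinsonian circuits
— the same increase raises discounting. The hyperbolic form, unlike
exponential discounting, produces preference reversal under a common
front-end delay, which the tests verify by direct evaluation. Ties in
delayed choice go to the sooner option (the impulsive default).

## What the simulations do and do not show

The synthetic drives emulate the *study conditions*: stationary agency
levels, isolated non-overlapping RPE events, homogeneous Poisson afferents
with slow rate fluctuations, and independent replicate wirings. They do
not emulate real recordings — no electrode sampling bias, no
non-stationary behavioural states, no D1/D2 receptor pharmacology, no
norepinephrine loss pathway, and no nigrostriatal (SNpc) system. Passing
tests therefore show that the implemented circuit reproduces the theory's
qualitative signatures (disinhibition chain, state double dissociation,
RPE-curve steepening and asymmetry, risk reversal, U-shaped discounting)
under controlled conditions, not that the parameter values are estimates
of biological quantities. Absolute DA concentrations and utility units
are arbitrary.

## Problem sizes and numerical choices

Default runs use 100 neurons per population and 12 s of simulated time
(2 s burn-in + 10 s window) at `dt = 0.5` ms; protocol statistics use 20
seeds, and RPE curves use 4 s runs per (RPE, seed). Wiring and run seeds
are separate, and every result object embeds its seed list and a config
hash so published artifacts can be regenerated bit-identically.
Degenerate inputs are defined rather than left to chance: a neuron at
exactly the silence threshold is tonic, ties in delayed choice are
"sooner", gambles must have probabilities summing to 1 within 1e-9, and
the acceptance band for gamble indifference is 1e-9 utility units.

## Known limitations

* The circuit's burst machinery is a QIF approximation; real DA bursts
  involve NMDA-dependent plateau dynamics and depolarization block, which
  bound burst length in ways a reset model cannot.
* The two-group pallidal innervation is a mechanism chosen to realize the
  recruitability asymmetry; the anatomy constrains the asymmetry, not the
  weight distribution.
* The loss-side decision pathway (norepinephrine-dependent) is outside
  the model; losses are handled entirely by the utility multipliers and
  the small aversive DA subset.
* Agency enters as an exogenous scalar; the network that estimates agency
  is not modelled.
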