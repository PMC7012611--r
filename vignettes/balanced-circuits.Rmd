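---
title: "Balanced cortical circuits under optogenetic interneuron drive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced cortical circuits under optogenetic interneuron drive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optobalance)
```

## The scientific problem

Photostimulating parvalbumin-positive (PV) interneurons sometimes
*decreases* their firing — the paradoxical effect. In two-population
models this happens only in the inhibition-stabilized regime, where
recurrent excitation alone would be unstable. `optobalance` implements a
different account, built on networks of strongly coupled spiking neurons:
couplings scale as $1/\sqrt{K}$ with the in-degree $K$, so excitation and
inhibition are individually much larger than the rheobase and must cancel.
In that balanced regime the population rates follow *linear* balance
equations, and whether the PV response is paradoxical is decided by
disinhibitory loops through other interneuron classes (SOM and VIP, or an
unidentified class X) rather than by recurrent excitation alone.

The package covers four layers of the analysis, each usable on its own:

1. **Circuit specifications** (`load_architecture()`): five reference
   architectures with their interaction tables — a two-population circuit
   (with and without recurrent excitation) and two four-population
   circuits. In the V1-like circuit, VIP projects only to SOM and SOM
   receives no PV input; in the PC/PV/SOM/X circuit the third inhibitory
   class does not project to SOM.
2. **Balance theory** (`solve_balance()`, `sweep_opto()`,
   `susceptibility()`, `paradox_audit()`): exact large-$N,K$ analytics.
3. **Spiking simulations** (`simulate_network()`,
   `intensity_sweep_sim()`): finite-size leaky integrate-and-fire networks
   with sparse Bernoulli connectivity.
4. **Spike-train analysis and synthetic recordings**
   (`normalize_responses()`, `response_slope()`, `generate_recording()`):
   the electrophysiology pipeline — unit classification by spike width,
   normalized rates, bootstrap uncertainty — and a generator of synthetic
   recordings with known ground truth to validate it end to end.

## The balance equations

With populations $\alpha$ (polarity $\epsilon_\beta = \pm 1$), interaction
strengths $J_{\alpha\beta} \ge 0$ (µA·ms·cm⁻², rows postsynaptic),
feedforward strengths $J_{\alpha 0}$, an external rate $r_0 = 5$ Hz and an
optogenetic current $I^\alpha_{\mathrm{opto}}$, the net input per neuron
stays finite as $K \to \infty$ only if

$$2 J_{\alpha 0} r_0 + I^\alpha_{\mathrm{opto}}
  + \sum_\beta J_{\alpha\beta}\,\epsilon_\beta\, r_\beta = 0 .$$

`balance_problem()` assembles the signed matrix
$A_{\alpha\beta} = \epsilon_\beta J_{\alpha\beta}$ and the input vector;
`solve_balance()` solves the linear system on an assumed active set, pins
the other populations at zero rate, and checks self-consistency: active
rates must be nonnegative and silent populations must receive
hyperpolarizing net input. As the drive grows, populations silence one at
a time, so rates are piecewise linear with breakpoints that
`sweep_opto()` locates by bisection (to $10^{-8}$ on the drive).

```{r}
m2 <- load_architecture("model2")
tidy(solve_balance(balance_problem(m2)))
```

The susceptibility $\chi = -A^{-1}$ (restricted to the active set) gives
the rate response to a small extra input; its `["I", "I"]` element decides
the paradoxical effect. `paradox_audit()` evaluates the closed-form
criteria — $J_{EE} < J_{EE}^* = J_{VE}J_{ES}/J_{VS}$ for the V1-like
circuit, $J_{EX}J_{XS} > J_{XX}J_{ES}$ for the PC/PV/SOM/X circuit
(independent of $J_{EE}$), $J_{EE} > 0$ for the two-population circuit —
and cross-checks each against $\mathrm{sign}(\chi_{II})$:

```{r}
glance(paradox_audit(m2))
```

Because SOM neurons receive only PC and PV input in this circuit, their
balance ties $r_I / r_E = J_{SE}/J_{SI} = 26/12$ at *all* drive levels
while SOM is active — the robust proportional co-suppression of PCs and PV
that distinguishes this architecture. In the V1-like circuit the same
mechanism ties $r_V / r_E$ instead.

## Units

Internally: time in ms, voltages in mV, $C_M$ in µF/cm², $g_{\mathrm{leak}}$
in mS/cm², $J$ in µA·ms·cm⁻². With rates in Hz, $2 J_{\alpha0} r_0$ and
$J r$ are currents in nA/cm², the natural scale of the balance equations;
the amplitude $I_0 = 8$ of the light-transduction law is read as nA/cm²,
the only dimensionally consistent reading. The simulator works in µA/cm².
The laser-intensity map $I_{\mathrm{opto}} = I_0 \ln(1 + \Gamma/\Gamma_0)$
uses the natural logarithm (a base change only rescales $\Gamma_0$).
Because the absolute current scale cannot be pinned tighter than this from
dimensional analysis alone, the mapping from physical laser power to rates
may differ from any particular experiment by a scale factor on $\Gamma$;
all dimensionless predictions (signs, ratios, breakpoint structure) are
unaffected.

## The spiking simulator

`simulate_network()` integrates
$C_M \dot V = -g_{\mathrm{leak}}(V - V_R) + I_{\mathrm{rec}} +
\Lambda_{\mathrm{ext}} + \Lambda_{\mathrm{opto}}$ with threshold −50 mV
and reset −70 mV. Connectivity is unstructured: each ordered pair is
connected independently with probability $K/N_\beta$ (single contact, no
autapses). Couplings are $J/\sqrt K$; the feedforward drive is the
constant current $2 K j_{\alpha 0} r_0$; the optogenetic drive is
$\sqrt K\, I_{\mathrm{opto}}(\Gamma)$ into the PV population. Synapses are
exponential with unit-integral kernels $e^{-t/\tau}/\tau$.

Numerical choices:

* The membrane potential advances by a second-order Runge–Kutta step with
  the synaptic input evaluated at both stage times; synaptic traces decay
  *exactly* between spikes (equivalent to the kernel sum, and immune to
  RK error on the stiff synapse). Spikes are recorded at end-of-step times
  without interpolation; threshold equality counts as a spike.
* Default `dt = 0.01` ms; the suite verifies that halving `dt` moves
  population rates by < 3%.
* Initial conditions: $V \sim U(V_R, V_{th})$, synapses at zero; the first
  1 s is discarded as warmup. Both are conventional choices, made once.
* A $|V| > 1000$ mV excursion aborts with a diagnostic rather than
  returning garbage.
* Everything is deterministic given the seed (own Mersenne-Twister in the
  C++ core, so results do not depend on R's RNG state).

Reference scale is $N = 76{,}800$, $K = 500$, 100 s — the scale at which
the reference baselines were produced; `network_sizes()` defaults to
it. Routine testing uses a reduced scale chosen once for this package's
test suite: $N = 4800$, $K = 150$, `dt = 0.02` ms, 10 s of analyzed
activity, laser grid $\Gamma \in \{0, 1, 10\}$ mW/mm². At this scale every
architecture reproduces its qualitative response pattern with wide
margins (PV suppressed at low intensity in the paradoxical circuits,
elevated otherwise; PC–PV co-suppression within 5% in the PC/PV/SOM/X
circuit), the balanced-regime hallmarks hold (ISI CV near 1, across-neuron
rate CV > 0.5), and the deviation from the balance-theory rates shrinks
like $1/\sqrt K$ (checked over $K = 50, 150, 450$ at fixed $N/K$).
Quantitative agreement with the reference full-scale baselines is *not*
asserted at reduced scale — finite-$K$ corrections of order $1/\sqrt K$
are substantial (e.g. the two-population baseline sits ~40% above its
large-$K$ limit at $K = 150$).

## The electrophysiology analysis

Units are classified by trough-to-peak spike width: fast-spiking
(putatively PV) below 0.35 ms, putative pyramidal above 0.45 ms,
intermediate widths excluded (boundaries excluded too — the
classification rule uses strict inequalities). Rates are counted in a 1 s window during
photostimulation and a 500 ms window before onset. The *population*
normalized rate averages rates across units first and then divides by the
averaged baseline — the order matters and is preserved throughout
(averaging per-unit ratios would weight low-baseline units up).

Design choices where the procedure was underdetermined:

* The per-unit baseline pools the pre-stimulus windows of all trials
  (every trial has one); the laser-off point of a normalized curve is the
  baseline itself, hence exactly 1.
* Slopes are unweighted ordinary least squares of normalized rate against
  intensity, using points at or below the chosen `max_intensity` (below
  the PV turning point) and including the laser-off point.
* Uncertainty: bootstrap over *neurons* (values of a resampled neuron move
  together), 10,000 replicates by default, seeded. The PV/PC slope-ratio
  SEM bootstraps the two classes independently and takes the SD of the
  resampled ratios.
* Response categories at a given intensity: *silenced* if the stimulation
  rate is below 0.1 Hz (evaluated on the stimulation rate alone, taking
  precedence), otherwise *increase*/*decrease* if the change from baseline
  exceeds 0.1 Hz, else *no change*.

## Synthetic recordings and what they do (not) show

`generate_recording()` emulates the structure the analysis relies on:
PC/FS unit counts per area preset (S1 52/8; ALM layer 2/3 26/9; layer 5
62/12), lognormal baselines (median 5 Hz, $\sigma_{\log} = 1$), spike
widths uniform within class bands, the standard laser grids, 20 trials per
intensity, 1.3 s stimulation epochs analyzed over 1 s. Each unit's
normalized response is a class template scaled by a unit gain
$g \sim N(1, \sigma_g)$, optionally sign-flipped with probability
$p_{\mathrm{inc}}$ to create incongruous units; spiking is homogeneous
Poisson within each window, clipped at zero rate before sampling. Ground
truth is closed form: the population curve is
$1 + (1 - 2 p_{\mathrm{inc}})(T(\Gamma) - 1)$, slopes are exact OLS on it
(clipping is neglected, so heavy suppression combined with wide gain
spread makes the truth slightly optimistic — recovery tests stay in the
regime where this bias is negligible).

What passing recovery tests shows: the pipeline's estimators are unbiased
at realistic counts and their bootstrap SEMs have the right scale. What it
does not show: robustness to features real recordings have and the
generator does not — non-Poisson spiking, drift, the 40 Hz photostimulus
ripple and masking flash (integrated out by the windows), sorting errors,
or correlated unit noise.

`from_simulation()` closes the loop: it slices a simulated intensity sweep
into pseudo-trials (stimulation windows from each intensity's run,
baseline windows from unused slices of the laser-off run), labels E as PC
and PV as FS with synthetic widths, and hands the result to the same
pipeline — which then reports, e.g., a negative PV population slope at low
intensity for the paradoxical V1-like circuit.

## Known limitations

* Only the determinant (rate-divergence) stability condition is checked,
  as $(-1)^n \det A > 0$; full dynamical stability depends on the synaptic
  time constants and is not analyzed.
* Reference susceptibility magnitudes for the V1-like circuit (1.6, −5.1)
  are not reproducible from the definition above under any unit
  convention tried here; only signs are asserted.
* No conductance synapses, delays, refractoriness, short-term plasticity,
  spatial structure, or interlaminar circuitry; all neurons within a
  population are identical, so response heterogeneity is purely
  connectivity-driven.
* When several partially balanced states coexist, sweeps follow the state
  continuous with the previous grid point and fall back to the largest
  active set, reporting the multiplicity; the theory itself does not
  select among them.
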