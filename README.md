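# optobalance

Balanced-network models of how cortical circuits respond to optogenetic
stimulation of PV interneurons — the theory, the spiking simulations, and
the spike-train analysis, in one R package.

## The problem

Driving an inhibitory population harder sometimes makes it fire *less*:
the **paradoxical effect**. In two-population models this only happens in
the inhibition-stabilized regime (strong recurrent excitation). But mouse
recordings show richer behavior — PV activity rises with laser intensity
in one cortical layer, falls paradoxically in another, and in barrel
cortex PCs and PV neurons are suppressed in exact proportion. This
package implements a framework in which those patterns follow from
circuit *architecture* in strongly coupled (balanced) networks with
several interneuron classes, where the paradoxical effect is driven by
disinhibitory loops and is **not** evidence of inhibition stabilization.

It is intended for computational neuroscientists who want to (1) analyze
balanced-circuit architectures exactly, (2) simulate the corresponding
finite-size spiking networks, and (3) run the standard optogenetic
electrophysiology analysis on real or synthetic recordings.

## The model in brief

Populations α ∈ {E, I, S, V or X} interact with strengths J\_αβ ≥ 0 and
polarities ε\_β = ±1; synapses scale as J/√K with the in-degree K. As
K → ∞ the net input must stay finite, forcing the linear **balance
equations**

    2 J_α0 r0 + I_opto^α + Σ_β J_αβ ε_β r_β = 0 .

Solutions with negative rates are replaced by *partially balanced* states
(some populations silent, self-consistently hyperpolarized), so rates are
piecewise linear in the optogenetic current, which enters the PV
population as I\_opto = I₀ ln(1 + Γ/Γ₀). The susceptibility χ = −A⁻¹
(A\_αβ = ε\_β J\_αβ) decides the paradoxical effect via sign(χ\_II), with
closed-form criteria per architecture: J\_EE < J\_EE\* = J\_VE·J\_ES/J\_VS
for the V1-like PC/PV/SOM/VIP circuit, and J\_EX·J\_XS > J\_XX·J\_ES
(independent of J\_EE) for the PC/PV/SOM/X circuit, whose SOM balance
additionally pins r\_I/r\_E = J\_SE/J\_SI at every drive level.

The finite-size counterpart is a network of leaky integrate-and-fire
neurons (C\_M V̇ = −g\_leak(V−V\_R) + I\_rec + Λ\_ext + Λ\_opto, threshold
−50 mV, reset −70 mV) with sparse Bernoulli connectivity and exponential
synapses, integrated in C++ (RK2, exact synaptic decay, no spike
interpolation).

## Worked example

```r
library(optobalance)

# exact balance-theory baseline of the PC/PV/SOM/X circuit
m2 <- load_architecture("model2")
tidy(solve_balance(balance_problem(m2)))
#> # A tibble: 4 × 4
#>   population  rate active net_input
#>   <chr>      <dbl> <lgl>      <dbl>
#> 1 E           3.04 TRUE           0
#> 2 I           6.58 TRUE           0
#> 3 S           6.27 TRUE           0
#> 4 X           3.97 TRUE           0

glance(paradox_audit(m2))
#> # A tibble: 1 × 5
#>   topology paradoxical  chi_II agreement jee_star
#>   <chr>    <lgl>         <dbl> <lgl>        <dbl>
#> 1 model2   TRUE        -0.0372 TRUE            NA
```

The PC rate is 3.04 Hz (the reference value, 3.0 Hz, to one decimal) and
the audit reports the paradoxical regime: χ_II < 0, because the
SOM–X–PC–SOM loop gain exceeds the J_XX·J_ES product (margin 1296 vs
704). A reduced-scale spiking simulation of the same circuit
(N = 4800 neurons, K = 150, 10 s):

```r
sw <- intensity_sweep_sim(m2, Gamma = c(0, 1, 10),
                          config = sim_config(dt = 0.02, duration = 11000,
                                              warmup = 1000, seed = 11),
                          sizes = network_sizes(m2, N = 4800, K = 150))
sw$population
#> # A tibble: 12 × 4
#>    Gamma population  rate norm_rate
#>  1     0 E           4.90     1
#>  2     0 I           6.64     1
#>  3     0 S           6.54     1
#>  4     0 X           4.67     1
#>  5     1 E           4.77     0.974
#>  6     1 I           6.48     0.976
#>  7     1 S           6.00     0.918
#>  8     1 X           5.21     1.12
#>  9    10 E           4.53     0.925
#> 10    10 I           6.18     0.932
#> 11    10 S           5.10     0.780
#> 12    10 X           6.14     1.31
```

PC and PV are suppressed *in proportion* (0.974 vs 0.976, then 0.925 vs
0.932 — the SOM balance at work), SOM falls, and the X population is
disinhibited, exactly the architecture's signature. `autoplot(sw)`
overlays single-neuron responses on the population curves;
`from_simulation()` + `normalize_responses()` + `response_slope()` run
the full electrophysiology pipeline (spike-width classification,
average-then-normalize rates, bootstrap SEMs, PV/PC slope ratio) on this
output or on synthetic recordings from `generate_recording()`.

Full-scale runs (N = 76,800, K = 500, 100 s — the default
`network_sizes()`), take CPU-hours per intensity; the reduced scale above
reproduces every qualitative result and is what the test suite exercises.

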