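---
title: "Modelling stroke recovery through excitatory-inhibitory homeostasis"
author: "strokenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stroke recovery through excitatory-inhibitory homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokenet)
```

## The model

`strokenet` simulates whole-cortex dynamics as a network of Wilson-Cowan
neural masses coupled through a structural connectome, with homeostatic
scaling of local inhibition, and uses that machinery to ask what happens to
functional networks when a cortical region is destroyed and the cortex
re-balances its excitation and inhibition.

Each region $i$ holds an excitatory and an inhibitory population with rates
$r^E_i, r^I_i \in (0,1)$:

$$
\tau_E \dot r^E_i = -r^E_i +
  F\!\left(c_{EE} r^E_i - c_{EI,i}\, r^I_i +
  C \sum_j W_{ij}\, r^E_j(t - \tau_{ij}) + \xi + P\right),
\qquad
\tau_I \dot r^I_i = -r^I_i + F\!\left(c_{IE} r^E_i + \xi\right),
$$

with the sigmoid $F(x) = 1/(1 + e^{-(x-\mu)/\sigma})$. Long-range coupling
runs only between excitatory populations (long white-matter projections are
essentially excitatory), scaled by the global coupling $C$ and delayed by
$\tau_{ij}$, obtained from tract lengths via a conduction speed chosen so the
mean delay over connected pairs matches a configured value. $\xi$ is
independent Gaussian input noise of variance 0.01 per population and step.

Fixed parameters (`wc_config()` defaults): $\tau_E = 2.5$ ms, $\tau_I = 5$
ms, $c_{EE} = 3.5$, $c_{IE} = 3.75$, $P = 0.31$, $\mu = 1$, $\sigma = 0.25$.
With these time constants an isolated mass oscillates in the gamma band. The
Jacobian of the isolated two-population system shows a Hopf bifurcation; at
$c_{EI} = 2.5$ the onset sits at $P_c \approx 0.34$ with an onset frequency
of about 45 Hz, and just above onset the simulated spectral peak is ~40 Hz:

```{r gamma}
sim <- single_node_sim(P = 0.4, cei = 2.5, duration_s = 6, discard_s = 2)
spectral_peak(sim$rE[1, ], fs = 1000)
```

The free parameters are the global coupling $C \in [0.1, 14]$, the mean
delay (0-15 ms) and the homeostatic target rate $\rho \in [0.05, 0.3]$;
defaults are the working point $C = 4.07$, 4 ms, $\rho = 0.2$.

## Homeostatic scaling of inhibition

Local inhibitory weights adapt by synaptic scaling so that excitatory
activity tracks the target rate $\rho$:

$$\tau_{homeo}\, \dot c_{EI,i} = r^I_i\,(r^E_i - \rho),$$

clamped at zero (inhibition cannot become negative), with
$\tau_{homeo} = 2.5$ s. The steady state is invariant to $\tau_{homeo}$
(tested at 2.5 s vs 25 s) - the constant only sets how fast weights move.

**Which rates the rule senses.** A point that matters and is easy to miss:
with these parameters, any state with $r^E = 0.2$ is locally unstable
(the Jacobian trace $(-1 + c_{EE} F')/\tau_E - 1/\tau_I$ is positive
whenever $c_{EE} F' > 1 + \tau_E/\tau_I$, i.e. for all
$0.08 \lesssim r^E \lesssim 0.92$), so the operating regime is oscillatory.
If the scaling rule multiplies the *instantaneous* rates, its fixed point is
$\langle r^I (r^E - \rho)\rangle = 0$: it pins the $r^I$-weighted average of
$r^E$, and because $r^E$ and $r^I$ co-fluctuate over the gamma cycle the
plain time-mean rate lands far below $\rho$ (about a third below, in our
measurements). Biological synaptic scaling integrates activity over minutes
to days, far beyond a gamma period, so the implementation senses the rates
through an exponential moving average with time constant `tau_sense` (1 s by
default; still updated every Euler step). With slow sensing the fixed point
is the plain time-average, and after convergence every node's mean rate sits
within a couple of percent of $\rho$. Setting `tau_sense = 0` recovers the
literal instantaneous product for comparison.

**Steady-state detection.** Inhibitory weights are sampled every 10 s. The
trajectory counts as converged at the first window of consecutive samples in
which every node's within-window range, relative to
$\max(|c_{EI,i}|, 0.1)$, stays below `tol`. Two defaults encode what we
measured about the model's own noise floor: the tolerance is 0.02 (converged
weights keep wandering at the 0.5-1% scale per 100 s with the network's slow
state fluctuations, so a much tighter tolerance never triggers), and the
window spans $40\,\tau_{homeo}$ of simulated time (10 samples at the default
$\tau_{homeo}$), so that slower plasticity is not mistaken for a plateau
mid-ramp. For measurements that need the asymptote to better than 1%
(e.g. the $\tau_{homeo}$-invariance check), the recommended estimator is to
detect convergence, continue with plasticity for a further
$\sim 150\,\tau_{homeo}$ with `detect = FALSE`, and average the sampled
weights - across seeds this reproduces the steady state to ~0.2%.

## From rates to BOLD

Excitatory rates (recorded at 1 ms resolution, which keeps the 40 Hz
content with margin) drive a balloon-Windkessel model per region:
vasodilatory signal $s$, inflow $f$, venous volume $v$, deoxyhemoglobin $q$,

$$
\dot s = r^E - \kappa s - \gamma (f - 1), \quad \dot f = s, \quad
\tau_h \dot v = f - v^{1/\alpha}, \quad
\tau_h \dot q = f\,\frac{1 - (1-\rho_h)^{1/f}}{\rho_h} - v^{1/\alpha} \frac{q}{v},
$$

$$y = V_0\,(7\rho_h(1 - q) + 2(1 - q/v) + (2\rho_h - 0.2)(1 - v)),$$

with the standard constants $\kappa = 0.65\,s^{-1}$, $\gamma = 0.41\,s^{-1}$,
$\tau_h = 0.98$ s, $\alpha = 0.32$, $\rho_h = 0.34$, $V_0 = 0.02$. At rest
($s = 0$, $f = v = q = 1$) the output is exactly zero. BOLD is downsampled
to TR = 0.72 s (the HCP resting-state TR), the first 10 samples are dropped
(onset transient), and analyses run on a 0.01-0.1 Hz zero-phase 2nd-order
Butterworth band-pass, the standard resting-state band.

## The lesion protocol

`run_protocol()` implements the three-phase in-silico stroke:

1. **T0** - record the intact network at the converged weights, plasticity
   off.
2. Remove all connections of one region (`apply_lesion()`); the region stays
   in the simulation as an isolated, noise-driven node.
3. **T1** (acute) - record with plasticity still off.
4. Re-enable plasticity until the weights re-converge (or a configurable cap,
   flagged if hit).
5. **T2** (chronic) - record at the new weights, plasticity off.

Plasticity is disabled during all recordings so measured activity is not
confounded by weight drift. Lesioned regions are excluded from modularity and
small-world computations and, by default, from FC distance as well (so all
three time points are compared over the same node set; a flag includes them).

## Metrics

* **FC**: Pearson correlations between band-passed BOLD series.
* **FCD**: FC in windows of 80 samples with 80% overlap (step 16);
  correlations between windowed upper-triangular FC patterns.
* **Fit metrics**: FC correlation and MSE over upper triangles;
  Kolmogorov-Smirnov distance between FCD value distributions.
* **FC distance**: Frobenius norm of the FC difference. (The named norm
  includes the square root; a printed variant omitting it is not a metric
  and disagrees with reported magnitudes.)
* **Synchrony/metastability**: mean and SD over time of the Kuramoto order
  parameter computed on Hilbert phases of band-passed BOLD.
* **Avalanches**: per-node Z-scored series; events are first crossings of
  each excursion beyond ±2.3 SD (upward and downward excursions counted
  separately); an avalanche is a maximal run of consecutive 1-ms bins with
  at least one event network-wide.
* **Criticality $k$**: mean difference between the reference CDF (discrete
  power law, exponent -1.5, truncated at the network size) and the empirical
  avalanche-size CDF at 10 log-spaced points,
  $k = 1 + \frac1m \sum_n (F^{PL}(\beta_n) - F^{NA}(\beta_n))$. The sign is
  chosen so that an excess of small avalanches (subcritical) gives $k < 1$
  and an excess of system-size events $k > 1$; a printed form with the
  opposite orientation contradicts that reading, and the interpretation
  governs here.
* **Modularity**: $Q = \sum_u (e_{uu} - a_u^2)$ on density-thresholded
  binary graphs under a partition fixed a priori (consensus k-means on a
  baseline FC: k = 6, 200 restarts, co-assignment matrix re-clustered once),
  never re-optimised per network. Densities 4-40% in 2% steps.
* **Small-world**: $(C/C_{rand})/(L/L_{rand})$ versus Erdős-Rényi
  G(n, m) graphs with identical node and edge counts (resampled until
  connected), averaged over 100 draws; densities 20-40%, where thresholded
  graphs stay connected.
* **Excitability maps**: per-region percentage change of $c_{EI}$ between T0
  and T2 (negative = more excitable), their exponential fit against distance
  to the lesion ($a e^{-d/\lambda} + c$; the offset lets distant regions
  plateau at zero), the right/left motor asymmetry index
  $\frac{c_R(T2)/c_L(T2)}{c_R(T0)/c_L(T0)} - 1$, and sweep-level
  correlations with structural weight to the lesion and with lesion
  strength.

## The synthetic connectome

Tests and examples run on generated connectomes (`synth_connectome()`)
that emulate the statistical structure the analyses rely on:

* regions placed mirror-symmetrically in two 60 mm half-ball "hemispheres"
  80 mm apart, giving inter-regional distances (and hence delays) in the
  empirical cortical range;
* weights decaying exponentially with distance (default length constant
  40 mm, in the range reported for cortical connectomes), under
  multiplicative lognormal jitter ($\sigma = 0.5$, giving the heavy-tailed
  weight distribution characteristic of tractography);
* homotopic pairs boosted (×3) and always retained - interhemispheric
  mirror connections are disproportionately strong in real connectomes;
* thresholded to 50% density, tract lengths equal to Euclidean distances;
* weights normalised to unit mean node strength. This normalisation is what
  lets the working point $C = 4.07$, $\rho = 0.2$, 4 ms carry over to
  generated fixtures: simulations there sit in the same regime of
  partially-synchronised, metastable, near-critical dynamics that makes the
  working point interesting, which the acceptance suite verifies
  quantitatively. Without a strength convention the same $C$ can land the
  network in a bistable saturating regime.

The default fixture has 16 regions (desk scale; generation supports any even
count) versus 78 in a full cortical parcellation. What the generator does
*not* emulate: realistic tract geometry (lengths are straight-line),
subject variability, the empirical community structure of cortical FC, or
distance-dependent tract-length/weight correlations beyond the exponential
rule. Passing tests on synthetic fixtures therefore validate the machinery
and the qualitative lesion phenomenology, not any claim about a specific
empirical connectome.

## Numerical choices

* Euler integration at dt = 0.2 ms (5 kHz); halving dt changes noise-free
  trajectories by well under 1% RMS (tested).
* Delays rounded to the nearest integer step, minimum one step for connected
  pairs when a nonzero mean delay is requested; the delay buffer is
  initialised with the initial rates to avoid a spurious zero-input
  transient, and the first seconds of every recording are discarded anyway.
* Noise is injected inside the sigmoid argument, independently per node,
  population and step, with SD 0.1, *not* scaled by $\sqrt{dt}$ - the
  discrete input-fluctuation convention of the neural-mass lineage this
  model follows.
* Initial conditions are deterministic ($r^E = r^I = 0.1$, $c_{EI} = 1$);
  the homeostatic steady state is insensitive to them (tested: initialising
  at 0.5 vs 3.5 changes the steady state by ~0.2%).
* All randomness flows through R's RNG; every user-facing function takes a
  seed, sweeps derive per-lesion seeds from (master seed, node), and
  repeated runs are bit-identical.
* Ties at density-threshold cutoffs are broken by a stable sort on
  (value, row, column).
* k-means consensus uses `stats::kmeans` with seeded restarts; the final
  partition clusters the co-assignment matrix once.

## Problem sizes

The shipped tests and the acceptance analysis run at desk scale, chosen to
exercise every stage of the full protocol: 16-region fixtures, 5-minute
recordings, a 50-minute cap on re-stabilisation, 5 lesions × 3 seeds for
directional statistics, and a 3×3 mini-grid for the parameter-recovery
check. The full-scale settings (78 regions, 30-minute recordings, 500-minute
caps, all-node sweeps, 25×26×16 grid) are plain configuration changes; the
procedures are identical.

## Known limitations

* Single-node lesions only; no volumetric or white-matter (edge) lesions.
* Only inhibitory-weight homeostasis; no excitatory scaling, intrinsic
  excitability regulation, or structural plasticity.
* One conduction velocity for all tracts.
* Homogeneous hemodynamics across regions.
* Euler is the only integrator (matching the reference procedure); the
  stochastic term is a discrete-time convention, so trajectories are
  comparable across dt only in the noise-free case.
* With instantaneous-rate plasticity (`tau_sense = 0`) the controlled
  quantity is the inhibition-weighted mean rate, not the mean rate; see
  above.
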