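---
title: "Self-organisation of neural assemblies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organisation of neural assemblies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hebbnet` simulates how neural assemblies — groups of neurons that activate
together in synchronous bursts — can emerge in a developing circuit that
receives no structured afferent input, purely from the interaction of
spontaneous activity, Hebbian plasticity and synaptic normalisation. This
vignette is the package's own account of the model, the analysis methods, the
choices we made where the design was genuinely open, and what the bundled
tests do and do not establish.

## The network model

The population consists of `N_e` excitatory and `N_i = N_e / 4` inhibitory
binary neurons, fully connected without autapses. Activity updates
synchronously: every neuron computes, from the previous state vector,

    x_i(t+1) = Theta( sum_j w_ij^(XE) x_j^E(t) - sum_j w_ij^(XI) x_j^I(t)
                      + beta_i(t) - theta )

where `Theta` is the Heaviside step function and `theta` the activation
threshold. The noise term `beta_i(t)` equals `1 + theta` with a per-neuron
probability `p_i ~ N(mu, sigma^2)` (clamped to `[0, 1]`) and `0` otherwise;
a noise event therefore guarantees activation regardless of synaptic input,
and drives all spontaneous activity. We take `Theta(0) = 0`: a neuron fires
only if its net input strictly exceeds the threshold. One timestep represents
one second of model time, which is also why the analysis functions treat a
raster column as one second by default.

Excitatory-to-excitatory synapses are plastic. At every step, after the
running activity means `<x_i>_t` (arithmetic means over steps `1..t`,
maintained online and *including* the current state, which is what the rule
below requires) have been updated, every off-diagonal EE weight changes by the
covariance rule

    dw_ij = eta * (x_i(t) - <x_i>_t) * (x_j(t) - <x_j>_t)

with a lower saturation at 0. The weights are then renormalised in two steps:
each *column* is divided by its sum (presynaptic competition: a neuron's total
output is rescaled), then each *row* (postsynaptic: each neuron's summed input
becomes exactly 1, so `theta` is always a fixed proportion of the maximal
input). Rows or columns that are entirely zero are skipped rather than
divided, so fully silenced synapses stay at zero instead of producing NaNs.
The normalisation implicitly bounds every weight by 1. EI, IE and II blocks
are initialised from U(0,1), normalised once per block with the same two-step
rule, and stay fixed.

Per-timestep order of operations: dynamics, running means, covariance update,
clamp at 0, two-step normalisation, and (spatial variant) the distance cap.

Default parameters of the basic model: `N_e = 100`, `N_i = 25`,
`eta = 0.03`, `mu = 4e-3`, `sigma = 3e-4`, `theta = 0.1`, 100,000 steps.
`eta` and `theta` set the *structural* properties of the mature network
(assembly count, within-assembly strength), while `mu` mostly sets the
*speed* of development.

### Spatial variant

The spatial variant places the excitatory neurons on a square toroidal grid
(row-major mapping, neuron `i` at `((i-1) mod L, (i-1) div L)`) and caps
every EE weight at `w_max(d) = a * exp(-d^2 / (2 kappa^2))`, with `d` the
Euclidean distance under periodic boundary conditions. Standard values:
`N_e = 1024`, `N_i = 256`, `eta = 0.04`, `mu = 2e-3`, `a = 0.1`,
`kappa = 3`. Inhibitory neurons have no coordinates and innervate every
excitatory neuron. The cap is applied *after* each normalisation cycle, so a
capped row may sum to slightly less than 1; the alternative (cap before
normalising, or iterating cap and normalisation to a fixed point) would
redistribute the capped mass but breaks the cap itself, and at the standard
parameters the chosen order is stable. This ordering is a genuine open point
of the model description and is the one place where the row-sum invariant is
deliberately relaxed.

## Structural analysis

**Modularity.** Community structure is always assessed on the symmetrised
matrix `w~ = w + t(w)` (the plasticity rule is symmetric and the two-step
normalisation spreads weight both ways, so mature matrices are nearly
symmetric already). We implement standard Newman–Girvan weighted modularity:
with `S` the total weight over ordered pairs and `k_i` the node strengths,

    Q = (1/S) * sum_{ij in same community} ( w~_ij - k_i k_j / S ).

On `k` disconnected equal communities this gives `Q = 1 - 1/k` (0.8 for five
assemblies), which matches both the magnitudes modular networks reach in
practice and the convention of the widely used Louvain implementations — this
is the convention `detect_assemblies_weights()` optimises. A literal
alternative normalisation that halves the prefactor and the null term
(yielding `1/2 - 1/(4k)` on the same case) is available as
`modularity_q(..., variant = "methods")` for comparison; we do not use it
anywhere else because its scale is inconsistent with the Louvain convention.

**Assembly detection from weights.** `detect_assemblies_weights()` runs
igraph's Louvain greedy modularity maximisation under several seeded random
node permutations (default 10 restarts) and keeps the partition with the
highest `Q` as evaluated by our own modularity function. Every community
counts as an assembly — no minimum-size filter. Communities are relabelled by
their smallest member, so the output is stable under neuron relabelling.

**Eigengap.** With `k` the number of detected assemblies, the eigenvalues of
the *raw* (non-symmetrised) EE matrix are sorted by descending real part
(ties broken by descending imaginary part; mature spectra are effectively
real, so the tie-break rarely matters) and
`delta_lambda = Re(lambda_k) - Re(lambda_{k+1})`. As assemblies strengthen,
`k` eigenvalues detach from the spectral band and the gap widens.

**Size dispersion.** `assembly_size_cv()` uses the sample (n−1) standard
deviation of assembly sizes over their mean.

## Activity analysis

**Binarisation and events.** A dF/F trace is active where it exceeds its own
mean by two standard deviations. An assembly *event* is a local maximum of
the assembly's active-member count at which at least 50% of members are
active, with events at least 5 frames apart. The model description does not
say how to resolve two qualifying peaks closer than 5 frames; we select
greedily by descending peak height (plateaus keep their first index), which
guarantees both rules hold on every output and keeps the taller peak in a
conflict.

**Best match and autosimilarity.** Two collections of assemblies are compared
by the symmetric best-match score built from maximal pairwise Jaccard
overlaps; it is 1 exactly on identical collections and 0 when all pairs are
disjoint. An empty collection scores 0 against anything, which keeps the
autosimilarity defined on degenerate samples. The autosimilarity experiment
samples the detected assemblies every 1,000 steps after a 100,000-step
formation period and averages the best-match score over all sample pairs at
each lag; one Louvain seed is shared across samples so that identical weight
matrices always produce identical partitions (a frozen network then has a
constant curve, as it must). The decay curve is fit by Levenberg–Marquardt
nonlinear least squares to `y = b0 + b1 * exp(-dt / tau)` with data-driven
starting values (baseline `min(y)`, amplitude `max(y) - min(y)`, decay a
third of the lag range) and jittered restarts; constant curves are flagged
degenerate rather than fitted.

**ICA detection.** The activity-based detector z-scores each neuron, counts
correlation-matrix eigenvalues above the Marchenko–Pastur upper bound
`(1 + sqrt(n/T))^2` to estimate the assembly count, whitens onto that many
principal components, and runs symmetric FastICA with the logcosh contrast
(implemented in-package). A component's assembly is the set of neurons whose
loading magnitude exceeds two standard deviations of that component's
loadings, after aligning each component's sign so its largest-magnitude
loading is positive. On weight matrices with embedded assemblies, Louvain on
the weights matches or beats ICA on a 10,000-step activity raster in
essentially every condition — ICA needs the assemblies to actually *activate*
during the sampled window, which weakly modular networks rarely do.

**Stimulation probe.** To measure how many neurons ignite an assembly, the
weights are frozen, background noise is disabled, and every combination of
1, 2 or 3 members (an exact enumeration, or a seeded subsample above 2,000
combinations per assembly) is forced active at `t = 0`. A trial triggers if
the *complete* assembly — all members simultaneously active; the required
fraction is configurable because "complete" is an operational choice the
probe statistics are sensitive to — occurs within 20 steps. Activation is
transient: once the full assembly fires, the inhibitory population shuts the
burst down a couple of steps later, so completion is checked per step, not at
the horizon.

## The synthetic calcium fixture

`generate_dff_fixture()` emulates a dF/F recording at 1 s resolution with a
known answer: `k` disjoint assemblies partition the population, each fires
synchronous unit-amplitude events at Poisson times thinned to a minimum
5-frame separation, and each member's trace is the event train convolved with
an `exp(-t / tau)` kernel plus Gaussian noise (defaults: 100 neurons, 5,000
frames, 5 assemblies, rate 0.01/frame, `tau = 2` frames, noise SD 0.1 —
chosen once as representative of nuclear GCaMP kinetics and imaging noise at
this timescale). It deliberately does *not* model per-neuron amplitude
variability, partial assembly participation, overlapping assemblies, neuropil
contamination or slow drift; tests passing on the fixture show the analysis
chain is correct, not that it is robust to every artefact of real imaging
data.

## Problem sizes and what the tests establish

The bundled tests and the acceptance script run the full study at desk scale,
chosen so the whole suite completes in a few minutes: 10–20 independent
100,000-step developmental runs (the original dispersion figure pooled 1,000),
a 40,000-step post-formation autosimilarity horizon sampled every 1,000 steps,
and stimulation probes pooled over 20 mature networks. At these sizes the
mean assembly-size CV lands at ~0.19, the pooled single/pair/triple
triggering fractions at ~0 / 16–25 / 84–87%, and the exponential fit's R² at
0.99+. Pair fractions deserve a caveat: they depend strongly on the detected
assembly count of each network (networks that settle at 4 large assemblies
yield far fewer igniting pairs than networks with 5 smaller ones), so they
are the most seed-sensitive statistic in the package and are pooled over
trials across many networks for that reason. The 200-day co-membership
experiment and the 1,000-run CV histogram are supported by the same functions
(`co_membership()`, `run_development_experiment()`) but are not desk-scale
defaults.

## Known limitations

- Binary threshold units: no conductances, no spike timing, no calcium
  forward model inside the simulator.
- Only EE synapses are plastic; there is no inhibitory or homeostatic
  plasticity (the one-second timestep keeps the network stable without them).
- The spatial variant's cap-after-normalisation ordering relaxes exact row
  stochasticity (see above).
- Louvain is a greedy heuristic: on near-unstructured matrices different
  restarts can return different near-optimal partitions, which is why
  detection seeds are explicit everywhere reproducibility matters.
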