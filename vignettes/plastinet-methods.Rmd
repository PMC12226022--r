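---
title: "plastinet: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plastinet: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the plasticity
model and its assumptions, the reduced voltage driver that replaces a
morphologically detailed circuit, the calibration of the shipped defaults,
the analysis pipeline's statistical choices, and the limits of what the
synthetic-data tests demonstrate.

## 1. The calcium-based plasticity model

Synaptic efficacy $\rho \in [0,1]$ follows a bistable cubic with two
Heaviside drive terms,

$$\tau \dot\rho = -\rho(1-\rho)(\rho_*-\rho)
  + \gamma_p (1-\rho)\,\Theta(Ca^* - \theta_p)
  - \gamma_d \,\rho\,\Theta(Ca^* - \theta_d),$$

with $\tau = 70$ s, $\rho_* = 0.5$, $\gamma_d = 101.5$, $\gamma_p = 216.2$.
With no calcium drive, trajectories converge to 0 or 1 according to the
side of $\rho_*$; `rho_separatrix()` recovers the boundary by bisection.
Near the separatrix the linearised growth rate is
$\rho_*(1-\rho_*)/\tau \approx 1/280\ \mathrm{s}^{-1}$, and close to the
stable points the relaxation rate is $\rho_*\,/\tau \approx 1/140$ s$^{-1}$:
from $\rho(0)=0.9$ the exact solution reaches $1 - 1.9\times10^{-3}$ after
600 s — convergence to within $10^{-3}$ of the fixed point takes roughly
650 s, which matters when asserting "arrival" at an attractor after a fixed
horizon.

Spine calcium is a leaky integrator of NMDA and VDCC influx,
$\dot{[Ca]} = (I^*_{NMDA} + I_{VDCC})\,\eta/(2FX) - ([Ca]-[Ca]_0)/\tau_{Ca}$
($\eta = 0.04$, $\tau_{Ca} = 12$ ms, $X$ the spine volume), and $Ca^*$ is a
second leaky integral of the calcium excess with $\tau^* = 278.318$ ms. The
NMDA current uses the Jahr–Stevens magnesium block with the cortical refit
$\theta = 2.552$, $\kappa = 0.072$ and reversal $E_{NMDA} = -3$ mV.

Two printed values deserve comment:

* **Resting calcium.** The source prints 70 pM, three orders of magnitude
  below typical resting calcium. The default is `ca_rest = 0.07` µM; the
  pM-scale value remains reachable through configuration. Because both
  calcium equations act on the *excess* over rest, this choice is an offset
  convention and does not change any reported dynamics.
* **$E_{NMDA} = -3$ mV** is unusual for an NMDA reversal potential; it is
  implemented as printed and configurable. The calcium current uses the
  influx-positive convention $I^* = g\,m(V)\,(E_{NMDA}-V)$, clamped at zero
  above reversal so depolarisation with open channels always means influx.

Efficacy is converted into the release probability $U_{SE}$ and the peak
AMPA conductance by exponential relaxation (τ = 100 s) toward
endpoint-interpolated targets, continuously at every integration step; at
export the peak NMDA conductance is rescaled in proportion to the
rho-interpolated AMPA target. Short-term (Tsodyks–Markram) release dynamics
are *not* simulated: network spiking here is synthetic input, so release
dynamics would have no consumer; $U_{SE}$ is carried as a plasticity output
only, with the extracellular-calcium effect reduced to a configurable
multiplicative scale (`use_ca_scale`).

## 2. The reduced voltage driver

The source model computes local dendritic voltage in full morphologies. Here
each synapse sees a kernel model with three mechanisms:

* a presynaptic spike (after a 1 ms delay) opens a double-exponential NMDA
  conductance (2/65 ms) and deposits a local EPSP kernel (1/20 ms, 8 mV);
* a postsynaptic spike deposits a back-propagating action potential kernel
  (0.5/5 ms, 45 mV at the branch origin) attenuated as
  $e^{-d/\lambda}$ with $\lambda = 200$ µm of path offset, and an
  instantaneous VDCC calcium impulse (0.1 µM) attenuated the same way.

The short BAP decay keeps the coincidence window asymmetric: a BAP arriving
~10 ms after NMDA opening rides on a large conductance, whereas a BAP 10 ms
*before* transmitter release has mostly decayed, which yields the causal
timing preference checked in the tests. Kernel parameters are effective
constants of the reduced driver, not measurements; they are all explicit
configuration.

With the defaults, a lone presynaptic spike produces a ~13 µM calcium peak
(`c_pre`) and a lone postsynaptic spike ~0.1 µM (`c_post`), preserving the
two-orders-of-magnitude dominance of presynaptically evoked transients that
the full model reports (three orders there; the reduced driver guarantees
at least two).

## 3. Threshold calibration

The fitted 2×2 matrices mapping $(c_{pre}, c_{post})$ to
$(\theta_d, \theta_p)$ are not public. `calibrate_threshold_matrix()`
derives defaults from three protocols on a reference synapse: (i) a lone
presynaptic spike must cross neither threshold, (ii) a single coincident
pre+post pair (10 ms lag) must cross only $\theta_d$, (iii) ten coincident
pairs at 50 Hz must cross $\theta_p$. Thresholds are placed at the
geometric midpoints of the corresponding peak $Ca^*$ values and expressed
per unit of the synapse's own transients (98 % carried by the $c_{pre}$
column, 2 % by $c_{post}$), so attenuated distal synapses scale their
thresholds down. The shipped defaults are the frozen output of this
helper; apical and basal matrices start identical because the generator
gives both neurite classes the same kernel family.

A consequence worth knowing: because the single-pair $Ca^*$ peak exceeds
the lone-spike peak by only ~40 %, $\theta_d$ sits close above the
single-spike response, and *pairs of presynaptic spikes* arriving within a
few hundred milliseconds can also cross $\theta_d$ through $Ca^*$
summation. The full model is sparser in practice because release is
stochastic and transients are dendritically filtered; the reduced driver
transmits every spike. Analyses at desk scale therefore keep background
rates low (≤ 2 Hz) and, for direction checks, classify "changed" with a
magnitude criterion (section 6).

## 4. Numerical scheme

Operator splitting at `dt = 0.1` ms: the two linear calcium equations use
exponential Euler (exact for piecewise-constant drive), the cubic uses
forward Euler clamped to $[0,1]$, and the Heaviside terms are evaluated on
the post-step $Ca^*$. Kernel states are pairs of exponentials updated by
per-step decay factors and incremented at (step-quantised) spike times, so
cost is strictly linear in steps and spikes. Halving `dt` on a burst-pairing
protocol moves the final $\rho$ by under $10^{-4}$; the inner loop is
compiled (Rcpp), and a pure-R reference integrator at `dt/10` agrees to
$5\times10^{-3}$ in the tests. Non-plastic synapses carry sentinel
thresholds of −1, which the integrator treats as "never crossed" (a negative
threshold would otherwise *always* be crossed, since $Ca^*$ is bounded below
by $-[Ca]_0\tau^*$).

## 5. Synthetic-data generator: what it emulates

* **Network**: nodes in a cylinder with six layer strata (uniform by
  default — only the labels, not the geometry, enter the analyses), edges
  drawn independently with a distance-decaying probability. Expected edge
  count is the sum of pairwise probabilities, which the tests check to 3σ.
* **Synapses per connection**: the study conditions state moments
  (4.1 ± 2.3) only. A one-parameter shifted geometric cannot match both
  (matching the mean forces SD ≈ 3.3 after truncation), so the law is a
  shifted negative binomial truncated to [1, 20] — the family containing
  the geometric — moment-matched numerically. Branches are abstract 1-D
  segments (200 µm, 20 per neuron), apical with probability 0.3 per
  post-synaptic layer.
* **Stimulus patterns**: fibers get 2-D flat-map locations, k-means bundles
  (100 by default), four disjoint base patterns of 12 % of bundles each and
  the six standard unions (E = A∪B, F = B∪C, G = C∪D, H = A∪B∪C,
  I = B∪C∪D, J = all), so H and I share two thirds of their bundles.
* **Stimulus spikes**: the adapting stimulus process is replaced by a
  three-parameter profile — linear rise over 10 ms to the 17.5 Hz peak,
  exponential adaptation with τ = 50 ms over the 100 ms stimulus — sampled
  as an inhomogeneous Poisson process by thinning. The nonspecific fiber
  group fires the same profile at half the peak rate for every
  presentation. Bouton-density depth profiles are *not* reproduced;
  fiber-to-neuron innervation in the scenarios is uniform.
* **Planted activity**: groups of neurons assigned to (pattern, 20 ms
  latency window) slots fire at an elevated rate inside their windows over
  a Poisson background, giving ground truth for recovery scoring.
* **Initial states**: every synapse starts at a fixed point, potentiated
  with a pathway-dependent probability, with $U_{SE}$ and AMPA conductance
  at the matching endpoints.

All generators are bit-identical under a fixed seed.

## 6. Analysis pipeline choices

* **Significant bins**: "shifted by any amount" is implemented as a
  per-neuron circular shift uniform over the recording, preserving each
  neuron's rate and ISI structure. The threshold statistic — ambiguous in
  prose — is resolved as mean population rate plus the 95th percentile,
  over 100 shuffles, of the standard deviation of the shuffled
  population-rate trace; both components are attached to the mask.
* **Clustering**: Ward linkage (`ward.D2`) on 1 − cosine of activation
  vectors (per-neuron counts, not binarised); the cluster number scans
  5–20 by default and minimises the Davies–Bouldin index computed with the
  standard Euclidean definition (a documented metric mismatch with the
  cosine linkage); ties break toward smaller k. Recovery tests scan 2–10
  because they plant fewer than five assemblies.
* **Membership**: neuron-to-cluster correlations use the *binary* cluster
  activation series (config-switchable); the shuffle null samples 1000
  circular shifts from the exact all-shift correlation set computed by FFT
  cross-correlation. Because membership admits ~5 % of unrelated neurons
  by construction (95th-percentile rule), recovered-membership Jaccard
  scores land near $|G|/(|G| + 0.05 N_{noise})$ for planted groups of size
  $|G|$; scenarios keep the unplanted population small enough that this
  stays above 0.9.
* **Synapse clusters**: along-branch distances equal Euclidean distances
  because generated branches are straight. Significance uses consecutive
  inter-synapse gaps, which are iid exponential under a homogeneous
  Poisson placement, so the sum of a cluster's gaps is compared against
  the lower Gamma tail with the rate fitted from all same-branch gaps on
  the neuron; this makes the null p-values uniform by construction (the
  tests verify with a KS test at 1000 draws). The synaptic clustering
  coefficient — defined in a companion study, not printed — is implemented
  as a sign-flipped z-score of the mean nearest-neighbour distance among
  assembly synapses against 1000 random same-size subsets, and is
  config-replaceable.
* **Change classification**: a synapse or connection counts as changed
  when $|\Delta\rho|$ between first and last report exceeds a tolerance,
  $10^{-3}$ by default. In the desk-scale direction-check scenarios the
  tolerance is raised to 0.2: with deterministic release, a single stray
  coincidence already moves $\rho$ by $\sim10^{-1}$ (section 3), and the
  magnitude criterion separates saturated induction from stray drift.
* **Distances**: input distances are exact earth mover's distances between
  pattern fiber clouds — uniform masses replicated to the least common
  denominator and solved as an assignment problem with an in-package
  Hungarian solver (cross-checked against brute-force transport and an
  independent assignment library); clouds whose replicated size exceeds
  600 points fall back to a Sinkhorn approximation, flagged on the result.
  Output distances over mean-efficacy vectors offer Euclidean, changed-flag
  Hamming, and 1-D EMD variants; all-connection (not changing-only)
  indexing is used. The input–output correlation is Pearson on condensed
  upper triangles with a Mantel-style permutation p-value (10⁴ label
  permutations by default; the test statistic's null is calibrated in the
  tests).
* **Probability-of-change curves** use integer bins when the metric tops
  out at 12 (k-edge indegrees at desk scale) and logarithmic bins above,
  suppressing bins under 50 edges (configurable; scenarios use 30).
* **STDP control**: all-to-all pairing by default (the classic rule;
  nearest-neighbour available), weights unbounded, depression accumulated
  as negative updates on the same scalar weight. Simplices: reciprocal
  edges count as two directed edges; self-loops are rejected; enumeration
  is vertex-ordered DFS over intersected out-neighbourhoods with `k_max`
  6 and early stop at the first empty dimension.

## 7. Problem sizes and runtimes

The shipped tests run: single-synapse induction protocols (15–60 s of
biological time, seconds of wall time); assembly recovery on 150-neuron
networks with 12–15 presentations of 3 patterns across 20 seeds; topology
oracles on 100 random graphs of 5–12 nodes; a 100-neuron co-firing
scenario (30 s biological, ~900 synapses) and a six-condition thalamic
drive scenario (40 neurons × 25 fibers each, ~4.7 s per condition). These
sizes were chosen so the full suite completes in a few minutes on one CPU
while every direction check retains a large planted effect.

## 8. What passing tests do and do not show

The generators emulate the *structure* of the study conditions (layered
connectivity, multi-synapse dendritic placement, overlapping patterns,
assembly sequences), not the biophysics of a full circuit: there is no
recurrent spiking dynamics (activity is prescribed, not emergent), no
stochastic release, no dendritic nonlinearities beyond the kernel driver,
and no morphology. Consequently the headline circuit-scale numbers of the
source study (overall change fractions near 7 %, input–output correlation
r = 0.716, layer-wise percentages) are *not* reproduced here and are
treated as qualitative direction checks only: sparser/specific changes for
assembly and high-edge-centrality synapses, positive input–output distance
correlation, timing-asymmetric induction. Quantities that are exact
properties of the model itself — the separatrix, STDP update magnitudes,
pattern algebra, null calibrations, brute-force topology equivalence — are
asserted at tight tolerances.
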