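---
title: "A spiking-network multivariate classifier modelled on the insect antennal lobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking-network multivariate classifier modelled on the insect antennal lobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alclassify)
```

## The model

`alclassify` implements a generic multivariate classifier built from a
spiking neural network whose architecture abstracts the insect olfactory
system, in particular the antennal lobe. The design separates three
concerns:

1. **Encoding.** Real-valued samples in $[0,1]^d$ are projected onto a set
   of $N_{VR}$ *virtual receptors* (VRs): points in feature space placed by
   the neural gas vector-quantization algorithm, fitted on the training
   split alone. Each receptor responds through a cone-shaped radial basis
   function
   $$r_i(x) = \max\!\left(0,\; 1 - \frac{d(x, w_i)}{\sigma}\right),$$
   giving large, overlapping receptive fields. Responses map affinely onto
   firing rates in $[f_{\min}, f_{\max}]$, and each rate drives a cluster
   of stochastic *receptor neurons* (RNs) as a population rate code,
   realized by Poisson (per-step Bernoulli) or Gamma-renewal spike
   generation.

2. **Network.** A three-layer network of leaky integrate-and-fire (LIF)
   neurons with exponential current-based synapses, integrated
   clock-driven with exponential-Euler updates. RN clusters excite
   matching *projection neuron* (PN) clusters one-to-one; PN clusters
   inhibit each other laterally (decorrelation and sparsening of the
   receptor code); PNs project all-to-all through the single plastic
   weight matrix onto *association neuron* (AN) clusters, one per class,
   which compete through strong mutual inhibition — a winner-take-all
   circuit. The class decision is the AN cluster with the highest spike
   count during a sample's presentation window.

3. **Learning.** Two supervised schemes train the PN→AN matrix:
   * **Symmetric STDP with a teaching signal** (continuous-run
     semantics): weights start at zero; one uninterrupted simulation
     presents every training sample for 120 ms followed by a 20 ms
     silence, while a Poisson teaching signal stimulates the correct AN
     cluster. The STDP curve is symmetric — every nearest-neighbour
     pre/post pairing within ±10 ms adds the same increment $a_+$,
     regardless of order — so co-activity of a PN and the taught AN
     cluster strengthens their connection (supervised Hebbian
     association). Weights are clipped to $[0, w_{\max}]$.
   * **Per-sample perceptron rule** (stepped semantics): each sample is
     presented for 500 ms to a freshly reset network with frozen weights;
     at the end of the presentation, a misclassified sample triggers an
     error-driven, cluster-granular update
     $\Delta W_{i,\text{true}} = +\eta\, a_i$,
     $\Delta W_{i,\text{pred}} = -\eta\, a_i$, with
     $a_i = c_i / \max_j c_j$ the normalized PN-cluster spike counts, and
     the full matrix is replaced atomically (clipped to $[0, w_{\max}]$).
     Weights are initialized uniformly on $[0, 0.1\,w_{\max}]$.

Testing is in both modes a single pass over the test set with plasticity
disabled.

## Why these defaults

The design the package follows deliberately specifies control flow and
contracts but leaves many numerical constants open; the values below are
the package's own choices, each with its reasoning.

**Neuron and synapse constants.** $\tau_m = 20$ ms, $V_{rest} = -65$ mV,
$V_{thresh} = -50$ mV, $V_{reset} = -70$ mV, $t_{ref} = 2$ ms,
$R_m = 40\,\mathrm{M\Omega}$, $\tau_{syn} = 5$ ms (excitatory) / 10 ms
(inhibitory): conventional cortical-model values. With them, a single
suprathreshold afferent at 70 Hz and weight 2 nA drives its LIF partner
at roughly 45 Hz — a workable population rate code at the 1 ms timestep.

**Rate bounds.** $f_{\min} = 0$, $f_{\max} = 70$ Hz keeps the per-step
Bernoulli probability at 0.07 for $dt = 1$ ms, well inside the validity
of clock-driven Poisson generation.

**Lateral inhibition.** Expressed as two scalars with the AN stage an
order of magnitude stronger than the PN stage: the PN stage *sparsens*,
the AN stage *decides*. Both per-synapse weights are normalized by the
number of competing clusters ($-0.1/(N_{VR}-1)$ and
$-4/(n_{classes}-1)$), so the total inhibition a neuron receives from one
fully active rival cluster does not grow with network size. Without this
normalization the PN layer falls silent at large receptor counts, which
would contradict the architecture's central scaling property (accuracy
should not degrade as receptors are added).

**STDP.** $a_+ = w_{\max}/200$, window ±10 ms, $w_{\max} = 0.25$ nA.
Nearest-neighbour pairing bounds the per-spike update; the narrow window
plus the 20 ms inter-sample silence confines pairings to one sample. With
$w_{\max} = 0.25$ and 30-neuron clusters, a fully potentiated PN cluster
firing at ~40 Hz injects ~1.5 nA into each AN neuron — reliably
suprathreshold against the winner-take-all inhibition.

**Teaching signal.** 200 Hz Poisson per AN neuron at weight 2 nA: strong
enough to force postsynaptic firing in the taught cluster against WTA
suppression, so the supervised pairings exist from the first sample even
with zero-initialized weights.

**Perceptron.** $\eta = 0.01$ (4% of $w_{\max}$ per unit activity): large
enough to converge in a single pass over a few hundred samples, small
enough not to oscillate on the easy benchmarks.

**Small-population ("spikey") preset.** Mirrors a 192-neuron mixed-signal
device: 6 RNs, 7 PNs, 8 ANs per cluster, with explicit inhibitory
local-interneuron populations (6 and 8 neurons per cluster, matching the
raster-plot banding of the hardware implementation) mediating both
inhibition stages. Input defaults to a Gamma process of order 5 — more
regular trains and lower spike-count variability than Poisson, which
matters when a population rate must be read from only 6–8 neurons — with
1 s presentations. The plastic bound rises to $w_{\max} = 1.5$ because
the plastic fan-in is roughly twenty times smaller.

**Neural gas.** $\varepsilon: 0.5 \to 0.01$,
$\lambda: N_{VR}/2 \to 0.01$, both decayed exponentially over
$20\,n$ sample presentations drawn with replacement; centroids
initialized as random training samples. These are the standard schedules
from the vector-quantization literature. $\sigma$ defaults to the
maximum pairwise centroid distance (maximally overlapping fields) and is
configurable; the cone response itself is the simplest function matching
the "proportional to proximity, cut off at a radius" contract.

## What the synthetic generator emulates — and what it does not

`make_synthetic()` places $k$ class means on a regular simplex centred in
the unit cube (all pairwise distances equal to `separation`), draws
isotropic Gaussian samples with `noise_sd`, clips to $[0,1]^d$, and
returns the samples in randomized interleaved class order. Interleaving
matters: a class-blocked traversal starves an error-driven rule of
training errors (the winner-take-all output simply tracks the current
block), which no real benchmark traversal exhibits.

The generator exercises everything the pipeline does — receptor
placement, encoding, competition, both learning rules, scaling — under
controlled difficulty, but it is *not* image data: it has no correlated
pixel structure, no class-conditional manifolds, and its noise is
isotropic. Passing the suite therefore demonstrates the mechanism, not
digit-recognition performance. One consequence worth noting: in 784
dimensions the total noise norm is `noise_sd`·√784, so a per-feature
noise that is trivial in 10 dimensions can exceed the class separation
entirely in 784; the high-dimensional IDX-format checks use
`noise_sd = 0.02` for that reason.

## Numerical choices

* **Integration** is exponential-Euler for membrane and synapse — exact
  for piecewise-constant input — with synaptic impulses adding their full
  weight (the injected charge per spike is exactly the weight, which the
  test suite checks by charge accounting). Holding the current constant
  within a step over-integrates by $O(dt/2\tau_{syn})$; near rheobase the
  steep f–I curve amplifies this, so dt-robustness is asserted in a
  robustly driven regime (well above rheobase), where halving $dt$ from
  1 ms to 0.5 ms shifts output counts by ~5%.
* **Delays** are uniformly one timestep; delays play no functional role
  in the model.
* **Refractoriness** holds the membrane at $V_{reset}$ for
  $\mathrm{round}(t_{ref}/dt)$ steps; no neuron can emit two spikes
  closer than $t_{ref}$ (asserted as an invariant).
* **Ties** in the winner-take-all readout break deterministically to the
  lowest cluster index by default (a seeded-random rule is available);
  ties are flagged on the returned decision. A window with no output
  spikes is *undecided*: scored as an error, tallied separately, excluded
  from the confusion matrix (whose rows therefore sum to per-class
  *decided* counts).
* **Determinism.** Every stochastic operation takes an explicit seed; a
  run-level master seed derives per-component seeds by fixed offsets.
  The simulator itself is deterministic — all randomness lives in spike
  generation — so a full run is bit-identical under the same
  configuration and seed.
* **Grid snapping** of Gamma-renewal spike times floors onto the
  simulation grid and merges same-step duplicates, keeping event lists
  valid at any supported $dt \in \{0.1, 0.5, 1\}$ ms.

## Problem sizes used by the test suite

The suite runs entirely on generated data: two-class Gaussian benchmarks
(separation 0.8, noise 0.05, 10-d, up to 100 train + 100 test per class),
a harder four-class task (separation 0.45, noise 0.15) for the
receptor-count scaling comparison over five seeds, orthogonal-pattern
pairs in 2-d for STDP association (receptor cutoff $\sigma = 0.3$, below
the 0.6 class separation, so the two active receptor sets are disjoint),
and a 784-dimensional two-class stand-in shipped through the binary IDX
image format for the external-data path. Spike-statistics checks use
single neurons over 200 s horizons. These sizes keep the whole suite
within a few minutes while leaving every statistical margin wide (e.g.
binomial concentration bounds at 4 standard deviations).

## Known limitations

* Rulkov map neurons are not implemented; LIF is used uniformly. The
  platform-comparison context this design comes from found classification
  performance implementation-independent, so this choice does not affect
  the classifier's behaviour of interest.
* The shared-Poisson-pool input trick used on real-time digital hardware
  is replaced by direct per-neuron stochastic generation, which provides
  the same population rate code without the platform constraint.
* No conductance-based synapses, axonal-delay heterogeneity, or
  three-factor (reward-modulated) plasticity.
* With hard winner-take-all readouts and error-driven learning, runs on
  label-shuffled data are individually all-or-nothing (the network locks
  onto an arbitrary mapping); chance-level behaviour emerges in the mean
  over seeds, not per run.

## A worked example

```{r, eval = FALSE}
train <- make_synthetic(2, 10, 100, separation = 0.8, noise_sd = 0.05,
                        seed = 1)
test <- make_synthetic(2, 10, 100, separation = 0.8, noise_sd = 0.05,
                       seed = 2)
cfg <- classifier_config(n_vr = 10, mode = "perceptron", seed = 3)
run <- run_experiment(cfg, train, test)
run$eval$accuracy
run$eval$confusion
```

The same pipeline with `mode = "stdp"` trains by teaching-signal
association in one continuous simulation; `scaling_grid()` sweeps
receptor counts and class subsets and returns a long-format accuracy
table.
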