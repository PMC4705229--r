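# alclassify

A spiking-neural-network classifier for multivariate real-valued data,
modelled on the insect olfactory system (the antennal lobe). The package
is a portable, single-machine implementation of a network design
originally deployed on neuromorphic hardware: it is aimed at
computational neuroscientists and neuromorphic-computing researchers who
want to study the classifier's behaviour — encoding resolution, learning
dynamics, scaling with network size — without any special hardware.

## The model

A labelled sample $x \in [0,1]^d$ is encoded by $N_{VR}$ **virtual
receptors**: points $w_i$ placed in feature space by the **neural gas**
algorithm (fitted on training data only), each responding through a
cone-shaped radial basis function

$$r_i(x) = \max\left(0,\ 1 - d(x, w_i)/\sigma\right),$$

whose response sets the firing rate $f_i = f_{\min} + r_i (f_{\max} -
f_{\min})$ of a cluster of stochastic receptor neurons (Poisson or
Gamma-renewal spike trains). The spikes drive a three-layer network of
leaky integrate-and-fire neurons with exponential current synapses:
receptor-neuron (RN) clusters excite matching projection-neuron (PN)
clusters; PN clusters laterally inhibit each other (sparsening); PNs
project through a plastic all-to-all matrix onto association-neuron (AN)
clusters — one per class — which compete by strong mutual inhibition.
The decision is winner-take-all: the AN cluster with the highest spike
count in the presentation window.

Two supervised rules train the PN→AN matrix:

* **Symmetric STDP + teaching signal** — one continuous run over the
  training set (120 ms per sample + 20 ms silence); a teaching spike
  source forces activity in the correct AN cluster, and a symmetric
  spike-timing-dependent plasticity window (equal positive increment for
  either pairing order within ±10 ms) turns co-activity into association.
* **Per-sample perceptron rule** — each sample presented 500 ms to a
  reset network; on a misclassification, weights from each PN cluster to
  the true (predicted) class are increased (decreased) in proportion to
  that cluster's normalized spike count, and the matrix is replaced
  atomically.

Both modes test with frozen weights in a single pass. A small-population
`"spikey"` preset (6 RNs / 7 PNs / 8 ANs per cluster, explicit
inhibitory interneuron populations, Gamma order-5 input, 1 s
presentations) mirrors a 192-neuron mixed-signal device.

## Worked example

```r
library(alclassify)

train <- make_synthetic(2, 10, 100, separation = 0.8, noise_sd = 0.05,
                        seed = 1)
test  <- make_synthetic(2, 10, 100, separation = 0.8, noise_sd = 0.05,
                        seed = 2)

cfg <- classifier_config(n_vr = 10, mode = "perceptron", seed = 3)
run <- run_experiment(cfg, train, test)
run
#> <al_run> mode perceptron, 10 VRs, 2 classes
#> <eval_result> accuracy 1.000 (200/200 correct, 0 undecided)
#>     predicted
#> true   0   1
#>    0 100   0
#>    1   0 100
run$train_errors
#> [1] 4
run$vrs
#> <vr_set> 10 receptors in 10-d space, sigma = 0.8289 (euclidean)
```

The run fits 10 virtual receptors on the 200 training samples, trains the
plastic matrix in a single pass (4 training errors before convergence),
and classifies all 200 held-out samples correctly; the confusion matrix
is diagonal and no test window was left undecided. `mode = "stdp"`
trains the same task by teaching-signal association;
`scaling_grid(cfg, c(10, 50, 100), list(c(0, 1)), train, test)` sweeps
receptor counts and returns a long-format accuracy table.

MNIST-style IDX image/label files load with
`load_idx(images_path, labels_path)` (pixels scaled to [0,1]), and
benchmark subsets follow the first-come rule via
`build_subset(dataset, c(5, 7), max_per_class = 1000)`. A thin
command-line front end lives at `inst/cli/alclassify.R`
(subcommands `synth`, `fit-vrs`, `run`, `grid`).

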