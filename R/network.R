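#' Leaky integrate-and-fire neuron parameters
#'
#' Conventional cortical-model defaults; all configurable. Units: ms for
#' time constants, mV for potentials, megaohm for membrane resistance.
#'
#' @param tau_m membrane time constant (ms).
#' @param v_rest resting potential (mV).
#' @param v_thresh spike threshold (mV); must exceed `v_rest`.
#' @param v_reset post-spike reset potential (mV); at most `v_rest`.
#' @param t_ref absolute refractory period (ms).
#' @param r_m membrane resistance (megaohm), converting nA of synaptic
#'   current into mV of steady-state depolarization.
#' @return A named list of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 20, v_rest = -65, v_thresh = -50,
                          v_reset = -70, t_ref = 2, r_m = 40) {
  if (!(v_reset <= v_rest && v_rest < v_thresh)) {
    stop_input("need v_reset <= v_rest < v_thresh")
  }
  if (tau_m <= 0 || t_ref < 0) stop_input("tau_m > 0 and t_ref >= 0 required")
  structure(list(tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
                 v_reset = v_reset, t_ref = t_ref, r_m = r_m),
            class = "neuron_params")
}

#' Single LIF integration step
#'
#' Exponential-Euler update of one leaky integrate-and-fire neuron over
#' `dt` ms under a synaptic current held constant within the step. During
#' the refractory period the membrane is held at `v_reset` and the timer
#' decremented. Crossing `v_thresh` emits a spike, resets the membrane and
#' starts the refractory period.
#'
#' @param v membrane potential (mV).
#' @param refractory_remaining time left in refractory (ms).
#' @param i_syn total synaptic current (nA).
#' @param p a [neuron_params].
#' @param dt timestep (ms).
#' @return List with `v`, `spiked` (logical) and `refractory_remaining`.
#' @export
lif_step <- function(v, refractory_remaining, i_syn, p, dt) {
  if (dt <= 0) stop_input("dt must be > 0")
  if (refractory_remaining > 0) {
    return(list(v = p$v_reset, spiked = FALSE,
                refractory_remaining = max(refractory_remaining - dt, 0)))
  }
  e_target <- p$v_rest + p$r_m * i_syn
  v_new <- e_target + (v - e_target) * exp(-dt / p$tau_m)
  if (v_new >= p$v_thresh) {
    list(v = p$v_reset, spiked = TRUE, refractory_remaining = p$t_ref)
  } else {
    list(v = v_new, spiked = FALSE, refractory_remaining = 0)
  }
}

#' Exponential current-based synapse step
#'
#' `i_syn' = i_syn * exp(-dt / tau_syn) + incoming_weighted_spikes`:
#' the postsynaptic current decays exponentially and each arriving spike
#' adds its synaptic weight instantaneously (linear superposition).
#'
#' @param i_syn current (nA).
#' @param incoming_weighted_spikes summed weight of spikes arriving this
#'   step (nA).
#' @param tau_syn synaptic time constant (ms).
#' @param dt timestep (ms).
#' @return Updated current (nA).
#' @export
synapse_step <- function(i_syn, incoming_weighted_spikes, tau_syn, dt) {
  if (tau_syn <= 0) stop_input("tau_syn must be > 0")
  i_syn * exp(-dt / tau_syn) + incoming_weighted_spikes
}

preset_sizes <- function(preset, cluster_size) {
  if (preset == "standard") {
    list(rn = cluster_size, pn = cluster_size, an = cluster_size,
         ln_pn = 0L, ln_an = 0L)
  } else {
    # small-population preset with explicit inhibitory interneurons:
    # 6 receptor / 7 projection / 8 association neurons per cluster
    list(rn = 6L, pn = 7L, an = 8L, ln_pn = 6L, ln_an = 8L)
  }
}

# Per-synapse defaults. Lateral-inhibition weights are normalized by the
# number of competing clusters so that the total inhibition a neuron
# receives from one fully active rival cluster is independent of network
# size; the AN stage is an order of magnitude stronger than the PN stage
# (winner-take-all vs. sparsening).
default_weights <- function(preset, n_vr, n_classes) {
  if (preset == "standard") {
    # RN->PN is one-to-one, so the single afferent must drive its PN alone
    list(w_rn_pn = 2.0,
         w_pn_inh = -0.1 / max(n_vr - 1, 1),
         w_an_inh = -4.0 / max(n_classes - 1, 1),
         w_pn_ln = 0, w_ln_pn = 0, w_an_ln = 0, w_ln_an = 0)
  } else {
    # cluster-to-cluster all-to-all fan-in; inhibition via LN populations
    list(w_rn_pn = 0.4, w_pn_inh = 0, w_an_inh = 0,
         w_pn_ln = 0.6,
         w_ln_pn = -0.25 / max(n_vr - 1, 1),
         w_an_ln = 0.6,
         w_ln_an = -1.2 / max(n_classes - 1, 1))
  }
}

#' Build the three-layer classifier topology
#'
#' Constructs the population and projection structure of the classifier:
#' a receptor-neuron (RN) layer with one cluster per virtual receptor, a
#' projection-neuron (PN) layer with matching clusters and lateral
#' inhibition between distinct clusters (sparsening/decorrelation), and an
#' association-neuron (AN) layer with one cluster per class, strong mutual
#' inhibition (winner-take-all) and an all-to-all plastic PN->AN
#' projection.
#'
#' Two presets are available. `"standard"` uses equal-size clusters
#' (default 30 neurons) and abstracts the inhibitory interneurons into
#' direct inhibitory synapses between principal neurons. `"spikey"`
#' mirrors a small mixed-signal device: 6 RNs, 7 PNs and 8 ANs per
#' cluster, with explicit local-interneuron (LN) populations mediating
#' both inhibition stages.
#'
#' @param n_vr number of virtual receptors (>= `n_classes`).
#' @param n_classes number of classes (>= 2).
#' @param cluster_size neurons per cluster (standard preset).
#' @param preset `"standard"` or `"spikey"`.
#' @param neuron a [neuron_params].
#' @param tau_syn_exc,tau_syn_inh synaptic time constants (ms).
#' @param weights named list overriding projection weights (nA per spike):
#'   `w_rn_pn`, `w_pn_inh`, `w_an_inh` and, for the spikey preset,
#'   `w_pn_ln`, `w_ln_pn`, `w_an_ln`, `w_ln_an`. Inhibitory weights are
#'   <= 0, excitatory >= 0.
#' @param w_max upper bound for plastic PN->AN weights.
#' @param neuron_budget soft cap on total simulated neurons; exceeding it
#'   raises a capacity warning.
#' @return An object of class `al_topology` with a zero-initialized
#'   plastic weight matrix.
#' @export
build_topology <- function(n_vr, n_classes, cluster_size = 30L,
                           preset = c("standard", "spikey"),
                           neuron = neuron_params(),
                           tau_syn_exc = 5, tau_syn_inh = 10,
                           weights = list(), w_max = NULL,
                           neuron_budget = 100000L) {
  preset <- match.arg(preset)
  # plastic fan-in is far smaller in the small-population preset, so each
  # synapse must be allowed to carry more drive
  if (is.null(w_max)) w_max <- if (preset == "spikey") 1.5 else 0.25
  if (n_classes < 2) stop_input("n_classes must be >= 2")
  if (n_vr < n_classes) stop_input("n_vr must be >= n_classes")
  if (cluster_size < 1) stop_input("cluster_size must be >= 1")
  sz <- preset_sizes(preset, as.integer(cluster_size))
  w <- utils::modifyList(default_weights(preset, n_vr, n_classes), weights)
  if (w$w_pn_inh > 0 || w$w_an_inh > 0 || w$w_ln_pn > 0 || w$w_ln_an > 0) {
    stop_input("inhibitory weights must be <= 0")
  }
  if (w$w_rn_pn < 0 || w$w_pn_ln < 0 || w$w_an_ln < 0) {
    stop_input("excitatory weights must be >= 0")
  }
  n_rn <- n_vr * sz$rn; n_pn <- n_vr * sz$pn; n_an <- n_classes * sz$an
  n_total <- n_rn + n_pn + n_an + n_vr * sz$ln_pn + n_classes * sz$ln_an
  if (n_total > neuron_budget) {
    warning("topology uses ", n_total, " neurons, exceeding the budget of ",
            neuron_budget, call. = FALSE)
  }
  structure(
    list(preset = preset, n_vr = as.integer(n_vr),
         n_classes = as.integer(n_classes), sizes = sz,
         n_rn = n_rn, n_pn = n_pn, n_an = n_an,
         neuron = neuron, tau_syn_exc = tau_syn_exc,
         tau_syn_inh = tau_syn_inh, weights = w,
         w_max = w_max, delay_steps = 1L,
         W = matrix(0, nrow = n_pn, ncol = n_an)),
    class = "al_topology"
  )
}

#' @export
print.al_topology <- function(x, ...) {
  cat("<al_topology> preset ", x$preset, ": ", x$n_vr, " VRs x ",
      x$n_classes, " classes; RN ", x$n_rn, ", PN ", x$n_pn, ", AN ",
      x$n_an, " neurons; ", x$n_pn * x$n_an, " plastic synapses\n",
      sep = "")
  invisible(x)
}

events_to_steps <- function(trains, dt, duration) {
  if (nrow(trains$events) &&
      any(trains$events$time >= duration | trains$events$time < 0)) {
    stop_input("spike events outside [0, duration)")
  }
  as.integer(round(trains$events$time / dt))
}

#' Run the clock-driven network simulation
#'
#' Simulates the PN/AN (and, for the spikey preset, LN) populations for
#' `duration` ms at timestep `dt`, driven by pre-built RN spike trains and
#' an optional teaching spike train injected into AN neurons. The loop is
#' fully deterministic given its inputs: all stochasticity lives in spike
#' train generation. With `plastic = TRUE` the PN->AN matrix is updated
#' online by symmetric STDP (see [stdp_params]).
#'
#' @param topology an [al_topology].
#' @param input a [spike_trains] over the RN population (neuron indices
#'   `1..n_rn`).
#' @param duration simulated ms; defaults to `input$duration`.
#' @param dt timestep in ms.
#' @param teaching optional [spike_trains] over the AN population.
#' @param teach_w synaptic weight of teaching events (nA).
#' @param plastic enable STDP on PN->AN.
#' @param stdp an [stdp_params] (required when `plastic`).
#' @param W weight matrix to use; defaults to `topology$W`.
#' @param pn_bias,an_bias optional constant bias currents (nA), length
#'   `n_pn` / `n_an` or scalar.
#' @param record populations to record: subset of `c("pn", "an", "ln")`.
#' @param record_vm record membrane traces of the first PN and AN neuron.
#' @return An object of class `sim_record`: recorded [spike_trains] per
#'   population, the final weight matrix `W`, per-projection injected
#'   charge, and the weight-bound diagnostics `w_min_seen`/`w_max_seen`.
#' @export
simulate_network <- function(topology, input, duration = NULL, dt = 1,
                             teaching = NULL, teach_w = 2,
                             plastic = FALSE, stdp = NULL, W = NULL,
                             pn_bias = NULL, an_bias = NULL,
                             record = c("pn", "an"), record_vm = FALSE) {
  if (is.null(duration)) duration <- input$duration
  n_steps <- as.integer(round(duration / dt))
  if (input$n_neurons > topology$n_rn ||
      (nrow(input$events) && max(input$events$neuron) > topology$n_rn)) {
    stop_input("input neuron indices exceed the RN population")
  }
  in_step <- events_to_steps(input, dt, duration)
  in_id <- input$events$neuron - 1L
  if (!is.null(teaching)) {
    if (nrow(teaching$events) && max(teaching$events$neuron) > topology$n_an) {
      stop_input("teaching neuron indices exceed the AN population")
    }
    te_step <- events_to_steps(teaching, dt, duration)
    te_id <- teaching$events$neuron - 1L
  } else {
    te_step <- integer(0); te_id <- integer(0)
  }
  if (plastic && is.null(stdp)) {
    stdp <- stdp_params(w_max = topology$w_max)
  }
  if (is.null(W)) W <- topology$W
  expand_bias <- function(b, n) {
    if (is.null(b)) return(numeric(0))
    if (length(b) == 1L) b <- rep(b, n)
    as.numeric(b)
  }
  np <- topology$neuron
  sz <- topology$sizes
  w <- topology$weights
  res <- cpp_simulate(
    preset = if (topology$preset == "spikey") 1L else 0L,
    n_vr = topology$n_vr, n_classes = topology$n_classes,
    rn_cluster = sz$rn, pn_cluster = sz$pn, an_cluster = sz$an,
    ln_pn_cluster = sz$ln_pn, ln_an_cluster = sz$ln_an,
    np = c(np$tau_m, np$v_rest, np$v_thresh, np$v_reset, np$t_ref, np$r_m),
    tau_exc = topology$tau_syn_exc, tau_inh = topology$tau_syn_inh,
    w_rn_pn = w$w_rn_pn, w_pn_inh = w$w_pn_inh, w_an_inh = w$w_an_inh,
    w_pn_ln = w$w_pn_ln, w_ln_pn = w$w_ln_pn,
    w_an_ln = w$w_an_ln, w_ln_an = w$w_ln_an,
    W_in = W, n_steps = n_steps, dt = dt,
    in_id = in_id, in_step = in_step,
    teach_id = te_id, teach_step = te_step, teach_w = teach_w,
    plastic = plastic,
    a_plus = if (plastic) stdp$a_plus else 0,
    win_steps = if (plastic) as.integer(round(stdp$tau_window / dt)) else 0L,
    w_max = if (plastic) stdp$w_max else topology$w_max,
    pn_bias = expand_bias(pn_bias, topology$n_pn),
    an_bias = expand_bias(an_bias, topology$n_an),
    record_pn = "pn" %in% record, record_an = "an" %in% record,
    record_ln = "ln" %in% record, record_vm = record_vm)

  mk_trains <- function(id, step, n) {
    spike_trains(id + 1L, step * dt, n, duration, dt)
  }
  structure(
    list(rn = input,
         pn = mk_trains(res$pn_id, res$pn_step, topology$n_pn),
         an = mk_trains(res$an_id, res$an_step, topology$n_an),
         ln = if (topology$preset == "spikey" && "ln" %in% record) {
           mk_trains(res$ln_id, res$ln_step,
                     topology$n_vr * sz$ln_pn + topology$n_classes * sz$ln_an)
         },
         W = res$W, charge = res$charge,
         w_min_seen = res$w_min_seen, w_max_seen = res$w_max_seen,
         vm = if (record_vm) matrix(res$vm, ncol = 2L, byrow = TRUE,
                                    dimnames = list(NULL, c("pn1", "an1"))),
         duration = duration, dt = dt),
    class = "sim_record"
  )
}

#' @export
print.sim_record <- function(x, ...) {
  cat("<sim_record> ", x$duration, " ms at dt = ", x$dt, " ms; PN spikes: ",
      nrow(x$pn$events), ", AN spikes: ", nrow(x$an$events), "\n", sep = "")
  invisible(x)
}

#' Per-cluster spike counts in a time window
#'
#' Counts spikes of each contiguous cluster of `cluster_size` neurons
#' inside the half-open window `[start, end)`.
#'
#' @param trains a [spike_trains].
#' @param cluster_size neurons per cluster.
#' @param window `c(start, end)` in ms; default the whole horizon.
#' @return Integer vector of per-cluster counts.
#' @export
cluster_counts <- function(trains, cluster_size, window = NULL) {
  if (is.null(window)) window <- c(0, trains$duration)
  n_cl <- trains$n_neurons %/% cluster_size
  ev <- trains$events
  keep <- ev$time >= window[1L] & ev$time < window[2L]
  cl <- (ev$neuron[keep] - 1L) %/% cluster_size + 1L
  tabulate(cl, nbins = n_cl)
}
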