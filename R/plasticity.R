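#' Symmetric STDP parameters
#'
#' The supervised Hebbian scheme uses a symmetric spike-timing-dependent
#' plasticity curve: every closely paired pre/post spike, irrespective of
#' order, adds the same positive increment `a_plus`, and weights are
#' clipped to `[0, w_max]`. Pairing is nearest-neighbour: each spike pairs
#' only with the most recent opposite-side spike, which bounds the
#' per-spike update and limits inappropriate weight changes from
#' accidental pairings. The narrow window `tau_window`, together with the
#' silence gap between presentations, keeps associations within one
#' sample.
#'
#' @param a_plus weight increment per pairing (> 0); default `w_max / 200`.
#' @param tau_window pairing half-window in ms (> 0).
#' @param w_max weight bound (> 0).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(a_plus = w_max / 200, tau_window = 10,
                        w_max = 0.25) {
  if (w_max <= 0 || a_plus <= 0 || tau_window <= 0) {
    stop_input("a_plus, tau_window and w_max must be > 0")
  }
  structure(list(a_plus = a_plus, tau_window = tau_window, w_max = w_max),
            class = "stdp_params")
}

#' Symmetric STDP weight change for a spike-pair interval
#'
#' Returns `a_plus` when the pre/post interval `delta_t` lies within the
#' pairing window (`|delta_t| <= tau_window`) and 0 outside; an even
#' function of `delta_t`, so pre-before-post and post-before-pre pairings
#' potentiate identically.
#'
#' @param delta_t spike-pair interval in ms (vectorized).
#' @param p an [stdp_params].
#' @return Weight change(s).
#' @export
stdp_delta <- function(delta_t, p) {
  ifelse(abs(delta_t) <= p$tau_window, p$a_plus, 0)
}

#' Perceptron-rule parameters
#'
#' Error-driven, cluster-granular learning applied between presentations:
#' after a misclassified sample, weights from each PN cluster to the true
#' class rise, and to the predicted class fall, in proportion to that
#' cluster's normalized activity.
#'
#' @param learning_rate weight change per unit normalized PN activity.
#' @param w_max weight bound.
#' @param init `"random"` (seeded uniform on `[0, init_scale * w_max]`) or
#'   `"zero"`.
#' @param init_scale fraction of `w_max` bounding random initial weights.
#' @return An object of class `perceptron_params`.
#' @export
perceptron_params <- function(learning_rate = 0.01, w_max = 0.25,
                              init = c("random", "zero"),
                              init_scale = 0.1) {
  if (learning_rate <= 0) stop_input("learning_rate must be > 0")
  structure(list(learning_rate = learning_rate, w_max = w_max,
                 init = match.arg(init), init_scale = init_scale),
            class = "perceptron_params")
}

init_weights <- function(n_pn, n_an, p, seed) {
  if (p$init == "zero") {
    matrix(0, n_pn, n_an)
  } else {
    with_seed(seed, matrix(runif(n_pn * n_an, 0, p$init_scale * p$w_max),
                           n_pn, n_an))
  }
}

#' Build a teaching-signal schedule
#'
#' For sample k with label c, Poisson teaching spikes at `teach_rate` Hz
#' are injected into every neuron of AN cluster c during that sample's
#' presentation window; silence gaps contain no teaching events. The
#' teaching signal externally stimulates concurrent activity in the
#' correct output population, turning Hebbian STDP into supervised
#' association learning.
#'
#' @param labels integer cluster indices (1-based), one per sample in
#'   presentation order.
#' @param n_classes number of AN clusters.
#' @param an_cluster neurons per AN cluster.
#' @param presentation_ms presentation window per sample (> 0).
#' @param silence_ms silence gap between presentations (>= 0).
#' @param teach_rate teaching rate per AN neuron (Hz).
#' @param dt grid step (ms).
#' @param seed integer seed.
#' @return A [spike_trains] over the AN population covering
#'   `length(labels) * (presentation_ms + silence_ms)` ms.
#' @export
build_teaching_schedule <- function(labels, n_classes, an_cluster = 30L,
                                    presentation_ms = 120, silence_ms = 20,
                                    teach_rate = 200, dt = 1, seed = 1L) {
  if (presentation_ms <= 0) stop_input("presentation_ms must be > 0")
  if (silence_ms < 0) stop_input("silence_ms must be >= 0")
  if (any(labels < 1 | labels > n_classes)) {
    stop_input("labels must be cluster indices in 1..n_classes")
  }
  period <- presentation_ms + silence_ms
  duration <- length(labels) * period
  p <- teach_rate * dt / 1000
  steps_per_pres <- as.integer(round(presentation_ms / dt))
  with_seed(seed, {
    neuron <- vector("list", length(labels))
    time <- vector("list", length(labels))
    for (k in seq_along(labels)) {
      if (p <= 0) next
      u <- matrix(runif(an_cluster * steps_per_pres), nrow = an_cluster)
      hit <- which(u < p, arr.ind = TRUE)
      neuron[[k]] <- (labels[k] - 1L) * an_cluster + hit[, 1L]
      time[[k]] <- (k - 1L) * period + (hit[, 2L] - 1L) * dt
    }
    spike_trains(unlist(neuron) %||% integer(0),
                 unlist(time) %||% numeric(0),
                 n_classes * an_cluster, duration, dt)
  })
}

# Encode one dataset as a concatenated RN spike train over consecutive
# presentation windows (plus optional silences), for the continuous-run
# training/test mode.
encode_concatenated <- function(dataset, vrs, topology,
                                f_min, f_max, presentation_ms, silence_ms,
                                dt, generator = "poisson", gamma_order = 5L,
                                seed = 1L) {
  period <- presentation_ms + silence_ms
  n <- nrow(dataset$samples)
  responses <- vr_response(dataset$samples, vrs)
  neuron <- vector("list", n); time <- vector("list", n)
  for (k in seq_len(n)) {
    rates <- responses_to_rates(responses[k, ], f_min, f_max)
    tr <- if (generator == "poisson") {
      gen_poisson_trains(rates, topology$sizes$rn, presentation_ms, dt,
                         seed = derive_seed(seed, k))
    } else {
      gen_gamma_trains(rates, gamma_order, topology$sizes$rn,
                       presentation_ms, dt, seed = derive_seed(seed, k))
    }
    neuron[[k]] <- tr$events$neuron
    time[[k]] <- tr$events$time + (k - 1L) * period
  }
  spike_trains(unlist(neuron) %||% integer(0),
               unlist(time) %||% numeric(0),
               topology$n_rn, n * period, dt)
}

#' Train the plastic projection with symmetric STDP and a teaching signal
#'
#' One continuous simulation over the whole training set: each sample's
#' rate pattern drives the receptor layer for `presentation_ms`, followed
#' by a `silence_ms` gap, while the teaching signal stimulates the correct
#' AN cluster. Weights start at zero and grow by symmetric
#' nearest-neighbour STDP, clipped to `[0, w_max]`.
#'
#' @param topology an [al_topology].
#' @param train an [al_dataset]; labels are mapped to AN clusters in
#'   `class_set` order.
#' @param vrs a [vr_set] fitted on the training data.
#' @param stdp an [stdp_params].
#' @param f_min,f_max rate-code bounds (Hz).
#' @param presentation_ms,silence_ms schedule per sample (ms).
#' @param teach_rate,teach_w teaching signal rate (Hz) and weight (nA).
#' @param dt timestep (ms).
#' @param generator `"poisson"` or `"gamma"`.
#' @param gamma_order Gamma shape when `generator = "gamma"`.
#' @param seed integer seed for encoding and teaching noise.
#' @param record also return the training [simulate_network] record.
#' @return The trained weight matrix (`n_pn` x `n_an`), with the training
#'   record attached as attribute `"record"` when `record = TRUE`.
#' @export
train_stdp <- function(topology, train, vrs, stdp = NULL,
                       f_min = 0, f_max = 70,
                       presentation_ms = 120, silence_ms = 20,
                       teach_rate = 200, teach_w = 2, dt = 1,
                       generator = "poisson", gamma_order = 5L,
                       seed = 1L, record = FALSE) {
  if (is.null(stdp)) stdp <- stdp_params(w_max = topology$w_max)
  input <- encode_concatenated(train, vrs, topology, f_min, f_max,
                               presentation_ms, silence_ms, dt,
                               generator, gamma_order,
                               seed = derive_seed(seed, 101L))
  cluster_labels <- match(train$labels, train$class_set)
  teaching <- build_teaching_schedule(
    cluster_labels, topology$n_classes, topology$sizes$an,
    presentation_ms, silence_ms, teach_rate, dt,
    seed = derive_seed(seed, 202L))
  rec <- simulate_network(topology, input, duration = input$duration,
                          dt = dt, teaching = teaching, teach_w = teach_w,
                          plastic = TRUE, stdp = stdp,
                          W = matrix(0, topology$n_pn, topology$n_an))
  W <- rec$W
  if (record) attr(W, "record") <- rec
  W
}

#' Apply the per-sample perceptron update
#'
#' Error-driven rule applied at the end of one presentation: if the
#' prediction was correct the matrix is unchanged; otherwise weights from
#' PN cluster i to the true class rise by `learning_rate * a_i` and to the
#' predicted class fall by the same amount, where
#' `a_i = pn_counts_i / max(pn_counts)` is the cluster's normalized
#' activity. The whole matrix is replaced atomically and clipped to
#' `[0, w_max]`. An undecided prediction potentiates the true class only.
#'
#' @param W current weight matrix (`n_pn` x `n_an`).
#' @param pn_counts per-PN-cluster spike counts (length `n_vr`).
#' @param predicted predicted cluster index (1-based) or `NA` (undecided).
#' @param true_class true cluster index (1-based).
#' @param p a [perceptron_params].
#' @param pn_cluster,an_cluster cluster sizes used for block broadcast.
#' @return The updated weight matrix.
#' @export
perceptron_update <- function(W, pn_counts, predicted, true_class, p,
                              pn_cluster = 30L, an_cluster = 30L) {
  if (any(pn_counts < 0)) stop_input("pn_counts must be >= 0")
  if (!is.na(predicted) && predicted == true_class) return(W)
  m <- max(pn_counts)
  if (m == 0) {
    warning("all-zero PN activity; no update applied", call. = FALSE)
    return(W)
  }
  a <- pn_counts / m
  da <- rep(a, each = pn_cluster) * p$learning_rate
  cols_true <- (true_class - 1L) * an_cluster + seq_len(an_cluster)
  W[, cols_true] <- W[, cols_true] + da
  if (!is.na(predicted)) {
    cols_pred <- (predicted - 1L) * an_cluster + seq_len(an_cluster)
    W[, cols_pred] <- W[, cols_pred] - da
  }
  W[W < 0] <- 0
  W[W > p$w_max] <- p$w_max
  W
}

#' Train the plastic projection with the per-sample perceptron rule
#'
#' Stepped-simulation semantics: each training sample is presented to a
#' freshly reset network for `presentation_ms`, the winner is read from AN
#' cluster spike counts, and the weight matrix is revised between
#' presentations by [perceptron_update] (full-matrix replacement).
#' Starting weights are initialized per `p$init`.
#'
#' @inheritParams train_stdp
#' @param p a [perceptron_params].
#' @param epochs passes over the training set (single pass by default).
#' @param tie_rule tie handling for the training-time decision (see
#'   [classify_window]).
#' @return The trained weight matrix with attribute `"train_errors"`:
#'   per-epoch training error counts.
#' @export
train_perceptron <- function(topology, train, vrs, p = NULL,
                             f_min = 0, f_max = 70,
                             presentation_ms = 500, dt = 0.5,
                             generator = "poisson", gamma_order = 5L,
                             epochs = 1L, tie_rule = "lowest_index",
                             seed = 1L) {
  if (is.null(p)) p <- perceptron_params(w_max = topology$w_max)
  W <- init_weights(topology$n_pn, topology$n_an, p,
                    seed = derive_seed(seed, 303L))
  responses <- vr_response(train$samples, vrs)
  cluster_labels <- match(train$labels, train$class_set)
  n <- nrow(train$samples)
  errors <- integer(epochs)
  for (ep in seq_len(epochs)) {
    for (k in seq_len(n)) {
      rates <- responses_to_rates(responses[k, ], f_min, f_max)
      input <- gen_poisson_or_gamma(rates, generator, gamma_order,
                                    topology$sizes$rn, presentation_ms, dt,
                                    seed = derive_seed(seed, (ep - 1L) * n + k))
      rec <- simulate_network(topology, input, duration = presentation_ms,
                              dt = dt, W = W, record = c("pn", "an"))
      pn_counts <- cluster_counts(rec$pn, topology$sizes$pn)
      pred <- classify_window(rec, c(0, presentation_ms),
                              an_cluster = topology$sizes$an,
                              n_classes = topology$n_classes,
                              tie_rule = tie_rule)
      if (is.na(pred) || pred != cluster_labels[k]) {
        errors[ep] <- errors[ep] + 1L
      }
      W <- perceptron_update(W, pn_counts, pred, cluster_labels[k], p,
                             pn_cluster = topology$sizes$pn,
                             an_cluster = topology$sizes$an)
    }
  }
  attr(W, "train_errors") <- errors
  W
}

gen_poisson_or_gamma <- function(rates, generator, gamma_order,
                                 cluster_size, duration, dt, seed) {
  if (generator == "poisson") {
    gen_poisson_trains(rates, cluster_size, duration, dt, seed)
  } else {
    gen_gamma_trains(rates, gamma_order, cluster_size, duration, dt, seed)
  }
}

#' Serialize a trained weight matrix with provenance
#'
#' Delimited text with a header recording the learning mode, seed and key
#' parameters, mirroring the extract-then-rebuild workflow in which
#' training and test stages are separate runs.
#'
#' @param W weight matrix.
#' @param path output path.
#' @param mode,seed,params provenance fields recorded in the header.
#' @return Invisibly, `W`.
#' @export
write_weights <- function(W, path, mode = "unknown", seed = NA,
                          params = list()) {
  pstr <- paste(names(params), unlist(params), sep = "=", collapse = " ")
  h <- sprintf("# mode=%s seed=%s %s", mode, seed, pstr)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(h, con)
  write.table(format(W, digits = 17, scientific = TRUE, trim = TRUE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(W)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  W <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  attr(W, "header") <- sub("^# ", "", lines[startsWith(lines, "#")][1L])
  W
}
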