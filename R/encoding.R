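#' Virtual receptor set
#'
#' A set of points ("virtual receptors", VRs) in feature space acting as
#' radial-basis detectors. Each VR responds to an input sample in
#' proportion to proximity, with a linear cone profile cut off at distance
#' `sigma`.
#'
#' @param centroids numeric matrix, one VR per row.
#' @param sigma response cutoff radius (> 0). By default the maximum
#'   pairwise centroid distance, giving large, overlapping receptive
#'   fields.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return An object of class `vr_set`.
#' @export
vr_set <- function(centroids, sigma = NULL,
                   metric = c("euclidean", "manhattan")) {
  centroids <- as.matrix(centroids)
  metric <- match.arg(metric)
  if (is.null(sigma)) {
    sigma <- max(dist(centroids, method = metric))
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  if (sigma <= 0) stop_input("sigma must be > 0")
  structure(list(centroids = centroids, sigma = sigma, metric = metric),
            class = "vr_set")
}

#' @export
print.vr_set <- function(x, ...) {
  cat("<vr_set> ", nrow(x$centroids), " receptors in ", ncol(x$centroids),
      "-d space, sigma = ", signif(x$sigma, 4), " (", x$metric, ")\n",
      sep = "")
  invisible(x)
}

vr_distances <- function(samples, centroids, metric) {
  samples <- matrix(samples, ncol = ncol(centroids))
  if (metric == "euclidean") {
    # |x - c|^2 = |x|^2 + |c|^2 - 2 x.c, computed blockwise
    cross <- tcrossprod(samples, centroids)
    d2 <- outer(rowSums(samples^2), rowSums(centroids^2), `+`) - 2 * cross
    d2[d2 < 0] <- 0
    sqrt(d2)
  } else {
    t(apply(samples, 1L, function(x)
      colSums(abs(t(centroids) - x))))
  }
}

#' Place virtual receptors with the neural gas algorithm
#'
#' Standard neural gas vector quantization: for each presented sample all
#' centroids are ranked by distance and centroid with rank k moves by
#' `eps(t) * exp(-k / lambda(t)) * (x - w_k)`, with the step size `eps`
#' and neighbourhood range `lambda` decayed exponentially from their start
#' to their end values over the run. Centroids are initialized as random
#' training samples. Receptors are fitted on the training split alone.
#'
#' @param samples numeric matrix of training samples (rows).
#' @param n_vr number of receptors to place (>= 1; at least the number of
#'   classes for classification use).
#' @param iterations number of sample presentations; default
#'   `20 * nrow(samples)`. `iterations = 0` returns the seeded
#'   initialization unchanged.
#' @param eps step-size schedule `c(start, end)`, decayed exponentially.
#' @param lambda neighbourhood-range schedule `c(start, end)`; default
#'   start `n_vr / 2`.
#' @param metric distance metric for ranking and for the receptive field.
#' @param sigma response cutoff passed to [vr_set]; `NULL` for the
#'   max-pairwise-distance default.
#' @param seed integer seed (initialization and presentation order).
#'
#' @return A [vr_set].
#' @export
fit_neural_gas <- function(samples, n_vr, iterations = NULL,
                           eps = c(0.5, 0.01), lambda = NULL,
                           metric = c("euclidean", "manhattan"),
                           sigma = NULL, seed = 1L) {
  samples <- as.matrix(samples)
  metric <- match.arg(metric)
  n <- nrow(samples)
  if (n < 1) stop_input("samples must be nonempty")
  if (n_vr < 1) stop_input("n_vr must be >= 1")
  if (anyNA(samples)) stop_input("samples contain NA values")
  if (n_vr > n) {
    warning("n_vr exceeds the number of samples; duplicated initializations",
            call. = FALSE)
  }
  if (is.null(iterations)) iterations <- 20L * n
  if (is.null(lambda)) lambda <- c(max(n_vr / 2, 0.02), 0.01)
  if (any(eps <= 0) || any(lambda <= 0) || eps[1] < eps[2] ||
      lambda[1] < lambda[2]) {
    stop_input("schedules must be positive with start >= end")
  }

  with_seed(seed, {
    w <- samples[sample.int(n, n_vr, replace = n_vr > n), , drop = FALSE]
    if (iterations > 0) {
      order_idx <- sample.int(n, iterations, replace = TRUE)
      frac <- seq_len(iterations) / iterations
      eps_t <- eps[1] * (eps[2] / eps[1])^frac
      lam_t <- lambda[1] * (lambda[2] / lambda[1])^frac
      for (t in seq_len(iterations)) {
        x <- samples[order_idx[t], ]
        d <- if (metric == "euclidean") {
          sqrt(rowSums((w - rep(x, each = n_vr))^2))
        } else {
          rowSums(abs(w - rep(x, each = n_vr)))
        }
        ranks <- rank(d, ties.method = "first") - 1
        h <- eps_t[t] * exp(-ranks / lam_t[t])
        w <- w + h * (rep(x, each = n_vr) - w)
      }
    }
    vr_set(w, sigma = sigma, metric = metric)
  })
}

#' Mean quantization error of a receptor set
#'
#' Average distance from each sample to its nearest centroid; the quantity
#' neural gas fitting drives down.
#'
#' @param samples numeric matrix.
#' @param vrs a [vr_set].
#' @return A scalar.
#' @export
quantization_error <- function(samples, vrs) {
  d <- vr_distances(as.matrix(samples), vrs$centroids, vrs$metric)
  mean(apply(d, 1L, min))
}

#' Proximity-based receptor responses
#'
#' Linear cone radial basis function: `max(0, 1 - d/sigma)` for the chosen
#' metric distance `d` between the sample and each centroid. Responses are
#' 1 at the centroid, decrease linearly with distance, and are 0 at or
#' beyond the cutoff `sigma`.
#'
#' @param sample a single d-vector or an n x d matrix of samples.
#' @param vrs a [vr_set] with matching dimensionality.
#' @return A response vector in \[0, 1\] (or an n x N_VR matrix).
#' @export
vr_response <- function(sample, vrs) {
  x <- if (is.matrix(sample)) sample else matrix(sample, nrow = 1L)
  if (ncol(x) != ncol(vrs$centroids)) {
    stop_input("sample dimensionality (", ncol(x),
               ") does not match receptors (", ncol(vrs$centroids), ")")
  }
  d <- vr_distances(x, vrs$centroids, vrs$metric)
  r <- 1 - d / vrs$sigma
  r[r < 0] <- 0
  if (is.matrix(sample)) r else drop(r)
}

#' Map receptor responses to firing rates
#'
#' Affine, order-preserving map from the response interval \[0, 1\] to the
#' rate interval \[`f_min`, `f_max`\] Hz: each receptor channel's commanded
#' population rate is proportional to its response.
#'
#' @param responses numeric vector in \[0, 1\].
#' @param f_min,f_max rate bounds in Hz, `0 <= f_min < f_max`.
#' @return Numeric vector of rates (Hz), class `rate_pattern`.
#' @export
responses_to_rates <- function(responses, f_min = 0, f_max = 70) {
  if (f_min < 0 || f_min >= f_max) stop_input("need 0 <= f_min < f_max")
  if (any(responses < -1e-12 | responses > 1 + 1e-12)) {
    stop_input("responses must lie in [0, 1]")
  }
  structure(f_min + pmin(pmax(responses, 0), 1) * (f_max - f_min),
            class = "rate_pattern")
}

#' Spike train set
#'
#' Events are (neuron index, spike time in ms), sorted by time then neuron
#' index, on a fixed simulation grid.
#'
#' @param neuron integer neuron indices (1-based).
#' @param time spike times in ms within `[0, duration)`.
#' @param n_neurons number of source neurons.
#' @param duration horizon in ms.
#' @param dt simulation timestep in ms.
#' @return An object of class `spike_trains`.
#' @export
spike_trains <- function(neuron, time, n_neurons, duration, dt) {
  ord <- order(time, neuron)
  structure(
    list(events = data.frame(neuron = as.integer(neuron[ord]),
                             time = as.numeric(time[ord])),
         n_neurons = as.integer(n_neurons),
         duration = as.numeric(duration),
         dt = as.numeric(dt)),
    class = "spike_trains"
  )
}

#' @export
print.spike_trains <- function(x, ...) {
  cat("<spike_trains> ", nrow(x$events), " events / ", x$n_neurons,
      " neurons over ", x$duration, " ms (dt = ", x$dt, " ms)\n", sep = "")
  invisible(x)
}

#' Generate Poisson spike trains for a rate pattern
#'
#' Clock-driven generation matched to the simulators' fixed-timestep
#' regime: each of the `cluster_size` neurons assigned to receptor channel
#' i fires independently in each timestep with probability
#' `rate_i * dt / 1000` (a per-step Bernoulli draw). Neuron
#' `(i-1)*cluster_size + j` is the j-th neuron of channel i.
#'
#' @param pattern numeric rate vector (Hz), one entry per receptor channel.
#' @param cluster_size neurons per channel.
#' @param duration horizon in ms.
#' @param dt timestep in ms; `rate * dt / 1000` must be < 1.
#' @param seed integer seed.
#' @return A [spike_trains] over `length(pattern) * cluster_size` neurons.
#' @export
gen_poisson_trains <- function(pattern, cluster_size = 30L,
                               duration = 500, dt = 1, seed = 1L) {
  rates <- as.numeric(pattern)
  p <- rates * dt / 1000
  if (any(p >= 1)) {
    stop_input("rate * dt / 1000 must be < 1 for every channel; reduce dt")
  }
  n_steps <- as.integer(round(duration / dt))
  n_neurons <- length(rates) * cluster_size
  p_neuron <- rep(p, each = cluster_size)
  with_seed(seed, {
    active <- which(p_neuron > 0)
    neuron <- integer(0); step <- integer(0)
    if (length(active) && n_steps > 0) {
      # draw per active neuron to bound memory at large horizons
      u <- matrix(runif(length(active) * n_steps), nrow = length(active))
      hit <- which(u < p_neuron[active], arr.ind = TRUE)
      neuron <- active[hit[, 1L]]
      step <- hit[, 2L]
    }
    spike_trains(neuron, (step - 1L) * dt, n_neurons, duration, dt)
  })
}

#' Generate Gamma-process spike trains for a rate pattern
#'
#' Renewal process with Gamma-distributed inter-spike intervals of shape
#' `order` and mean `1000 / rate` ms (rate-preserving), started from a
#' random phase and snapped to the simulation grid. Higher orders give
#' more regular trains (ISI CV = 1 / sqrt(order)) and lower spike-count
#' variability than a Poisson process of equal rate; order 1 is the
#' Poisson-equivalent exponential case.
#'
#' @param pattern numeric rate vector (Hz) per receptor channel.
#' @param order Gamma shape parameter (>= 1).
#' @param cluster_size neurons per channel.
#' @param duration horizon in ms.
#' @param dt grid step for snapping, ms.
#' @param seed integer seed.
#' @return A [spike_trains].
#' @export
gen_gamma_trains <- function(pattern, order = 5L, cluster_size = 30L,
                             duration = 1000, dt = 1, seed = 1L) {
  if (order < 1) stop_input("order must be >= 1")
  rates <- as.numeric(pattern)
  n_neurons <- length(rates) * cluster_size
  rate_neuron <- rep(rates, each = cluster_size)
  with_seed(seed, {
    neuron <- vector("list", n_neurons)
    time <- vector("list", n_neurons)
    for (j in seq_len(n_neurons)) {
      r <- rate_neuron[j]
      if (r <= 0) next
      mean_isi <- 1000 / r
      n_draw <- ceiling(duration / mean_isi + 6 * sqrt(duration / mean_isi) + 10)
      isis <- rgamma(n_draw, shape = order, rate = order / mean_isi)
      t <- cumsum(isis) - runif(1L) * isis[1L]  # random phase in first interval
      while (t[length(t)] < duration) {
        extra <- rgamma(n_draw, shape = order, rate = order / mean_isi)
        t <- c(t, t[length(t)] + cumsum(extra))
      }
      t <- t[t >= 0 & t < duration]
      t <- unique(floor(t / dt) * dt)  # grid snap; merge same-step events
      neuron[[j]] <- rep.int(j, length(t))
      time[[j]] <- t
    }
    spike_trains(unlist(neuron) %||% integer(0),
                 unlist(time) %||% numeric(0),
                 n_neurons, duration, dt)
  })
}

#' Write / read spike trains as two-column delimited text
#'
#' The raster-export format: one event per line, `neuron_id time_ms`,
#' sorted by time then neuron.
#'
#' @param trains a [spike_trains].
#' @param path output path.
#' @return Invisibly, the input.
#' @export
write_spike_trains <- function(trains, path) {
  h <- sprintf("# n_neurons=%d duration=%g dt=%g",
               trains$n_neurons, trains$duration, trains$dt)
  writeLines(c(h, sprintf("%d\t%g", trains$events$neuron,
                          trains$events$time)), path)
  invisible(trains)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(sub("^# ", "", lines[1L]), " ")[[1L]]
  kv <- do.call(rbind, strsplit(meta, "="))
  vals <- setNames(as.numeric(kv[, 2L]), kv[, 1L])
  body <- lines[-1L]
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "\t"))
    neuron <- as.integer(parts[, 1L]); time <- as.numeric(parts[, 2L])
  } else {
    neuron <- integer(0); time <- numeric(0)
  }
  spike_trains(neuron, time, vals[["n_neurons"]], vals[["duration"]],
               vals[["dt"]])
}

#' Write / read a receptor set as delimited text
#'
#' One centroid per row, preceded by a small header recording `sigma` and
#' the metric.
#'
#' @param vrs a [vr_set].
#' @param path file path.
#' @return [write_vr_set] returns its input invisibly; [read_vr_set]
#'   returns a [vr_set].
#' @export
write_vr_set <- function(vrs, path) {
  h <- sprintf("# sigma=%.17g metric=%s", vrs$sigma, vrs$metric)
  body <- apply(vrs$centroids, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(h, body), path)
  invisible(vrs)
}

#' @rdname write_vr_set
#' @export
read_vr_set <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(sub("^# ", "", lines[1L]), " ")[[1L]]
  sigma <- as.numeric(sub("sigma=", "", meta[1L]))
  metric <- sub("metric=", "", meta[2L])
  w <- do.call(rbind, lapply(strsplit(lines[-1L], "\t"), as.numeric))
  vr_set(w, sigma = sigma, metric = metric)
}
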