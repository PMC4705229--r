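test_that("neural gas collapses onto a single attractor", {
  p <- c(0.3, 0.7, 0.5)
  samples <- matrix(rep(p, each = 20), nrow = 20)
  vrs <- fit_neural_gas(samples, 3, seed = 1, sigma = 1)
  expect_true(all(abs(sweep(vrs$centroids, 2, p)) < 1e-6))
})

test_that("neural gas finds two well-separated cluster centres", {
  ds <- make_synthetic(2, 10, 50, separation = 0.8, noise_sd = 0.05,
                       seed = 5)
  means <- attr(ds, "class_means")
  vrs <- fit_neural_gas(ds$samples, 2, seed = 2)
  # each centroid sits within the noise scale of one distinct cluster mean
  d <- vr_distances_for_test(vrs$centroids, means)
  assign_best <- apply(d, 1L, which.min)
  expect_setequal(assign_best, 1:2)
  expect_true(all(apply(d, 1L, min) < 3 * 0.05))
})

test_that("fitting reduces quantization error below the initialization", {
  ds <- make_synthetic(3, 8, 40, separation = 0.5, noise_sd = 0.1,
                       seed = 9)
  init <- fit_neural_gas(ds$samples, 6, iterations = 0, seed = 4, sigma = 1)
  fitted <- fit_neural_gas(ds$samples, 6, seed = 4, sigma = 1)
  expect_lt(quantization_error(ds$samples, fitted),
            quantization_error(ds$samples, init))
})

test_that("neural gas is deterministic and iterations = 0 returns the init", {
  ds <- make_synthetic(2, 4, 20, separation = 0.5, seed = 11)
  a <- fit_neural_gas(ds$samples, 5, seed = 3)
  b <- fit_neural_gas(ds$samples, 5, seed = 3)
  expect_identical(a$centroids, b$centroids)

  init <- fit_neural_gas(ds$samples, 5, iterations = 0, seed = 3, sigma = 1)
  # every initial centroid is one of the training samples
  expect_true(all(apply(init$centroids, 1L, function(w)
    any(apply(ds$samples, 1L, function(x) all(x == w))))))

  expect_error(fit_neural_gas(ds$samples, 0), "n_vr")
  expect_warning(fit_neural_gas(ds$samples[1:3, ], 5, iterations = 1,
                                sigma = 1), "exceeds")
  bad <- ds$samples; bad[1, 1] <- NA
  expect_error(fit_neural_gas(bad, 2), "NA")
})

test_that("receptor responses follow the linear cone profile", {
  centroids <- rbind(c(0.2, 0.2), c(0.8, 0.8))
  vrs <- vr_set(centroids, sigma = 0.5)
  expect_equal(vr_response(c(0.2, 0.2), vrs)[1], 1)
  # at distance sigma/2 the response is exactly one half
  x <- c(0.2 + 0.25, 0.2)
  expect_equal(vr_response(x, vrs)[1], 0.5)
  # at or beyond sigma the response is zero
  expect_equal(vr_response(c(0.7, 0.2), vrs)[1], 0)
  expect_equal(vr_response(c(0.95, 0.2), vrs)[1], 0)
  # strictly decreasing in distance inside the cutoff
  d <- seq(0, 0.45, by = 0.05)
  r <- vapply(d, function(dd) vr_response(c(0.2 + dd, 0.2), vrs)[1],
              numeric(1))
  expect_true(all(diff(r) < 0))
  expect_error(vr_response(c(1, 2, 3), vrs), "dimensionality")
})

test_that("responses are permutation-equivariant in the receptor set", {
  set.seed(8)
  centroids <- matrix(runif(12), nrow = 4)
  x <- runif(3)
  vrs <- vr_set(centroids, sigma = 1)
  perm <- c(3, 1, 4, 2)
  vrs_p <- vr_set(centroids[perm, ], sigma = 1)
  expect_equal(vr_response(x, vrs_p), vr_response(x, vrs)[perm])
})

test_that("rate mapping is affine and order-preserving", {
  expect_equal(as.numeric(responses_to_rates(c(0, 1, 0.5), 10, 90)),
               c(10, 90, 50))
  r <- runif(6)
  rates <- as.numeric(responses_to_rates(r, 0, 70))
  perm <- sample(6)
  expect_equal(as.numeric(responses_to_rates(r[perm], 0, 70)), rates[perm])
  expect_error(responses_to_rates(c(0.2, 1.4)), "\\[0, 1\\]")
  expect_error(responses_to_rates(0.5, 50, 50), "f_min")
})

test_that("Poisson trains match commanded rate and ISI statistics", {
  # zero intensity: no events
  z <- gen_poisson_trains(c(0, 0), 5, 100, 1, seed = 1)
  expect_equal(nrow(z$events), 0L)

  # count concentration: one neuron, 100 Hz, 100 s
  tr <- gen_poisson_trains(100, 1, 1e5, 1, seed = 2)
  expect_lt(abs(nrow(tr$events) - 1e4), 4 * sqrt(1e4))

  # ISI coefficient of variation near 1 at 50 Hz on a fine grid
  tr2 <- gen_poisson_trains(50, 1, 2e5, 0.1, seed = 3)
  rate_hat <- nrow(tr2$events) / 200
  expect_lt(abs(rate_hat - 50) / 50, 0.02)
  expect_gt(isi_cv(tr2), 0.9)
  expect_lt(isi_cv(tr2), 1.1)

  expect_error(gen_poisson_trains(2000, 1, 10, 1), "reduce dt")

  # determinism
  expect_identical(gen_poisson_trains(40, 3, 500, 1, seed = 9)$events,
                   gen_poisson_trains(40, 3, 500, 1, seed = 9)$events)
})

test_that("Gamma trains are rate-preserving and more regular", {
  # order 1 is the Poisson-equivalent exponential case
  g1 <- gen_gamma_trains(50, 1, 1, 2e5, 0.1, seed = 4)
  expect_gt(isi_cv(g1), 0.9)
  expect_lt(isi_cv(g1), 1.1)

  # order 5: CV near 1/sqrt(5)
  g5 <- gen_gamma_trains(50, 5, 1, 2e5, 0.1, seed = 5)
  expect_gt(isi_cv(g5), 0.40)
  expect_lt(isi_cv(g5), 0.50)
  rate_hat <- nrow(g5$events) / 200
  expect_lt(abs(rate_hat - 50) / 50, 0.02)

  # per-second spike-count variance below the Poisson process of equal rate
  count_var <- function(tr) {
    var(tabulate(floor(tr$events$time / 1000) + 1L, nbins = 200))
  }
  expect_lt(count_var(g5), count_var(g1))

  expect_error(gen_gamma_trains(50, 0, 1, 100, 1), "order")
})

test_that("spike trains and receptor sets round-trip through text", {
  tr <- gen_poisson_trains(c(30, 60), 4, 200, 0.5, seed = 6)
  path <- tempfile()
  write_spike_trains(tr, path)
  back <- read_spike_trains(path)
  expect_equal(back$events, tr$events)
  expect_equal(back$n_neurons, tr$n_neurons)
  expect_equal(back$dt, tr$dt)

  vrs <- vr_set(matrix(runif(8), 4), sigma = 0.7, metric = "manhattan")
  vp <- tempfile()
  write_vr_set(vrs, vp)
  back2 <- read_vr_set(vp)
  expect_equal(back2$centroids, vrs$centroids, ignore_attr = TRUE)
  expect_equal(back2$sigma, vrs$sigma)
  expect_equal(back2$metric, vrs$metric)
})
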