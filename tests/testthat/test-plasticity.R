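test_that("the STDP curve is symmetric, positive and windowed", {
  p <- stdp_params(a_plus = 0.002, tau_window = 10, w_max = 0.25)
  expect_equal(stdp_delta(0, p), 0.002)
  expect_equal(stdp_delta(10, p), 0.002)
  expect_equal(stdp_delta(-10, p), 0.002)
  expect_equal(stdp_delta(10.001, p), 0)
  expect_equal(stdp_delta(-10.001, p), 0)
  x <- seq(-30, 30, by = 0.5)
  expect_equal(stdp_delta(x, p), stdp_delta(-x, p))
  expect_true(all(stdp_delta(x, p) >= 0))
})

test_that("teaching schedules target the correct cluster and spare silences", {
  sched <- build_teaching_schedule(c(1L, 2L), 2, 10, 120, 20, 200, 1,
                                   seed = 3)
  ev <- sched$events
  cl <- (ev$neuron - 1L) %/% 10 + 1L
  # cluster 1 events only in [0, 120); cluster 2 only in [140, 260)
  expect_true(all(ev$time[cl == 1] >= 0 & ev$time[cl == 1] < 120))
  expect_true(all(ev$time[cl == 2] >= 140 & ev$time[cl == 2] < 260))
  # silence gaps contain no events at all
  expect_false(any(ev$time >= 120 & ev$time < 140))
  expect_equal(sched$duration, 280)

  none <- build_teaching_schedule(c(1L, 2L), 2, 10, 120, 20, 0, 1, seed = 3)
  expect_equal(nrow(none$events), 0L)
  expect_error(build_teaching_schedule(c(0L), 2, 10, 120, 20, 200, 1),
               "cluster indices")
})

test_that("without teaching, zero-initialized weights stay at zero", {
  pair <- orthogonal_pair(n = 5)
  topo <- build_topology(6, 2, cluster_size = 10)
  vrs <- fit_neural_gas(pair$train$samples, 6, sigma = 0.3, seed = 2)
  W <- train_stdp(topo, pair$train, vrs, teach_rate = 0, seed = 4)
  expect_true(all(W == 0))
})

test_that("STDP training builds the correct class-block structure", {
  pair <- orthogonal_pair(n = 20)
  topo <- build_topology(10, 2, cluster_size = 10)
  vrs <- fit_neural_gas(pair$train$samples, 10, sigma = 0.3, seed = 5)
  W <- train_stdp(topo, pair$train, vrs, seed = 6, record = TRUE)
  rec <- attr(W, "record")
  # weights clipped to [0, w_max] at every step of training
  expect_gte(rec$w_min_seen, 0)
  expect_lte(rec$w_max_seen, topo$w_max + 1e-12)

  means <- attr(pair$train, "class_means")
  resp <- vr_response(means, vrs)
  for (cl in 1:2) {
    active <- which(resp[cl, ] > 0.2)
    own <- block_mean(W, active, cl, 10, 10)
    cross <- block_mean(W, active, 3 - cl, 10, 10)
    expect_gt(own, cross)
  }
})

test_that("label-shuffled teaching yields no class-block contrast", {
  pair <- orthogonal_pair(n = 16)
  topo <- build_topology(6, 2, cluster_size = 8)
  vrs <- fit_neural_gas(pair$train$samples, 6, sigma = 0.3, seed = 7)
  means <- attr(pair$train, "class_means")
  resp <- vr_response(means, vrs)
  contrast <- vapply(1:6, function(s) {
    shuffled <- pair$train
    shuffled$labels <- with_seed_for_test(900 + s,
                                          sample(shuffled$labels))
    W <- train_stdp(topo, shuffled, vrs, seed = s)
    mean(vapply(1:2, function(cl) {
      active <- which(resp[cl, ] > 0.2)
      block_mean(W, active, cl, 8, 8) - block_mean(W, active, 3 - cl, 8, 8)
    }, numeric(1)))
  }, numeric(1))
  se <- sd(contrast) / sqrt(length(contrast))
  expect_lt(abs(mean(contrast)), 3 * se + 1e-9)
})

test_that("perceptron update is error-driven, bounded and atomic", {
  p <- perceptron_params(learning_rate = 0.05, w_max = 0.25)
  W <- matrix(0.1, 4 * 2, 2 * 2)  # 4 PN clusters x 2 AN clusters, size 2
  # correct prediction: no change
  expect_identical(perceptron_update(W, c(3, 0, 1, 2), 1L, 1L, p, 2L, 2L), W)
  # single active cluster, unit activity
  W2 <- perceptron_update(W, c(5, 0, 0, 0), 2L, 1L, p, 2L, 2L)
  expect_equal(W2[1, 1], 0.1 + 0.05)   # potentiated toward true class
  expect_equal(W2[1, 3], 0.1 - 0.05)   # depressed toward predicted class
  expect_equal(W2[3, 1], 0.1)          # inactive cluster untouched
  # floor at zero
  W3 <- W; W3[] <- 0.01
  W3 <- perceptron_update(W3, c(5, 0, 0, 0), 2L, 1L, p, 2L, 2L)
  expect_equal(W3[1, 3], 0)
  expect_true(all(W3 >= 0 & W3 <= p$w_max))
  # all-zero activity: warning, no-op
  expect_warning(W4 <- perceptron_update(W, c(0, 0, 0, 0), 2L, 1L, p, 2L, 2L),
                 "all-zero")
  expect_identical(W4, W)
})

test_that("repeated perceptron updates converge on separable patterns", {
  # two fixed cluster-activity patterns with disjoint support
  a1 <- c(10, 8, 0, 0); a2 <- c(0, 0, 9, 11)
  p <- perceptron_params(learning_rate = 0.02, w_max = 0.5)
  Wc <- matrix(0.05, 4, 2)  # cluster-level weights
  predict_cl <- function(Wc, a) which.max(as.numeric(a %*% Wc))
  updates <- 0
  for (pass in 1:50) {
    changed <- FALSE
    for (k in 1:2) {
      a <- list(a1, a2)[[k]]
      pred <- predict_cl(Wc, a)
      if (pred != k) {
        Wc <- perceptron_update(Wc, a, pred, k, p, 1L, 1L)
        changed <- TRUE; updates <- updates + 1
      }
    }
    if (!changed) break
  }
  expect_equal(predict_cl(Wc, a1), 1L)
  expect_equal(predict_cl(Wc, a2), 2L)
  expect_lt(updates, 50)  # updates cease once separated
})

test_that("a perceptron training pass reduces training error over epochs", {
  pair <- easy_pair(n = 15)
  topo <- build_topology(6, 2, cluster_size = 10)
  vrs <- fit_neural_gas(pair$train$samples, 6, seed = 8)
  W <- train_perceptron(topo, pair$train, vrs,
                        presentation_ms = 200, dt = 1,
                        epochs = 3, seed = 9)
  errs <- attr(W, "train_errors")
  expect_equal(length(errs), 3L)
  expect_lte(errs[3], errs[1])
  expect_true(all(W >= 0 & W <= topo$w_max))
})

test_that("weight matrices round-trip with their provenance header", {
  W <- matrix(runif(12), 4)
  path <- tempfile()
  write_weights(W, path, mode = "stdp", seed = 42,
                params = list(a_plus = 0.00125))
  back <- read_weights(path)
  expect_equal(unclass(back), W, ignore_attr = TRUE, tolerance = 1e-15)
  expect_match(attr(back, "header"), "mode=stdp")
  expect_match(attr(back, "header"), "a_plus")
})
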