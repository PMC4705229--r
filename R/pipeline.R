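#' Classifier run configuration
#'
#' Validated bundle of every knob for a train-then-test run. Mode-specific
#' defaults mirror the two training control flows: STDP mode uses 120 ms
#' presentations with a 20 ms silence gap, zero-initialized weights and a
#' 1 ms timestep in one continuous simulation; perceptron mode uses 500 ms
#' presentations with no gap, random initial weights and a 0.5 ms timestep
#' with a per-sample reset. Unknown fields are rejected.
#'
#' @param n_vr number of virtual receptors.
#' @param classes class labels to keep (`NULL` = all classes present).
#' @param cluster_size neurons per cluster (standard preset).
#' @param preset `"standard"` or `"spikey"`.
#' @param mode `"stdp"` or `"perceptron"`.
#' @param dt timestep (ms); defaults by mode (1 / 0.5).
#' @param presentation_ms,silence_ms schedule; defaults by mode.
#' @param f_min,f_max rate-code bounds (Hz).
#' @param generator `"poisson"` or `"gamma"`.
#' @param gamma_order Gamma shape for `generator = "gamma"`.
#' @param max_per_class cap on examples per class when subsetting.
#' @param seed master seed; all component seeds derive from it.
#' @param ... overrides forwarded to [build_topology] (`weights`,
#'   `neuron`, `tau_syn_exc`, `tau_syn_inh`, `w_max`) and to the learning
#'   rules (`stdp`, `perceptron`, `teach_rate`, `teach_w`, `epochs`,
#'   `ng_iterations`, `sigma`, `metric`, `tie_rule`).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(n_vr = 10L, classes = NULL,
                              cluster_size = 30L,
                              preset = c("standard", "spikey"),
                              mode = c("perceptron", "stdp"),
                              dt = NULL, presentation_ms = NULL,
                              silence_ms = NULL,
                              f_min = 0, f_max = 70,
                              generator = c("poisson", "gamma"),
                              gamma_order = 5L,
                              max_per_class = 1000L,
                              seed = 1L, ...) {
  preset <- match.arg(preset)
  mode <- match.arg(mode)
  if (identical(generator, c("poisson", "gamma")) && preset == "spikey") {
    generator <- "gamma"  # more regular trains for tiny populations
  }
  generator <- match.arg(generator)
  extra <- list(...)
  allowed_extra <- c("weights", "neuron", "tau_syn_exc", "tau_syn_inh",
                     "w_max", "stdp", "perceptron", "teach_rate", "teach_w",
                     "epochs", "ng_iterations", "sigma", "metric",
                     "tie_rule")
  bad <- setdiff(names(extra), allowed_extra)
  if (length(bad)) stop_input("unknown config fields: ",
                              paste(bad, collapse = ", "))
  if (is.null(dt)) dt <- if (mode == "stdp") 1 else 0.5
  if (preset == "spikey") dt <- 1
  if (!dt %in% c(0.1, 0.5, 1.0)) {
    stop_input("dt must be one of 0.1, 0.5, 1.0 ms")
  }
  if (is.null(presentation_ms)) {
    presentation_ms <- if (preset == "spikey") 1000
      else if (mode == "stdp") 120 else 500
  }
  if (is.null(silence_ms)) silence_ms <- if (mode == "stdp") 20 else 0
  cfg <- c(list(n_vr = as.integer(n_vr), classes = classes,
                cluster_size = as.integer(cluster_size), preset = preset,
                mode = mode, dt = dt, presentation_ms = presentation_ms,
                silence_ms = silence_ms, f_min = f_min, f_max = f_max,
                generator = generator, gamma_order = as.integer(gamma_order),
                max_per_class = as.integer(max_per_class),
                seed = as.integer(seed)),
           extra)
  structure(cfg, class = "classifier_config")
}

#' Read / write a configuration as YAML
#'
#' Plain-text hierarchical key-value snapshot; reading validates through
#' [classifier_config], so unknown keys are rejected.
#'
#' @param config a `classifier_config`.
#' @param path file path.
#' @return `write_config` returns its input invisibly; `read_config`
#'   returns a `classifier_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(classifier_config, vals)
}

cfg_topology <- function(config, n_classes) {
  build_topology(
    n_vr = config$n_vr, n_classes = n_classes,
    cluster_size = config$cluster_size, preset = config$preset,
    neuron = config$neuron %||% neuron_params(),
    tau_syn_exc = config$tau_syn_exc %||% 5,
    tau_syn_inh = config$tau_syn_inh %||% 10,
    weights = config$weights %||% list(),
    w_max = config$w_max %||% 0.25)
}

# Test stage for the continuous-run (STDP) control flow: one extended
# simulation over the test set with plasticity off, decisions read from
# per-presentation windows (silence gaps excluded).
test_pass_continuous <- function(topology, test, vrs, W, config) {
  input <- encode_concatenated(
    test, vrs, topology, config$f_min, config$f_max,
    config$presentation_ms, config$silence_ms, config$dt,
    config$generator, config$gamma_order,
    seed = derive_seed(config$seed, 404L))
  rec <- simulate_network(topology, input, duration = input$duration,
                          dt = config$dt, W = W, record = "an")
  period <- config$presentation_ms + config$silence_ms
  vapply(seq_len(nrow(test$samples)), function(k) {
    win <- c((k - 1) * period, (k - 1) * period + config$presentation_ms)
    classify_window(rec, win, an_cluster = topology$sizes$an,
                    n_classes = topology$n_classes,
                    tie_rule = config$tie_rule %||% "lowest_index")
  }, integer(1))
}

# Test stage for the stepped (perceptron) control flow: each sample is
# presented to a freshly reset network.
test_pass_stepped <- function(topology, test, vrs, W, config) {
  responses <- vr_response(test$samples, vrs)
  vapply(seq_len(nrow(test$samples)), function(k) {
    rates <- responses_to_rates(responses[k, ], config$f_min, config$f_max)
    input <- gen_poisson_or_gamma(
      rates, config$generator, config$gamma_order, topology$sizes$rn,
      config$presentation_ms, config$dt,
      seed = derive_seed(config$seed, 500000L + k))
    rec <- simulate_network(topology, input,
                            duration = config$presentation_ms,
                            dt = config$dt, W = W, record = "an")
    classify_window(rec, c(0, config$presentation_ms),
                    an_cluster = topology$sizes$an,
                    n_classes = topology$n_classes,
                    tie_rule = config$tie_rule %||% "lowest_index")
  }, integer(1))
}

#' Run a full train-then-test experiment
#'
#' The complete pipeline: subset both splits to the configured classes,
#' fit virtual receptors on the training split alone, encode and train
#' with the configured learning mode, freeze the weights, run a single
#' pass over the test set with plasticity disabled, and score the
#' winner-take-all decisions. Fully deterministic for a fixed master
#' seed.
#'
#' @param config a [classifier_config].
#' @param train,test [al_dataset] splits with features in \[0, 1\].
#' @param vrs optional pre-fitted [vr_set] (reused across runs, e.g.
#'   across learning modes); fitted on `train` when `NULL`.
#' @param out_dir optional directory; when given, the config snapshot,
#'   receptor set, weight matrix and evaluation files are written there.
#' @return A list of class `al_run`: `eval` (an `eval_result` over test
#'   labels), `weights`, `vrs`, `topology`, `config` and
#'   `train_errors` (perceptron mode).
#' @export
run_experiment <- function(config, train, test, vrs = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(config, "classifier_config"))
  if (!is.null(config$classes)) {
    train <- build_subset(train, config$classes, config$max_per_class)
    test <- build_subset(test, config$classes, config$max_per_class)
  }
  class_set <- train$class_set
  test$class_set <- class_set
  n_classes <- length(class_set)
  if (config$n_vr < n_classes) {
    stop_input("n_vr must be at least the number of classes")
  }
  topology <- cfg_topology(config, n_classes)
  if (is.null(vrs)) {
    vrs <- fit_neural_gas(train$samples, config$n_vr,
                          iterations = config$ng_iterations,
                          metric = config$metric %||% "euclidean",
                          sigma = config$sigma,
                          seed = derive_seed(config$seed, 1L))
  }
  train_errors <- NULL
  if (config$mode == "stdp") {
    W <- train_stdp(topology, train, vrs,
                    stdp = config$stdp,
                    f_min = config$f_min, f_max = config$f_max,
                    presentation_ms = config$presentation_ms,
                    silence_ms = config$silence_ms,
                    teach_rate = config$teach_rate %||% 200,
                    teach_w = config$teach_w %||% 2,
                    dt = config$dt, generator = config$generator,
                    gamma_order = config$gamma_order,
                    seed = derive_seed(config$seed, 2L))
    predictions_idx <- test_pass_continuous(topology, test, vrs, W, config)
  } else {
    W <- train_perceptron(topology, train, vrs,
                          p = config$perceptron,
                          f_min = config$f_min, f_max = config$f_max,
                          presentation_ms = config$presentation_ms,
                          dt = config$dt, generator = config$generator,
                          gamma_order = config$gamma_order,
                          epochs = config$epochs %||% 1L,
                          tie_rule = config$tie_rule %||% "lowest_index",
                          seed = derive_seed(config$seed, 3L))
    train_errors <- attr(W, "train_errors")
    attr(W, "train_errors") <- NULL
    predictions_idx <- test_pass_stepped(topology, test, vrs, W, config)
  }
  predictions <- class_set[predictions_idx]
  eval <- score(predictions, test$labels, class_set)
  run <- structure(
    list(eval = eval, weights = W, vrs = vrs, topology = topology,
         config = config, train_errors = train_errors),
    class = "al_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    write_vr_set(vrs, file.path(out_dir, "vr_set.tsv"))
    write_weights(W, file.path(out_dir, "weights.tsv"),
                  mode = config$mode, seed = config$seed)
    write_eval_result(eval, test$labels, file.path(out_dir, "result"))
  }
  run
}

#' @export
print.al_run <- function(x, ...) {
  cat("<al_run> mode ", x$config$mode, ", ", x$config$n_vr, " VRs, ",
      x$topology$n_classes, " classes\n", sep = "")
  print(x$eval)
  invisible(x)
}

#' Sweep receptor counts and class sets
#'
#' Runs one [run_experiment] per (VR count, class set) cell and collects a
#' long-format results table, the protocol behind classification-scaling
#' plots. Within each class set the fitted receptor set of each VR count
#' is reused across learning modes when `modes` has several entries.
#' Infeasible cells (fewer receptors than classes) are skipped with a
#' logged reason.
#'
#' @param base_config a [classifier_config]; `n_vr` and `classes` are
#'   overridden per cell.
#' @param vr_list integer vector of receptor counts.
#' @param class_sets list of class-label vectors.
#' @param train,test [al_dataset] splits.
#' @param modes learning modes to run per cell.
#' @return A data.frame with columns `n_vr`, `classes`, `n_classes`,
#'   `mode`, `accuracy`, `undecided`, `skipped`.
#' @export
scaling_grid <- function(base_config, vr_list, class_sets, train, test,
                         modes = base_config$mode) {
  rows <- list()
  for (cs in class_sets) {
    for (nv in vr_list) {
      key <- paste(cs, collapse = ",")
      if (nv < length(cs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          n_vr = nv, classes = key, n_classes = length(cs),
          mode = NA_character_, accuracy = NA_real_,
          undecided = NA_integer_, skipped = "n_vr < n_classes")
        next
      }
      vrs <- NULL
      for (mode in modes) {
        cfg <- base_config
        cfg$n_vr <- as.integer(nv)
        cfg$classes <- cs
        cfg$mode <- mode
        # re-derive mode defaults the caller did not pin down explicitly
        cfg <- do.call(classifier_config, unclass(cfg))
        sub_train <- build_subset(train, cs, cfg$max_per_class)
        if (is.null(vrs)) {
          vrs <- fit_neural_gas(sub_train$samples, cfg$n_vr,
                                iterations = cfg$ng_iterations,
                                metric = cfg$metric %||% "euclidean",
                                sigma = cfg$sigma,
                                seed = derive_seed(cfg$seed, 1L))
        }
        run <- run_experiment(cfg, train, test, vrs = vrs)
        rows[[length(rows) + 1L]] <- data.frame(
          n_vr = nv, classes = key, n_classes = length(cs), mode = mode,
          accuracy = run$eval$accuracy,
          undecided = run$eval$undecided_count, skipped = NA_character_)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(n_vr = integer(0), classes = character(0),
                      n_classes = integer(0), mode = character(0),
                      accuracy = numeric(0), undecided = integer(0),
                      skipped = character(0)))
  }
  do.call(rbind, rows)
}
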