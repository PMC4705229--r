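#' Winner-take-all class decision from an output spike record
#'
#' Counts AN spikes per class cluster inside the half-open window
#' `[start, end)` and returns the cluster with the highest count. The
#' winning class is the population with the highest spike count; exact
#' ties are resolved by `tie_rule`, and a record with no AN spikes in the
#' window is undecided (`NA`).
#'
#' @param record a `sim_record` (or a [spike_trains] over the AN
#'   population).
#' @param window `c(start, end)` in ms, `start < end`, within the record.
#' @param an_cluster neurons per AN cluster.
#' @param n_classes number of AN clusters.
#' @param tie_rule `"lowest_index"` (deterministic) or `"seeded_random"`.
#' @param tie_seed seed used by the `"seeded_random"` rule.
#' @return Winning cluster index (1-based) with attribute `"tie"` set to
#'   `TRUE` when a tie was broken, or `NA_integer_` when undecided.
#' @export
classify_window <- function(record, window, an_cluster = 30L,
                            n_classes = NULL,
                            tie_rule = c("lowest_index", "seeded_random"),
                            tie_seed = 1L) {
  tie_rule <- match.arg(tie_rule)
  an <- if (inherits(record, "spike_trains")) record else record$an
  if (window[2L] <= window[1L]) stop_input("empty decision window")
  if (is.null(n_classes)) n_classes <- an$n_neurons %/% an_cluster
  counts <- cluster_counts(an, an_cluster, window)[seq_len(n_classes)]
  if (all(counts == 0)) return(NA_integer_)
  winners <- which(counts == max(counts))
  out <- if (length(winners) == 1L) {
    winners
  } else if (tie_rule == "lowest_index") {
    structure(winners[1L], tie = TRUE)
  } else {
    structure(with_seed(tie_seed, sample(winners, 1L)), tie = TRUE)
  }
  out
}

#' Score predictions against true labels
#'
#' Accuracy is the fraction of samples whose prediction matches the label;
#' undecided predictions (`NA`) never match and are tallied separately.
#' The confusion matrix counts decided predictions with rows indexed by
#' true class and columns by predicted class, in `class_set` order.
#'
#' @param predictions vector of predicted labels (values from `class_set`,
#'   or `NA` for undecided).
#' @param labels vector of true labels, same length.
#' @param class_set ordered class labels; defaults to those present in
#'   `labels`.
#' @return An object of class `eval_result`: `predictions`, `accuracy`,
#'   `confusion` and `undecided_count`.
#' @export
score <- function(predictions, labels, class_set = unique(labels)) {
  if (length(predictions) != length(labels)) {
    stop_input("predictions and labels differ in length")
  }
  n_cl <- length(class_set)
  confusion <- matrix(0L, n_cl, n_cl,
                      dimnames = list(true = class_set,
                                      predicted = class_set))
  for (i in seq_along(labels)) {
    if (is.na(predictions[i])) next
    r <- match(labels[i], class_set)
    c <- match(predictions[i], class_set)
    confusion[r, c] <- confusion[r, c] + 1L
  }
  acc <- sum(diag(confusion)) / length(labels)
  structure(
    list(predictions = predictions,
         accuracy = acc,
         confusion = confusion,
         undecided_count = sum(is.na(predictions))),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> accuracy ", sprintf("%.3f", x$accuracy), " (",
      sum(diag(x$confusion)), "/", length(x$predictions), " correct, ",
      x$undecided_count, " undecided)\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold split
#'
#' Partitions the sample indices into `k` folds preserving per-class
#' proportions to within one sample per fold; deterministic for a fixed
#' seed. Used for development-time cross-validation.
#'
#' @param labels class labels, one per sample (or an [al_dataset]).
#' @param k number of folds; every class must have at least `k` samples.
#' @param seed integer seed.
#' @return List of `k` elements, each `list(train = idx, test = idx)`;
#'   the test folds partition the full index set.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  if (inherits(labels, "al_dataset")) labels <- labels$labels
  tab <- table(labels)
  if (any(tab < k)) {
    stop_input("every class needs >= k samples (smallest has ", min(tab), ")")
  }
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == as.integer(cl)))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Export an evaluation result as delimited files
#'
#' Writes a per-sample prediction file, a confusion-matrix file and a
#' one-line accuracy record suitable for assembling scaling grids.
#'
#' @param result an `eval_result`.
#' @param labels true labels used in scoring.
#' @param prefix path prefix; files get suffixes `_predictions.tsv`,
#'   `_confusion.tsv` and `_accuracy.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_eval_result <- function(result, labels, prefix) {
  pp <- paste0(prefix, "_predictions.tsv")
  cp <- paste0(prefix, "_confusion.tsv")
  ap <- paste0(prefix, "_accuracy.tsv")
  write.table(data.frame(sample = seq_along(labels), true = labels,
                         predicted = result$predictions),
              pp, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(result$confusion, cp, sep = "\t", quote = FALSE,
              col.names = NA)
  writeLines(sprintf("accuracy\tundecided\n%.6f\t%d", result$accuracy,
                     result$undecided_count), ap)
  invisible(c(pp, cp, ap))
}
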