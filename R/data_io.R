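#' Labeled multivariate dataset
#'
#' Container for real-valued labeled samples. Features are expected to lie
#' in the unit interval after scaling; virtual-receptor distances are then
#' commensurate with the unit cube.
#'
#' @param samples numeric matrix, one sample per row.
#' @param labels integer-like class labels, one per row of `samples`.
#'
#' @return An object of class `al_dataset`: a list with elements `samples`
#'   (n x d matrix), `labels` (integer vector) and `class_set` (distinct
#'   labels in first-appearance order).
#' @export
al_dataset <- function(samples, labels) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  labels <- as.integer(labels)
  if (nrow(samples) != length(labels)) {
    stop_input("number of samples (", nrow(samples),
               ") does not match number of labels (", length(labels), ")")
  }
  if (anyNA(samples)) stop_input("samples contain NA values")
  structure(
    list(samples = samples, labels = labels,
         class_set = unique(labels)),
    class = "al_dataset"
  )
}

#' @export
print.al_dataset <- function(x, ...) {
  cat("<al_dataset> ", nrow(x$samples), " samples x ", ncol(x$samples),
      " features, classes: ", paste(x$class_set, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.al_dataset <- function(x) dim(x$samples)

idx_read_header <- function(con, expect_magic) {
  magic <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(magic) == 0L || is.na(magic) || magic != expect_magic) {
    stop_input("IDX format error: expected magic number ", expect_magic,
               ", got ", if (length(magic)) magic else "EOF")
  }
  ndim <- bitwAnd(magic, 255L)  # low byte of the magic number is the rank
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  if (length(dims) != ndim || anyNA(dims)) {
    stop_input("IDX format error: truncated header")
  }
  dims
}

#' Read an MNIST-style IDX image/label pair
#'
#' Reads the big-endian IDX binary convention used by MNIST: magic number
#' 2051 for unsigned-byte image files (n x rows x cols) and 2049 for label
#' files. Images are flattened row-major into d = rows*cols features and
#' pixel values are divided by 255 so features lie in \[0, 1\].
#'
#' @param images_path path to the IDX image file.
#' @param labels_path path to the IDX label file.
#'
#' @return An [al_dataset].
#' @export
load_idx <- function(images_path, labels_path) {
  icon <- file(images_path, "rb"); on.exit(close(icon), add = TRUE)
  idims <- idx_read_header(icon, 2051L)
  n <- idims[1L]; d <- prod(idims[-1L])
  pix <- readBin(icon, "integer", n = n * d, size = 1L, signed = FALSE,
                 endian = "big")
  if (length(pix) != n * d) stop_input("IDX format error: truncated image data")

  lcon <- file(labels_path, "rb"); on.exit(close(lcon), add = TRUE)
  ldims <- idx_read_header(lcon, 2049L)
  if (ldims[1L] != n) {
    stop_input("IDX consistency error: ", n, " images but ", ldims[1L],
               " labels")
  }
  labels <- readBin(lcon, "integer", n = n, size = 1L, signed = FALSE,
                    endian = "big")
  if (length(labels) != n) stop_input("IDX format error: truncated label data")

  # row-major flattening: each image's pixels are already contiguous
  samples <- matrix(pix / 255, nrow = n, ncol = d, byrow = TRUE)
  al_dataset(samples, labels)
}

#' Write a dataset as an IDX image/label pair
#'
#' Inverse of [load_idx] for datasets whose feature count is a perfect
#' image shape. Feature values are multiplied by 255 and rounded to
#' unsigned bytes.
#'
#' @param dataset an [al_dataset] with features in \[0, 1\].
#' @param images_path,labels_path output paths.
#' @param rows,cols image shape; `rows * cols` must equal the feature count.
#' @return Invisibly, the dataset.
#' @export
write_idx <- function(dataset, images_path, labels_path,
                      rows = NULL, cols = NULL) {
  d <- ncol(dataset$samples)
  if (is.null(rows)) rows <- as.integer(round(sqrt(d)))
  if (is.null(cols)) cols <- as.integer(d / rows)
  if (rows * cols != d) stop_input("rows * cols must equal feature count")
  n <- nrow(dataset$samples)

  icon <- file(images_path, "wb"); on.exit(close(icon), add = TRUE)
  writeBin(c(2051L, n, rows, cols), icon, size = 4L, endian = "big")
  pix <- as.integer(round(t(dataset$samples) * 255))
  writeBin(as.raw(pix), icon)

  lcon <- file(labels_path, "wb"); on.exit(close(lcon), add = TRUE)
  writeBin(c(2049L, n), lcon, size = 4L, endian = "big")
  writeBin(as.raw(as.integer(dataset$labels)), lcon)
  invisible(dataset)
}

#' Build a benchmark subset by first-come traversal
#'
#' Traverses the dataset in its stored order, without shuffling, keeping
#' each sample whose label is in `allowed` until that class has reached
#' `max_per_class` examples. This mirrors the usual benchmark-construction
#' rule of taking up to a fixed number of examples of each class in
#' encounter order.
#'
#' @param dataset an [al_dataset].
#' @param allowed vector of class labels to keep.
#' @param max_per_class maximum examples retained per class (>= 1).
#'
#' @return An [al_dataset] with samples in their original relative order.
#' @export
build_subset <- function(dataset, allowed, max_per_class) {
  if (max_per_class < 1) stop_input("max_per_class must be >= 1")
  allowed <- as.integer(allowed)
  missing_cls <- setdiff(allowed, dataset$class_set)
  if (length(missing_cls)) {
    warning("classes not present in dataset, dropped: ",
            paste(missing_cls, collapse = ", "), call. = FALSE)
    allowed <- setdiff(allowed, missing_cls)
  }
  taken <- integer(0)
  count <- setNames(integer(length(allowed)), allowed)
  for (i in seq_along(dataset$labels)) {
    lab <- as.character(dataset$labels[i])
    if (lab %in% names(count) && count[[lab]] < max_per_class) {
      taken <- c(taken, i)
      count[[lab]] <- count[[lab]] + 1L
    }
  }
  al_dataset(dataset$samples[taken, , drop = FALSE],
             dataset$labels[taken])
}

#' Generate synthetic Gaussian-cluster class data
#'
#' Places `k_classes` isotropic Gaussian clusters on a regular simplex of
#' means centred in the unit cube so that all pairwise mean distances equal
#' `separation`, then draws `n_per_class` samples per class with standard
#' deviation `noise_sd` and clips them into \[0, 1\]^dim. This is the
#' package's stand-in for external benchmark data: it exercises receptor
#' placement, encoding and class separation under controlled difficulty.
#'
#' @param k_classes number of classes (>= 2, and <= `dim`).
#' @param dim feature dimensionality.
#' @param n_per_class samples drawn for each class.
#' @param separation pairwise distance between class means.
#' @param noise_sd isotropic within-class standard deviation (>= 0).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#'
#' @return An [al_dataset] with labels `0:(k_classes-1)`, samples in
#'   randomized interleaved class order.
#' @export
make_synthetic <- function(k_classes, dim, n_per_class,
                           separation = 0.8, noise_sd = 0.05, seed = 1L) {
  if (k_classes < 2) stop_input("k_classes must be >= 2")
  if (dim < 1) stop_input("dim must be >= 1")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  if (k_classes > dim) {
    stop_input("cannot place ", k_classes,
               " equidistant class means in ", dim, " dimensions")
  }
  # regular simplex: mean_c = center + s*(e_c - 1/k), pairwise distance s*sqrt(2)
  s <- separation / sqrt(2)
  means <- matrix(0.5, nrow = k_classes, ncol = dim)
  for (c in seq_len(k_classes)) {
    means[c, seq_len(k_classes)] <- 0.5 - s / k_classes
    means[c, c] <- 0.5 + s * (1 - 1 / k_classes)
  }
  if (any(means < 0) || any(means > 1)) {
    stop_input("infeasible placement: separation ", separation,
               " pushes class means outside the unit cube")
  }
  with_seed(seed, {
    samples <- matrix(0, nrow = k_classes * n_per_class, ncol = dim)
    labels <- integer(k_classes * n_per_class)
    for (c in seq_len(k_classes)) {
      idx <- (c - 1L) * n_per_class + seq_len(n_per_class)
      noise <- matrix(rnorm(n_per_class * dim, sd = noise_sd),
                      nrow = n_per_class)
      samples[idx, ] <- sweep(noise, 2L, means[c, ], `+`)
      labels[idx] <- c - 1L
    }
    samples[samples < 0] <- 0
    samples[samples > 1] <- 1
    # interleave classes, as a traversal of a real benchmark set would be;
    # blocked-by-class order would starve error-driven learning rules
    ord <- sample.int(nrow(samples))
    ds <- al_dataset(samples[ord, , drop = FALSE], labels[ord])
    ds$class_set <- sort(ds$class_set)
    attr(ds, "class_means") <- means
    ds
  })
}

#' Min-max feature scaling fit on the training split
#'
#' Computes per-feature minimum and range on the training samples only and
#' applies the same affine map to both splits, so no information leaks from
#' the test split. Constant features map to 0. Test values are clipped to
#' \[0, 1\].
#'
#' @param train,test [al_dataset] objects (`test` may be `NULL`).
#' @return A list with scaled `train` and `test` datasets.
#' @export
scale_features <- function(train, test = NULL) {
  lo <- apply(train$samples, 2L, min)
  hi <- apply(train$samples, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  rescale <- function(ds) {
    x <- sweep(sweep(ds$samples, 2L, lo, `-`), 2L, rng, `/`)
    x[x < 0] <- 0; x[x > 1] <- 1
    al_dataset(x, ds$labels)
  }
  list(train = rescale(train),
       test = if (!is.null(test)) rescale(test))
}

#' Read a delimited-text dataset
#'
#' One sample per row; the class label sits in a designated column and all
#' remaining columns are features.
#'
#' @param path file path.
#' @param label_col 1-based index of the label column.
#' @param sep field separator (default: any whitespace).
#' @param header whether the file has a header row.
#' @return An [al_dataset] (unscaled; see [scale_features]).
#' @export
read_delim_dataset <- function(path, label_col = 1L, sep = "",
                               header = FALSE) {
  tab <- read.table(path, sep = sep, header = header)
  labels <- tab[[label_col]]
  feats <- as.matrix(tab[, -label_col, drop = FALSE])
  al_dataset(feats, labels)
}
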