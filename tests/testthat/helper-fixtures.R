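# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no binary fixtures are stored.

# easy, well-separated two-class task in 10 dimensions
easy_pair <- function(n = 30, seed_train = 11, seed_test = 12) {
  list(train = make_synthetic(2, 10, n, separation = 0.8, noise_sd = 0.05,
                              seed = seed_train),
       test = make_synthetic(2, 10, n, separation = 0.8, noise_sd = 0.05,
                             seed = seed_test))
}

# two far-apart classes in 2-d; with sigma = 0.3 their active receptor
# sets after neural gas fitting are disjoint
orthogonal_pair <- function(n = 30, seed_train = 21, seed_test = 22) {
  list(train = make_synthetic(2, 2, n, separation = 0.6, noise_sd = 0.03,
                              seed = seed_train),
       test = make_synthetic(2, 2, n, separation = 0.6, noise_sd = 0.03,
                             seed = seed_test))
}

# a small standard-topology network for simulator unit tests
tiny_topology <- function(n_vr = 4, n_classes = 2, cluster_size = 10, ...) {
  build_topology(n_vr, n_classes, cluster_size, ...)
}

empty_input <- function(topology, duration, dt = 1) {
  spike_trains(integer(0), numeric(0), topology$n_rn, duration, dt)
}

isi_cv <- function(trains, neuron = 1L) {
  t <- trains$events$time[trains$events$neuron == neuron]
  isi <- diff(t)
  sd(isi) / mean(isi)
}

with_seed_for_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# plain Euclidean distance matrix between row sets (independent of the
# package's own distance code)
vr_distances_for_test <- function(a, b) {
  outer(seq_len(nrow(a)), seq_len(nrow(b)),
        Vectorize(function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))))
}

# mean weight of the block linking PN clusters `vr_idx` to AN cluster `cl`
block_mean <- function(W, vr_idx, cl, pn_cluster, an_cluster) {
  rows <- as.vector(outer(seq_len(pn_cluster), (vr_idx - 1L) * pn_cluster, `+`))
  cols <- (cl - 1L) * an_cluster + seq_len(an_cluster)
  mean(W[rows, cols])
}
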