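# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately re-derive quantities by the dumbest
# reliable route so they stay independent of the package's code paths.

# Total cost of the best medoid set found by exhaustive search.
brute_pam_cost <- function(points, k) {
  n <- nrow(points)
  dm <- as.matrix(stats::dist(points))
  best <- Inf
  sets <- utils::combn(n, k)
  for (j in seq_len(ncol(sets))) {
    cost <- sum(apply(dm[, sets[, j], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# Mean silhouette width recomputed from first principles.
brute_silhouette <- function(points, labels) {
  dm <- as.matrix(stats::dist(points))
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(dm[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Well-separated Gaussian blobs in the plane.
make_blobs <- function(centers, n_per = 25, sd = 0.05, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(stats::rnorm(n_per, centers[i, 1], sd),
          stats::rnorm(n_per, centers[i, 2], sd))
  }))
}

# A small, fast configuration for unit tests of the engine.
fast_config <- function(...) {
  args <- list(...)
  defaults <- list(initial_population = 60, total_resource = 300,
                   steps = 50, snapshot_every = 25, seed = 99,
                   grid_nrow = 3, grid_ncol = 3)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

total_resource_of <- function(state) {
  state$pool + sum(state$agents$resource)
}
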