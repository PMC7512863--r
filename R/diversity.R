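# Run code under a fixed seed without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv,
                      inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

validate_proportions <- function(p, tol = 1e-9) {
  if (length(p) == 0 || any(p < 0) || abs(sum(p) - 1) > tol) {
    stop("`p` must be nonnegative proportions summing to 1")
  }
  p
}

#' Shannon entropy of an abundance distribution
#'
#' \eqn{H = -\sum_i p_i \log_b p_i}, with the convention
#' \eqn{0 \log 0 = 0}. With `base = 2` this is the classic
#' Shannon-Wiener index: 3.0 for eight equally common species, 4.0 for
#' sixteen — an *index* of diversity, not an effective number of species
#' (see [hill_number()] for the conversion to true diversity).
#'
#' @param p Species proportions (nonnegative, summing to 1).
#' @param base Logarithm base, > 1. Default 2.
#' @return The entropy (nonnegative scalar).
#' @export
shannon_entropy <- function(p, base = 2) {
  p <- validate_proportions(p)
  if (!is.numeric(base) || length(base) != 1 || base <= 1) {
    stop("`base` must be a single number > 1")
  }
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Hill number (true diversity) of order q
#'
#' The effective number of equally common species,
#' \deqn{{}^qD = \Big(\sum_{i=1}^{S} p_i^q\Big)^{1/(1-q)},}
#' with the q = 1 limit taken as the exponential of Shannon entropy
#' (natural log). Order 0 is species richness, orders below 1 weight
#' rare species, orders above 1 weight common species; for equally
#' common species every order returns the species count, and splitting
#' each species into two equal halves doubles the value at every order
#' (the doubling property).
#'
#' @param p Species proportions (nonnegative, summing to 1).
#' @param q Diversity order, >= 0.
#' @return The effective number of species.
#' @examples
#' hill_number(rep(1 / 8, 8), 1)   # 8
#' hill_number(c(0.8, 0.2), 2)     # 1 / 0.68
#' @export
hill_number <- function(p, q) {
  p <- validate_proportions(p)
  if (!is.numeric(q) || length(q) != 1 || q < 0) {
    stop("`q` must be a single number >= 0")
  }
  p <- p[p > 0]
  if (q == 0) return(length(p))
  if (abs(q - 1) < 1e-9) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Hill numbers at several orders
#'
#' @inheritParams hill_number
#' @param q Vector of orders; defaults to the four reported by the
#'   simulator's diversity reports.
#' @return Named numeric vector (`D0`, `D0.5`, ...).
#' @export
hill_numbers <- function(p, q = c(0, 0.5, 1, 2)) {
  out <- vapply(q, function(qi) hill_number(p, qi), numeric(1))
  names(out) <- paste0("D", q)
  out
}

#' Mean distance from the population centroid
#'
#' The centroid-distance diversity of a population: the average
#' Euclidean distance of genotype points from their arithmetic mean.
#'
#' @param points Numeric matrix of points (one per row) or a single
#'   point as a vector.
#' @return Nonnegative scalar.
#' @export
centroid_distance <- function(points) {
  if (!is.matrix(points)) points <- matrix(points, nrow = 1)
  if (nrow(points) == 0) stop("`points` must be nonempty")
  ctr <- colMeans(points)
  mean(sqrt(rowSums(sweep(points, 2, ctr)^2)))
}

#' Partition points around k medoids
#'
#' Euclidean k-medoids (PAM: BUILD followed by SWAP to convergence, via
#' \pkg{cluster}), so every cluster centre is a data point and the total
#' within-cluster distance is non-increasing over the swap phase. The
#' procedure is deterministic for a given input.
#'
#' @param points Numeric matrix of points, one per row.
#' @param k Number of clusters, between 1 and the number of distinct
#'   points.
#' @param diss Optional precomputed [stats::dist()] of `points` (reused
#'   by [detect_species()] across candidate k).
#' @return An object of class `species_partition`: list with `labels`
#'   (per-point cluster ids, relabelled canonically by decreasing
#'   cluster size), `medoids` (matrix of representative points),
#'   `medoid_idx`, `k`, `cost` (total within-cluster distance) and
#'   `silhouette` (mean silhouette width; `NA` for k = 1).
#' @export
pam_cluster <- function(points, k, diss = NULL) {
  if (!is.matrix(points)) points <- as.matrix(points)
  n <- nrow(points)
  n_distinct <- nrow(unique(points))
  if (k < 1 || k > n_distinct) {
    stop("`k` must be between 1 and the number of distinct points (",
         n_distinct, ")")
  }
  if (is.null(diss)) diss <- stats::dist(points)
  if (k == n) {
    # every point its own medoid; canonical order by coordinates
    ord <- order(points[, 1], points[, 2])
    labels <- integer(n)
    labels[ord] <- seq_len(n)
    part <- list(labels = labels, medoids = points[ord, , drop = FALSE],
                 medoid_idx = ord, k = as.integer(k), cost = 0,
                 silhouette = NA_real_)
    return(structure(part, class = "species_partition"))
  }
  if (k == 1) {
    dm <- as.matrix(diss)
    costs <- colSums(dm)
    med <- which.min(costs)
    part <- list(labels = rep(1L, n),
                 medoids = points[med, , drop = FALSE],
                 medoid_idx = med, k = 1L, cost = costs[[med]],
                 silhouette = NA_real_)
    return(structure(part, class = "species_partition"))
  }
  # pamonce = 3 is an exact acceleration of BUILD + SWAP (same optimum)
  fit <- cluster::pam(diss, k = k, diss = TRUE, keep.diss = FALSE,
                      pamonce = 3)
  dm <- as.matrix(diss)
  swap_cost <- function(f) sum(dm[cbind(seq_len(n),
                                        f$id.med[f$clustering])])
  cost <- swap_cost(fit)
  if (n <= 100) {
    # BUILD can start in a poor basin on tiny instances; a few seeded
    # random restarts make the swap phase reliably reach the optimum.
    # The RNG state of the caller is preserved.
    alt <- with_preserved_seed(n + 1000L * k, {
      cluster::pam(diss, k = k, diss = TRUE, keep.diss = FALSE,
                   medoids = "random", nstart = 10, pamonce = 3)
    })
    if (swap_cost(alt) < cost - 1e-12) {
      fit <- alt
      cost <- swap_cost(alt)
    }
  }
  labels <- as.integer(fit$clustering)
  med_idx <- as.integer(fit$id.med)
  part <- canonical_relabel(labels, med_idx, points)
  structure(list(labels = part$labels,
                 medoids = points[part$medoid_idx, , drop = FALSE],
                 medoid_idx = part$medoid_idx, k = as.integer(k),
                 cost = cost,
                 silhouette = fit$silinfo$avg.width),
            class = "species_partition")
}

# Relabel clusters 1..k by decreasing size; ties broken by medoid
# coordinates (lexicographically), so labels do not depend on input
# order.
canonical_relabel <- function(labels, med_idx, points) {
  sizes <- tabulate(labels, nbins = length(med_idx))
  ord <- order(-sizes, points[med_idx, 1], points[med_idx, 2])
  new_of_old <- integer(length(med_idx))
  new_of_old[ord] <- seq_along(ord)
  list(labels = new_of_old[labels], medoid_idx = med_idx[ord])
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("<species_partition: k = %d, n = %d, mean silhouette = %s>\n",
              x$k, length(x$labels),
              ifelse(is.na(x$silhouette), "NA",
                     formatC(x$silhouette, digits = 3, format = "f"))))
  invisible(x)
}

#' Detect species by k-medoid clustering with silhouette selection
#'
#' Runs [pam_cluster()] for k = 2..`kmax` and keeps the k with the
#' largest mean silhouette width (ties go to the smaller k). When even
#' the best mean silhouette falls below `silhouette_floor` the
#' population is treated as a single species (k = 1); fewer than two
#' points, or fewer than two distinct points, also give the trivial
#' single-cluster partition. Species are defined in genetic space:
#' cluster on the genotype `x` coordinates only.
#'
#' The floor guards against splitting structureless point clouds: a
#' single Gaussian or uniform blob scores a best mean silhouette of
#' roughly 0.3-0.45 under k-medoids, while genuinely separated groups
#' score well above 0.5, so 0.5 is used as the default boundary.
#'
#' @param points Numeric matrix of genotype coordinates, one agent per
#'   row.
#' @param kmax Largest cluster count tried (default 10).
#' @param silhouette_floor Minimum acceptable mean silhouette width
#'   (default 0.5) below which k = 1 is returned.
#' @return A `species_partition` (see [pam_cluster()]).
#' @export
detect_species <- function(points, kmax = 10, silhouette_floor = 0.5) {
  if (!is.matrix(points)) points <- as.matrix(points)
  n <- nrow(points)
  trivial <- function() {
    structure(list(labels = rep(1L, n),
                   medoids = points[min(1, n), , drop = FALSE],
                   medoid_idx = if (n) 1L else integer(0), k = 1L,
                   cost = NA_real_, silhouette = NA_real_),
              class = "species_partition")
  }
  if (n < 2 || nrow(unique(points)) < 2) return(trivial())
  diss <- stats::dist(points)
  ks <- 2:min(kmax, nrow(unique(points)))
  best <- NULL
  for (k in ks) {
    part <- pam_cluster(points, k, diss = diss)
    if (is.null(best) || isTRUE(part$silhouette > best$silhouette)) {
      best <- part
    }
  }
  if (is.na(best$silhouette) || best$silhouette < silhouette_floor) {
    part <- pam_cluster(points, 1, diss = diss)
    part$silhouette <- best$silhouette
    return(part)
  }
  best
}

#' Species abundances of a partition
#'
#' @param partition A `species_partition`.
#' @return Proportions of agents per species, ready for
#'   [hill_number()].
#' @export
species_abundances <- function(partition) {
  counts <- tabulate(partition$labels, nbins = partition$k)
  counts / sum(counts)
}

#' Full diversity report for a population snapshot
#'
#' Detects species with [detect_species()], converts the label counts to
#' abundances, and reports the four Hill numbers together with the
#' centroid-distance diversity.
#'
#' @param points Numeric matrix of genotype coordinates (one agent per
#'   row); may be empty.
#' @param kmax Passed to [detect_species()].
#' @param max_points Clustering is performed on an evenly strided
#'   subsample of at most this many points when the population is larger
#'   (centroid distance always uses all points).
#' @return A one-row `data.frame`: `n_agents`, `n_species`, `D0`,
#'   `D0.5`, `D1`, `D2`, `centroid_distance`, `silhouette`.
#' @export
diversity_report <- function(points, kmax = 10, max_points = 2000) {
  if (!is.matrix(points)) points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) {
    return(data.frame(n_agents = 0L, n_species = 0L, D0 = NA_real_,
                      "D0.5" = NA_real_, D1 = NA_real_, D2 = NA_real_,
                      centroid_distance = NA_real_,
                      silhouette = NA_real_, check.names = FALSE))
  }
  cl_points <- if (n > max_points) {
    points[seq(1, n, length.out = max_points), , drop = FALSE]
  } else {
    points
  }
  part <- detect_species(cl_points, kmax = kmax)
  p <- species_abundances(part)
  d <- hill_numbers(p)
  data.frame(n_agents = n, n_species = part$k,
             D0 = d[["D0"]], "D0.5" = d[["D0.5"]], D1 = d[["D1"]],
             D2 = d[["D2"]],
             centroid_distance = centroid_distance(points),
             silhouette = part$silhouette, check.names = FALSE)
}
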