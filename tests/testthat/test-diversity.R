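test_that("shannon entropy reproduces the textbook worked example", {
  expect_equal(shannon_entropy(rep(1 / 8, 8), base = 2), 3.0)
  expect_equal(shannon_entropy(rep(1 / 16, 16), base = 2), 4.0)
  expect_equal(shannon_entropy(1, base = 2), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0), base = 2), 1)  # 0 log 0 = 0
  expect_error(shannon_entropy(rep(1 / 4, 4), base = 1), "> 1")
  expect_error(shannon_entropy(c(0.5, 0.4)), "summing to 1")
})

test_that("hill numbers give S for equal abundances at every order", {
  for (S in c(1, 2, 8, 16)) {
    p <- rep(1 / S, S)
    for (q in c(0, 0.5, 1, 2)) {
      expect_equal(hill_number(p, q), S)
    }
  }
  # direct evaluation at q = 2: 1 / (0.64 + 0.04)
  expect_equal(hill_number(c(0.8, 0.2), 2), 1 / 0.68)
  expect_equal(hill_number(c(0.8, 0.2), 0), 2)
  expect_error(hill_number(c(0.8, 0.2), -1), ">= 0")
})

test_that("the doubling property holds at all four orders", {
  set.seed(14)
  for (i in 1:20) {
    p <- as.numeric(rmultinom(1, 500, runif(sample(2:12, 1))))
    p <- p[p > 0] / sum(p)
    halves <- rep(p / 2, each = 2)
    for (q in c(0, 0.5, 1, 2)) {
      expect_equal(hill_number(halves, q), 2 * hill_number(p, q))
    }
  }
})

test_that("hill numbers are non-increasing in q and continuous at q = 1", {
  set.seed(15)
  for (i in 1:20) {
    p <- runif(sample(2:15, 1)); p <- p / sum(p)
    qs <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3)
    d <- vapply(qs, function(q) hill_number(p, q), numeric(1))
    expect_true(all(diff(d) <= 1e-9))
    expect_lt(abs(hill_number(p, 1 + 1e-6) - hill_number(p, 1)), 1e-4)
    expect_lt(abs(hill_number(p, 1 - 1e-6) - hill_number(p, 1)), 1e-4)
    # exp-shannon identity with the natural log
    expect_equal(shannon_entropy(p, base = exp(1)),
                 log(hill_number(p, 1)))
  }
})

test_that("centroid distance equals a brute-force reimplementation", {
  expect_equal(centroid_distance(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
  expect_equal(centroid_distance(rbind(c(0, 0), c(2, 0))), 1)
  set.seed(16)
  X <- matrix(rnorm(200), ncol = 2)
  ctr <- c(mean(X[, 1]), mean(X[, 2]))
  brute <- mean(apply(X, 1, function(r) sqrt(sum((r - ctr)^2))))
  expect_equal(centroid_distance(X), brute, tolerance = 1e-12)
  expect_error(centroid_distance(X[0, , drop = FALSE]), "nonempty")
})

test_that("pam matches exhaustive medoid search on tiny instances", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    k <- sample(1:3, 1)
    X <- matrix(runif(2 * n, 0, 10), ncol = 2)
    part <- pam_cluster(X, k)
    expect_equal(part$cost, brute_pam_cost(X, k), tolerance = 1e-9)
    expect_equal(sort(unique(part$labels)), seq_len(k))
  }
})

test_that("pam separates well-separated groups and handles k = n", {
  X <- rbind(make_blobs(rbind(c(0, 0)), 3, 0.01, seed = 2),
             make_blobs(rbind(c(10, 10)), 3, 0.01, seed = 3))
  part <- pam_cluster(X, 2)
  expect_equal(part$labels[1:3], rep(part$labels[1], 3))
  expect_equal(part$labels[4:6], rep(part$labels[4], 3))
  expect_true(part$labels[1] != part$labels[4])
  Y <- matrix(c(0, 0, 1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE)
  expect_equal(pam_cluster(Y, 4)$cost, 0)
  expect_error(pam_cluster(Y, 5), "distinct")
})

test_that("species detection recovers blob counts via the silhouette", {
  two <- make_blobs(rbind(c(0, 0), c(5, 5)), 30, 0.5, seed = 4)
  p2 <- detect_species(two)
  expect_equal(p2$k, 2L)
  four <- make_blobs(rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8)), 25, 0.4,
                     seed = 5)
  p4 <- detect_species(four, kmax = 10)
  expect_equal(p4$k, 4L)
  # the implementation's silhouette agrees with a brute-force one
  expect_equal(p4$silhouette, brute_silhouette(four, p4$labels),
               tolerance = 1e-9)
  # and its chosen k maximizes the brute-force mean silhouette over 2..6
  sil <- vapply(2:6, function(k) {
    brute_silhouette(four, pam_cluster(four, k)$labels)
  }, numeric(1))
  expect_equal(which.max(sil) + 1L, p4$k)
})

test_that("a single diffuse blob falls back to one species", {
  one <- make_blobs(rbind(c(0, 0)), 80, 1.0, seed = 6)
  expect_equal(detect_species(one)$k, 1L)
  # degenerate inputs
  expect_equal(detect_species(one[1, , drop = FALSE])$k, 1L)
  expect_equal(detect_species(rbind(c(1, 1), c(1, 1), c(1, 1)))$k, 1L)
})

test_that("species labels are invariant to input order", {
  X <- rbind(make_blobs(rbind(c(0, 0)), 40, 0.4, seed = 7),
             make_blobs(rbind(c(8, 0)), 30, 0.4, seed = 8),
             make_blobs(rbind(c(0, 8)), 20, 0.4, seed = 9))
  set.seed(10)
  perm <- sample(nrow(X))
  a <- detect_species(X)
  b <- detect_species(X[perm, , drop = FALSE])
  expect_equal(a$k, b$k)
  expect_equal(a$labels[perm], b$labels)
  # canonical labels are ordered by decreasing cluster size
  expect_true(all(diff(tabulate(a$labels, a$k)) <= 0))
})

test_that("diversity reports combine species counts and hill numbers", {
  X <- rbind(make_blobs(rbind(c(0, 0)), 30, 0.2, seed = 11),
             make_blobs(rbind(c(6, 6)), 10, 0.2, seed = 12))
  rep <- diversity_report(X)
  expect_equal(rep$n_agents, 40L)
  expect_equal(rep$n_species, 2L)
  p <- c(30, 10) / 40
  expect_equal(rep$D0, 2)
  expect_equal(rep$D1, hill_number(p, 1))
  expect_equal(rep$D2, hill_number(p, 2))
  expect_equal(rep$centroid_distance, centroid_distance(X))
  empty <- diversity_report(X[0, , drop = FALSE])
  expect_equal(empty$n_agents, 0L)
  expect_true(is.na(empty$D1))
})
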