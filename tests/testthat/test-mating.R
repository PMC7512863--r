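test_that("readiness is an inclusive threshold on the nominal share", {
  expect_false(ready_for_reproduction(0, 0.5, 5))
  expect_true(ready_for_reproduction(2.5, 0.5, 5))
  expect_false(ready_for_reproduction(2.49, 0.5, 5))
  expect_equal(ready_for_reproduction(c(1, 3), 0.5, 5), c(FALSE, TRUE))
})

test_that("preference distance is the symmetric euclidean metric", {
  expect_equal(preference_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(preference_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(preference_distance(c(3, 4), c(0, 0)), 5)
  expect_equal(preference_distance(c(0, 0), rbind(c(3, 4), c(0, 1))),
               c(5, 1))
})

test_that("choice weights decrease in distance as 1/(1+d)", {
  expect_equal(choice_weights(0), 1)
  expect_equal(choice_weights(c(0, 1)), c(2 / 3, 1 / 3))
  w <- choice_weights(c(0, 0.5, 1, 4))
  expect_true(all(diff(w) < 0))
  expect_equal(sum(w), 1)
  expect_error(choice_weights(numeric(0)), "empty")
})

test_that("partner sampling matches the stated laws over many draws", {
  d <- c(0, 1, 3)
  p_true <- choice_weights(d)  # (4/7, 2/7, 1/7)
  expect_equal(p_true, c(4, 2, 1) / 7)
  n <- 1e5
  set.seed(21)
  picks <- replicate(n, choose_partner(d, sexual_selection = TRUE))
  freq <- tabulate(picks, 3) / n
  tol <- 3 * sqrt(p_true * (1 - p_true) / n)
  expect_true(all(abs(freq - p_true) < tol))
  # uniform when sexual selection is off
  set.seed(22)
  picks0 <- replicate(n, choose_partner(d, sexual_selection = FALSE))
  freq0 <- tabulate(picks0, 3) / n
  tol0 <- 3 * sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq0 - 1 / 3) < tol0))
  # degenerate candidate sets
  expect_identical(choose_partner(numeric(0)), NA_integer_)
  expect_identical(choose_partner(2.5), 1L)
  expect_identical(choose_partner(2.5, FALSE), 1L)
})

test_that("pair formation enforces the field-of-view and state invariants", {
  st <- initialize_world(fast_config())
  fem <- st$agents$id[st$agents$sex == "F"]
  mal <- st$agents$id[st$agents$sex == "M"]
  fi <- match(fem[1], st$agents$id)
  mi <- match(mal[1], st$agents$id)
  st$agents$node[mi] <- st$agents$node[fi]
  st2 <- form_pair(st, fem[1], mal[1])
  expect_length(st2$pairs$id, 1)
  expect_equal(st2$pairs$age, 0L)
  expect_equal(st2$agents$pair_id[c(fi, mi)], rep(st2$pairs$id, 2))
  # same sex, already paired, and cross-node requests are rejected
  expect_error(form_pair(st2, fem[1], mal[2]), "unpaired")
  expect_error(form_pair(st, fem[1], fem[2]), "female and one male")
  mj <- match(mal[2], st$agents$id)
  st$agents$node[mj] <- setdiff(seq_along(st$graph), st$agents$node[fi])[1]
  expect_error(form_pair(st, fem[1], mal[2]), "same node")
  # a starving agent cannot pair
  st$agents$resource[fi] <- 0
  st$agents$node[mj] <- st$agents$node[fi]
  expect_error(form_pair(st, fem[1], mal[2]), "ready")
})

test_that("pairs age, expire past max_pair_age, and widows are released", {
  st <- initialize_world(fast_config())
  fem <- st$agents$id[st$agents$sex == "F"][1]
  mal <- st$agents$id[st$agents$sex == "M"][1]
  fi <- match(fem, st$agents$id); mi <- match(mal, st$agents$id)
  st$agents$node[mi] <- st$agents$node[fi]
  st <- form_pair(st, fem, mal)
  st2 <- age_and_dissolve_pairs(st, max_pair_age = 10)
  expect_equal(st2$pairs$age, 1L)
  st3 <- age_and_dissolve_pairs(st, max_pair_age = 0)
  expect_length(st3$pairs$id, 0)
  expect_true(all(is.na(st3$agents$pair_id)))
  # partner death dissolves the pair and unpairs the survivor
  st4 <- st
  dead <- match(mal, st4$agents$id)
  for (f in c("id", "sex", "resource", "node", "pair_id", "age")) {
    st4$agents[[f]] <- st4$agents[[f]][-dead]
  }
  st4$agents$x <- st4$agents$x[-dead, , drop = FALSE]
  st4$agents$sigma <- st4$agents$sigma[-dead, , drop = FALSE]
  st4 <- age_and_dissolve_pairs(st4, max_pair_age = 10)
  expect_length(st4$pairs$id, 0)
  expect_true(is.na(st4$agents$pair_id[match(fem, st4$agents$id)]))
})

test_that("ephemeral pairs (max age 0) reproduce once and vanish", {
  cfg <- fast_config(pairing = FALSE, steps = 0)
  st <- initialize_world(cfg)
  expect_equal(st$config$max_pair_age, 0L)
  st1 <- sim_step(st)
  formed <- length(st1$pairs$id)
  expect_gt(formed, 0)  # pairs do form and reproduce within the step
  expect_gt(length(st1$agents$id), length(st$agents$id))
  st2 <- sim_step(st1)
  # pairs born at step t are gone by the mate-choice phase of t+1:
  # every pair alive after step t+1 was formed at t+1 (age 0)
  expect_true(all(st2$pairs$age == 0L))
  expect_false(any(st1$pairs$id %in% st2$pairs$id))
})

test_that("reproduction transfers the stated resource and conserves it", {
  st <- initialize_world(fast_config())
  fem <- st$agents$id[st$agents$sex == "F"][1]
  mal <- st$agents$id[st$agents$sex == "M"][1]
  fi <- match(fem, st$agents$id); mi <- match(mal, st$agents$id)
  st$agents$node[mi] <- st$agents$node[fi]
  st$agents$resource[c(fi, mi)] <- c(1, 1) * st$nominal_share
  st <- form_pair(st, fem, mal)
  total0 <- total_resource_of(st)
  n0 <- length(st$agents$id)
  set.seed(31)
  st2 <- reproduce_pair(st, st$pairs$id[1])
  expect_equal(length(st2$agents$id), n0 + 2)
  s <- st$nominal_share
  # female pays 40%, male 20%, children split the transfer equally
  expect_equal(st2$agents$resource[fi], 0.6 * s)
  expect_equal(st2$agents$resource[mi], 0.8 * s)
  kids <- (n0 + 1):(n0 + 2)
  expect_equal(st2$agents$resource[kids], rep((0.4 * s + 0.2 * s) / 2, 2))
  expect_equal(sort(st2$agents$sex[kids]), c("F", "M"))
  expect_equal(st2$agents$node[kids], rep(st$agents$node[fi], 2))
  expect_equal(total_resource_of(st2), total0)
  # offspring lie inside the landscape domain box
  land <- st$land
  expect_true(all(st2$agents$x[kids, 1] >= land$lower[1] &
                    st2$agents$x[kids, 1] <= land$upper[1]))
  # a not-ready pair skips reproduction silently
  st$agents$resource[fi] <- 0.1
  st3 <- reproduce_pair(st, st$pairs$id[1])
  expect_equal(length(st3$agents$id), n0)
})

test_that("identical parents with mutation suppressed breed true", {
  st <- initialize_world(fast_config(mut_prob = 0))
  fem <- st$agents$id[st$agents$sex == "F"][1]
  mal <- st$agents$id[st$agents$sex == "M"][1]
  fi <- match(fem, st$agents$id); mi <- match(mal, st$agents$id)
  st$agents$node[mi] <- st$agents$node[fi]
  st$agents$x[mi, ] <- st$agents$x[fi, ]
  st$agents$sigma[mi, ] <- st$agents$sigma[fi, ]
  st <- form_pair(st, fem, mal)
  set.seed(8)
  st2 <- reproduce_pair(st, st$pairs$id[1])
  n <- length(st2$agents$id)
  expect_equal(st2$agents$x[n - 1, ], st$agents$x[fi, ])
  expect_equal(st2$agents$x[n, ], st$agents$x[fi, ])
})

test_that("sexual selection over identical males is uniform choice", {
  d <- rep(1.25, 6)
  expect_equal(choice_weights(d), rep(1 / 6, 6))
})

test_that("no same-sex or cross-node reproduction occurs in a run", {
  res <- run_simulation(fast_config(steps = 40, snapshot_every = 40))
  st <- res$final_state
  if (length(st$pairs$id)) {
    fr <- match(st$pairs$female, st$agents$id)
    mr <- match(st$pairs$male, st$agents$id)
    expect_true(all(st$agents$sex[fr] == "F"))
    expect_true(all(st$agents$sex[mr] == "M"))
    expect_true(all(st$agents$node[fr] == st$agents$node[mr]))
  }
})
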