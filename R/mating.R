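#' Is an agent ready for reproduction?
#'
#' An agent is ready when its resource level is at least `min_rep_res`
#' times the nominal per-capita share (total resource divided by the
#' founding population size); the boundary is inclusive.
#'
#' @param resource Numeric vector of agent resource levels.
#' @param min_rep_res Readiness coefficient (default 0.5).
#' @param nominal_share Nominal per-capita resource share.
#' @return Logical vector.
#' @export
ready_for_reproduction <- function(resource, min_rep_res, nominal_share) {
  resource >= min_rep_res * nominal_share
}

#' Distance between female preferences and male displayed traits
#'
#' Mate choice operates in genetic space: the Euclidean distance between
#' a female's preference vector and a male's trait vector (both are the
#' genotype's independent variables). Genetic space has nothing in common
#' with the environment graph in which the agents are located.
#'
#' @param female_x,male_x Numeric 2-vectors, or a single female vector
#'   and an n x 2 matrix of male trait rows.
#' @return Nonnegative distance(s).
#' @export
preference_distance <- function(female_x, male_x) {
  if (is.matrix(male_x)) {
    sqrt((male_x[, 1] - female_x[1])^2 + (male_x[, 2] - female_x[2])^2)
  } else {
    sqrt(sum((female_x - male_x)^2))
  }
}

#' Mate-choice probabilities from preference distances
#'
#' The better a male's displayed traits match the female's preferences,
#' the higher his selection probability. The weight form is
#' \eqn{w_i = 1/(1 + d_i)}, normalized to sum to one: bounded, strictly
#' decreasing in distance, and never exactly zero, so a small flow of
#' genes between emerging subpopulations always remains possible.
#'
#' @param distances Nonempty vector of nonnegative distances.
#' @return Probability vector over the candidates.
#' @examples
#' choice_weights(c(0, 1))  # c(2/3, 1/3)
#' @export
choice_weights <- function(distances) {
  if (length(distances) == 0) stop("empty candidate set")
  w <- 1 / (1 + distances)
  w / sum(w)
}

#' Sample a partner index for a female
#'
#' With sexual selection on, samples one candidate male with probability
#' proportional to [choice_weights()] of the preference distances; with
#' sexual selection off, samples uniformly. Draws come from R's global
#' RNG stream.
#'
#' @param distances Preference distances to the candidate males (may be
#'   empty).
#' @param sexual_selection Logical toggle.
#' @return Integer index into the candidate set, or `NA_integer_` when
#'   there are no candidates.
#' @export
choose_partner <- function(distances, sexual_selection = TRUE) {
  m <- length(distances)
  if (m == 0) return(NA_integer_)
  if (m == 1) return(1L)
  if (sexual_selection) {
    sample.int(m, 1, prob = choice_weights(distances))
  } else {
    sample.int(m, 1)
  }
}

#' Bind a female and a male into a pair
#'
#' Both agents must be alive, unpaired, of opposite sexes, in the same
#' node, and ready for reproduction. The new pair starts at pair age 0;
#' from then on the two migrate together and reproduce until the pair
#' dissolves.
#'
#' @param state A `world_state`.
#' @param female_id,male_id Agent ids.
#' @return The updated `world_state`.
#' @export
form_pair <- function(state, female_id, male_id) {
  fi <- match(female_id, state$agents$id)
  mi <- match(male_id, state$agents$id)
  if (is.na(fi) || is.na(mi)) stop("unknown agent id")
  if (state$agents$sex[fi] != "F" || state$agents$sex[mi] != "M") {
    stop("a pair binds one female and one male")
  }
  if (!is.na(state$agents$pair_id[fi]) || !is.na(state$agents$pair_id[mi])) {
    stop("both agents must be unpaired")
  }
  if (state$agents$node[fi] != state$agents$node[mi]) {
    stop("agents can only pair within the same node")
  }
  thr <- state$config$min_rep_res * state$nominal_share
  if (state$agents$resource[fi] < thr || state$agents$resource[mi] < thr) {
    stop("both agents must be ready for reproduction")
  }
  pid <- state$next_pair
  state$next_pair <- pid + 1L
  state$pairs$id <- c(state$pairs$id, pid)
  state$pairs$female <- c(state$pairs$female, female_id)
  state$pairs$male <- c(state$pairs$male, male_id)
  state$pairs$age <- c(state$pairs$age, 0L)
  state$agents$pair_id[c(fi, mi)] <- pid
  state
}

#' Age pairs and dissolve expired or widowed ones
#'
#' Increments every pair's age by one step, then dissolves pairs that are
#' older than `max_pair_age` or have lost a member. With
#' `max_pair_age = 0` a pair formed at step t reproduces at most once and
#' is dissolved here at the start of step t+1, before any mate choice, so
#' pairing is effectively ephemeral.
#'
#' @param state A `world_state`.
#' @param max_pair_age Maximum pair age in steps; defaults to the
#'   configured value.
#' @return The updated `world_state`.
#' @export
age_and_dissolve_pairs <- function(state,
                                   max_pair_age = state$config$max_pair_age) {
  if (length(state$pairs$id) == 0) return(state)
  state$pairs$age <- state$pairs$age + 1L
  alive_f <- state$pairs$female %in% state$agents$id
  alive_m <- state$pairs$male %in% state$agents$id
  drop <- state$pairs$age > max_pair_age | !alive_f | !alive_m
  dissolve_pairs(state, which(drop))
}

# Remove pairs by registry position, unlinking surviving members.
dissolve_pairs <- function(state, pos) {
  if (length(pos) == 0) return(state)
  members <- c(state$pairs$female[pos], state$pairs$male[pos])
  rows <- match(members, state$agents$id)
  state$agents$pair_id[rows[!is.na(rows)]] <- NA_integer_
  for (f in c("id", "female", "male", "age")) {
    state$pairs[[f]] <- state$pairs[[f]][-pos]
  }
  state
}

#' Reproduce a pair
#'
#' If both members are ready for reproduction, two offspring are created.
#' Each offspring genotype comes from [offspring_genotype()] (intermediate
#' recombination with probability `rec_prob`, then self-adaptive mutation
#' with probability `mut_prob`) and is clamped to the landscape's domain
#' box. The parents transfer `female_rep_cost * r_female +
#' male_rep_cost * r_male` of resource, split equally between the two
#' children — reproduction is costlier for the female — and the children
#' are placed in the pair's node at age 0. By default one child is female
#' and one male, preserving the near-equal sex ratio; set
#' `offspring_sex_rule = "coin"` in the configuration for independent
#' fair-coin sexes. If either member is not ready, reproduction is
#' silently skipped.
#'
#' @param state A `world_state`.
#' @param pair_id Id of the pair.
#' @return The updated `world_state`; total resource is unchanged.
#' @export
reproduce_pair <- function(state, pair_id) {
  p <- match(pair_id, state$pairs$id)
  if (is.na(p)) stop("unknown pair id: ", pair_id)
  fi <- match(state$pairs$female[p], state$agents$id)
  mi <- match(state$pairs$male[p], state$agents$id)
  thr <- state$config$min_rep_res * state$nominal_share
  r_f <- state$agents$resource[fi]
  r_m <- state$agents$resource[mi]
  if (r_f < thr || r_m < thr) return(state)

  vp <- state$vparams
  g_f <- genotype(state$agents$x[fi, ], state$agents$sigma[fi, ])
  g_m <- genotype(state$agents$x[mi, ], state$agents$sigma[mi, ])
  kids <- lapply(1:2, function(i) offspring_genotype(g_f, g_m, vp))

  transfer <- state$config$female_rep_cost * r_f +
    state$config$male_rep_cost * r_m
  state$agents$resource[fi] <- r_f - state$config$female_rep_cost * r_f
  state$agents$resource[mi] <- r_m - state$config$male_rep_cost * r_m

  sexes <- if (identical(state$config$offspring_sex_rule, "coin")) {
    ifelse(stats::runif(2) < 0.5, "F", "M")
  } else {
    c("F", "M")
  }
  node <- state$agents$node[fi]
  for (i in 1:2) {
    xi <- clamp_to_domain(state$land, kids[[i]]$x)
    state <- add_agent(state, sex = sexes[i], x = xi,
                       sigma = kids[[i]]$sigma, resource = transfer / 2,
                       node = node)
  }
  state
}
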