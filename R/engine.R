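#' Simulation configuration
#'
#' Collects every tunable of the simulator with the model's reference
#' values as defaults. Resource coefficients are fractions in [0, 1];
#' `max_pair_age` is in steps (0 means pairs dissolve right after their
#' first reproduction opportunity; use a value >= `steps` for lifelong
#' pairs).
#'
#' @param landscape Landscape name (see [landscape_names()]).
#' @param grid_nrow,grid_ncol Torus grid dimensions of the environment.
#' @param initial_population Number of founders (must be even, for an
#'   exact 50/50 sex split).
#' @param total_resource Total resource circulating in the closed system.
#' @param dispense_rate Fraction of the environment pool released per
#'   step, split equally over occupied nodes and within each node in
#'   proportion to [quality_weights()].
#' @param upkeep Per-step living cost charged to every agent, expressed
#'   as a fraction of the nominal per-capita share
#'   (`total_resource / initial_population`); agents unable to pay fall
#'   to zero and die.
#' @param max_pair_age Maximum pair age in steps.
#' @param mut_prob,rec_prob Mutation / recombination probabilities per
#'   offspring.
#' @param min_rep_res Readiness coefficient: reproduction requires at
#'   least `min_rep_res` times the nominal per-capita share.
#' @param female_rep_cost,male_rep_cost Fractions of the parents' current
#'   resource transferred to the brood (the female's is higher).
#' @param mig_cost Fraction of an agent's resource returned to the
#'   environment on migration.
#' @param sexual_selection Logical: females choose by preference match
#'   (`TRUE`) or uniformly (`FALSE`).
#' @param pairing Logical: `FALSE` forces `max_pair_age = 0` (ephemeral
#'   pairs, i.e. no pair-bond persistence).
#' @param move_prob Per-step probability of a spontaneous move for
#'   unpaired non-searching agents and for pairs.
#' @param selection_eps Floor coefficient of [quality_weights()] used
#'   when dispensing: small values give harsh winner-take-all selection,
#'   larger values a milder income gradient between niches.
#' @param search_success Probability that a searching female completes
#'   a partner choice in a given step; searching costs resource every
#'   step it goes on, so values below 1 make partner search consume
#'   both time and resource.
#' @param dispensing `"global"` (fitness-proportional over the whole
#'   population) or `"per_node"` (pool split equally over occupied
#'   nodes, fitness-proportional within each node).
#' @param init_sigma_frac Founders' mutation deviations as a fraction of
#'   each coordinate's domain width.
#' @param death_floor_frac An agent dies when its resource falls to or
#'   below this fraction of the nominal share.
#' @param offspring_sex_rule `"balanced"` (one female + one male per
#'   brood) or `"coin"`.
#' @param steps Number of steps for [run_simulation()].
#' @param snapshot_every Snapshot cadence in steps.
#' @param seed Integer RNG seed; every stochastic decision in a run comes
#'   from the single stream it initializes.
#' @param michalewicz_m Steepness parameter of the Michalewicz landscape.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(landscape = "rastrigin",
                       grid_nrow = 4, grid_ncol = 4,
                       initial_population = 200,
                       total_resource = 1000,
                       dispense_rate = 0.1,
                       upkeep = 0.01,
                       max_pair_age = 5000,
                       mut_prob = 0.1,
                       rec_prob = 0.8,
                       min_rep_res = 0.5,
                       female_rep_cost = 0.4,
                       male_rep_cost = 0.2,
                       mig_cost = 0.05,
                       sexual_selection = TRUE,
                       pairing = TRUE,
                       move_prob = 0.01,
                       selection_eps = 0.03,
                       search_success = 1,
                       dispensing = c("global", "per_node"),
                       init_sigma_frac = 0.1,
                       death_floor_frac = 1e-6,
                       offspring_sex_rule = c("balanced", "coin"),
                       steps = 5000,
                       snapshot_every = 500,
                       seed = 42L,
                       michalewicz_m = 10) {
  cfg <- list(landscape = landscape, grid_nrow = grid_nrow,
              grid_ncol = grid_ncol,
              initial_population = as.integer(initial_population),
              total_resource = total_resource,
              dispense_rate = dispense_rate, upkeep = upkeep,
              max_pair_age = as.integer(max_pair_age),
              mut_prob = mut_prob, rec_prob = rec_prob,
              min_rep_res = min_rep_res,
              female_rep_cost = female_rep_cost,
              male_rep_cost = male_rep_cost, mig_cost = mig_cost,
              sexual_selection = isTRUE(sexual_selection),
              pairing = isTRUE(pairing), move_prob = move_prob,
              selection_eps = selection_eps,
              search_success = search_success,
              dispensing = match.arg(dispensing),
              init_sigma_frac = init_sigma_frac,
              death_floor_frac = death_floor_frac,
              offspring_sex_rule = match.arg(offspring_sex_rule),
              steps = as.integer(steps),
              snapshot_every = as.integer(snapshot_every),
              seed = as.integer(seed), michalewicz_m = michalewicz_m)
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  if (!cfg$landscape %in% landscape_names()) {
    stop("unknown landscape: '", cfg$landscape, "'")
  }
  fracs <- c("dispense_rate", "upkeep", "mut_prob", "rec_prob",
             "female_rep_cost", "male_rep_cost", "mig_cost", "move_prob",
             "search_success")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("configuration error: `", f, "` must be a fraction in [0, 1]")
    }
  }
  if (cfg$initial_population < 2 || cfg$initial_population %% 2 != 0) {
    stop("configuration error: `initial_population` must be even ",
         "(exact 50/50 sex split) and >= 2")
  }
  if (cfg$steps < 0) stop("configuration error: `steps` must be >= 0")
  if (cfg$max_pair_age < 0) {
    stop("configuration error: `max_pair_age` must be >= 0")
  }
  if (cfg$total_resource <= 0) {
    stop("configuration error: `total_resource` must be positive")
  }
  if (cfg$snapshot_every < 1) {
    stop("configuration error: `snapshot_every` must be >= 1")
  }
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds flat `key: value` pairs matching the arguments of
#' [sim_config()]; unset keys take their defaults. `overrides` (e.g. from
#' command-line flags) win over file values.
#'
#' @param path Path to a YAML file.
#' @param overrides Named list of values overriding the file.
#' @return A [sim_config()] object.
#' @export
read_config <- function(path, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (length(vals) && is.null(names(vals))) {
    stop("configuration file must hold named key: value pairs")
  }
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

# Append one agent to the registry; id is allocated here.
add_agent <- function(state, sex, x, sigma, resource, node, age = 0L) {
  id <- state$next_agent
  state$next_agent <- id + 1L
  a <- state$agents
  a$id <- c(a$id, id)
  a$sex <- c(a$sex, sex)
  a$x <- rbind(a$x, unname(x), deparse.level = 0)
  dimnames(a$x) <- NULL
  a$sigma <- rbind(a$sigma, unname(sigma), deparse.level = 0)
  dimnames(a$sigma) <- NULL
  a$resource <- c(a$resource, unname(resource))
  a$node <- c(a$node, as.integer(node))
  a$pair_id <- c(a$pair_id, NA_integer_)
  a$age <- c(a$age, as.integer(age))
  state$agents <- a
  state
}

empty_agents <- function() {
  list(id = integer(0), sex = character(0),
       x = matrix(numeric(0), ncol = 2), sigma = matrix(numeric(0), ncol = 2),
       resource = numeric(0), node = integer(0), pair_id = integer(0),
       age = integer(0))
}

#' Initialize a world state from a configuration
#'
#' Seeds the RNG, builds the torus environment, and places the founders:
#' uniform random genotypes over the landscape's domain box, mutation
#' deviations at `init_sigma_frac` of each domain width, equal resource
#' shares summing to the total (the environment pool starts empty), sexes
#' split exactly 50/50 and assigned alternately, and nodes drawn
#' uniformly. With the same seed the founder population is identical
#' across calls.
#'
#' @param config A [sim_config()].
#' @return An object of class `world_state`.
#' @export
initialize_world <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  land <- landscape(config$landscape, m = config$michalewicz_m)
  graph <- torus_graph(config$grid_nrow, config$grid_ncol)
  n0 <- config$initial_population
  taus <- default_taus(land$dimension)
  state <- structure(list(
    config = config,
    land = land,
    graph = graph,
    vparams = variation_params(taus[["tau0"]], taus[["tau"]],
                               mut_prob = config$mut_prob,
                               rec_prob = config$rec_prob),
    agents = empty_agents(),
    pairs = list(id = integer(0), female = integer(0), male = integer(0),
                 age = integer(0)),
    pool = 0,
    step = 0L,
    next_agent = 1L,
    next_pair = 1L,
    nominal_share = config$total_resource / n0,
    death_floor = config$death_floor_frac *
      config$total_resource / n0
  ), class = "world_state")
  if (!config$pairing) state$config$max_pair_age <- 0L

  width <- land$upper - land$lower
  share <- config$total_resource / n0
  x1 <- stats::runif(n0, land$lower[1], land$upper[1])
  x2 <- stats::runif(n0, land$lower[2], land$upper[2])
  nodes <- sample.int(length(graph), n0, replace = TRUE)
  state$agents <- list(
    id = seq_len(n0),
    sex = rep(c("F", "M"), length.out = n0),
    x = cbind(x1, x2, deparse.level = 0),
    sigma = matrix(rep(config$init_sigma_frac * width, each = n0),
                   ncol = 2),
    resource = rep(share, n0),
    node = as.integer(nodes),
    pair_id = rep(NA_integer_, n0),
    age = integer(n0)
  )
  state$next_agent <- n0 + 1L
  state
}

#' Advance the world by one step
#'
#' Executes the fixed phase order: (a) aging and upkeep, (b) per-node
#' resource dispensing by fitness, (c) pair aging and dissolution, (d)
#' mate choice and pair formation (females iterate in seeded random
#' order within each node), (e) reproduction of ready pairs, (f)
#' migration — unsuccessful searchers move to a random neighbour, other
#' unpaired agents and pairs move spontaneously with probability
#' `move_prob` — and (g) death cleanup (agents at or below the death
#' floor return their resource to the pool). Total resource is conserved
#' throughout.
#'
#' @param state A `world_state`.
#' @return The updated `world_state` with `step` incremented.
#' @export
sim_step <- function(state) {
  cfg <- state$config
  a <- state$agents
  n <- length(a$id)

  # (a) aging and upkeep: a flat living cost (fraction of the nominal
  # share). An agent that cannot cover it is starved: it surrenders what
  # it holds and is removed in the death phase of this step.
  starved_ids <- integer(0)
  if (n > 0) {
    a$age <- a$age + 1L
    due <- cfg$upkeep * state$nominal_share
    starved_ids <- a$id[a$resource < due]
    paid <- pmin(a$resource, due)
    a$resource <- a$resource - paid
    state$pool <- state$pool + sum(paid)
  }

  # (b) dispensing. Default "global": fitness-proportional over the
  # whole population (the environment evaluates agents; nodes only
  # limit the field of view). Alternative "per_node": the released pool
  # is split equally over occupied nodes first, then distributed by
  # quality within each node.
  if (n > 0 && state$pool > 0 && cfg$dispense_rate > 0) {
    fit <- evaluate_matrix(state$land, a$x)
    if (identical(cfg$dispensing, "per_node")) {
      occupied <- sort(unique(a$node))
      node_share <- cfg$dispense_rate * state$pool / length(occupied)
      for (nd in occupied) {
        idx <- which(a$node == nd)
        gains <- node_share * quality_weights(fit[idx],
                                              eps = cfg$selection_eps)
        a$resource[idx] <- a$resource[idx] + gains
        state$pool <- state$pool - sum(gains)
      }
    } else {
      gains <- cfg$dispense_rate * state$pool *
        quality_weights(fit, eps = cfg$selection_eps)
      a$resource <- a$resource + gains
      state$pool <- state$pool - sum(gains)
    }
  }
  state$agents <- a

  # (c) pair aging / dissolution
  state <- age_and_dissolve_pairs(state)

  # (d) mate choice and pair formation. Searching for a partner consumes
  # resources: every unpaired ready agent initiates a search and pays
  # the search cost (the migration-cost fraction of its holding) for
  # doing so, whether or not a partner is found. Members of existing
  # pairs never search, which is what makes pair persistence valuable.
  a <- state$agents
  thr <- cfg$min_rep_res * state$nominal_share
  searched <- is.na(a$pair_id) & a$resource >= thr & a$age > 0L
  for (nd in sort(unique(a$node))) {
    in_node <- a$node == nd
    fem <- which(in_node & a$sex == "F" & searched)
    males <- which(in_node & a$sex == "M" & searched)
    if (length(fem) == 0 || length(males) == 0) next
    fem <- fem[sample.int(length(fem))]
    for (fi in fem) {
      if (length(males) == 0) break
      # searching takes time: a searching female only completes her
      # choice this step with probability search_success
      if (cfg$search_success < 1 &&
          stats::runif(1) >= cfg$search_success) next
      d <- preference_distance(a$x[fi, ], a$x[males, , drop = FALSE])
      pick <- choose_partner(d, cfg$sexual_selection)
      mi <- males[pick]
      males <- males[-pick]
      state <- form_pair(state, a$id[fi], a$id[mi])
    }
  }
  searched_ids <- a$id[searched]

  # (e) reproduction of ready pairs (registry order)
  for (pid in state$pairs$id) {
    state <- reproduce_pair(state, pid)
  }

  # Search costs are settled after the mating episode, so a searcher
  # that paired this step still reproduces before paying. The cost of a
  # search is absolute (mig_cost fraction of the nominal share, capped
  # by the agent's holding): roaming for a partner takes the same
  # effort whether the agent is rich or poor, which is what makes
  # repeated searching lethal for agents from low-income niches.
  a <- state$agents
  hit <- a$id %in% searched_ids
  if (any(hit)) {
    paid <- pmin(a$resource[hit], cfg$mig_cost * state$nominal_share)
    a$resource[hit] <- a$resource[hit] - paid
    state$pool <- state$pool + sum(paid)
    state$agents <- a
  }

  # (f) migration: unsuccessful searchers roam to a neighbouring node,
  # then spontaneous movers, then pairs
  a <- state$agents
  searcher <- (a$id %in% searched_ids) & is.na(a$pair_id)
  for (i in which(searcher)) {
    nbr <- state$graph[[a$node[i]]]
    target <- nbr[sample.int(length(nbr), 1)]
    state <- migrate(state, agent_id = a$id[i], target_node = target)
  }
  a <- state$agents
  wander <- which(is.na(a$pair_id) & !(a$id %in% searched_ids))
  if (length(wander)) {
    move <- wander[stats::runif(length(wander)) < cfg$move_prob]
    for (i in move) {
      nbr <- state$graph[[a$node[i]]]
      target <- nbr[sample.int(length(nbr), 1)]
      state <- migrate(state, agent_id = a$id[i], target_node = target)
    }
  }
  np <- length(state$pairs$id)
  if (np > 0) {
    move <- which(stats::runif(np) < cfg$move_prob)
    for (p in move) {
      fi <- match(state$pairs$female[p], state$agents$id)
      nbr <- state$graph[[state$agents$node[fi]]]
      target <- nbr[sample.int(length(nbr), 1)]
      state <- migrate(state, pair_id = state$pairs$id[p],
                       target_node = target)
    }
  }

  # (g) death cleanup: starved agents and agents at the resource floor
  a <- state$agents
  dead <- which(a$resource <= state$death_floor | a$id %in% starved_ids)
  if (length(dead)) {
    state$pool <- state$pool + sum(a$resource[dead])
    widowed <- which(state$pairs$female %in% a$id[dead] |
                     state$pairs$male %in% a$id[dead])
    for (f in c("id", "sex", "resource", "node", "pair_id", "age")) {
      a[[f]] <- a[[f]][-dead]
    }
    a$x <- a$x[-dead, , drop = FALSE]
    a$sigma <- a$sigma[-dead, , drop = FALSE]
    state$agents <- a
    state <- dissolve_pairs(state, widowed)
  }

  state$step <- state$step + 1L
  state
}

#' Snapshot the population
#'
#' A pure copy of the per-agent records at the current step, suitable for
#' CSV export and for the diversity analysis layer. Replaying a run with
#' the same seed reproduces snapshots exactly.
#'
#' @param state A `world_state`.
#' @return A `data.frame` with one row per agent (columns `step`, `id`,
#'   `sex`, `node`, `x1`, `x2`, `sigma1`, `sigma2`, `resource`,
#'   `pair_id`, `age`) and the environment pool level in attribute
#'   `"pool"`.
#' @export
snapshot_population <- function(state) {
  a <- state$agents
  out <- data.frame(
    step = rep(state$step, length(a$id)),
    id = a$id, sex = a$sex, node = a$node,
    x1 = a$x[, 1], x2 = a$x[, 2],
    sigma1 = a$sigma[, 1], sigma2 = a$sigma[, 2],
    resource = a$resource, pair_id = a$pair_id, age = a$age,
    row.names = NULL
  )
  attr(out, "pool") <- state$pool
  out
}

#' Run a full simulation
#'
#' Initializes the world from `config` (seeding the single RNG stream),
#' advances it `config$steps` steps, and emits a population snapshot with
#' an attached diversity report every `config$snapshot_every` steps
#' (including step 0 and the final step).
#'
#' @param config A [sim_config()].
#' @param kmax Maximum number of clusters tried by [detect_species()]
#'   for the per-snapshot diversity reports.
#' @return An object of class `sim_result`: list with `snapshots` (list
#'   of snapshot data frames), `diversity` (data frame with one row per
#'   snapshot: `step`, `n_agents`, `pool`, `n_species`, `D0`, `D0.5`,
#'   `D1`, `D2`, `centroid_distance`), `config`, and the `final_state`.
#' @export
run_simulation <- function(config, kmax = 10) {
  state <- initialize_world(config)
  snaps <- list()
  divs <- list()
  take <- function(state) {
    snap <- snapshot_population(state)
    rep <- diversity_report(state$agents$x, kmax = kmax)
    rep <- cbind(step = state$step, rep, pool = state$pool)
    list(snap = snap, rep = rep)
  }
  got <- take(state)
  snaps[[1]] <- got$snap; divs[[1]] <- got$rep
  if (config$steps > 0) {
    for (t in seq_len(config$steps)) {
      state <- sim_step(state)
      if (t %% config$snapshot_every == 0 || t == config$steps) {
        got <- take(state)
        k <- length(snaps) + 1
        snaps[[k]] <- got$snap; divs[[k]] <- got$rep
      }
    }
  }
  divs <- do.call(rbind, divs)
  rownames(divs) <- NULL
  structure(list(snapshots = snaps, diversity = divs, config = config,
                 final_state = state), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  last <- x$diversity[nrow(x$diversity), ]
  cat(sprintf(
    "<sim_result: %s, %d steps, seed %d>\n", x$config$landscape,
    x$config$steps, x$config$seed))
  cat(sprintf(
    "  final: N = %d agents, %d species, D0 = %.3g, D1 = %.3g, centroid distance = %.4g\n",
    last$n_agents, last$n_species, last$D0, last$D1,
    last$centroid_distance))
  invisible(x)
}

#' Write a run's outputs as CSV files
#'
#' Writes the concatenated snapshots (one row per agent per snapshot) and
#' the diversity time series. Identical (config, seed) runs write
#' byte-identical files.
#'
#' @param result A [run_simulation()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths (`snapshots`, `diversity`).
#' @export
write_run_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  snap_path <- file.path(dir, "snapshots.csv")
  div_path <- file.path(dir, "diversity.csv")
  snaps <- do.call(rbind, result$snapshots)
  utils::write.csv(snaps, snap_path, row.names = FALSE)
  utils::write.csv(result$diversity, div_path, row.names = FALSE)
  invisible(c(snapshots = snap_path, diversity = div_path))
}
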