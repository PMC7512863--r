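#' Build a toroidal grid environment graph
#'
#' The environment is a connected, undirected graph of nodes joined by
#' paths; an agent's field of view is exactly its node, and migration is
#' only possible along paths. The default topology is an `nrow` x `ncol`
#' torus (wrap-around 4-neighbour grid), which is symmetric and free of
#' boundary artefacts.
#'
#' @param nrow,ncol Grid dimensions (each >= 2 so the torus is simple).
#' @return An adjacency list of class `environment_graph`: a list whose
#'   i-th element is the integer vector of neighbours of node i.
#' @export
torus_graph <- function(nrow = 4, ncol = 4) {
  stopifnot(nrow >= 2, ncol >= 2)
  g <- igraph::make_lattice(dimvector = c(nrow, ncol), periodic = TRUE)
  g <- igraph::simplify(g)
  environment_graph(lapply(igraph::as_adj_list(g), as.integer))
}

#' Validate an adjacency list as an environment graph
#'
#' Checks that adjacency is symmetric (paths are undirected) and the
#' graph is connected (agents can reach every node), then stamps the
#' class.
#'
#' @param adjacency List of integer vectors; element i holds the
#'   neighbours of node i.
#' @return The adjacency list with class `environment_graph`.
#' @export
environment_graph <- function(adjacency) {
  n <- length(adjacency)
  stopifnot(n >= 1)
  adjacency <- lapply(adjacency, function(v) sort(unique(as.integer(v))))
  for (i in seq_len(n)) {
    for (j in adjacency[[i]]) {
      if (j < 1 || j > n) stop("neighbour index out of range at node ", i)
      if (!(i %in% adjacency[[j]])) {
        stop("adjacency is not symmetric: ", i, " -> ", j)
      }
    }
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    js <- adjacency[[i]]
    if (length(js)) cbind(i, js) else NULL
  }))
  g <- if (is.null(edges)) {
    igraph::make_empty_graph(n, directed = FALSE)
  } else {
    igraph::graph_from_edgelist(edges, directed = FALSE)
  }
  if (n > 1 && !igraph::is_connected(g)) {
    stop("environment graph must be connected")
  }
  structure(adjacency, class = "environment_graph")
}

#' Fitness-proportional resource weights for one node
#'
#' The environment distributes resource in proportion to agent quality.
#' On a minimization landscape raw proportionality is ill-defined (values
#' can be negative), so fitness values are linearly rescaled against the
#' current worst: \eqn{w_i = (\max_j f_j - f_i) + \epsilon (\max_j f_j -
#' \min_j f_j + 1)}, then normalized to sum to one. The floor term keeps
#' every weight strictly positive, and the rescaling makes the weights
#' invariant to adding a constant to all fitness values.
#'
#' @param fitness_values Nonempty numeric vector of (minimization)
#'   fitness values of the agents in a node.
#' @param eps Positive floor coefficient; default 0.01.
#' @return Normalized weights summing to 1, all strictly positive.
#' @examples
#' quality_weights(c(0, 1))  # c(1.02, 0.02) / 1.04
#' @export
quality_weights <- function(fitness_values, eps = 0.01) {
  if (length(fitness_values) == 0) {
    stop("`fitness_values` must be nonempty")
  }
  hi <- max(fitness_values)
  lo <- min(fitness_values)
  w <- (hi - fitness_values) + eps * (hi - lo + 1)
  w / sum(w)
}

#' Resource ledgers
#'
#' The total amount of resource in the system is constant: at any time it
#' is split between the environment pool and the agents, and every action
#' merely moves resource between the two. A `resource_ledger` is the
#' minimal bookkeeping object for that economy.
#'
#' @param pool Nonnegative environment pool.
#' @param per_agent Named (by agent id) nonnegative numeric vector of
#'   agent holdings.
#' @return An object of class `resource_ledger` with elements `pool` and
#'   `per_agent`; its `total` is conserved by [dispense()] and
#'   [pay_cost()].
#' @export
resource_ledger <- function(pool, per_agent = numeric(0)) {
  stopifnot(pool >= 0, all(per_agent >= 0))
  structure(list(pool = pool, per_agent = per_agent),
            class = "resource_ledger")
}

#' @rdname resource_ledger
#' @param ledger A `resource_ledger`.
#' @export
ledger_total <- function(ledger) {
  ledger$pool + sum(ledger$per_agent)
}

#' Dispense resource from the environment to agents
#'
#' Moves `dispense_rate * pool` from the environment pool to the agents,
#' split in proportion to `weights` (normally [quality_weights()]).
#'
#' @param ledger A [resource_ledger()].
#' @param weights Normalized weights, one per ledger agent, summing to 1.
#' @param dispense_rate Fraction of the pool to release, in [0, 1].
#' @return The updated ledger; total resource is unchanged.
#' @export
dispense <- function(ledger, weights, dispense_rate) {
  stopifnot(length(weights) == length(ledger$per_agent),
            dispense_rate >= 0, dispense_rate <= 1)
  gains <- dispense_rate * ledger$pool * weights
  ledger$per_agent <- ledger$per_agent + gains
  ledger$pool <- ledger$pool - sum(gains)
  ledger
}

#' Charge an agent a fractional action cost
#'
#' `fraction` of the agent's current holding returns to the environment
#' pool (migration, upkeep and similar actions are charged this way).
#'
#' @param ledger A [resource_ledger()].
#' @param agent_id Name of the agent in the ledger.
#' @param fraction Fraction of the agent's holding to return, in [0, 1].
#' @return The updated ledger; total resource is unchanged.
#' @export
pay_cost <- function(ledger, agent_id, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  i <- match(as.character(agent_id), names(ledger$per_agent))
  if (is.na(i)) stop("unknown agent id: ", agent_id)
  paid <- fraction * ledger$per_agent[[i]]
  ledger$per_agent[[i]] <- ledger$per_agent[[i]] - paid
  ledger$pool <- ledger$pool + paid
  ledger
}

#' Move an agent or a pair to an adjacent node
#'
#' Relocates the mover and charges each moved agent the migration cost
#' (`mig_cost` fraction of its holding, returned to the environment
#' pool). A pair moves as one unit: both members relocate together and
#' both pay. Moves to non-adjacent nodes are rejected.
#'
#' @param state A `world_state` (see [initialize_world()]).
#' @param agent_id,pair_id Exactly one of the two: the id of the moving
#'   agent (which must be unpaired) or of the moving pair.
#' @param target_node Node index adjacent to the mover's current node.
#' @param mig_cost Migration cost fraction; defaults to the state's
#'   configured value.
#' @return The updated `world_state`.
#' @export
migrate <- function(state, agent_id = NULL, pair_id = NULL, target_node,
                    mig_cost = state$config$mig_cost) {
  if (is.null(agent_id) == is.null(pair_id)) {
    stop("supply exactly one of `agent_id` or `pair_id`")
  }
  rows <- if (is.null(pair_id)) {
    i <- match(agent_id, state$agents$id)
    if (is.na(i)) stop("unknown agent id: ", agent_id)
    if (!is.na(state$agents$pair_id[i])) {
      stop("agent ", agent_id, " is paired; move the pair instead")
    }
    i
  } else {
    p <- match(pair_id, state$pairs$id)
    if (is.na(p)) stop("unknown pair id: ", pair_id)
    match(c(state$pairs$female[p], state$pairs$male[p]), state$agents$id)
  }
  from <- state$agents$node[rows[1]]
  if (!(target_node %in% state$graph[[from]])) {
    stop("node ", target_node, " is not adjacent to node ", from)
  }
  paid <- mig_cost * state$agents$resource[rows]
  state$agents$resource[rows] <- state$agents$resource[rows] - paid
  state$pool <- state$pool + sum(paid)
  state$agents$node[rows] <- target_node
  state
}
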