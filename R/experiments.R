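#' Scaled experiment configuration
#'
#' The replicated experiments run at a reduced scale chosen to preserve
#' the qualitative orderings of interest while completing in minutes on
#' one CPU: 3000 steps, 150 founders, with pairs by default persisting
#' for the whole run (`max_pair_age = steps`, i.e. lifelong pairs).
#' Full-scale runs are a matter of passing `steps = 5000`,
#' `initial_population = 200` (the [sim_config()] defaults).
#'
#' @param landscape Landscape name.
#' @param ... Further overrides passed to [sim_config()]; unless given,
#'   `max_pair_age` follows `steps`.
#' @return A [sim_config()].
#' @export
experiment_config <- function(landscape = "rastrigin", ...) {
  args <- list(...)
  defaults <- list(landscape = landscape, steps = 3000,
                   initial_population = 150, snapshot_every = 500)
  defaults[names(args)] <- args
  if (is.null(defaults$max_pair_age)) {
    defaults$max_pair_age <- defaults$steps
  }
  do.call(sim_config, defaults)
}

#' Run the four mechanism-control conditions
#'
#' Executes the 2 x 2 crossing of {sexual selection on/off} x {pair
#' persistence on/off} with shared seeds, so all four conditions start
#' from identical founder populations within each replicate. "Pairing
#' off" means `max_pair_age = 0`: pairs still form and reproduce but
#' dissolve immediately, so every agent must search anew each step.
#'
#' @param config Base [sim_config()]; its `sexual_selection`, `pairing`
#'   and `seed` fields are overridden per condition/replicate.
#' @param seeds Integer vector of replicate seeds.
#' @return A data frame with the diversity time series of every run,
#'   with columns `condition` (one of `"none"`, `"pairing_only"`,
#'   `"selection_only"`, `"selection_pairing"`), `seed`, and the
#'   [diversity_report()] columns per snapshot step.
#' @export
run_controls <- function(config = experiment_config(),
                         seeds = config$seed) {
  conditions <- list(
    none              = c(sexual_selection = FALSE, pairing = FALSE),
    pairing_only      = c(sexual_selection = FALSE, pairing = TRUE),
    selection_only    = c(sexual_selection = TRUE, pairing = FALSE),
    selection_pairing = c(sexual_selection = TRUE, pairing = TRUE)
  )
  out <- list()
  for (seed in seeds) {
    for (cond in names(conditions)) {
      cfg <- config
      cfg$sexual_selection <- conditions[[cond]][["sexual_selection"]]
      cfg$pairing <- conditions[[cond]][["pairing"]]
      cfg$seed <- as.integer(seed)
      res <- run_simulation(cfg)
      div <- res$diversity
      out[[length(out) + 1]] <- cbind(condition = cond, seed = seed, div)
    }
  }
  do.call(rbind, out)
}

#' Specify a pair-persistence sweep
#'
#' @param max_pair_ages Integer vector of maximum pair ages to compare
#'   (0 means no pair persistence).
#' @param replicates Number of replicate runs per condition (>= 1).
#' @param base_config Base [sim_config()] shared by all runs.
#' @param seeds Optional distinct integer seeds, one per replicate;
#'   defaults to `base_config$seed + 0:(replicates - 1)`.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(max_pair_ages = c(0, 1000, 2000, 3000, 4000, 5000),
                       replicates = 5,
                       base_config = experiment_config(),
                       seeds = NULL) {
  if (is.null(seeds)) {
    seeds <- base_config$seed + seq_len(replicates) - 1L
  }
  stopifnot(replicates >= 1, length(seeds) == replicates,
            !anyDuplicated(seeds))
  structure(list(max_pair_ages = as.integer(max_pair_ages),
                 replicates = as.integer(replicates),
                 base_config = base_config, seeds = as.integer(seeds)),
            class = "sweep_spec")
}

#' Run a pair-persistence sweep
#'
#' For every (`max_pair_age`, replicate) combination, runs a full
#' simulation and collects the diversity time series; replicates share
#' seeds across `max_pair_age` values so conditions are compared on
#' identical founder populations.
#'
#' @param spec A [sweep_spec()].
#' @return A tidy data frame: `max_pair_age`, `seed`, plus the
#'   [diversity_report()] columns per snapshot step.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  out <- list()
  for (mpa in spec$max_pair_ages) {
    for (seed in spec$seeds) {
      cfg <- spec$base_config
      cfg$max_pair_age <- as.integer(mpa)
      cfg$pairing <- mpa > 0
      cfg$seed <- as.integer(seed)
      res <- run_simulation(cfg)
      out[[length(out) + 1]] <-
        cbind(max_pair_age = mpa, seed = seed, res$diversity)
    }
  }
  do.call(rbind, out)
}

#' Summarize a sweep over the final epoch
#'
#' Averages each run's centroid-distance diversity (and species count)
#' over the snapshots of the final `window` steps, then aggregates to
#' mean and standard deviation per `max_pair_age`.
#'
#' @param sweep_df Result of [run_sweep()].
#' @param window Width of the final epoch, in steps (default 500).
#' @return A list with `per_run` (one row per run) and `summary` (one
#'   row per `max_pair_age` with mean and sd columns).
#' @export
summarize_sweep <- function(sweep_df, window = 500) {
  last_step <- max(sweep_df$step)
  fin <- sweep_df[sweep_df$step >= last_step - window, , drop = FALSE]
  per_run <- stats::aggregate(
    cbind(centroid_distance, n_species) ~ max_pair_age + seed, data = fin,
    FUN = mean)
  agg_m <- stats::aggregate(
    cbind(centroid_distance, n_species) ~ max_pair_age, data = per_run,
    FUN = mean)
  agg_s <- stats::aggregate(
    cbind(centroid_distance, n_species) ~ max_pair_age, data = per_run,
    FUN = stats::sd)
  names(agg_m)[-1] <- paste0("mean_", names(agg_m)[-1])
  names(agg_s)[-1] <- paste0("sd_", names(agg_s)[-1])
  list(per_run = per_run, summary = merge(agg_m, agg_s,
                                          by = "max_pair_age"))
}
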