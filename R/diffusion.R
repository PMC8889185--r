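#' Randomly remove a fraction of interactions
#'
#' Removes exactly `round(fraction * n_events)` events, chosen uniformly
#' without replacement; the surviving events keep their original
#' timestamps and order. Used to equalize interaction rates before
#' diffusion: runs with uniform activity levels produce substantially
#' more interactions than runs with variable activity, so 20% of their
#' interactions are dropped prior to simulating spread.
#'
#' @param log An `"interaction_log"`.
#' @param fraction Removal fraction in `[0, 1)`.
#' @param seed Optional seed for the removal draw.
#' @return The thinned `"interaction_log"` (attributes preserved).
#' @export
thin_interactions <- function(log, fraction = 0.2, seed = NULL) {
  if (fraction < 0 || fraction >= 1) {
    stop("`fraction` must be in [0, 1)", call. = FALSE)
  }
  m <- nrow(log)
  n_drop <- round(fraction * m)
  if (n_drop == 0) return(log)
  draw <- function() sample.int(m, n_drop)
  drop_idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- log[-sort(drop_idx), ]
  for (a in c("config", "traits", "n_agents", "n_steps")) {
    attr(out, a) <- attr(log, a, exact = TRUE)
  }
  class(out) <- class(log)
  out
}

#' Simulate time-ordered information diffusion over a log
#'
#' The signaller of the first logged event is the initially informed
#' individual. Events are processed in time order (within a step, in
#' logged order): a naive agent becomes informed the moment it receives
#' an event from an informed signaller, and can relay in any later event,
#' including later events of the same time step. Transmission speed is
#' `T50`, the earliest time step at which at least 50% of agents
#' (`ceiling(n_agents / 2)`) are informed; efficiency is the cumulative
#' number of events with an informed signaller (whether directed to naive
#' or informed receivers) occurring at `t <= T50` — fewer means more
#' efficient spread.
#'
#' @param log A nonempty `"interaction_log"`.
#' @return A list of class `"diffusion_result"`: `seed_agent`, `t50`
#'   (`NA` if 50% is never reached), `efficiency` (`NA` when `t50` is),
#'   `n_agents`, `threshold`, `n_informed_final` and `trajectory`, a
#'   tibble of the informed count at the end of each step `1..n_steps`.
#' @examples
#' log <- run_simulation(sim_config(n_agents = 30, n_steps = 500, seed = 7))
#' res <- simulate_diffusion(log)
#' glance(res)
#' @export
simulate_diffusion <- function(log) {
  if (nrow(log) == 0) stop("empty interaction log", call. = FALSE)
  n <- log_n_agents(log)
  threshold <- ceiling(0.5 * n)
  core <- .diffusion_core(log$signaller, log$receiver, n)
  hit <- which(core$count_after >= threshold)
  t50 <- if (length(hit) == 0) NA_integer_ else log$t[hit[1]]
  efficiency <- if (is.na(t50)) NA_integer_ else {
    sum(core$signaller_informed & log$t <= t50)
  }
  n_steps <- log_n_steps(log)
  # informed count at the end of each step: last event count per step,
  # carried forward; 1 (the seed) before the first event
  per_step <- rep(NA_integer_, n_steps)
  last_idx <- vapply(split(seq_len(nrow(log)), log$t), max, integer(1))
  per_step[as.integer(names(last_idx))] <- core$count_after[last_idx]
  filled <- cummax_na(per_step, init = 1L)
  structure(
    list(
      seed_agent = core$seed_agent, t50 = t50, efficiency = efficiency,
      n_agents = n, threshold = threshold,
      n_informed_final = core$count_after[nrow(log)],
      trajectory = tibble::tibble(step = seq_len(n_steps), informed = filled)
    ),
    class = "diffusion_result"
  )
}

# carry last observation forward over NAs (counts are nondecreasing)
cummax_na <- function(x, init) {
  out <- integer(length(x))
  cur <- init
  for (k in seq_along(x)) {
    if (!is.na(x[k])) cur <- x[k]
    out[k] <- cur
  }
  out
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat("<diffusion_result>\n")
  cat(sprintf("  seed agent %d of %d; %d informed by the end\n",
              x$seed_agent, x$n_agents, x$n_informed_final))
  if (is.na(x$t50)) {
    cat(sprintf("  T50: not reached (threshold %d)\n", x$threshold))
  } else {
    cat(sprintf("  T50 = %d (threshold %d), efficiency = %d outgoing events\n",
                x$t50, x$threshold, x$efficiency))
  }
  invisible(x)
}

#' Run the diffusion experiment across behavioural conditions
#'
#' Runs `n_runs` independent simulations per condition under the default
#' interaction rules, thins interactions by `thin_fraction` for the
#' conditions in which activity levels are uniform across agents
#' (`uniform` and `ti_variable`), simulates diffusion on each log and
#' returns per-run speed and efficiency, log-transformed alongside.
#'
#' @param conditions Character vector of behavioural conditions.
#' @param n_runs Simulations per condition.
#' @param thin_fraction Removal fraction applied to uniform-activity runs
#'   (default 0.2).
#' @param seed Master seed; per-run seeds are derived from it and
#'   recorded.
#' @param n_agents,n_steps,grid_size,a_m,t_m Passed to [sim_config()].
#' @return A tibble of class `"diffusion_runs"`: `condition`, `run`,
#'   `seed`, `thinned`, `n_events`, `seed_agent`, `t50`, `efficiency`,
#'   `log_t50`, `log_efficiency`. Runs that never reach 50% informed have
#'   `NA` outcomes.
#' @export
run_diffusion_experiment <- function(conditions = condition_levels(),
                                     n_runs = 100, thin_fraction = 0.2,
                                     seed = NULL, n_agents = 100,
                                     n_steps = 5000, grid_size = 50,
                                     a_m = 1, t_m = 60) {
  conditions <- vapply(conditions, match_condition, character(1), USE.NAMES = FALSE)
  cells <- tidyr::expand_grid(condition = conditions, run = seq_len(n_runs))
  seeds <- derive_seeds(seed, 2L * nrow(cells))
  sim_seeds <- seeds[seq_len(nrow(cells))]
  thin_seeds <- seeds[nrow(cells) + seq_len(nrow(cells))]
  out <- purrr::pmap(
    list(cells$condition, cells$run, sim_seeds, thin_seeds),
    function(cond, run, s, ts) {
      cfg <- sim_config(n_agents = n_agents, n_steps = n_steps,
                        grid_size = grid_size, a_m = a_m, t_m = t_m,
                        condition = cond, seed = s)
      log <- run_simulation(cfg)
      thinned <- cond %in% c("uniform", "ti_variable") && thin_fraction > 0
      if (thinned) log <- thin_interactions(log, thin_fraction, seed = ts)
      res <- simulate_diffusion(log)
      tibble::tibble(
        condition = cond, run = run, seed = s, thinned = thinned,
        n_events = nrow(log), seed_agent = res$seed_agent,
        t50 = res$t50, efficiency = res$efficiency
      )
    }
  )
  out <- dplyr::bind_rows(out)
  n_undefined <- sum(is.na(out$t50))
  if (n_undefined > 0) {
    warning(sprintf("%d run(s) never reached 50%% informed; outcomes set to NA",
                    n_undefined), call. = FALSE)
  }
  out$log_t50 <- log(out$t50)
  out$log_efficiency <- log(out$efficiency)
  class(out) <- c("diffusion_runs", class(out))
  out
}

#' Synchronous diffusion over the static aggregated network
#'
#' Exploratory variant: instead of replaying the time-ordered events,
#' information spreads in synchronous rounds over the binary aggregated
#' network (every informed node informs all of its out-neighbours each
#' round, with mutual dyads traversable both ways). Reported in rounds,
#' not simulation time steps.
#'
#' @param g A `"binary_digraph"`.
#' @param seed_agent Initially informed node (0-based id).
#' @return A tibble with `round` and `informed` count per round until the
#'   informed set stops growing.
#' @export
static_diffusion <- function(g, seed_agent = 0L) {
  nn <- n_nodes(g)
  informed <- logical(nn)
  informed[seed_agent + 1L] <- TRUE
  from <- c(g$from, g$to[g$mutual]) + 1L
  to <- c(g$to, g$from[g$mutual]) + 1L
  out <- tibble::tibble(round = 0L, informed = 1L)
  repeat {
    reach <- unique(to[informed[from]])
    new <- reach[!informed[reach]]
    if (length(new) == 0) break
    informed[new] <- TRUE
    out <- dplyr::bind_rows(out, tibble::tibble(
      round = out$round[nrow(out)] + 1L, informed = sum(informed)
    ))
  }
  out
}
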