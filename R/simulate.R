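#' Simulation configuration
#'
#' Bundles every parameter of one simulation run. Defaults reproduce the
#' reference setup: 100 agents on a bounded 50 x 50 patch nest for 5000
#' time steps, step length and interaction radius of half a patch (one
#' body length), trait means `a_m = 1` and `t_m = 60` degrees, interactions
#' initiated by currently active agents which signal outward.
#'
#' @param n_agents Number of agents (>= 2).
#' @param n_steps Number of time steps (>= 1).
#' @param grid_size Side of the square nest in patches.
#' @param step_length Distance moved per active step, in patches (one body
#'   length = 0.5).
#' @param interaction_radius Maximum distance, in patches, at which two
#'   agents are in contact.
#' @param a_m,t_m Population trait means passed to [build_traits()].
#' @param condition Behavioural condition; see [build_traits()].
#' @param initiation_rule `"by_activity"` (only currently active agents
#'   with a neighbour initiate) or `"random_half"` (every agent with a
#'   neighbour initiates with probability 0.5 regardless of activity).
#' @param direction_rule Who signals once a pair forms:
#'   `"active_outgoing"` (initiator signals), `"random"` (fair coin),
#'   `"relative_activity"` (initiator i signals with probability
#'   `A_i / (A_i + A_j)`), or `"to_active"` (initiator receives).
#' @param boundary_rule How a step that would cross the nest boundary is
#'   handled, all three preventing any crossing. `"reflect"` (default):
#'   the step bounces off the wall and the heading is mirrored, so walls
#'   are non-sticky — straight walkers criss-cross the nest instead of
#'   accumulating at the boundary, which keeps the population contact
#'   rate independent of the turning-index distribution. `"truncate"`:
#'   the agent advances along its heading only as far as the boundary and
#'   an agent pressed against the wall with an outward heading stays put.
#'   `"clamp"`: each coordinate of the full step is clamped to the
#'   boundary independently, letting agents slide along the wall; under
#'   `"truncate"` and `"clamp"` the heading is never altered by the
#'   boundary. See the methods vignette for why sticky walls distort
#'   contact rates when turning indices vary.
#' @param seed Integer seed for the run, or `NULL` to use the current RNG
#'   state.
#' @return A list of class `"sim_config"`.
#' @examples
#' sim_config(n_agents = 50, n_steps = 1000, condition = "correlated", seed = 1)
#' @export
sim_config <- function(n_agents = 100, n_steps = 5000, grid_size = 50,
                       step_length = 0.5, interaction_radius = 0.5,
                       a_m = 1, t_m = 60, condition = "uniform",
                       initiation_rule = c("by_activity", "random_half"),
                       direction_rule = c("active_outgoing", "random",
                                          "relative_activity", "to_active"),
                       boundary_rule = c("reflect", "truncate", "clamp"),
                       seed = NULL) {
  initiation_rule <- match.arg(initiation_rule)
  direction_rule <- match.arg(direction_rule)
  boundary_rule <- match.arg(boundary_rule)
  condition <- match_condition(condition)
  stopifnot(
    n_agents >= 2, n_steps >= 1, grid_size > 0,
    step_length > 0, interaction_radius > 0
  )
  if (a_m <= 0 || t_m <= 0) {
    stop("trait means `a_m` and `t_m` must be positive", call. = FALSE)
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(
      n_agents = as.integer(n_agents), n_steps = as.integer(n_steps),
      grid_size = grid_size, step_length = step_length,
      interaction_radius = interaction_radius,
      a_m = a_m, t_m = t_m, condition = condition,
      initiation_rule = initiation_rule, direction_rule = direction_rule,
      boundary_rule = boundary_rule, seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d agents, %d steps, %g x %g nest\n",
              x$n_agents, x$n_steps, x$grid_size, x$grid_size))
  cat(sprintf("  condition: %s (a_m = %g, t_m = %g)\n", x$condition, x$a_m, x$t_m))
  cat(sprintf("  initiation: %s, direction: %s, seed: %s\n",
              x$initiation_rule, x$direction_rule,
              if (is.null(x$seed)) "<current RNG>" else x$seed))
  invisible(x)
}

#' Per-step activation draw
#'
#' An agent is active on a time step iff a fresh Exponential(mean 1) draw
#' falls below its activity level, i.e. with probability
#' `1 - exp(-activity)`. With activity levels themselves drawn from
#' Exponential(mean 1), the population-average activation probability is
#' exactly 1/2.
#'
#' @param activity Numeric vector of activity levels (one draw per element).
#' @return Logical vector of the same length.
#' @export
is_active <- function(activity) {
  if (any(activity <= 0)) stop("activity levels must be positive", call. = FALSE)
  rexp(length(activity)) < activity
}

#' Agents within interaction radius
#'
#' Brute-force all-pairs Euclidean distance filter (no wraparound); the
#' boundary is inclusive, so a pair at exactly `radius` apart are
#' neighbours of each other.
#'
#' @param agent_id Focal agent id.
#' @param positions Data frame with columns `agent_id`, `x`, `y`.
#' @param radius Interaction radius in patches.
#' @return Integer vector of neighbour ids (possibly empty).
#' @export
find_neighbours <- function(agent_id, positions, radius = 0.5) {
  stopifnot(radius > 0)
  focal <- positions[positions$agent_id == agent_id, , drop = FALSE]
  if (nrow(focal) != 1) stop("focal agent not found in `positions`", call. = FALSE)
  others <- positions[positions$agent_id != agent_id, , drop = FALSE]
  d2 <- (others$x - focal$x)^2 + (others$y - focal$y)^2
  others$agent_id[d2 <= radius^2]
}

#' Move one agent by one correlated-random-walk step
#'
#' If the agent is inactive this step the state is returned unchanged.
#' Otherwise its heading is perturbed by a Normal(0, `turning` degrees)
#' draw (wrapped to `[0, 360)`) and it advances `step_length` patches
#' along the new heading, with boundary crossings handled per
#' `boundary_rule` (see [sim_config()]). This is the plain-R single-agent
#' primitive; [run_simulation()] runs the same rules in compiled code.
#'
#' @param state List or one-row data frame with `x`, `y`, `heading` and
#'   logical `active`.
#' @param turning The agent's turning index (degrees).
#' @param step_length,grid_size,boundary_rule Arena geometry and boundary
#'   handling; see [sim_config()].
#' @return A list with updated `x`, `y`, `heading`, `active`.
#' @export
move_agent <- function(state, turning, step_length = 0.5, grid_size = 50,
                       boundary_rule = c("reflect", "truncate", "clamp")) {
  boundary_rule <- match.arg(boundary_rule)
  state <- as.list(state)[c("x", "y", "heading", "active")]
  if (!isTRUE(state$active)) return(state)
  h <- (state$heading + stats::rnorm(1, 0, turning)) %% 360
  dx <- step_length * cos(h * pi / 180)
  dy <- step_length * sin(h * pi / 180)
  nx <- state$x + dx
  ny <- state$y + dy
  if (boundary_rule == "reflect") {
    if (nx < 0) { nx <- -nx; h <- 180 - h }
    else if (nx > grid_size) { nx <- 2 * grid_size - nx; h <- 180 - h }
    if (ny < 0) { ny <- -ny; h <- -h }
    else if (ny > grid_size) { ny <- 2 * grid_size - ny; h <- -h }
    h <- h %% 360
  } else if (boundary_rule == "truncate") {
    f <- 1
    if (nx < 0) f <- min(f, (0 - state$x) / dx)
    if (nx > grid_size) f <- min(f, (grid_size - state$x) / dx)
    if (ny < 0) f <- min(f, (0 - state$y) / dy)
    if (ny > grid_size) f <- min(f, (grid_size - state$y) / dy)
    nx <- state$x + f * dx
    ny <- state$y + f * dy
  }
  state$heading <- h
  state$x <- min(max(nx, 0), grid_size)
  state$y <- min(max(ny, 0), grid_size)
  state
}

#' Single-step interaction phase (reference implementation)
#'
#' Visits agents in a fresh uniformly random order; each visited agent may
#' initiate at most one interaction with a uniformly chosen neighbour,
#' with initiation and signalling direction governed by the configured
#' rules (see [sim_config()]). This is the plain-R single-step primitive;
#' [run_simulation()] runs the same rules in compiled code.
#'
#' @param positions Data frame with columns `agent_id`, `x`, `y`.
#' @param active Logical vector indexed like `positions$agent_id` (0-based
#'   ids: element `i + 1` is agent `i`).
#' @param activity Numeric vector of activity levels, indexed the same way.
#' @param t Time step recorded on the events.
#' @param initiation_rule,direction_rule,interaction_radius See
#'   [sim_config()].
#' @return A tibble with columns `t`, `signaller`, `receiver`, in
#'   initiation order.
#' @export
interaction_phase <- function(positions, active, activity, t = 1L,
                              initiation_rule = c("by_activity", "random_half"),
                              direction_rule = c("active_outgoing", "random",
                                                 "relative_activity", "to_active"),
                              interaction_radius = 0.5) {
  initiation_rule <- match.arg(initiation_rule)
  direction_rule <- match.arg(direction_rule)
  ids <- positions$agent_id
  events <- list()
  for (i in sample(ids)) {
    if (initiation_rule == "by_activity" && !active[i + 1L]) next
    nb <- find_neighbours(i, positions, interaction_radius)
    if (length(nb) == 0) next
    if (initiation_rule == "random_half" && runif(1) >= 0.5) next
    j <- if (length(nb) == 1) nb else sample(nb, 1)
    sr <- switch(direction_rule,
      active_outgoing = c(i, j),
      random = if (runif(1) < 0.5) c(i, j) else c(j, i),
      relative_activity = {
        p <- activity[i + 1L] / (activity[i + 1L] + activity[j + 1L])
        if (runif(1) < p) c(i, j) else c(j, i)
      },
      to_active = c(j, i)
    )
    events[[length(events) + 1L]] <- c(t, sr)
  }
  if (length(events) == 0) {
    return(tibble::tibble(t = integer(), signaller = integer(), receiver = integer()))
  }
  m <- do.call(rbind, events)
  tibble::tibble(t = as.integer(m[, 1]), signaller = as.integer(m[, 2]),
                 receiver = as.integer(m[, 3]))
}

#' Run one simulation and collect its interaction log
#'
#' Initializes traits (unless supplied), places agents uniformly at random
#' with uniform random headings, then iterates the per-step cycle: draw
#' per-agent active flags, move all agents in a fresh random order, run
#' the interaction phase in another fresh random order, and append the
#' resulting directed events. The whole run consumes a single RNG stream
#' seeded from `config$seed`, so identical seeds give byte-identical logs.
#'
#' @param config A [sim_config()].
#' @param traits Optional trait tibble (as from [build_traits()]); by
#'   default traits are drawn inside the run according to
#'   `config$condition`.
#' @param record_positions If `TRUE`, attach per-step agent positions
#'   (steps 0..n_steps) as attributes `pos_x` / `pos_y` for trajectory
#'   diagnostics.
#' @return A tibble of class `"interaction_log"` with integer columns `t`,
#'   `signaller`, `receiver` (0-based agent ids), time-ordered, carrying
#'   the `config` and `traits` as attributes.
#' @examples
#' log <- run_simulation(sim_config(n_agents = 20, n_steps = 200, seed = 1))
#' head(log)
#' @export
run_simulation <- function(config, traits = NULL, record_positions = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  body <- function() {
    tr <- traits %||% build_traits(config$n_agents, config$condition,
                                   config$a_m, config$t_m)
    stopifnot(nrow(tr) == config$n_agents)
    raw <- .sim_core(
      config$n_agents, config$n_steps, config$grid_size, config$step_length,
      config$interaction_radius, tr$activity, tr$turning,
      match(config$initiation_rule, c("by_activity", "random_half")) - 1L,
      match(config$direction_rule,
            c("active_outgoing", "random", "relative_activity", "to_active")) - 1L,
      match(config$boundary_rule %||% "reflect", c("truncate", "clamp", "reflect")) - 1L,
      record_positions
    )
    log <- tibble::tibble(t = raw$t, signaller = raw$signaller,
                          receiver = raw$receiver)
    attr(log, "config") <- config
    attr(log, "traits") <- tr
    if (record_positions) {
      attr(log, "pos_x") <- raw$pos_x
      attr(log, "pos_y") <- raw$pos_y
    }
    class(log) <- c("interaction_log", class(log))
    log
  }
  if (is.null(config$seed)) body() else withr::with_seed(config$seed, body())
}

#' Coerce a data frame of events into an interaction log
#'
#' For replaying externally stored event lists (or building fixtures):
#' `df` needs integer columns `t`, `signaller`, `receiver` with 0-based
#' agent ids, already in time order.
#'
#' @param df Data frame of events.
#' @param n_agents,n_steps Dimensions of the originating simulation.
#' @return An `"interaction_log"` tibble.
#' @export
as_interaction_log <- function(df, n_agents, n_steps = max(df$t, 1L)) {
  stopifnot(all(c("t", "signaller", "receiver") %in% names(df)))
  if (any(df$signaller == df$receiver)) {
    stop("events may not be self-directed", call. = FALSE)
  }
  if (nrow(df) > 0 && (any(df$t < 1) || any(df$t > n_steps))) {
    stop("event times must lie in [1, n_steps]", call. = FALSE)
  }
  if (is.unsorted(df$t)) stop("events must be in time order", call. = FALSE)
  log <- tibble::tibble(t = as.integer(df$t),
                        signaller = as.integer(df$signaller),
                        receiver = as.integer(df$receiver))
  attr(log, "n_agents") <- as.integer(n_agents)
  attr(log, "n_steps") <- as.integer(n_steps)
  class(log) <- c("interaction_log", class(log))
  log
}

#' Accessors for an interaction log
#'
#' @param log An `"interaction_log"` tibble from [run_simulation()] (or
#'   [read_interaction_log()]).
#' @return `log_config()` the [sim_config()]; `log_traits()` the trait
#'   tibble; `log_n_agents()` / `log_n_steps()` integers.
#' @export
log_config <- function(log) attr(log, "config", exact = TRUE)

#' @rdname log_config
#' @export
log_traits <- function(log) attr(log, "traits", exact = TRUE)

#' @rdname log_config
#' @export
log_n_agents <- function(log) {
  cfg <- log_config(log)
  if (!is.null(cfg)) return(cfg$n_agents)
  attr(log, "n_agents", exact = TRUE) %||%
    (max(log$signaller, log$receiver) + 1L)
}

#' @rdname log_config
#' @export
log_n_steps <- function(log) {
  cfg <- log_config(log)
  if (!is.null(cfg)) return(cfg$n_steps)
  attr(log, "n_steps", exact = TRUE) %||% max(log$t, 1L)
}

#' Read or write an interaction log as CSV plus a JSON sidecar
#'
#' The log itself is a plain CSV with header `t,signaller,receiver`, one
#' row per event in time order. The sidecar (`<path>.json`) carries the
#' full configuration, seed and trait table so any run can be audited or
#' replayed in isolation.
#'
#' @param log An `"interaction_log"`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_interaction_log()` returns `log` invisibly;
#'   `read_interaction_log()` returns the reconstructed log.
#' @export
write_interaction_log <- function(log, path) {
  readr::write_csv(tibble::as_tibble(log)[, c("t", "signaller", "receiver")], path)
  cfg <- log_config(log)
  sidecar <- list(config = unclass(cfg), traits = log_traits(log))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(log)
}

#' @rdname write_interaction_log
#' @export
read_interaction_log <- function(path) {
  log <- readr::read_csv(path, col_types = readr::cols(
    t = readr::col_integer(),
    signaller = readr::col_integer(),
    receiver = readr::col_integer()
  ))
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    cfg <- sc$config
    attr(log, "config") <- do.call(sim_config, cfg[setdiff(names(cfg), character())])
    attr(log, "traits") <- tibble::as_tibble(sc$traits)
  }
  class(log) <- c("interaction_log", class(log))
  log
}

`%||%` <- function(a, b) if (is.null(a)) b else a
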