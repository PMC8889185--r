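# Independent per-run seeds derived from one master seed (recorded in the
# output so any single run can be re-created in isolation).
derive_seeds <- function(master, n) {
  draw <- function() sample.int(2147483646L, n)
  if (is.null(master)) draw() else withr::with_seed(as.integer(master), draw())
}

run_one_ttri <- function(cfg, target_edges, edge_counting = "dyads") {
  log <- run_simulation(cfg)
  g <- tryCatch(grow_to_density(log, target_edges, edge_counting),
                error = function(e) NULL)
  if (is.null(g)) {
    return(tibble::tibble(t_end = NA_integer_, n_events = nrow(log),
                          n_transitive = NA_real_, n_cyclic = NA_real_,
                          p_t = NA_real_, t_tri = NA_real_))
  }
  tt <- triangle_transitivity(g)
  tibble::tibble(t_end = attr(g, "t_end"), n_events = nrow(log),
                 n_transitive = tt$n_transitive, n_cyclic = tt$n_cyclic,
                 p_t = tt$p_t, t_tri = tt$t_tri)
}

#' Behavioural-variation experiment: condition effects on transitivity
#'
#' Runs the condition-by-density design: for each behavioural condition,
#' `runs_per_condition` independent simulations, each assigned (in
#' blocks: runs 1..k to the first density target, the next k to the
#' second, ...) one target edge count from the density schedule, with
#' exactly one binary network extracted per run at its target.
#'
#' @param conditions Behavioural conditions to run (default all five).
#' @param runs_per_condition Simulations per condition (default 100; a
#'   multiple of `length(density_targets)` keeps the blocks balanced).
#' @param density_targets Edge-count schedule (default 150 to 1500 in
#'   increments of 150).
#' @param seed Master seed.
#' @param n_agents,n_steps,grid_size,a_m,t_m Passed to [sim_config()].
#' @param edge_counting See [grow_to_density()].
#' @return A tibble of class `"ttri_runs"`: `condition`, `run`, `seed`,
#'   `density_target`, `t_end`, `n_events`, `n_transitive`, `n_cyclic`,
#'   `p_t`, `t_tri`. Runs whose network never reaches the target, or has
#'   no all-asymmetric triangle, carry `NA`s.
#' @export
run_transitivity_experiment <- function(conditions = condition_levels(),
                                        runs_per_condition = 100,
                                        density_targets = seq(150, 1500, by = 150),
                                        seed = NULL, n_agents = 100,
                                        n_steps = 5000, grid_size = 50,
                                        a_m = 1, t_m = 60,
                                        edge_counting = "dyads") {
  conditions <- vapply(conditions, match_condition, character(1), USE.NAMES = FALSE)
  targets <- rep(density_targets,
                 each = ceiling(runs_per_condition / length(density_targets)),
                 length.out = runs_per_condition)
  cells <- tidyr::expand_grid(condition = conditions, run = seq_len(runs_per_condition))
  cells$density_target <- targets[cells$run]
  cells$seed <- derive_seeds(seed, nrow(cells))
  res <- purrr::pmap(
    list(cells$condition, cells$seed, cells$density_target),
    function(cond, s, target) {
      cfg <- sim_config(n_agents = n_agents, n_steps = n_steps,
                        grid_size = grid_size, a_m = a_m, t_m = t_m,
                        condition = cond, seed = s)
      run_one_ttri(cfg, target, edge_counting)
    }
  )
  out <- dplyr::bind_cols(cells, dplyr::bind_rows(res))
  report_failed_runs(out)
  class(out) <- c("ttri_runs", class(out))
  out
}

#' Activity-decomposition experiment: initiation and direction variants
#'
#' Crosses behavioural condition (uniform vs activity-variable) with
#' whether interaction initiation and interaction direction are governed
#' by activity or assigned at random. `initiation = "activity"` means
#' only currently active agents initiate; `"random"` means every agent
#' with a neighbour initiates with probability 0.5. `direction =
#' "activity"` means the signaller is determined by activity — the
#' initiator signals outward under activity-based initiation, and under
#' random initiation the pair member `i` signals with probability
#' `A_i / (A_i + A_j)`; `"random"` resolves the signaller by a fair coin.
#' One binary network at `target_edges` (default 1000) is extracted per
#' run.
#'
#' @param conditions Conditions to run (default uniform and
#'   activity-variable).
#' @param initiations,directions Factor levels to include, each a subset
#'   of `c("activity", "random")`.
#' @param n_runs Simulations per cell.
#' @param target_edges Binary edge count per network.
#' @param seed Master seed.
#' @param n_agents,n_steps,grid_size,a_m,t_m Passed to [sim_config()].
#' @param edge_counting See [grow_to_density()].
#' @return A tibble of class `"activity_runs"` with the cell identifiers
#'   (`condition`, `initiation`, `direction`), per-run metadata and
#'   `t_tri` columns as in [run_transitivity_experiment()].
#' @export
run_activity_experiment <- function(conditions = c("uniform", "activity_variable"),
                                    initiations = c("activity", "random"),
                                    directions = c("activity", "random"),
                                    n_runs = 100, target_edges = 1000,
                                    seed = NULL, n_agents = 100, n_steps = 5000,
                                    grid_size = 50, a_m = 1, t_m = 60,
                                    edge_counting = "dyads") {
  conditions <- vapply(conditions, match_condition, character(1), USE.NAMES = FALSE)
  initiations <- match.arg(initiations, c("activity", "random"), several.ok = TRUE)
  directions <- match.arg(directions, c("activity", "random"), several.ok = TRUE)
  cells <- tidyr::expand_grid(condition = conditions, initiation = initiations,
                              direction = directions, run = seq_len(n_runs))
  cells$seed <- derive_seeds(seed, nrow(cells))
  res <- purrr::pmap(
    list(cells$condition, cells$initiation, cells$direction, cells$seed),
    function(cond, init, dir, s) {
      cfg <- sim_config(
        n_agents = n_agents, n_steps = n_steps, grid_size = grid_size,
        a_m = a_m, t_m = t_m, condition = cond,
        initiation_rule = if (init == "activity") "by_activity" else "random_half",
        direction_rule = if (dir == "random") "random"
                         else if (init == "activity") "active_outgoing"
                         else "relative_activity",
        seed = s
      )
      run_one_ttri(cfg, target_edges, edge_counting)
    }
  )
  out <- dplyr::bind_cols(cells, dplyr::bind_rows(res))
  report_failed_runs(out)
  class(out) <- c("activity_runs", class(out))
  out
}

report_failed_runs <- function(out) {
  n_bad <- sum(is.na(out$t_tri))
  if (n_bad > 0) {
    warning(sprintf(
      "%d run(s) yielded no t_tri (density not reached or no eligible triangle)",
      n_bad), call. = FALSE)
  }
  invisible(out)
}

#' Null ensemble of triangle censuses from uniform-condition runs
#'
#' Runs `n_networks` independent simulations (by default under the
#' uniform condition, the spatially explicit null in which all agents
#' share the mean activity and turning index), extracts one binary
#' network at `target_edges` from each and returns the triangle census of
#' every network, for use as the null in [tsp_profile()]. A run whose
#' full log never reaches the target edge count is redrawn with a fresh
#' seed, up to `max_retries` per network.
#'
#' @param n_networks Ensemble size (default 100; minimum 2).
#' @param target_edges Binary edge count per network (default 1000).
#' @param seed Master seed.
#' @param config Base [sim_config()] for the null runs (its `seed` is
#'   overridden per run).
#' @param edge_counting See [grow_to_density()].
#' @param max_retries Redraws allowed per network before failing.
#' @return A tibble with `run`, `seed`, `t_end` and the seven triangle
#'   class columns.
#' @export
make_null_ensemble <- function(n_networks = 100, target_edges = 1000,
                               seed = NULL, config = sim_config(),
                               edge_counting = "dyads", max_retries = 5) {
  stopifnot(n_networks >= 2)
  seeds <- derive_seeds(seed, n_networks * (max_retries + 1L))
  pool <- n_networks
  rows <- vector("list", n_networks)
  for (k in seq_len(n_networks)) {
    s <- seeds[k]
    g <- NULL
    for (attempt in 0:max_retries) {
      cfg <- config
      cfg$seed <- s
      log <- run_simulation(cfg)
      g <- tryCatch(grow_to_density(log, target_edges, edge_counting),
                    error = function(e) NULL)
      if (!is.null(g)) break
      pool <- pool + 1L
      s <- seeds[pool]
    }
    if (is.null(g)) {
      stop(sprintf("network %d never reached %d edges after %d retries",
                   k, target_edges, max_retries), call. = FALSE)
    }
    census <- triangle_census(g)
    rows[[k]] <- dplyr::bind_cols(
      tibble::tibble(run = k, seed = s, t_end = attr(g, "t_end")),
      tibble::as_tibble(as.list(unclass(census)))
    )
  }
  dplyr::bind_rows(rows)
}

#' Cell means, standard deviations and contrasts against a reference cell
#'
#' Balanced-design summary standing in for coefficient tables: per cell
#' (the crossing of the `by` columns) the number of non-missing runs, the
#' mean and standard deviation of the response, and the mean difference
#' from the reference cell.
#'
#' @param data A per-run result table.
#' @param response Name of the response column (e.g. `"t_tri"`,
#'   `"log_t50"`).
#' @param by Character vector of cell identifier columns.
#' @param reference Named character vector picking the reference cell,
#'   e.g. `c(condition = "uniform")`; must match exactly one cell.
#' @return A tibble with the `by` columns plus `n`, `mean`, `sd`,
#'   `contrast`.
#' @examples
#' runs <- tibble::tibble(condition = rep(c("uniform", "correlated"), each = 3),
#'                        t_tri = c(0, 0.01, -0.01, 0.5, 0.55, 0.6))
#' summarize_contrasts(runs, "t_tri", by = "condition",
#'                     reference = c(condition = "uniform"))
#' @export
summarize_contrasts <- function(data, response, by = "condition",
                                reference = c(condition = "uniform")) {
  stopifnot(all(by %in% names(data)), response %in% names(data))
  cells <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = sum(!is.na(.data[[response]])),
      mean = mean(.data[[response]], na.rm = TRUE),
      sd = sd(.data[[response]], na.rm = TRUE),
      .groups = "drop"
    )
  if (any(cells$n == 0)) {
    bad <- cells[cells$n == 0, by, drop = FALSE]
    stop("empty cell(s): ", paste(do.call(paste, bad), collapse = "; "),
         call. = FALSE)
  }
  is_ref <- rep(TRUE, nrow(cells))
  for (nm in names(reference)) is_ref <- is_ref & cells[[nm]] == reference[[nm]]
  if (sum(is_ref) != 1) {
    stop("`reference` must select exactly one cell", call. = FALSE)
  }
  cells$contrast <- cells$mean - cells$mean[is_ref]
  cells
}

#' OLS models mirroring the experiment designs
#'
#' `fit_transitivity_model()` regresses `t_tri` on behavioural condition,
#' standardized network density (the density target, centred and scaled)
#' and their interaction, with treatment coding and the uniform condition
#' as reference. `fit_activity_model()` regresses `t_tri` on the full
#' crossing of condition, initiation and direction present in the data
#' (factors with a single level are dropped), with reference levels
#' uniform / activity / activity. On these balanced simulated designs the
#' coefficients are the condition contrasts.
#'
#' @param data A `"ttri_runs"` or `"activity_runs"` table.
#' @return A fitted [stats::lm] object.
#' @export
fit_transitivity_model <- function(data) {
  data <- dplyr::filter(data, !is.na(.data$t_tri))
  data$condition <- factor(data$condition, levels = condition_levels())
  data$condition <- droplevels(data$condition)
  data$density_std <- as.numeric(scale(data$density_target))
  lm(t_tri ~ condition * density_std, data = data)
}

#' @rdname fit_transitivity_model
#' @export
fit_activity_model <- function(data) {
  data <- dplyr::filter(data, !is.na(.data$t_tri))
  data$condition <- factor(data$condition, levels = c("uniform", "activity_variable"))
  data$initiation <- factor(data$initiation, levels = c("activity", "random"))
  data$direction <- factor(data$direction, levels = c("activity", "random"))
  terms <- c("condition", "initiation", "direction")
  keep <- terms[vapply(terms, function(v) nlevels(droplevels(data[[v]])) > 1,
                       logical(1))]
  if (length(keep) == 0) stop("no varying factor in `data`", call. = FALSE)
  fml <- stats::as.formula(paste("t_tri ~", paste(keep, collapse = " * ")))
  lm(fml, data = data)
}
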