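test_that("the density schedule is assigned in balanced blocks", {
  res <- run_transitivity_experiment(
    conditions = "uniform", runs_per_condition = 4,
    density_targets = c(20, 40), seed = 1,
    n_agents = 30, n_steps = 500, grid_size = 20
  )
  expect_equal(res$density_target, c(20, 20, 40, 40))
  expect_equal(nrow(res), 4L)
  # deterministic under the master seed
  res2 <- run_transitivity_experiment(
    conditions = "uniform", runs_per_condition = 4,
    density_targets = c(20, 40), seed = 1,
    n_agents = 30, n_steps = 500, grid_size = 20
  )
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("the activity experiment maps rule labels onto simulator rules", {
  res <- run_activity_experiment(
    conditions = "activity_variable", n_runs = 1, target_edges = 30,
    seed = 3, n_agents = 30, n_steps = 800, grid_size = 20
  )
  expect_equal(nrow(res), 4L)
  expect_setequal(paste(res$initiation, res$direction),
                  c("activity activity", "activity random",
                    "random activity", "random random"))
})

test_that("contrast summaries are reference-cell arithmetic", {
  runs <- tibble::tibble(
    condition = rep(c("uniform", "activity_variable"), each = 3),
    t_tri = c(0.00, 0.01, 0.02, 0.54, 0.56, 0.55)
  )
  s <- summarize_contrasts(runs, "t_tri", by = "condition",
                           reference = c(condition = "uniform"))
  expect_equal(s$contrast[s$condition == "uniform"], 0)
  expect_equal(s$contrast[s$condition == "activity_variable"], 0.54, tolerance = 1e-12)
  expect_equal(s$n, c(3L, 3L))
  expect_error(
    summarize_contrasts(runs, "t_tri", reference = c(condition = "nope")),
    "exactly one"
  )
  runs$t_tri[1:3] <- NA
  expect_error(
    summarize_contrasts(runs, "t_tri", reference = c(condition = "uniform")),
    "empty cell"
  )
})

test_that("the activity-design OLS recovers the cell-mean interaction", {
  # balanced two-factor design with known cell means: treatment-coded OLS
  # coefficients are exactly the cell-mean differences
  cells <- tidyr::expand_grid(
    condition = c("uniform", "activity_variable"),
    initiation = "activity",
    direction = c("activity", "random"),
    run = 1:5
  )
  mu <- c("uniform.activity" = 0, "uniform.random" = 0.003,
          "activity_variable.activity" = 0.569, "activity_variable.random" = 0.026)
  cells$t_tri <- mu[paste(cells$condition, cells$direction, sep = ".")]
  fit <- fit_activity_model(cells)
  coefs <- coef(fit)
  expect_equal(unname(coefs["conditionactivity_variable:directionrandom"]),
               (0.026 - 0.569) - (0.003 - 0), tolerance = 1e-10)
  expect_equal(unname(coefs["conditionactivity_variable"]), 0.569, tolerance = 1e-10)
})

test_that("the density model standardizes density and uses uniform as reference", {
  runs <- tidyr::expand_grid(condition = c("uniform", "correlated"),
                             density_target = c(150, 300), run = 1:3)
  runs$t_tri <- ifelse(runs$condition == "uniform", 0.01, 0.52)
  fit <- fit_transitivity_model(runs)
  expect_equal(unname(coef(fit)["conditioncorrelated"]), 0.51, tolerance = 1e-10)
  expect_true("density_std" %in% names(fit$model))
  expect_equal(mean(fit$model$density_std), 0)
})

test_that("small null ensembles are valid and self-consistent", {
  ens <- make_null_ensemble(
    n_networks = 3, target_edges = 40, seed = 21,
    config = sim_config(n_agents = 30, n_steps = 800, grid_size = 20)
  )
  expect_equal(nrow(ens), 3L)
  expect_true(all(c("030T", "030C", "300") %in% names(ens)))
  expect_true(all(ens$t_end <= 800))
  # an observation drawn from the same process standardizes to modest Z
  g <- grow_to_density(run_simulation(
    sim_config(n_agents = 30, n_steps = 800, grid_size = 20, seed = 99)
  ), 40)
  prof <- tsp_profile(triangle_census(g), ens)
  expect_equal(nrow(prof), 7L)
  expect_true(all(is.finite(prof$z_norm)))
  expect_lte(sqrt(sum(prof$z_norm^2)), 1 + 1e-9)
})

test_that("unreachable targets surface as experiment failures, not crashes", {
  expect_warning(
    res <- run_transitivity_experiment(
      conditions = "uniform", runs_per_condition = 1,
      density_targets = 400, seed = 5,
      n_agents = 30, n_steps = 40, grid_size = 20
    ),
    "no t_tri"
  )
  expect_true(is.na(res$t_tri))
  expect_error(
    make_null_ensemble(n_networks = 2, target_edges = 400, seed = 5,
                       config = sim_config(n_agents = 30, n_steps = 40,
                                           grid_size = 20),
                       max_retries = 1),
    "never reached"
  )
})

test_that("experiment tables tidy into cell summaries", {
  res <- run_transitivity_experiment(
    conditions = c("uniform", "activity_variable"), runs_per_condition = 2,
    density_targets = 30, seed = 8, n_agents = 30, n_steps = 800,
    grid_size = 20
  )
  s <- tidy(res)
  expect_equal(nrow(s), 2L)
  expect_true(all(c("mean", "sd", "contrast") %in% names(s)))
  g <- glance(res)
  expect_equal(g$n_runs, 4L)
})
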