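test_that("activation follows the exponential gate", {
  expect_error(is_active(c(1, -2)), "positive")
  # enormous activity level: essentially always active
  expect_true(all(withr::with_seed(1, is_active(rep(1e6, 1000)))))
  # A = 1: empirical frequency near 1 - exp(-1) within 3 standard errors
  p <- 1 - exp(-1)
  hits <- withr::with_seed(2, mean(is_active(rep(1, 1e5))))
  expect_lt(abs(hits - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("neighbour search is an inclusive Euclidean radius filter", {
  pos <- tibble::tibble(agent_id = 0:2, x = c(0, 0.5, 3), y = c(0, 0, 0))
  expect_equal(find_neighbours(0, pos, 0.5), 1L)   # boundary inclusive
  expect_equal(find_neighbours(1, pos, 0.5), 0L)
  expect_equal(find_neighbours(2, pos, 0.5), integer(0))
  # agreement with an all-pairs distance-matrix filter on random positions
  pos <- withr::with_seed(5, tibble::tibble(
    agent_id = 0:99, x = runif(100, 0, 10), y = runif(100, 0, 10)
  ))
  d <- as.matrix(dist(cbind(pos$x, pos$y)))
  for (i in c(1, 25, 77)) {
    expect_setequal(find_neighbours(i, pos, 1.5),
                    pos$agent_id[d[i + 1, ] <= 1.5 & pos$agent_id != i])
  }
})

test_that("move_agent handles activity gating, straight walks and boundaries", {
  s <- list(x = 10, y = 10, heading = 90, active = FALSE)
  expect_identical(move_agent(s, turning = 60), s)
  # zero turning noise: ten active steps due north cover 5 patches
  s$active <- TRUE
  for (k in 1:10) s <- move_agent(s, turning = 0)
  expect_equal(c(s$x, s$y), c(10, 15))
  # clamp: the x coordinate is set to that of the boundary
  s <- list(x = 49.9, y = 10, heading = 0, active = TRUE)
  expect_equal(move_agent(s, 0, boundary_rule = "clamp")$x, 50)
  # truncate: the step stops at the wall
  expect_equal(move_agent(s, 0, boundary_rule = "truncate")$x, 50)
  # reflect: the step bounces and the heading mirrors
  r <- move_agent(s, 0, boundary_rule = "reflect")
  expect_equal(r$x, 49.6)
  expect_equal(r$heading, 180)
})

test_that("simulations are byte-identical under a fixed seed", {
  cfg <- quick_config(condition = "uncorrelated", seed = 314)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_interaction_log(run_simulation(cfg), f1)
  write_interaction_log(run_simulation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("positions stay in bounds and per-step displacement never exceeds one step", {
  for (boundary in c("reflect", "truncate", "clamp")) {
    cfg <- quick_config(condition = "ti_variable", seed = 21,
                        boundary_rule = boundary)
    log <- run_simulation(cfg, record_positions = TRUE)
    px <- attr(log, "pos_x")
    py <- attr(log, "pos_y")
    expect_true(all(px >= 0 & px <= cfg$grid_size))
    expect_true(all(py >= 0 & py <= cfg$grid_size))
    disp <- sqrt(diff(px)^2 + diff(py)^2)
    expect_lte(max(disp), cfg$step_length + 1e-9)
  }
})

test_that("an agent signals at most once per step; events are time-ordered", {
  log <- run_simulation(quick_config(seed = 99))
  expect_false(is.unsorted(log$t))
  expect_true(all(log$signaller != log$receiver))
  expect_lte(max(table(paste(log$t, log$signaller))), 1)
  expect_true(all(log$t >= 1 & log$t <= 1000))
})

test_that("interaction phase follows the initiation and direction rules", {
  pos <- tibble::tibble(agent_id = 0:2, x = c(0, 0.3, 10), y = c(0, 0, 0))
  active <- c(TRUE, FALSE, FALSE)
  # one active agent with a single neighbour: exactly one event i -> j
  ev <- withr::with_seed(1, interaction_phase(pos, active, activity = rep(1, 3)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$signaller, 0L)
  expect_equal(ev$receiver, 1L)
  # to_active reverses the edge
  ev <- withr::with_seed(1, interaction_phase(pos, active, rep(1, 3),
                                              direction_rule = "to_active"))
  expect_equal(ev$signaller, 1L)
  expect_equal(ev$receiver, 0L)
  # no agent has a neighbour: no events
  far <- tibble::tibble(agent_id = 0:1, x = c(0, 20), y = c(0, 0))
  ev <- interaction_phase(far, c(TRUE, TRUE), rep(1, 2))
  expect_equal(nrow(ev), 0L)
})

test_that("relative-activity direction assigns signallers proportionally", {
  # two agents confined to a tiny nest are always within radius; with
  # A = (3, 1) the event should point 0 -> 1 with probability 3/4
  traits <- tibble::tibble(agent_id = 0:1, activity = c(3, 1), turning = c(60, 60))
  cfg <- sim_config(n_agents = 2, n_steps = 20000, grid_size = 0.3,
                    initiation_rule = "random_half",
                    direction_rule = "relative_activity", seed = 8)
  log <- run_simulation(cfg, traits = traits)
  expect_gt(nrow(log), 10000)
  frac <- mean(log$signaller == 0)
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / nrow(log)))
})

test_that("random direction splits signallers evenly", {
  traits <- tibble::tibble(agent_id = 0:1, activity = c(3, 1), turning = c(60, 60))
  cfg <- sim_config(n_agents = 2, n_steps = 20000, grid_size = 0.3,
                    direction_rule = "random", seed = 9)
  log <- run_simulation(cfg, traits = traits)
  frac <- mean(log$signaller == 0)
  # agent 0 initiates more often (higher activity) but the coin is fair
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(log)))
})

test_that("uniform-activity colonies interact more than variable-activity ones", {
  n_uni <- nrow(run_simulation(sim_config(condition = "uniform", seed = 101)))
  n_var <- nrow(run_simulation(sim_config(condition = "activity_variable", seed = 102)))
  expect_gt(n_uni, n_var)
})

test_that("straighter walkers cover more of the nest than sinuous ones", {
  cfg <- sim_config(condition = "ti_variable", seed = 55)
  log <- run_simulation(cfg, record_positions = TRUE)
  tr <- log_traits(log)
  px <- attr(log, "pos_x")
  py <- attr(log, "pos_y")
  patches <- vapply(seq_len(cfg$n_agents), function(i) {
    length(unique(paste(floor(pmin(px[, i], 49.999)),
                        floor(pmin(py[, i], 49.999)))))
  }, numeric(1))
  q <- cut(tr$turning, quantile(tr$turning, 0:4 / 4), include.lowest = TRUE,
           labels = FALSE)
  cover <- tapply(patches, q, mean)
  # monotone decline in nest coverage across turning-index quartiles
  expect_true(all(diff(cover) < 0))
})

test_that("interaction logs roundtrip through CSV with their sidecar", {
  cfg <- quick_config(condition = "correlated", seed = 77)
  log <- run_simulation(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_interaction_log(log, path)
  back <- read_interaction_log(path)
  expect_equal(as.data.frame(back), as.data.frame(log))
  expect_equal(log_config(back)[order(names(log_config(back)))],
               cfg[order(names(cfg))], ignore_attr = TRUE)
  expect_equal(as.data.frame(log_traits(back)), as.data.frame(log_traits(log)),
               tolerance = 1e-12)
})
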