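#' Tidiers for diffusion results
#'
#' `tidy()` returns the informed-count trajectory (one row per time
#' step); `glance()` returns a one-row summary with the seed agent, T50
#' and efficiency.
#'
#' @param x A `"diffusion_result"` from [simulate_diffusion()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.diffusion_result <- function(x, ...) {
  x$trajectory
}

#' @rdname tidy.diffusion_result
#' @export
glance.diffusion_result <- function(x, ...) {
  tibble::tibble(
    seed_agent = x$seed_agent, n_agents = x$n_agents,
    threshold = x$threshold, t50 = x$t50, efficiency = x$efficiency,
    n_informed_final = x$n_informed_final
  )
}

#' Tidiers for per-run experiment tables
#'
#' `tidy()` on a transitivity or activity experiment table returns the
#' cell summary from [summarize_contrasts()]; `glance()` returns one row
#' with run and failure counts.
#'
#' @param x A `"ttri_runs"`, `"activity_runs"` or `"diffusion_runs"`
#'   table.
#' @param reference Reference cell passed to [summarize_contrasts()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ttri_runs <- function(x, reference = c(condition = "uniform"), ...) {
  summarize_contrasts(x, "t_tri", by = "condition", reference = reference)
}

#' @rdname tidy.ttri_runs
#' @export
tidy.activity_runs <- function(x, reference = c(condition = "uniform",
                                                initiation = "activity",
                                                direction = "activity"), ...) {
  by <- intersect(c("condition", "initiation", "direction"), names(x))
  summarize_contrasts(x, "t_tri", by = by, reference = reference[by])
}

#' @rdname tidy.ttri_runs
#' @export
tidy.diffusion_runs <- function(x, reference = c(condition = "uniform"), ...) {
  speed <- summarize_contrasts(x, "log_t50", by = "condition",
                               reference = reference)
  eff <- summarize_contrasts(x, "log_efficiency", by = "condition",
                             reference = reference)
  dplyr::bind_rows(
    dplyr::mutate(speed, response = "log_t50", .before = 1),
    dplyr::mutate(eff, response = "log_efficiency", .before = 1)
  )
}

#' @rdname tidy.ttri_runs
#' @export
glance.ttri_runs <- function(x, ...) {
  tibble::tibble(n_runs = nrow(x), n_failed = sum(is.na(x$t_tri)))
}

#' @rdname tidy.ttri_runs
#' @export
glance.activity_runs <- glance.ttri_runs

#' @rdname tidy.ttri_runs
#' @export
glance.diffusion_runs <- function(x, ...) {
  tibble::tibble(n_runs = nrow(x), n_undefined_t50 = sum(is.na(x$t50)))
}
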