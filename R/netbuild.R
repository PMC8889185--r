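#' Construct a weighted directed network by hand
#'
#' @param from,to Integer vectors of agent ids (0-based).
#' @param weight Integer event counts per ordered pair.
#' @param n_nodes Number of nodes in the network.
#' @return A tibble of class `"weighted_digraph"` with columns `from`,
#'   `to`, `weight` and an `n_nodes` attribute.
#' @export
weighted_digraph <- function(from = integer(), to = integer(),
                             weight = integer(), n_nodes) {
  stopifnot(length(from) == length(to), length(from) == length(weight))
  if (any(from == to)) stop("self-loops are not allowed", call. = FALSE)
  if (any(weight < 0)) stop("weights must be nonnegative", call. = FALSE)
  g <- tibble::tibble(from = as.integer(from), to = as.integer(to),
                      weight = as.integer(weight))
  attr(g, "n_nodes") <- as.integer(n_nodes)
  class(g) <- c("weighted_digraph", class(g))
  g
}

#' Construct a binary directed network by hand
#'
#' Each row is a connected dyad: `mutual = FALSE` rows are asymmetric
#' edges `from -> to`; `mutual = TRUE` rows are bidirectional dyads
#' (stored once, with `from < to`).
#'
#' @param from,to Integer agent ids (0-based).
#' @param mutual Logical; whether the dyad is bidirectional.
#' @param n_nodes Number of nodes.
#' @return A tibble of class `"binary_digraph"` with an `n_nodes`
#'   attribute.
#' @examples
#' # a feed-forward loop: A -> B, A -> C, B -> C
#' binary_digraph(from = c(0, 0, 1), to = c(1, 2, 2),
#'                mutual = c(FALSE, FALSE, FALSE), n_nodes = 3)
#' @export
binary_digraph <- function(from = integer(), to = integer(),
                           mutual = logical(length(from)), n_nodes) {
  stopifnot(length(from) == length(to), length(from) == length(mutual))
  if (any(from == to)) stop("self-loops are not allowed", call. = FALSE)
  from <- as.integer(from); to <- as.integer(to); mutual <- as.logical(mutual)
  swap <- mutual & from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste(pmin(from, to), pmax(from, to))
  if (anyDuplicated(key)) stop("each dyad may appear at most once", call. = FALSE)
  g <- tibble::tibble(from = from, to = to, mutual = mutual)
  attr(g, "n_nodes") <- as.integer(n_nodes)
  class(g) <- c("binary_digraph", class(g))
  g
}

#' Number of nodes of a network object
#'
#' @param g A `"weighted_digraph"` or `"binary_digraph"`.
#' @return Integer node count.
#' @export
n_nodes <- function(g) attr(g, "n_nodes", exact = TRUE)

#' Count edges of a binary network
#'
#' Under `"dyads"` counting (the default everywhere in the package) each
#' connected dyad counts once, whether asymmetric or mutual; under
#' `"arcs"` counting a mutual dyad contributes two directed arcs.
#'
#' @param g A `"binary_digraph"`.
#' @param edge_counting `"dyads"` or `"arcs"`.
#' @return Integer edge count.
#' @export
edge_count <- function(g, edge_counting = c("dyads", "arcs")) {
  edge_counting <- match.arg(edge_counting)
  if (edge_counting == "dyads") nrow(g) else nrow(g) + sum(g$mutual)
}

#' Aggregate an interaction log into a weighted directed network
#'
#' Counts, for every ordered pair, the events with time step `<= t_end`,
#' giving the weighted time-aggregated network over the window
#' `[0, t_end]`.
#'
#' @param log An `"interaction_log"`.
#' @param t_end Last time step included in the window (defaults to the
#'   full run).
#' @return A `"weighted_digraph"`.
#' @export
aggregate_interactions <- function(log, t_end = log_n_steps(log)) {
  n_steps <- log_n_steps(log)
  if (t_end < 0 || t_end > n_steps) {
    stop(sprintf("`t_end` must be in [0, %d]", n_steps), call. = FALSE)
  }
  ev <- dplyr::filter(tibble::as_tibble(log), .data$t <= t_end)
  w <- dplyr::count(ev, .data$signaller, .data$receiver, name = "weight")
  weighted_digraph(w$signaller, w$receiver, w$weight, n_nodes = log_n_agents(log))
}

#' Binarize a weighted network by majority direction
#'
#' Per dyad: no events in either direction leaves the dyad absent; events
#' in a single direction, or a strict majority in one direction, give an
#' asymmetric edge in that direction; equal nonzero counts in both
#' directions give a mutual (bidirectional) edge.
#'
#' @param w A `"weighted_digraph"`.
#' @return A `"binary_digraph"`.
#' @examples
#' w <- weighted_digraph(from = c(0, 1), to = c(1, 0), weight = c(3, 2),
#'                       n_nodes = 2)
#' binarize_network(w)   # 0 -> 1 wins the majority
#' @export
binarize_network <- function(w) {
  stopifnot(inherits(w, "weighted_digraph"))
  nn <- n_nodes(w)
  if (nrow(w) == 0) return(binary_digraph(n_nodes = nn))
  dy <- w |>
    dplyr::filter(.data$weight > 0) |>
    dplyr::mutate(i = pmin(.data$from, .data$to), j = pmax(.data$from, .data$to)) |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(
      w_ij = sum(.data$weight[.data$from == .data$i]),
      w_ji = sum(.data$weight[.data$from == .data$j]),
      .groups = "drop"
    )
  if (nrow(dy) == 0) return(binary_digraph(n_nodes = nn))
  from <- ifelse(dy$w_ij >= dy$w_ji, dy$i, dy$j)
  to <- ifelse(dy$w_ij >= dy$w_ji, dy$j, dy$i)
  binary_digraph(from, to, mutual = dy$w_ij == dy$w_ji, n_nodes = nn)
}

#' Grow the aggregation window until a target edge count is reached
#'
#' Builds time-aggregated networks over increasingly larger windows
#' (anchored at `t = 0`, one time step at a time) and returns the binary
#' network at the smallest `t_end` whose edge count is at least
#' `n_edges`.
#'
#' @param log An `"interaction_log"`.
#' @param n_edges Target edge count.
#' @param edge_counting `"dyads"` (default: a mutual dyad counts once) or
#'   `"arcs"` (a mutual dyad counts twice).
#' @return A `"binary_digraph"` with attribute `t_end`, the window length
#'   used.
#' @export
grow_to_density <- function(log, n_edges, edge_counting = c("dyads", "arcs")) {
  edge_counting <- match.arg(edge_counting)
  stopifnot(n_edges >= 1)
  ev <- tibble::as_tibble(log)
  t_end <- if (edge_counting == "dyads") {
    first_density_step_dyads(ev, n_edges)
  } else {
    first_density_step_arcs(ev, n_edges)
  }
  if (is.na(t_end)) {
    achieved <- if (nrow(ev) == 0) 0L else {
      edge_count(binarize_network(aggregate_interactions(log, log_n_steps(log))),
                 edge_counting)
    }
    stop(sprintf(
      "density not reached: %d edges requested but only %d present in the full log",
      n_edges, achieved
    ), call. = FALSE)
  }
  g <- binarize_network(aggregate_interactions(log, t_end))
  attr(g, "t_end") <- t_end
  g
}

# Smallest step at which the number of distinct connected dyads reaches the
# target: the target-th smallest per-dyad first-event time.
first_density_step_dyads <- function(ev, n_edges) {
  if (nrow(ev) == 0) return(NA_integer_)
  first_t <- ev |>
    dplyr::mutate(i = pmin(.data$signaller, .data$receiver),
                  j = pmax(.data$signaller, .data$receiver)) |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(t0 = min(.data$t), .groups = "drop")
  if (nrow(first_t) < n_edges) return(NA_integer_)
  sort(first_t$t0)[n_edges]
}

# Arc counting is not monotone within a dyad (a mutual dyad becoming
# asymmetric loses an arc), so scan events in order, tracking each dyad's
# current contribution (1 asymmetric, 2 mutual) and evaluate the total at
# the end of every time step.
first_density_step_arcs <- function(ev, n_edges) {
  if (nrow(ev) == 0) return(NA_integer_)
  ev <- ev |>
    dplyr::mutate(
      ord = dplyr::row_number(),
      i = pmin(.data$signaller, .data$receiver),
      j = pmax(.data$signaller, .data$receiver),
      fwd = .data$signaller < .data$receiver
    ) |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::mutate(k = dplyr::row_number()) |>
    dplyr::group_by(.data$i, .data$j, .data$fwd) |>
    dplyr::mutate(c_dir = dplyr::row_number()) |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::mutate(
      contribution = 1L + (.data$c_dir == .data$k - .data$c_dir),
      delta = .data$contribution - dplyr::lag(.data$contribution, default = 0L)
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$ord) |>
    dplyr::mutate(total = cumsum(.data$delta))
  step_totals <- ev |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(total = dplyr::last(.data$total), .groups = "drop")
  hit <- which(step_totals$total >= n_edges)
  if (length(hit) == 0) NA_integer_ else step_totals$t[hit[1]]
}

#' Write network edge lists as CSV
#'
#' Weighted networks are written as `source,target,weight`; binary
#' networks as `source,target,mutual` with mutual dyads emitted once
#' (`mutual = 1`).
#'
#' @param g A `"weighted_digraph"` or `"binary_digraph"`.
#' @param path File path.
#' @return `g`, invisibly.
#' @export
write_network <- function(g, path) {
  if (inherits(g, "weighted_digraph")) {
    out <- tibble::tibble(source = g$from, target = g$to, weight = g$weight)
  } else if (inherits(g, "binary_digraph")) {
    out <- tibble::tibble(source = g$from, target = g$to,
                          mutual = as.integer(g$mutual))
  } else {
    stop("`g` must be a weighted_digraph or binary_digraph", call. = FALSE)
  }
  readr::write_csv(out, path)
  invisible(g)
}
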