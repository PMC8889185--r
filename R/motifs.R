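triad_classes <- function() c("030T", "030C", "120D", "120U", "120C", "210", "300")

# n x n dyad-code matrix: 0 absent, 1 edge low->high, 2 edge high->low,
# 3 mutual (indices 1-based over 0-based agent ids)
dyad_code_matrix <- function(g) {
  nn <- n_nodes(g)
  code <- matrix(0L, nn, nn)
  lo <- pmin(g$from, g$to) + 1L
  hi <- pmax(g$from, g$to) + 1L
  val <- ifelse(g$mutual, 3L, ifelse(g$from < g$to, 1L, 2L))
  code[cbind(lo, hi)] <- val
  code
}

# direction helpers on the code matrix; a, b are 1-based with a < b
has_arc <- function(code, a, b) {
  # is there an arc a -> b?
  if (a < b) code[a, b] %in% c(1L, 3L) else code[b, a] %in% c(2L, 3L)
}

classify_triangle <- function(code, a, b, c) {
  idx <- sort(c(a, b, c))
  d <- c(code[idx[1], idx[2]], code[idx[1], idx[3]], code[idx[2], idx[3]])
  m <- sum(d == 3L)
  if (m == 3L) return("300")
  if (m == 2L) return("210")
  if (m == 1L) {
    pairs <- rbind(idx[c(1, 2)], idx[c(1, 3)], idx[c(2, 3)])
    mut <- pairs[d == 3L, ]
    w <- setdiff(idx, mut)
    out_w <- has_arc(code, w, mut[1]) + has_arc(code, w, mut[2])
    return(switch(as.character(out_w), "2" = "120D", "0" = "120U", "120C"))
  }
  outdeg <- vapply(idx, function(v) {
    sum(vapply(setdiff(idx, v), function(u) has_arc(code, v, u), logical(1)))
  }, integer(1))
  if (max(outdeg) == 2L) "030T" else "030C"
}

#' Census of the seven complete-triangle configurations
#'
#' Enumerates every node triple whose three dyads are all connected and
#' classifies each into one of the seven directed triangle classes,
#' labelled by the standard triad taxonomy restricted to complete
#' triangles: `030T` (transitive / feed-forward loop), `030C` (cyclic),
#' `120D`, `120U`, `120C` (one mutual dyad), `210` (two mutual dyads) and
#' `300` (all mutual). Labels for `120D`/`120U` follow the convention used
#' by [igraph::triad_census()].
#'
#' @param g A `"binary_digraph"`.
#' @return A named integer vector of class `"triad_census"` over the seven
#'   classes; its sum is the number of complete triangles.
#' @examples
#' ffl <- binary_digraph(from = c(0, 0, 1), to = c(1, 2, 2),
#'                       mutual = rep(FALSE, 3), n_nodes = 3)
#' triangle_census(ffl)
#' @export
triangle_census <- function(g) {
  stopifnot(inherits(g, "binary_digraph"))
  counts <- setNames(integer(7), triad_classes())
  if (nrow(g) >= 3) {
    skeleton <- igraph::graph_from_edgelist(
      cbind(g$from + 1L, g$to + 1L), directed = FALSE
    )
    if (igraph::vcount(skeleton) < n_nodes(g)) {
      skeleton <- igraph::add_vertices(skeleton, n_nodes(g) - igraph::vcount(skeleton))
    }
    tri <- matrix(as.integer(igraph::triangles(skeleton)), nrow = 3)
    if (ncol(tri) > 0) {
      code <- dyad_code_matrix(g)
      for (k in seq_len(ncol(tri))) {
        cls <- classify_triangle(code, tri[1, k], tri[2, k], tri[3, k])
        counts[cls] <- counts[cls] + 1L
      }
    }
  }
  class(counts) <- "triad_census"
  counts
}

#' @export
print.triad_census <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' Triangle transitivity
#'
#' Quantifies the tendency of complete triangles to be transitive
#' (feed-forward loops) rather than cyclic. With `p_t` the proportion of
#' transitive triangles, `t_tri = 4 * (p_t - 0.75)`, so 0 matches the
#' random-orientation expectation (three quarters of fully oriented
#' triangles are transitive by chance), 1 means all triangles are
#' transitive and -3 all cyclic.
#'
#' Triangles containing mutual (bidirectional) dyads are handled per
#' `mutual`:
#'
#' * `"weighted"` (default): every complete triangle counts, with each of
#'   its mutual dyads resolved in both directions at weight 1/2, so a
#'   class contributes the fraction of its orientations that are
#'   transitive — `030T` 1, `030C` 0, `120D` and `120U` 1, `120C` 1/2,
#'   `210` and `300` 3/4.
#' * `"exclude"`: only all-asymmetric triangles (`030T` vs `030C`) enter
#'   `p_t`.
#'
#' @param g A `"binary_digraph"`, or a `"triad_census"` already computed
#'   from one.
#' @param mutual `"weighted"` or `"exclude"`; see Details.
#' @return A one-row tibble with `n_transitive`, `n_cyclic` (weighted
#'   counts under `"weighted"`), `p_t`, `t_tri`; `p_t` and `t_tri` are
#'   `NA` when no triangle is eligible.
#' @examples
#' cyc <- binary_digraph(from = c(0, 1, 2), to = c(1, 2, 0),
#'                       mutual = rep(FALSE, 3), n_nodes = 3)
#' triangle_transitivity(cyc)   # t_tri = -3
#' @export
triangle_transitivity <- function(g, mutual = c("weighted", "exclude")) {
  mutual <- match.arg(mutual)
  census <- if (inherits(g, "triad_census")) g else triangle_census(g)
  if (mutual == "weighted") {
    w <- c("030T" = 1, "030C" = 0, "120D" = 1, "120U" = 1, "120C" = 0.5,
           "210" = 0.75, "300" = 0.75)
    n_t <- sum(w[triad_classes()] * as.numeric(census[triad_classes()]))
    n_c <- sum(census) - n_t
  } else {
    n_t <- as.numeric(census[["030T"]])
    n_c <- as.numeric(census[["030C"]])
  }
  if (n_t + n_c == 0) {
    p_t <- NA_real_
    t_tri <- NA_real_
  } else {
    p_t <- n_t / (n_t + n_c)
    t_tri <- 4 * (p_t - 0.75)
  }
  tibble::tibble(n_transitive = n_t, n_cyclic = n_c, p_t = p_t, t_tri = t_tri)
}

# coerce a census, list of censuses, or data frame of class columns to a
# numeric matrix with the seven class columns
census_matrix <- function(x) {
  cls <- triad_classes()
  if (inherits(x, "triad_census")) return(matrix(as.numeric(x), 1,
                                                 dimnames = list(NULL, cls)))
  if (is.data.frame(x)) {
    missing <- setdiff(cls, names(x))
    if (length(missing)) {
      stop("census table lacks class columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    return(as.matrix(x[, cls]))
  }
  if (is.list(x)) return(do.call(rbind, lapply(x, census_matrix)))
  stop("cannot interpret `x` as triad censuses", call. = FALSE)
}

#' Triad significance profile against a null ensemble
#'
#' For each triangle class, the raw Z-score compares the observed count
#' with the mean and standard deviation of that class across a null
#' ensemble (typically 100 uniform-condition networks at the same binary
#' edge count, produced by [make_null_ensemble()]); the vector of
#' Z-scores is then scaled to unit Euclidean norm. A class whose null
#' standard deviation is zero gets `z = 0` when the observation equals
#' the null mean and is an error otherwise (it cannot be standardized).
#'
#' @param observed A `"triad_census"` for the network of interest.
#' @param null A census table: a data frame with the seven class columns
#'   (one row per null network, as returned by [make_null_ensemble()]), or
#'   a list of `"triad_census"` objects. At least two rows.
#' @return A tibble with one row per class: `class`, `n_obs`,
#'   `null_mean`, `null_sd`, `z`, `z_norm`.
#' @export
tsp_profile <- function(observed, null) {
  obs <- drop(census_matrix(observed))
  nul <- census_matrix(null)
  if (nrow(nul) < 2) stop("null ensemble needs at least 2 networks", call. = FALSE)
  mu <- colMeans(nul)
  sdev <- apply(nul, 2, sd)
  z <- numeric(length(obs))
  degenerate <- sdev == 0
  if (any(degenerate & obs != mu)) {
    stop("null standard deviation is zero for class(es) with a discrepant ",
         "observation: cannot standardize", call. = FALSE)
  }
  z[!degenerate] <- (obs[!degenerate] - mu[!degenerate]) / sdev[!degenerate]
  norm <- sqrt(sum(z^2))
  z_norm <- if (norm > 0) z / norm else z
  tibble::tibble(
    class = triad_classes(), n_obs = as.numeric(obs),
    null_mean = as.numeric(mu), null_sd = as.numeric(sdev),
    z = z, z_norm = z_norm
  )
}
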