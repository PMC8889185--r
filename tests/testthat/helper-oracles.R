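# Independent oracles and fixture builders for the test suite.

# Reference adjacency patterns for the seven complete-triangle classes
# (rows signal to columns), following igraph's 120D/120U convention.
triangle_reference_patterns <- function() {
  pat <- function(edges) {
    m <- matrix(0L, 3, 3)
    for (e in edges) m[e[1], e[2]] <- 1L
    m
  }
  list(
    "030T" = pat(list(c(1, 2), c(1, 3), c(2, 3))),
    "030C" = pat(list(c(1, 2), c(2, 3), c(3, 1))),
    # 120D: third node B sends to both members of the mutual pair
    "120D" = pat(list(c(2, 1), c(2, 3), c(1, 3), c(3, 1))),
    # 120U: third node B receives from both members of the mutual pair
    "120U" = pat(list(c(1, 2), c(3, 2), c(1, 3), c(3, 1))),
    "120C" = pat(list(c(1, 2), c(2, 3), c(1, 3), c(3, 1))),
    "210"  = pat(list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3))),
    "300"  = pat(list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)))
  )
}

# classify a 3x3 0/1 adjacency matrix by exhaustive isomorphism against the
# reference patterns (all 6 node permutations); NA if not a complete triangle
oracle_classify_adjacency <- function(a) {
  connected <- (a + t(a)) > 0
  if (!all(connected[upper.tri(connected)])) return(NA_character_)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  refs <- triangle_reference_patterns()
  for (nm in names(refs)) {
    for (p in perms) {
      if (identical(a[p, p], refs[[nm]])) return(nm)
    }
  }
  stop("unclassifiable complete triangle (oracle bug)")
}

# brute-force census: enumerate all node triples of a binary_digraph
oracle_triangle_census <- function(g) {
  nn <- n_nodes(g)
  adj <- matrix(0L, nn, nn)
  for (k in seq_len(nrow(g))) {
    i <- g$from[k] + 1L
    j <- g$to[k] + 1L
    adj[i, j] <- 1L
    if (g$mutual[k]) adj[j, i] <- 1L
  }
  counts <- setNames(integer(7), c("030T", "030C", "120D", "120U", "120C", "210", "300"))
  if (nn < 3) return(counts)
  for (trip in utils::combn(nn, 3, simplify = FALSE)) {
    cls <- oracle_classify_adjacency(adj[trip, trip])
    if (!is.na(cls)) counts[cls] <- counts[cls] + 1L
  }
  counts
}

# random binary digraph: n_edges distinct dyads, each mutual with
# probability p_mutual, otherwise uniformly oriented
random_binary_digraph <- function(n_nodes, n_edges, p_mutual = 0.2) {
  pairs <- utils::combn(n_nodes, 2)
  pick <- sample(ncol(pairs), n_edges)
  i <- pairs[1, pick] - 1L
  j <- pairs[2, pick] - 1L
  mutual <- runif(n_edges) < p_mutual
  flip <- !mutual & runif(n_edges) < 0.5
  from <- ifelse(flip, j, i)
  to <- ifelse(flip, i, j)
  binary_digraph(from, to, mutual, n_nodes = n_nodes)
}

# igraph object carrying mutual dyads as two arcs, for triad_census
as_igraph_directed <- function(g) {
  from <- c(g$from, g$to[g$mutual]) + 1L
  to <- c(g$to, g$from[g$mutual]) + 1L
  ig <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  if (igraph::vcount(ig) < n_nodes(g)) {
    ig <- igraph::add_vertices(ig, n_nodes(g) - igraph::vcount(ig))
  }
  ig
}

# small fixture log builder
make_log <- function(t, signaller, receiver, n_agents, n_steps = max(t)) {
  as_interaction_log(
    tibble::tibble(t = t, signaller = signaller, receiver = receiver),
    n_agents = n_agents, n_steps = n_steps
  )
}

# a quick small simulation configuration for property tests
quick_config <- function(...) {
  args <- utils::modifyList(list(n_agents = 40, n_steps = 1000, grid_size = 25),
                            list(...))
  do.call(sim_config, args)
}
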