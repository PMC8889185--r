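fixture_graph <- function(class) {
  switch(class,
    "030T" = binary_digraph(c(0, 0, 1), c(1, 2, 2), rep(FALSE, 3), 3),
    "030C" = binary_digraph(c(0, 1, 2), c(1, 2, 0), rep(FALSE, 3), 3),
    "120D" = binary_digraph(c(2, 2, 0), c(0, 1, 1), c(FALSE, FALSE, TRUE), 3),
    "120U" = binary_digraph(c(0, 1, 0), c(2, 2, 1), c(FALSE, FALSE, TRUE), 3),
    "120C" = binary_digraph(c(0, 2, 0), c(2, 1, 1), c(FALSE, FALSE, TRUE), 3),
    "210"  = binary_digraph(c(0, 0, 1), c(1, 2, 2), c(TRUE, TRUE, FALSE), 3),
    "300"  = binary_digraph(c(0, 0, 1), c(1, 2, 2), rep(TRUE, 3), 3)
  )
}

test_that("each single-triangle fixture lands in its own census class", {
  for (cls in c("030T", "030C", "120D", "120U", "120C", "210", "300")) {
    cen <- triangle_census(fixture_graph(cls))
    expect_equal(sum(cen), 1L, info = cls)
    expect_equal(as.integer(cen[[cls]]), 1L, info = cls)
    # and the brute-force isomorphism oracle agrees
    expect_equal(unclass(cen)[], oracle_triangle_census(fixture_graph(cls)),
                 info = cls, ignore_attr = TRUE)
  }
})

test_that("census agrees with exhaustive enumeration and igraph on random digraphs", {
  withr::local_seed(77)
  for (k in 1:100) {
    n <- sample(5:12, 1)
    g <- random_binary_digraph(n, sample.int(n * (n - 1) / 2, 1),
                               p_mutual = runif(1, 0, 0.5))
    cen <- triangle_census(g)
    expect_equal(unclass(cen)[], oracle_triangle_census(g), ignore_attr = TRUE)
    # igraph's Batagelj-Mrvar triad census as a second, independent oracle
    full <- igraph::triad_census(as_igraph_directed(g))
    expect_equal(as.numeric(cen),
                 full[c(9, 10, 12, 13, 14, 15, 16)])
  }
})

test_that("transitivity hits its analytic anchors", {
  expect_equal(triangle_transitivity(fixture_graph("030T"))$t_tri, 1)
  expect_equal(triangle_transitivity(fixture_graph("030C"))$t_tri, -3)
  # three transitive and one cyclic triangle in disjoint components: the
  # proportion transitive is exactly the null 3/4, so t_tri = 0
  g <- binary_digraph(
    from = c(0, 0, 1, 3, 3, 4, 6, 6, 7, 9, 10, 11),
    to   = c(1, 2, 2, 4, 5, 5, 7, 8, 8, 10, 11, 9),
    mutual = rep(FALSE, 12), n_nodes = 12
  )
  tt <- triangle_transitivity(g)
  expect_equal(tt$n_transitive, 3)
  expect_equal(tt$n_cyclic, 1)
  expect_equal(tt$t_tri, 0)
  # identical under both mutual-dyad treatments when no dyad is mutual
  expect_equal(triangle_transitivity(g, mutual = "exclude")$t_tri, 0)
})

test_that("mutual-dyad triangles contribute their orientation fractions", {
  for (cls in c("120D", "120U")) {
    expect_equal(triangle_transitivity(fixture_graph(cls))$t_tri, 1, info = cls)
  }
  expect_equal(triangle_transitivity(fixture_graph("120C"))$p_t, 0.5)
  expect_equal(triangle_transitivity(fixture_graph("210"))$t_tri, 0)
  expect_equal(triangle_transitivity(fixture_graph("300"))$t_tri, 0)
  # under the exclusion rule these triangles are ineligible
  expect_true(is.na(triangle_transitivity(fixture_graph("300"),
                                          mutual = "exclude")$t_tri))
  expect_true(is.na(triangle_transitivity(binary_digraph(n_nodes = 3))$t_tri))
})

test_that("t_tri stays in [-3, 1], is label-invariant, and centres on 0 for random orientations", {
  withr::local_seed(123)
  vals <- replicate(100, {
    g <- random_binary_digraph(100, 1000, p_mutual = 0)
    triangle_transitivity(g)$t_tri
  })
  expect_true(all(vals >= -3 & vals <= 1))
  expect_lt(abs(mean(vals)), 0.05)
  # node relabelling leaves t_tri unchanged
  g <- random_binary_digraph(12, 30)
  perm <- sample(0:11)
  g2 <- binary_digraph(perm[g$from + 1], perm[g$to + 1], g$mutual, 12)
  expect_equal(triangle_transitivity(g2)$t_tri, triangle_transitivity(g)$t_tri)
})

test_that("census total matches the undirected triangle count", {
  withr::local_seed(9)
  g <- random_binary_digraph(30, 120)
  skel <- igraph::graph_from_edgelist(cbind(g$from, g$to) + 1, directed = FALSE)
  expect_equal(sum(triangle_census(g)),
               length(igraph::triangles(skel)) / 3)
})

test_that("triad significance profiles standardize and normalize correctly", {
  cls <- c("030T", "030C", "120D", "120U", "120C", "210", "300")
  null <- tibble::as_tibble(setNames(as.list(rep(5, 7)), cls))[rep(1, 4), ]
  null[2, ] <- null[2, ] + 1 # give every class sd > 0
  obs <- structure(setNames(rep(5.25, 7), cls), class = "triad_census")
  prof <- tsp_profile(obs, null)
  expect_equal(prof$z, rep(0, 7))
  expect_equal(prof$z_norm, rep(0, 7))
  # unit-norm arithmetic: raw Z (3, 4, 0, ...) normalizes to (0.6, 0.8, 0, ...)
  null2 <- null
  obs2 <- obs
  obs2[1] <- 5.25 + 3 * sd(null2[["030T"]])
  obs2[2] <- 5.25 + 4 * sd(null2[["030C"]])
  prof2 <- tsp_profile(obs2, null2)
  expect_equal(prof2$z_norm[1:2], c(0.6, 0.8))
  expect_equal(sqrt(sum(prof2$z_norm^2)), 1)
  # degenerate null sd with a discrepant observation cannot be standardized
  null3 <- null
  null3[["030T"]] <- rep(5, 4)
  obs3 <- obs
  obs3[1] <- 9
  expect_error(tsp_profile(obs3, null3), "cannot standardize")
  expect_error(tsp_profile(obs, null[1, ]), "at least 2")
})
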