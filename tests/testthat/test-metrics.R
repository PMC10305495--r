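# degree, centralities, diameter/radius and their oracles

test_that("degree counts incident edges under the self-pair convention", {
  net <- path_abc()
  expect_equal(node_degree(net, "B"), 2)
  solo <- interactome(edges = rbind(c("X", "X")))
  expect_equal(node_degree(solo, "X"), 1)
  expect_equal(node_degree(solo, "X", self_loops = "double"), 2)
  expect_error(node_degree(net, "Q"), "Q")
})

test_that("degree sum identity holds on random graphs", {
  set.seed(5)
  for (rep in 1:10) {
    rg <- random_graph_edges(25, p_edge = 0.2, p_self = 0.2)
    net <- interactome(nodes = rg$nodes, edges = rg$edges)
    degs <- vapply(net$nodes, function(v) node_degree(net, v), integer(1))
    plain <- sum(net$edges$a != net$edges$b)
    expect_equal(sum(degs), 2 * plain + n_self_pairs(net))
  }
})

test_that("betweenness matches hand-enumerated cases", {
  net <- path_abc()
  b <- betweenness_centrality(net)
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))

  star <- star_net()
  b2 <- betweenness_centrality(star)
  expect_equal(unname(b2["C0"]), 6)  # C(4,2) leaf pairs
  expect_true(all(b2[names(b2) != "C0"] == 0))

  k5 <- interactome(edges = t(utils::combn(LETTERS[1:5], 2)))
  expect_true(all(betweenness_centrality(k5) == 0))

  # normalization scales by 2/((n-1)(n-2))
  bn <- betweenness_centrality(star, normalized = TRUE)
  expect_equal(unname(bn["C0"]), 6 * 2 / (4 * 3))
})

test_that("closeness matches the component-scaled formula", {
  net <- path_abc()
  cl <- closeness_centrality(net)
  expect_equal(unname(cl["B"]), 1.0)
  expect_equal(unname(cl["A"]), 2 / 3)

  single <- interactome(nodes = "X")
  expect_equal(unname(closeness_centrality(single)), 0)

  two_edges <- interactome(edges = rbind(c("A", "B"), c("C", "D")))
  expect_equal(unname(closeness_centrality(two_edges)),
               rep(1 / 3, 4))
})

test_that("diameter and radius on canonical graphs", {
  p4 <- interactome(edges = rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  dr <- diameter_radius(p4)
  expect_equal(dr$diameter, 3)
  expect_equal(dr$radius, 2)

  dr2 <- diameter_radius(star_net())
  expect_equal(dr2$diameter, 2)
  expect_equal(dr2$radius, 1)

  expect_error(diameter_radius(interactome()), "empty")
})

test_that("centralities and eccentricities match brute-force oracles", {
  set.seed(314)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    rg <- random_graph_edges(n, p_edge = 0.4, p_self = 0.15)
    net <- interactome(nodes = rg$nodes, edges = rg$edges)
    oracle <- bf_graph_oracle(rg$nodes, net$edges)

    expect_equal(betweenness_centrality(net)[rg$nodes],
                 oracle$betweenness[rg$nodes], tolerance = 1e-10)
    expect_equal(closeness_centrality(net)[rg$nodes],
                 bf_closeness(oracle$dist)[rg$nodes], tolerance = 1e-10)
    dr <- diameter_radius(net)
    bf <- bf_diameter_radius(oracle$dist)
    expect_equal(dr$diameter, bf$diameter)
    expect_equal(dr$radius, bf$radius)
    expect_equal(dr$component_count, bf$component_count)
    expect_true(dr$radius <= dr$diameter)
    expect_true(dr$diameter <= 2 * dr$radius || dr$diameter == 0)
  }
})

test_that("diameter/radius are invariant under node relabeling", {
  set.seed(21)
  rg <- random_graph_edges(7, p_edge = 0.4)
  net <- interactome(nodes = rg$nodes, edges = rg$edges)
  relab <- stats::setNames(sample(sprintf("Z%02d", 1:7)), rg$nodes)
  ed2 <- data.frame(a = unname(relab[rg$edges$a]),
                    b = unname(relab[rg$edges$b]),
                    stringsAsFactors = FALSE)
  net2 <- interactome(nodes = unname(relab), edges = ed2)
  expect_equal(diameter_radius(net)[1:2], diameter_radius(net2)[1:2])
})

test_that("adding an edge never increases any shortest-path distance", {
  set.seed(88)
  for (rep in 1:5) {
    rg <- random_graph_edges(7, p_edge = 0.3)
    net <- interactome(nodes = rg$nodes, edges = rg$edges)
    d0 <- bf_graph_oracle(rg$nodes, net$edges)$dist
    absent <- t(utils::combn(rg$nodes, 2))
    present <- paste(net$edges$a, net$edges$b)
    absent <- absent[!paste(pmin(absent[, 1], absent[, 2]),
                            pmax(absent[, 1], absent[, 2])) %in% present, ,
                     drop = FALSE]
    if (nrow(absent) == 0) next
    pick <- absent[sample(nrow(absent), 1), ]
    net2 <- interactome(nodes = rg$nodes,
                        edges = rbind(net$edges,
                                      data.frame(a = pick[1], b = pick[2])))
    d1 <- bf_graph_oracle(rg$nodes, net2$edges)$dist
    expect_true(all(d1[rg$nodes, rg$nodes] <= d0[rg$nodes, rg$nodes]))
  }
})

test_that("mean neighbor degree uses whole-interactome degrees", {
  star <- star_net()
  expect_equal(mean_neighbor_degree(star, "C0"), 1.0)
  expect_equal(mean_neighbor_degree(path_abc(), "B"), 1.0)

  # hub fixture: neighbor degrees summed by hand in the full graph
  net <- interactome(edges = rbind(c("H", "A"), c("H", "B"), c("A", "B"),
                                   c("B", "C"), c("C", "D")))
  # neighbors of H: A (deg 2), B (deg 3)
  expect_equal(mean_neighbor_degree(net, "H"), 2.5)

  iso <- interactome(nodes = "L")
  expect_error(mean_neighbor_degree(iso, "L"), "undefined")
})

test_that("node_metrics tabulates all three measures consistently", {
  net <- ten_node_fixture()
  tab <- node_metrics(net)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$node[1], "T")   # highest degree first
  expect_equal(tab$degree[1], 9)
  b <- betweenness_centrality(net)
  expect_equal(tab$betweenness, unname(b[tab$node]))
})
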