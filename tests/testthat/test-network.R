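# first-neighbor extraction and protein-drug network assembly

test_that("first_neighbors follows edges and excludes self", {
  net <- path_abc()
  expect_setequal(first_neighbors(net, "B")$neighbors, c("A", "C"))
  expect_setequal(first_neighbors(net, "A")$neighbors, "B")

  solo <- interactome(edges = rbind(c("X", "X")))
  expect_length(first_neighbors(solo, "X")$neighbors, 0)

  expect_error(first_neighbors(net, "Z"), "Z")
})

test_that("first_neighbors equals an exhaustive edge scan on random graphs", {
  set.seed(42)
  for (rep in 1:10) {
    rg <- random_graph_edges(50, p_edge = 0.08, p_self = 0.1)
    net <- interactome(nodes = rg$nodes, edges = rg$edges)
    for (v in sample(rg$nodes, 5)) {
      ed <- net$edges
      expected <- sort(unique(setdiff(
        c(ed$b[ed$a == v], ed$a[ed$b == v]), v)))
      expect_identical(first_neighbors(net, v)$neighbors, expected)
    }
  }
})

test_that("target_subnetwork induces the full first-neighbor subgraph", {
  net <- ten_node_fixture()
  sub <- target_subnetwork(net, "T")
  expect_equal(length(sub$nodes), 10)
  expect_equal(nrow(sub$edges), 18)

  iso <- interactome(nodes = "Z", edges = rbind(c("A", "B")))
  sub2 <- target_subnetwork(iso, "Z")
  expect_equal(sub2$nodes, "Z")
  expect_equal(nrow(sub2$edges), 0)

  star <- star_net()
  sub3 <- target_subnetwork(star, "C0")
  expect_setequal(sub3$nodes, star$nodes)
  expect_equal(nrow(sub3$edges), nrow(star$edges))

  expect_error(target_subnetwork(net, c("T", "missing")), "missing")
})

test_that("toy network construction matches the definitional composition", {
  eco <- toy_ecosystem()
  net <- build_protein_drug_network(eco$net, eco$targets, "D1",
                                    drugs = eco$drugs)
  expect_setequal(net$nodes$id, c("D1", "T", "N1", "N2", "D2"))
  types <- stats::setNames(net$nodes$type, net$nodes$id)
  expect_equal(unname(types[c("D1", "T", "N1", "N2", "D2")]),
               c("focal_drug", "target", "neighbor", "neighbor",
                 "other_drug"))
  key <- paste(net$edges$from, net$edges$to, net$edges$type)
  expect_setequal(key, c("D1 T binds", "D2 N1 binds",
                         "N1 T ppi", "N2 T ppi"))
})

test_that("group collapse replaces members with one node, same edge count", {
  net0 <- interactome(edges = rbind(c("T", "N1"), c("T", "N2")))
  targets <- data.frame(drug_id = c("D1", "D1b"), target = "T",
                        organism = "HUMAN", stringsAsFactors = FALSE)
  class(targets) <- c("drug_target_table", "data.frame")
  drugs <- data.frame(drug_id = c("D1", "D1b"), name = c("a", "b"),
                      smiles = NA, group = "Grp", stringsAsFactors = FALSE)
  plain <- build_protein_drug_network(net0, targets, c("D1", "D1b"),
                                      drugs = drugs)
  collapsed <- build_protein_drug_network(net0, targets, c("D1", "D1b"),
                                          drugs = drugs,
                                          collapse_groups = TRUE)
  expect_true("Grp" %in% collapsed$nodes$id)
  expect_false(any(c("D1", "D1b") %in% collapsed$nodes$id))
  expect_equal(collapsed$nodes$type[collapsed$nodes$id == "Grp"],
               "drug_group")
  # two member binds edges to T collapse into one group edge
  expect_equal(sum(plain$edges$type == "binds"), 2)
  expect_equal(sum(collapsed$edges$type == "binds"), 1)
  expect_equal(sum(collapsed$edges$type == "ppi"),
               sum(plain$edges$type == "ppi"))
})

test_that("build errors on empty or unresolvable focal sets", {
  eco <- toy_ecosystem()
  expect_error(build_protein_drug_network(eco$net, eco$targets,
                                          character(0)), "empty")
  expect_error(build_protein_drug_network(eco$net, eco$targets, "nope"),
               "nope")
})

test_that("build is deterministic under input row order", {
  set.seed(99)
  rg <- random_graph_edges(40, p_edge = 0.1)
  net <- interactome(nodes = rg$nodes, edges = rg$edges)
  targets <- data.frame(
    drug_id = c("D1", "D1", "D2", "D3"),
    target = c(rg$nodes[1], rg$nodes[5], rg$nodes[2], rg$nodes[9]),
    organism = "HUMAN", stringsAsFactors = FALSE)
  class(targets) <- c("drug_target_table", "data.frame")
  perm <- sample(nrow(targets))
  shuffled <- targets[perm, ]
  class(shuffled) <- c("drug_target_table", "data.frame")
  net_shuf <- interactome(nodes = rev(rg$nodes),
                          edges = rg$edges[sample(nrow(rg$edges)), ])
  a <- build_protein_drug_network(net, targets, c("D1", "D2"))
  b <- build_protein_drug_network(net_shuf, shuffled, c("D2", "D1"))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
})

test_that("enlarging the focal drug set never removes nodes or edges", {
  set.seed(7)
  rg <- random_graph_edges(40, p_edge = 0.1)
  net <- interactome(nodes = rg$nodes, edges = rg$edges)
  targets <- data.frame(
    drug_id = c("D1", "D2", "D3"),
    target = rg$nodes[c(1, 8, 15)],
    organism = "HUMAN", stringsAsFactors = FALSE)
  class(targets) <- c("drug_target_table", "data.frame")
  small <- build_protein_drug_network(net, targets, "D1")
  big <- build_protein_drug_network(net, targets, c("D1", "D2", "D3"))
  expect_true(all(small$nodes$id %in% big$nodes$id))
  key <- function(x) paste(x$edges$from, x$edges$to, x$edges$type)
  expect_true(all(key(small) %in% key(big)))
})

test_that("merging a focal target is idempotent and unions correctly", {
  eco <- toy_ecosystem()
  base <- build_protein_drug_network(eco$net, eco$targets, "D1",
                                     drugs = eco$drugs)
  again <- merge_focal_targets(base, "T", eco$net, eco$targets, eco$drugs)
  expect_identical(base$edges, again$edges)
  expect_setequal(base$nodes$id, again$nodes$id)

  # isolated extra target bound by one drug: +2 nodes, +1 edge
  net2 <- interactome(nodes = c(eco$net$nodes, "ISO"),
                      edges = eco$net$edges)
  targets2 <- rbind(eco$targets,
                    data.frame(drug_id = "D9", target = "ISO",
                               organism = "HUMAN",
                               stringsAsFactors = FALSE))
  class(targets2) <- c("drug_target_table", "data.frame")
  merged <- merge_focal_targets(base, "ISO", net2, targets2)
  expect_equal(nrow(merged$nodes), nrow(base$nodes) + 2)
  expect_equal(nrow(merged$edges), nrow(base$edges) + 1)
  expect_error(merge_focal_targets(base, "GONE", net2, targets2), "GONE")
})

test_that("merge equals rebuilding with the enlarged focal target set", {
  set.seed(13)
  for (rep in 1:5) {
    rg <- random_graph_edges(35, p_edge = 0.1, p_self = 0.05)
    net <- interactome(nodes = rg$nodes, edges = rg$edges)
    targets <- data.frame(
      drug_id = sprintf("D%d", 1:6),
      target = sample(rg$nodes, 6),
      organism = "HUMAN", stringsAsFactors = FALSE)
    class(targets) <- c("drug_target_table", "data.frame")
    extra <- sample(setdiff(rg$nodes, targets$target), 1)
    base <- build_protein_drug_network(net, targets, c("D1", "D2"))
    merged <- merge_focal_targets(base, extra, net, targets)
    rebuilt <- build_protein_drug_network(net, targets, c("D1", "D2"),
                                          extra_targets = extra)
    expect_identical(merged$nodes, rebuilt$nodes)
    expect_identical(merged$edges, rebuilt$edges)
  }
})
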