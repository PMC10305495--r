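# seeded synthetic-data generators and their ground-truth bookkeeping

test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_proteins = 0), "positive")
  expect_error(sim_config(pa_m = 50, n_proteins = 10), "pa_m")
  expect_error(sim_config(neighbor_overlap = 1.5), "\\[0, 1\\]")
  w <- default_weights <- sim_config()$ptm_weights
  w[1] <- w[1] + 0.5
  expect_error(sim_config(ptm_weights = w), "sum to 1")
})

test_that("interactome generation is a pure function of the seed", {
  cfg <- sim_config(seed = 2024, n_proteins = 150)
  a <- simulate_interactome(cfg)
  b <- simulate_interactome(cfg)
  expect_identical(a$net$edges, b$net$edges)
  expect_identical(a$gt, b$gt)
  c_ <- simulate_interactome(sim_config(seed = 2025, n_proteins = 150))
  expect_false(identical(a$net$edges, c_$net$edges))
})

test_that("m = 1 growth yields a tree plus self-pairs", {
  cfg <- sim_config(seed = 5, n_proteins = 80, pa_m = 1,
                    self_pair_fraction = 0.1, overlap_pool = 10)
  sim <- simulate_interactome(cfg)
  net <- sim$net
  n_self <- n_self_pairs(net)
  # 79 growth edges + 2 * planted pool wiring + self-pairs
  expect_equal(nrow(net$edges), sim$gt$n_edges)
  expect_equal(nrow(net$edges) - n_self, sim$gt$n_edges_no_self)
  # the 80 grown nodes alone form an acyclic connected graph
  grown <- sprintf("P%05d", 1:80)
  ed <- net$edges[net$edges$a %in% grown & net$edges$b %in% grown &
                    net$edges$a != net$edges$b, ]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = grown)
  expect_equal(igraph::ecount(g), 79)
  expect_equal(igraph::components(g)$no, 1)  # n-1 edges + connected = tree
})

test_that("self-pair fraction zero means no node neighbors itself", {
  cfg <- sim_config(seed = 9, n_proteins = 100, self_pair_fraction = 0)
  sim <- simulate_interactome(cfg)
  expect_equal(n_self_pairs(sim$net), 0)
})

test_that("ground-truth adjacency matches first_neighbors on the output", {
  cfg <- sim_config(seed = 77, n_proteins = 120, overlap_pool = 16)
  sim <- simulate_interactome(cfg)
  probe <- c(sim$gt$hub, sim$gt$planted_targets$a,
             sample(names(sim$gt$adjacency), 10))
  for (v in probe) {
    expect_identical(first_neighbors(sim$net, v)$neighbors,
                     sim$gt$adjacency[[v]])
  }
})

test_that("planted neighbor overlap is exact by construction", {
  for (rho in c(0, 0.25, 0.5, 1)) {
    cfg <- sim_config(seed = 33, n_proteins = 150,
                      neighbor_overlap = rho, overlap_pool = 20)
    sim <- simulate_interactome(cfg)
    ta <- sim$gt$planted_targets$a
    tb <- sim$gt$planted_targets$b
    cmp <- neighbor_jaccard(first_neighbors(sim$net, ta)$neighbors,
                            first_neighbors(sim$net, tb)$neighbors,
                            zero_if_empty = TRUE)
    expect_equal(cmp$m11, sim$gt$comparison_neighbors$m11)
    expect_equal(cmp$m10, sim$gt$comparison_neighbors$m10)
    expect_equal(cmp$m01, sim$gt$comparison_neighbors$m01)
    expect_equal(cmp$j, rho)
    if (rho == 1) expect_equal(cmp$m10 + cmp$m01, 0)
  }
})

test_that("drug class members share the hub target and its neighbor set", {
  cfg <- sim_config(seed = 3, n_proteins = 200, n_drugs = 15,
                    class_size = 6, class_extra_targets = 0)
  sim <- simulate_interactome(cfg)
  dt <- simulate_drug_targets(cfg, sim)
  class_ids <- dt$gt$class_drugs
  human <- dt$targets[dt$targets$organism == "HUMAN", ]
  hub_rows <- human[human$drug_id %in% class_ids, ]
  expect_true(all(hub_rows$target == sim$gt$hub))
  sets <- dt$gt$drug_neighbor_sets[class_ids]
  for (s in sets) expect_identical(s, sets[[1]])
  # the viral row is excluded by the organism filter
  expect_true("VIRAL" %in% dt$targets$organism)
  expect_false("VIRAL" %in% filter_organism(dt$targets)$organism)
})

test_that("planted annotation term achieves the requested fold exactly", {
  cfg <- sim_config(seed = 12, planted_fold = 5, study_size = 20,
                    term_rate = 0.05)
  proteins <- sprintf("P%05d", 1:1000)
  sim <- simulate_annotations(cfg, proteins)
  m <- sim$gt$planted_margins
  expect_equal(m$k, round(5 * m$n * m$K / m$N))
  members <- sim$ann$term_proteins[[sim$gt$planted_term]]
  expect_equal(length(intersect(members, sim$gt$study)), m$k)
  expect_equal(length(members), m$K)
  expect_error(
    simulate_annotations(sim_config(planted_fold = 50, study_size = 5,
                                    term_rate = 0.01),
                         sprintf("P%d", 1:100)),
    "unachievable")
})

test_that("null annotations (fold 1) plant nothing", {
  cfg <- sim_config(seed = 12, planted_fold = 1, n_proteins = 200)
  sim <- simulate_annotations(cfg, sprintf("P%d", 1:200))
  expect_true(is.na(sim$gt$planted_term))
  expect_false("GO:PLANTED" %in% names(sim$ann$term_proteins))
})

test_that("proteoform category frequencies converge to the weights", {
  cfg <- sim_config(seed = 8, ptm_mean_events = 5)
  proteins <- sprintf("P%05d", 1:2000)   # ~10,000 events
  sim <- simulate_proteoforms(cfg, proteins)
  total <- nrow(sim$pf$ptm)
  expect_gt(total, 8000)
  obs <- table(factor(sim$pf$ptm$category, levels = ptm_categories))
  for (cat in ptm_categories) {
    w <- cfg$ptm_weights[[cat]]
    bound <- 3 * sqrt(total * w * (1 - w))
    expect_lt(abs(obs[[cat]] - total * w), bound + 1)
  }
  # totals bookkeeping
  p <- proteins[7]
  expect_equal(proteoform_count(sim$pf, p),
               as.integer(sim$gt$totals[[p]]))
})

test_that("planted disease dominates the ranking", {
  cfg <- sim_config(seed = 21, n_diseases = 15)
  genes <- sprintf("G%02d", 1:40)
  sim <- simulate_diseases(cfg, genes, planted_gene = "G05")
  top <- top_diseases(sim$dt, genes, k = 3)
  expect_equal(top$disease[1], "PlantedDisease")
  # k beyond the table size returns the full ranking
  all_rk <- top_diseases(sim$dt, genes, k = 10000)
  expect_lte(nrow(all_rk), 16)
})

test_that("preferential attachment produces right-skewed degrees", {
  cfg <- sim_config(seed = 101, n_proteins = 500)
  sim <- simulate_interactome(cfg)
  grown <- sprintf("P%05d", 1:500)
  degs <- vapply(grown, function(v)
    length(sim$gt$adjacency[[v]]), integer(1))
  expect_gte(max(degs), 3 * stats::median(degs))
})

test_that("snapshot files reproduce the in-memory objects", {
  cfg <- sim_config(seed = 55, n_proteins = 120, n_drugs = 10,
                    overlap_pool = 16)
  dir <- tempfile("snap")
  snap <- simulate_snapshot(cfg, dir)
  expect_true(all(file.exists(unlist(snap$paths))))
  net <- read_ppi_edges(snap$paths$ppi)
  expect_identical(net$edges, snap$net$edges)
  dt <- read_drug_targets(snap$paths$drug_targets)
  expect_setequal(dt$drugs$drug_id, snap$drugs$drug_id)
  gt_json <- jsonlite::read_json(snap$paths$ground_truth)
  expect_equal(gt_json$interactome$hub, snap$gt$hub)
  # regenerating under the same seed is byte-identical
  dir2 <- tempfile("snap")
  simulate_snapshot(cfg, dir2)
  for (f in c("ppi_edges.tsv", "drug_targets.tsv", "annotations.tsv",
              "diseases.tsv", "proteoforms.tsv", "ground_truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
})
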