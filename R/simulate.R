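# Seeded synthetic-data generators.
#
# These emulate the flat-file snapshots the pipeline ingests (drug-target
# table, binary interactome, annotations, disease scores, proteoform
# events) with known ground truth: planted neighbor overlaps, a planted
# enriched term and a planted top disease are exact by construction, so the
# whole pipeline can be validated offline against the generator's
# bookkeeping.

default_ptm_weights <- c(
  modified_residue = 0.40, glycosylation = 0.15, disulfide_bond = 0.10,
  chain = 0.10, cross_link = 0.07, lipidation = 0.05, signal = 0.04,
  initiator_methionine = 0.04, transit_peptide = 0.02, peptide = 0.02,
  propeptide = 0.01)

#' Simulation configuration
#'
#' Bundles every generator parameter; all randomness flows from `seed` (each
#' generator derives its own sub-seed, so outputs do not depend on call
#' order).
#'
#' @param seed Integer master seed.
#' @param n_proteins Interactome size before the two planted target nodes.
#' @param pa_m Preferential-attachment parameter: edges added per new node.
#' @param self_pair_fraction Fraction of proteins given a self-pair
#'   (emulating homodimers).
#' @param n_drugs Total drugs emitted.
#' @param class_size Size of the drug class sharing one hub target.
#' @param class_extra_targets How many class members get a second target.
#' @param neighbor_overlap Planted Jaccard overlap (rho) between the two
#'   planted targets' neighbor sets.
#' @param overlap_pool Union size of the two planted neighbor sets.
#' @param n_terms Background annotation terms.
#' @param term_rate Per-protein membership rate of each background term.
#' @param planted_fold Fold-enrichment target of the planted term
#'   (1 = no planting, a pure null annotation model).
#' @param study_size Study-set size used when no study set is supplied.
#' @param n_diseases Disease labels in the association table.
#' @param diseases_per_gene Associations drawn per gene.
#' @param ptm_weights Named probability vector over [ptm_categories].
#' @param ptm_mean_events,allelic_mean,splice_mean Poisson means for PTM
#'   events, allelic variants and splice transcripts per protein.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_proteins = 1000, pa_m = 2,
                       self_pair_fraction = 0.02, n_drugs = 40,
                       class_size = 6, class_extra_targets = 2,
                       neighbor_overlap = 0.5, overlap_pool = 40,
                       n_terms = 50, term_rate = 0.05, planted_fold = 5,
                       study_size = 20, n_diseases = 30,
                       diseases_per_gene = 3,
                       ptm_weights = default_ptm_weights,
                       ptm_mean_events = 3, allelic_mean = 1,
                       splice_mean = 2) {
  cfg <- list(seed = as.integer(seed), n_proteins = n_proteins,
              pa_m = pa_m, self_pair_fraction = self_pair_fraction,
              n_drugs = n_drugs, class_size = class_size,
              class_extra_targets = class_extra_targets,
              neighbor_overlap = neighbor_overlap,
              overlap_pool = overlap_pool, n_terms = n_terms,
              term_rate = term_rate, planted_fold = planted_fold,
              study_size = study_size, n_diseases = n_diseases,
              diseases_per_gene = diseases_per_gene,
              ptm_weights = ptm_weights,
              ptm_mean_events = ptm_mean_events,
              allelic_mean = allelic_mean, splice_mean = splice_mean)
  counts <- c(cfg$n_proteins, cfg$pa_m, cfg$n_drugs, cfg$class_size,
              cfg$overlap_pool, cfg$n_terms, cfg$study_size,
              cfg$n_diseases, cfg$diseases_per_gene)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (cfg$pa_m >= cfg$n_proteins) {
    stop("pa_m must be smaller than n_proteins", call. = FALSE)
  }
  probs <- c(cfg$self_pair_fraction, cfg$neighbor_overlap, cfg$term_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("fractions and rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$ptm_weights < 0) ||
      abs(sum(cfg$ptm_weights) - 1) > 1e-8) {
    stop("ptm_weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (!setequal(names(cfg$ptm_weights), ptm_categories) &&
      !all(names(cfg$ptm_weights) %in% ptm_categories)) {
    stop("ptm_weights names must be PTM categories", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a binary interactome
#'
#' Grows a preferential-attachment graph (each new node attaches to `pa_m`
#' distinct existing nodes with probability proportional to degree + 1, so
#' hubs emerge as in real interactomes), adds a configurable fraction of
#' self-pairs emulating homodimers, and wires two extra planted target
#' nodes to a shared neighbor pool plus private pools sized so that the
#' Jaccard overlap of their neighbor sets equals `neighbor_overlap` exactly
#' (up to integer rounding of the pool split). Fully determined by the
#' seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `net` (an [interactome()]) and `gt` (ground truth:
#'   adjacency bookkeeping, hub id, planted targets and their pools,
#'   expected comparison counts, edge counts).
#' @export
simulate_interactome <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  ids <- sprintf("P%05d", seq_len(n))
  deg <- integer(n)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)[-1]) {
    m_i <- min(cfg$pa_m, i - 1)
    tgt <- if (i == 2) 1L else
      sample(seq_len(i - 1), m_i, prob = deg[seq_len(i - 1)] + 1)
    from <- c(from, rep(i, m_i)); to <- c(to, tgt)
    deg[i] <- deg[i] + m_i
    deg[tgt] <- deg[tgt] + 1L
  }
  # planted targets wired to shared + private pools (exact overlap)
  u <- as.integer(cfg$overlap_pool)
  s <- as.integer(round(cfg$neighbor_overlap * u))
  ua <- as.integer(ceiling((u - s) / 2))
  ub <- u - s - ua
  pool <- sample(seq_len(n), u)
  shared <- pool[seq_len(s)]
  only_a <- pool[s + seq_len(ua)]
  only_b <- pool[s + ua + seq_len(ub)]
  ta <- sprintf("P%05d", n + 1)
  tb <- sprintf("P%05d", n + 2)
  all_ids <- c(ids, ta, tb)

  edges <- data.frame(
    a = c(ids[from], rep(ta, s + ua), rep(tb, s + ub)),
    b = c(ids[to], ids[c(shared, only_a)], ids[c(shared, only_b)]),
    stringsAsFactors = FALSE)
  n_self <- round(cfg$self_pair_fraction * n)
  selfers <- if (n_self > 0) ids[sample(seq_len(n), n_self)] else character(0)
  if (n_self > 0) {
    edges <- rbind(edges, data.frame(a = selfers, b = selfers,
                                     stringsAsFactors = FALSE))
  }
  net <- interactome(nodes = all_ids, edges = edges)

  adjacency <- lapply(seq_len(n), function(i) {
    nb <- c(ids[to[from == i]], ids[from[to == i]])
    if (i %in% shared) nb <- c(nb, ta, tb)
    if (i %in% only_a) nb <- c(nb, ta)
    if (i %in% only_b) nb <- c(nb, tb)
    sort(unique(nb))
  })
  names(adjacency) <- ids
  adjacency[[ta]] <- sort(ids[c(shared, only_a)])
  adjacency[[tb]] <- sort(ids[c(shared, only_b)])

  gt <- list(
    adjacency = adjacency,
    hub = ids[which.max(deg)],
    planted_targets = list(a = ta, b = tb),
    pools = list(shared = sort(ids[shared]), only_a = sort(ids[only_a]),
                 only_b = sort(ids[only_b])),
    comparison_neighbors = list(m11 = s, m10 = ua, m01 = ub,
                                j = s / u),
    # with the targets themselves included in each drug's protein set
    comparison_with_targets = list(m11 = s, m10 = ua + 1L, m01 = ub + 1L,
                                   j = s / (u + 2)),
    self_pairs = sort(selfers),
    n_nodes = n + 2L,
    n_edges = length(from) + (s + ua) + (s + ub) + n_self,
    n_edges_no_self = length(from) + (s + ua) + (s + ub))
  list(net = net, gt = gt)
}

#' Simulate a drug-target table
#'
#' Emits a drug class sharing one hub target (a few members get a second
#' target, as real drug classes do), one drug on each planted overlap
#' target, and singleton drugs on other proteins (half of them binding hub
#' neighbors so that "other drug" nodes appear in built networks). One
#' class-drug row targets a non-human (viral) protein to exercise the
#' organism filter. Expected per-drug first-neighbor sets are recorded from
#' the generator's own adjacency bookkeeping.
#'
#' @param cfg A [sim_config()].
#' @param sim Result of [simulate_interactome()] (the same cfg).
#' @return List with `drugs` (drug records), `targets`
#'   (`drug_target_table`) and `gt` (per-drug target and neighbor sets,
#'   focal pair labels).
#' @export
simulate_drug_targets <- function(cfg, sim) {
  set.seed(cfg$seed + 1L)
  gt <- sim$gt
  n_single <- cfg$n_drugs - cfg$class_size - 2L
  if (n_single < 0) {
    stop("n_drugs must cover the class plus the two focal drugs",
         call. = FALSE)
  }
  smiles_pool <- c("CCO", "CCC", "CCCC", "CCN", "CCCN", "CC(C)C", "CCOC",
                   "CCCO")
  hub <- gt$hub
  protein_ids <- names(gt$adjacency)
  plain <- setdiff(protein_ids,
                   c(hub, gt$planted_targets$a, gt$planted_targets$b))

  class_ids <- sprintf("DRGC%02d", seq_len(cfg$class_size))
  rows <- data.frame(drug_id = class_ids, target = hub,
                     organism = "HUMAN", stringsAsFactors = FALSE)
  n_extra <- min(cfg$class_extra_targets, cfg$class_size)
  if (n_extra > 0) {
    extra_t <- sample(plain, n_extra)
    rows <- rbind(rows, data.frame(drug_id = class_ids[seq_len(n_extra)],
                                   target = extra_t, organism = "HUMAN",
                                   stringsAsFactors = FALSE))
  }
  rows <- rbind(rows,
                data.frame(drug_id = class_ids[1], target = "PVIRAL01",
                           organism = "VIRAL", stringsAsFactors = FALSE),
                data.frame(drug_id = "DRGA", target = gt$planted_targets$a,
                           organism = "HUMAN", stringsAsFactors = FALSE),
                data.frame(drug_id = "DRGB", target = gt$planted_targets$b,
                           organism = "HUMAN", stringsAsFactors = FALSE))
  if (n_single > 0) {
    single_ids <- sprintf("DRGS%02d", seq_len(n_single))
    hub_nb <- gt$adjacency[[hub]]
    n_on_nb <- min(length(hub_nb), ceiling(n_single / 2))
    singles_t <- c(sample(hub_nb, n_on_nb),
                   sample(plain, n_single - n_on_nb))
    rows <- rbind(rows, data.frame(drug_id = single_ids, target = singles_t,
                                   organism = "HUMAN",
                                   stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  class(rows) <- c("drug_target_table", "data.frame")

  all_ids <- unique(rows$drug_id)
  drugs <- data.frame(
    drug_id = all_ids,
    name = paste0("Drug ", all_ids),
    smiles = smiles_pool[(seq_along(all_ids) - 1L) %% length(smiles_pool) + 1L],
    group = ifelse(all_ids %in% class_ids, "MainClass", NA_character_),
    stringsAsFactors = FALSE)

  human <- rows[rows$organism == "HUMAN", ]
  drug_targets_gt <- split(human$target, human$drug_id)
  neighbor_sets <- lapply(drug_targets_gt, function(tg) {
    sort(unique(unlist(gt$adjacency[tg])))
  })
  gt_out <- list(
    drug_targets = lapply(drug_targets_gt, function(x) sort(unique(x))),
    drug_neighbor_sets = neighbor_sets,
    focal_pair = c("DRGA", "DRGB"),
    class_drugs = class_ids)
  list(drugs = drugs, targets = rows, gt = gt_out)
}

#' Simulate an annotation table
#'
#' Background terms annotate each protein independently at a uniform rate
#' (the null model). When `planted_fold > 1`, one extra term is planted
#' whose study-set hit count k = round(fold * n * K / N) achieves the
#' requested fold enrichment exactly (up to that integer rounding); the
#' study set defaults to a random draw of `study_size` proteins.
#'
#' @param cfg A [sim_config()].
#' @param proteins Character vector: the annotation/background universe.
#' @param study Optional study set (character, subset of `proteins`).
#' @return List with `ann` (an [annotation_table()]) and `gt` (study set,
#'   planted term id and its (k, n, K, N) margins; `planted_term` is NA
#'   under the null).
#' @export
simulate_annotations <- function(cfg, proteins, study = NULL) {
  set.seed(cfg$seed + 2L)
  N <- length(proteins)
  if (is.null(study)) {
    study <- sample(proteins, min(cfg$study_size, N))
  }
  stopifnot(all(study %in% proteins))
  n <- length(study)

  term_ids <- sprintf("GO:SIM%04d", seq_len(cfg$n_terms))
  members <- lapply(term_ids, function(tm) {
    proteins[stats::runif(N) < cfg$term_rate]
  })
  names(members) <- term_ids
  planted <- NA_character_
  planted_margins <- NULL
  if (cfg$planted_fold > 1) {
    K <- max(1L, as.integer(round(cfg$term_rate * N)))
    k <- as.integer(round(cfg$planted_fold * n * K / N))
    if (k < 1 || k > min(n, K)) {
      stop("unachievable planted fold for these sizes (k = ", k, ")",
           call. = FALSE)
    }
    planted <- "GO:PLANTED"
    non_study <- setdiff(proteins, study)
    members[[planted]] <- c(sample(study, k),
                            if (K > k) sample(non_study, K - k))
    planted_margins <- list(k = k, n = n, K = K, N = N,
                            fold = (k / n) / (K / N))
  }
  members <- members[lengths(members) > 0]
  term_names <- stats::setNames(
    ifelse(names(members) == "GO:PLANTED", "planted enriched process",
           paste("simulated process", names(members))),
    names(members))
  prot <- unlist(members, use.names = FALSE)
  term <- rep(names(members), lengths(members))
  ann <- annotation_table(split(term, prot), term_names)
  list(ann = ann,
       gt = list(study = sort(study), planted_term = planted,
                 planted_margins = planted_margins))
}

#' Simulate a proteoform table
#'
#' Per protein: a Poisson number of PTM events with multinomial categories
#' drawn from `ptm_weights`, plus Poisson allelic-variant and
#' splice-transcript counts. Per-protein event totals are recorded as
#' ground truth.
#'
#' @param cfg A [sim_config()].
#' @param proteins Character vector of accessions.
#' @return List with `pf` (a [proteoform_table()]) and `gt` (named vector
#'   of per-protein proteoform totals).
#' @export
simulate_proteoforms <- function(cfg, proteins) {
  set.seed(cfg$seed + 3L)
  n_ev <- stats::rpois(length(proteins), cfg$ptm_mean_events)
  cats <- sample(names(cfg$ptm_weights), sum(n_ev), replace = TRUE,
                 prob = cfg$ptm_weights)
  ptm <- data.frame(protein = rep(proteins, n_ev), category = cats,
                    description = paste("simulated", cats, "event"),
                    stringsAsFactors = FALSE)
  counts <- data.frame(
    protein = proteins,
    allelic_variants = stats::rpois(length(proteins), cfg$allelic_mean),
    splice_transcripts = stats::rpois(length(proteins), cfg$splice_mean),
    stringsAsFactors = FALSE)
  pf <- proteoform_table(ptm, counts)
  totals <- n_ev + counts$allelic_variants + counts$splice_transcripts
  names(totals) <- proteins
  list(pf = pf, gt = list(totals = totals))
}

#' Simulate a gene-disease association table
#'
#' Draws a few scored disease associations per gene (scores uniform in
#' [0.05, 0.9]) and plants one dominating disease: a chosen gene gets the
#' `PlantedDisease` label at score 0.99, above every other score, so a
#' correct ranking must surface it first.
#'
#' @param cfg A [sim_config()].
#' @param genes Character vector of gene ids.
#' @param planted_gene Gene carrying the planted disease (default: the
#'   first of `genes`).
#' @return List with `dt` (a `disease_table`) and `gt` (planted disease and
#'   gene).
#' @export
simulate_diseases <- function(cfg, genes, planted_gene = genes[1]) {
  set.seed(cfg$seed + 4L)
  stopifnot(planted_gene %in% genes)
  labels <- sprintf("Disease%02d", seq_len(cfg$n_diseases))
  k <- min(cfg$diseases_per_gene, cfg$n_diseases)
  assoc <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g, disease = sample(labels, k),
               score = stats::runif(k, 0.05, 0.9),
               stringsAsFactors = FALSE)
  }))
  assoc <- rbind(assoc, data.frame(gene = planted_gene,
                                   disease = "PlantedDisease", score = 0.99,
                                   stringsAsFactors = FALSE))
  dt <- disease_table(assoc)
  list(dt = dt, gt = list(planted_disease = "PlantedDisease",
                          planted_gene = planted_gene))
}

#' Generate and write a full synthetic snapshot
#'
#' Runs every generator under one configuration, writes the TSV snapshot
#' suite (ppi_edges.tsv, drug_targets.tsv, annotations.tsv, diseases.tsv,
#' proteoforms.tsv) plus a ground_truth.json to `dir`, and returns the
#' in-memory objects. The annotation study set is the planted focal drug's
#' protein set (planted target A plus its neighbors) and the planted
#' disease gene is drawn from target A's neighbor pool, so the full
#' pipeline run over the snapshot must recover both.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects, the merged ground
#'   truth, and the file paths.
#' @export
simulate_snapshot <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_interactome(cfg)
  dt <- simulate_drug_targets(cfg, sim)
  proteins <- c(names(sim$gt$adjacency))
  ta <- sim$gt$planted_targets$a
  study <- sort(unique(c(ta, sim$gt$adjacency[[ta]])))
  ann <- simulate_annotations(cfg, proteins, study = study)
  pf <- simulate_proteoforms(cfg, proteins)
  dis <- simulate_diseases(cfg, proteins,
                           planted_gene = sim$gt$pools$shared[1])

  paths <- list(
    ppi = file.path(dir, "ppi_edges.tsv"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    diseases = file.path(dir, "diseases.tsv"),
    proteoforms = file.path(dir, "proteoforms.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  write_ppi_edges(sim$net, paths$ppi)
  write_drug_targets(dt$drugs, dt$targets, paths$drug_targets)
  write_annotations(ann$ann, paths$annotations)
  write_diseases(dis$dt, paths$diseases)
  write_proteoforms(pf$pf, paths$proteoforms)

  gt <- list(interactome = sim$gt[setdiff(names(sim$gt), "adjacency")],
             drugs = dt$gt, annotation = ann$gt, diseases = dis$gt,
             proteoforms = list(totals = as.list(pf$gt$totals)))
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(cfg = cfg, net = sim$net,
                 gt = c(sim$gt, dt$gt, ann$gt, dis$gt, pf$gt),
                 drugs = dt$drugs, targets = dt$targets, ann = ann$ann,
                 pf = pf$pf, diseases = dis$dt, paths = paths))
}
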