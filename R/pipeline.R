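# One-shot analysis pipeline: build networks per focal drug group, compute
# topology, compare group neighborhoods (Jaccard), run over-representation
# per group, profile proteoforms and disease associations, and write a
# reproducible report bundle with a run manifest.

normalize_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(config$focal_groups)) {
      config$focal_groups <- lapply(config$focal_groups, as.character)
    }
  }
  defaults <- list(organism = "HUMAN", collapse_groups = FALSE,
                   alpha = 0.05, include_targets = TRUE,
                   aggregate = "max", normalized = FALSE, top_k = 10,
                   seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

read_config_inputs <- function(config) {
  inp <- list()
  inp$net <- read_ppi_edges(config$ppi)
  dtab <- read_drug_targets(config$drug_targets)
  inp$drugs <- dtab$drugs
  inp$targets_all <- dtab$targets
  inp$targets <- filter_organism(dtab$targets, config$organism)
  if (!is.null(config$annotations)) {
    inp$ann <- read_annotations(config$annotations)
  }
  if (!is.null(config$diseases)) inp$dis <- read_diseases(config$diseases)
  if (!is.null(config$proteoforms)) {
    inp$pf <- read_proteoforms(config$proteoforms)
  }
  inp
}

#' Validate pipeline inputs
#'
#' Cross-file referential checks without running the pipeline: focal drugs
#' resolvable in the drug-target table, their targets (for the configured
#' organism) present in the interactome, and annotation / disease /
#' proteoform identifiers overlapping the interactome.
#'
#' @param config Config list or path to a JSON config (fields: `ppi`,
#'   `drug_targets`, `focal_groups`, optional `annotations`, `diseases`,
#'   `proteoforms`, `organism`, ...).
#' @return Data.frame of diagnostics with columns `level` ("error" or
#'   "warning") and `message`; zero rows means a fully consistent snapshot.
#' @export
validate_inputs <- function(config) {
  config <- normalize_config(config)
  inp <- read_config_inputs(config)
  diag <- list()
  note <- function(level, msg) {
    diag[[length(diag) + 1]] <<- data.frame(level = level, message = msg,
                                            stringsAsFactors = FALSE)
  }
  focal <- unique(unlist(config$focal_groups))
  absent <- setdiff(focal, inp$targets$drug_id)
  if (length(absent) > 0) {
    note("error", paste0("focal drug(s) without a ", config$organism,
                         " target: ", paste(absent, collapse = ", ")))
  }
  miss_t <- setdiff(unique(inp$targets$target), inp$net$nodes)
  if (length(miss_t) > 0) {
    note("error", paste0("drug target(s) absent from the interactome: ",
                         paste(utils::head(miss_t, 10), collapse = ", ")))
  }
  if (!is.null(inp$ann)) {
    ann_ids <- names(inp$ann$protein_terms)
    n_hit <- length(intersect(ann_ids, inp$net$nodes))
    if (n_hit == 0) {
      note("warning", paste0("annotation ids disjoint from the interactome (",
                             length(ann_ids), " unmatched)"))
    }
  }
  if (!is.null(inp$dis)) {
    n_hit <- length(intersect(unique(inp$dis$gene), inp$net$nodes))
    if (n_hit == 0) note("warning", "disease genes disjoint from the interactome")
  }
  if (!is.null(inp$pf)) {
    pf_ids <- union(inp$pf$ptm$protein, inp$pf$counts$protein)
    if (length(intersect(pf_ids, inp$net$nodes)) == 0) {
      note("warning", "proteoform proteins disjoint from the interactome")
    }
  }
  if (length(diag) == 0) {
    return(data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, diag)
}

group_protein_set <- function(net_build, include_targets = TRUE) {
  types <- if (include_targets) c("target", "neighbor") else "neighbor"
  sort(net_build$nodes$id[net_build$nodes$type %in% types])
}

write_report_tsv <- function(df, path, manifest_hash) {
  write_tsv_snapshot(df, path,
                     header_comment = paste0("manifest: ", manifest_hash))
}

#' Run the full analysis pipeline
#'
#' For each focal drug group: builds the protein-drug network, exports it
#' (SIF + GraphML), computes per-node topology and a graph summary; then
#' compares every pair of groups by the Jaccard index of their protein sets
#' (targets plus first neighbors by default), runs term-for-term
#' over-representation per group, and emits proteoform breakdowns and
#' disease rankings where those tables are configured. All outputs carry
#' the manifest hash and the run is byte-reproducible from equal inputs.
#'
#' @param config Config list or JSON path. Required fields: `ppi`,
#'   `drug_targets`, `focal_groups` (named list of at least two drug-id
#'   vectors), `out_dir`. Optional: `annotations`, `diseases`,
#'   `proteoforms`, `organism` ("HUMAN"), `collapse_groups`, `alpha`
#'   (0.05), `include_targets` (TRUE), `aggregate` ("max"), `normalized`,
#'   `top_k` (10), `seed`.
#' @return Invisibly, a list with the per-group networks, summaries,
#'   metrics, the comparison table, enrichment results, proteoform
#'   breakdowns, disease rankings, and the manifest.
#' @export
run_pipeline <- function(config) {
  config <- normalize_config(config)
  groups <- config$focal_groups
  if (is.null(groups) || length(groups) < 2 || is.null(names(groups))) {
    stop("pipeline stage config: need >= 2 named focal drug groups",
         call. = FALSE)
  }
  if (is.null(config$out_dir)) {
    stop("pipeline stage config: out_dir is required", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- tryCatch(read_config_inputs(config), error = function(e) {
    stop("pipeline stage ingest: ", conditionMessage(e), call. = FALSE)
  })

  # manifest first; its hash stamps every table
  input_files <- unlist(config[c("ppi", "drug_targets", "annotations",
                                 "diseases", "proteoforms")])
  manifest <- list(
    tool = "dtnet",
    version = as.character(utils::packageVersion("dtnet")),
    inputs = lapply(stats::setNames(nm = names(input_files)), function(nm) {
      list(path = unname(input_files[[nm]]),
           md5 = unname(tools::md5sum(input_files[[nm]])))
    }),
    parameters = config[c("organism", "collapse_groups", "alpha",
                          "include_targets", "aggregate", "normalized",
                          "top_k", "seed")],
    focal_groups = groups)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest_hash <- unname(tools::md5sum(manifest_path))

  gnames <- sort(names(groups))
  nets <- list(); summaries <- list(); metrics <- list()
  protein_sets <- list()
  for (g in gnames) {
    net_g <- tryCatch(
      build_protein_drug_network(inp$net, inp$targets, groups[[g]],
                                 drugs = inp$drugs,
                                 collapse_groups = config$collapse_groups),
      error = function(e) stop("pipeline stage build [", g, "]: ",
                               conditionMessage(e), call. = FALSE))
    nets[[g]] <- net_g
    write_network(net_g, file.path(config$out_dir,
                                   paste0("network_", g, ".sif")), "sif")
    write_network(net_g, file.path(config$out_dir,
                                   paste0("network_", g, ".graphml")),
                  "graphml")
    summaries[[g]] <- graph_summary(net_g)
    metrics[[g]] <- node_metrics(net_g, normalized = config$normalized)
    write_report_tsv(metrics[[g]],
                     file.path(config$out_dir,
                               paste0("metrics_", g, ".tsv")),
                     manifest_hash)
    protein_sets[[g]] <- group_protein_set(net_g, config$include_targets)
  }
  summary_df <- do.call(rbind, lapply(gnames, function(g) {
    s <- summaries[[g]]
    data.frame(group = g, n_nodes = s$n_nodes, n_edges = s$n_edges,
               n_edges_no_self = s$n_edges_no_self,
               n_self_pairs = s$n_self_pairs, diameter = s$diameter,
               radius = s$radius, component_count = s$component_count,
               stringsAsFactors = FALSE)
  }))
  write_report_tsv(summary_df, file.path(config$out_dir, "summary.tsv"),
                   manifest_hash)

  # pairwise Jaccard comparisons, lexicographic by (label_a, label_b)
  pairs <- utils::combn(gnames, 2, simplify = FALSE)
  comparisons <- do.call(rbind, lapply(pairs, function(p) {
    neighbor_jaccard(protein_sets[[p[1]]], protein_sets[[p[2]]],
                     label_a = p[1], label_b = p[2])
  }))
  comparisons <- comparisons[order(comparisons$label_a,
                                   comparisons$label_b), , drop = FALSE]
  rownames(comparisons) <- NULL
  out_cmp <- comparisons
  out_cmp$j <- sprintf("%.6f", out_cmp$j)
  out_cmp$dj <- sprintf("%.6f", out_cmp$dj)
  write_report_tsv(out_cmp, file.path(config$out_dir, "comparisons.tsv"),
                   manifest_hash)

  enrichment <- list(); proteoforms <- list(); diseases <- list()
  for (g in gnames) {
    if (!is.null(inp$ann)) {
      study <- intersect(protein_sets[[g]], inp$net$nodes)
      res <- tryCatch(
        enrich(study, inp$ann, background = inp$net$nodes,
               alpha = config$alpha),
        error = function(e) stop("pipeline stage enrichment [", g, "]: ",
                                 conditionMessage(e), call. = FALSE))
      enrichment[[g]] <- res
      out <- data.frame(term = res$term, label = res$label,
                        fold_enrichment = format_fold(res$fold_enrichment),
                        p = res$p, fdr = res$q, k = res$k, n = res$n,
                        K = res$K, N = res$N, displayed = res$displayed,
                        stringsAsFactors = FALSE)
      write_report_tsv(out,
                       file.path(config$out_dir,
                                 paste0("enrichment_", g, ".tsv")),
                       manifest_hash)
    }
    if (!is.null(inp$pf)) {
      tg <- nets[[g]]$nodes$id[nets[[g]]$nodes$type == "target"]
      nb <- nets[[g]]$nodes$id[nets[[g]]$nodes$type == "neighbor"]
      known <- union(inp$pf$ptm$protein, inp$pf$counts$protein)
      bd <- lapply(list(targets = intersect(tg, known),
                        neighbors = intersect(nb, known)),
                   function(set) {
                     if (length(set) == 0) return(NULL)
                     tryCatch(ptm_breakdown(inp$pf, set),
                              error = function(e) NULL)
                   })
      proteoforms[[g]] <- bd
      rows <- do.call(rbind, lapply(names(bd), function(scope) {
        if (is.null(bd[[scope]])) return(NULL)
        cbind(data.frame(scope = scope, stringsAsFactors = FALSE),
              as.data.frame(bd[[scope]]))
      }))
      if (!is.null(rows)) {
        write_report_tsv(rows,
                         file.path(config$out_dir,
                                   paste0("proteoforms_", g, ".tsv")),
                         manifest_hash)
      }
    }
    if (!is.null(inp$dis)) {
      rk <- top_diseases(inp$dis, protein_sets[[g]], k = config$top_k,
                         aggregate = config$aggregate)
      diseases[[g]] <- rk
      write_report_tsv(as.data.frame(rk),
                       file.path(config$out_dir,
                                 paste0("diseases_", g, ".tsv")),
                       manifest_hash)
    }
  }

  invisible(list(networks = nets, summaries = summaries, metrics = metrics,
                 protein_sets = protein_sets, comparisons = comparisons,
                 enrichment = enrichment, proteoforms = proteoforms,
                 diseases = diseases, manifest = manifest,
                 manifest_hash = manifest_hash))
}
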