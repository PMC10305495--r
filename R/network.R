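# Protein-drug network construction: projecting drug targets into the
# interactome, extracting first neighbors, and assembling the heterogeneous
# drug + target + neighbor graph.

node_types <- c("focal_drug", "drug_group", "target", "neighbor", "other_drug")

# length-safe node/edge frames (data.frame() cannot recycle into zero rows)
node_frame <- function(id, type, group = NA_character_) {
  data.frame(id = id, type = rep_len(type, length(id)),
             group = rep_len(group, length(id)), stringsAsFactors = FALSE)
}

typed_edges <- function(from, to, type) {
  data.frame(from = from, to = to, type = rep_len(type, length(from)),
             stringsAsFactors = FALSE)
}
drug_node_types <- c("focal_drug", "drug_group", "other_drug")
protein_node_types <- c("target", "neighbor")

#' Construct a protein-drug network
#'
#' A heterogeneous undirected graph mixing drug nodes (connected by `binds`
#' edges to the proteins they bind) and protein nodes (connected by `ppi`
#' edges). No node is both a drug and a protein, and no drug-drug edges
#' exist.
#'
#' @param nodes Data.frame with columns `id`, `type` (one of focal_drug,
#'   drug_group, target, neighbor, other_drug) and optionally `group`.
#' @param edges Data.frame with columns `from`, `to`, `type` (`binds` or
#'   `ppi`).
#' @param provenance Character note on the source table/interactome.
#' @return An object of class `protein_drug_network`.
#' @export
protein_drug_network <- function(nodes, edges, provenance = "") {
  if (!"group" %in% names(nodes)) nodes$group <- NA_character_
  nodes <- nodes[!duplicated(nodes$id), c("id", "type", "group")]
  bad <- setdiff(unique(nodes$type), node_types)
  if (length(bad) > 0) {
    stop("unknown node type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tmap <- stats::setNames(nodes$type, nodes$id)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    if (any(!edges$type %in% c("binds", "ppi"))) {
      stop("edge type must be binds or ppi", call. = FALSE)
    }
    ft <- tmap[edges$from]
    tt <- tmap[edges$to]
    if (any(is.na(ft)) || any(is.na(tt))) {
      stop("edge endpoint not among nodes", call. = FALSE)
    }
    binds <- edges$type == "binds"
    ok_binds <- xor(ft %in% drug_node_types, tt %in% drug_node_types)
    if (any(binds & !ok_binds)) {
      stop("binds edges must connect one drug node to one protein node",
           call. = FALSE)
    }
    if (any(!binds & (ft %in% drug_node_types | tt %in% drug_node_types))) {
      stop("ppi edges must connect protein nodes", call. = FALSE)
    }
    # canonical unordered representation, drug first on binds edges
    a <- ifelse(binds, ifelse(ft %in% drug_node_types, edges$from, edges$to),
                pmin(edges$from, edges$to))
    b <- ifelse(binds, ifelse(ft %in% drug_node_types, edges$to, edges$from),
                pmax(edges$from, edges$to))
    keep <- !duplicated(paste(a, b, edges$type, sep = "\r"))
    edges <- data.frame(from = a[keep], to = b[keep],
                        type = edges$type[keep], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        type = character(), stringsAsFactors = FALSE)
  }
  ord <- order(nodes$id)
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  ord <- order(edges$type, edges$from, edges$to)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "protein_drug_network")
}

#' @export
print.protein_drug_network <- function(x, ...) {
  cat("Protein-drug network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  tab <- table(x$nodes$type)
  cat("  nodes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  tab <- table(x$edges$type)
  cat("  edges:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' First neighbors of a protein in the interactome
#'
#' The first neighbors of a target are the proteins it physically interacts
#' with: all nodes sharing an edge with it, excluding the protein itself
#' (a self-pair never contributes a neighbor). These are the off-target
#' candidate set for drugs binding the target.
#'
#' @param net An [interactome()].
#' @param target Protein accession; must be a node of the interactome.
#' @return An object of class `neighbor_set`: list with `target` and
#'   `neighbors` (character vector, sorted).
#' @export
first_neighbors <- function(net, target) {
  if (!target %in% net$nodes) {
    stop("protein not in interactome: ", target, call. = FALSE)
  }
  ed <- net$edges
  nb <- c(ed$b[ed$a == target], ed$a[ed$b == target])
  nb <- sort(unique(nb[nb != target]))
  structure(list(target = target, neighbors = nb), class = "neighbor_set")
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat("First neighbors of", x$target, ":", length(x$neighbors),
      "protein(s)\n")
  invisible(x)
}

#' Induced target subnetwork of an interactome
#'
#' Projects a set of target proteins into the interactome: the induced
#' subgraph on the targets plus the union of their first neighbors,
#' retaining every interactome edge among the included proteins (including
#' neighbor-neighbor edges and self-pairs).
#'
#' @param net An [interactome()].
#' @param targets Character vector of target accessions.
#' @return An [interactome()] restricted to the neighborhood.
#' @export
target_subnetwork <- function(net, targets) {
  missing <- setdiff(targets, net$nodes)
  if (length(missing) > 0) {
    stop("target(s) not in interactome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  nbrs <- unlist(lapply(targets, function(t) first_neighbors(net, t)$neighbors))
  keep <- unique(c(targets, nbrs))
  ed <- net$edges
  ed <- ed[ed$a %in% keep & ed$b %in% keep, , drop = FALSE]
  interactome(nodes = keep, edges = ed)
}

#' Build a protein-drug interaction network
#'
#' Assembles the heterogeneous network around a set of focal drugs: the
#' focal drugs themselves (optionally collapsed to one node per drug group),
#' their protein targets, the targets' first neighbors in the interactome,
#' and every other drug in the table binding any included protein. Edges are
#' `binds` edges from drugs to the included proteins they bind plus all
#' interactome (`ppi`) edges among included proteins. Expansion is strictly
#' one hop: neighbors of neighbors are never pulled in.
#'
#' @param net An [interactome()].
#' @param targets A `drug_target_table` (see [read_drug_targets()]),
#'   already restricted to the organism of interest (see
#'   [filter_organism()]).
#' @param focal_drugs Character vector of focal drug ids.
#' @param drugs Optional drug records data.frame supplying `group` labels.
#' @param collapse_groups Collapse focal drugs sharing a `group` label into
#'   a single `drug_group` node carrying the union of their binds edges.
#' @param extra_targets Additional focal target accessions to include beyond
#'   the focal drugs' own targets (e.g. a second receptor of interest).
#' @return A `protein_drug_network`.
#' @export
build_protein_drug_network <- function(net, targets, focal_drugs,
                                       drugs = NULL,
                                       collapse_groups = FALSE,
                                       extra_targets = character()) {
  if (length(focal_drugs) == 0) {
    stop("empty focal drug set", call. = FALSE)
  }
  absent <- setdiff(focal_drugs, targets$drug_id)
  if (length(absent) > 0) {
    stop("focal drug(s) with no target in the table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  focal_rows <- targets[targets$drug_id %in% focal_drugs, , drop = FALSE]
  focal_targets <- unique(c(focal_rows$target, extra_targets))
  missing <- setdiff(focal_targets, net$nodes)
  if (length(missing) > 0) {
    stop("target(s) not in interactome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  neighbors <- sort(setdiff(
    unique(unlist(lapply(focal_targets,
                         function(t) first_neighbors(net, t)$neighbors))),
    focal_targets))
  proteins <- c(focal_targets, neighbors)

  other_rows <- targets[!targets$drug_id %in% focal_drugs &
                          targets$target %in% proteins, , drop = FALSE]
  other_drugs <- sort(unique(other_rows$drug_id))

  group_of <- function(ids) {
    if (is.null(drugs)) return(rep(NA_character_, length(ids)))
    drugs$group[match(ids, drugs$drug_id)]
  }

  focal_ids <- sort(unique(focal_rows$drug_id))
  fgroups <- group_of(focal_ids)
  binds_focal <- data.frame(from = focal_rows$drug_id,
                            to = focal_rows$target,
                            stringsAsFactors = FALSE)
  if (collapse_groups && !all(is.na(fgroups))) {
    grouped <- !is.na(fgroups)
    relabel <- stats::setNames(ifelse(grouped, fgroups, focal_ids), focal_ids)
    binds_focal$from <- unname(relabel[binds_focal$from])
    focal_nodes <- data.frame(
      id = unique(unname(relabel)),
      type = ifelse(unique(unname(relabel)) %in% fgroups[grouped],
                    "drug_group", "focal_drug"),
      group = ifelse(unique(unname(relabel)) %in% fgroups[grouped],
                     unique(unname(relabel)), NA_character_),
      stringsAsFactors = FALSE)
  } else {
    focal_nodes <- data.frame(id = focal_ids, type = "focal_drug",
                              group = fgroups, stringsAsFactors = FALSE)
  }

  nodes <- rbind(
    focal_nodes,
    node_frame(focal_targets, "target"),
    node_frame(neighbors, "neighbor"),
    node_frame(other_drugs, "other_drug", group_of(other_drugs)))

  ppi <- net$edges[net$edges$a %in% proteins & net$edges$b %in% proteins, ,
                   drop = FALSE]
  edges <- rbind(
    typed_edges(binds_focal$from, binds_focal$to, "binds"),
    typed_edges(other_rows$drug_id, other_rows$target, "binds"),
    typed_edges(ppi$a, ppi$b, "ppi"))

  protein_drug_network(
    nodes, edges,
    provenance = paste0("focal=", paste(sort(focal_drugs), collapse = ",")))
}

#' Merge an additional focal target into a protein-drug network
#'
#' Unions the base network with the extra target's first-neighborhood and
#' every drug binding an included protein, e.g. to append a second receptor
#' and its interactors to an existing drug network. Idempotent when the
#' target is already a network protein.
#'
#' @param base A `protein_drug_network` built from the same interactome and
#'   drug-target table.
#' @param extra_target Protein accession to add; must be in the interactome.
#' @param net The [interactome()].
#' @param targets The `drug_target_table` used for `base`.
#' @param drugs Optional drug records for group labels.
#' @return The enlarged `protein_drug_network`.
#' @export
merge_focal_targets <- function(base, extra_target, net, targets,
                                drugs = NULL) {
  if (!extra_target %in% net$nodes) {
    stop("target not in interactome: ", extra_target, call. = FALSE)
  }
  base_targets <- base$nodes$id[base$nodes$type == "target"]
  all_targets <- unique(c(base_targets, extra_target))
  nbrs <- unlist(lapply(all_targets,
                        function(t) first_neighbors(net, t)$neighbors))
  proteins <- unique(c(all_targets, setdiff(nbrs, all_targets)))
  neighbors <- sort(setdiff(proteins, all_targets))

  drug_rows <- targets[targets$target %in% proteins, , drop = FALSE]
  base_drug_nodes <- base$nodes[base$nodes$type %in% drug_node_types, ,
                                drop = FALSE]
  focal_ids <- base_drug_nodes$id[base_drug_nodes$type %in%
                                    c("focal_drug", "drug_group")]
  # drugs represented by a collapsed group node keep binding through it
  collapse_map <- stats::setNames(base_drug_nodes$id, base_drug_nodes$id)
  if (!is.null(drugs)) {
    grp <- drugs$group
    grouped_ids <- drugs$drug_id[!is.na(grp) & grp %in% focal_ids]
    collapse_map[grouped_ids] <- drugs$group[match(grouped_ids,
                                                   drugs$drug_id)]
  }
  from_id <- ifelse(drug_rows$drug_id %in% names(collapse_map),
                    unname(collapse_map[drug_rows$drug_id]),
                    drug_rows$drug_id)
  new_drugs <- setdiff(unique(from_id), base_drug_nodes$id)
  grp_new <- if (is.null(drugs)) rep(NA_character_, length(new_drugs)) else
    drugs$group[match(new_drugs, drugs$drug_id)]

  nodes <- rbind(
    base_drug_nodes,
    node_frame(new_drugs, "other_drug", grp_new),
    node_frame(all_targets, "target"),
    node_frame(neighbors, "neighbor"))

  ppi <- net$edges[net$edges$a %in% proteins & net$edges$b %in% proteins, ,
                   drop = FALSE]
  edges <- rbind(
    base$edges[base$edges$type == "binds", , drop = FALSE],
    typed_edges(from_id, drug_rows$target, "binds"),
    typed_edges(ppi$a, ppi$b, "ppi"))

  protein_drug_network(
    nodes, edges,
    provenance = paste0(base$provenance, "+", extra_target))
}
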