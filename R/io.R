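# Domain containers and flat-file I/O.
#
# All inputs are UTF-8 tab-delimited snapshots with a header row; lines
# starting with '#' are comments. Protein nodes are keyed by their accession
# string (UniProt-style); there is no identifier-mapping layer.

#' PTM event categories
#'
#' The fixed vocabulary of post-translational-modification feature classes
#' accepted in proteoform tables. Unknown categories are rejected at parse
#' time so that category breakdowns are always well defined.
#'
#' @format Character vector of 11 category names.
#' @export
ptm_categories <- c(
  "modified_residue", "glycosylation", "disulfide_bond", "chain",
  "cross_link", "lipidation", "signal", "initiator_methionine",
  "transit_peptide", "peptide", "propeptide"
)

read_tsv_snapshot <- function(path, required = character()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          blank.lines.skip = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("format error in ", path, ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv_snapshot <- function(df, path, header_comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---- interactome -----------------------------------------------------------

#' Construct an interactome
#'
#' An interactome is an undirected binary protein-protein interaction graph
#' at the protein-accession level. Self-pairs (a protein interacting with
#' itself, e.g. homodimers) are retained as edges but flagged; neighbor
#' extraction excludes them, because a protein is not its own first neighbor.
#'
#' @param nodes Character vector of protein accessions.
#' @param edges Two-column character matrix or data.frame of interacting
#'   accession pairs. Order within a pair is irrelevant; duplicates under
#'   unordered comparison are collapsed.
#' @return An object of class `interactome` with elements `nodes` (character)
#'   and `edges` (data.frame with columns `a`, `b`, canonically ordered so
#'   that `a <= b`; rows with `a == b` are self-pairs).
#' @export
interactome <- function(nodes = character(), edges = NULL) {
  nodes <- unique(as.character(nodes))
  if (any(!nzchar(nodes))) stop("empty protein accession", call. = FALSE)
  if (is.null(edges) || NROW(edges) == 0) {
    ed <- data.frame(a = character(), b = character(),
                     stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2) stop("edges need two columns", call. = FALSE)
    x <- as.character(edges[[1]])
    y <- as.character(edges[[2]])
    a <- ifelse(x <= y, x, y)
    b <- ifelse(x <= y, y, x)
    keep <- !duplicated(paste(a, b, sep = "\r"))
    ed <- data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
  }
  nodes <- unique(c(nodes, ed$a, ed$b))
  structure(list(nodes = nodes, edges = ed), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  ns <- sum(x$edges$a == x$edges$b)
  cat("Interactome:", length(x$nodes), "proteins,",
      nrow(x$edges), "interactions", sprintf("(%d self-pairs)\n", ns))
  invisible(x)
}

#' Number of self-pairs in an interactome or network
#' @param x An `interactome` or `protein_drug_network`.
#' @return Integer count of self-referencing edges.
#' @export
n_self_pairs <- function(x) {
  ed <- edge_frame(x)
  sum(ed$a == ed$b)
}

# Normalized (a, b) edge frame for any graph-like object in the package.
edge_frame <- function(x) {
  if (inherits(x, "interactome")) return(x$edges)
  if (inherits(x, "protein_drug_network")) {
    return(data.frame(a = x$edges$from, b = x$edges$to,
                      stringsAsFactors = FALSE))
  }
  stop("not a graph object", call. = FALSE)
}

node_ids <- function(x) {
  if (inherits(x, "interactome")) return(x$nodes)
  if (inherits(x, "protein_drug_network")) return(x$nodes$id)
  stop("not a graph object", call. = FALSE)
}

#' Convert to an igraph graph
#'
#' @param x An `interactome` or `protein_drug_network`.
#' @param drop_self Drop self-referencing edges (default TRUE; distances and
#'   centralities are insensitive to them).
#' @return An undirected `igraph` graph carrying node/edge type attributes
#'   where the source object has them.
#' @export
as_igraph <- function(x, drop_self = TRUE) {
  ed <- edge_frame(x)
  if (drop_self) ed <- ed[ed$a != ed$b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = node_ids(x), stringsAsFactors = FALSE))
  if (inherits(x, "protein_drug_network")) {
    idx <- match(igraph::V(g)$name, x$nodes$id)
    igraph::V(g)$node_type <- x$nodes$type[idx]
    if (drop_self) {
      igraph::E(g)$edge_type <- x$edges$type[x$edges$from != x$edges$to]
    } else {
      igraph::E(g)$edge_type <- x$edges$type
    }
  }
  g
}

#' Test membership of an undirected edge
#'
#' @param x Graph object.
#' @param u,v Node identifiers; order is irrelevant.
#' @return TRUE if the (unordered) edge is present.
#' @export
has_edge <- function(x, u, v) {
  ed <- edge_frame(x)
  a <- min(u, v); b <- max(u, v)
  any(ed$a == a & ed$b == b)
}

#' Read a PPI edge list
#'
#' Reads an undirected binary interactome snapshot: a TSV whose first two
#' columns hold interacting protein accessions. `(A,B)` and `(B,A)` collapse
#' to one edge; `(A,A)` is retained as a self-pair.
#'
#' @param path Path to the TSV file (header required).
#' @return An [interactome()].
#' @export
read_ppi_edges <- function(path) {
  df <- read_tsv_snapshot(path)
  if (ncol(df) < 2) {
    stop("format error in ", path, ": need two accession columns",
         call. = FALSE)
  }
  bad <- which(is.na(df[[1]]) | is.na(df[[2]]) |
                 !nzchar(df[[1]]) | !nzchar(df[[2]]))
  if (length(bad) > 0) {
    stop("format error in ", path, ": row ", bad[1],
         " has fewer than two fields", call. = FALSE)
  }
  interactome(edges = df[, 1:2])
}

#' Write a PPI edge list
#' @param net An [interactome()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_ppi_edges <- function(net, path) {
  df <- data.frame(accession_a = net$edges$a, accession_b = net$edges$b,
                   stringsAsFactors = FALSE)
  write_tsv_snapshot(df, path)
}

# ---- drug-target table -----------------------------------------------------

#' Read a drug-target table
#'
#' Reads a drug to protein-target snapshot (columns `drug_id`, `drug_name`,
#' `target_accession`, `organism`, optional `smiles`, optional `group`).
#' Duplicate (drug, target) rows are collapsed with a warning; row order in
#' the file does not affect the result.
#'
#' @param path Path to the TSV file.
#' @return A list with `drugs` (data.frame: drug_id, name, smiles, group)
#'   and `targets` (a `drug_target_table` data.frame: drug_id, target,
#'   organism).
#' @export
read_drug_targets <- function(path) {
  df <- read_tsv_snapshot(
    path, required = c("drug_id", "drug_name", "target_accession", "organism"))
  if (!"smiles" %in% names(df)) df$smiles <- NA_character_
  if (!"group" %in% names(df)) df$group <- NA_character_
  df$smiles[!nzchar(df$smiles) | is.na(df$smiles)] <- NA_character_
  df$group[!nzchar(df$group) | is.na(df$group)] <- NA_character_
  df <- df[order(df$drug_id, df$target_accession), , drop = FALSE]

  dup <- duplicated(df[, c("drug_id", "target_accession")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (drug, target) row(s) dropped; first kept",
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  drugs <- df[!duplicated(df$drug_id),
              c("drug_id", "drug_name", "smiles", "group")]
  names(drugs)[2] <- "name"
  rownames(drugs) <- NULL
  targets <- df[, c("drug_id", "target_accession", "organism")]
  names(targets)[2] <- "target"
  rownames(targets) <- NULL
  class(targets) <- c("drug_target_table", "data.frame")
  list(drugs = drugs, targets = targets)
}

#' Write a drug-target table
#' @param drugs Drug records data.frame (drug_id, name, smiles, group).
#' @param targets `drug_target_table` (drug_id, target, organism).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_drug_targets <- function(drugs, targets, path) {
  m <- match(targets$drug_id, drugs$drug_id)
  df <- data.frame(drug_id = targets$drug_id,
                   drug_name = drugs$name[m],
                   target_accession = targets$target,
                   organism = targets$organism,
                   smiles = ifelse(is.na(drugs$smiles[m]), "",
                                   drugs$smiles[m]),
                   group = ifelse(is.na(drugs$group[m]), "", drugs$group[m]),
                   stringsAsFactors = FALSE)
  write_tsv_snapshot(df, path)
}

#' Restrict a drug-target table to one organism
#'
#' Only rows for the configured organism enter human-network construction;
#' e.g. a viral protease target row is excluded from a human-network build.
#'
#' @param targets A `drug_target_table`.
#' @param organism Organism label to keep (default "HUMAN").
#' @return The filtered table.
#' @export
filter_organism <- function(targets, organism = "HUMAN") {
  out <- targets[targets$organism == organism, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("drug_target_table", "data.frame")
  out
}

# ---- annotations -----------------------------------------------------------

#' Construct an annotation table
#'
#' @param protein_terms Named list: protein/gene id -> character vector of
#'   annotation term ids (deduplicated on construction).
#' @param term_names Named character vector: term id -> label. Every term
#'   used in `protein_terms` must have a label.
#' @return An object of class `annotation_table` with `protein_terms`,
#'   `term_proteins` (the inverted index) and `term_names`.
#' @export
annotation_table <- function(protein_terms, term_names) {
  protein_terms <- lapply(protein_terms, function(v) unique(as.character(v)))
  used <- unique(unlist(protein_terms, use.names = FALSE))
  unlabeled <- setdiff(used, names(term_names))
  if (length(unlabeled) > 0) {
    stop("annotation term(s) without a label: ",
         paste(utils::head(unlabeled, 5), collapse = ", "), call. = FALSE)
  }
  prot <- rep(names(protein_terms), lengths(protein_terms))
  term <- unlist(protein_terms, use.names = FALSE)
  term_proteins <- split(prot, term)
  structure(list(protein_terms = protein_terms,
                 term_proteins = term_proteins,
                 term_names = term_names),
            class = "annotation_table")
}

#' Read a protein-to-term annotation table
#'
#' TSV columns: `protein`, `term`, `term_name`.
#'
#' @param path Path to the TSV file.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path) {
  df <- read_tsv_snapshot(path, required = c("protein", "term", "term_name"))
  term_names <- df$term_name[!duplicated(df$term)]
  names(term_names) <- df$term[!duplicated(df$term)]
  annotation_table(split(df$term, df$protein), term_names)
}

#' Write an annotation table
#' @param ann An [annotation_table()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(ann, path) {
  prot <- rep(names(ann$protein_terms), lengths(ann$protein_terms))
  term <- unlist(ann$protein_terms, use.names = FALSE)
  df <- data.frame(protein = prot, term = term,
                   term_name = unname(ann$term_names[term]),
                   stringsAsFactors = FALSE)
  write_tsv_snapshot(df, path)
}

# ---- diseases --------------------------------------------------------------

#' Read a gene-disease association table
#'
#' TSV columns: `gene`, `disease`, `score` with scores in [0, 1] and unique
#' (gene, disease) pairs.
#'
#' @param path Path to the TSV file.
#' @return A `disease_table` data.frame (gene, disease, score).
#' @export
read_diseases <- function(path) {
  df <- read_tsv_snapshot(path, required = c("gene", "disease", "score"))
  df$score <- as.numeric(df$score)
  disease_table(df)
}

#' Construct a disease table
#' @param df Data.frame with columns gene, disease, score.
#' @return A validated `disease_table`.
#' @export
disease_table <- function(df) {
  stopifnot(all(c("gene", "disease", "score") %in% names(df)))
  if (any(is.na(df$score) | df$score < 0 | df$score > 1)) {
    stop("disease scores must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(df[, c("gene", "disease")])) {
    stop("duplicate (gene, disease) pair", call. = FALSE)
  }
  df <- df[, c("gene", "disease", "score")]
  rownames(df) <- NULL
  class(df) <- c("disease_table", "data.frame")
  df
}

#' Write a disease table
#' @param dt A `disease_table`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_diseases <- function(dt, path) {
  write_tsv_snapshot(as.data.frame(dt), path)
}

# ---- proteoforms -----------------------------------------------------------

#' Construct a proteoform table
#'
#' Proteoforms arise from post-translational modifications, allelic gene
#' variants, and alternative splicing; the table records per-protein PTM
#' events (one of the 11 categories in [ptm_categories]) plus allelic-variant
#' and splice-transcript counts.
#'
#' @param ptm Data.frame with columns protein, category, description.
#' @param counts Data.frame with columns protein, allelic_variants,
#'   splice_transcripts (non-negative integers).
#' @return An object of class `proteoform_table`.
#' @export
proteoform_table <- function(ptm, counts) {
  bad <- setdiff(unique(ptm$category), ptm_categories)
  if (length(bad) > 0) {
    stop("unknown PTM category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts$allelic_variants <- as.integer(counts$allelic_variants)
  counts$splice_transcripts <- as.integer(counts$splice_transcripts)
  if (any(is.na(counts$allelic_variants)) ||
      any(is.na(counts$splice_transcripts)) ||
      any(counts$allelic_variants < 0) ||
      any(counts$splice_transcripts < 0)) {
    stop("allelic/splice counts must be non-negative integers",
         call. = FALSE)
  }
  if (anyDuplicated(counts$protein)) {
    stop("duplicate protein in proteoform counts", call. = FALSE)
  }
  structure(list(ptm = ptm, counts = counts), class = "proteoform_table")
}

#' Read a proteoform event table
#'
#' TSV columns: `protein`, `event_type`, `detail`, `description`.
#' `event_type` is `ptm` (with `detail` = category), `allelic_variants` or
#' `splice_transcripts` (with `detail` = integer count).
#'
#' @param path Path to the TSV file.
#' @return A [proteoform_table()].
#' @export
read_proteoforms <- function(path) {
  df <- read_tsv_snapshot(
    path, required = c("protein", "event_type", "detail"))
  if (!"description" %in% names(df)) df$description <- ""
  bad_type <- setdiff(unique(df$event_type),
                      c("ptm", "allelic_variants", "splice_transcripts"))
  if (length(bad_type) > 0) {
    stop("unknown event_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  ptm <- df[df$event_type == "ptm",
            c("protein", "detail", "description")]
  names(ptm) <- c("protein", "category", "description")
  rownames(ptm) <- NULL
  prots <- unique(df$protein)
  counts <- data.frame(protein = prots, allelic_variants = 0L,
                       splice_transcripts = 0L, stringsAsFactors = FALSE)
  for (ev in c("allelic_variants", "splice_transcripts")) {
    sub <- df[df$event_type == ev, ]
    counts[[ev]][match(sub$protein, counts$protein)] <-
      as.integer(sub$detail)
  }
  proteoform_table(ptm, counts)
}

#' Write a proteoform table
#' @param pf A [proteoform_table()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_proteoforms <- function(pf, path) {
  rows <- list(
    data.frame(protein = pf$ptm$protein, event_type = "ptm",
               detail = pf$ptm$category,
               description = pf$ptm$description, stringsAsFactors = FALSE),
    data.frame(protein = pf$counts$protein, event_type = "allelic_variants",
               detail = as.character(pf$counts$allelic_variants),
               description = "", stringsAsFactors = FALSE),
    data.frame(protein = pf$counts$protein, event_type = "splice_transcripts",
               detail = as.character(pf$counts$splice_transcripts),
               description = "", stringsAsFactors = FALSE))
  write_tsv_snapshot(do.call(rbind, rows), path)
}

# ---- network export --------------------------------------------------------

#' Write a protein-drug network to SIF or GraphML
#'
#' SIF rows are `source<TAB>relation<TAB>target` with relation `binds`
#' (drug to protein, drug written first) or `ppi` (protein to protein).
#' GraphML (written through igraph) additionally carries the node type and
#' drug group as attributes, and represents target self-pairs as
#' self-referencing edge elements.
#'
#' @param net A `protein_drug_network`.
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @return The path, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "graphml")) {
  format <- tolower(format[1])
  if (!format %in% c("sif", "graphml")) {
    stop("unknown network format: ", format, call. = FALSE)
  }
  if (format == "sif") {
    ed <- net$edges
    drug_types <- c("focal_drug", "drug_group", "other_drug")
    from_is_drug <- net$nodes$type[match(ed$from, net$nodes$id)] %in% drug_types
    src <- ifelse(ed$type == "binds" & !from_is_drug, ed$to, ed$from)
    dst <- ifelse(ed$type == "binds" & !from_is_drug, ed$from, ed$to)
    lines <- paste(src, ed$type, dst, sep = "\t")
    # isolated nodes: single-field SIF rows keep them in the file
    iso <- setdiff(net$nodes$id, c(ed$from, ed$to))
    writeLines(c(lines, iso), path)
  } else {
    g <- as_igraph(net, drop_self = FALSE)
    idx <- match(igraph::V(g)$name, net$nodes$id)
    igraph::V(g)$node_type <- net$nodes$type[idx]
    grp <- net$nodes$group[idx]
    igraph::V(g)$drug_group <- ifelse(is.na(grp), "", grp)
    igraph::E(g)$edge_type <- net$edges$type
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a protein-drug network written by [write_network()]
#'
#' @param path Input path.
#' @param format `"sif"` or `"graphml"`.
#' @return A `protein_drug_network`. GraphML restores node types and drug
#'   groups exactly; SIF restores the node/edge structure with coarse types
#'   (binds-edge sources become `focal_drug`, proteins become `target`).
#' @export
read_network <- function(path, format = c("sif", "graphml")) {
  format <- tolower(format[1])
  if (!format %in% c("sif", "graphml")) {
    stop("unknown network format: ", format, call. = FALSE)
  }
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    len <- lengths(parts)
    ed <- do.call(rbind, lapply(parts[len == 3], function(p) {
      data.frame(from = p[1], type = p[2], to = p[3],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(ed)) {
      ed <- data.frame(from = character(), type = character(),
                       to = character(), stringsAsFactors = FALSE)
    }
    iso <- unlist(parts[len == 1])
    drugs <- unique(ed$from[ed$type == "binds"])
    prots <- setdiff(unique(c(ed$from[ed$type == "ppi"],
                              ed$to[ed$type == "ppi"],
                              ed$to[ed$type == "binds"])), drugs)
    nodes <- data.frame(
      id = c(drugs, prots, setdiff(iso, c(drugs, prots))),
      type = c(rep("focal_drug", length(drugs)),
               rep("target", length(prots) +
                     length(setdiff(iso, c(drugs, prots))))),
      group = NA_character_, stringsAsFactors = FALSE)
    protein_drug_network(nodes,
                         ed[, c("from", "to", "type")],
                         provenance = paste0("sif:", path))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    grp <- igraph::V(g)$drug_group
    nodes <- data.frame(id = igraph::V(g)$name,
                        type = igraph::V(g)$node_type,
                        group = ifelse(nzchar(grp), grp, NA_character_),
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    ed <- data.frame(from = el[, 1], to = el[, 2],
                     type = igraph::E(g)$edge_type, stringsAsFactors = FALSE)
    protein_drug_network(nodes, ed, provenance = paste0("graphml:", path))
  }
}
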