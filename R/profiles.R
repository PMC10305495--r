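# Proteoform tallies and gene-disease association ranking for targets and
# their first neighbors.

# round-half-up at `digits` decimals (the two-decimal percentage style)
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Total proteoform events for a protein
#'
#' Experimentally supported proteoform events arise from three sources:
#' post-translational modifications, allelic gene variants, and alternative
#' splicing. The total is their sum.
#'
#' @param pf A [proteoform_table()].
#' @param protein Protein accession; must appear in the table.
#' @return Integer event count.
#' @export
proteoform_count <- function(pf, protein) {
  known <- union(pf$ptm$protein, pf$counts$protein)
  if (!protein %in% known) {
    stop("protein not in proteoform table: ", protein, call. = FALSE)
  }
  n_ptm <- sum(pf$ptm$protein == protein)
  i <- match(protein, pf$counts$protein)
  extra <- if (is.na(i)) 0L else
    pf$counts$allelic_variants[i] + pf$counts$splice_transcripts[i]
  as.integer(n_ptm + extra)
}

#' PTM category breakdown over a protein set
#'
#' Pools the PTM events of the listed proteins and reports per-category
#' counts and percentages of the total (rounded half-up to 2 decimals), the
#' numbers behind a category pie/bar chart of a target set's modifications.
#'
#' @param pf A [proteoform_table()].
#' @param proteins Non-empty character vector of accessions.
#' @return Data.frame of class `ptm_breakdown` (category, count, percent),
#'   sorted by decreasing count then category, with attribute
#'   `total_events`.
#' @export
ptm_breakdown <- function(pf, proteins) {
  if (length(proteins) == 0) stop("empty protein set", call. = FALSE)
  ev <- pf$ptm[pf$ptm$protein %in% proteins, , drop = FALSE]
  total <- nrow(ev)
  if (total == 0) {
    stop("no PTM events among the supplied proteins; breakdown undefined",
         call. = FALSE)
  }
  tab <- table(factor(ev$category, levels = ptm_categories))
  tab <- tab[tab > 0]
  out <- data.frame(category = names(tab), count = as.integer(tab),
                    percent = round_half_up(100 * as.integer(tab) / total),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$category), ]
  rownames(out) <- NULL
  attr(out, "total_events") <- total
  class(out) <- c("ptm_breakdown", "data.frame")
  out
}

#' Top disease associations for a gene set
#'
#' Ranks diseases by their aggregated gene-disease association score over
#' the queried genes (default aggregation: maximum score, so one strong
#' association surfaces; `"mean"` averages over supporting genes). Ties are
#' broken by disease label.
#'
#' @param dt A `disease_table` (see [read_diseases()]).
#' @param genes Character vector of gene ids.
#' @param k Number of diseases to return (>= 1).
#' @param aggregate `"max"` (default) or `"mean"`.
#' @return Data.frame of class `disease_ranking`: disease, score, genes
#'   (comma-separated supporting genes), at most k rows, descending score.
#' @export
top_diseases <- function(dt, genes, k = 10, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  sub <- dt[dt$gene %in% genes, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("none of the queried genes appear in the disease table",
            call. = FALSE)
    out <- data.frame(disease = character(), score = numeric(),
                      genes = character(), stringsAsFactors = FALSE)
    class(out) <- c("disease_ranking", "data.frame")
    return(out)
  }
  agg_fun <- switch(aggregate, max = max, mean = mean)
  score <- tapply(sub$score, sub$disease, agg_fun)
  supp <- tapply(sub$gene, sub$disease,
                 function(g) paste(sort(unique(g)), collapse = ","))
  out <- data.frame(disease = names(score), score = as.numeric(score),
                    genes = as.character(supp[names(score)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$disease), , drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  class(out) <- c("disease_ranking", "data.frame")
  out
}
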