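# Term-for-term over-representation statistics: each annotation term is
# tested individually for excess membership in a study set versus a
# background, via the hypergeometric upper tail (equivalently the one-sided
# Fisher exact test), with Benjamini-Hochberg FDR across the tested terms.

check_margins <- function(k, n, K, N) {
  v <- c(k, n, K, N)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
    stop("k, n, K, N must be non-negative integers", call. = FALSE)
  }
  if (k > n || k > K || K > N || n > N) {
    stop("invalid margins: need k <= n, k <= K, K <= N, n <= N",
         call. = FALSE)
  }
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) for X ~ Hypergeometric(N, K, n): the
#' chance that a random study set of size n drawn from a background of N
#' genes (K of them carrying the term) contains at least the observed k
#' carriers. Evaluated through the numerically stable upper-tail routine.
#'
#' @param k Study hits.
#' @param n Study size.
#' @param K Background hits.
#' @param N Background size.
#' @return p-value in (0, 1].
#' @export
hypergeom_overrep <- function(k, n, K, N) {
  check_margins(k, n, K, N)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-sided Fisher exact test (greater)
#'
#' Exact p-value for over-representation from the 2x2 table
#' (k, n-k; K-k, N-n-K+k); mathematically identical to
#' [hypergeom_overrep()] on the same margins but computed through the
#' exact-test route.
#'
#' @inheritParams hypergeom_overrep
#' @return p-value in (0, 1].
#' @export
fisher_exact_greater <- function(k, n, K, N) {
  check_margins(k, n, K, N)
  tab <- matrix(c(k, K - k, n - k, N - n - (K - k)), nrow = 2)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: q_(i) = min over j >= i of m * p_(j) / j,
#' capped at 1, returned in the input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Fold enrichment
#'
#' Ratio of the study hit rate to the background hit rate,
#' (k/n) / (K/N). Values strictly above 100 are conventionally rendered as
#' ">100" in reports (see [format_fold()]).
#'
#' @inheritParams hypergeom_overrep
#' @return Numeric fold enrichment.
#' @export
fold_enrichment <- function(k, n, K, N) {
  check_margins(k, n, K, N)
  if (n == 0 || K == 0) {
    stop("fold enrichment undefined for zero study size or zero background hits",
         call. = FALSE)
  }
  (k / n) / (K / N)
}

#' Render a fold enrichment for reports
#' @param fold Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Character vector; values strictly above 100 become ">100".
#' @export
format_fold <- function(fold, digits = 2) {
  ifelse(fold > 100, ">100", formatC(fold, format = "f", digits = digits))
}

#' Term-for-term over-representation analysis
#'
#' Tests every annotation term with at least one background carrier for
#' over-representation in the study set: p by the hypergeometric upper tail,
#' q by Benjamini-Hochberg over all tested terms (one family per run).
#' Annotations are used as given (no ontology-graph propagation). The
#' background defaults to every gene supplied, annotated or not; set
#' `annotated_only = TRUE` to restrict it to annotated genes.
#'
#' @param study Character vector of study gene/protein ids; must be a
#'   subset of the background.
#' @param annotation An [annotation_table()].
#' @param background Character vector of background ids.
#' @param alpha FDR threshold for flagging displayed terms (default 0.05).
#' @param annotated_only Restrict the background (and study) to annotated
#'   genes.
#' @return Data.frame of class `enrichment_result`, one row per tested
#'   term, sorted by (p, term): term, label, k, n, K, N, fold_enrichment,
#'   p, q, displayed.
#' @export
enrich <- function(study, annotation, background, alpha = 0.05,
                   annotated_only = FALSE) {
  study <- unique(as.character(study))
  background <- unique(as.character(background))
  if (length(study) == 0) stop("empty study set", call. = FALSE)
  out_of_bg <- setdiff(study, background)
  if (length(out_of_bg) > 0) {
    stop("study genes missing from background: ",
         paste(utils::head(out_of_bg, 5), collapse = ", "), call. = FALSE)
  }
  if (annotated_only) {
    annotated <- names(annotation$protein_terms)
    background <- intersect(background, annotated)
    study <- intersect(study, annotated)
    if (length(study) == 0) stop("empty annotated study set", call. = FALSE)
  }
  n <- length(study)
  N <- length(background)

  term_ids <- sort(names(annotation$term_proteins))
  rows <- lapply(term_ids, function(tm) {
    members <- annotation$term_proteins[[tm]]
    K <- length(intersect(members, background))
    if (K == 0) return(NULL)
    k <- length(intersect(members, study))
    data.frame(term = tm,
               label = unname(annotation$term_names[tm]),
               k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N),
               p = hypergeom_overrep(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    res <- data.frame(term = character(), label = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold_enrichment = numeric(),
                      p = numeric(), q = numeric(), displayed = logical(),
                      stringsAsFactors = FALSE)
    class(res) <- c("enrichment_result", "data.frame")
    return(res)
  }
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$p, res$q, res$term), , drop = FALSE]
  res$displayed <- res$q < alpha
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
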