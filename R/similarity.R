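# Neighborhood and structural similarity.
#
# Drug networks are compared through the Jaccard index of their
# first-neighbor protein sets; drug structures through the Tanimoto
# coefficient on path-based molecular fingerprints. The two coefficients
# are the same set statistic: |A intersect B| / |A union B|.

#' Jaccard index and distance from contingency counts
#'
#' From the shared-neighbor count M11 and the counts unique to each side
#' (M10, M01): J = M11 / (M11 + M10 + M01), dJ = 1 - J.
#'
#' @param m11 Shared count.
#' @param m10 Count unique to side A.
#' @param m01 Count unique to side B.
#' @return List with `j` and `dj`.
#' @export
jaccard_from_counts <- function(m11, m10, m01) {
  counts <- c(m11, m10, m01)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  denom <- m11 + m10 + m01
  if (denom == 0) {
    stop("similarity undefined: all counts are zero (empty union)",
         call. = FALSE)
  }
  j <- m11 / denom
  list(j = j, dj = 1 - j)
}

#' Compare two first-neighbor sets
#'
#' Builds the shared/unique contingency counts of two protein sets and
#' their Jaccard index, the similarity used as a proxy of the probability
#' that two drug neighborhoods overlap functionally.
#'
#' @param neighbors_a,neighbors_b Character vectors of protein accessions.
#' @param label_a,label_b Labels for the two sides (e.g. drug or drug-group
#'   names).
#' @param zero_if_empty With both sets empty, report J = 0 instead of
#'   signalling an undefined similarity.
#' @return One-row data.frame of class `neighbor_comparison`: label_a,
#'   label_b, m11, m10, m01, j, dj.
#' @export
neighbor_jaccard <- function(neighbors_a, neighbors_b,
                             label_a = "A", label_b = "B",
                             zero_if_empty = FALSE) {
  a <- unique(as.character(neighbors_a))
  b <- unique(as.character(neighbors_b))
  m11 <- length(intersect(a, b))
  m10 <- length(setdiff(a, b))
  m01 <- length(setdiff(b, a))
  if (m11 + m10 + m01 == 0) {
    if (!zero_if_empty) {
      stop("similarity undefined: both neighbor sets are empty",
           call. = FALSE)
    }
    j <- 0
  } else {
    j <- jaccard_from_counts(m11, m10, m01)$j
  }
  out <- data.frame(label_a = label_a, label_b = label_b,
                    m11 = m11, m10 = m10, m01 = m01,
                    j = j, dj = 1 - j, stringsAsFactors = FALSE)
  class(out) <- c("neighbor_comparison", "data.frame")
  out
}

#' The printed neighbor-comparison counts fixture
#'
#' Six published comparisons of drug-network first-neighbor sets
#' (shared/unique counts with their Jaccard index and distance), shipped as
#' a TSV fixture for regression checks and for `compare_counts`-style runs.
#'
#' @return Data.frame: label_a, label_b, m11, m10, m01, j, dj.
#' @export
neighbor_counts_fixture <- function() {
  path <- system.file("extdata", "table3_counts.tsv", package = "dtnet")
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  df
}

# ---- fingerprints ----------------------------------------------------------

# Deterministic 31-ary polynomial string hash into [0, 2^31 - 2].
hash_feature <- function(s) {
  vapply(s, function(x) {
    h <- 0
    for (c in utf8ToInt(x)) h <- (h * 31 + c) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Path-based molecular fingerprint from a SMILES string
#'
#' Parses the SMILES (through ChemmineR/Open Babel), then enumerates every
#' linear (non-self-intersecting) atom-bond path of 1 to `max_path` bonds
#' plus the single-atom features, canonicalizes each path string
#' (lexicographically smaller reading direction) and hashes it to an
#' integer feature id. The same SMILES always yields the same bit set.
#'
#' @param smiles SMILES string of the molecule.
#' @param scheme Fingerprint scheme; only `"path_based"` is defined.
#' @param max_path Maximum path length in bonds (default 7).
#' @return Object of class `fingerprint`: list with `bits` (sorted integer
#'   feature ids), `scheme`, `molecule` (the input SMILES).
#' @export
fingerprint <- function(smiles, scheme = "path_based", max_path = 7) {
  if (scheme != "path_based") {
    stop("unknown fingerprint scheme: ", scheme, call. = FALSE)
  }
  mol <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL)
  atoms <- if (is.null(mol)) NULL else
    tryCatch(ChemmineR::atomblock(mol[[1]]), error = function(e) NULL)
  if (is.null(atoms) || nrow(atoms) == 0) {
    stop("unparsable SMILES: ", smiles, call. = FALSE)
  }
  symbols <- sub("_[0-9]+$", "", rownames(atoms))
  bonds <- tryCatch(ChemmineR::bondblock(mol[[1]]), error = function(e) NULL)
  if (is.null(bonds) || ncol(bonds) < 3 ||
      !all(grepl("^[A-Za-z]", symbols))) {
    # single-atom molecules trip the SDF container parse; recover the atom
    # and bond blocks from the V2000 text itself
    v2000 <- strsplit(ChemmineOB::convertFormat("SMI", "SDF", smiles),
                      "\n", fixed = TRUE)[[1]]
    counts <- strsplit(trimws(v2000[4]), "\\s+")[[1]]
    n_at <- as.integer(counts[1]); n_bd <- as.integer(counts[2])
    if (is.na(n_at) || n_at == 0) {
      stop("unparsable SMILES: ", smiles, call. = FALSE)
    }
    at_lines <- v2000[4 + seq_len(n_at)]
    symbols <- vapply(strsplit(trimws(at_lines), "\\s+"),
                      function(f) f[4], character(1))
    bonds <- if (n_bd > 0) {
      do.call(rbind, lapply(strsplit(trimws(v2000[4 + n_at + seq_len(n_bd)]),
                                     "\\s+"),
                            function(f) as.integer(f[1:3])))
    } else {
      matrix(integer(0), ncol = 3)
    }
  }

  paths <- character(0)
  adj <- vector("list", length(symbols))
  bond_order <- list()
  if (!is.null(bonds) && nrow(bonds) > 0) {
    for (i in seq_len(nrow(bonds))) {
      u <- bonds[i, 1]; v <- bonds[i, 2]; o <- bonds[i, 3]
      adj[[u]] <- c(adj[[u]], v)
      adj[[v]] <- c(adj[[v]], u)
      bond_order[[paste(min(u, v), max(u, v))]] <- o
    }
  }
  path_string <- function(p) {
    parts <- symbols[p[1]]
    for (i in seq_along(p)[-1]) {
      o <- bond_order[[paste(min(p[i - 1], p[i]), max(p[i - 1], p[i]))]]
      parts <- c(parts, o, symbols[p[i]])
    }
    fwd <- paste(parts, collapse = "-")
    rev_ <- paste(rev(parts), collapse = "-")
    if (fwd <= rev_) fwd else rev_
  }
  walk <- function(p) {
    if (length(p) > 1) paths[[length(paths) + 1]] <<- path_string(p)
    if (length(p) > max_path) return(invisible())
    for (nxt in adj[[p[length(p)]]]) {
      if (!nxt %in% p) walk(c(p, nxt))
    }
    invisible()
  }
  paths <- as.list(symbols)  # single-atom features
  for (s in seq_along(symbols)) walk(s)
  bits <- sort(unique(hash_feature(unique(unlist(paths)))))
  structure(list(bits = bits, scheme = scheme, molecule = smiles),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("Fingerprint (", x$scheme, "): ", length(x$bits), " features for ",
      x$molecule, "\n", sep = "")
  invisible(x)
}

#' Tanimoto coefficient of two fingerprints
#'
#' |A intersect B| / |A union B| over the feature-id sets; 1 means the two
#' molecules share every enumerated structural feature. Fingerprints must
#' come from the same scheme.
#'
#' @param fa,fb [fingerprint()] objects.
#' @return Numeric in [0, 1].
#' @export
tanimoto <- function(fa, fb) {
  if (!inherits(fa, "fingerprint") || !inherits(fb, "fingerprint")) {
    stop("tanimoto() expects fingerprint objects", call. = FALSE)
  }
  if (fa$scheme != fb$scheme) {
    stop("fingerprint scheme mismatch: ", fa$scheme, " vs ", fb$scheme,
         call. = FALSE)
  }
  u <- length(union(fa$bits, fb$bits))
  if (u == 0) {
    stop("similarity undefined: both fingerprints are empty", call. = FALSE)
  }
  length(intersect(fa$bits, fb$bits)) / u
}
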