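# Exhaustive brute-force oracles, independent of the package's igraph-based
# implementations: shortest paths by DFS enumeration of all simple paths,
# hypergeometric tails by enumeration of all draws.

# adjacency list (self loops dropped) from a two-column character edge frame
bf_adjacency <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (a == b) next
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

# all simple paths between two nodes, as lists of node names
bf_simple_paths <- function(adj, s, t) {
  paths <- list()
  walk <- function(p) {
    v <- p[length(p)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- p
      return(invisible())
    }
    for (w in adj[[v]]) if (!w %in% p) walk(c(p, w))
  }
  walk(s)
  paths
}

# distance matrix + unnormalized pair-count betweenness by full enumeration
bf_graph_oracle <- function(nodes, edges) {
  adj <- bf_adjacency(nodes, edges)
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  btw <- stats::setNames(numeric(n), nodes)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        paths <- bf_simple_paths(adj, nodes[i], nodes[j])
        if (length(paths) == 0) next
        lens <- lengths(paths)
        d[i, j] <- d[j, i] <- min(lens) - 1
        shortest <- paths[lens == min(lens)]
        sigma <- length(shortest)
        for (p in shortest) {
          interior <- p[-c(1, length(p))]
          btw[interior] <- btw[interior] + 1 / sigma
        }
      }
    }
  }
  list(dist = d, betweenness = btw)
}

bf_closeness <- function(dist) {
  n <- nrow(dist)
  if (n == 1) return(stats::setNames(0, rownames(dist)))
  out <- numeric(n)
  for (i in seq_len(n)) {
    dv <- dist[i, -i]
    dv <- dv[is.finite(dv)]
    out[i] <- if (length(dv) == 0) 0 else
      (length(dv) / sum(dv)) * (length(dv) / (n - 1))
  }
  stats::setNames(out, rownames(dist))
}

bf_diameter_radius <- function(dist) {
  # components by finite-distance closure; measure on the largest one
  n <- nrow(dist)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[is.finite(dist[i, ])] <- cid
    }
  }
  big <- which(comp == which.max(tabulate(comp)))
  sub <- dist[big, big, drop = FALSE]
  ecc <- apply(sub, 1, max)
  list(diameter = as.integer(max(ecc)), radius = as.integer(min(ecc)),
       component_count = max(comp))
}

# upper-tail hypergeometric probability by enumerating every size-n draw
# from N elements of which the first K carry the term
bf_hypergeom_upper <- function(k, n, K, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(draws <= K, nrow = n))
  mean(hits >= k)
}

# seeded random graph over `n` named nodes
random_graph_edges <- function(n, p_edge = 0.35, p_self = 0.1) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  ed <- t(pairs[, keep, drop = FALSE])
  selfers <- nodes[stats::runif(n) < p_self]
  ed <- rbind(ed, cbind(selfers, selfers))
  list(nodes = nodes,
       edges = data.frame(a = ed[, 1], b = ed[, 2],
                          stringsAsFactors = FALSE))
}
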