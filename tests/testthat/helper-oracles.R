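# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph where the package uses igraph), so
# each check compares two independent routes to the same quantity.

# largest connected component size by hand-rolled BFS over an adjacency
# list of integer vectors; `keep` marks the surviving vertices
bfs_largest_component <- function(adj, keep) {
  seen <- !keep
  best <- 0L
  for (s in seq_along(adj)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      for (u in adj[[v]]) if (!seen[u]) {
        seen[u] <- TRUE
        queue <- c(queue, u)
      }
    }
    best <- max(best, size)
  }
  best
}

# delete-one-node percolation census from an edge matrix (2 columns of
# integer vertex indices, n vertices)
percolation_census <- function(edges, n) {
  adj <- lapply(seq_len(n), function(i) integer())
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  S <- bfs_largest_component(adj, rep(TRUE, n))
  if (S == 1) return(rep(0, n))
  vapply(seq_len(n), function(v) {
    keep <- rep(TRUE, n)
    keep[v] <- FALSE
    adj_v <- lapply(adj, function(x) x[x != v])
    s_minus <- bfs_largest_component(adj_v, keep)
    min(max((S - 1 - s_minus) / (S - 1), 0), 1)
  }, numeric(1))
}

# hypergeometric upper tail by exhaustive enumeration of all query-sized
# subsets of the universe
hyper_enum <- function(universe_size, set_size, query_size, overlap) {
  subsets <- utils::combn(universe_size, query_size)
  in_set <- seq_len(set_size)   # wlog the first set_size elements
  hits <- apply(subsets, 2, function(s) sum(s %in% in_set) >= overlap)
  mean(hits)
}

# log-rank chi-square by the textbook observed-minus-expected loop
logrank_hand <- function(time, event, grp) {
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# small random connected graph with named vertices
random_connected_graph <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::components(g)$no == 1) break
  }
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

# default truth object for survival generators
surv_truth <- function(hr) {
  synthetic_truth("gX", survival_gene = "gX", hazard_ratio = hr)
}
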