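#' Restrict an interactome to a differential-expression signature
#'
#' Induced subgraph on the genes selected by a signature. Nodes left
#' without edges are retained: they can still contribute as neighbours in a
#' later expansion step. An empty intersection yields an empty graph with a
#' warning rather than an error.
#'
#' @param graph igraph object with vertex names.
#' @param signature a `gene_signature` (see [de_signature()]) or a plain
#'   character vector of selected gene identifiers.
#' @return the induced igraph subgraph.
#' @export
subset_by_signature <- function(graph, signature) {
  sel <- if (inherits(signature, "gene_signature"))
    signature$gene_id[signature$selected] else as.character(signature)
  keep <- intersect(igraph::V(graph)$name, sel)
  if (length(keep) == 0)
    warning("signature selects no node of the graph")
  igraph::induced_subgraph(graph, keep)
}

#' Percolation scores and hub calls
#'
#' For each node v the percolation score measures how much deleting v
#' shrinks the graph's largest connected component:
#' `score(v) = (S - 1 - S_-v) / (S - 1)`, where `S` is the size of the
#' largest component and `S_-v` the size of the largest component after
#' removing v. The score is 0 for nodes whose removal is harmless and
#' approaches 1 for nodes that shatter the component; it is clipped to
#' \[0, 1\]. Hubs are the nodes scoring more than two sample standard
#' deviations above the mean score.
#'
#' This disruption reading of "percolation score" is an interpretation: the
#' term is used in the field for related centrality notions; this variant is
#' parameter-free and directly testable against an exhaustive delete-one
#' census (see the methods vignette).
#'
#' @param graph non-empty igraph object with vertex names.
#' @param n_sd hub threshold in standard deviations above the mean
#'   (default 2).
#' @return A `data.frame` of class `hub_report` with columns `node`,
#'   `percolation_score`, `is_hub`; population `mean`, `sd` and `threshold`
#'   are attached as attributes.
#' @export
percolation_scores <- function(graph, n_sd = 2) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph")
  comp <- igraph::components(graph)
  S <- max(comp$csize)
  nodes <- igraph::V(graph)$name
  if (S == 1) {
    score <- rep(0, n)
  } else {
    score <- vapply(seq_len(n), function(i) {
      g2 <- igraph::delete_vertices(graph, i)
      S_minus <- if (igraph::vcount(g2) == 0) 0
                 else max(igraph::components(g2)$csize)
      (S - 1 - S_minus) / (S - 1)
    }, numeric(1))
    score <- pmin(pmax(score, 0), 1)
  }
  mu <- mean(score)
  sdev <- stats::sd(score)
  thr <- mu + n_sd * sdev
  structure(data.frame(node = nodes, percolation_score = score,
                       is_hub = score > thr, stringsAsFactors = FALSE),
            class = c("hub_report", "data.frame"),
            mean = mu, sd = sdev, threshold = thr)
}

#' Expand a hub set to its first neighbours
#'
#' Induced subgraph on the hubs together with all their direct neighbours.
#'
#' @param graph igraph object with vertex names.
#' @param hubs character vector of hub node names (subset of the graph).
#' @return the induced igraph subgraph; an empty hub set yields an empty
#'   graph.
#' @export
expand_to_neighbours <- function(graph, hubs) {
  hubs <- as.character(hubs)
  if (!all(hubs %in% igraph::V(graph)$name))
    stop("hubs must be nodes of the graph")
  if (length(hubs) == 0)
    return(igraph::induced_subgraph(graph, character()))
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(graph, hubs), names)))
  igraph::induced_subgraph(graph, union(hubs, nb))
}

#' Community detection by greedy modularity with local refinement
#'
#' Partitions a network into communities by greedy modularity maximization
#' ([igraph::cluster_fast_greedy()]) followed by a local refinement pass
#' that repeatedly moves single nodes to a neighbouring community while the
#' partition modularity improves. Communities smaller than `min_size` are
#' dropped from the report (the partition modularity is computed before
#' dropping). Isolated nodes take no part in modularity and are excluded.
#'
#' @param graph igraph object with at least one edge.
#' @param min_size smallest community reported (default 5).
#' @param seed integer seed (the procedure is deterministic; the seed fixes
#'   tie-breaking order in the refinement pass).
#' @return An object of class `module_set`: list with `communities` (list
#'   of character vectors), `membership` (named integer vector over
#'   non-isolated nodes) and `modularity`.
#' @export
detect_communities <- function(graph, min_size = 5, seed = 1) {
  if (igraph::ecount(graph) == 0)
    stop("graph has no edges; subset/expand the interactome first")
  deg <- igraph::degree(graph)
  g <- igraph::induced_subgraph(graph, names(deg)[deg > 0])
  fc <- igraph::cluster_fast_greedy(g)
  memb <- igraph::membership(fc)

  # local refinement: single-node moves to adjacent communities
  set.seed(seed)
  adj <- igraph::as_adj_list(g)
  nodes <- seq_len(igraph::vcount(g))
  improved <- TRUE
  passes <- 0
  current_q <- igraph::modularity(g, memb)
  while (improved && passes < 10) {
    improved <- FALSE
    passes <- passes + 1
    for (v in sample(nodes)) {
      neigh_comms <- unique(memb[as.integer(adj[[v]])])
      neigh_comms <- setdiff(neigh_comms, memb[v])
      for (cc in neigh_comms) {
        trial <- memb
        trial[v] <- cc
        q <- igraph::modularity(g, trial)
        if (q > current_q + 1e-12) {
          memb <- trial
          current_q <- q
          improved <- TRUE
          break
        }
      }
    }
  }
  memb <- setNames(as.integer(factor(memb)), igraph::V(g)$name)
  comms <- split(names(memb), memb)
  comms <- comms[vapply(comms, length, integer(1)) >= min_size]
  comms <- unname(comms[order(-vapply(comms, length, integer(1)))])
  structure(list(communities = comms, membership = memb,
                 modularity = current_q),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("module_set:", length(x$communities), "communities (modularity",
      round(x$modularity, 4), ")\n")
  cat("sizes:", paste(vapply(x$communities, length, integer(1)),
                      collapse = ", "), "\n")
  invisible(x)
}
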