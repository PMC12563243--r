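#' Read an undirected weighted gene network from an edge-list TSV
#'
#' The expected format is three tab-separated columns
#' `gene_a<TAB>gene_b<TAB>weight` without a header (a header row is detected
#' and skipped when the third field is not numeric). Self-loops are rejected.
#'
#' @param path Path to the edge-list file.
#' @return An undirected `igraph` graph with a `weight` edge attribute.
#' @export
read_network <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) > 0 && is.na(suppressWarnings(as.numeric(df[1, 3])))) {
    df <- df[-1, , drop = FALSE]
  }
  names(df)[1:3] <- c("gene_a", "gene_b", "weight")
  df$weight <- as.numeric(df$weight)
  graph_from_edge_table(df)
}

#' Build an igraph network from an edge table
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` and optionally
#'   `weight` (defaults to 1).
#' @return An undirected `igraph` graph, simplified, with `weight` attribute.
#' @export
graph_from_edge_table <- function(edges) {
  if (is.null(edges$weight)) edges$weight <- 1
  if (any(edges$gene_a == edges$gene_b)) {
    abort_input("self-loops are not allowed in the gene network")
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "weight")],
    directed = FALSE
  )
  igraph::simplify(g, edge.attr.comb = list(weight = "max"))
}

#' Node centrality profiles for a gene interaction network
#'
#' Computes, for every node: raw degree, degree centrality `deg/(n-1)`,
#' betweenness normalized by `2/((n-1)(n-2))`, closeness with
#' Wasserman-Faust component scaling (so that disconnected graphs remain
#' well defined), and eigenvector centrality computed on the largest
#' connected component (zero elsewhere) rescaled to unit Euclidean norm
#' over the whole graph. Centralities are computed on the unweighted
#' topology; edge weights are interaction confidences, not distances.
#'
#' @param graph An undirected `igraph` graph (no self-loops).
#' @return A data frame with columns `gene`, `degree`, `degree_centrality`,
#'   `betweenness`, `closeness`, `eigenvector`, one row per node, ordered
#'   by gene symbol.
#' @export
compute_centralities <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) abort_input("empty network")
  genes <- igraph::V(graph)$name
  if (is.null(genes)) genes <- as.character(seq_len(n))

  deg <- igraph::degree(graph)
  dc <- if (n > 1) deg / (n - 1) else rep(0, n)

  btw <- if (n > 2) {
    igraph::betweenness(graph, weights = NA, normalized = TRUE)
  } else {
    rep(0, n)
  }

  # Wasserman-Faust closeness: (r/(n-1)) * (r / sum of finite distances),
  # where r is the number of other nodes reachable from i.
  cc <- rep(0, n)
  if (n > 1) {
    d <- igraph::distances(graph, weights = NA)
    for (i in seq_len(n)) {
      di <- d[i, -i]
      reach <- is.finite(di)
      r <- sum(reach)
      if (r > 0) cc[i] <- (r / (n - 1)) * (r / sum(di[reach]))
    }
  }

  ec <- rep(0, n)
  if (n == 1) {
    ec <- 1
  } else {
    comp <- igraph::components(graph)
    big <- which.max(comp$csize)
    idx <- which(comp$membership == big)
    if (length(idx) == 1) {
      ec[idx] <- 1
    } else {
      sub <- igraph::induced_subgraph(graph, idx)
      ev <- igraph::eigen_centrality(sub, weights = NA)$vector
      ec[idx] <- ev[match(genes[idx], names(ev))]
    }
    nrm <- sqrt(sum(ec^2))
    if (nrm > 0) ec <- ec / nrm
  }

  out <- data.frame(
    gene = genes,
    degree = as.integer(deg),
    degree_centrality = as.numeric(dc),
    betweenness = as.numeric(btw),
    closeness = as.numeric(cc),
    eigenvector = as.numeric(ec),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
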