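#' Random-walk-with-restart configuration
#'
#' @param restart_alpha Restart probability in (0, 1); default 0.7.
#' @param tol L1 convergence tolerance; default 1e-6.
#' @param max_iter Iteration cap; default 1000.
#' @param max_subgraph_nodes Node cap used by [subsample_for_rwr()];
#'   default 10000.
#' @return A list of class `rwr_config`.
#' @export
rwr_config <- function(restart_alpha = 0.7, tol = 1e-6, max_iter = 1000,
                       max_subgraph_nodes = 10000) {
  if (restart_alpha <= 0 || restart_alpha >= 1) {
    abort_input("restart_alpha must lie in (0, 1)")
  }
  structure(
    list(restart_alpha = restart_alpha, tol = tol, max_iter = max_iter,
         max_subgraph_nodes = max_subgraph_nodes),
    class = "rwr_config"
  )
}

#' Random walk with restart
#'
#' Iterates `p(t+1) = (1 - alpha) P p(t) + alpha p0` where P is the
#' column-normalized weighted adjacency matrix and p0 is uniform over the
#' seed nodes, until the L1 change falls below the tolerance or the
#' iteration cap is reached. Degree-zero (dangling) columns teleport all
#' their mass back to the restart distribution.
#'
#' @param graph An undirected weighted `igraph` graph.
#' @param seed_nodes Character vector of seed node names (must intersect
#'   the graph's node set).
#' @param cfg An [rwr_config()].
#' @return Named numeric vector of steady-state probabilities summing
#'   to 1.
#' @export
rwr <- function(graph, seed_nodes, cfg = rwr_config()) {
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  seeds <- intersect(seed_nodes, nodes)
  if (length(seeds) == 0) abort_input("empty seed set")

  p0 <- numeric(n)
  p0[match(seeds, nodes)] <- 1 / length(seeds)
  if (n == 1) return(setNames(1, nodes))

  has_w <- "weight" %in% igraph::edge_attr_names(graph)
  adj <- igraph::as_adjacency_matrix(graph, attr = if (has_w) "weight",
                                     sparse = TRUE)
  colsum <- Matrix::colSums(adj)
  dangling <- colsum == 0
  scale <- ifelse(dangling, 0, 1 / pmax(colsum, .Machine$double.eps))
  pmat <- adj %*% Matrix::Diagonal(n, scale)

  alpha <- cfg$restart_alpha
  p <- p0
  for (it in seq_len(cfg$max_iter)) {
    p_new <- as.numeric((1 - alpha) * (pmat %*% p)) +
      ((1 - alpha) * sum(p[dangling]) + alpha) * p0
    if (sum(abs(p_new - p)) < cfg$tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  p <- p / sum(p)
  setNames(as.numeric(p), nodes)
}

#' Target-centred subgraph for large-network propagation
#'
#' Keeps all target nodes and grows breadth-first neighbourhoods around
#' them in increasing hop order, adding whole hops while they fit and
#' filling the remainder lexicographically, until the node cap is
#' reached.
#'
#' @param graph An `igraph` graph.
#' @param target_nodes Character vector of node names to preserve.
#' @param max_nodes Node budget (must be at least the number of targets
#'   present in the graph).
#' @return The induced `igraph` subgraph.
#' @export
subsample_for_rwr <- function(graph, target_nodes, max_nodes = 10000) {
  nodes <- igraph::V(graph)$name
  targets <- intersect(target_nodes, nodes)
  if (length(targets) == 0) abort_input("no target nodes present in graph")
  if (max_nodes < length(targets)) {
    abort_input("max_nodes smaller than the number of target nodes")
  }
  if (igraph::vcount(graph) <= max_nodes) return(graph)

  dists <- igraph::distances(graph, v = targets, weights = NA)
  hop <- apply(dists, 2, min)
  keep <- character(0)
  for (h in sort(unique(hop[is.finite(hop)]))) {
    at_h <- sort(nodes[hop == h])
    room <- max_nodes - length(keep)
    if (room <= 0) break
    keep <- c(keep, head(at_h, room))
  }
  igraph::induced_subgraph(graph, keep)
}

#' Shortest-path proximity of a drug to its target genes
#'
#' Mean shortest-path length from the drug node to each target gene,
#' with unreachable pairs charged a penalty distance equal to the node
#' count of the graph; the proximity score is `1 / (1 + dSP)`.
#'
#' @param graph An `igraph` graph containing the drug node.
#' @param drug Drug name (prefixed internally).
#' @param target_genes Character vector of gene symbols.
#' @return A one-row data frame with `avg_sp_distance` and `proximity`.
#' @export
proximity_scores <- function(graph, drug, target_genes) {
  if (length(target_genes) == 0) abort_input("no target genes supplied")
  nodes <- igraph::V(graph)$name
  dnode <- drug_node(drug)
  if (!dnode %in% nodes) abort_input(sprintf("drug %s not in network", drug))
  gnodes <- gene_node(target_genes)
  penalty <- igraph::vcount(graph)
  present <- gnodes[gnodes %in% nodes]
  d <- rep(penalty, length(gnodes))
  if (length(present) > 0) {
    dd <- igraph::distances(graph, v = dnode, to = present, weights = NA)[1, ]
    dd[!is.finite(dd)] <- penalty
    d[match(present, gnodes)] <- dd
  }
  dsp <- mean(d)
  data.frame(avg_sp_distance = dsp, proximity = 1 / (1 + dsp))
}

#' Direct-interaction score of a drug against a target set
#'
#' Mean over the target genes of the recorded interaction score times an
#' indicator that the interaction exists.
#'
#' @param drug Drug name.
#' @param target_genes Character vector of gene symbols (non-empty).
#' @param interactions Interaction table with `drug`, `gene`, `score`
#'   columns (missing scores already imputed to 0.5 by [build_layers()]).
#' @return Mean interaction evidence over the target set.
#' @export
direct_interaction_score <- function(drug, target_genes, interactions) {
  if (length(target_genes) == 0) abort_input("no target genes supplied")
  drug <- canonical_drug_name(drug)
  if (is.null(interactions$score)) interactions$score <- NA_real_
  interactions$score[is.na(interactions$score)] <- 0.5
  hits <- interactions[canonical_drug_name(interactions$drug) == drug &
                         interactions$gene %in% target_genes, , drop = FALSE]
  sum(hits$score) / length(target_genes)
}

#' Weighted combination of the three network scores
#'
#' @param rwr_score,proximity,direct Nonnegative component scores.
#' @param weights Numeric vector of length 3 summing to 1; default
#'   `c(0.4, 0.3, 0.3)` over (RWR, proximity, direct interaction).
#' @return The combined score.
#' @export
combined_score <- function(rwr_score, proximity, direct,
                           weights = c(0.4, 0.3, 0.3)) {
  if (abs(sum(weights) - 1) > 1e-9) abort_input("weights must sum to 1")
  weights[1] * rwr_score + weights[2] * proximity + weights[3] * direct
}

#' Diffusion proximity of a drug to a target set
#'
#' Random walk with restart at a broader-neighbourhood restart
#' probability of 0.5, seeded at the target genes and read off at the
#' drug node. Reported alongside the combined score but not entering it.
#'
#' @param graph An `igraph` graph.
#' @param drug Drug name.
#' @param target_genes Character vector of gene symbols.
#' @param cfg Base [rwr_config()] (alpha is overridden to 0.5).
#' @return The steady-state probability at the drug node.
#' @export
diffusion_proximity <- function(graph, drug, target_genes,
                                cfg = rwr_config()) {
  cfg$restart_alpha <- 0.5
  nodes <- igraph::V(graph)$name
  gnodes <- intersect(gene_node(target_genes), nodes)
  if (length(gnodes) == 0) abort_input("empty seed set")
  dnode <- drug_node(drug)
  if (!dnode %in% nodes) return(0)
  p <- rwr(graph, gnodes, cfg)
  unname(p[dnode])
}

#' Resistance distance between two nodes
#'
#' Effective resistance computed from the Moore-Penrose pseudoinverse of
#' the graph Laplacian; only offered for graphs of at most 2000 nodes.
#'
#' @param graph A connected `igraph` graph (at most 2000 nodes).
#' @param from,to Node names.
#' @return The effective resistance between the nodes.
#' @export
resistance_distance <- function(graph, from, to) {
  n <- igraph::vcount(graph)
  if (n > 2000) abort_input("resistance distance limited to 2000 nodes")
  if (!requireNamespace("MASS", quietly = TRUE)) {
    abort_input("resistance_distance requires the MASS package")
  }
  lap <- as.matrix(igraph::laplacian_matrix(graph, weights = NA))
  linv <- MASS::ginv(lap)
  nodes <- igraph::V(graph)$name
  i <- match(from, nodes); j <- match(to, nodes)
  if (is.na(i) || is.na(j)) abort_input("node not present in graph")
  linv[i, i] + linv[j, j] - 2 * linv[i, j]
}

#' Score every drug in a layered network against a target gene set
#'
#' Runs one RWR seeded at the target genes on the integrated graph
#' (subsampled when larger than the configured cap), then computes
#' shortest-path proximity, direct-interaction and combined scores per
#' drug, plus the side-channel diffusion proximity.
#'
#' @param layers A [build_layers()] result.
#' @param target_genes Character vector of target gene symbols.
#' @param cfg An [rwr_config()].
#' @param weights Combined-score weights, default `c(0.4, 0.3, 0.3)`.
#' @return Data frame `drug, rwr, avg_sp_distance, proximity, direct,
#'   combined, diffusion`, sorted by combined score (descending, ties by
#'   name).
#' @export
score_drugs <- function(layers, target_genes, cfg = rwr_config(),
                        weights = c(0.4, 0.3, 0.3)) {
  graph <- layers$integrated
  gseeds <- intersect(gene_node(target_genes), igraph::V(graph)$name)
  if (length(gseeds) == 0) abort_input("empty seed set")
  if (igraph::vcount(graph) > cfg$max_subgraph_nodes) {
    graph <- subsample_for_rwr(graph, gseeds, cfg$max_subgraph_nodes)
  }

  p <- rwr(graph, gseeds, cfg)
  p_diff <- rwr(graph, gseeds, {
    cfg2 <- cfg; cfg2$restart_alpha <- 0.5; cfg2
  })

  drugs <- sort(unique(layers$interactions$drug))
  rows <- lapply(drugs, function(d) {
    dnode <- drug_node(d)
    in_graph <- dnode %in% names(p)
    prox <- if (in_graph) {
      proximity_scores(graph, d, target_genes)
    } else {
      data.frame(avg_sp_distance = igraph::vcount(graph), proximity = 0)
    }
    srwr <- if (in_graph) unname(p[dnode]) else 0
    sdi <- direct_interaction_score(d, target_genes, layers$interactions)
    data.frame(
      drug = d,
      rwr = srwr,
      avg_sp_distance = prox$avg_sp_distance,
      proximity = prox$proximity,
      direct = sdi,
      combined = combined_score(srwr, prox$proximity, sdi, weights),
      diffusion = if (in_graph) unname(p_diff[dnode]) else 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$combined, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}
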