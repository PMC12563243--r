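#' Default CNS filter configuration
#'
#' Four complementary retention criteria: CNS-related substrings in the
#' drug name, a curated list of established CNS drugs, interaction with
#' neurologically relevant gene symbols, and (optionally) blanket
#' inclusion of approved drugs.
#'
#' @param name_keywords Character vector of case-insensitive name
#'   substrings.
#' @param curated_cns_drugs Character vector of canonical drug names.
#' @param neuro_gene_keywords Character vector of gene-symbol substrings.
#' @param include_all_approved Retain every approved drug regardless of
#'   other criteria.
#' @return A list of class `cns_filter_config`.
#' @export
cns_filter_config <- function(
    name_keywords = c("NEURO", "BRAIN", "COGNITIVE", "PSYCH",
                      "ANTICONVULSANT", "ANALGESIC", "ANTIPSYCHOTIC",
                      "ANTIDEPRESS", "EPILEP", "PARKINSON", "ALZHEIMER"),
    curated_cns_drugs = c(
      "MEMANTINE", "DONEPEZIL", "RIVASTIGMINE", "GALANTAMINE",
      "FLUOXETINE", "SERTRALINE", "VENLAFAXINE", "DULOXETINE",
      "QUETIAPINE", "RISPERIDONE", "OLANZAPINE", "ARIPIPRAZOLE",
      "LEVETIRACETAM", "TOPIRAMATE", "GABAPENTIN", "PREGABALIN"
    ),
    neuro_gene_keywords = c("GABR", "GRIN", "GRIA", "DRD", "HTR", "CHRN",
                            "CHRM", "APP", "PSEN", "APOE", "SNCA", "LRRK2",
                            "MAOA", "COMT", "SLC6A3", "SLC6A4"),
    include_all_approved = TRUE) {
  structure(
    list(
      name_keywords = toupper(name_keywords),
      curated_cns_drugs = canonical_drug_name(curated_cns_drugs),
      neuro_gene_keywords = toupper(neuro_gene_keywords),
      include_all_approved = isTRUE(include_all_approved)
    ),
    class = "cns_filter_config"
  )
}

#' CNS pre-filter over a drug table
#'
#' A drug is retained when any of the enabled criteria fires: its name
#' contains a CNS keyword, it appears on the curated CNS list, it
#' interacts with a gene matching a neurological gene keyword, or it is
#' approved and approved drugs are blanket-included. Per-drug provenance
#' records which criteria fired; retention and reduction percentages are
#' attached as the `summary` attribute.
#'
#' @param drugs Data frame with columns `name` and logical `approved`.
#' @param interactions Data frame with columns `drug` and `gene`
#'   (canonical names); may have zero rows.
#' @param cfg A [cns_filter_config()].
#' @return The drug table with logical columns `by_name_keyword`,
#'   `by_curated_list`, `by_neuro_target`, `by_approved`, `retained`.
#' @export
cns_filter <- function(drugs, interactions = NULL, cfg = cns_filter_config()) {
  if (is.null(drugs) || nrow(drugs) == 0) abort_input("empty drug list")
  drugs$name <- canonical_drug_name(drugs$name)

  nm <- drugs$name
  kw_pattern <- paste(cfg$name_keywords, collapse = "|")
  by_name <- if (length(cfg$name_keywords) > 0) grepl(kw_pattern, nm) else
    rep(FALSE, length(nm))
  by_list <- nm %in% cfg$curated_cns_drugs

  by_target <- rep(FALSE, length(nm))
  if (!is.null(interactions) && nrow(interactions) > 0 &&
      length(cfg$neuro_gene_keywords) > 0) {
    gene_pattern <- paste(cfg$neuro_gene_keywords, collapse = "|")
    hit_genes <- grepl(gene_pattern, toupper(interactions$gene))
    hit_drugs <- unique(canonical_drug_name(interactions$drug[hit_genes]))
    by_target <- nm %in% hit_drugs
  }
  by_approved <- cfg$include_all_approved & as.logical(drugs$approved)

  drugs$by_name_keyword <- by_name
  drugs$by_curated_list <- by_list
  drugs$by_neuro_target <- by_target
  drugs$by_approved <- by_approved
  drugs$retained <- by_name | by_list | by_target | by_approved

  n_total <- nrow(drugs)
  n_kept <- sum(drugs$retained)
  attr(drugs, "summary") <- list(
    n_total = n_total,
    n_retained = n_kept,
    retention_pct = 100 * n_kept / n_total,
    reduction_pct = 100 * (1 - n_kept / n_total)
  )
  drugs
}

#' Jaccard similarity of two identifier sets
#'
#' @param a,b Character vectors treated as sets.
#' @return `|a intersect b| / |a union b|`; 0 (with a warning) when both
#'   sets are empty.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    warning("Jaccard of two empty sets defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

# Internal node-id helpers: drug and gene nodes share the integrated
# graph's namespace, so they are prefixed by type.
drug_node <- function(x) paste0("drug:", canonical_drug_name(x))
gene_node <- function(x) paste0("gene:", x)

# Internal: pairwise Jaccard layer from a binary incidence matrix.
# Rows are the entities being compared; columns the shared feature space.
.jaccard_layer <- function(inc, threshold, prefix) {
  inter <- methods::as(Matrix::tcrossprod(inc), "TsparseMatrix")
  sizes <- Matrix::rowSums(inc)
  i <- inter@i + 1L
  j <- inter@j + 1L
  x <- inter@x
  keep <- i < j
  i <- i[keep]; j <- j[keep]; x <- x[keep]
  if (length(i) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  w <- as.numeric(x / (sizes[i] + sizes[j] - x))
  idx <- which(w >= threshold)
  if (length(idx) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(
    from = paste0(prefix, rownames(inc)[i[idx]]),
    to = paste0(prefix, rownames(inc)[j[idx]]),
    weight = w[idx],
    stringsAsFactors = FALSE
  )
}

#' Build the three-layer pharmacogenomic network
#'
#' Constructs the drug-gene bipartite layer (edges weighted by
#' interaction scores, missing scores imputed to 0.5), a drug-drug layer
#' connecting drugs whose target-set Jaccard similarity reaches the
#' threshold, a gene-gene layer built the same way over shared
#' interacting-drug sets, and the integrated union of all three. Drug
#' nodes are prefixed `drug:`, gene nodes `gene:`.
#'
#' @param interactions Data frame with columns `drug`, `gene` and
#'   optional `score` (NA or absent imputed to 0.5).
#' @param sim_threshold Jaccard threshold for the similarity layers
#'   (default 0.15, inclusive).
#' @return A list of class `layered_network` with `igraph` elements
#'   `bipartite`, `drug_drug`, `gene_gene`, `integrated`, plus the
#'   cleaned interaction table.
#' @export
build_layers <- function(interactions, sim_threshold = 0.15) {
  if (nrow(interactions) == 0) abort_input("no interactions supplied")
  interactions$drug <- canonical_drug_name(interactions$drug)
  if (is.null(interactions$score)) interactions$score <- NA_real_
  interactions$score[is.na(interactions$score)] <- 0.5
  interactions <- unique(interactions[, c("drug", "gene", "score")])
  interactions <- interactions[order(interactions$drug, interactions$gene), ,
                               drop = FALSE]
  rownames(interactions) <- NULL

  bip_edges <- data.frame(
    from = drug_node(interactions$drug),
    to = gene_node(interactions$gene),
    weight = interactions$score,
    stringsAsFactors = FALSE
  )
  bipartite <- igraph::graph_from_data_frame(bip_edges, directed = FALSE)

  drugs <- sort(unique(interactions$drug))
  genes <- sort(unique(interactions$gene))
  inc <- Matrix::sparseMatrix(
    i = match(interactions$drug, drugs),
    j = match(interactions$gene, genes),
    x = 1,
    dims = c(length(drugs), length(genes)),
    dimnames = list(drugs, genes)
  )
  inc@x[] <- 1

  dd_edges <- .jaccard_layer(inc, sim_threshold, "drug:")
  gg_edges <- .jaccard_layer(Matrix::t(inc), sim_threshold, "gene:")

  drug_drug <- igraph::graph_from_data_frame(
    dd_edges, directed = FALSE,
    vertices = data.frame(name = drug_node(drugs))
  )
  gene_gene <- igraph::graph_from_data_frame(
    gg_edges, directed = FALSE,
    vertices = data.frame(name = gene_node(genes))
  )

  all_edges <- rbind(bip_edges, dd_edges, gg_edges)
  integrated <- igraph::graph_from_data_frame(
    all_edges, directed = FALSE,
    vertices = data.frame(name = c(drug_node(drugs), gene_node(genes)))
  )

  structure(
    list(bipartite = bipartite, drug_drug = drug_drug,
         gene_gene = gene_gene, integrated = integrated,
         interactions = interactions),
    class = "layered_network"
  )
}

#' Topology summary of a network
#'
#' Node and edge counts, undirected density `2E/(N(N-1))`, connected
#' components, average local clustering, global transitivity, and an
#' average shortest-path length estimated over sampled reachable node
#' pairs.
#'
#' @param graph An `igraph` graph.
#' @param sample_pairs Number of node pairs sampled for the path-length
#'   estimate (default 1000; exhaustive when fewer pairs exist).
#' @param seed Integer seed for the pair sampling.
#' @return A one-row data frame of summary statistics.
#' @export
topology_summary <- function(graph, sample_pairs = 1000, seed = 42) {
  n <- igraph::vcount(graph)
  if (n == 0) abort_input("empty network")
  e <- igraph::ecount(graph)
  dens <- if (n > 1) 2 * e / (n * (n - 1)) else 0
  comp <- igraph::components(graph)

  avg_path <- NA_real_
  if (n > 1) {
    set.seed(seed)
    n_pairs <- min(sample_pairs, n * (n - 1) / 2)
    from <- sample.int(n, n_pairs, replace = TRUE)
    to <- sample.int(n, n_pairs, replace = TRUE)
    ok <- from != to
    from <- from[ok]; to <- to[ok]
    us <- sort(unique(from))
    dmat <- igraph::distances(graph, v = us, weights = NA)
    d <- dmat[cbind(match(from, us), to)]
    d <- d[is.finite(d)]
    if (length(d) > 0) avg_path <- mean(d)
  }

  data.frame(
    nodes = n,
    edges = e,
    density = dens,
    n_components = comp$no,
    largest_component = max(comp$csize),
    avg_clustering = igraph::transitivity(graph, type = "localaverage",
                                          isolates = "zero"),
    transitivity = igraph::transitivity(graph, type = "global"),
    sampled_avg_path_length = avg_path
  )
}
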