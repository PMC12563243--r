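#' Database weights used by the pathway centrality index
#'
#' GO Biological Process 1.0, KEGG 0.8, Reactome 0.6, GO Molecular
#' Function 0.4, MSigDB Hallmark 0.3.
#'
#' @return Named numeric vector of database weights.
#' @export
pathway_db_weights <- function() {
  c(GO_BP = 1.0, KEGG = 0.8, Reactome = 0.6, GO_MF = 0.4, Hallmark = 0.3)
}

#' Temporal intervention-stage weights
#'
#' Early intervention 1.0, progression modifier 0.8, neuroprotection 0.9,
#' symptomatic treatment 0.6, uncategorized 0.5.
#'
#' @return Named numeric vector of temporal weights.
#' @export
temporal_weights <- function() {
  c(
    early_intervention = 1.0,
    progression_modifier = 0.8,
    neuroprotection = 0.9,
    symptomatic = 0.6,
    uncategorized = 0.5
  )
}

#' Network plasticity score
#'
#' Quantifies a gene's structural importance as the mean of three
#' components: degree impact `D = DC * BC`, clustering disruption
#' `C = degree * (1 - CC)` (raw degree, not degree centrality), and
#' network influence `N = EC * D`.
#'
#' @param profile Data frame of centrality profiles as produced by
#'   [compute_centralities()].
#' @return The input with columns `degree_impact`, `clustering_disruption`,
#'   `network_influence` and `plasticity` appended.
#' @export
plasticity_score <- function(profile) {
  d_i <- profile$degree_centrality * profile$betweenness
  c_i <- profile$degree * (1 - profile$closeness)
  n_i <- profile$eigenvector * d_i
  profile$degree_impact <- d_i
  profile$clustering_disruption <- c_i
  profile$network_influence <- n_i
  profile$plasticity <- (d_i + c_i + n_i) / 3
  profile
}

#' Pathway centrality index for one gene
#'
#' `PCI = 0.3*PD + 0.4*PS + 0.1*PC + 0.2*WS` where PD is the number of
#' distinct database types, PS the mean -log10 adjusted p-value, PC the
#' number of annotation records, and WS the mean database-weighted
#' -log10 adjusted p-value.
#'
#' @param annotations Data frame with columns `pathway_id`, `db_type`,
#'   `adj_p` for a single gene; zero rows give a zero index with an
#'   `unannotated` flag.
#' @return A one-row data frame with columns `pd`, `ps`, `pc`, `ws`,
#'   `pci`, `unannotated`.
#' @export
pathway_centrality_index <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    return(data.frame(pd = 0, ps = 0, pc = 0, ws = 0, pci = 0,
                      unannotated = TRUE))
  }
  if (any(annotations$adj_p <= 0 | annotations$adj_p > 1)) {
    abort_input("adjusted p-values must lie in (0, 1]")
  }
  w <- pathway_db_weights()
  unknown <- setdiff(unique(annotations$db_type), names(w))
  if (length(unknown) > 0) {
    abort_input(sprintf("unknown pathway database type: %s",
                        paste(unknown, collapse = ", ")))
  }
  nl <- -log10(annotations$adj_p)
  pd <- length(unique(annotations$db_type))
  ps <- mean(nl)
  pc <- nrow(annotations)
  ws <- mean(w[annotations$db_type] * nl)
  data.frame(
    pd = pd, ps = ps, pc = pc, ws = ws,
    pci = 0.3 * pd + 0.4 * ps + 0.1 * pc + 0.2 * ws,
    unannotated = FALSE
  )
}

#' Druggability potential score
#'
#' Base druggability plus fixed bonuses for membrane association (0.2),
#' enzymatic function (0.15), GPCR (0.3), ion channel (0.25) and
#' neurotransmitter-system membership (0.2), capped at 1.0.
#'
#' @param flags Data frame (or one-row list) with logical columns
#'   `is_membrane`, `is_enzyme`, `is_gpcr`, `is_ion_channel`,
#'   `is_neurotransmitter` and numeric `base_druggability` in \[0, 1\].
#' @return Numeric vector of druggability scores in \[0, 1\].
#' @export
druggability_score <- function(flags) {
  check_range(flags$base_druggability, 0, 1, "base_druggability")
  s <- flags$base_druggability +
    0.2 * as.numeric(flags$is_membrane) +
    0.15 * as.numeric(flags$is_enzyme) +
    0.3 * as.numeric(flags$is_gpcr) +
    0.25 * as.numeric(flags$is_ion_channel) +
    0.2 * as.numeric(flags$is_neurotransmitter)
  pmin(1.0, s)
}

#' Disease proximity score
#'
#' `DP = 0.4*DA + 0.3*CP + 0.2*PP + 0.1*FP` with centrality proximity
#' `CP = (DC + BC + EC)/3`, pathway proximity `PP = min(1, overlap/10)`
#' and functional proximity `FP = 0.8 * PP`.
#'
#' @param flags Data frame with numeric `direct_ad_association` in \[0, 1\]
#'   and nonnegative integer `ad_pathway_set_overlap`.
#' @param profile Matching centrality profile rows (same gene order).
#' @return Data frame with columns `cp`, `pp`, `fp`, `disease_proximity`.
#' @export
disease_proximity <- function(flags, profile) {
  check_range(flags$direct_ad_association, 0, 1, "direct_ad_association")
  cp <- (profile$degree_centrality + profile$betweenness +
           profile$eigenvector) / 3
  pp <- pmin(1, flags$ad_pathway_set_overlap / 10)
  fp <- 0.8 * pp
  data.frame(
    cp = cp, pp = pp, fp = fp,
    disease_proximity = 0.4 * flags$direct_ad_association +
      0.3 * cp + 0.2 * pp + 0.1 * fp
  )
}

#' Adaptive integration of the four dimension scores
#'
#' Base weights of 0.25 over (plasticity, pathway centrality,
#' druggability, disease proximity); the druggability weight is
#' multiplied by 1.5 for membrane proteins, the plasticity weight by 1.3
#' when plasticity exceeds 0.5, and the pathway-centrality weight by 1.2
#' when the index exceeds 1.0; weights are renormalized to sum to one.
#'
#' @param plasticity,pci,druggability,disease_prox Numeric vectors of the
#'   four dimension scores (recycled to common length).
#' @param is_membrane Logical vector flagging membrane proteins.
#' @return Data frame with the four weights used (`w_plasticity`, `w_pci`,
#'   `w_druggability`, `w_proximity`) and the integrated score
#'   (`integrated`).
#' @export
adaptive_integrate <- function(plasticity, pci, druggability, disease_prox,
                               is_membrane) {
  n <- max(length(plasticity), length(pci), length(druggability),
           length(disease_prox), length(is_membrane))
  plasticity <- rep_len(plasticity, n)
  pci <- rep_len(pci, n)
  druggability <- rep_len(druggability, n)
  disease_prox <- rep_len(disease_prox, n)
  is_membrane <- rep_len(as.logical(is_membrane), n)

  w1 <- rep(0.25, n) * ifelse(plasticity > 0.5, 1.3, 1)
  w2 <- rep(0.25, n) * ifelse(pci > 1.0, 1.2, 1)
  w3 <- rep(0.25, n) * ifelse(is_membrane, 1.5, 1)
  w4 <- rep(0.25, n)
  tot <- w1 + w2 + w3 + w4
  w1 <- w1 / tot; w2 <- w2 / tot; w3 <- w3 / tot; w4 <- w4 / tot
  data.frame(
    w_plasticity = w1, w_pci = w2, w_druggability = w3, w_proximity = w4,
    integrated = w1 * plasticity + w2 * pci + w3 * druggability +
      w4 * disease_prox
  )
}

#' Temporal weighting of the integrated score
#'
#' @param integrated Nonnegative integrated scores.
#' @param category Temporal category labels (one of
#'   `early_intervention`, `progression_modifier`, `neuroprotection`,
#'   `symptomatic`, `uncategorized`).
#' @return Data frame with `temporal_weight` and `final_score`.
#' @export
temporal_final_score <- function(integrated, category) {
  tw_map <- temporal_weights()
  category <- as.character(category)
  if (any(!category %in% names(tw_map))) {
    abort_input("unknown temporal category")
  }
  tw <- unname(tw_map[category])
  data.frame(temporal_weight = tw, final_score = integrated * tw)
}

# Internal: integrated scores for every gene under both membrane settings.
# Used to make label permutation O(n) per shuffle.
.integrated_both <- function(tab) {
  list(
    mem = adaptive_integrate(tab$plasticity, tab$pci, tab$druggability,
                             tab$disease_proximity, TRUE)$integrated,
    nomem = adaptive_integrate(tab$plasticity, tab$pci, tab$druggability,
                               tab$disease_proximity, FALSE)$integrated
  )
}

#' Permutation significance of final gene scores
#'
#' Builds per-gene null distributions by shuffling the assignment of
#' dimensional-score vectors to gene labels; for each shuffle the
#' integrated score is recomputed from the permuted score vector under
#' the receiving gene's membrane flag and multiplied by the receiving
#' gene's temporal weight. A gene is significant when its observed final
#' score exceeds the 95th percentile of its own null.
#'
#' @param tab Data frame with columns `gene`, `plasticity`, `pci`,
#'   `druggability`, `disease_proximity`, `is_membrane`,
#'   `temporal_category`.
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed for reproducibility.
#' @return `tab` with `final_score`, `permutation_p` and `significant_95`
#'   appended.
#' @export
permutation_significance <- function(tab, n_perm = 1000, seed = 42) {
  if (nrow(tab) < 2) abort_input("at least two genes are required")
  if (n_perm < 100) abort_input("insufficient permutations")
  n <- nrow(tab)
  tw <- unname(temporal_weights()[as.character(tab$temporal_category)])
  if (any(is.na(tw))) abort_input("unknown temporal category")

  both <- .integrated_both(tab)
  is_obs <- ifelse(tab$is_membrane, both$mem, both$nomem)
  obs <- is_obs * tw

  null_mat <- matrix(0, nrow = n, ncol = n_perm)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    is_b <- ifelse(tab$is_membrane, both$mem[perm], both$nomem[perm])
    null_mat[, b] <- is_b * tw
  }
  q95 <- apply(null_mat, 1, quantile, probs = 0.95)
  pvals <- (rowSums(null_mat >= obs) + 1) / (n_perm + 1)
  tab$final_score <- obs
  tab$permutation_p <- pvals
  tab$significant_95 <- obs > q95
  tab
}

#' Bootstrap stability of gene rankings
#'
#' Resamples genes with replacement, recomputes final scores and ranks
#' within each replicate, and reports per-gene coefficient of variation
#' of the final score across replicates together with the frequency of
#' membership in the top `top_k`.
#'
#' @param tab Data frame as for [permutation_significance()].
#' @param top_k Size of the top set tracked (default 10).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return Data frame with columns `gene`, `cv_final_score`,
#'   `topk_frequency`.
#' @export
bootstrap_stability <- function(tab, top_k = 10, n_boot = 1000, seed = 42) {
  n <- nrow(tab)
  if (top_k > n) abort_input("top_k exceeds the number of genes")
  tw <- unname(temporal_weights()[as.character(tab$temporal_category)])
  both <- .integrated_both(tab)
  fs <- ifelse(tab$is_membrane, both$mem, both$nomem) * tw

  sums <- numeric(n); sq <- numeric(n); cnt <- integer(n); topk <- integer(n)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    u <- unique(idx)
    sums[u] <- sums[u] + fs[u]
    sq[u] <- sq[u] + fs[u]^2
    cnt[u] <- cnt[u] + 1L
    ord <- u[order(-fs[u], tab$gene[u])]
    topk[head(ord, top_k)] <- topk[head(ord, top_k)] + 1L
  }
  m <- ifelse(cnt > 0, sums / cnt, NA_real_)
  v <- ifelse(cnt > 1, pmax(0, sq / cnt - m^2) * cnt / (cnt - 1), 0)
  v[v < (m^2 + 1) * 1e-14] <- 0  # guard against accumulation round-off
  cv <- ifelse(cnt > 0 & m != 0, sqrt(v) / abs(m), 0)
  data.frame(
    gene = tab$gene,
    cv_final_score = cv,
    topk_frequency = ifelse(cnt > 0, topk / cnt, 0)
  )
}

#' Run the full multi-dimensional gene prioritization
#'
#' Computes the four dimensional scores from a network, a pathway
#' annotation table and a gene feature-flag table, integrates them
#' adaptively, applies the temporal filter, ranks genes, and (optionally)
#' attaches permutation significance.
#'
#' @param graph Undirected `igraph` gene network.
#' @param pathways Data frame with columns `gene`, `pathway_id`,
#'   `db_type`, `adj_p`.
#' @param flags Data frame with one row per gene: logical feature flags,
#'   `base_druggability`, `direct_ad_association`,
#'   `ad_pathway_set_overlap`, `temporal_category`. Genes absent from
#'   the table receive all-false flags, base druggability 0.1, no direct
#'   association, zero overlap, and the uncategorized temporal class.
#' @param n_perm Permutations for significance testing; set to 0 to skip.
#' @param seed Integer seed.
#' @return Prioritization data frame with one row per network gene,
#'   ranked by final score (ties broken by gene symbol).
#' @export
run_mnptd <- function(graph, pathways, flags, n_perm = 1000, seed = 42) {
  prof <- compute_centralities(graph)
  prof <- plasticity_score(prof)

  flags <- merge(
    data.frame(gene = prof$gene, stringsAsFactors = FALSE),
    flags, by = "gene", all.x = TRUE
  )
  flags <- flags[match(prof$gene, flags$gene), , drop = FALSE]
  for (col in c("is_membrane", "is_enzyme", "is_gpcr", "is_ion_channel",
                "is_neurotransmitter", "is_known_ad_target")) {
    if (is.null(flags[[col]])) flags[[col]] <- FALSE
    flags[[col]] <- !is.na(flags[[col]]) & as.logical(flags[[col]])
  }
  if (is.null(flags$base_druggability)) flags$base_druggability <- NA_real_
  flags$base_druggability <- ifelse(
    is.na(flags$base_druggability),
    ifelse(flags$is_known_ad_target, 0.3, 0.1),
    flags$base_druggability
  )
  if (is.null(flags$direct_ad_association)) flags$direct_ad_association <- NA_real_
  flags$direct_ad_association <- ifelse(
    is.na(flags$direct_ad_association),
    ifelse(flags$is_known_ad_target, 1.0, 0.0),
    flags$direct_ad_association
  )
  if (is.null(flags$ad_pathway_set_overlap)) flags$ad_pathway_set_overlap <- 0
  flags$ad_pathway_set_overlap[is.na(flags$ad_pathway_set_overlap)] <- 0
  if (is.null(flags$temporal_category)) flags$temporal_category <- NA_character_
  flags$temporal_category[is.na(flags$temporal_category)] <- "uncategorized"

  pci <- vapply(prof$gene, function(g) {
    pathway_centrality_index(pathways[pathways$gene == g, , drop = FALSE])$pci
  }, numeric(1))

  ds <- druggability_score(flags)
  dp <- disease_proximity(flags, prof)$disease_proximity

  tab <- data.frame(
    gene = prof$gene,
    plasticity = prof$plasticity,
    pci = as.numeric(pci),
    druggability = ds,
    disease_proximity = dp,
    is_membrane = flags$is_membrane,
    temporal_category = flags$temporal_category,
    stringsAsFactors = FALSE
  )

  intg <- adaptive_integrate(tab$plasticity, tab$pci, tab$druggability,
                             tab$disease_proximity, tab$is_membrane)
  tab$integrated <- intg$integrated
  fin <- temporal_final_score(tab$integrated, tab$temporal_category)
  tab$temporal_weight <- fin$temporal_weight
  tab$final_score <- fin$final_score

  if (n_perm > 0) {
    sig <- permutation_significance(tab, n_perm = n_perm, seed = seed)
    tab$permutation_p <- sig$permutation_p
    tab$significant_95 <- sig$significant_95
  } else {
    tab$permutation_p <- NA_real_
    tab$significant_95 <- NA
  }

  ord <- order(-tab$final_score, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
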