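#' Synthetic-data configuration
#'
#' Defaults describe the study conditions the pipeline is exercised
#' under: a scale-free protein interaction network with a densely wired
#' disease module, a sparse bipartite drug-gene layer with five planted
#' true positives among decoys and 0.5-imputed missing scores,
#' small-molecule property distributions centred on the summary
#' statistics of CNS-compliant repurposing candidates (MW 317.8 +/- 77.4
#' Da, LogP 2.18 +/- 0.96, PSA 52.3 +/- 20.2 A^2), and a separable
#' 70/40 two-class descriptor set for the supervised BBB harness.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of network genes.
#' @param n_drugs Number of drugs.
#' @param attachment_m Preferential-attachment edges per new node.
#' @param n_target_genes Size of the planted disease module.
#' @param n_planted_drugs Planted module-targeting drugs.
#' @param approved_fraction Fraction of drugs flagged approved.
#' @param missing_score_fraction Fraction of interaction rows emitted
#'   without a score.
#' @param property_means,property_sds Named vectors over the five
#'   descriptors for small-molecule property generation.
#' @param peptide_fraction,biologic_fraction Minority modality fractions
#'   in the property table.
#' @param n_bbb_positive,n_bbb_negative Labeled BBB set class sizes.
#' @param class_separation Standardized mean shift between the two BBB
#'   classes (total Euclidean separation across the five descriptors).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 42,
    n_genes = 500,
    n_drugs = 100,
    attachment_m = 3,
    n_target_genes = 20,
    n_planted_drugs = 5,
    approved_fraction = 0.5,
    missing_score_fraction = 0.1,
    property_means = c(mw = 317.8, logp = 2.18, psa = 52.3,
                       hbd = 1.37, hba = 3.24),
    property_sds = c(mw = 77.4, logp = 0.96, psa = 20.2,
                     hbd = 1.12, hba = 1.98),
    peptide_fraction = 0.02,
    biologic_fraction = 0.01,
    n_bbb_positive = 70,
    n_bbb_negative = 40,
    class_separation = 3) {
  stopifnot(n_genes > attachment_m, n_drugs >= n_planted_drugs,
            n_target_genes >= 0, class_separation >= 0)
  structure(
    list(
      seed = seed, n_genes = n_genes, n_drugs = n_drugs,
      attachment_m = attachment_m, n_target_genes = n_target_genes,
      n_planted_drugs = n_planted_drugs,
      approved_fraction = approved_fraction,
      missing_score_fraction = missing_score_fraction,
      property_means = property_means, property_sds = property_sds,
      peptide_fraction = peptide_fraction,
      biologic_fraction = biologic_fraction,
      n_bbb_positive = n_bbb_positive, n_bbb_negative = n_bbb_negative,
      class_separation = class_separation
    ),
    class = "synthetic_config"
  )
}

# Internal: zero-padded synthetic identifiers.
.synth_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

#' Generate a scale-free gene interaction network
#'
#' Barabasi-Albert preferential attachment, optionally steered to an
#' exact edge count via a mixed per-node out-degree sequence, with the
#' first `n_target_genes` nodes additionally wired into a dense disease
#' module (all within-module pairs connected).
#'
#' @param cfg A [synthetic_config()].
#' @param target_edges Optional exact attachment edge count; when NULL
#'   every new node attaches with `attachment_m` edges.
#' @return A list with the `igraph` `graph`, the edge data frame
#'   `edges`, and the `module` gene ids.
#' @export
gen_ppi_network <- function(cfg = synthetic_config(), target_edges = NULL) {
  n <- cfg$n_genes
  m <- cfg$attachment_m
  if (n < m + 1) abort_input("n_genes must exceed attachment_m")
  set.seed(cfg$seed)

  if (is.null(target_edges)) {
    out_seq <- c(0, rep(m, n - 1))
  } else {
    base <- target_edges %/% (n - 1)
    extra <- target_edges - base * (n - 1)
    out_seq <- c(0, sample(c(rep(base + 1, extra), rep(base, n - 1 - extra))))
  }
  g <- igraph::sample_pa(n, out.seq = out_seq, directed = FALSE,
                         algorithm = "psumtree")
  g <- igraph::simplify(g)
  igraph::V(g)$name <- .synth_ids("G", n)

  # attachment collisions can drop below an exact edge budget: top up
  # with uniformly random absent edges
  if (!is.null(target_edges)) {
    while (igraph::ecount(g) < target_edges) {
      cand <- sample.int(n, 2)
      if (cand[1] != cand[2] &&
          !igraph::are_adjacent(g, cand[1], cand[2])) {
        g <- igraph::add_edges(g, cand)
      }
    }
  }

  module <- character(0)
  if (cfg$n_target_genes > 0) {
    module <- .synth_ids("G", n)[seq_len(cfg$n_target_genes)]
    pairs <- t(utils::combn(module, 2))
    g <- igraph::add_edges(g, t(pairs))
    g <- igraph::simplify(g)
  }
  el <- igraph::as_edgelist(g)
  edges <- data.frame(
    gene_a = el[, 1], gene_b = el[, 2],
    weight = round(runif(nrow(el), 0.4, 1.0), 3),
    stringsAsFactors = FALSE
  )
  g <- graph_from_edge_table(edges)
  list(graph = g, edges = edges, module = module)
}

#' Generate a pathway annotation table
#'
#' Per gene, Poisson-distributed membership counts across the five
#' database types; adjusted p-values drawn log-uniform in
#' \[1e-10, 0.05\]. Genes of the disease module receive higher expected
#' counts and smaller p-values, so their pathway centrality exceeds the
#' background in expectation.
#'
#' @param genes Character vector of gene ids.
#' @param module Character vector of module gene ids (subset of
#'   `genes`).
#' @param cfg A [synthetic_config()].
#' @param lambda_background,lambda_module Mean annotations per database
#'   type.
#' @return Data frame `gene, pathway_id, db_type, adj_p`.
#' @export
gen_pathway_table <- function(genes, module = character(0),
                              cfg = synthetic_config(),
                              lambda_background = 0.8,
                              lambda_module = 3) {
  if (length(genes) == 0) abort_input("no genes supplied")
  set.seed(cfg$seed + 1L)
  dbs <- names(pathway_db_weights())
  rows <- list()
  k <- 0L
  for (g in genes) {
    in_mod <- g %in% module
    lam <- if (in_mod) lambda_module else lambda_background
    for (db in dbs) {
      cnt <- rpois(1, lam)
      if (cnt == 0) next
      lo <- if (in_mod) -10 else -6
      hi <- if (in_mod) -4 else log10(0.05)
      p <- 10^runif(cnt, lo, hi)
      k <- k + 1L
      rows[[k]] <- data.frame(
        gene = g,
        pathway_id = sprintf("%s_%s_%d", db, g, seq_len(cnt)),
        db_type = db,
        adj_p = pmin(p, 0.05),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate gene feature flags
#'
#' Bernoulli feature flags with module genes enriched for membership,
#' disease association and favourable temporal categories.
#'
#' @param genes Character vector of gene ids.
#' @param module Module gene ids.
#' @param cfg A [synthetic_config()].
#' @return Data frame of gene feature flags.
#' @export
gen_gene_flags <- function(genes, module = character(0),
                           cfg = synthetic_config()) {
  set.seed(cfg$seed + 2L)
  n <- length(genes)
  in_mod <- genes %in% module
  bern <- function(p_bg, p_mod) runif(n) < ifelse(in_mod, p_mod, p_bg)
  cats <- names(temporal_weights())
  data.frame(
    gene = genes,
    is_membrane = bern(0.25, 0.5),
    is_enzyme = bern(0.2, 0.3),
    is_gpcr = bern(0.05, 0.15),
    is_ion_channel = bern(0.05, 0.2),
    is_neurotransmitter = bern(0.1, 0.3),
    is_known_ad_target = in_mod,
    base_druggability = ifelse(in_mod, 0.3, 0.1),
    direct_ad_association = ifelse(in_mod, 1.0, 0.0),
    ad_pathway_set_overlap = ifelse(in_mod, rpois(n, 6), rpois(n, 1)),
    temporal_category = ifelse(
      in_mod,
      sample(cats[1:3], n, replace = TRUE),
      sample(cats, n, replace = TRUE, prob = c(.1, .1, .1, .2, .5))
    ),
    stringsAsFactors = FALSE
  )
}

#' Generate a sparse drug-gene interaction table
#'
#' Planted drugs receive several high-score edges into the disease
#' module; decoy drugs wire uniformly at random over non-module genes.
#' A configured fraction of rows is emitted without a score (NA), to be
#' imputed to 0.5 downstream.
#'
#' @param cfg A [synthetic_config()].
#' @param genes Gene ids; defaults to the ids [gen_ppi_network()] uses.
#' @param module Module gene ids.
#' @return A list with the interaction data frame `interactions`, the
#'   drug table `drugs` (name, approved), and the planted drug names.
#' @export
gen_interactions <- function(cfg = synthetic_config(),
                             genes = .synth_ids("G", cfg$n_genes),
                             module = genes[seq_len(cfg$n_target_genes)]) {
  set.seed(cfg$seed + 3L)
  drug_names <- .synth_ids("DRUG", cfg$n_drugs)
  planted <- drug_names[seq_len(cfg$n_planted_drugs)]
  background <- setdiff(genes, module)

  rows <- list()
  for (d in drug_names) {
    if (d %in% planted) {
      k <- sample(3:6, 1)
      tg <- sample(module, min(k, length(module)))
      sc <- round(runif(length(tg), 0.7, 1.0), 3)
    } else {
      k <- rpois(1, 2) + 1
      tg <- sample(background, min(k, length(background)))
      sc <- round(runif(length(tg), 0.1, 0.9), 3)
    }
    rows[[d]] <- data.frame(drug = d, gene = tg, score = sc,
                            stringsAsFactors = FALSE)
  }
  interactions <- do.call(rbind, rows)
  rownames(interactions) <- NULL
  miss <- runif(nrow(interactions)) < cfg$missing_score_fraction
  interactions$score[miss] <- NA_real_

  drugs <- data.frame(
    name = drug_names,
    approved = runif(cfg$n_drugs) < cfg$approved_fraction,
    stringsAsFactors = FALSE
  )
  list(interactions = interactions, drugs = drugs, planted = planted)
}

# Internal: truncated normal draw by resampling.
.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

#' Generate per-drug physicochemical properties
#'
#' Small-molecule descriptors are truncated normals centred on the
#' configured means; a configured minority is emitted at peptide scale
#' (MW 1000-5000 Da, strongly polar) and biologic scale (MW > 1500 Da
#' with antibody nomenclature).
#'
#' @param drugs Character vector of drug names.
#' @param cfg A [synthetic_config()].
#' @return Data frame `drug, mw, logp, psa, hbd, hba, rotatable_bonds,
#'   n_plus_o, reactivity_flags`.
#' @export
gen_property_table <- function(drugs, cfg = synthetic_config()) {
  set.seed(cfg$seed + 4L)
  n <- length(drugs)
  mu <- cfg$property_means
  sdv <- cfg$property_sds

  mw <- .rtruncnorm(n, mu["mw"], sdv["mw"], lo = 50)
  logp <- rnorm(n, mu["logp"], sdv["logp"])
  psa <- .rtruncnorm(n, mu["psa"], sdv["psa"], lo = 0)
  hbd <- pmax(0, round(rnorm(n, mu["hbd"], sdv["hbd"])))
  hba <- pmax(1, round(rnorm(n, mu["hba"], sdv["hba"])))

  u <- runif(n)
  is_bio <- u < cfg$biologic_fraction
  is_pep <- !is_bio & u < cfg$biologic_fraction + cfg$peptide_fraction
  if (any(is_pep)) {
    mw[is_pep] <- runif(sum(is_pep), 500, 1450)
    logp[is_pep] <- runif(sum(is_pep), -2, 2)
    psa[is_pep] <- mw[is_pep] * runif(sum(is_pep), 0.15, 0.2)
    hbd[is_pep] <- round(mw[is_pep] / 150)
    hba[is_pep] <- round(mw[is_pep] / 90)
  }
  if (any(is_bio)) {
    mw[is_bio] <- runif(sum(is_bio), 50000, 150000)
    logp[is_bio] <- runif(sum(is_bio), -10, -5)
    psa[is_bio] <- runif(sum(is_bio), 2000, 6000)
    hbd[is_bio] <- round(runif(sum(is_bio), 100, 400))
    hba[is_bio] <- round(runif(sum(is_bio), 200, 600))
  }

  flags <- rep("", n)
  risky <- runif(n) < 0.03
  flags[risky] <- sample(names(default_alert_table()), sum(risky),
                         replace = TRUE)

  data.frame(
    drug = drugs,
    peptidic = is_pep,
    mw = round(mw, 1),
    logp = round(logp, 2),
    psa = round(psa, 1),
    hbd = as.integer(hbd),
    hba = as.integer(hba),
    rotatable_bonds = pmax(0L, as.integer(round(rnorm(n, 4, 2)))),
    n_plus_o = as.integer(hba + rpois(n, 0.5)),
    reactivity_flags = flags,
    stringsAsFactors = FALSE
  )
}

#' Generate a labeled BBB validation set
#'
#' Two class-conditional Gaussian clouds over the five descriptors.
#' Non-penetrant compounds are shifted against the penetrant class by
#' `class_separation` standardized units in total (per-feature shift
#' `class_separation/sqrt(5)` sd, higher MW/PSA/HBD/HBA and lower LogP),
#' mirroring the physicochemical contrast between CNS-penetrant and
#' peripherally restricted drugs.
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame `drug, mw, logp, psa, hbd, hba, cns_label` with
#'   `n_bbb_positive` rows labeled 1 and `n_bbb_negative` labeled 0.
#' @export
gen_bbb_validation <- function(cfg = synthetic_config()) {
  if (cfg$class_separation < 0) abort_input("class_separation must be >= 0")
  set.seed(cfg$seed + 5L)
  n1 <- cfg$n_bbb_positive
  n0 <- cfg$n_bbb_negative
  mu <- cfg$property_means
  sdv <- cfg$property_sds
  shift <- cfg$class_separation / sqrt(5)
  dir <- c(mw = 1, logp = -1, psa = 1, hbd = 1, hba = 1)

  draw <- function(n, class_shift) {
    vapply(bbb_features(), function(f) {
      rnorm(n, mu[f] + class_shift * dir[f] * shift * sdv[f], sdv[f])
    }, numeric(n))
  }
  x1 <- draw(n1, 0)
  x0 <- draw(n0, 1)
  out <- as.data.frame(rbind(x1, x0))
  names(out) <- bbb_features()
  out$hbd <- pmax(0, round(out$hbd))
  out$hba <- pmax(0, round(out$hba))
  out$psa <- pmax(0, out$psa)
  out$mw <- pmax(50, out$mw)
  data.frame(
    drug = .synth_ids("CMPD", n1 + n0),
    out,
    cns_label = c(rep(1L, n1), rep(0L, n0)),
    stringsAsFactors = FALSE
  )
}

#' Generate every synthetic input for the pipeline
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `network` (graph/edges/module), `pathways`,
#'   `gene_flags`, `interactions`, `drugs`, `planted`, `properties`,
#'   `bbb_labeled`.
#' @export
gen_all <- function(cfg = synthetic_config()) {
  net <- gen_ppi_network(cfg)
  genes <- igraph::V(net$graph)$name
  inter <- gen_interactions(cfg, genes = sort(genes), module = net$module)
  props <- gen_property_table(inter$drugs$name, cfg)
  list(
    network = net,
    pathways = gen_pathway_table(sort(genes), net$module, cfg),
    gene_flags = gen_gene_flags(sort(genes), net$module, cfg),
    interactions = inter$interactions,
    drugs = inter$drugs,
    planted = inter$planted,
    properties = props,
    bbb_labeled = gen_bbb_validation(cfg)
  )
}
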