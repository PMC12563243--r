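#' Read a DGIdb-like drug-gene interaction TSV
#'
#' Expected columns: `drug_name`, `approved` (0/1), `gene_symbol` and
#' optional `interaction_score` (blank or missing values imputed later).
#'
#' @param path Path to the TSV.
#' @return A list with `interactions` (`drug, gene, score`) and `drugs`
#'   (`name, approved`).
#' @export
read_interactions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_name", "approved", "gene_symbol")
  if (!all(need %in% names(df))) {
    abort_input(sprintf("interaction table must have columns: %s",
                        paste(need, collapse = ", ")))
  }
  score <- if ("interaction_score" %in% names(df)) {
    suppressWarnings(as.numeric(df$interaction_score))
  } else {
    NA_real_
  }
  interactions <- data.frame(
    drug = canonical_drug_name(df$drug_name),
    gene = df$gene_symbol,
    score = score,
    stringsAsFactors = FALSE
  )
  drugs <- unique(data.frame(
    name = interactions$drug,
    approved = as.logical(df$approved),
    stringsAsFactors = FALSE
  ))
  list(interactions = interactions, drugs = drugs)
}

#' Write/read the ranked candidate table
#'
#' Tab-separated, fixed column order, lossless round-trip.
#'
#' @param table Ranked candidate data frame from [assess_candidates()].
#' @param path Output path.
#' @return Invisibly, the path (write) or the parsed data frame (read).
#' @export
write_candidate_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidate_table
#' @export
read_candidate_table <- function(path) {
  out <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE),
    error = function(e) abort_input(sprintf("malformed candidate table: %s",
                                            conditionMessage(e)))
  )
  out
}

#' Pipeline configuration
#'
#' One configuration object holding every tunable constant: the RWR
#' settings, CNS filter lists, combined-score weights, similarity
#' threshold, and seed. All printed defaults live here rather than being
#' hard-coded at call sites.
#'
#' @param seed Integer seed.
#' @param rwr An [rwr_config()].
#' @param cns_filter A [cns_filter_config()].
#' @param score_weights Combined-score weights (RWR, proximity, direct).
#' @param sim_threshold Jaccard similarity threshold for the layers.
#' @param evidence_table Named vector drug -> evidence level.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42,
                            rwr = rwr_config(),
                            cns_filter = cns_filter_config(),
                            score_weights = c(0.4, 0.3, 0.3),
                            sim_threshold = 0.15,
                            evidence_table = character(0)) {
  if (abs(sum(score_weights) - 1) > 1e-9) {
    abort_input("score_weights must sum to 1")
  }
  structure(
    list(seed = seed, rwr = rwr, cns_filter = cns_filter,
         score_weights = score_weights, sim_threshold = sim_threshold,
         evidence_table = evidence_table),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; unknown
#' keys are rejected. Nested sections `rwr` and `cns_filter` override
#' individual fields of their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "rwr", "cns_filter", "score_weights", "sim_threshold",
             "evidence_table")
  extra <- setdiff(names(y), known)
  if (length(extra) > 0) {
    abort_input(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")))
  }
  rwr_cfg <- do.call(rwr_config, modifyList(list(), y$rwr %||% list()))
  filt_cfg <- do.call(cns_filter_config,
                      modifyList(list(), y$cns_filter %||% list()))
  ev <- unlist(y$evidence_table %||% character(0))
  pipeline_config(
    seed = y$seed %||% 42,
    rwr = rwr_cfg,
    cns_filter = filt_cfg,
    score_weights = unlist(y$score_weights %||% c(0.4, 0.3, 0.3)),
    sim_threshold = y$sim_threshold %||% 0.15,
    evidence_table = ev
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end candidate pipeline
#'
#' Stages, in order: CNS pre-filter of the drug table, multi-layer
#' network construction on the retained drugs, RWR/proximity/direct
#' scoring against the target genes, optional supervised BBB probability
#' prediction, medicinal-chemistry assessment, and modality-stratified
#' ranking. Per-stage row counts are logged to stderr; a manifest
#' records the seed and a config hash.
#'
#' @param drugs Drug table (`name`, `approved`).
#' @param interactions Interaction table (`drug`, `gene`, `score`).
#' @param properties Physicochemical table (see [assess_candidates()]).
#' @param target_genes Character vector of target gene symbols.
#' @param bbb_labeled Optional labeled BBB set; when supplied, the best
#'   supervised model predicts per-drug penetration probabilities.
#' @param cfg A [pipeline_config()].
#' @return A list with `candidates` (ranked table), `scores`,
#'   `filtered`, `bbb` (validation result or NULL), and `manifest`.
#' @export
run_pipeline <- function(drugs, interactions, properties, target_genes,
                         bbb_labeled = NULL, cfg = pipeline_config()) {
  log_stage <- function(stage, n) {
    message(sprintf("[cnsrepurpose] %s: %d rows", stage, n))
  }
  log_stage("input drugs", nrow(drugs))

  filtered <- cns_filter(drugs, interactions, cfg$cns_filter)
  kept <- filtered$name[filtered$retained]
  if (length(kept) == 0) abort_input("0 drugs retained by the CNS filter")
  log_stage("after CNS filter", length(kept))

  inter_kept <- interactions[canonical_drug_name(interactions$drug) %in% kept,
                             , drop = FALSE]
  layers <- build_layers(inter_kept, cfg$sim_threshold)
  scores <- score_drugs(layers, target_genes, cfg$rwr, cfg$score_weights)
  log_stage("scored drugs", nrow(scores))

  bbb <- NULL
  ml_prob <- NULL
  if (!is.null(bbb_labeled)) {
    bbb <- run_bbb_validation(bbb_labeled, seed = cfg$seed)
    best <- bbb$models[[bbb$best]]
    preds <- predict_bbb(best, bbb$params, properties)
    ml_prob <- setNames(preds$probability, preds$drug)
  }

  props_kept <- properties[canonical_drug_name(properties$drug) %in% kept,
                           , drop = FALSE]
  approved <- setNames(as.logical(drugs$approved),
                       canonical_drug_name(drugs$name))
  candidates <- assess_candidates(
    props_kept, scores = scores, ml_probability = ml_prob,
    approved = approved, evidence_table = cfg$evidence_table
  )
  log_stage("assessed candidates", nrow(candidates))

  manifest <- list(
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    n_input_drugs = nrow(drugs),
    n_retained = length(kept),
    n_scored = nrow(scores),
    n_assessed = nrow(candidates),
    package_version = as.character(utils::packageVersion("cnsrepurpose"))
  )
  list(candidates = candidates, scores = scores, filtered = filtered,
       bbb = bbb, manifest = manifest)
}

#' Stable hash of a configuration object
#'
#' @param cfg Any serializable R object.
#' @return Hex md5 string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
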