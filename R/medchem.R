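#' Rule-based blood-brain barrier penetration score
#'
#' Six weighted physicochemical criteria: MW <= 450 Da (1.0),
#' 1.5 <= LogP <= 3.5 (2.0), PSA <= 70 A^2 (1.0), HBD <= 3 (0.5),
#' HBA <= 7 (0.5), N+O atom count <= 5 (1.0); the maximum achievable
#' score is 6.0. When the N+O count is unavailable it is approximated by
#' the HBA count (acceptors are N/O atoms) and the assessment is marked
#' approximated. Classes: >= 5 High, \[4, 5) ModerateHigh, \[3, 4)
#' Moderate, \[2, 3) Low, < 2 VeryLow.
#'
#' @param mw Molecular weight (Da).
#' @param logp Octanol-water partition coefficient.
#' @param psa Polar surface area (A^2).
#' @param hbd,hba Hydrogen-bond donor / acceptor counts.
#' @param n_plus_o Total nitrogen + oxygen atom count (optional).
#' @return A list with `rule_score`, `violations` (criterion ids),
#'   `rule_class`, and `n_plus_o_approximated`.
#' @export
bbb_rule_score <- function(mw, logp, psa, hbd, hba, n_plus_o = NULL) {
  for (nm in c("mw", "logp", "psa", "hbd", "hba")) {
    v <- get(nm)
    if (is.null(v) || length(v) != 1 || is.na(v)) {
      abort_input(sprintf("missing mandatory descriptor: %s", nm))
    }
  }
  approx_no <- is.null(n_plus_o) || is.na(n_plus_o)
  if (approx_no) n_plus_o <- hba

  crit <- c(
    mw = mw <= 450,
    logp = logp >= 1.5 && logp <= 3.5,
    psa = psa <= 70,
    hbd = hbd <= 3,
    hba = hba <= 7,
    n_plus_o = n_plus_o <= 5
  )
  wts <- c(mw = 1.0, logp = 2.0, psa = 1.0, hbd = 0.5, hba = 0.5,
           n_plus_o = 1.0)
  score <- sum(wts[crit])
  list(
    rule_score = score,
    violations = names(crit)[!crit],
    rule_class = .bbb_band(score, c(5, 4, 3, 2)),
    n_plus_o_approximated = approx_no
  )
}

# Internal: map a score onto the five-band scale with lower-edge
# inclusive boundaries.
.bbb_band <- function(x, edges) {
  if (x >= edges[1]) "High"
  else if (x >= edges[2]) "ModerateHigh"
  else if (x >= edges[3]) "Moderate"
  else if (x >= edges[4]) "Low"
  else "VeryLow"
}

#' CNS drug-likeness compliance
#'
#' A compound is CNS compliant when it satisfies all six rule-based BBB
#' criteria simultaneously (no violations).
#'
#' @inheritParams bbb_rule_score
#' @return Logical scalar.
#' @export
cns_compliance <- function(mw, logp, psa, hbd, hba, n_plus_o = NULL) {
  length(bbb_rule_score(mw, logp, psa, hbd, hba, n_plus_o)$violations) == 0
}

#' BBB class from a machine-learning probability
#'
#' High (P >= 0.8), ModerateHigh (0.6 <= P < 0.8), Moderate
#' (0.4 <= P < 0.6), Low (0.2 <= P < 0.4), VeryLow (P < 0.2).
#'
#' @param pml Probability in \[0, 1\] (vectorized).
#' @return Character vector of class labels.
#' @export
bbb_class_from_probability <- function(pml) {
  check_range(pml, 0, 1, "BBB probability")
  vapply(pml, .bbb_band, character(1), edges = c(0.8, 0.6, 0.4, 0.2))
}

#' P-glycoprotein efflux liability
#'
#' Counts the risk factors MW > 400 Da, LogP > 3.0 and HBA >= 8:
#' 0 factors Low, exactly 1 Moderate, 2 or more High.
#'
#' @param mw,logp,hba Descriptors (vectorized).
#' @return Character vector of liability levels.
#' @export
pgp_liability <- function(mw, logp, hba) {
  k <- (mw > 400) + (logp > 3.0) + (hba >= 8)
  c("Low", "Moderate", "High", "High")[k + 1]
}

#' Default structural-alert table for reactivity assessment
#'
#' Maps reactivity flag strings to risk levels; overridable per call.
#'
#' @return Named character vector flag -> level.
#' @export
default_alert_table <- function() {
  c(
    electrophile = "Moderate",
    michael_acceptor = "Moderate",
    epoxide = "High",
    protein_crosslinker = "High",
    crosslinker = "High",
    alkylating_agent = "VeryHigh",
    nitroso = "VeryHigh",
    metabolic_liability = "Moderate",
    oxidatively_labile = "Moderate"
  )
}

#' Chemical reactivity risk from structural-alert flags
#'
#' The risk level is the maximum level over matched alerts (Low when no
#' flag matches); the numeric penalty score maps Low 0.1, Moderate 0.4,
#' High 0.7, VeryHigh 1.0 (overridable).
#'
#' @param flags Character vector of reactivity flags (may be empty).
#' @param alert_table Named vector flag -> level; see
#'   [default_alert_table()].
#' @param score_map Named numeric vector level -> penalty score.
#' @return A list with `risk` and `reactivity_score`.
#' @export
reactivity_risk <- function(flags, alert_table = default_alert_table(),
                            score_map = c(Low = 0.1, Moderate = 0.4,
                                          High = 0.7, VeryHigh = 1.0)) {
  levels_ord <- c("Low", "Moderate", "High", "VeryHigh")
  flags <- flags[!is.na(flags) & nzchar(flags)]
  unknown <- setdiff(flags, names(alert_table))
  if (length(unknown) > 0) {
    warning(sprintf("ignoring unknown reactivity flags: %s",
                    paste(unknown, collapse = ", ")))
    flags <- setdiff(flags, unknown)
  }
  risk <- "Low"
  if (length(flags) > 0) {
    lv <- alert_table[flags]
    risk <- levels_ord[max(match(lv, levels_ord))]
  }
  list(risk = risk, reactivity_score = unname(score_map[risk]))
}

#' Four-class chemical tractability
#'
#' Three criteria: favourable BBB class (High or ModerateHigh),
#' acceptable reactivity (Low or Moderate), and MW <= 450 Da. All three
#' met gives Class I, exactly two Class II; otherwise Class IV when the
#' BBB class is VeryLow, else Class III.
#'
#' @param bbb_class BBB class label (machine-learning class when a
#'   probability is available, else the rule class).
#' @param reactivity Reactivity risk level.
#' @param mw Molecular weight (Da).
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
tractability_class <- function(bbb_class, reactivity, mw) {
  met <- sum(
    bbb_class %in% c("High", "ModerateHigh"),
    reactivity %in% c("Low", "Moderate"),
    mw <= 450
  )
  if (met == 3) "I"
  else if (met == 2) "II"
  else if (bbb_class == "VeryLow") "IV"
  else "III"
}

#' Development feasibility and translation timeline
#'
#' Feasibility maps tractability I/II/III/IV onto High/ModerateHigh/
#' Moderate/Low. Timeline: approved Class I compounds are Immediate
#' (0-1 y), experimental Class I ShortTerm (1-3 y), Class II MediumTerm,
#' Class III LongTerm, Class IV Research.
#'
#' @param tractability Tractability class (`"I"`..`"IV"`).
#' @param approved Logical approval status.
#' @return A list with `feasibility` and `timeline`.
#' @export
feasibility_and_timeline <- function(tractability, approved) {
  feas <- c(I = "High", II = "ModerateHigh", III = "Moderate",
            IV = "Low")[[tractability]]
  timeline <- switch(
    tractability,
    I = if (isTRUE(approved)) "Immediate" else "ShortTerm",
    II = "MediumTerm",
    III = "LongTerm",
    IV = "Research"
  )
  list(feasibility = feas, timeline = timeline)
}

#' Overall safety profile
#'
#' High or VeryHigh reactivity gives HighRisk; Low reactivity plus full
#' CNS compliance gives SafeForCNS; every other combination LowRisk.
#'
#' @param reactivity Reactivity risk level.
#' @param cns_compliant Logical CNS compliance.
#' @return One of `"SafeForCNS"`, `"LowRisk"`, `"HighRisk"`.
#' @export
safety_profile <- function(reactivity, cns_compliant) {
  if (reactivity %in% c("High", "VeryHigh")) "HighRisk"
  else if (reactivity == "Low" && isTRUE(cns_compliant)) "SafeForCNS"
  else "LowRisk"
}

#' Default list of known peptide therapeutics
#'
#' Compounds classified as peptides regardless of molecular weight.
#'
#' @return Character vector of canonical names.
#' @export
known_peptides <- function() {
  canonical_drug_name(c(
    "TROFINETIDE", "EXENATIDE", "LIRAGLUTIDE", "OCTREOTIDE", "LANREOTIDE",
    "PASIREOTIDE", "SOMATOSTATIN", "GLUCAGON", "VASOPRESSIN"
  ))
}

#' Therapeutic modality classification
#'
#' Precedence: (1) names on the known-peptide list are peptides;
#' (2) biologic nomenclature suffixes (-mab, -zumab, -cept, -tinib) or
#' MW > 1500 Da give biologic; (3) MW in (450, 1500\] with peptidic
#' evidence (suffix -tide / -pressin, or an explicit peptidic flag)
#' gives peptide; (4) otherwise small molecule.
#'
#' @param name Drug name.
#' @param mw Molecular weight (Da).
#' @param peptidic_flag Optional logical: external evidence of peptidic
#'   structure (amide-bond rich, high nitrogen content).
#' @param peptide_list Known-peptide names; see [known_peptides()].
#' @return One of `"small_molecule"`, `"peptide"`, `"biologic"`.
#' @export
classify_modality <- function(name, mw, peptidic_flag = FALSE,
                              peptide_list = known_peptides()) {
  nm <- canonical_drug_name(name)
  if (nm %in% peptide_list) return("peptide")
  if (grepl("(MAB|ZUMAB|CEPT|TINIB)$", nm) || mw > 1500) return("biologic")
  peptidic <- grepl("(TIDE|PRESSIN)$", nm) || isTRUE(peptidic_flag)
  if (mw > 450 && mw <= 1500 && peptidic) return("peptide")
  "small_molecule"
}

#' Medicinal-chemistry BBB penalty
#'
#' `penalty = 0.3 * (1 - P_ML) + 0.2 * reactivity_score`, bounded in
#' \[0, 0.5\].
#'
#' @param ml_probability Machine-learning BBB probability in \[0, 1\].
#' @param reactivity_score Normalized reactivity penalty in \[0, 1\].
#' @return The penalty (vectorized).
#' @export
medchem_penalty <- function(ml_probability, reactivity_score) {
  check_range(ml_probability, 0, 1, "ml_probability")
  check_range(reactivity_score, 0, 1, "reactivity_score")
  0.3 * (1 - ml_probability) + 0.2 * reactivity_score
}

#' Modality-adjusted combined score
#'
#' Small molecules take the full penalty, peptides half of it, biologics
#' one fifth: `combined * (1 - m * penalty)` with m = 1 / 0.5 / 0.2.
#'
#' @param combined Nonnegative network combined score.
#' @param penalty Penalty from [medchem_penalty()].
#' @param modality Modality label.
#' @return The adjusted score.
#' @export
modality_adjusted_score <- function(combined, penalty, modality) {
  mult <- c(small_molecule = 1.0, peptide = 0.5, biologic = 0.2)[[modality]]
  combined * (1 - mult * penalty)
}

#' Disease-specific evidence level
#'
#' Looks the drug up in a curated evidence table (name -> level in
#' Established, Clinical, Preclinical, Mechanistic, Speculative); drugs
#' absent from the table default to Mechanistic when a mechanistic
#' pathway tag is present and Speculative otherwise.
#'
#' @param name Drug name.
#' @param evidence_table Named character vector drug -> level (may be
#'   empty).
#' @param pathway_tag Optional mechanistic-pathway tag (non-empty string
#'   marks pathway-level rationale).
#' @return The evidence level label.
#' @export
evidence_level <- function(name, evidence_table = character(0),
                           pathway_tag = NULL) {
  nm <- canonical_drug_name(name)
  if (length(evidence_table) > 0) {
    names(evidence_table) <- canonical_drug_name(names(evidence_table))
    if (nm %in% names(evidence_table)) return(unname(evidence_table[nm]))
  }
  if (!is.null(pathway_tag) && length(pathway_tag) == 1 &&
      !is.na(pathway_tag) && nzchar(pathway_tag)) {
    return("Mechanistic")
  }
  "Speculative"
}

#' Modality-stratified candidate ranking
#'
#' Within each modality, candidates sort by descending adjusted score;
#' ties break by higher BBB probability (small molecules and peptides)
#' or higher direct-interaction score (biologics), then lexicographic
#' name. Ranks run 1..n per modality.
#'
#' @param candidates Data frame with columns `drug`, `modality`,
#'   `adjusted`, `ml_probability`, `direct`.
#' @return The input with a `rank_in_modality` column, sorted by
#'   modality then rank.
#' @export
rank_within_modality <- function(candidates) {
  if (nrow(candidates) == 0) abort_input("no candidates to rank")
  parts <- split(candidates, candidates$modality)
  ranked <- lapply(parts, function(df) {
    tie <- if (unique(df$modality) == "biologic") df$direct else
      df$ml_probability
    ord <- order(-df$adjusted, -tie, df$drug)
    df <- df[ord, , drop = FALSE]
    df$rank_in_modality <- seq_len(nrow(df))
    df
  })
  out <- do.call(rbind, ranked)
  rownames(out) <- NULL
  out
}

#' Full medicinal-chemistry assessment of a candidate table
#'
#' Applies the rule-based BBB score, CNS compliance, probability
#' banding, P-gp liability, reactivity, tractability, feasibility and
#' timeline, safety stratification, modality classification, penalty,
#' modality-adjusted score and evidence level to every drug, then ranks
#' within modality.
#'
#' @param properties Data frame with columns `drug`, `mw`, `logp`,
#'   `psa`, `hbd`, `hba`, optional `n_plus_o`, optional
#'   `reactivity_flags` (semicolon-separated string).
#' @param scores Network score table (`drug`, `combined`, `direct`, ...)
#'   as from [score_drugs()]; drugs missing from it score 0.
#' @param ml_probability Optional named vector drug -> BBB probability;
#'   when absent the tractability input falls back to the rule class and
#'   the penalty uses a neutral probability derived from the rule score
#'   (`rule_score / 6`).
#' @param approved Optional named logical vector drug -> approval.
#' @param evidence_table Named vector drug -> evidence level.
#' @param alert_table Structural-alert table for [reactivity_risk()].
#' @return Assessment data frame, one row per drug, ranked within
#'   modality.
#' @export
assess_candidates <- function(properties, scores = NULL,
                              ml_probability = NULL, approved = NULL,
                              evidence_table = character(0),
                              alert_table = default_alert_table()) {
  properties$drug <- canonical_drug_name(properties$drug)
  if (!is.null(ml_probability)) {
    names(ml_probability) <- canonical_drug_name(names(ml_probability))
  }
  if (!is.null(approved)) names(approved) <- canonical_drug_name(names(approved))

  rows <- lapply(seq_len(nrow(properties)), function(i) {
    p <- properties[i, , drop = FALSE]
    npo <- if (!is.null(p$n_plus_o)) p$n_plus_o else NULL
    rule <- bbb_rule_score(p$mw, p$logp, p$psa, p$hbd, p$hba, npo)
    compliant <- length(rule$violations) == 0

    flags <- character(0)
    if (!is.null(p$reactivity_flags) && !is.na(p$reactivity_flags) &&
        nzchar(p$reactivity_flags)) {
      flags <- trimws(strsplit(p$reactivity_flags, ";")[[1]])
    }
    react <- reactivity_risk(flags, alert_table)

    pml <- if (!is.null(ml_probability) && p$drug %in% names(ml_probability)) {
      unname(ml_probability[p$drug])
    } else {
      rule$rule_score / 6
    }
    ml_class <- bbb_class_from_probability(pml)
    bbb_for_tract <- if (!is.null(ml_probability) &&
                         p$drug %in% names(ml_probability)) {
      ml_class
    } else {
      rule$rule_class
    }
    tract <- tractability_class(bbb_for_tract, react$risk, p$mw)
    appr <- if (!is.null(approved) && p$drug %in% names(approved)) {
      isTRUE(unname(approved[p$drug]))
    } else {
      FALSE
    }
    ft <- feasibility_and_timeline(tract, appr)
    safety <- safety_profile(react$risk, compliant)
    pep_flag <- !is.null(p$peptidic) && isTRUE(p$peptidic)
    modality <- classify_modality(p$drug, p$mw, peptidic_flag = pep_flag)
    penalty <- medchem_penalty(pml, react$reactivity_score)

    comb <- 0
    dir <- 0
    if (!is.null(scores)) {
      hit <- scores[canonical_drug_name(scores$drug) == p$drug, , drop = FALSE]
      if (nrow(hit) > 0) {
        comb <- hit$combined[1]
        dir <- hit$direct[1]
      }
    }
    adjusted <- modality_adjusted_score(comb, penalty, modality)
    ev <- evidence_level(p$drug, evidence_table)

    data.frame(
      drug = p$drug, approved = appr,
      mw = p$mw, logp = p$logp, psa = p$psa, hbd = p$hbd, hba = p$hba,
      rule_score = rule$rule_score, rule_class = rule$rule_class,
      cns_compliant = compliant,
      ml_probability = pml, ml_class = ml_class,
      pgp = pgp_liability(p$mw, p$logp, p$hba),
      reactivity = react$risk, reactivity_score = react$reactivity_score,
      tractability = tract,
      feasibility = ft$feasibility, timeline = ft$timeline,
      safety = safety,
      modality = modality,
      network_combined = comb, direct = dir,
      penalty = penalty, adjusted = adjusted,
      evidence = ev,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rank_within_modality(out)
}
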