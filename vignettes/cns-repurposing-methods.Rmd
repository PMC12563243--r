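---
title: "Methods: network-medicine prioritization of CNS repurposing candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-medicine prioritization of CNS repurposing candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnsrepurpose)
```

## Overview

`cnsrepurpose` implements a drug-repurposing workflow for central nervous
system disease built from four connected pieces:

1. **Multi-dimensional gene prioritization.** Genes of a protein
   interaction network are scored on four dimensions — network
   plasticity, pathway centrality, druggability, and disease proximity —
   integrated with adaptive weights, and filtered by an
   intervention-timing weight. Significance comes from a label
   permutation test, stability from bootstrap resampling.
2. **Multi-layer pharmacogenomic network scoring.** A drug–gene
   bipartite layer (interaction scores, missing values imputed to 0.5),
   drug–drug and gene–gene Jaccard similarity layers (threshold 0.15),
   and their union. Drugs are scored by random walk with restart seeded
   at the target genes (restart probability 0.7, tolerance 1e-6),
   shortest-path proximity `1/(1 + dSP)`, and direct-interaction
   evidence, combined 0.4/0.3/0.3.
3. **Medicinal-chemistry assessment.** A six-criterion rule-based
   blood–brain barrier (BBB) score (maximum 6.0), CNS drug-likeness
   compliance, P-glycoprotein liability, reactivity risk, four-class
   tractability, feasibility/timeline, safety stratification, modality
   classification, a BBB/reactivity penalty, and modality-stratified
   ranking.
4. **Supervised BBB validation.** Four classifier families (random
   forest, gradient boosting, XGBoost, RBF-kernel SVM) trained on a
   labeled 70/40 compound set over five descriptors (MW, LogP, PSA,
   HBD, HBA), selected by balanced accuracy.

A seeded synthetic-data module generates every input, so the whole
pipeline is testable without downloads.

## Gene prioritization model

For gene $i$ with degree centrality $DC_i$, betweenness $BC_i$,
closeness $CC_i$, eigenvector centrality $EC_i$ and raw degree $deg_i$:

$$P_i = \tfrac13\bigl(D_i + C_i + N_i\bigr),\qquad
D_i = DC_i \cdot BC_i,\quad
C_i = deg_i\,(1 - CC_i),\quad
N_i = EC_i \cdot D_i.$$

The clustering-disruption term deliberately uses the *raw* degree, which
is what lets plasticity reach magnitudes of ~10 on hub genes while the
other components stay below 1.

Pathway centrality for gene $j$ over its annotation records:
$$PCI_j = 0.3\,PD_j + 0.4\,PS_j + 0.1\,PC_j + 0.2\,WS_j$$
with $PD$ the count of distinct database types, $PS$ the mean
$-\log_{10}$ adjusted p-value, $PC$ the record count, and $WS$ the mean
database-weighted $-\log_{10}$ p (weights: GO BP 1.0, KEGG 0.8,
Reactome 0.6, GO MF 0.4, Hallmark 0.3).

Druggability adds fixed bonuses (membrane 0.2, enzyme 0.15, GPCR 0.3,
ion channel 0.25, neurotransmitter 0.2) to a base value and caps at 1.
Disease proximity combines direct association, centrality proximity
$(DC+BC+EC)/3$, pathway overlap $\min(1,\,|P_h\cap P_{AD}|/10)$ and a
functional term fixed at 0.8 times the pathway term.

Integration starts from equal weights of 0.25 and multiplies the
druggability weight by 1.5 for membrane proteins, the plasticity weight
by 1.3 when plasticity exceeds 0.5, and the pathway weight by 1.2 when
the index exceeds 1.0, then renormalizes. Two remarks a user should
know:

* With realistic pathway tables the index is almost always above 1, so
  the pathway modifier fires for nearly every annotated gene. The
  thresholds are applied exactly as stated; they are not re-tuned here.
* The temporal weight (early intervention 1.0, neuroprotection 0.9,
  progression modifier 0.8, symptomatic 0.6, uncategorized 0.5)
  multiplies the integrated score at the end, so it reorders genes only
  across categories, never within one.

### Permutation significance and bootstrap stability

The null is built by shuffling the assignment of dimensional-score
vectors to gene labels and recomputing the integrated and final score
per shuffle; each shuffled score is evaluated under the *receiving*
gene's membrane flag and temporal weight, so the null reflects "this
gene's context with exchanged evidence". A gene is significant when its
observed final score exceeds the 95th percentile of its own null. On
exchangeable inputs the false-positive rate sits at the nominal 5%
(the suite checks 3–7% with 200 genes and 1000 permutations).

Because no step of the scoring normalizes across genes, a gene's final
score is invariant under resampling of the *other* genes; the bootstrap
therefore reports a coefficient of variation of exactly zero per gene,
and the informative output is the top-$k$ membership frequency, which
does vary because ranks are relative. If cross-gene normalization were
ever added, the same machinery would report nonzero CVs.

### Centrality conventions

Degree centrality is $deg/(n-1)$, betweenness is normalized by
$2/((n-1)(n-2))$, closeness uses Wasserman–Faust component scaling so
disconnected graphs stay defined, and the eigenvector is computed on the
largest connected component (zero elsewhere) and rescaled to unit
Euclidean norm over the whole graph; a single-node graph takes
eigenvector 1 by convention. All centralities are computed on the
unweighted topology: the edge weights of a confidence-scored interaction
network are affinities, and treating them as shortest-path distances
would invert their meaning.

## Network scoring

The random walk iterates
$p^{(t+1)} = (1-\alpha) P\, p^{(t)} + \alpha\, p^{(0)}$ with $P$ the
column-normalized weighted adjacency and $p^{(0)}$ uniform over the seed
genes. Numerical choices: degree-zero columns teleport their whole mass
to the restart vector (the standard dangling-node fix, keeping the
iterate a probability vector); convergence is declared on an L1 change
below 1e-6 within 1000 iterations; the result is renormalized to sum
exactly to one. On graphs of up to 50 nodes the iterate matches a dense
linear solve of the same fixed point to 1e-6 (a property test in the
suite).

Unreachable drug–target pairs in the shortest-path average are charged a
penalty distance equal to the node count of the graph — this keeps the
proximity score defined while strictly penalizing disconnection, rather
than silently dropping pairs. The Jaccard similarity threshold is
applied inclusively (≥ 0.15). For networks beyond a configured cap
(default 10,000 nodes) the walk runs on a target-centred subgraph grown
breadth-first, whole hop levels at a time, with lexicographic
tie-breaking inside a hop so the subsample is reproducible. Diffusion
proximity (the same walk at restart 0.5 read off at the drug node) and
resistance distance (Laplacian pseudoinverse, graphs ≤ 2000 nodes) are
reported as side channels and do not enter the combined score: how they
would be weighted against it is not specified by the scoring scheme, so
they are exposed for inspection only.

The three network layers enter the integrated graph with their native
edge weights; no relative layer multiplier is applied by default because
no principled constant is available, and the multipliers are exposed in
configuration rather than hidden in code.

## Medicinal-chemistry rules

The six BBB criteria earn weights 1.0 (MW ≤ 450 Da), 2.0
(1.5 ≤ LogP ≤ 3.5), 1.0 (PSA ≤ 70 Å²), 0.5 (HBD ≤ 3), 0.5 (HBA ≤ 7)
and 1.0 (N+O ≤ 5); all band boundaries here and in the probability
classes are inclusive at the lower edge. When an N+O atom count is not
available it is approximated by the acceptor count — acceptors are
nitrogen and oxygen atoms, so the approximation is conservative — and
the assessment is flagged.

Tractability requires favourable BBB class, acceptable reactivity and
MW ≤ 450; all three give Class I, exactly two Class II. The split
between III and IV is decided here: a compound missing two or more
criteria is Class IV only when its BBB class is VeryLow, otherwise III.
This is the unique assignment consistent with moderately sized polar
peptides landing in III while very large hormones land in IV. When a
machine-learning probability is available its class drives tractability;
otherwise the rule class does.

The reactivity penalty map (Low 0.1, Moderate 0.4, High 0.7, VeryHigh
1.0) is a package choice required to put a reactivity level on the
$[0,1]$ scale of the penalty
$p = 0.3\,(1 - P_{ML}) + 0.2\,R$; it is exposed in configuration.
Modality multiplies the penalty by 1 (small molecule), 0.5 (peptide) or
0.2 (biologic) before adjusting the combined network score, reflecting
transporter-mediated and receptor-mediated delivery routes that relax
passive-diffusion criteria.

Timeline assignments for Classes II and III (MediumTerm, LongTerm) are
interpolated between the stated endpoints (approved Class I: Immediate;
Class IV: Research) to keep the mapping total. Evidence levels are
annotation-driven from a curated table; no text mining is attempted, and
drugs absent from the table default to Mechanistic only when a pathway
tag exists, else Speculative.

## Supervised BBB validation

Standardization uses the population (divide-by-n) standard deviation of
the training rows — this makes a two-point feature scale exactly to
±1 — and the training parameters are applied unchanged to test rows and
later predictions. The split takes `round(class_n × test_frac)` per
class, so a 70/40 set at 0.2 gives 88 training (56/32) and 22 test
(14/8) compounds.

Model families and fixed hyperparameters: random forest (200 trees,
depth 10; `ranger`), gradient boosting (100 rounds, depth 5, learning
rate 0.1, L1/L2 regularization off — classical sequential boosting) and
XGBoost (same size, library-default L1/L2 regularization), both via the
`xgboost` library; RBF SVM (C = 1, gamma 1/n features, Platt-scaled
probabilities; `e1071`). On standardized inputs the SVM gamma equals
the variance-scaled convention. The AUC is a rank statistic (ties half
credit), invariant to monotone score transformations; the best model is
the balanced-accuracy argmax with ties broken by AUC and then by the
fixed family order. The binary threshold is inclusive at 0.5.

## What the synthetic data emulate — and what they do not

The generators are pure functions of a configuration and a seed:

* `gen_ppi_network()` — preferential attachment (one-parameter
  scale-free topology), optionally steered to an exact edge count, with
  a densely wired disease module. Preferential attachment was chosen
  over configuration-model sampling because one parameter reproduces
  the heavy-tailed degree pattern the analysis assumes.
* `gen_pathway_table()` — Poisson memberships per database type,
  log-uniform adjusted p-values in [1e-10, 0.05], module genes enriched.
* `gen_interactions()` — planted drugs wired into the module with high
  scores, decoys wired uniformly over non-module genes, a configured
  fraction of scores missing.
* `gen_property_table()` — truncated normals centred on MW 317.8 ± 77.4
  Da, LogP 2.18 ± 0.96, PSA 52.3 ± 20.2 Å² with physically sensible
  truncation (MW > 50, PSA ≥ 0, counts ≥ 0), plus small peptide-scale
  and biologic-scale minorities (2% and 1% by default, mirroring the
  order of magnitude seen in modality-classified candidate sets).
* `gen_bbb_validation()` — 70 penetrant / 40 non-penetrant compounds as
  two Gaussian clouds separated by a configurable standardized shift
  (default 3, split evenly across the five descriptors: non-penetrant
  higher MW/PSA/HBD/HBA, lower LogP).

These fixtures reproduce the *statistical shape* the methods assume —
scale-free connectivity, sparse bipartite interactions, separable
descriptor classes — not real pharmacology: drug names are synthetic,
interaction scores carry no assay semantics, and the BBB classes are
cleanly Gaussian where real compounds overlap and carry efflux effects
no descriptor captures. A passing suite therefore demonstrates that the
algorithms are implemented correctly and behave as designed under known
conditions, not that any particular real compound will penetrate the
BBB.

## Problem sizes and determinism

The default test conditions are a 500-gene network with a 20-gene
module, 100 drugs with 5 planted positives, and the 110-compound labeled
BBB set; the end-to-end smoke test runs 300 drugs. These sizes keep the
full suite comfortably within interactive runtimes while leaving every
statistical check adequately powered (the permutation calibration uses
200 genes × 1000 permutations). Every stochastic step takes an explicit
seed, defaulting to 42 throughout; identical configuration and seed give
byte-identical outputs, which the suite asserts.

## Known limitations

* Pathway enrichment p-values are consumed as an input table, never
  recomputed.
* Evidence classification is only as good as the curated table supplied.
* The BBB classifier sees only five descriptors; efflux (P-gp) is
  handled by a separate rule, not learned.
* Bootstrap CV is structurally zero (see above) unless cross-gene
  normalization is introduced.
* Absolute scores from the original disease networks are not
  reproducible without those networks; the package validates behaviour
  on synthetic data and printed worked examples instead.

## A short worked example

```{r example, eval = FALSE}
syn <- gen_all(synthetic_config(seed = 42))

# gene prioritization
prio <- run_mnptd(syn$network$graph, syn$pathways, syn$gene_flags,
                  n_perm = 1000, seed = 42)
head(prio[, c("gene", "final_score", "rank", "significant_95")])

# drug scoring against the disease module
layers <- build_layers(syn$interactions)
scores <- score_drugs(layers, syn$network$module)

# medicinal-chemistry assessment with supervised BBB probabilities
val <- run_bbb_validation(syn$bbb_labeled, seed = 42)
preds <- predict_bbb(val$models[[val$best]], val$params, syn$properties)
ranked <- assess_candidates(
  syn$properties, scores,
  ml_probability = setNames(preds$probability, preds$drug)
)
head(ranked)
```
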