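# Shared fixtures built in code.

# 3-node path A-B-C: hand-enumerable centralities.
path3_graph <- function() {
  graph_from_edge_table(data.frame(gene_a = c("A", "B"),
                                   gene_b = c("B", "C")))
}

# Complete graph on 4 nodes.
k4_graph <- function() {
  pairs <- t(combn(LETTERS[1:4], 2))
  graph_from_edge_table(data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2]))
}

# Top-15 small-molecule candidate characterization (printed reference
# rows used as inputs: descriptors, ML probability/class, printed P-gp,
# tractability and evidence calls).
top_small_molecules <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = '
drug mw logp psa hbd hba ml_prob ml_class pgp tract react evidence
PLERIXAFOR 502.8 2.15 118.4 8 12 0.650 ModerateHigh Moderate I Low Mechanistic
PRENYLAMINE 329.5 4.26 38.8 0 2 0.920 High Moderate I Low Mechanistic
DULOXETINE 297.4 4.23 44.9 1 2 0.890 High Moderate I Low Mechanistic
MEMANTINE 179.3 3.28 26.0 1 1 0.950 High Low I Low Established
DONEPEZIL 379.5 4.26 38.8 0 3 0.910 High Moderate I Low Established
SERTRALINE 306.2 5.29 12.0 1 1 0.880 High Moderate I Low Mechanistic
RISPERIDONE 410.5 3.04 61.8 0 5 0.820 High Moderate I Low Mechanistic
QUETIAPINE 383.5 2.87 73.8 1 6 0.750 ModerateHigh Moderate I Low Mechanistic
LEVETIRACETAM 170.2 -0.64 63.4 1 3 0.780 ModerateHigh Low I Low Mechanistic
FLUOXETINE 309.3 4.05 21.3 1 2 0.920 High Moderate I Low Mechanistic
TOPIRAMATE 339.4 0.89 118.0 0 9 0.580 Moderate Low II Low Mechanistic
GABAPENTIN 171.2 -1.10 63.3 2 3 0.720 ModerateHigh Low I Low Mechanistic
OLANZAPINE 312.4 3.00 44.0 1 4 0.880 High Moderate I Low Mechanistic
CARBAMAZEPINE 236.3 2.45 46.3 1 2 0.910 High Low I Low Mechanistic
VALPROATE 144.2 2.75 37.3 1 2 0.930 High Low I Low Mechanistic
')
  df
}

# Top-10 peptide candidate characterization rows.
top_peptides <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = '
drug mw logp psa hbd hba ml_prob ml_class pgp tract react evidence
TROFINETIDE 341.4 1.89 45.2 1 3 0.917 High Low I Low Speculative
CALCDPWW 287.4 1.60 41.9 1 3 0.917 High Low I Low Mechanistic
SOMATOSTATIN 1638.0 -3.15 456.2 18 26 0.145 Low High III Low Mechanistic
OCTREOTIDE 1019.2 -0.85 267.5 10 14 0.320 Low High III Low Mechanistic
LANREOTIDE 1096.4 -1.12 289.8 11 15 0.295 Low High III Low Mechanistic
PASIREOTIDE 1047.2 -0.98 279.3 10 14 0.308 Low High III Low Mechanistic
VASOACTIVE_INT 3326.0 -5.89 892.4 32 48 0.052 VeryLow High IV Low Mechanistic
GLUCAGON 3483.0 -6.12 945.6 35 51 0.048 VeryLow High IV Low Mechanistic
INSULIN_LISPRO 5808.0 -8.45 1567.0 52 78 0.015 VeryLow High IV Low Mechanistic
EXENATIDE 4186.6 -7.23 1234.5 41 62 0.025 VeryLow High IV Low Mechanistic
')
}

# Small exchangeable MNPTD table (identical flags/temporal class).
exchangeable_mnptd_table <- function(n_genes, seed = 1) {
  set.seed(seed)
  data.frame(
    gene = sprintf("G%03d", seq_len(n_genes)),
    plasticity = runif(n_genes, 0, 2),
    pci = runif(n_genes, 0, 4),
    druggability = runif(n_genes),
    disease_proximity = runif(n_genes),
    is_membrane = FALSE,
    temporal_category = "uncategorized",
    stringsAsFactors = FALSE
  )
}

# Tiny bipartite interaction fixture: 2 drugs x 3 genes.
tiny_interactions <- function() {
  data.frame(
    drug = c("D1", "D1", "D2", "D2"),
    gene = c("GA", "GB", "GA", "GC"),
    score = c(0.9, NA, 0.4, 0.8),
    stringsAsFactors = FALSE
  )
}
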