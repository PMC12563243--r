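test_that("centrality profiles match hand enumeration on small graphs", {
  expect_error(compute_centralities(igraph::make_empty_graph(0)),
               "empty network")

  # single isolated node
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "X"
  p1 <- compute_centralities(g1)
  expect_equal(p1$degree, 0L)
  expect_equal(p1$degree_centrality, 0)
  expect_equal(p1$betweenness, 0)
  expect_equal(p1$closeness, 0)
  expect_equal(p1$eigenvector, 1)

  # 3-node path: center B carries all shortest paths
  p3 <- compute_centralities(path3_graph())
  b <- p3[p3$gene == "B", ]
  expect_equal(b$degree_centrality, 1.0)
  expect_equal(b$betweenness, 1.0)
  expect_equal(b$closeness, 1.0)
  expect_equal(b$eigenvector, 1 / sqrt(2), tolerance = 1e-10)
  a <- p3[p3$gene == "A", ]
  expect_equal(a$closeness, 2 / 3, tolerance = 1e-12)

  # K4: full symmetry, no brokerage
  pk <- compute_centralities(k4_graph())
  expect_true(all(pk$degree_centrality == 1))
  expect_true(all(pk$betweenness == 0))
  expect_equal(pk$eigenvector, rep(0.5, 4), tolerance = 1e-10)

  # eigenvector has unit Euclidean norm over the graph
  expect_equal(sum(p3$eigenvector^2), 1, tolerance = 1e-10)
})

test_that("centralities on disconnected graphs use component conventions", {
  edges <- data.frame(gene_a = c("A", "B", "X"), gene_b = c("B", "C", "Y"))
  g <- graph_from_edge_table(edges)
  p <- compute_centralities(g)
  # eigenvector restricted to the largest component, zero elsewhere
  expect_equal(p$eigenvector[p$gene %in% c("X", "Y")], c(0, 0))
  expect_gt(p$eigenvector[p$gene == "B"], 0)
  # Wasserman-Faust closeness: X reaches only Y at distance 1, n = 5
  expect_equal(p$closeness[p$gene == "X"], (1 / 4) * (1 / 1))
})

test_that("plasticity score follows its three-component identity", {
  prof <- data.frame(gene = "g", degree = 4L, degree_centrality = 0.5,
                     betweenness = 0.2, closeness = 0.5, eigenvector = 0.3)
  out <- plasticity_score(prof)
  expect_equal(out$degree_impact, 0.1)
  expect_equal(out$clustering_disruption, 2.0)
  expect_equal(out$network_influence, 0.03)
  expect_equal(out$plasticity, (0.1 + 2 + 0.03) / 3, tolerance = 1e-12)

  # isolated node: only the clustering-disruption term can survive
  iso <- data.frame(gene = "i", degree = 0L, degree_centrality = 0,
                    betweenness = 0, closeness = 0, eigenvector = 0)
  expect_equal(plasticity_score(iso)$plasticity, 0)

  # path center from the centrality oracle
  p3 <- plasticity_score(compute_centralities(path3_graph()))
  expect_equal(p3$plasticity[p3$gene == "B"], (1 + 0 + 1 / sqrt(2)) / 3,
               tolerance = 1e-10)
})

test_that("pathway centrality index matches hand arithmetic", {
  one <- pathway_centrality_index(
    data.frame(pathway_id = "p", db_type = "GO_BP", adj_p = 0.1)
  )
  expect_equal(one$pd, 1)
  expect_equal(one$ps, 1)
  expect_equal(one$pc, 1)
  expect_equal(one$ws, 1)
  expect_equal(one$pci, 1.0)

  two <- pathway_centrality_index(
    data.frame(pathway_id = c("p", "q"), db_type = c("GO_BP", "KEGG"),
               adj_p = c(1e-3, 1e-5))
  )
  expect_equal(two$ws, 3.5)
  expect_equal(two$pci, 3.1, tolerance = 1e-12)

  empty <- pathway_centrality_index(NULL)
  expect_equal(empty$pci, 0)
  expect_true(empty$unannotated)

  expect_error(pathway_centrality_index(
    data.frame(pathway_id = "p", db_type = "GO_BP", adj_p = 0)
  ), "p-values")
})

test_that("druggability score adds bonuses and caps at one", {
  mk <- function(base, ...) {
    f <- list(is_membrane = FALSE, is_enzyme = FALSE, is_gpcr = FALSE,
              is_ion_channel = FALSE, is_neurotransmitter = FALSE)
    f[names(list(...))] <- list(...)
    do.call(data.frame, c(list(base_druggability = base), f))
  }
  expect_equal(druggability_score(mk(0.3)), 0.3)
  expect_equal(druggability_score(
    mk(0.6, is_membrane = TRUE, is_enzyme = TRUE, is_gpcr = TRUE,
       is_ion_channel = TRUE, is_neurotransmitter = TRUE)), 1.0)
  expect_equal(druggability_score(
    mk(0.15, is_membrane = TRUE, is_ion_channel = TRUE,
       is_neurotransmitter = TRUE)), 0.80)
  # monotone in each flag, never above 1
  for (flag in c("is_membrane", "is_enzyme", "is_gpcr", "is_ion_channel",
                 "is_neurotransmitter")) {
    args <- setNames(list(TRUE), flag)
    with_flag <- druggability_score(do.call(mk, c(list(0.5), args)))
    expect_gte(with_flag, druggability_score(mk(0.5)))
    expect_lte(with_flag, 1.0)
  }
})

test_that("disease proximity combines its four components", {
  mk_prof <- function(dc, bc, ec) {
    data.frame(degree_centrality = dc, betweenness = bc, closeness = 0,
               eigenvector = ec)
  }
  z <- disease_proximity(
    data.frame(direct_ad_association = 0, ad_pathway_set_overlap = 0),
    mk_prof(0, 0, 0))
  expect_equal(z$disease_proximity, 0)

  full <- disease_proximity(
    data.frame(direct_ad_association = 1, ad_pathway_set_overlap = 12),
    mk_prof(1, 1, 1))
  expect_equal(full$disease_proximity, 0.98, tolerance = 1e-12)

  mid <- disease_proximity(
    data.frame(direct_ad_association = 0.5, ad_pathway_set_overlap = 5),
    mk_prof(0.2, 0.1, 0.3))
  expect_equal(mid$cp, 0.2, tolerance = 1e-12)
  expect_equal(mid$pp, 0.5)
  expect_equal(mid$fp, 0.4)
  expect_equal(mid$disease_proximity, 0.40, tolerance = 1e-12)
})

test_that("adaptive integration renormalizes weights and is monotone", {
  # no modifier triggers: flat weights and identity on equal scores
  flat <- adaptive_integrate(0.4, 0.9, 1, 1, FALSE)
  expect_equal(unlist(flat[1, 1:4]), rep(0.25, 4), ignore_attr = TRUE)

  # membrane modifier only
  mem <- adaptive_integrate(0.4, 0.9, 1, 1, TRUE)
  expect_equal(unlist(mem[1, 1:4]),
               c(0.25, 0.25, 0.375, 0.25) / 1.125, ignore_attr = TRUE,
               tolerance = 1e-12)
  # plasticity 2 > 0.5 additionally triggers the plasticity modifier
  mem2 <- adaptive_integrate(2, 0.9, 1, 1, TRUE)
  expect_equal(
    mem2$integrated,
    (2 * 0.325 + 0.9 * 0.25 + 0.375 + 0.25) / 1.2,
    tolerance = 1e-12
  )

  # all modifiers with equal scores: weighted mean of equal scores
  all3 <- adaptive_integrate(1, 2, 1, 1, TRUE)
  expect_equal(sum(unlist(all3[1, 1:4])), 1, tolerance = 1e-9)

  # weight normalization + monotonicity properties over random cases
  set.seed(11)
  for (i in 1:25) {
    s <- runif(4, 0, 3)
    memb <- runif(1) < 0.5
    base <- adaptive_integrate(s[1], s[2], s[3], s[4], memb)
    expect_equal(sum(unlist(base[1, 1:4])), 1, tolerance = 1e-9)
    j <- sample(4, 1)
    s2 <- s; s2[j] <- s2[j] + runif(1, 0, 2)
    up <- adaptive_integrate(s2[1], s2[2], s2[3], s2[4], memb)
    expect_gte(up$integrated, base$integrated - 1e-12)
  }
})

test_that("temporal weighting maps categories and rejects unknown ones", {
  expect_equal(temporal_final_score(10, "early_intervention")$final_score, 10)
  expect_equal(temporal_final_score(10, "symptomatic")$final_score, 6.0)
  expect_equal(temporal_final_score(0, "neuroprotection")$final_score, 0)
  expect_equal(temporal_final_score(1, "progression_modifier")$temporal_weight,
               0.8)
  expect_error(temporal_final_score(1, "sometime"), "unknown temporal")
})

test_that("permutation test flags a planted gene and not exchangeable ones", {
  expect_error(
    permutation_significance(exchangeable_mnptd_table(10), n_perm = 50),
    "insufficient permutations"
  )

  # identical score vectors: the null equals the observed score everywhere
  tab <- exchangeable_mnptd_table(12)
  tab[, 2:5] <- 1
  res <- permutation_significance(tab, n_perm = 200, seed = 3)
  expect_false(any(res$significant_95))

  # one planted gene dominating by two orders of magnitude
  tab2 <- exchangeable_mnptd_table(60, seed = 5)
  tab2[1, c("plasticity", "pci", "druggability", "disease_proximity")] <-
    c(100, 100, 1, 1)
  res2 <- permutation_significance(tab2, n_perm = 300, seed = 7)
  expect_true(res2$significant_95[1])

  # determinism under a fixed seed
  res3 <- permutation_significance(tab2, n_perm = 300, seed = 7)
  expect_identical(res2, res3)
})

test_that("bootstrap stability reports top-k membership and zero CV", {
  tab <- exchangeable_mnptd_table(30, seed = 9)
  expect_error(bootstrap_stability(tab, top_k = 31), "top_k")

  # deterministic per-gene scores: CV identically zero
  bs <- bootstrap_stability(tab, top_k = 5, n_boot = 50, seed = 1)
  expect_true(all(bs$cv_final_score == 0))

  # a strongly separated top gene is in the top-k whenever sampled
  tab[1, c("plasticity", "pci")] <- c(50, 50)
  bs2 <- bootstrap_stability(tab, top_k = 5, n_boot = 200, seed = 2)
  expect_equal(bs2$topk_frequency[1], 1.0)

  bs3 <- bootstrap_stability(tab, top_k = 5, n_boot = 1, seed = 3)
  expect_true(all(bs3$cv_final_score == 0))
})

test_that("run_mnptd produces a complete, ranked prioritization", {
  syn <- gen_all(synthetic_config(seed = 2, n_genes = 60, n_drugs = 10,
                                  n_target_genes = 6))
  out <- run_mnptd(syn$network$graph, syn$pathways, syn$gene_flags,
                   n_perm = 200, seed = 2)
  expect_equal(nrow(out), igraph::vcount(syn$network$graph))
  expect_equal(sort(out$rank), seq_len(nrow(out)))
  expect_true(all(diff(out$final_score) <= 1e-12))
  expect_equal(out$final_score, out$integrated * out$temporal_weight,
               tolerance = 1e-12)
  # module genes are enriched and should concentrate near the top
  top10 <- out$gene[1:10]
  expect_gte(sum(top10 %in% syn$network$module), 5)
})
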