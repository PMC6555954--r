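test_that("a group identical to the background has zero enrichment", {
  cfg <- simulation_config(seed = 42, n_genes = 30,
    length_range_codons = c(30L, 60L))
  tx <- simulate_transcriptome(cfg)
  u <- codon_usage(tx$cds)
  for (lvl in c("codon", "amino_acid")) {
    e <- group_codon_enrichment(u, u$gene_id, level = lvl)
    expect_true(all(e$log2_fc[e$background_mean_freq > 0] == 0))
  }
})

test_that("enrichment matches hand computation on the two-gene fixture", {
  cds <- tibble::tibble(
    gene_id = c("g1", "g2"),
    sequence = c("GCCGCC", "GCAGCA")
  )
  u <- codon_usage(cds)
  e <- group_codon_enrichment(u, "g1")
  expect_equal(e$group_mean_freq[e$feature == "GCC"], 1.0)
  expect_equal(e$background_mean_freq[e$feature == "GCC"], 0.5)
  expect_equal(e$log2_fc[e$feature == "GCC"], 1.0)
  # amino-acid level: GCC and GCA are both Ala, so no enrichment remains
  ea <- group_codon_enrichment(u, "g1", level = "amino_acid")
  expect_equal(ea$log2_fc[ea$feature == "A"], 0)
})

test_that("enrichment equals a brute-force recomputation on a small fixture", {
  cfg <- simulation_config(seed = 11, n_genes = 10,
    length_range_codons = c(20L, 40L))
  tx <- simulate_transcriptome(cfg)
  u <- codon_usage(tx$cds)
  group <- u$gene_id[c(2, 5, 7)]
  e <- group_codon_enrichment(u, group)
  freq_mat <- as.matrix(u[, ALL_CODONS])
  grp_mean <- colMeans(freq_mat[u$gene_id %in% group, ])
  bkg_mean <- colMeans(freq_mat)
  expect_equal(e$group_mean_freq, unname(grp_mean), tolerance = 1e-12)
  expect_equal(e$background_mean_freq, unname(bkg_mean), tolerance = 1e-12)
  expect_equal(e$log2_fc, unname(log2(grp_mean / bkg_mean)),
    tolerance = 1e-12)
})

test_that("pooled-count summaries weight genes by length", {
  cds <- tibble::tibble(
    gene_id = c("short", "long"),
    sequence = c("AAA", strrep("CCC", 9))
  )
  u <- codon_usage(cds)
  e <- group_codon_enrichment(u, c("short", "long"), method = "pooled")
  expect_equal(e$group_mean_freq[e$feature == "CCC"], 0.9)
  e_mean <- group_codon_enrichment(u, c("short", "long"), method = "mean")
  expect_equal(e_mean$group_mean_freq[e_mean$feature == "CCC"], 0.5)
})

test_that("stability classes degenerate to frequency one when unique", {
  cds <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
    sequence = c("ATGAAA", "ATGCCC", "ATGGGG"))
  u <- codon_usage(cds, include_stops = FALSE)
  one_class <- tibble::tibble(codon = setdiff(ALL_CODONS,
    c("TAA", "TAG", "TGA")), stability_class = "only")
  st <- stability_enrichment(u, "g1", "g2", one_class)
  expect_true(all(abs(st$enrichment$group_mean_freq - 1) < 1e-9))
  expect_true(all(st$enrichment$log2_fc == 0))
})

test_that("opposite stability compositions separate with small rank-sum p", {
  # group A: all destabilizing (A/T-ending) codons; group B: all stabilizing
  a_seqs <- replicate(8, paste(sample(c("AAA", "GCT", "CTT", "GGA"), 30,
    TRUE), collapse = ""))
  b_seqs <- replicate(8, paste(sample(c("AAG", "GCC", "CTG", "GGC"), 30,
    TRUE), collapse = ""))
  cds <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:16),
    sequence = c(a_seqs, b_seqs)
  )
  u <- codon_usage(cds, include_stops = FALSE)
  st <- stability_enrichment(u, cds$gene_id[1:8], cds$gene_id[9:16],
    synthetic_stability_map())
  expect_true(all(st$tests$p < 0.01))
})

test_that("identical groups give non-significant stability differences", {
  with_seed_results <- replicate(20, {
    n <- 16
    seqs <- replicate(n, paste(sample(setdiff(ALL_CODONS,
      c("TAA", "TAG", "TGA")), 40, TRUE), collapse = ""))
    cds <- tibble::tibble(gene_id = sprintf("g%02d", 1:n), sequence = seqs)
    u <- codon_usage(cds, include_stops = FALSE)
    g <- sample(cds$gene_id, n / 2)
    st <- stability_enrichment(u, g, setdiff(cds$gene_id, g),
      synthetic_stability_map())
    all(st$tests$q >= 0.05)
  })
  expect_gte(mean(with_seed_results), 0.95)
})

test_that("stability map must cover the sense codons", {
  cds <- tibble::tibble(gene_id = "g1", sequence = "ATGAAA")
  u <- codon_usage(cds, include_stops = FALSE)
  bad <- tibble::tibble(codon = "AAA", stability_class = "x")
  expect_error(stability_enrichment(u, "g1", "g1", bad), "cover all 61")
  worse <- tibble::tibble(codon = c(setdiff(ALL_CODONS,
    c("TAA", "TAG", "TGA")), "TAA"), stability_class = "x")
  expect_error(stability_enrichment(u, "g1", "g1", worse), "unknown codon")
})

test_that("GC3-expression association recovers monotone structure", {
  cfg <- simulation_config(seed = 42, n_genes = 200)
  tx <- simulate_transcriptome(cfg)
  u <- codon_usage(tx$cds)
  de_mono <- tibble::tibble(gene_id = u$gene_id, log2fc = rank(u$gc3),
    padj = 0.01)
  expect_equal(gc_expression_association(u, de_mono)$rho, 1)
  de_anti <- tibble::tibble(gene_id = u$gene_id, log2fc = -rank(u$gc3),
    padj = 0.01)
  expect_equal(gc_expression_association(u, de_anti)$rho, -1)
})

test_that("GC3 association is near zero under an independent null", {
  cfg <- simulation_config(seed = 42, n_genes = 1000,
    length_range_codons = c(60L, 120L))
  tx <- simulate_transcriptome(cfg)
  u <- codon_usage(tx$cds)
  set.seed(42)
  hits <- replicate(20, {
    de <- tibble::tibble(gene_id = u$gene_id, log2fc = rnorm(1000),
      padj = runif(1000))
    abs(gc_expression_association(u, de)$rho) < 0.1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("GO profiles enforce the minimum term size after vector matching", {
  cfg <- simulation_config(seed = 42, n_genes = 100,
    length_range_codons = c(30L, 60L))
  tx <- simulate_transcriptome(cfg)
  u <- codon_usage(tx$cds)
  g2g <- dplyr::bind_rows(
    tibble::tibble(gene_id = u$gene_id[1:39], term_id = "GO:small"),
    tibble::tibble(gene_id = u$gene_id[1:40], term_id = "GO:exact"),
    tibble::tibble(gene_id = c(u$gene_id[1:40], "missing_gene"),
      term_id = "GO:with_missing")
  )
  prof <- go_profiles(g2g, u, min_genes = 40)
  expect_setequal(prof$term_id, c("GO:exact", "GO:with_missing"))
  expect_equal(prof$n_genes[prof$term_id == "GO:with_missing"], 40L)
  # term means equal an independent recomputation
  m <- colMeans(as.matrix(u[1:40, ALL_CODONS]))
  got <- unlist(prof[prof$term_id == "GO:exact", ALL_CODONS])
  expect_equal(unname(got), unname(m), tolerance = 1e-12)
})

test_that("a term of identical genes reproduces that gene's vector", {
  cds <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
    sequence = rep("ATGGCTGCAAAGTAA", 40))
  u <- codon_usage(cds)
  g2g <- tibble::tibble(gene_id = cds$gene_id, term_id = "GO:clone")
  prof <- go_profiles(g2g, u, min_genes = 40)
  expect_equal(unname(unlist(prof[1, ALL_CODONS])),
    unname(unlist(u[1, ALL_CODONS])), tolerance = 1e-12)
})

test_that("GO PCA recovers a planted GC3 gradient on PC1", {
  cfg <- simulation_config(seed = 42, n_genes = 400)
  tx <- simulate_transcriptome(cfg)
  u <- codon_usage(tx$cds)
  g2g <- simulate_gene2go(tx, n_terms = 25, genes_per_term = 60, seed = 42)
  prof <- go_profiles(g2g, u, min_genes = 40)
  pca <- go_pca(prof)
  expect_gt(abs(cor(pca$scores$PC1, pca$scores$gc3)), 0.95)
  # orientation contract: PC1 increases with AT3
  expect_gt(cor(pca$scores$PC1, 1 - pca$scores$gc3), 0)
  # explained variance non-increasing, sums to <= 1
  ev <- pca$explained_variance
  expect_true(all(diff(ev) <= 1e-9))
  expect_lte(sum(ev), 1 + 1e-9)
  # loadings orthonormal
  rot <- as.matrix(pca$loadings[, grep("^PC", names(pca$loadings))])
  gram <- crossprod(rot)
  expect_equal(gram, diag(ncol(rot)), tolerance = 1e-6,
    ignore_attr = TRUE)
  # hetADAT nnC codons load with four-fold-degenerate nnG codons
  ld <- pca$loadings
  nnc <- ld$PC1[!is.na(ld$hetadat_class) & ld$hetadat_class == "nnC"]
  nng4 <- ld$PC1[ld$third_base_class == "nnG" & ld$degeneracy == 4]
  expect_true(all(sign(nnc) == sign(nnc[1])))
  expect_true(all(sign(nng4) == sign(nnc[1])))
})

test_that("duplicated profiles score identically and tiny inputs error", {
  cfg <- simulation_config(seed = 7, n_genes = 200)
  tx <- simulate_transcriptome(cfg)
  u <- codon_usage(tx$cds)
  g2g <- simulate_gene2go(tx, n_terms = 6, genes_per_term = 45, seed = 7)
  prof <- go_profiles(g2g, u, min_genes = 40)
  dup <- dplyr::bind_rows(prof, dplyr::mutate(prof,
    term_id = paste0(term_id, "_copy")))
  pca <- go_pca(structure(dup, class = class(prof)))
  for (t in prof$term_id) {
    s1 <- pca$scores[pca$scores$term_id == t, "PC1"][[1]]
    s2 <- pca$scores[pca$scores$term_id == paste0(t, "_copy"), "PC1"][[1]]
    expect_equal(s1, s2, tolerance = 1e-9)
  }
  expect_error(go_pca(prof[1:2, ]), "at least 3")
})

test_that("de_gene_sets splits by sign at the padj cutoff", {
  de <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(2, -2, 1, -1),
    padj = c(0.01, 0.01, 0.5, 0.04)
  )
  sets <- de_gene_sets(de)
  expect_setequal(sets$up, "a")
  expect_setequal(sets$down, c("b", "d"))
})
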