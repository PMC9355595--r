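test_that("configurations are validated", {
  expect_error(sim_config(n_genes = 0), "non-positive")
  expect_error(sim_config(within_module_cor = 1.2), "within_module_cor")
  expect_error(sim_config(trait_module_index = 5, n_modules = 3),
               "trait_module_index")
  expect_error(sim_config(n_noise_genes = 600, n_genes = 600), "noise")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
})

test_that("every generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7, n_genes = 120, n_noise_genes = 30,
                    n_de_genes = 10)
  e1 <- simulate_expression(cfg)
  e2 <- simulate_expression(cfg)
  expect_identical(e1$counts$values, e2$counts$values)
  expect_identical(e1$fpkm$values, e2$fpkm$values)
  expect_identical(e1$trait, e2$trait)
  s1 <- simulate_target_sites(cfg)
  s2 <- simulate_target_sites(cfg)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$truth, s2$truth)
  d1 <- simulate_degradome(s1$truth, s1$transcripts, cfg)
  d2 <- simulate_degradome(s2$truth, s2$transcripts, cfg)
  expect_identical(d1, d2)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$expression$counts$values, b2$expression$counts$values)
  expect_identical(b1$degradome, b2$degradome)
  expect_identical(b1$truth_edges, b2$truth_edges)
})

test_that("module members correlate as configured and independents do not", {
  cfg <- sim_config(seed = 1)
  sim <- simulate_expression(cfg)
  mat <- log2(sim$fpkm$values + 1)
  mod <- sim$truth$module
  within <- sapply(1:3, function(m) {
    sel <- names(mod)[mod == m][2:41] # skip the planted hub
    cc <- cor(t(mat[sel, ]))
    mean(abs(cc[upper.tri(cc)]))
  })
  expect_true(all(within >= 0.7 & within <= 0.9))
  # zero within-module correlation leaves members independent
  cfg0 <- sim_config(seed = 2, within_module_cor = 0)
  sim0 <- simulate_expression(cfg0)
  mat0 <- log2(sim0$fpkm$values + 1)
  sel <- names(sim0$truth$module)[sim0$truth$module == 1][2:41]
  cc0 <- cor(t(mat0[sel, ]))
  expect_lt(mean(abs(cc0[upper.tri(cc0)])), 0.35)
})

test_that("the trait tracks the planted module's latent factor", {
  sim <- simulate_expression(sim_config(seed = 3))
  expect_gte(abs(cor(sim$trait, sim$truth$latent[1, ])), 0.9)
  expect_lte(abs(cor(sim$trait, sim$truth$latent[2, ])), 0.5)
})

test_that("planted fold changes are realized within tolerance", {
  cfg <- sim_config(seed = 6)
  sim <- simulate_expression(cfg)
  tg <- sim$truth$de_genes
  counts <- sim$counts$values
  stage <- sim$counts$samples$stage
  realized <- sapply(seq_len(nrow(tg)), function(i) {
    bumped <- stage == tg$bump_stage[i]
    ref <- stage == cfg$stages[match(tg$bump_stage[i], cfg$stages) - 1]
    tg$sign[i] * log2(mean(counts[tg$id[i], bumped]) /
                        mean(counts[tg$id[i], ref]))
  })
  expect_lt(abs(mean(realized) - cfg$de_effect_log2fc), 0.3)
})

test_that("site descriptors plant the requested defect patterns", {
  cfg <- sim_config(seed = 5)
  sites <- simulate_target_sites(cfg)
  tr <- sites$truth
  expect_equal(sum(tr$compliant), 50)
  expect_equal(sum(!tr$compliant), 50)
  # at least 8 violations of every criterion across the set
  for (cn in paste0("c", 1:6)) {
    expect_gte(sum(!tr[[cn]]), 8)
  }
  # each violator breaks exactly its intended criterion
  viol <- tr[!tr$compliant, ]
  for (i in seq_len(nrow(viol))) {
    flags <- unlist(viol[i, paste0("c", 1:6)])
    expect_equal(sum(!flags), 1)
    expect_false(flags[[viol$violates[i]]])
  }
  # pattern positions beyond the miRNA length are rejected
  bad <- list(mirnet:::site_spec("bad", mismatch = 25L))
  expect_error(simulate_target_sites(cfg, specs = bad), "exceeds")
})

test_that("truth labels agree with the alignment engine's verdicts", {
  cfg <- sim_config(seed = 8)
  sites <- simulate_target_sites(cfg)
  tr <- sites$truth
  for (i in seq_len(nrow(tr))) {
    w <- substr(sites$transcripts[[tr$transcript_id[i]]],
                tr$site_start[i], tr$site_end[i])
    d <- align_duplex(sites$mirnas[[tr$mirna_id[i]]], w, max_gaps = 0)
    v <- apply_criteria(d)
    expect_equal(unname(unlist(v[paste0("c", 1:6)])),
                 unname(unlist(tr[i, paste0("c", 1:6)])))
    expect_equal(v$pass, tr$compliant[i])
  }
})

test_that("a compliant descriptor with no defects is criterion-clean", {
  cfg <- sim_config(seed = 9)
  sites <- simulate_target_sites(cfg, specs = list(mirnet:::site_spec("perfect")))
  expect_true(sites$truth$compliant)
  # one mismatch at position 10 flips criterion 5
  s2 <- simulate_target_sites(cfg, specs = list(
    mirnet:::site_spec("v", mismatch = 10L)))
  expect_false(s2$truth$c5)
  expect_false(s2$truth$compliant)
  # mismatches at 1, 19, 20, 21 plus one wobble weigh 4.5 -> criterion 2
  s3 <- simulate_target_sites(cfg, specs = list(
    mirnet:::site_spec("v2", mismatch = c(1L, 19L, 20L, 21L), gu = 5L,
                       composition = "gu5")))
  expect_false(s3$truth$c2)
})

test_that("bundles carry consistent cross-references", {
  b <- simulate_bundle(sim_config(seed = 2))
  expect_setequal(b$truth_sites$transcript_id, names(b$transcripts))
  expect_true(all(b$truth_edges$mirna_id %in% rownames(b$mirna_expr$values)))
  expect_true(all(b$truth_edges$target_id %in%
                  rownames(b$expression$counts$values)))
  expect_true(all(b$truth_edges$target_id %in% b$tf_annotation$gene_id))
  # planted TF targets sit in the trait module
  mod <- b$expression$truth$module
  expect_true(all(mod[b$truth_edges$target_id] == 1))
  f <- withr::local_tempdir()
  write_bundle(b, f)
  expect_true(all(file.exists(file.path(f,
    c("transcripts.fasta", "mirnas.fasta", "counts.tsv", "fpkm.tsv",
      "mirna_counts.tsv", "samples.tsv", "trait.tsv", "degradome.tsv",
      "truth_sites.tsv", "tf_annotation.tsv", "annotations.tsv")))))
  tx <- read_fasta(file.path(f, "transcripts.fasta"))
  expect_identical(unname(tx), unname(b$transcripts))
})
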