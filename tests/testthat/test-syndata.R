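test_that("panel simulation is deterministic and respects coding invariants", {
  cfg <- sim_config(n_lines = 20, n_per_line = 5, n_variants = 200, seed = 1)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel$geno, b$panel$geno)
  expect_identical(a$panel$variants, b$panel$variants)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_true(all(a$panel$geno %in% c(0L, 1L)))
  expect_false(anyNA(a$panel$geno))

  # missingness only when enabled
  cfgm <- sim_config(n_lines = 20, n_per_line = 5, n_variants = 200,
                     missing_rate = 0.1, seed = 1)
  expect_true(anyNA(simulate_panel(cfgm)$panel$geno))
})

test_that("allele frequencies track maf_range", {
  cfg <- sim_config(n_lines = 300, n_per_line = 2, n_variants = 200,
                    maf_range = c(0.5, 0.5), seed = 2)
  p <- colMeans(simulate_panel(cfg)$panel$geno)
  expect_lt(max(abs(p - 0.5)), 0.15)
  expect_lt(abs(mean(p) - 0.5), 0.02)
})

test_that("full-scale panel has gene-mapped and unmapped variants", {
  cfg <- sim_config(n_lines = 167, n_per_line = 12, n_variants = 5000,
                    seed = 3)
  sim <- simulate_panel(cfg)
  expect_equal(dim(sim$panel$geno), c(167L, 5000L))
  spans <- dplyr::filter(sim$genes, feature == "gene")
  pos <- sim$panel$variants$pos
  # exhaustive interval check: at least one variant inside a gene and at
  # least one farther than 1 kb from every gene span
  inside <- vapply(pos, function(p)
    any(p >= spans$start & p <= spans$end), logical(1))
  dist <- vapply(pos, function(p)
    min(pmax(spans$start - p, 0) + pmax(p - spans$end, 0)), numeric(1))
  expect_true(any(inside))
  expect_true(any(dist > 1000))
  # gene model intervals stay inside their gene spans
  feats <- dplyr::filter(sim$genes, feature != "gene")
  j <- match(feats$gene_id, spans$gene_id)
  expect_true(all(feats$start >= spans$start[j] & feats$end <= spans$end[j]))
})

test_that("simulator rejects inconsistent configurations", {
  expect_error(sim_config(n_variants = 1e6, genome_length = 1000),
               "genome_length")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(n_causal_mean = 10, n_variants = 5), "causal")
  expect_error(simulate_motif_windows(10, 151, "ACGT", plant_fraction = 1.5),
               "plant_fraction")
  expect_error(simulate_motif_windows(10, 3, "ACGTA"), "at least the motif")
})

test_that("null phenotype model yields near-zero heritability", {
  base <- default_trait_baselines()
  base$between_sd <- 0
  cfg <- sim_config(n_lines = 100, n_per_line = 10, n_variants = 50,
                    n_causal_mean = 0, n_causal_var = 0, gamma_var = 1,
                    outlier_rate = 0, trait_baselines = base, seed = 5)
  sim <- simulate_panel(cfg)
  ph <- simulate_phenotypes(sim$panel, cfg)
  g <- ph$truth$line_genetic_values$EDD$value
  expect_lt(var(g), 1e-12)
  vc <- anova_components(ph$phenotypes, "EDD")
  expect_lt(vc$H2, 0.05)
})

test_that("variance-QTL carriers have inflated within-line SD", {
  cfg <- sim_config(n_lines = 100, n_per_line = 12, n_variants = 30,
                    n_causal_mean = 0, n_causal_var = 1, gamma_var = 3,
                    outlier_rate = 0, seed = 6)
  sim <- simulate_panel(cfg)
  ph <- simulate_phenotypes(sim$panel, cfg)
  vq <- ph$truth$causal_var$EDD$variant_id
  carrier <- sim$panel$geno[, vq] == 1
  sds <- tapply(ph$phenotypes$EDD, ph$phenotypes$line_id, sd)
  sds <- sds[sim$panel$line_ids]
  wt <- wilcox.test(sds[carrier], sds[!carrier], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("phenotype simulation is deterministic and HP = DI + SI", {
  cfg <- sim_config(n_lines = 15, n_per_line = 6, n_variants = 40, seed = 7)
  sim <- simulate_panel(cfg)
  a <- simulate_phenotypes(sim$panel, cfg)
  b <- simulate_phenotypes(sim$panel, cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_equal(a$phenotypes$HP, a$phenotypes$DI + a$phenotypes$SI)
  expect_true(all(a$truth$simulated_H2 >= 0 & a$truth$simulated_H2 <= 1))
  expect_true(all(unlist(purrr::map(a$truth$causal_mean, "variant_id")) %in%
                    sim$panel$variants$variant_id))
})

test_that("realized among-line variance matches the configured between-SD^2", {
  target <- default_trait_baselines()
  target_var <- target$between_sd[target$trait == "EDD"]^2
  vars <- vapply(seq_len(50), function(r) {
    cfg <- sim_config(n_lines = 167, n_per_line = 2, n_variants = 20,
                      n_causal_mean = 0, n_causal_var = 0, gamma_var = 1,
                      outlier_rate = 0, seed = 400 + r)
    sim <- simulate_panel(cfg)
    ph <- simulate_phenotypes(sim$panel, cfg)
    var(ph$truth$line_genetic_values$EDD$value)
  }, numeric(1))
  expect_lt(abs(mean(vars) - target_var) / target_var, 0.15)
})

test_that("motif window planting behaves at the extremes and in expectation", {
  w0 <- simulate_motif_windows(50, 30, "TCAAGTG", 0, seed = 1)
  expect_false(any(w0$planted))
  w1 <- simulate_motif_windows(20, 7, "TCAAGTG", 1, seed = 1)
  expect_true(all(w1$sequence == "TCAAGTG"))

  w <- simulate_motif_windows(200, 151, "TCAAGTG", 0.4, seed = 2)
  ci <- qbinom(c(0.005, 0.995), 200, 0.4)
  expect_gte(sum(w$planted), ci[1])
  expect_lte(sum(w$planted), ci[2])
  # planted windows really contain the motif at the recorded offset
  has <- vapply(which(w$planted), function(i)
    substr(w$sequence[i], w$offset[i], w$offset[i] + 6) == "TCAAGTG",
    logical(1))
  expect_true(all(has))
  # determinism
  expect_identical(w, simulate_motif_windows(200, 151, "TCAAGTG", 0.4,
                                             seed = 2))
})
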