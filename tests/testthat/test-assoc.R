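test_that("GRM matches an explicit standardization oracle", {
  # two lines, two variants, genotypes (0,1) at both
  G <- matrix(c(0L, 1L, 0L, 1L), 2, 2,
              dimnames = list(c("a", "b"), c("v1", "v2")))
  K <- compute_grm(G)
  Z <- apply(G, 2, function(g) (g - mean(g)) / sd(g))
  expect_equal(K, tcrossprod(Z) / 2, ignore_attr = TRUE)

  # identical genotype rows: off-diagonal equals the diagonal for that pair
  p <- toy_panel(n_lines = 10, n_variants = 20, seed = 1)
  p$geno[2, ] <- p$geno[1, ]
  K2 <- compute_grm(p)
  expect_equal(K2[1, 2], K2[1, 1])
  expect_equal(K2, t(K2))
  expect_gte(min(eigen(K2, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)

  # diagonal mean near 1 for a large random panel
  set.seed(2)
  Gbig <- matrix(rbinom(200 * 500, 1, runif(500, 0.1, 0.5)[rep(1:500,
                                                               each = 200)]),
                 200, 500)
  expect_equal(mean(diag(compute_grm(Gbig))), 1, tolerance = 0.05)

  expect_error(compute_grm(matrix(1L, 5, 3)), "monomorphic")
})

test_that("leverage filtering removes only fence-violating lines", {
  lv <- tibble::tibble(line_id = sprintf("L%03d", 1:167),
                       value = c(rnorm(166, 0.7, 0.02), 3.0))
  out <- leverage_filter(lv)
  expect_false(out$retained[167])
  expect_true(all(out$retained[1:166]))

  lv2 <- tibble::tibble(line_id = sprintf("L%02d", 1:20),
                        value = seq(0.5, 0.9, length.out = 20))
  expect_true(all(leverage_filter(lv2)$retained))
})

test_that("LMM with identity kinship reproduces OLS per-variant p-values", {
  p <- toy_panel(n_lines = 40, n_variants = 30, seed = 3)
  set.seed(9)
  y <- rnorm(40) + 0.8 * p$geno[, 5]
  resp <- tibble::tibble(line_id = p$line_ids, value = y)
  covs <- tibble::tibble(line_id = p$line_ids,
                         wolbachia = rbinom(40, 1, 0.5))
  scan <- suppressMessages(
    lmm_scan(p, resp, covs, K = diag(40)))
  for (v in scan$variant_id) {
    fit <- summary(lm(y ~ covs$wolbachia + p$geno[, v]))
    p_ols <- fit$coefficients[3, 4]
    p_lmm <- scan$p[scan$variant_id == v]
    expect_lt(abs(log10(p_lmm) - log10(p_ols)), 0.01)
  }
})

test_that("scan p-values are invariant under affine response transforms", {
  p <- toy_panel(n_lines = 30, n_variants = 25, seed = 4)
  set.seed(5)
  y <- rnorm(30)
  r1 <- tibble::tibble(line_id = p$line_ids, value = y)
  r2 <- tibble::tibble(line_id = p$line_ids, value = 3 - 2.5 * y)
  s1 <- suppressMessages(lmm_scan(p, r1))
  s2 <- suppressMessages(lmm_scan(p, r2))
  expect_equal(s1$p, s2$p, tolerance = 1e-8)
  expect_identical(s1$variant_id, s2$variant_id)
})

test_that("mean and CVe responses share the same code path", {
  p <- toy_panel(n_lines = 30, n_variants = 25, seed = 6)
  set.seed(6)
  y <- runif(30, 0.1, 0.3)
  resp <- tibble::tibble(line_id = p$line_ids, value = y)
  sm <- suppressMessages(lmm_scan(p, resp, response_kind = "mean"))
  sc <- suppressMessages(lmm_scan(p, resp, response_kind = "cve"))
  expect_equal(sm$p, sc$p)
  expect_equal(sm$beta, sc$beta)
  expect_identical(unique(sc$response_kind), "cve")
})

test_that("a strongly planted causal variant ranks first", {
  wins <- 0L
  for (r in seq_len(10)) {
    cfg <- sim_config(n_lines = 167, n_per_line = 2, n_variants = 150,
                      n_causal_mean = 0, n_causal_var = 0, gamma_var = 1,
                      outlier_rate = 0, seed = 700 + r)
    sim <- simulate_panel(cfg)
    set.seed(800 + r)
    b <- default_trait_baselines()
    sd_line <- b$between_sd[b$trait == "EDD"]
    causal <- sim$panel$variants$variant_id[75]
    y <- rnorm(167, 0, sd_line) + 1.5 * sd_line * sim$panel$geno[, causal]
    resp <- tibble::tibble(line_id = sim$panel$line_ids, value = y)
    scan <- suppressMessages(lmm_scan(sim$panel, resp))
    if (scan$variant_id[1] == causal) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("candidate selection is select-then-filter with deterministic ties", {
  v <- tibble::tibble(variant_id = sprintf("v%03d", 1:120),
                      chrom = "chrT", pos = 1:120,
                      ref = "A", alt = "G",
                      maf = c(rep(0.02, 13), rep(0.3, 107)),
                      site_class = c(rep(NA, 110),
                                     rep("synonymous", 10)))
  rec <- tibble::tibble(variant_id = v$variant_id,
                        p = rep(1e-4, 120))  # all tied
  out <- select_candidates(rec, v, top_k = 100)
  expect_equal(nrow(out), 87)  # 13 of the 100 selected fail the MAF filter

  # tie resolution by (position, ID) is invariant to input row order
  set.seed(8)
  rec_shuf <- rec[sample.int(120), ]
  out2 <- select_candidates(rec_shuf, v, top_k = 100)
  expect_identical(sort(out$variant_id), sort(out2$variant_id))
  expect_identical(out$variant_id, out2$variant_id)

  # all high-MAF: exactly top_k retained
  v2 <- dplyr::mutate(v, maf = 0.5, site_class = NA_character_)
  expect_equal(nrow(select_candidates(rec, v2, top_k = 100)), 100)

  # synonymous drop happens after selection
  v3 <- dplyr::mutate(v, maf = 0.5)
  rec3 <- dplyr::mutate(rec, p = seq(1e-6, 1e-3, length.out = 120))
  out3 <- select_candidates(rec3, v3, top_k = 120, drop_synonymous = TRUE)
  expect_equal(nrow(out3), 110)

  expect_warning(select_candidates(rec[1:5, ], v, top_k = 100), "taking all")
})

test_that("permuted responses give uniform p-values", {
  cfg <- sim_config(n_lines = 100, n_per_line = 2, n_variants = 300,
                    n_causal_mean = 0, n_causal_var = 0, gamma_var = 1,
                    outlier_rate = 0, seed = 21)
  sim <- simulate_panel(cfg)
  ph <- simulate_phenotypes(sim$panel, cfg)
  summ <- suppressWarnings(line_summaries(ph$phenotypes, qc_rule(min_line_n = 2)))
  resp <- summ |> dplyr::filter(trait == "EDD") |>
    dplyr::select(line_id, value = mean)
  set.seed(22)
  resp$value <- sample(resp$value)
  scan <- suppressMessages(lmm_scan(sim$panel, resp))
  ks <- suppressWarnings(ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("singular fixed-effect designs name the collinear covariate", {
  p <- toy_panel(n_lines = 20, n_variants = 10, seed = 10)
  set.seed(10)
  resp <- tibble::tibble(line_id = p$line_ids, value = rnorm(20))
  covs <- tibble::tibble(line_id = p$line_ids,
                         wolbachia = rep(1, 20))  # constant = intercept
  expect_error(suppressMessages(lmm_scan(p, resp, covs)), "wolbachia")
})
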