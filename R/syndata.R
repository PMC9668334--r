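#' Configuration for synthetic inbred-panel simulations
#'
#' Bundles every tunable of the panel simulator: panel dimensions, allele
#' frequency range, numbers of mean- and variance-acting causal variants and
#' their effect sizes, per-trait baselines (population mean, within-line SD,
#' between-line SD), binary covariate settings, and the outlier rate. Defaults
#' emulate a DGRP-style screen: 167 homozygous lines, ~12 females per line,
#' seven cardiac traits on the scales observed in such panels.
#'
#' @param n_lines Number of inbred lines.
#' @param n_per_line Individuals phenotyped per line.
#' @param n_variants Number of biallelic homozygous variants.
#' @param maf_range Length-2 numeric, the range of allele frequencies
#'   (each in (0, 0.5]) variants are drawn from.
#' @param n_causal_mean,n_causal_var Number of causal variants per trait acting
#'   on the line mean and on the within-line SD, respectively.
#' @param beta_mean Mean-effect size per alternate allele, in units of the
#'   trait's within-line SD.
#' @param gamma_var Multiplicative factor applied to the within-line SD per
#'   variance-QTL alternate allele (1 = no variance effect).
#' @param trait_baselines Tibble with columns `trait`, `mean`, `within_sd`,
#'   `between_sd`. The default covers the seven cardiac traits (DI, SI, HP,
#'   EDD, ESD, FS, AI) at realistic scales; HP is always derived as DI + SI.
#' @param covariate_prevalence Prevalence of the Wolbachia-like binary
#'   covariate across lines.
#' @param covariate_effect Covariate effect on each trait, in within-line SD
#'   units.
#' @param outlier_rate Per-individual probability of a technical outlier
#'   (noise inflated tenfold, symmetric about the line mean).
#' @param ld_block_size Variants per linkage block; 1 (default) simulates
#'   independent variants, larger values correlate neighbouring variants.
#' @param missing_rate Per-genotype missingness probability (default 0).
#' @param genome_length Length in bp of the synthetic contig; defaults to a
#'   length that accommodates `n_variants` comfortably.
#' @param seed Integer seed; all simulator operations are deterministic given
#'   the config seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 167,
                       n_per_line = 12,
                       n_variants = 5000,
                       maf_range = c(0.05, 0.5),
                       n_causal_mean = 10,
                       n_causal_var = 5,
                       beta_mean = 0.3,
                       gamma_var = 1.5,
                       trait_baselines = default_trait_baselines(),
                       covariate_prevalence = 0.5,
                       covariate_effect = 0.1,
                       outlier_rate = 0.01,
                       ld_block_size = 1,
                       missing_rate = 0,
                       genome_length = NULL,
                       seed = 1L) {
  assert_count(n_lines, "n_lines")
  assert_count(n_per_line, "n_per_line")
  assert_count(n_variants, "n_variants")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5]")
  }
  if (n_causal_mean > n_variants || n_causal_var > n_variants) {
    abort("causal variant counts cannot exceed `n_variants`")
  }
  assert_prob(outlier_rate, "outlier_rate", allow_one = FALSE)
  assert_prob(covariate_prevalence, "covariate_prevalence")
  stopifnot(is.data.frame(trait_baselines),
            all(c("trait", "mean", "within_sd", "between_sd") %in%
                  names(trait_baselines)))
  if (is.null(genome_length)) genome_length <- max(20000L, 60L * n_variants)
  if (n_variants > genome_length) {
    abort("`n_variants` exceeds `genome_length`: cannot place distinct positions")
  }
  structure(
    list(n_lines = as.integer(n_lines), n_per_line = as.integer(n_per_line),
         n_variants = as.integer(n_variants), maf_range = as.numeric(maf_range),
         n_causal_mean = as.integer(n_causal_mean),
         n_causal_var = as.integer(n_causal_var),
         beta_mean = beta_mean, gamma_var = gamma_var,
         trait_baselines = tibble::as_tibble(trait_baselines),
         covariate_prevalence = covariate_prevalence,
         covariate_effect = covariate_effect,
         outlier_rate = outlier_rate,
         ld_block_size = as.integer(ld_block_size),
         missing_rate = missing_rate,
         genome_length = as.integer(genome_length),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Default per-trait baselines for the seven cardiac traits
#'
#' Population mean, within-line SD and between-line SD for diastolic interval
#' (DI, s), systolic interval (SI, s), heart period (HP = DI + SI, s), end
#' diastolic and systolic diameters (EDD, ESD, um), fractional shortening (FS)
#' and arrhythmia index (AI), at the scales observed in inbred fly panels.
#'
#' @return A tibble with columns `trait`, `mean`, `within_sd`, `between_sd`.
#' @export
default_trait_baselines <- function() {
  tibble::tribble(
    ~trait, ~mean,   ~within_sd, ~between_sd,
    "DI",   0.4638,  0.209,      0.161,
    "SI",   0.2166,  0.0231,     0.0224,
    "HP",   0.6883,  0.2196,     0.169,
    "EDD",  79.42,   9.30,       10.63,
    "ESD",  51.05,   6.82,       6.63,
    "FS",   0.3538,  0.0558,     0.0396,
    "AI",   0.2475,  0.252,      0.149)
}

#' Simulate a homozygous inbred-line panel with genome and gene models
#'
#' Generates a line-by-variant genotype matrix (0/1 haploid-equivalent coding,
#' as appropriate for fully inbred lines), a random nucleotide genome on one
#' synthetic contig, and gene models tiling that genome with UTR/exon/intron
#' substructure separated by intergenic gaps larger than 2 kb, so both
#' gene-mapped and unmapped variants exist. Variant site classes (UTR, exon
#' synonymous/non-synonymous, intron, 1-kb upstream/downstream, NA) are
#' assigned from the gene models.
#'
#' @param config A [sim_config()].
#' @return A list with elements `panel` (see Details), `genes` (gene-model
#'   tibble with one row per feature), and `genome` (a named
#'   [Biostrings::DNAStringSet]).
#' @details The panel is a list of class `panel` with `line_ids`, `geno`
#'   (lines x variants integer matrix) and `variants` (tibble with
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `maf`, `site_class`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 11), {
    chrom <- "chrS"
    L <- config$genome_length
    genome_seq <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    genome <- Biostrings::DNAStringSet(setNames(genome_seq, chrom))

    genes <- tile_gene_models(L, chrom)

    line_ids <- sprintf("line_%03d", seq_len(config$n_lines))
    n_v <- config$n_variants
    pos <- sort(sample.int(L, n_v))
    freqs <- runif(ceiling(n_v / config$ld_block_size),
                   config$maf_range[1], config$maf_range[2])
    block_of <- rep(seq_along(freqs), each = config$ld_block_size)[seq_len(n_v)]

    geno <- matrix(0L, config$n_lines, n_v,
                   dimnames = list(line_ids, sprintf("var_%05d", seq_len(n_v))))
    for (b in unique(block_of)) {
      idx <- which(block_of == b)
      base_g <- rbinom(config$n_lines, 1L, freqs[b])
      for (j in idx) {
        if (config$ld_block_size > 1 && j != idx[1]) {
          flip <- rbinom(config$n_lines, 1L, 0.1)
          geno[, j] <- ifelse(flip == 1L, 1L - base_g, base_g)
        } else {
          geno[, j] <- base_g
        }
      }
    }
    if (config$missing_rate > 0) {
      miss <- matrix(runif(length(geno)) < config$missing_rate, nrow(geno))
      geno[miss] <- NA_integer_
    }

    ref <- strsplit(genome_seq, "")[[1]][pos]
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1), "")
    p_hat <- unname(colMeans(geno, na.rm = TRUE))
    variants <- tibble::tibble(
      variant_id = colnames(geno),
      chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
      maf = pmin(p_hat, 1 - p_hat))

    variants$site_class <- assign_site_class(variants, genes)

    panel <- structure(list(line_ids = line_ids, geno = geno,
                            variants = variants),
                       class = "panel")
    list(panel = panel, genes = genes, genome = genome)
  })
}

# Tile the contig with gene/intergenic alternation. Each gene: two exons
# flanking one intron; 100-bp UTRs at the transcript ends. Gaps are > 2 kb so
# some variants fall farther than 1 kb from any gene.
tile_gene_models <- function(L, chrom) {
  feats <- list()
  cursor <- 1L
  gid <- 0L
  repeat {
    gap <- sample(2200:4000, 1)
    start <- cursor + gap
    glen <- sample(1200:3000, 1)
    end <- start + glen - 1L
    if (end + 2200L > L) break
    gid <- gid + 1L
    strand <- sample(c("+", "-"), 1)
    gene_id <- sprintf("gene_%04d", gid)
    exon1 <- c(start, start + 299L)
    exon2 <- c(end - 299L, end)
    # UTRs sit at the transcript ends; which physical end is 5' depends on strand
    utr_left <- c(start, start + 99L)
    utr_right <- c(end - 99L, end)
    u5 <- if (strand == "+") utr_left else utr_right
    u3 <- if (strand == "+") utr_right else utr_left
    feats[[length(feats) + 1L]] <- tibble::tibble(
      gene_id = gene_id, chrom = chrom, strand = strand,
      feature = c("gene", "exon", "exon", "intron",
                  "five_prime_UTR", "three_prime_UTR"),
      start = c(start, exon1[1], exon2[1], exon1[2] + 1L, u5[1], u3[1]),
      end   = c(end,   exon1[2], exon2[2], exon2[1] - 1L, u5[2], u3[2]))
    cursor <- end + 1L
  }
  dplyr::bind_rows(feats)
}

# Site class from gene structure; exonic non-UTR variants are randomly
# synonymous (30%) or non-synonymous, mimicking an annotation input.
assign_site_class <- function(variants, genes) {
  mapped <- map_variants(variants, genes)
  first_cat <- mapped |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("variant_id", "category")
  cls <- first_cat$category[match(variants$variant_id, first_cat$variant_id)]
  exon_idx <- which(!is.na(cls) & cls == "exon")
  if (length(exon_idx)) {
    syn <- rbinom(length(exon_idx), 1, 0.3) == 1
    cls[exon_idx] <- ifelse(syn, "synonymous", "non-synonymous")
  }
  cls[!is.na(cls) & cls == "5'UTR"] <- "5'UTR"
  cls
}

#' Simulate individual phenotypes on a panel
#'
#' Each individual value is trait baseline + sum of causal mean effects given
#' the line genotype + covariate effects + a line-level polygenic effect
#' (SD = `between_sd`) + within-line Gaussian noise whose SD is multiplied by
#' `gamma_var` per alternate allele at each variance-QTL. Technical outliers
#' are injected at `outlier_rate` by inflating the noise tenfold. HP is the
#' per-individual sum DI + SI.
#'
#' @param panel A panel from [simulate_panel()].
#' @param config The same [sim_config()] used to build the panel.
#' @return A list with `phenotypes` (tibble: `line_id`, `indiv_id`, one column
#'   per trait), `covariates` (tibble: `line_id`, `wolbachia`, `inv_2L`,
#'   `inv_3R`), and `truth` (list of class `truth_record`: per-trait causal
#'   mean/variance variants with effects, line genetic values, realized
#'   simulated H2).
#' @export
simulate_phenotypes <- function(panel, config) {
  stopifnot(inherits(panel, "panel"), inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 23), {
    lines <- panel$line_ids
    n_l <- length(lines)
    n_i <- config$n_per_line
    geno <- panel$geno
    geno_f <- geno
    if (anyNA(geno_f)) {
      for (j in seq_len(ncol(geno_f))) {
        nas <- is.na(geno_f[, j])
        if (any(nas)) geno_f[nas, j] <- round(mean(geno_f[, j], na.rm = TRUE))
      }
    }

    covariates <- tibble::tibble(
      line_id = lines,
      wolbachia = rbinom(n_l, 1, config$covariate_prevalence),
      inv_2L = rbinom(n_l, 1, 0.15),
      inv_3R = rbinom(n_l, 1, 0.15))

    base <- config$trait_baselines
    sim_traits <- setdiff(base$trait, "HP")

    truth <- list(causal_mean = list(), causal_var = list(),
                  line_genetic_values = list(), simulated_H2 = numeric(0))
    pheno <- tibble::tibble(
      line_id = rep(lines, each = n_i),
      indiv_id = paste0(rep(lines, each = n_i), "_",
                        rep(seq_len(n_i), times = n_l)))

    for (tr in sim_traits) {
      b <- base[base$trait == tr, ]
      cm <- if (config$n_causal_mean > 0)
        sample(colnames(geno), config$n_causal_mean) else character(0)
      cv <- if (config$n_causal_var > 0)
        sample(colnames(geno), config$n_causal_var) else character(0)
      betas <- if (length(cm))
        config$beta_mean * b$within_sd * sample(c(-1, 1), length(cm), TRUE) else numeric(0)

      snp_val <- if (length(cm)) drop(geno_f[, cm, drop = FALSE] %*% betas) else rep(0, n_l)
      polygenic <- rnorm(n_l, 0, b$between_sd)
      gvals <- snp_val + polygenic

      var_alleles <- if (length(cv))
        rowSums(geno_f[, cv, drop = FALSE]) else rep(0, n_l)
      line_sd <- b$within_sd * config$gamma_var^var_alleles

      cov_eff <- config$covariate_effect * b$within_sd *
        (covariates$wolbachia + 0.5 * covariates$inv_2L + 0.5 * covariates$inv_3R)

      line_mu <- b$mean + gvals + cov_eff
      noise_sd <- rep(line_sd, each = n_i)
      outlier <- runif(n_l * n_i) < config$outlier_rate
      noise <- rnorm(n_l * n_i, 0, noise_sd * ifelse(outlier, 10, 1))
      pheno[[tr]] <- rep(line_mu, each = n_i) + noise

      vg <- var(gvals)
      ve <- mean(line_sd^2)
      truth$causal_mean[[tr]] <- tibble::tibble(variant_id = cm, beta = betas)
      truth$causal_var[[tr]] <- tibble::tibble(variant_id = cv,
                                               gamma = rep(config$gamma_var,
                                                           length(cv)))
      truth$line_genetic_values[[tr]] <- tibble::tibble(line_id = lines,
                                                        value = gvals)
      truth$simulated_H2[tr] <- vg / (vg + ve)
    }

    pheno$HP <- pheno$DI + pheno$SI
    hp_g <- truth$line_genetic_values$DI$value + truth$line_genetic_values$SI$value
    vg_hp <- var(hp_g)
    ve_hp <- mean((base$within_sd[base$trait == "DI"] *
                     config$gamma_var^0)^2) +
      mean((base$within_sd[base$trait == "SI"])^2)
    truth$line_genetic_values$HP <- tibble::tibble(line_id = lines, value = hp_g)
    truth$simulated_H2["HP"] <- vg_hp / (vg_hp + ve_hp)
    truth$causal_mean$HP <- dplyr::bind_rows(truth$causal_mean$DI,
                                             truth$causal_mean$SI)
    truth$causal_var$HP <- dplyr::bind_rows(truth$causal_var$DI,
                                            truth$causal_var$SI)
    pheno <- pheno[, c("line_id", "indiv_id", base$trait)]
    class(truth) <- "truth_record"
    list(phenotypes = pheno, covariates = covariates, truth = truth)
  })
}

#' Simulate sequence windows with a planted motif
#'
#' Generates `n_seqs` i.i.d. background sequences of the given length and
#' nucleotide composition; a `plant_fraction` of them receive one copy of
#' `motif` at a uniformly random offset. Fixture generator for the motif
#' discovery stage.
#'
#' @param n_seqs Number of sequences.
#' @param length Sequence length in bases (must be >= `nchar(motif)`).
#' @param motif Nucleotide string to plant.
#' @param plant_fraction Fraction of sequences that carry the motif, in [0,1].
#' @param seed Integer seed.
#' @param composition Background nucleotide probabilities (A, C, G, T).
#' @return Tibble with `seq_id`, `sequence`, `planted` (logical), `offset`
#'   (1-based plant position or NA).
#' @export
simulate_motif_windows <- function(n_seqs, length, motif,
                                   plant_fraction = 0.4, seed = 1L,
                                   composition = rep(0.25, 4)) {
  assert_count(n_seqs, "n_seqs")
  assert_count(length, "length")
  assert_prob(plant_fraction, "plant_fraction")
  motif <- toupper(motif)
  if (nchar(motif) > length) abort("`length` must be at least the motif length")
  if (!grepl("^[ACGT]+$", motif)) abort("`motif` must be an A/C/G/T string")
  with_seed(seed, {
    n_plant <- round(plant_fraction * n_seqs)
    planted <- seq_len(n_seqs) <= n_plant
    seqs <- vapply(seq_len(n_seqs), function(i) {
      paste(sample(DNA_BASES, length, replace = TRUE, prob = composition),
            collapse = "")
    }, "")
    offset <- rep(NA_integer_, n_seqs)
    w <- nchar(motif)
    for (i in which(planted)) {
      off <- sample.int(length - w + 1L, 1L)
      substr(seqs[i], off, off + w - 1L) <- motif
      offset[i] <- off
    }
    tibble::tibble(seq_id = sprintf("win_%04d", seq_len(n_seqs)),
                   sequence = seqs, planted = planted, offset = offset)
  })
}
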