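#' Run the full analysis pipeline on a panel
#'
#' Orchestrates every stage in order: per-line QC and summaries, variance
#' components and Levene tests, leverage filtering, single-marker LMM scans
#' on line means and line CVe, candidate selection, focal-SNP epistasis,
#' variant-to-gene mapping with a category bias test, gene-set combination
#' and mean/CVe overlap enrichment, and (optionally) k-mer/PSSM motif
#' discovery in windows around candidate variants. All stage outputs are
#' written as TSV/JSON under `out_dir` together with a manifest (input
#' hashes, settings, seed, package version); a rerun with identical inputs
#' reproduces identical outputs.
#'
#' @param panel,phenotypes,covariates,genes,genome Inputs as produced by
#'   [simulate_panel()] and [simulate_phenotypes()]; supply your own tibbles
#'   to run on real data. `genome` may be NULL if `run_motifs = FALSE`.
#' @param out_dir Output directory (created if needed).
#' @param traits Traits to scan (default: all trait columns present).
#' @param rule A [qc_rule()].
#' @param top_k,maf_min Candidate selection settings (see
#'   [select_candidates()]).
#' @param partner_maf_min Epistasis partner MAF threshold.
#' @param n_focal Number of top candidates used as epistasis focal SNPs per
#'   trait (kept small for tractable scans).
#' @param flank,k_range,e_threshold Motif stage settings.
#' @param run_motifs Run the motif stage (requires `genome`).
#' @param seed Seed recorded in the manifest and used by stochastic stages.
#' @return A list with all stage results plus `manifest`; outputs are also
#'   written to `out_dir`.
#' @export
run_pipeline <- function(panel, phenotypes, covariates = NULL, genes = NULL,
                         genome = NULL, out_dir = tempfile("cardiogwas_run_"),
                         traits = NULL, rule = qc_rule(), top_k = 100,
                         maf_min = 0.04, partner_maf_min = 0.05,
                         n_focal = 10, flank = 75, k_range = 6:8,
                         e_threshold = 1e-4, run_motifs = FALSE, seed = 1L) {
  if (run_motifs && is.null(genome)) {
    abort("configuration error: motif stage enabled but no genome supplied")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  trait_cols <- setdiff(names(phenotypes), c("line_id", "indiv_id"))
  traits <- traits %||% trait_cols
  stopifnot(all(traits %in% trait_cols))

  summ <- line_summaries(phenotypes, rule)
  qg <- quantgen_table(phenotypes[, c("line_id", "indiv_id", traits)], rule)

  scans <- list()
  candidates <- list()
  epi <- list()
  for (tr in traits) {
    for (kind in c("mean", "cve")) {
      resp <- summ |> dplyr::filter(.data$trait == tr) |>
        dplyr::select("line_id",
                      value = dplyr::all_of(if (kind == "mean") "mean" else "cve"))
      lev <- leverage_filter(resp, rule)
      resp <- lev |> dplyr::filter(.data$retained) |>
        dplyr::select("line_id", "value")
      scan <- lmm_scan(panel, resp, covariates, response_kind = kind)
      cand <- select_candidates(scan, panel$variants, top_k = top_k,
                                maf_min = maf_min, drop_synonymous = TRUE)
      key <- paste(tr, kind, sep = "_")
      scans[[key]] <- scan
      candidates[[key]] <- cand
      focal <- head(cand$variant_id, n_focal)
      epi[[key]] <- pairwise_scan(panel, resp, focal,
                                  partner_maf_min = partner_maf_min)
    }
  }

  cand_all <- dplyr::bind_rows(candidates, .id = "scan_id")
  epi_all <- dplyr::bind_rows(epi, .id = "scan_id")

  genemap_res <- NULL
  geneset_res <- NULL
  if (!is.null(genes)) {
    mapping <- map_variants(
      dplyr::distinct(cand_all, .data$variant_id, .data$chrom, .data$pos,
                      .data$site_class), genes)
    bg_cats <- variant_categories(map_variants(panel$variants, genes)) |>
      dplyr::count(.data$category)
    cand_cats <- variant_categories(mapping) |> dplyr::count(.data$category)
    bias <- category_bias_test(cand_cats, bg_cats)
    genemap_res <- list(mapping = mapping, bias = bias)

    gene_of <- mapping |> dplyr::filter(!is.na(.data$gene_id))
    mean_keys <- grepl("_mean$", cand_all$scan_id)
    sm_genes <- unique(gene_of$gene_id[gene_of$variant_id %in%
                                         cand_all$variant_id[mean_keys]])
    epi_partners <- epi_all |> dplyr::filter(!is.na(.data$partner_id))
    epi_map <- map_variants(
      panel$variants[panel$variants$variant_id %in% epi_partners$partner_id, ],
      genes)
    epi_genes <- unique(stats::na.omit(epi_map$gene_id))
    combined <- combine_gene_sets(sm_genes, epi_genes,
                                  universe_size = dplyr::n_distinct(genes$gene_id))
    cve_genes <- unique(gene_of$gene_id[gene_of$variant_id %in%
                                          cand_all$variant_id[!mean_keys]])
    all_mean <- union(sm_genes, epi_genes)
    overlap_mc <- if (length(all_mean) && length(cve_genes))
      hypergeom_enrichment(dplyr::n_distinct(genes$gene_id),
                           length(all_mean), length(cve_genes),
                           length(intersect(all_mean, cve_genes))) else NULL
    geneset_res <- list(single_marker = sm_genes, epistasis = epi_genes,
                        combined = combined, cve = cve_genes,
                        mean_cve_overlap = overlap_mc)
  }

  motif_res <- NULL
  if (run_motifs) {
    noncoding <- cand_all |>
      dplyr::filter(is.na(.data$site_class) |
                      !.data$site_class %in% c("synonymous", "non-synonymous")) |>
      dplyr::distinct(.data$variant_id, .data$chrom, .data$pos)
    if (nrow(noncoding) >= 10) {
      wins <- extract_windows(noncoding, genome, flank = flank)
      km <- kmer_overrepresentation(wins, k_range = k_range,
                                    e_threshold = e_threshold, seed = seed)
      pss <- if (any(km$significant)) assemble_pssms(km) else list()
      motif_res <- list(windows = wins, kmers = km, pssms = pss)
    } else {
      inform("fewer than 10 non-coding candidate windows: motif stage skipped")
    }
  }

  # ---- outputs + manifest -------------------------------------------------
  files <- list(
    line_summaries = file.path(out_dir, "line_summaries.tsv"),
    quantgen = file.path(out_dir, "quantgen_table.tsv"),
    associations = file.path(out_dir, "associations.tsv"),
    candidates = file.path(out_dir, "candidates.tsv"),
    epistasis = file.path(out_dir, "epistasis.tsv"))
  readr::write_tsv(summ, files$line_summaries)
  readr::write_tsv(qg, files$quantgen)
  readr::write_tsv(dplyr::bind_rows(purrr::map(scans, tibble::as_tibble),
                                    .id = "scan_id"), files$associations)
  readr::write_tsv(cand_all, files$candidates)
  readr::write_tsv(epi_all, files$epistasis)
  if (!is.null(genemap_res)) {
    files$gene_mapping <- file.path(out_dir, "gene_mapping.tsv")
    readr::write_tsv(genemap_res$mapping, files$gene_mapping)
    files$category_bias <- file.path(out_dir, "category_bias.json")
    jsonlite::write_json(
      list(statistic = genemap_res$bias$statistic, df = genemap_res$bias$df,
           p = genemap_res$bias$p, table = genemap_res$bias$table),
      files$category_bias, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(motif_res)) {
    files$kmers <- file.path(out_dir, "kmers.tsv")
    readr::write_tsv(tibble::as_tibble(motif_res$kmers), files$kmers)
    if (length(motif_res$pssms)) {
      files$pssms <- file.path(out_dir, "pssms.meme")
      write_meme(motif_res$pssms, files$pssms)
    }
  }
  settings <- list(traits = traits, qc_k = rule$k,
                   min_line_n = rule$min_line_n, top_k = top_k,
                   maf_min = maf_min, partner_maf_min = partner_maf_min,
                   n_focal = n_focal, flank = flank,
                   k_range = as.integer(k_range), e_threshold = e_threshold,
                   seed = as.integer(seed))
  manifest <- list(
    package = "cardiogwas",
    version = as.character(utils::packageVersion("cardiogwas")),
    settings = settings,
    input_hashes = list(
      genotypes = digest::digest(panel$geno),
      phenotypes = digest::digest(phenotypes)),
    output_hashes = purrr::map(files, ~ digest::digest(file = .x)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  list(line_summaries = summ, quantgen = qg, scans = scans,
       candidates = candidates, epistasis = epi_all, genemap = genemap_res,
       gene_sets = geneset_res, motifs = motif_res, manifest = manifest,
       out_dir = out_dir)
}
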