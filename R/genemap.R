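#' Map variants to genes by transcription-unit and 1-kb flank rules
#'
#' A variant is associated with a gene (i) if it lies inside the gene's
#' transcription unit (intron, exon, 5' or 3' UTR); (ii) otherwise, if its
#' distance from the nearer gene-span boundary (TSS or TES) is at most
#' `max_dist` bp, in which case the strand decides the upstream/downstream
#' label; (iii) otherwise it is unmapped (NA). Rule (i) takes precedence over
#' rule (ii) for the same gene; a variant may map to several genes (e.g.
#' inside one gene and within 1 kb of another).
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos` and optionally
#'   `site_class` (used to split exonic hits into synonymous /
#'   non-synonymous; codon effects are consumed, never recomputed).
#' @param genes Gene-model tibble as produced by [simulate_panel()] or
#'   [read_gene_models()]: columns `gene_id`, `chrom`, `strand`, `feature`
#'   (`gene`, `exon`, `intron`, `five_prime_UTR`, `three_prime_UTR`),
#'   `start`, `end` (1-based inclusive).
#' @param max_dist Flank distance in bp for rule (ii); 1000 ("within 1 kb",
#'   inclusive) by default.
#' @return Tibble with one row per (variant, gene) mapping, columns
#'   `variant_id`, `gene_id`, `category`; unmapped variants get a single row
#'   with `gene_id = NA`, `category = NA`. Categories: `5'UTR`, `3'UTR`,
#'   `exon` (or `exon_syn`/`exon_nonsyn` when `site_class` is available),
#'   `intron`, `upstream_1kb`, `downstream_1kb`.
#' @export
map_variants <- function(variants, genes, max_dist = 1000) {
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)))
  gene_spans <- genes |> dplyr::filter(.data$feature == "gene")
  has_class <- "site_class" %in% names(variants)

  out <- list()
  for (chr in unique(variants$chrom)) {
    v <- variants[variants$chrom == chr, ]
    ord <- order(v$pos)
    v <- v[ord, ]
    g <- gene_spans[gene_spans$chrom == chr, ]
    if (nrow(g) == 0) next
    sub <- genes[genes$chrom == chr & genes$feature != "gene", ]
    for (i in seq_len(nrow(g))) {
      lo <- g$start[i] - max_dist
      hi <- g$end[i] + max_dist
      j0 <- findInterval(lo - 1L, v$pos)
      j1 <- findInterval(hi, v$pos)
      if (j1 <= j0) next
      hit <- v[(j0 + 1L):j1, ]
      inside <- hit$pos >= g$start[i] & hit$pos <= g$end[i]
      cat <- character(nrow(hit))
      if (any(inside)) {
        feats <- sub[sub$gene_id == g$gene_id[i], ]
        for (m in which(inside)) {
          cat[m] <- classify_in_gene(hit$pos[m], feats,
                                     if (has_class) hit$site_class[m] else NA)
        }
      }
      if (any(!inside)) {
        upstream_side <- if (g$strand[i] == "+")
          hit$pos[!inside] < g$start[i] else hit$pos[!inside] > g$end[i]
        cat[!inside] <- ifelse(upstream_side, "upstream_1kb", "downstream_1kb")
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        variant_id = hit$variant_id, gene_id = g$gene_id[i], category = cat)
    }
  }
  mapped <- dplyr::bind_rows(out)
  if (nrow(mapped) == 0) {
    mapped <- tibble::tibble(variant_id = character(0),
                             gene_id = character(0),
                             category = character(0))
  }
  unmapped <- setdiff(variants$variant_id, mapped$variant_id)
  dplyr::bind_rows(
    mapped,
    tibble::tibble(variant_id = unmapped, gene_id = NA_character_,
                   category = NA_character_)) |>
    dplyr::arrange(match(.data$variant_id, variants$variant_id))
}

# Category of a position inside a gene body: UTRs beat exon beats intron.
classify_in_gene <- function(pos, feats, site_class = NA) {
  in_feat <- function(f) {
    rows <- feats[feats$feature == f, ]
    any(pos >= rows$start & pos <= rows$end)
  }
  if (in_feat("five_prime_UTR")) return("5'UTR")
  if (in_feat("three_prime_UTR")) return("3'UTR")
  if (in_feat("exon")) {
    if (!is.na(site_class) && site_class == "synonymous") return("exon_syn")
    if (!is.na(site_class) && site_class == "non-synonymous") return("exon_nonsyn")
    return("exon")
  }
  "intron"
}

#' Map a single variant
#'
#' Convenience wrapper around [map_variants()] for one variant.
#'
#' @inheritParams map_variants
#' @param variant One-row tibble (or list coercible to one).
#' @return Tibble of mappings for that variant.
#' @export
map_variant <- function(variant, genes, max_dist = 1000) {
  map_variants(tibble::as_tibble(variant), genes, max_dist)
}

#' One category per variant, by precedence
#'
#' For category counting each variant contributes a single category: gene-body
#' categories (UTRs, exon, intron) beat `upstream_1kb`, which beats
#' `downstream_1kb`; unmapped variants count as `"NA"`.
#'
#' @param mapping Output of [map_variants()].
#' @return Tibble `variant_id`, `category` with one row per variant.
#' @export
variant_categories <- function(mapping) {
  prec <- c("5'UTR" = 1, "3'UTR" = 2, exon_nonsyn = 3, exon_syn = 4, exon = 5,
            intron = 6, upstream_1kb = 7, downstream_1kb = 8)
  mapping |>
    dplyr::mutate(category = ifelse(is.na(.data$category), "NA", .data$category),
                  .rank = dplyr::coalesce(prec[.data$category], 9)) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::arrange(.data$.rank, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("variant_id", "category")
}

#' Chi-square test for genomic-location bias of candidate variants
#'
#' Compares candidate site-category counts against the category distribution
#' of a background variant set (e.g. all panel variants above the MAF filter).
#' Expected counts are background proportions scaled to the candidate total;
#' the statistic is the Pearson chi-square with per-category Pearson residuals
#' (O - E) / sqrt(E), whose squares sum to the statistic.
#'
#' @param observed Named numeric vector (or two-column tibble
#'   `category`, `n`) of candidate counts per category.
#' @param background Same shape, counts for the background set; must cover
#'   every candidate category with a positive count.
#' @return A list of class `category_bias` with `table` (tibble: category,
#'   observed, expected, residual), `statistic`, `df`, `p`.
#' @export
category_bias_test <- function(observed, background) {
  obs <- as_count_vector(observed)
  bg <- as_count_vector(background)
  missing_bg <- setdiff(names(obs)[obs > 0], names(bg)[bg > 0])
  if (length(missing_bg)) {
    abort(paste0("categories absent from background: ",
                 paste(missing_bg, collapse = ", "),
                 "; merge sparse categories before testing"))
  }
  cats <- names(bg)
  obs <- setNames(obs[match(cats, names(obs))], cats)
  obs[is.na(obs)] <- 0
  expected <- bg / sum(bg) * sum(obs)
  resid <- (obs - expected) / sqrt(expected)
  stat <- sum(resid^2)
  df <- length(cats) - 1L
  structure(list(
    table = tibble::tibble(category = cats, observed = unname(obs),
                           expected = unname(expected),
                           residual = unname(resid)),
    statistic = stat, df = df,
    p = stats::pchisq(stat, df, lower.tail = FALSE)),
    class = "category_bias")
}

as_count_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    setNames(as.numeric(x[[2]]), as.character(x[[1]]))
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

#' @export
print.category_bias <- function(x, ...) {
  cat(sprintf("Category bias chi-square: X2 = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p))
  print(x$table)
  invisible(x)
}
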