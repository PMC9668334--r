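#' Overlap coefficient between two gene sets
#'
#' |A intersect B| / min(|A|, |B|): 1 when one set contains the other, 0 when
#' disjoint.
#'
#' @param a,b Character vectors of gene IDs (duplicates are dropped).
#' @return A single fraction in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) abort("gene sets must be non-empty")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Hypergeometric enrichment with fold change
#'
#' Given a universe of N genes of which K belong to a category, and a sample
#' of n genes with k hits, reports the expected hit count n*K/N, the fold
#' change FC = k / expected (observed over expected), and the exact
#' upper-tail hypergeometric p-value P(X >= k), computed in log space so
#' p-values far below double precision underflow remain usable.
#'
#' @param N Universe size.
#' @param K Category size.
#' @param n Sample size.
#' @param k Observed hits.
#' @return A list of class `enrichment` with `N`, `K`, `n`, `k`, `expected`,
#'   `fc`, `p`, `log10_p`.
#' @examples
#' hypergeom_enrichment(N = 17500, K = 562, n = 566, k = 92)
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  for (v in c(N, K, n, k)) if (v < 0 || v != round(v))
    abort("all counts must be non-negative integers")
  if (K > N || n > N) abort("`K` and `n` cannot exceed `N`")
  if (k > min(n, K)) abort("`k` cannot exceed min(n, K)")
  if (k < max(0, n + K - N)) abort("`k` below the feasible minimum")
  expected <- n * K / N
  log_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  structure(list(N = N, K = K, n = n, k = k, expected = expected,
                 fc = if (expected > 0) k / expected else NA_real_,
                 p = exp(log_p), log10_p = log_p / log(10)),
            class = "enrichment")
}

#' @export
print.enrichment <- function(x, ...) {
  cat(sprintf(
    "Hypergeometric enrichment: k = %d / n = %d vs K = %d / N = %d\n",
    x$k, x$n, x$K, x$N))
  cat(sprintf("  expected = %.4g, FC = %.3g, p = %.3g (log10 p = %.2f)\n",
              x$expected, x$fc, x$p, x$log10_p))
  invisible(x)
}

#' @rdname hypergeom_enrichment
#' @param x An `enrichment` object.
#' @param ... Unused.
#' @export
tidy.enrichment <- function(x, ...) {
  tibble::tibble(N = x$N, K = x$K, n = x$n, k = x$k, expected = x$expected,
                 fc = x$fc, p.value = x$p, log10_p = x$log10_p)
}

#' Combine single-marker and epistasis gene sets
#'
#' Union and intersection bookkeeping for the two association routes, plus
#' the hypergeometric enrichment of the intersection against a stated
#' universe. Inclusion-exclusion (|A u B| + |A n B| = |A| + |B|) is asserted
#' on every call.
#'
#' @param single_marker,epistatic Character vectors of gene IDs.
#' @param universe_size Number of genes in the universe the two sets were
#'   drawn from.
#' @return List with `union`, `intersection`, `n_union`, `n_intersection`,
#'   and `enrichment` (an `enrichment` object for the overlap).
#' @export
combine_gene_sets <- function(single_marker, epistatic, universe_size) {
  a <- unique(single_marker); b <- unique(epistatic)
  u <- union(a, b); i <- intersect(a, b)
  stopifnot(length(u) + length(i) == length(a) + length(b))
  enr <- hypergeom_enrichment(universe_size, length(a), length(b), length(i))
  list(union = u, intersection = i,
       n_union = length(u), n_intersection = length(i), enrichment = enr)
}

#' Fly-to-human conservation enrichment table
#'
#' Row 1 tests whether a candidate gene list is enriched for genes bearing a
#' human orthologue, against the whole-genome universe. Each disease row
#' tests, within the orthologue-bearing sub-universe, whether the candidate
#' genes' orthologues are over-represented in a human disease gene list (a
#' fly gene counts as a hit if any of its orthologues is in the list).
#'
#' @param gene_set Character vector of candidate fly gene IDs.
#' @param label Label for the gene set column.
#' @param orthologs Tibble `fly_gene`, `human_gene` (optionally `rank`;
#'   filter upstream if only high/moderate-confidence pairs are wanted).
#' @param disease_lists Named list of character vectors of human gene IDs.
#' @param genome_size Total number of genes in the fly genome universe.
#' @return Tibble with one row per test: `set`, `test`, `universe`, `K`,
#'   `n`, `k`, `expected`, `fc`, `p`.
#' @export
conservation_table <- function(gene_set, label, orthologs, disease_lists,
                               genome_size) {
  gene_set <- unique(gene_set)
  ortho_fly <- unique(orthologs$fly_gene)
  n_missing <- sum(!gene_set %in% ortho_fly)
  if (n_missing > 0) {
    inform(sprintf(
      "%d candidate gene(s) absent from the orthologue map: treated as orthologue-free",
      n_missing))
  }
  with_ortho <- intersect(gene_set, ortho_fly)
  r1 <- hypergeom_enrichment(genome_size, length(ortho_fly),
                             length(gene_set), length(with_ortho))
  rows <- list(tibble::tibble(set = label, test = "human_orthologue",
                              universe = r1$N, K = r1$K, n = r1$n, k = r1$k,
                              expected = r1$expected, fc = r1$fc, p = r1$p))
  for (nm in names(disease_lists)) {
    hg <- unique(disease_lists[[nm]])
    if (length(hg) == 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        set = label, test = nm, universe = NA_integer_, K = 0L,
        n = length(with_ortho), k = NA_integer_, expected = NA_real_,
        fc = NA_real_, p = NA_real_)
      next
    }
    # fly genes whose any orthologue is a disease gene, within the
    # orthologue-bearing sub-universe
    fly_hits_all <- unique(orthologs$fly_gene[orthologs$human_gene %in% hg])
    r <- hypergeom_enrichment(length(ortho_fly), length(fly_hits_all),
                              length(with_ortho),
                              length(intersect(with_ortho, fly_hits_all)))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      set = label, test = nm, universe = r$N, K = r$K, n = r$n, k = r$k,
      expected = r$expected, fc = r$fc, p = r$p)
  }
  dplyr::bind_rows(rows)
}
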