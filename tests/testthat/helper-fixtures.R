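# Shared fixture builders. Everything is generated in code at test time.

# A tiny deterministic panel built by hand (no simulator involved), for
# oracle tests that must not depend on the simulator.
toy_panel <- function(n_lines = 12, n_variants = 8, seed = 42) {
  set.seed(seed)
  line_ids <- sprintf("L%02d", seq_len(n_lines))
  geno <- matrix(rbinom(n_lines * n_variants, 1, 0.4), n_lines, n_variants,
                 dimnames = list(line_ids,
                                 sprintf("v%03d", seq_len(n_variants))))
  # ensure polymorphism
  for (j in seq_len(n_variants)) {
    if (length(unique(geno[, j])) == 1) geno[1, j] <- 1L - geno[1, j]
  }
  variants <- tibble::tibble(
    variant_id = colnames(geno), chrom = "chrT",
    pos = sort(sample.int(1e5, n_variants)),
    ref = "A", alt = "G",
    maf = pmin(colMeans(geno), 1 - colMeans(geno)),
    site_class = NA_character_)
  structure(list(line_ids = line_ids, geno = geno, variants = variants),
            class = "panel")
}

# Gene models written out by hand for the mapping rule tests.
toy_genes <- function() {
  gene <- function(id, start, end, strand) {
    u5 <- if (strand == "+") c(start, start + 49L) else c(end - 49L, end)
    u3 <- if (strand == "+") c(end - 49L, end) else c(start, start + 49L)
    starts <- c(start, start, end - 199L, start + 200L, u5[1], u3[1])
    ends <- c(end, start + 199L, end, end - 200L, u5[2], u3[2])
    tibble::tibble(
      gene_id = id, chrom = "chrT", strand = strand,
      feature = c("gene", "exon", "exon", "intron",
                  "five_prime_UTR", "three_prime_UTR"),
      start = starts, end = ends)
  }
  dplyr::bind_rows(
    gene("gA", 5000L, 8000L, "+"),
    gene("gB", 12000L, 15000L, "-"))
}

# A sharp probability matrix for a consensus string.
consensus_pssm <- function(s, id = s, p = 0.97) {
  ch <- strsplit(s, "")[[1]]
  m <- matrix((1 - p) / 3, 4, length(ch),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(ch)) m[ch[j], j] <- p
  pssm(m, id)
}

# Long-format phenotype table with given per-line values for one trait.
pheno_from_lines <- function(values_by_line, trait = "EDD") {
  rows <- purrr::imap(values_by_line, function(v, nm) {
    tibble::tibble(line_id = nm,
                   indiv_id = paste0(nm, "_", seq_along(v)),
                   value = v)
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "value"] <- trait
  out
}
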