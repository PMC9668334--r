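# File-format interfaces. Genotypes travel as VCF (one pseudo-sample per
# line, homozygous GT only) or as a plain TSV matrix; phenotypes as CSV; gene
# models as GFF3; PSSM libraries in MEME minimal format.

#' Write / read a phenotype table as CSV
#'
#' Columns: `line_id`, `indiv_id`, then one column per trait.
#'
#' @param phenotypes Phenotype tibble.
#' @param path File path.
#' @return `read_phenotypes_csv()` returns the tibble.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(line_id = "c", indiv_id = "c"))
}

#' Write / read a panel as TSV (genotype matrix + variant metadata)
#'
#' @param panel A `panel`.
#' @param geno_path Path for the genotype matrix TSV (first column
#'   `line_id`, then one 0/1 column per variant).
#' @param variants_path Path for the variant metadata TSV.
#' @return `read_panel_tsv()` returns a `panel`.
#' @export
write_panel_tsv <- function(panel, geno_path, variants_path) {
  g <- tibble::as_tibble(panel$geno)
  g <- dplyr::bind_cols(tibble::tibble(line_id = panel$line_ids), g)
  readr::write_tsv(g, geno_path)
  readr::write_tsv(panel$variants, variants_path)
  invisible(geno_path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(geno_path, variants_path) {
  g <- readr::read_tsv(geno_path, show_col_types = FALSE)
  variants <- readr::read_tsv(variants_path, show_col_types = FALSE)
  line_ids <- as.character(g$line_id)
  geno <- as.matrix(g[, setdiff(names(g), "line_id")])
  storage.mode(geno) <- "integer"
  rownames(geno) <- line_ids
  structure(list(line_ids = line_ids, geno = geno,
                 variants = tibble::as_tibble(variants)),
            class = "panel")
}

#' Write / read a panel as VCF
#'
#' One pseudo-sample per inbred line; genotypes are written as homozygous
#' `0/0` / `1/1` calls (missing as `./.`), the natural encoding for fully
#' inbred lines. Reading uses the `vcfR` parser and rejects heterozygous
#' calls.
#'
#' @param panel A `panel`.
#' @param path VCF file path (plain text).
#' @param contig_length Optional contig length for the header.
#' @return `read_panel_vcf()` returns a `panel` (with `site_class` NA; join
#'   an annotation table for site classes).
#' @export
write_panel_vcf <- function(panel, path, contig_length = NULL) {
  v <- panel$variants
  gt <- t(panel$geno)
  gt_chr <- matrix("./.", nrow(gt), ncol(gt))
  gt_chr[!is.na(gt) & gt == 0L] <- "0/0"
  gt_chr[!is.na(gt) & gt == 1L] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cardiogwas",
    if (!is.null(contig_length))
      sprintf("##contig=<ID=%s,length=%d>", unique(v$chrom)[1], contig_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$line_ids), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "GT", apply(gt_chr, 1, paste, collapse = "\t"), sep = "\t")
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' @rdname write_panel_vcf
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(gt %in% c("0/1", "1/0", "0|1", "1|0"))) {
    abort("heterozygous calls found: panel lines must be homozygous")
  }
  geno <- matrix(NA_integer_, ncol(gt), nrow(gt),
                 dimnames = list(colnames(gt), rownames(gt)))
  geno[t(gt) %in% c("0/0", "0|0")] <- 0L
  geno[t(gt) %in% c("1/1", "1|1")] <- 1L
  fix <- tibble::as_tibble(vcfR::getFIX(vcf))
  p_hat <- colMeans(geno, na.rm = TRUE)
  variants <- tibble::tibble(
    variant_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, maf = pmin(p_hat, 1 - p_hat),
    site_class = NA_character_)
  structure(list(line_ids = rownames(geno), geno = geno, variants = variants),
            class = "panel")
}

#' Write / read gene models as GFF3
#'
#' The writer serializes the gene-model tibble (1-based inclusive
#' coordinates); the reader parses GFF3 via `rtracklayer` and returns the
#' same tibble layout, deriving `gene_id` from the `ID` / `Parent`
#' attributes.
#'
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `strand`, `feature`,
#'   `start`, `end`).
#' @param path GFF3 file path.
#' @return `read_gene_models()` returns the gene-model tibble.
#' @export
write_gff3 <- function(genes, path) {
  attrs <- ifelse(genes$feature == "gene",
                  paste0("ID=", genes$gene_id),
                  paste0("Parent=", genes$gene_id))
  lines <- paste(genes$chrom, "cardiogwas", genes$feature, genes$start,
                 genes$end, ".", genes$strand, ".", attrs, sep = "\t")
  readr::write_lines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  d <- tibble::as_tibble(as.data.frame(gr))
  gene_id <- ifelse(d$type == "gene", as.character(d$ID),
                    vapply(d$Parent, function(p)
                      if (length(p)) as.character(p[[1]]) else NA_character_,
                      ""))
  tibble::tibble(gene_id = gene_id, chrom = as.character(d$seqnames),
                 strand = as.character(d$strand),
                 feature = as.character(d$type),
                 start = as.integer(d$start), end = as.integer(d$end))
}

#' Write / read a PSSM library in MEME minimal format
#'
#' @param pssms List of `pssm` objects.
#' @param path File path.
#' @param background Background letter frequencies written to the header.
#' @return `read_meme()` returns a named list of `pssm` objects.
#' @export
write_meme <- function(pssms, path, background = rep(0.25, 4)) {
  if (inherits(pssms, "pssm")) pssms <- list(pssms)
  out <- c("MEME version 4", "",
           "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                   background[2], background[3], background[4]), "")
  for (p in pssms) {
    out <- c(out,
             paste("MOTIF", p$id, p$consensus),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                     p$width, p$nsites),
             apply(p$mat, 2, function(col)
               paste(sprintf("%.6f", col), collapse = "  ")),
             "")
  }
  readr::write_lines(out, path)
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readr::read_lines(path)
  idx <- grep("^MOTIF\\b", lines)
  out <- list()
  for (i in idx) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    id <- toks[2]
    hdr <- grep("letter-probability matrix", lines[seq(i, length(lines))])[1]
    hline <- lines[i + hdr - 1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hline))
    ns <- if (grepl("nsites=", hline))
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hline)) else 20L
    rows <- lines[(i + hdr):(i + hdr + w - 1)]
    mat <- vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4))
    dimnames(mat) <- NULL
    mat <- sweep(mat, 2, colSums(mat), "/")  # renormalize file rounding
    out[[id]] <- pssm(mat, id, nsites = ns)
  }
  out
}

#' Write gene sets as one-ID-per-line text
#'
#' @param genes Character vector of gene IDs.
#' @param path File path.
#' @return `read_gene_set()` returns the character vector.
#' @export
write_gene_set <- function(genes, path) {
  readr::write_lines(unique(genes), path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  readr::read_lines(path)
}
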