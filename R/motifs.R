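#' Extract plus-strand sequence windows around variants
#'
#' Each variant position is extended `flank` bases to both sides (151-bp
#' windows at the default 75) and the plus-strand sequence is retrieved from
#' the genome. Windows are clipped (and flagged) at contig edges; duplicate
#' windows from nearby variants are retained. Multi-nucleotide reference
#' alleles are anchored at their first base.
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos`.
#' @param genome A named [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param flank Bases added on each side (default 75).
#' @return Tibble `variant_id`, `chrom`, `start`, `end`, `clipped`,
#'   `sequence`.
#' @export
extract_windows <- function(variants, genome, flank = 75) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  nm <- sub("\\s.*$", "", names(genome))
  lens <- setNames(Biostrings::width(genome), nm)
  missing_chr <- setdiff(unique(variants$chrom), nm)
  if (length(missing_chr)) {
    abort(paste0("chromosome(s) absent from genome: ",
                 paste(missing_chr, collapse = ", ")))
  }
  beyond <- variants$pos > lens[variants$chrom] | variants$pos < 1
  if (any(beyond)) {
    abort(paste0("variant position beyond contig length: ",
                 paste(variants$variant_id[beyond], collapse = ", ")))
  }
  start <- pmax(1L, variants$pos - flank)
  end <- pmin(unname(lens[variants$chrom]), variants$pos + flank)
  seqs <- vapply(seq_len(nrow(variants)), function(i) {
    as.character(Biostrings::subseq(genome[[match(variants$chrom[i], nm)]],
                                    start[i], end[i]))
  }, "")
  tibble::tibble(variant_id = variants$variant_id, chrom = variants$chrom,
                 start = start, end = end,
                 clipped = start != variants$pos - flank |
                   end != variants$pos + flank,
                 sequence = seqs)
}

# Accept a window tibble (sequence column), character vector or DNAStringSet.
windows_to_dss <- function(windows) {
  if (inherits(windows, "DNAStringSet")) return(windows)
  if (is.data.frame(windows)) {
    stopifnot("sequence" %in% names(windows))
    return(Biostrings::DNAStringSet(windows$sequence))
  }
  Biostrings::DNAStringSet(windows)
}

# Strand-symmetric k-mer counts (forward counts of seqs and their reverse
# complements, summed).
kmer_counts_sym <- function(dss, k) {
  fwd <- colSums(Biostrings::oligonucleotideFrequency(dss, k))
  rev <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::reverseComplement(dss), k))
  fwd + rev
}

#' k-mer over-representation in variant windows
#'
#' Counts each k-mer (identified with its reverse complement) on the forward
#' strand of the windows and tests its count against a background expectation
#' with a one-sided binomial upper tail. Two background models: `intrinsic`
#' fits an order-(k-2) Markov model on the windows themselves (short k-mer
#' frequencies predict long k-mer frequencies, so only words exceeding their
#' own compositional expectation score); `random` estimates k-mer frequencies
#' from composition-matched shuffled sequences (or user-supplied background
#' sequences). The E-value is the p-value scaled by the number of distinct
#' canonical k-mers tested at that k; words with E <= `e_threshold` are
#' flagged significant.
#'
#' @param windows Window tibble from [extract_windows()] /
#'   [simulate_motif_windows()], a character vector, or a DNAStringSet.
#' @param k_range Integer vector of word lengths (default 6:8).
#' @param background `"intrinsic"` (default) or `"random"`.
#' @param e_threshold Significance threshold on the E-value (default 1e-4).
#' @param bg_seqs Optional background sequences for the `random` model; by
#'   default each window is letter-shuffled `n_shuffles` times (replication
#'   keeps the sampling noise of the background estimate well below the
#'   signal tested for).
#' @param n_shuffles Shuffle replicates per window for the default random
#'   background (default 10).
#' @param seed Seed for the shuffle (random background only).
#' @return Tibble of class `kmer_table`: `kmer` (canonical form), `k`,
#'   `observed`, `expected`, `p`, `e_value`, `significant`, ordered by
#'   ascending p.
#' @export
kmer_overrepresentation <- function(windows, k_range = 6:8,
                                    background = c("intrinsic", "random"),
                                    e_threshold = 1e-4, bg_seqs = NULL,
                                    n_shuffles = 10L, seed = 1L) {
  background <- match.arg(background)
  dss <- windows_to_dss(windows)
  if (length(dss) < 10) abort("need at least 10 windows")
  if (max(k_range) > min(Biostrings::width(dss))) {
    abort("k exceeds the shortest window length")
  }

  bg_dss <- NULL
  if (background == "random") {
    bg_dss <- if (!is.null(bg_seqs)) windows_to_dss(bg_seqs) else
      with_seed(seed, do.call(c, replicate(n_shuffles, shuffle_letters(dss),
                                           simplify = FALSE)))
  }

  out <- purrr::map(k_range, function(k) {
    cnt_fwd <- colSums(Biostrings::oligonucleotideFrequency(dss, k))
    kmers <- names(cnt_fwd)
    rc <- revcomp(kmers)
    canon <- ifelse(kmers <= rc, kmers, rc)
    obs <- tapply(cnt_fwd, canon, sum)      # k-mer + reverse complement
    n_trials <- sum(Biostrings::width(dss) - k + 1L)

    p_exp_single <- switch(background,
      intrinsic = markov_expected(dss, k),
      random = {
        cnt_bg <- colSums(Biostrings::oligonucleotideFrequency(bg_dss, k))
        n_bg <- sum(Biostrings::width(bg_dss) - k + 1L)
        (cnt_bg + 0.5) / (n_bg + 0.5 * length(cnt_bg))
      })
    p_canon <- tapply(p_exp_single[kmers], canon, sum)
    p_canon <- pmin(p_canon, 1)

    kc <- names(obs)
    pv <- stats::pbinom(obs - 1, n_trials, p_canon[kc], lower.tail = FALSE)
    n_tested <- length(obs)
    tibble::tibble(kmer = kc, k = k, observed = as.integer(obs),
                   expected = n_trials * as.numeric(p_canon[kc]),
                   p = as.numeric(pv),
                   e_value = pmin(as.numeric(pv) * n_tested, Inf)) |>
      dplyr::mutate(significant = .data$e_value <= e_threshold)
  })
  res <- dplyr::bind_rows(out) |> dplyr::arrange(.data$p, .data$kmer)
  class(res) <- c("kmer_table", class(res))
  res
}

# Expected k-mer frequency under an order-(k-2) Markov model estimated from
# the windows: p(w) = f(prefix_{k-1}) * f(suffix_{k-1}) / f(middle_{k-2}).
markov_expected <- function(dss, k) {
  stopifnot(k >= 2)
  f1 <- kmer_counts_sym(dss, k - 1L)
  f1 <- f1 / sum(f1)
  kmers <- Biostrings::mkAllStrings(DNA_BASES, k)
  pre <- substr(kmers, 1, k - 1)
  suf <- substr(kmers, 2, k)
  if (k == 2) {
    p <- f1[pre] * f1[suf]
  } else {
    f2 <- kmer_counts_sym(dss, k - 2L)
    f2 <- f2 / sum(f2)
    mid <- substr(kmers, 2, k - 1)
    denom <- f2[mid]
    p <- ifelse(denom > 0, f1[pre] * f1[suf] / denom, 0)
  }
  p[is.na(p)] <- 0
  setNames(pmin(as.numeric(p), 1), kmers)
}

shuffle_letters <- function(dss) {
  Biostrings::DNAStringSet(vapply(as.character(dss), function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE))
}

#' Position-specific scoring matrix
#'
#' @param mat 4 x width numeric matrix, rows A/C/G/T, each column summing
#'   to 1.
#' @param id Motif identifier.
#' @param source_kmers Optional character vector of the k-mers the matrix was
#'   assembled from.
#' @param nsites Number of supporting sites (used when writing MEME format).
#' @return An object of class `pssm`.
#' @export
pssm <- function(mat, id, source_kmers = character(0), nsites = 20L) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4)
  rownames(mat) <- DNA_BASES
  if (any(abs(colSums(mat) - 1) > 1e-6)) {
    abort("PSSM columns must each sum to 1")
  }
  structure(list(id = id, mat = mat, width = ncol(mat),
                 consensus = pssm_consensus(mat),
                 source_kmers = source_kmers, nsites = as.integer(nsites)),
            class = "pssm")
}

pssm_consensus <- function(mat) {
  paste(DNA_BASES[apply(mat, 2, which.max)], collapse = "")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM %s (width %d): consensus %s\n", x$id, x$width,
              x$consensus))
  print(round(x$mat, 3))
  invisible(x)
}

reverse_complement_pssm <- function(p) {
  m <- p$mat[c("T", "G", "C", "A"), rev(seq_len(p$width)), drop = FALSE]
  rownames(m) <- DNA_BASES
  pssm(m, paste0(p$id, "_rc"), revcomp(p$source_kmers), p$nsites)
}

#' Assemble significant k-mers into PSSMs
#'
#' Greedy agglomeration: the most significant unassigned k-mer seeds a
#' cluster; remaining k-mers join if they align to the cluster consensus
#' (either orientation) with an overlap of at least their length minus 2 and
#' at most one mismatch. Column probabilities come from the
#' observation-weighted base counts of the merged k-mers plus a pseudocount
#' of 0.25 per base; k-mers that never merge become single-k-mer PSSMs.
#'
#' @param kmer_results A [kmer_overrepresentation()] table (only rows with
#'   `significant == TRUE` are used unless none are flagged, in which case an
#'   error is raised).
#' @param pseudocount Added to every base count per column (default 0.25).
#' @return List of `pssm` objects, ordered by seed significance.
#' @export
assemble_pssms <- function(kmer_results, pseudocount = 0.25) {
  sig <- kmer_results |> dplyr::filter(.data$significant) |>
    dplyr::arrange(.data$p, .data$kmer)
  if (nrow(sig) == 0) abort("no significant k-mers to assemble")
  remaining <- sig
  out <- list()
  while (nrow(remaining) > 0) {
    seedrow <- remaining[1, ]
    remaining <- remaining[-1, ]
    members <- tibble::tibble(kmer = seedrow$kmer, offset = 0L,
                              weight = seedrow$observed)
    consensus <- seedrow$kmer
    if (nrow(remaining) > 0) {
      keep <- rep(TRUE, nrow(remaining))
      for (i in seq_len(nrow(remaining))) {
        cand <- remaining$kmer[i]
        al <- best_alignment(consensus, cand)
        if (!is.null(al)) {
          # alignment offsets are relative to the current consensus string,
          # whose origin is the leftmost member offset
          members <- dplyr::bind_rows(members, tibble::tibble(
            kmer = al$kmer, offset = al$offset + min(members$offset),
            weight = remaining$observed[i]))
          consensus <- members_consensus(members)
          keep[i] <- FALSE
        }
      }
      remaining <- remaining[keep, ]
    }
    out[[length(out) + 1L]] <- members_to_pssm(
      members, sprintf("motif_%02d", length(out) + 1L), pseudocount)
  }
  out
}

# Best qualifying alignment of `cand` (or its reverse complement) against the
# consensus: overlap >= nchar(cand) - 2, at most 1 mismatch; prefers larger
# overlap then fewer mismatches. Returns NULL if none qualifies.
best_alignment <- function(consensus, cand) {
  best <- NULL
  for (s in unique(c(cand, revcomp(cand)))) {
    lk <- nchar(s); lc <- nchar(consensus)
    for (off in seq(-(lk - 1L), lc - 1L)) {
      a0 <- max(1L, 1L + off); a1 <- min(lc, off + lk)
      ov <- a1 - a0 + 1L
      if (ov < lk - 2L) next
      cs <- substr(consensus, a0, a1)
      ks <- substr(s, a0 - off, a1 - off)
      mm <- sum(strsplit(cs, "")[[1]] != strsplit(ks, "")[[1]])
      if (mm > 1) next
      score <- c(ov, -mm)
      if (is.null(best) || score[1] > best$score[1] ||
          (score[1] == best$score[1] && score[2] > best$score[2])) {
        best <- list(kmer = s, offset = as.integer(off), score = score)
      }
    }
  }
  if (is.null(best)) NULL else best[c("kmer", "offset")]
}

members_counts <- function(members) {
  left <- min(members$offset)
  width <- max(members$offset + nchar(members$kmer)) - left
  counts <- matrix(0, 4, width, dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(nrow(members))) {
    chars <- strsplit(members$kmer[i], "")[[1]]
    cols <- members$offset[i] - left + seq_along(chars)
    for (j in seq_along(chars)) {
      counts[chars[j], cols[j]] <- counts[chars[j], cols[j]] +
        members$weight[i]
    }
  }
  counts
}

members_consensus <- function(members) {
  pssm_consensus(members_counts(members))
}

members_to_pssm <- function(members, id, pseudocount) {
  counts <- members_counts(members) + pseudocount
  mat <- sweep(counts, 2, colSums(counts), "/")
  pssm(mat, id, source_kmers = members$kmer,
       nsites = as.integer(sum(members$weight)))
}

#' Annotate query PSSMs against a reference motif library
#'
#' Slides each query over every library motif at all offsets and in both
#' orientations, requiring at least `min_overlap` aligned columns, and scores
#' each alignment as the mean column-wise Pearson correlation of the aligned
#' probability columns scaled by the aligned fraction of the narrower motif
#' (so a perfect match over the full alignable width reaches 1, while partial
#' overlaps are penalized). The best-scoring library motif is reported per
#' query.
#'
#' @param queries List of `pssm` objects (or a single one).
#' @param library Named list of `pssm` objects (e.g. from [read_meme()]).
#' @param min_overlap Minimum aligned columns (default 4).
#' @return Tibble `query_id`, `match_id`, `score`, `offset`, `orientation`.
#' @export
annotate_pssms <- function(queries, library, min_overlap = 4) {
  if (inherits(queries, "pssm")) queries <- list(queries)
  stopifnot(length(library) > 0)
  rows <- purrr::map(queries, function(q) {
    if (q$width < 4) abort("query PSSM narrower than 4 columns")
    best <- NULL
    for (li in seq_along(library)) {
      lib <- library[[li]]
      for (orient in c("forward", "reverse")) {
        qq <- if (orient == "forward") q else reverse_complement_pssm(q)
        for (off in seq(-(qq$width - 1L), lib$width - 1L)) {
          a0 <- max(1L, 1L + off); a1 <- min(lib$width, off + qq$width)
          ov <- a1 - a0 + 1L
          if (ov < min_overlap) next
          rs <- vapply(a0:a1, function(cidx) {
            column_correlation(lib$mat[, cidx], qq$mat[, cidx - off])
          }, 0)
          score <- mean(rs) * ov / min(qq$width, lib$width)
          if (is.null(best) || score > best$score) {
            best <- list(match_id = lib$id, score = score,
                         offset = as.integer(off), orientation = orient)
          }
        }
      }
    }
    tibble::tibble(query_id = q$id, match_id = best$match_id,
                   score = best$score, offset = best$offset,
                   orientation = best$orientation)
  })
  dplyr::bind_rows(rows)
}

column_correlation <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 && sy == 0) return(if (max(abs(x - y)) < 1e-12) 1 else 0)
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}
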