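#' Realized genetic relationship matrix from line genotypes
#'
#' K = Z Z' / m over the m polymorphic variants, where Z is the
#' column-standardized (default) or merely centred genotype matrix. Missing
#' genotypes are mean-imputed per variant before standardization; monomorphic
#' columns are excluded. For fully inbred lines the 0/1 genotype mean is the
#' line allele frequency.
#'
#' @param panel A `panel` (from [simulate_panel()] or [read_panel_tsv()]) or
#'   a lines x variants numeric matrix.
#' @param method `"standardized"` (default) or `"centered"`.
#' @return A symmetric lines x lines kinship matrix.
#' @export
compute_grm <- function(panel, method = c("standardized", "centered")) {
  method <- match.arg(method)
  G <- if (inherits(panel, "panel")) panel$geno else as.matrix(panel)
  G <- mean_impute(G)
  p <- colMeans(G)
  poly <- p > 0 & p < 1
  if (!any(poly)) abort("all variants are monomorphic: kinship undefined")
  Z <- sweep(G[, poly, drop = FALSE], 2, p[poly])
  if (method == "standardized") {
    Z <- sweep(Z, 2, apply(G[, poly, drop = FALSE], 2, stats::sd), "/")
  }
  K <- tcrossprod(Z) / ncol(Z)
  (K + t(K)) / 2
}

mean_impute <- function(G) {
  if (!anyNA(G)) return(G)
  for (j in seq_len(ncol(G))) {
    nas <- is.na(G[, j])
    if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
  }
  G
}

#' Remove high-leverage lines before association
#'
#' Line-level summary values (means or CVe) strictly outside the Tukey fences
#' \[Q1 - k*IQR, Q3 + k*IQR\] are discarded from the scan of that trait, since
#' extreme lines exert disproportionate leverage on the linear model.
#'
#' @param line_values Tibble with `line_id` and `value`.
#' @param rule A [qc_rule()] (only `k` and `quartile_method` are used).
#' @return Tibble `line_id`, `value`, `retained` (logical).
#' @export
leverage_filter <- function(line_values, rule = qc_rule()) {
  stopifnot(all(c("line_id", "value") %in% names(line_values)))
  out <- outside_fences(line_values$value, rule$k, rule$quartile_method)
  dplyr::mutate(line_values, retained = !out & !is.na(.data$value))
}

#' Fit the null linear mixed model and estimate the variance ratio
#'
#' Spectral trick: with K = U S U', rotating y and the fixed effects by U'
#' diagonalizes the covariance sigma_g^2 (S + delta I), so the likelihood in
#' delta = sigma_e^2 / sigma_g^2 is a cheap 1-D profile. delta is estimated
#' once on the covariates-only model by maximum likelihood and then held
#' fixed for every variant (the usual single-delta approximation).
#'
#' @param y Response vector (one value per line).
#' @param W Fixed-effect design matrix including the intercept column.
#' @param K Kinship matrix for the same lines.
#' @return List of class `lmm_fit`: `U`, `S`, `delta`, `loglik`, rotated
#'   response/design, dimensions.
#' @export
fit_lmm_null <- function(y, W, K) {
  n <- length(y)
  stopifnot(nrow(W) == n, nrow(K) == n, ncol(K) == n)
  if (qr(W)$rank < ncol(W)) {
    abort(collinear_message(W))
  }
  eig <- eigen(K, symmetric = TRUE)
  S <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, W)

  negll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (S + delta)
    fit <- stats::lm.wfit(Wt, yt, w)
    rss <- sum(w * fit$residuals^2)
    sig2 <- rss / n
    0.5 * (n * log(2 * pi) + n * log(sig2) + sum(log(S + delta)) + n)
  }
  opt <- stats::optimize(negll, interval = log(c(1e-6, 1e6)))
  structure(list(U = U, S = S, delta = exp(opt$minimum),
                 loglik = -opt$objective, yt = yt, Wt = Wt, n = n,
                 p_fixed = ncol(W)),
            class = "lmm_fit")
}

collinear_message <- function(W) {
  qrW <- qr(W)
  dropped <- colnames(W)[qrW$pivot[seq(qrW$rank + 1, ncol(W))]]
  sprintf("fixed-effect design is singular; collinear covariate(s): %s",
          paste(dropped, collapse = ", "))
}

#' @rdname fit_lmm_null
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(n = x$n, p_fixed = x$p_fixed, delta = x$delta,
                 logLik = x$loglik)
}

#' Single-marker linear mixed-model scan on line-level responses
#'
#' For each variant, fits y = W a + x b + u + e with u ~ N(0, sigma_g^2 K) on
#' line-level data (line means or line CVe), using one spectral decomposition
#' of K and the null-model delta for every variant, and reports the Wald/F
#' test of b = 0 (df1 = 1, df2 = n - rank(fixed effects) - 1). Records are
#' sorted by ascending p with dense ranks. Variants monomorphic in the
#' retained lines are skipped.
#'
#' @param panel A `panel`.
#' @param response Tibble `line_id`, `value` (already leverage-filtered if
#'   desired); only lines present in both panel and response are used.
#' @param covariates Optional tibble with `line_id` and binary covariate
#'   columns (e.g. Wolbachia infection status, inversion markers).
#' @param response_kind Label stored with the records, `"mean"` or `"cve"`.
#' @param K Optional precomputed kinship; default [compute_grm()] on the
#'   retained lines. Pass `diag(n)` to reduce the scan to ordinary
#'   regression.
#' @param delta Optional fixed variance ratio; default estimated on the null
#'   model by ML.
#' @return Tibble of class `assoc_scan`: `variant_id`, `trait` columns if
#'   supplied, `response_kind`, `beta`, `se`, `statistic`, `p`, `rank`.
#' @export
lmm_scan <- function(panel, response, covariates = NULL,
                     response_kind = c("mean", "cve"), K = NULL,
                     delta = NULL) {
  response_kind <- match.arg(response_kind)
  stopifnot(inherits(panel, "panel"),
            all(c("line_id", "value") %in% names(response)))
  response <- response[!is.na(response$value), ]
  lines <- intersect(panel$line_ids, response$line_id)
  if (length(lines) < 8) abort("need at least 8 lines for a scan")
  y <- response$value[match(lines, response$line_id)]
  G <- mean_impute(panel$geno[lines, , drop = FALSE])

  W <- matrix(1, length(lines), 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    cv <- covariates[match(lines, covariates$line_id), , drop = FALSE]
    cc <- setdiff(names(cv), "line_id")
    W <- cbind(W, as.matrix(cv[, cc, drop = FALSE]))
  }
  if (is.null(K)) K <- compute_grm(G)
  fit <- fit_lmm_null(y, W, K)
  if (!is.null(delta)) fit$delta <- delta

  w <- 1 / (fit$S + fit$delta)
  sw <- sqrt(w)
  yt <- fit$yt * sw
  Wt <- fit$Wt * sw
  Gt <- crossprod(fit$U, G) * sw

  # residualize response and each variant on the fixed effects once
  qw <- qr(Wt)
  ry <- qr.resid(qw, yt)
  rG <- qr.resid(qw, Gt)

  df2 <- length(lines) - ncol(W) - 1L
  sxx <- colSums(rG^2)
  p_line <- colMeans(G)
  mono <- p_line <= 0 | p_line >= 1 | sxx < 1e-12
  if (any(mono)) {
    inform(sprintf("%d variant(s) monomorphic in retained lines: skipped",
                   sum(mono)))
  }
  beta <- colSums(rG * ry) / sxx
  rss <- sum(ry^2) - beta^2 * sxx
  sigma2 <- rss / df2
  se <- sqrt(sigma2 / sxx)
  fstat <- (beta / se)^2
  pval <- stats::pf(fstat, 1, df2, lower.tail = FALSE)

  out <- tibble::tibble(variant_id = colnames(G),
                        response_kind = response_kind,
                        beta = beta, se = se, statistic = fstat, p = pval)
  out <- out[!mono, ]
  out <- dplyr::arrange(out, .data$p)
  out$rank <- dplyr::dense_rank(out$p)
  attr(out, "delta") <- fit$delta
  attr(out, "n_lines") <- length(lines)
  class(out) <- c("assoc_scan", class(out))
  out
}

#' Select candidate variants from a ranked scan
#'
#' Takes the `top_k` variants with the lowest p-values (ties broken
#' deterministically by genomic position then variant ID), then filters the
#' selection to minor allele frequency strictly above `maf_min`, then — when
#' requested — removes synonymous coding variants. Filtering happens after
#' selection, so fewer than `top_k` candidates may be returned.
#'
#' @param records An [lmm_scan()] result.
#' @param variants The panel's variant tibble (`variant_id`, `pos`, `maf`,
#'   `site_class`).
#' @param top_k Number of best-ranked variants to take (default 100).
#' @param maf_min MAF threshold, strict inequality (default 0.04).
#' @param drop_synonymous Drop variants whose `site_class` is
#'   `"synonymous"`.
#' @return Tibble of candidate records joined with variant metadata.
#' @export
select_candidates <- function(records, variants, top_k = 100,
                              maf_min = 0.04, drop_synonymous = FALSE) {
  joined <- dplyr::left_join(tibble::as_tibble(records), variants,
                             by = "variant_id")
  if (nrow(joined) < top_k) {
    warn(sprintf("only %d tested variants; taking all", nrow(joined)))
  }
  top <- joined |>
    dplyr::arrange(.data$p, .data$pos, .data$variant_id) |>
    head(top_k)
  out <- top |> dplyr::filter(.data$maf > maf_min)
  if (drop_synonymous) {
    out <- out |>
      dplyr::filter(is.na(.data$site_class) |
                      .data$site_class != "synonymous")
  }
  out
}

#' Observed vs expected quantiles of -log10 p
#'
#' @param records An [lmm_scan()] result (or any tibble with a `p` column).
#' @return Tibble `expected`, `observed` of -log10 p quantiles for QQ plots.
#' @export
qq_table <- function(records) {
  p <- sort(records$p)
  n <- length(p)
  tibble::tibble(expected = -log10((seq_len(n) - 0.5) / n),
                 observed = -log10(p))
}
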