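#' Focal-SNP exhaustive pairwise epistasis scan
#'
#' For each focal variant f and every partner t with MAF above
#' `partner_maf_min`, fits the two-locus line-level model
#' y ~ mu + g_f + g_t + g_f:g_t (0/1 homozygous coding) and tests the
#' interaction coefficient with a 1-df F test. The partner with the smallest
#' interaction p-value is reported per focal variant, with deterministic
#' tie-breaking by (position, variant ID). Partners identical or perfectly
#' collinear with the focal genotype (constant interaction column) are
#' skipped. The closed-form normal-equation batching gives results identical
#' to per-pair regression, only faster.
#'
#' @param panel A `panel`.
#' @param response Tibble `line_id`, `value` (line means or line CVe).
#' @param focal_set Character vector of focal variant IDs (subset of panel
#'   variants).
#' @param partner_maf_min Partner MAF threshold, strict (default 0.05).
#' @param covariates Optional covariate tibble; when supplied the response is
#'   residualized on the covariates before scanning.
#' @param all_partners If `TRUE`, return every tested pair instead of the
#'   best partner per focal variant.
#' @return Tibble with `focal_id`, `partner_id`, `beta_focal`,
#'   `beta_partner`, `beta_int`, `statistic`, `p_int`, `n_partners_tested`.
#'   A focal variant monomorphic in the retained lines yields a row with a
#'   missing partner.
#' @export
pairwise_scan <- function(panel, response, focal_set,
                          partner_maf_min = 0.05, covariates = NULL,
                          all_partners = FALSE) {
  stopifnot(inherits(panel, "panel"))
  if (!all(focal_set %in% colnames(panel$geno))) {
    abort("`focal_set` contains IDs absent from the panel")
  }
  response <- response[!is.na(response$value), ]
  lines <- intersect(panel$line_ids, response$line_id)
  y <- response$value[match(lines, response$line_id)]
  if (!is.null(covariates)) {
    cv <- covariates[match(lines, covariates$line_id), , drop = FALSE]
    X <- cbind(1, as.matrix(cv[, setdiff(names(cv), "line_id"), drop = FALSE]))
    y <- stats::lm.fit(X, y)$residuals
  }
  G <- mean_impute(panel$geno[lines, , drop = FALSE])
  n <- length(y)

  p_line <- colMeans(G)
  maf <- pmin(p_line, 1 - p_line)
  partners <- colnames(G)[maf > partner_maf_min]
  vmeta <- panel$variants
  pos_of <- setNames(vmeta$pos, vmeta$variant_id)

  # per-partner sufficient statistics, reused for every focal variant
  St <- colSums(G)
  Sty <- drop(crossprod(G, y))
  Sy <- sum(y)

  rows <- purrr::map(focal_set, function(f) {
    gf <- G[, f]
    if (stats::var(gf) == 0) {
      warn(sprintf("focal variant %s monomorphic in retained lines", f))
      return(tibble::tibble(focal_id = f, partner_id = NA_character_,
                            beta_focal = NA_real_, beta_partner = NA_real_,
                            beta_int = NA_real_, statistic = NA_real_,
                            p_int = NA_real_, n_partners_tested = 0L))
    }
    cand <- setdiff(partners, f)
    Gc <- G[, cand, drop = FALSE]
    Sf <- sum(gf)
    Sfy <- sum(gf * y)
    Sft <- drop(crossprod(Gc, gf))          # sum g_f * g_t (binary products)
    Sfty <- drop(crossprod(Gc, gf * y))
    # with 0/1 coding all squares and mixed powers collapse onto these sums
    res <- matrix(NA_real_, length(cand), 4,
                  dimnames = list(cand, c("bf", "bt", "bi", "F")))
    rssf <- rep(NA_real_, length(cand))
    for (j in seq_along(cand)) {
      st <- St[cand[j]]; sft <- Sft[j]
      XtX <- matrix(c(n,   Sf,  st,  sft,
                      Sf,  Sf,  sft, sft,
                      st,  sft, st,  sft,
                      sft, sft, sft, sft), 4, 4)
      if (qr(XtX)$rank < 4L) next        # collinear pair (g_f*g_t degenerate)
      Xty <- c(Sy, Sfy, Sty[cand[j]], Sfty[j])
      XtXi <- solve(XtX)
      b <- drop(XtXi %*% Xty)
      rss <- sum(y^2) - sum(b * Xty)
      df2 <- n - 4L
      sigma2 <- rss / df2
      se_i2 <- sigma2 * XtXi[4, 4]
      res[j, ] <- c(b[2], b[3], b[4], b[4]^2 / se_i2)
      rssf[j] <- rss
    }
    ok <- !is.na(res[, "F"])
    if (!any(ok)) {
      return(tibble::tibble(focal_id = f, partner_id = NA_character_,
                            beta_focal = NA_real_, beta_partner = NA_real_,
                            beta_int = NA_real_, statistic = NA_real_,
                            p_int = NA_real_, n_partners_tested = 0L))
    }
    pv <- stats::pf(res[, "F"], 1, n - 4L, lower.tail = FALSE)
    tab <- tibble::tibble(focal_id = f, partner_id = cand,
                          beta_focal = unname(res[, "bf"]),
                          beta_partner = unname(res[, "bt"]),
                          beta_int = unname(res[, "bi"]),
                          statistic = unname(res[, "F"]),
                          p_int = unname(pv),
                          n_partners_tested = sum(ok))[ok, ]
    if (all_partners) return(tab)
    tab |>
      dplyr::arrange(.data$p_int, pos_of[.data$partner_id],
                     .data$partner_id) |>
      head(1)
  })
  dplyr::bind_rows(rows)
}
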