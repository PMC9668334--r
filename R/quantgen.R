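#' One-way random-effects variance components and broad-sense heritability
#'
#' Classic among/within-line decomposition. With a lines each contributing
#' n_i individuals (N total), MS_among and MS_within come from the one-way
#' ANOVA; the effective replicate number for unbalanced designs is
#' n0 = (N - sum(n_i^2)/N) / (a - 1). Genetic variance is
#' Vg = max(0, (MS_among - MS_within) / n0) (negative estimates truncated so
#' H2 stays in \[0, 1\]), environmental variance Ve = MS_within, phenotypic
#' variance Vp = Vg + Ve, and broad-sense heritability H2 = Vg / Vp. The F
#' statistic is MS_among / MS_within with the usual F reference distribution.
#'
#' @param phenotypes Tibble with `line_id` and the trait column.
#' @param trait Name of the trait column to analyse.
#' @return A list of class `varcomp` with fields `trait`, `ms_among`,
#'   `ms_within`, `n0`, `Vg`, `Ve`, `Vp`, `H2`, `F`, `df`, `p_anova`.
#'   `tidy()` and `glance()` methods return tibbles.
#' @export
anova_components <- function(phenotypes, trait) {
  d <- tibble::tibble(line = factor(phenotypes$line_id),
                      y = phenotypes[[trait]])
  d <- d[!is.na(d$y), ]
  d$line <- droplevels(d$line)
  a <- nlevels(d$line)
  if (a < 2) abort("need at least two lines for variance components")
  ni <- tabulate(d$line)
  if (any(ni < 2)) abort("every line needs at least two individuals")
  N <- nrow(d)
  gm <- mean(d$y)
  line_means <- tapply(d$y, d$line, mean)
  ss_among <- sum(ni * (line_means - gm)^2)
  ss_within <- sum((d$y - line_means[d$line])^2)
  ms_among <- ss_among / (a - 1)
  ms_within <- ss_within / (N - a)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  if (ms_within == 0) {
    warn("zero within-line variance everywhere: H2 = 1")
    vg <- ms_among / n0
    ve <- 0
    f <- Inf
    p <- 0
  } else {
    vg <- max(0, (ms_among - ms_within) / n0)
    ve <- ms_within
    f <- ms_among / ms_within
    p <- stats::pf(f, a - 1, N - a, lower.tail = FALSE)
  }
  structure(list(trait = trait, ms_among = ms_among, ms_within = ms_within,
                 n0 = n0, Vg = vg, Ve = ve, Vp = vg + ve,
                 H2 = if (vg + ve > 0) vg / (vg + ve) else NA_real_,
                 F = f, df = c(a - 1, N - a), p_anova = p),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf(
    "Variance components for %s: Vg = %.4g, Ve = %.4g, Vp = %.4g, H2 = %.3f\n",
    x$trait, x$Vg, x$Ve, x$Vp, x$H2))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.3g\n", x$df[1], x$df[2], x$F,
              x$p_anova))
  invisible(x)
}

#' @rdname anova_components
#' @param x A `varcomp` object.
#' @param ... Unused.
#' @export
tidy.varcomp <- function(x, ...) {
  tibble::tibble(trait = x$trait,
                 component = c("genetic", "environmental", "phenotypic"),
                 variance = c(x$Vg, x$Ve, x$Vp))
}

#' @rdname anova_components
#' @export
glance.varcomp <- function(x, ...) {
  tibble::tibble(trait = x$trait, ms_among = x$ms_among,
                 ms_within = x$ms_within, n0 = x$n0, Vg = x$Vg, Ve = x$Ve,
                 Vp = x$Vp, H2 = x$H2, statistic = x$F,
                 df1 = x$df[1], df2 = x$df[2], p.value = x$p_anova)
}

#' Broad-sense heritability from variance components
#'
#' H2 = Vg / (Vg + Ve); negative genetic variance estimates are truncated at
#' zero so the ratio stays in \[0, 1\].
#'
#' @param Vg Genetic (among-line) variance.
#' @param Ve Environmental (within-line) variance.
#' @return H2 in \[0, 1\].
#' @examples
#' broad_sense_h2(113, 86.4)
#' @export
broad_sense_h2 <- function(Vg, Ve) {
  stopifnot(Ve >= 0)
  Vg <- pmax(Vg, 0)
  Vg / (Vg + Ve)
}

#' Levene test for heterogeneity of within-line variance
#'
#' One-way ANOVA on absolute deviations from each line's centre (mean for the
#' classical Levene statistic, median for the Brown-Forsythe variant). A
#' significant statistic indicates that lines differ in micro-environmental
#' variance.
#'
#' @inheritParams anova_components
#' @param center `"mean"` (classical, default) or `"median"`
#'   (Brown-Forsythe).
#' @return A list of class `levene_result`: `trait`, `statistic`, `df`, `p`,
#'   `center`.
#' @export
levene_test <- function(phenotypes, trait, center = c("mean", "median")) {
  center <- match.arg(center)
  d <- tibble::tibble(line = factor(phenotypes$line_id),
                      y = phenotypes[[trait]])
  d <- d[!is.na(d$y), ]
  d$line <- droplevels(d$line)
  if (nlevels(d$line) < 2) abort("need at least two lines")
  centre_fun <- if (center == "mean") mean else median
  centres <- tapply(d$y, d$line, centre_fun)
  z <- abs(d$y - centres[d$line])
  a <- nlevels(d$line)
  N <- nrow(d)
  zbar <- mean(z)
  zi <- tapply(z, d$line, mean)
  ni <- tabulate(d$line)
  ss_among <- sum(ni * (zi - zbar)^2)
  ss_within <- sum((z - zi[d$line])^2)
  if (ss_within == 0 && ss_among == 0) {
    return(structure(list(trait = trait, statistic = 0,
                          df = c(a - 1, N - a), p = 1, center = center),
                     class = "levene_result"))
  }
  f <- (ss_among / (a - 1)) / (ss_within / (N - a))
  structure(list(trait = trait, statistic = f, df = c(a - 1, N - a),
                 p = stats::pf(f, a - 1, N - a, lower.tail = FALSE),
                 center = center),
            class = "levene_result")
}

#' @export
print.levene_result <- function(x, ...) {
  cat(sprintf("Levene test (%s-centred) for %s: F(%d, %d) = %.4g, p = %.3g\n",
              x$center, x$trait, x$df[1], x$df[2], x$statistic, x$p))
  invisible(x)
}

#' @rdname levene_test
#' @param x A `levene_result`.
#' @param ... Unused.
#' @export
tidy.levene_result <- function(x, ...) {
  tibble::tibble(trait = x$trait, statistic = x$statistic,
                 df1 = x$df[1], df2 = x$df[2], p.value = x$p,
                 center = x$center)
}

#' Panel-level quantitative-genetics table
#'
#' Per trait: population mean/SD/CV over QC-retained individuals, line and
#' individual counts, variance components, H2, ANOVA F and p, and the Levene
#' heterogeneity-of-variance p-value. One row per trait, mirroring the usual
#' summary table of an inbred-panel screen.
#'
#' @param phenotypes Wide phenotype tibble (`line_id`, `indiv_id`, traits).
#' @param rule A [qc_rule()] applied before all computations.
#' @param levene_center Passed to [levene_test()].
#' @return Tibble with one row per trait.
#' @export
quantgen_table <- function(phenotypes, rule = qc_rule(),
                           levene_center = "mean") {
  kept <- apply_qc(phenotypes, rule)
  pop <- population_stats(phenotypes, rule)
  traits <- pop$trait
  rows <- purrr::map(traits, function(tr) {
    d <- kept |> dplyr::filter(.data$trait == tr)
    wide <- tibble::tibble(line_id = d$line_id)
    wide[[tr]] <- d$value
    vc <- anova_components(wide, tr)
    lv <- levene_test(wide, tr, levene_center)
    tibble::tibble(trait = tr, Vg = vc$Vg, Ve = vc$Ve, Vp = vc$Vp, H2 = vc$H2,
                   F_value = vc$F, p_anova = vc$p_anova, p_levene = lv$p)
  })
  dplyr::left_join(pop, dplyr::bind_rows(rows), by = "trait")
}

# Long table of QC-retained values for lines passing the min-n rule.
apply_qc <- function(phenotypes, rule) {
  long <- qc_long(pivot_traits_long(phenotypes), rule)
  kept <- long |> dplyr::filter(!.data$removed, !is.na(.data$value))
  cells <- kept |>
    dplyr::count(.data$line_id, .data$trait) |>
    dplyr::filter(.data$n >= rule$min_line_n)
  dplyr::semi_join(kept, cells, by = c("line_id", "trait"))
}
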