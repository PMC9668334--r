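#' Quality-control rule for per-line trait values
#'
#' Interquartile-range (Tukey fence) outlier rule applied per line per trait:
#' values strictly outside \[Q1 - k*IQR, Q3 + k*IQR\] are flagged; lines
#' retaining fewer than `min_line_n` observations are excluded from summaries.
#'
#' @param k IQR multiplier (default 1.5).
#' @param min_line_n Minimum observations a line must retain (default 7).
#' @param quartile_method `"linear"` (interpolated order statistics, default)
#'   or `"nearest"`.
#' @return A list of class `qc_rule`.
#' @export
qc_rule <- function(k = 1.5, min_line_n = 7, quartile_method = "linear") {
  stopifnot(k > 0, min_line_n >= 2)
  structure(list(k = k, min_line_n = as.integer(min_line_n),
                 quartile_method = match.arg(quartile_method,
                                             c("linear", "nearest"))),
            class = "qc_rule")
}

#' Derive per-fly cardiac traits from a beat series
#'
#' From per-beat diastolic and systolic intervals and the two diameters:
#' DI and SI are the means of the interval lists, per-beat heart period is
#' DI_i + SI_i with the fly HP its mean, the arrhythmia index AI is the sample
#' SD of per-beat HP normalized to a central HP (median by default), and
#' fractional shortening FS = (EDD - ESD) / EDD.
#'
#' @param di,si Numeric vectors of per-beat diastolic/systolic intervals
#'   (seconds), equal length.
#' @param edd,esd End diastolic / systolic diameters (um); `edd` must be > 0.
#' @param ai_center `"median"` (default) or `"mean"`: the HP centring used in
#'   the AI denominator.
#' @return One-row tibble with DI, SI, HP, AI, EDD, ESD, FS. With fewer than
#'   two beats AI is NA (undefined, not zero).
#' @examples
#' derive_fly_traits(di = c(0.5, 0.5), si = c(0.2, 0.2), edd = 80, esd = 50)
#' @export
derive_fly_traits <- function(di, si, edd, esd, ai_center = c("median", "mean")) {
  ai_center <- match.arg(ai_center)
  if (length(di) != length(si)) abort("`di` and `si` must have equal length")
  if (any(di <= 0) || any(si <= 0)) abort("intervals must be positive")
  if (edd <= 0) abort("`edd` must be positive")
  if (esd < 0) abort("`esd` must be non-negative")
  hp_beats <- di + si
  ai <- if (length(hp_beats) >= 2) {
    centre <- if (ai_center == "median") median(hp_beats) else mean(hp_beats)
    stats::sd(hp_beats) / centre
  } else NA_real_
  tibble::tibble(DI = mean(di), SI = mean(si), HP = mean(hp_beats), AI = ai,
                 EDD = edd, ESD = esd, FS = (edd - esd) / edd)
}

#' Flag IQR outliers in one line's trait values
#'
#' @param values Numeric vector of per-fly values for one line and one trait.
#' @param rule A [qc_rule()].
#' @return Tibble with `value`, `removed` (logical). With fewer than 4 values
#'   no filtering is applied (a warning is raised).
#' @export
qc_outliers <- function(values, rule = qc_rule()) {
  stopifnot(inherits(rule, "qc_rule"))
  if (length(values) < 4) {
    warn("fewer than 4 values: IQR fences not estimated, nothing removed")
    return(tibble::tibble(value = values, removed = FALSE))
  }
  removed <- outside_fences(values, rule$k, rule$quartile_method)
  tibble::tibble(value = values, removed = removed)
}

# QC every (line, trait) cell of a long phenotype table.
qc_long <- function(long, rule) {
  long |>
    dplyr::group_by(.data$line_id, .data$trait) |>
    dplyr::mutate(removed = if (dplyr::n() < 4) FALSE else
      outside_fences(.data$value, rule$k, rule$quartile_method)) |>
    dplyr::ungroup()
}

pivot_traits_long <- function(phenotypes) {
  trait_cols <- setdiff(names(phenotypes), c("line_id", "indiv_id"))
  tidyr::pivot_longer(phenotypes, dplyr::all_of(trait_cols),
                      names_to = "trait", values_to = "value")
}

#' Per-line summaries (mean, SD, CVe) after QC
#'
#' Applies the IQR rule within each line and trait, then summarises the kept
#' values. Lines retaining fewer than `min_line_n` observations are dropped
#' for that trait. CVe = SD / mean is the within-line coefficient of
#' variation, the metric of micro-environmental variance; it is set to NA
#' (with a warning) when a line mean is not positive.
#'
#' @param phenotypes Tibble `line_id`, `indiv_id`, then one column per trait.
#' @param rule A [qc_rule()].
#' @return Tibble with `line_id`, `trait`, `n_kept`, `n_removed`, `mean`,
#'   `sd` (n-1 denominator), `cve`.
#' @export
line_summaries <- function(phenotypes, rule = qc_rule()) {
  stopifnot(inherits(rule, "qc_rule"))
  long <- qc_long(pivot_traits_long(phenotypes), rule)
  out <- long |>
    dplyr::group_by(.data$line_id, .data$trait) |>
    dplyr::summarise(
      n_kept = sum(!.data$removed & !is.na(.data$value)),
      n_removed = sum(.data$removed),
      mean = mean(.data$value[!.data$removed], na.rm = TRUE),
      sd = sample_sd(.data$value[!.data$removed]),
      .groups = "drop") |>
    dplyr::filter(.data$n_kept >= rule$min_line_n) |>
    dplyr::mutate(cve = ifelse(.data$mean > 0, .data$sd / .data$mean, NA_real_))
  if (any(is.na(out$cve) & out$mean <= 0)) {
    warn("non-positive line means: CVe set to NA for those lines")
  }
  out
}

#' QC removal report
#'
#' Long table of every flagged observation with the fence that excluded it.
#'
#' @inheritParams line_summaries
#' @return Tibble `line_id`, `indiv_id`, `trait`, `value`, `lower`, `upper`.
#' @export
qc_report <- function(phenotypes, rule = qc_rule()) {
  long <- pivot_traits_long(phenotypes)
  long |>
    dplyr::group_by(.data$line_id, .data$trait) |>
    dplyr::mutate(
      removed = if (dplyr::n() < 4) FALSE else
        outside_fences(.data$value, rule$k, rule$quartile_method),
      lower = if (dplyr::n() < 4) NA_real_ else
        tukey_fences(.data$value, rule$k, rule$quartile_method)[1],
      upper = if (dplyr::n() < 4) NA_real_ else
        tukey_fences(.data$value, rule$k, rule$quartile_method)[2]) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$removed) |>
    dplyr::select("line_id", "indiv_id", "trait", "value", "lower", "upper")
}

#' Population-level summary statistics per trait
#'
#' Pools all QC-retained individuals across lines and reports count of lines,
#' individuals, mean, SD and coefficient of variation (CV = SD / mean), the
#' whole-population row of a panel summary table.
#'
#' @inheritParams line_summaries
#' @return Tibble `trait`, `n_lines`, `n_indiv`, `mean`, `sd`, `cv`.
#' @export
population_stats <- function(phenotypes, rule = qc_rule()) {
  long <- qc_long(pivot_traits_long(phenotypes), rule)
  kept <- long |> dplyr::filter(!.data$removed, !is.na(.data$value))
  # only lines passing the min-n rule contribute
  keep_cells <- kept |>
    dplyr::group_by(.data$line_id, .data$trait) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= rule$min_line_n)
  kept <- dplyr::semi_join(kept, keep_cells, by = c("line_id", "trait"))
  out <- kept |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(n_lines = dplyr::n_distinct(.data$line_id),
                     n_indiv = dplyr::n(),
                     mean = mean(.data$value),
                     sd = sample_sd(.data$value), .groups = "drop") |>
    dplyr::mutate(cv = .data$sd / .data$mean)
  if (any(kept |> dplyr::count(.data$trait) |> dplyr::pull(.data$n) < 2)) {
    abort("a trait has a single retained value: SD undefined")
  }
  out
}
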