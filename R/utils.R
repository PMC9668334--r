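# Internal helpers shared across modules.

# Quartiles by the stated method. "linear" is the classic linear interpolation
# between order statistics (R type 7); "nearest" (type 2) kept as an alternative
# since published QC pipelines differ.
quartiles <- function(x, method = c("linear", "nearest")) {
  method <- match.arg(method)
  type <- if (method == "linear") 7L else 2L
  stats::quantile(x, probs = c(0.25, 0.75), type = type, names = FALSE, na.rm = TRUE)
}

# Tukey fences [Q1 - k*IQR, Q3 + k*IQR]; closed interval, boundary values kept.
tukey_fences <- function(x, k = 1.5, method = "linear") {
  q <- quartiles(x, method)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

# TRUE for values strictly outside the fences.
outside_fences <- function(x, k = 1.5, method = "linear") {
  f <- tukey_fences(x, k, method)
  !is.na(x) & (x < f["lower"] | x > f["upper"])
}

assert_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s", name, deparse(x)))
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    abort(sprintf("`%s` must be a probability in [0,%s), got %s",
                  name, if (allow_one) "1]" else "1", deparse(x)))
  }
  invisible(as.numeric(x))
}

# Sample SD with n-1 denominator; NA below 2 observations.
sample_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

# Deterministic child seeds derived from one master seed (kept below 2^31).
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 2654435761 + stream * 97) %% 2147483587 + 1
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}
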