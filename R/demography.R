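#' Estimate age from the molar progression index
#'
#' Red kangaroo age is estimated from the molar index `M` (the number of
#' molars that have progressed past the posterior rims of the zygomatic
#' arches) with the standard macropod aging relationship
#' \deqn{\log_e A = 2.2278 + 0.359 M,}
#' where `A` is age in days. The relationship is implemented exactly as
#' published; `scale` is a post-hoc multiplier left at 1 by default (the
#' published intercept/slope yield sub-year ages for typical molar indices,
#' a unit tension in the source formula that is deliberately not resolved
#' here — see the methods vignette).
#'
#' @param M Numeric vector of molar indices, finite and `>= 0`.
#' @param scale Positive post-hoc multiplier applied to the day-scale age.
#' @return Numeric vector of ages in days.
#' @seealso [molar_index_from_age()] for the inverse,
#'   [age_years_from_molar_index()] for the year-scale convenience wrapper.
#' @export
#' @examples
#' age_from_molar_index(0)    # ~9.28 days
#' age_from_molar_index(4)    # ~39.0 days
age_from_molar_index <- function(M, scale = 1) {
  if (!is.numeric(M) || any(!is.finite(M)) || any(M < 0)) {
    stop("molar index must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("'scale' must be a single positive number", call. = FALSE)
  }
  scale * exp(2.2278 + 0.359 * M)
}

#' Invert the aging relationship: molar index for a given age
#'
#' @param age_days Numeric vector of ages in days, strictly positive.
#' @param scale Same post-hoc multiplier as in [age_from_molar_index()].
#' @return Numeric vector of molar indices (can be negative for ages below
#'   the `M = 0` intercept; the synthetic generator clamps at 0).
#' @export
molar_index_from_age <- function(age_days, scale = 1) {
  if (!is.numeric(age_days) || any(!is.finite(age_days)) || any(age_days <= 0)) {
    stop("age_days must be finite and > 0", call. = FALSE)
  }
  (log(age_days / scale) - 2.2278) / 0.359
}

#' @rdname age_from_molar_index
#' @export
age_years_from_molar_index <- function(M, scale = 1) {
  age_from_molar_index(M, scale = scale) / 365.25
}

#' Chi-squared test of sex-ratio homogeneity between two populations
#'
#' Pearson chi-squared test on a 2x2 population-by-sex contingency table.
#' The continuity (Yates) correction defaults on, matching
#' [stats::chisq.test()]'s default for 2x2 tables; both variants are
#' available via `yates`.
#'
#' @param counts 2x2 integer matrix, rows = populations, columns = sexes.
#' @param yates Logical; apply the continuity correction.
#' @return Object of class `sex_ratio_test` with elements `counts`,
#'   `statistic`, `df`, `p`, `yates`, `expected`.
#' @export
sex_ratio_test <- function(counts, yates = TRUE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) {
    stop("counts must be a 2x2 table", call. = FALSE)
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  }
  ct <- stats::chisq.test(counts, correct = yates)
  structure(
    list(
      counts = counts,
      statistic = unname(ct$statistic),
      df = unname(ct$parameter),
      p = ct$p.value,
      yates = yates,
      expected = ct$expected
    ),
    class = "sex_ratio_test"
  )
}

#' @export
print.sex_ratio_test <- function(x, ...) {
  cat(sprintf(
    "Sex-ratio chi-squared test (%s): X-squared = %.4g, df = %d, p = %.4g\n",
    if (x$yates) "Yates-corrected" else "uncorrected",
    x$statistic, x$df, x$p
  ))
  invisible(x)
}

#' Trim one population to the age range of the other
#'
#' Records of `trimmed_population` whose ages fall strictly outside the
#' closed age interval spanned by `reference_population` are removed and
#' counted by side (boundary ages are kept). The reference population is
#' untouched. This matches the rule of excluding individuals that extend
#' beyond the age range of the narrower sample before interpopulation
#' comparisons.
#'
#' @param records Specimen data frame with columns `property` and
#'   `age_years`.
#' @param reference_population,trimmed_population Property labels, e.g.
#'   `"dingoes_common"` / `"dingoes_rare"`.
#' @return Object of class `trim_report`: `kept` (data frame),
#'   `excluded_below`, `excluded_above`, `reference_range_years`.
#' @export
trim_to_common_age_range <- function(records,
                                     reference_population = "dingoes_common",
                                     trimmed_population = "dingoes_rare") {
  stopifnot(is.data.frame(records))
  if (!all(c("property", "age_years") %in% names(records))) {
    stop("records must have columns 'property' and 'age_years'", call. = FALSE)
  }
  if (any(is.na(records$age_years))) {
    stop("ages must be present for every record before trimming", call. = FALSE)
  }
  ref <- records$property == reference_population
  trm <- records$property == trimmed_population
  if (!any(ref) || !any(trm)) {
    stop("both populations must be non-empty", call. = FALSE)
  }
  rng <- range(records$age_years[ref])
  below <- trm & records$age_years < rng[1]
  above <- trm & records$age_years > rng[2]
  keep <- !(below | above)
  structure(
    list(
      kept = records[keep, , drop = FALSE],
      excluded_below = sum(below),
      excluded_above = sum(above),
      reference_range_years = rng
    ),
    class = "trim_report"
  )
}

#' @export
print.trim_report <- function(x, ...) {
  cat(sprintf(
    "Age-range trim: reference range %.3g-%.3g y; excluded %d below, %d above; %d kept\n",
    x$reference_range_years[1], x$reference_range_years[2],
    x$excluded_below, x$excluded_above, nrow(x$kept)
  ))
  invisible(x)
}

#' Demographic summary by population
#'
#' Counts, sex composition, and age quantiles per population.
#'
#' @param records Specimen data frame with columns `property`, `sex`, and
#'   `age_years`.
#' @return Data frame with one row per population: `property`, `n`,
#'   `n_female`, `n_male`, `female_prop`, `age_min`, `age_median`,
#'   `age_max`.
#' @export
demographic_summary <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty specimen table", call. = FALSE)
  if (!all(c("property", "sex", "age_years") %in% names(records))) {
    stop("records must have columns 'property', 'sex', 'age_years'",
         call. = FALSE)
  }
  props <- sort(unique(as.character(records$property)))
  out <- do.call(rbind, lapply(props, function(p) {
    r <- records[records$property == p, , drop = FALSE]
    nf <- sum(r$sex == "female")
    data.frame(
      property = p,
      n = nrow(r),
      n_female = nf,
      n_male = sum(r$sex == "male"),
      female_prop = nf / nrow(r),
      age_min = min(r$age_years),
      age_median = stats::median(r$age_years),
      age_max = max(r$age_years),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Minimum generation count over a span of years
#'
#' Number of whole generations elapsed between two calendar years given a
#' generation time in months (e.g. 30 months to female sexual maturity).
#'
#' @param year_start,year_end Calendar years.
#' @param months_per_generation Generation time in months.
#' @return List with `generations` (continuous) and `min_generations`
#'   (floor, the "minimum of ~N generations" convention).
#' @export
generation_count <- function(year_start, year_end, months_per_generation = 30) {
  if (year_end < year_start) stop("year_end before year_start", call. = FALSE)
  g <- (year_end - year_start) * 12 / months_per_generation
  list(generations = g, min_generations = floor(g))
}
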