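#' Run the full cross-fence analysis pipeline
#'
#' Orchestrates simulate -> demography -> growth -> morphometrics ->
#' vegetation on synthetic data: generates specimens, landmarks, and the
#' two-site vegetation series from the per-stage seeds in `config`, then
#' summarizes demography, tests the sex ratio, trims the wider population
#' to the common age range (trimming precedes every interpopulation test),
#' fits and contrasts growth curves, superimposes the landmarks with the
#' bilateral-symmetry decomposition, runs the permutation linear models,
#' and computes the vegetation anomaly randomization test. All statistics
#' are fully determined by `config` (seeds included), so rerunning with
#' the same config reproduces the report bit for bit.
#'
#' @param config A [run_config()].
#' @param stages Character subset of
#'   `c("demography", "growth", "morphometrics", "vegetation")`.
#' @param specs Population specifications for the specimen generator.
#' @param evi_spec Vegetation simulation specification.
#' @param landmark_args Extra arguments passed to [gen_landmarks()].
#' @return Object of class `run_report` with one block per executed stage
#'   plus the simulated inputs and the config echo.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("demography", "growth", "morphometrics",
                                    "vegetation"),
                         specs = default_population_specs(),
                         evi_spec = evi_sim_spec(),
                         landmark_args = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(config = config, stages = stages,
                 version = as.character(utils::packageVersion("fenceroo")))

  records <- gen_specimens(specs, seed = config$seeds$specimens)
  report$records <- records

  lm_out <- NULL
  shapes <- NULL
  if ("morphometrics" %in% stages || "growth" %in% stages) {
    lm_out <- do.call(gen_landmarks, c(list(records = records,
                                            seed = config$seeds$landmarks),
                                       landmark_args))
    shapes <- bilateral_symmetry(lm_out$configs, lm_out$pairing)
    records$cranial_size <-
      shapes$centroid_sizes[match(records$specimen_id, shapes$specimen_ids)]
    report$records <- records
  }

  if ("demography" %in% stages) {
    counts <- table(factor(records$property, levels = PROPERTY_LEVELS),
                    factor(records$sex, levels = SEX_LEVELS))
    report$demography <- list(
      summary = demographic_summary(records),
      sex_ratio = sex_ratio_test(unclass(counts)),
      trim = trim_to_common_age_range(records)
    )
  }

  trimmed <- trim_to_common_age_range(records)$kept

  if ("growth" %in% stages) {
    traits <- c("cranial_size", "weight_kg", "pes_length_cm")
    traits <- intersect(traits, names(records))
    fits <- lapply(traits, function(tr) {
      f <- compare_vb_groups(records, tr, grouping = "sex")
      f$divergence <- divergence_age(f, threshold = 0.05 *
                                       max(f$coef[[1]]["L_inf"],
                                           f$coef[[2]]["L_inf"]))
      f
    })
    names(fits) <- traits
    report$growth <- fits
  }

  if ("morphometrics" %in% stages) {
    allo <- allometry_model(shapes, records, n_perm = config$n_perm_shape,
                            seed = config$seeds$perm)
    pes_dat <- data.frame(
      log_cs = log(shapes$centroid_sizes),
      sex = factor(records$sex[match(shapes$specimen_ids,
                                     records$specimen_id)]),
      pes = records$pes_length_cm[match(shapes$specimen_ids,
                                        records$specimen_id)]
    )
    pes_allo <- rrpp_lm(pes_dat$pes, ~ log_cs * sex, pes_dat,
                        n_perm = config$n_perm_shape,
                        seed = config$seeds$perm + 1L)
    interpop <- interpopulation_tests(trimmed, shapes,
                                      n_perm = config$n_perm_shape,
                                      seed = config$seeds$perm + 2L,
                                      alpha = config$alpha)
    report$morphometrics <- list(shapes = shapes, allometry = allo,
                                 pes_allometry = pes_allo,
                                 interpopulation = interpop)
  }

  if ("vegetation" %in% stages) {
    evi <- gen_evi(evi_spec, seed = config$seeds$evi)
    evi <- clamp_nonnegative(evi)
    anom <- seasonal_anomaly(evi)
    anom <- moving_window(anom, window = config$window_length)
    rand <- randomization_median_test(
      anom$delta_evi[anom$site == "south"],
      anom$delta_evi[anom$site == "north"],
      n_iter = config$n_iter_randomization,
      seed = config$seeds$randomization
    )
    report$vegetation <- list(n_clamped = attr(evi, "n_clamped"),
                              anomalies = anom, randomization = rand)
  }

  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Cross-fence analysis run (fenceroo", x$version, ")\n")
  cat("stages:", paste(x$stages, collapse = ", "), "\n\n")
  if (!is.null(x$demography)) {
    print(x$demography$summary)
    print(x$demography$sex_ratio)
    print(x$demography$trim)
    cat("\n")
  }
  if (!is.null(x$growth)) {
    for (f in x$growth) { print(f); cat("\n") }
  }
  if (!is.null(x$morphometrics)) {
    print(x$morphometrics$interpopulation)
    cat("\nShape allometry:\n")
    print(x$morphometrics$allometry$perm)
    cat("\n")
  }
  if (!is.null(x$vegetation)) {
    print(x$vegetation$randomization)
  }
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Writes the numeric content of the report (summary tables, test
#' statistics, growth parameters, permutation tables, randomization
#' result) as a JSON file that can be diffed across reruns.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  out <- list(version = report$version, seed = report$config$seed,
              seeds = report$config$seeds, stages = report$stages)
  if (!is.null(report$demography)) {
    d <- report$demography
    out$demography <- list(
      summary = d$summary,
      sex_ratio = list(statistic = d$sex_ratio$statistic,
                       df = d$sex_ratio$df, p = d$sex_ratio$p,
                       yates = d$sex_ratio$yates),
      trim = list(excluded_below = d$trim$excluded_below,
                  excluded_above = d$trim$excluded_above,
                  reference_range_years = d$trim$reference_range_years)
    )
  }
  if (!is.null(report$growth)) {
    out$growth <- lapply(report$growth, function(f) {
      list(trait = f$trait, groups = f$groups,
           coef = lapply(f$coef, as.list), deltas = f$deltas, df = f$df,
           divergence_age_years = f$divergence$age_years)
    })
  }
  if (!is.null(report$morphometrics)) {
    m <- report$morphometrics
    out$morphometrics <- list(
      allometry = m$allometry$perm$aov_table,
      pes_allometry = m$pes_allometry$aov_table,
      interpopulation = m$interpopulation$table
    )
  }
  if (!is.null(report$vegetation)) {
    v <- report$vegetation
    out$vegetation <- list(
      n_clamped = v$n_clamped,
      observed = v$randomization$observed,
      ci_low = v$randomization$ci_low, ci_high = v$randomization$ci_high,
      p = v$randomization$p, n_iter = v$randomization$n_iter
    )
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Figures for a run report
#'
#' Growth scatter-plus-fitted-curve panels per trait and a violin/box
#' summary of the vegetation anomalies per site. Returns ggplot objects
#' (requires the ggplot2 package); stage blocks absent from the report are
#' skipped.
#'
#' @param report A `run_report`.
#' @return Named list of ggplot objects.
#' @export
make_figures <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for make_figures()", call. = FALSE)
  }
  figs <- list()
  rec <- report$records
  if (!is.null(report$growth)) {
    for (tr in names(report$growth)) {
      f <- report$growth[[tr]]
      grid <- seq(min(rec$age_years), max(rec$age_years), length.out = 200)
      curves <- do.call(rbind, lapply(f$groups, function(gname) {
        p <- f$coef[[gname]]
        data.frame(age_years = grid,
                   value = vb_curve(grid, p["L_inf"], p["k"], p["t0"]),
                   group = gname)
      }))
      dat <- data.frame(age_years = rec$age_years, value = rec[[tr]],
                        group = rec[[f$grouping]])
      figs[[paste0("growth_", tr)]] <-
        ggplot2::ggplot(dat, ggplot2::aes(.data$age_years, .data$value,
                                          colour = .data$group)) +
        ggplot2::geom_point(alpha = 0.6) +
        ggplot2::geom_line(data = curves, linewidth = 1) +
        ggplot2::labs(x = "age (years)", y = tr,
                      title = paste("Von Bertalanffy growth:", tr)) +
        ggplot2::theme_minimal()
    }
  }
  if (!is.null(report$vegetation)) {
    anom <- report$vegetation$anomalies
    figs$vegetation_anomalies <-
      ggplot2::ggplot(anom, ggplot2::aes(.data$site, .data$delta_evi)) +
      ggplot2::geom_violin(fill = "grey85") +
      ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
      ggplot2::labs(x = NULL, y = "scaled vegetation-index anomaly") +
      ggplot2::theme_minimal()
  }
  figs
}
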