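#' Population specification for the specimen generator
#'
#' @param n Number of specimens.
#' @param female_prop Probability that a specimen is female.
#' @param age_range_years `(min, max)` of the uniform age distribution.
#' @param vb Von Bertalanffy parameters per sex per trait: a list
#'   `list(female = list(weight_kg = c(L_inf, k, t0), pes_length_cm = ...),
#'   male = ...)`. Units: kg and cm; `k` per year.
#' @param noise_sd Named Gaussian noise sd per trait, same trait names.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n, female_prop, age_range_years, vb, noise_sd) {
  stopifnot(n >= 1, female_prop > 0, female_prop < 1,
            length(age_range_years) == 2)
  if (diff(age_range_years) <= 0) {
    stop("degenerate age range: min must be strictly below max",
         call. = FALSE)
  }
  for (sx in names(vb)) for (tr in names(vb[[sx]])) {
    p <- vb[[sx]][[tr]]
    if (p[1] <= 0 || p[2] <= 0) stop("L_inf and k must be > 0", call. = FALSE)
  }
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n = as.integer(n), female_prop = female_prop,
                 age_range_years = age_range_years, vb = vb,
                 noise_sd = noise_sd),
            class = "population_spec")
}

#' Default study-structure population specifications
#'
#' Two populations with the sample sizes and sex compositions of the field
#' collection (dingoes-rare n = 115, 67.8% female; dingoes-common n = 51,
#' 39.2% female), the rare population's age range enveloping the common
#' one's, and a faster-growing common population (same asymptotes, growth
#' coefficient scaled by `k_ratio_common`) so the growth curves diverge at
#' young ages and converge in older animals.
#'
#' @param k_ratio_common Multiplier on the growth coefficient for the
#'   dingoes-common population.
#' @return Named list of two `population_spec`s.
#' @export
default_population_specs <- function(k_ratio_common = 1.3) {
  vb_rare <- list(
    female = list(weight_kg = c(L_inf = 30, k = 0.55, t0 = -0.2),
                  pes_length_cm = c(L_inf = 32, k = 0.9, t0 = -0.5)),
    male = list(weight_kg = c(L_inf = 66, k = 0.35, t0 = -0.2),
                pes_length_cm = c(L_inf = 37, k = 0.8, t0 = -0.5))
  )
  vb_common <- lapply(vb_rare, function(by_trait) {
    lapply(by_trait, function(p) { p["k"] <- p["k"] * k_ratio_common; p })
  })
  noise <- c(weight_kg = 2, pes_length_cm = 1)
  list(
    dingoes_rare = population_spec(115, 0.678, c(1.5, 11), vb_rare, noise),
    dingoes_common = population_spec(51, 0.392, c(3, 10.5), vb_common, noise)
  )
}

#' Generate a synthetic specimen table
#'
#' Sexes are Bernoulli draws at each population's female proportion, ages
#' uniform on the population's range, the molar index back-solved from age
#' through the inverse of the aging relationship, and each size trait a
#' von Bertalanffy curve value (sex- and population-specific parameters)
#' plus Gaussian noise. Fully reproducible per seed.
#'
#' @param specs Named list of `population_spec` (names are the property
#'   labels).
#' @param seed Integer seed.
#' @return Validated specimen data frame (with derived `age_days`,
#'   `age_years`).
#' @export
gen_specimens <- function(specs = default_population_specs(), seed = 1L) {
  set.seed(as.integer(seed))
  rows <- list()
  for (prop in names(specs)) {
    sp <- specs[[prop]]
    sex <- ifelse(stats::runif(sp$n) < sp$female_prop, "female", "male")
    age <- stats::runif(sp$n, sp$age_range_years[1], sp$age_range_years[2])
    M <- molar_index_from_age(age * 365.25)
    if (any(M < 0)) stop("age range implies a negative molar index",
                         call. = FALSE)
    traits <- lapply(names(sp$noise_sd), function(tr) {
      vals <- vapply(seq_len(sp$n), function(i) {
        p <- sp$vb[[sex[i]]][[tr]]
        vb_curve(age[i], p[["L_inf"]], p[["k"]], p[["t0"]])
      }, numeric(1))
      vals + stats::rnorm(sp$n, 0, sp$noise_sd[[tr]])
    })
    names(traits) <- names(sp$noise_sd)
    rows[[prop]] <- data.frame(
      specimen_id = sprintf("%s_%03d", prop, seq_len(sp$n)),
      property = prop, sex = sex, molar_index = M,
      weight_kg = traits$weight_kg, pes_length_cm = traits$pes_length_cm,
      stringsAsFactors = FALSE
    )
  }
  out <- validate_specimens(do.call(rbind, rows))
  if (nrow(out$problems)) {
    stop("generator produced invalid records (tighten noise_sd): ",
         out$problems$message[1], call. = FALSE)
  }
  rownames(out$records) <- NULL
  out$records
}

# symmetrize / antisymmetrize a k x 3 field with respect to the pairing
symmetric_part <- function(R, pairing) (R + reflect_relabel(R, pairing)) / 2
antisymmetric_part <- function(R, pairing) (R - reflect_relabel(R, pairing)) / 2

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate synthetic cranial landmark configurations
#'
#' Builds a bilaterally symmetric labeled point-cloud template (mirror
#' pairs across the x = 0 plane plus midline points — deliberately not
#' anatomical), then for each specimen produces
#' `centroid_size x (template + allometric deformation + symmetric
#' individual variation + antisymmetric noise)` in a random orientation
#' and position. Centroid size follows a sex-specific von Bertalanffy
#' curve of age; the allometric deformation is a fixed symmetric unit
#' field scaled by `allometric_vector_scale x (log cs - mean log cs)`, so
#' shape covaries with size only when the scale is nonzero. Antisymmetric
#' noise adds `v` to a landmark and minus its mirrored image to the
#' partner, so the asymmetric component is nonzero only when
#' `asym_sd > 0`.
#'
#' @param records Specimen data frame (uses `specimen_id`, `sex`,
#'   `age_years`).
#' @param template_k Landmark count, `>= 8`.
#' @param allometric_vector_scale Magnitude of shape change per unit log
#'   centroid size.
#' @param asym_sd Scale of the antisymmetric noise (shape units).
#' @param ind_sd Scale of the symmetric individual variation.
#' @param cs_params Per-sex von Bertalanffy parameters for centroid size
#'   (arbitrary units).
#' @param cs_noise_sd Gaussian noise on centroid size.
#' @param seed Integer seed.
#' @return List: `configs` (list of `landmark_config` with the pairing
#'   attached), `pairing`, and `truth` (template, allometric field,
#'   centroid sizes) for calibration tests.
#' @export
gen_landmarks <- function(records, template_k = 12L,
                          allometric_vector_scale = 0.1, asym_sd = 0.005,
                          ind_sd = 0.01,
                          cs_params = list(
                            female = c(L_inf = 28, k = 0.45, t0 = -0.6),
                            male = c(L_inf = 32, k = 0.35, t0 = -0.6)),
                          cs_noise_sd = 0.3, seed = 1L) {
  if (template_k < 8L) stop("template_k must be >= 8", call. = FALSE)
  if (asym_sd < 0) stop("asym_sd must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  k <- as.integer(template_k)
  n_mid <- if (k %% 2L == 0L) 4L else 3L
  n_pair <- (k - n_mid) %/% 2L
  # template: right-side points at x > 0, mirrored left side, midline at x = 0
  right <- cbind(stats::runif(n_pair, 0.3, 1), stats::runif(n_pair, -1, 1),
                 stats::runif(n_pair, -1, 1))
  left <- right * matrix(c(-1, 1, 1), n_pair, 3, byrow = TRUE)
  mid <- cbind(0, stats::runif(n_mid, -1, 1), stats::runif(n_mid, -1, 1))
  template <- rbind(left, right, mid)
  template <- center_scale(template)
  pairing <- make_pairing(cbind(seq_len(n_pair), n_pair + seq_len(n_pair)),
                          midline = 2L * n_pair + seq_len(n_mid))
  # fixed symmetric allometric field, unit norm
  D <- symmetric_part(matrix(stats::rnorm(3 * k), k, 3), pairing)
  D <- D / sqrt(sum(D^2))

  n <- nrow(records)
  cs <- vapply(seq_len(n), function(i) {
    p <- cs_params[[records$sex[i]]]
    vb_curve(records$age_years[i], p[["L_inf"]], p[["k"]], p[["t0"]])
  }, numeric(1)) + stats::rnorm(n, 0, cs_noise_sd)
  if (any(cs <= 0)) stop("centroid-size curve produced non-positive sizes",
                         call. = FALSE)
  center <- mean(log(cs))
  configs <- vector("list", n)
  for (i in seq_len(n)) {
    sym_noise <- symmetric_part(matrix(stats::rnorm(3 * k, 0, ind_sd), k, 3),
                                pairing)
    asym_noise <- antisymmetric_part(
      matrix(stats::rnorm(3 * k, 0, asym_sd), k, 3), pairing)
    shape <- template +
      allometric_vector_scale * (log(cs[i]) - center) * D +
      sym_noise + asym_noise
    X <- cs[i] * shape %*% random_rotation() +
      matrix(stats::rnorm(3, 0, 50), k, 3, byrow = TRUE)
    configs[[i]] <- landmark_config(records$specimen_id[i], X,
                                    pairing = pairing)
  }
  list(configs = configs, pairing = pairing,
       truth = list(template = template, allometric_field = D,
                    centroid_sizes = stats::setNames(cs, records$specimen_id),
                    log_cs_center = center))
}

#' Simulation specification for the two-site vegetation series
#'
#' @param n_cells_per_site Grid cells per site.
#' @param baseline Mean index level of the north site.
#' @param site_offset Constant south-minus-north offset on the raw index.
#'   Note that a cell-constant offset cancels exactly under the per-cell
#'   monthly standardization (see the methods vignette).
#' @param seasonal_amplitude Amplitude of the annual sinusoid.
#' @param noise_sd Stationary standard deviation of the AR(1) noise.
#' @param ar_coefficient AR(1) coefficient in `[0, 1)`.
#' @param start,end Period bounds (dates).
#' @param cadence_days Composite interval (16 days).
#' @return An `evi_sim_spec` list.
#' @export
evi_sim_spec <- function(n_cells_per_site = 3L, baseline = 0.18,
                         site_offset = 0, seasonal_amplitude = 0.08,
                         noise_sd = 0.05, ar_coefficient = 0.5,
                         start = as.Date("2011-01-01"),
                         end = as.Date("2021-12-31"),
                         cadence_days = 16L) {
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop("end date before start date", call. = FALSE)
  stopifnot(n_cells_per_site >= 1L, ar_coefficient >= 0, ar_coefficient < 1,
            noise_sd >= 0)
  structure(list(n_cells_per_site = as.integer(n_cells_per_site),
                 baseline = baseline, site_offset = site_offset,
                 seasonal_amplitude = seasonal_amplitude,
                 noise_sd = noise_sd, ar_coefficient = ar_coefficient,
                 start = start, end = end,
                 cadence_days = as.integer(cadence_days)),
            class = "evi_sim_spec")
}

#' Generate a two-site vegetation-index series
#'
#' Per cell: `evi(t) = baseline + site_offset x I(south) +
#' seasonal_amplitude x sin(2 pi doy / 365.25) + AR(1) noise` on an exact
#' 16-day (or configured) cadence. Negative values are retained — clamping
#' is the analysis pipeline's job. The AR(1) noise is parameterized by its
#' stationary standard deviation, so moving-window smoothing has a visible
#' effect at the default coefficient 0.5.
#'
#' @param spec An `evi_sim_spec`.
#' @param seed Integer seed.
#' @return EVI observation data frame (`cell_id`, `lat`, `lon`, `date`,
#'   `evi`, `site`).
#' @export
gen_evi <- function(spec = evi_sim_spec(), seed = 1L) {
  stopifnot(inherits(spec, "evi_sim_spec"))
  set.seed(as.integer(seed))
  dates <- seq(spec$start, spec$end, by = spec$cadence_days)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- spec$seasonal_amplitude * sin(2 * pi * doy / 365.25)
  m <- length(dates)
  site_lat <- c(north = -30.362, south = -31.433)
  site_lon <- c(north = 140.696, south = 140.797)
  out <- list()
  for (site in c("north", "south")) {
    for (cell in seq_len(spec$n_cells_per_site)) {
      innov_sd <- spec$noise_sd * sqrt(1 - spec$ar_coefficient^2)
      noise <- numeric(m)
      noise[1] <- stats::rnorm(1, 0, spec$noise_sd)
      if (m > 1L) for (t in 2:m) {
        noise[t] <- spec$ar_coefficient * noise[t - 1] +
          stats::rnorm(1, 0, innov_sd)
      }
      evi <- spec$baseline + spec$site_offset * (site == "south") +
        seasonal + noise
      out[[length(out) + 1L]] <- data.frame(
        cell_id = sprintf("%s_c%02d", site, cell),
        lat = site_lat[[site]] + 0.002 * cell,
        lon = site_lon[[site]] + 0.002 * cell,
        date = dates, evi = evi, site = site, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
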