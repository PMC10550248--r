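#' Clamp negative vegetation-index values to zero
#'
#' An enhanced vegetation index below zero indicates absence of vegetation
#' in the grid cell, so negative values are set to zero before anomaly
#' computation.
#'
#' @param observations EVI observation data frame (column `evi`).
#' @return Same data frame with `evi = max(evi, 0)`; the number of clamped
#'   values is attached as attribute `"n_clamped"`.
#' @export
clamp_nonnegative <- function(observations) {
  stopifnot("evi" %in% names(observations))
  neg <- observations$evi < 0
  observations$evi[neg] <- 0
  attr(observations, "n_clamped") <- sum(neg)
  observations
}

#' Seasonal standardized vegetation-index anomaly
#'
#' For each grid cell, observations are grouped by calendar month over the
#' whole period and standardized within the group:
#' \deqn{\Delta EVI(i,t) = (EVI(i,t) - mean_m) / sd_m}
#' where `mean_m`, `sd_m` are the cell's mean and (sample, n-1) standard
#' deviation over all dates falling in calendar month `m`. The anomaly is
#' unitless; one unit is one within-cell monthly standard deviation, and
#' zero is the cell's baseline productivity for that month. Groups with
#' zero standard deviation yield anomaly 0 and are flagged.
#'
#' @param observations EVI data frame (`cell_id`, `date`, `evi`, `site`).
#' @return Data frame of class `anomaly_series`: input columns plus
#'   `month`, `delta_evi`, `sd_zero_flag`; per-cell-month baselines in
#'   attribute `"month_baselines"`.
#' @export
seasonal_anomaly <- function(observations) {
  need <- c("cell_id", "date", "evi", "site")
  stopifnot(all(need %in% names(observations)))
  obs <- observations[order(observations$site, observations$cell_id,
                            observations$date), , drop = FALSE]
  obs$month <- as.integer(format(as.Date(obs$date), "%m"))
  key <- interaction(obs$cell_id, obs$month, drop = TRUE)
  sizes <- table(key)
  if (any(sizes < 2L)) {
    bad <- names(sizes)[sizes < 2L][1]
    stop("cell-month group ", bad,
         " has a single observation; need >= 2 to standardize",
         call. = FALSE)
  }
  mu <- stats::ave(obs$evi, key, FUN = mean)
  sd_ <- stats::ave(obs$evi, key, FUN = stats::sd)
  zero_sd <- sd_ == 0
  obs$delta_evi <- ifelse(zero_sd, 0, (obs$evi - mu) / ifelse(zero_sd, 1, sd_))
  obs$sd_zero_flag <- zero_sd
  baselines <- unique(data.frame(cell_id = obs$cell_id, month = obs$month,
                                 mean = mu, sd = sd_,
                                 stringsAsFactors = FALSE))
  rownames(obs) <- NULL
  attr(obs, "month_baselines") <- baselines
  class(obs) <- c("anomaly_series", class(obs))
  obs
}

#' Temporal moving-window smoothing of anomalies
#'
#' Averages each cell's anomalies over `window` consecutive composites
#' starting at each date (default 6 composites of 16 days = 96 days),
#' suppressing residual noise from clouds or aerosols. The smoothed value
#' is defined only where the full window fits before the series end.
#'
#' @param anomalies An `anomaly_series` (column `delta_evi`).
#' @param window Window length in composites.
#' @param stride Composite stride between the averaged samples; the
#'   default 1 averages consecutive composites. (A literal 8-composite
#'   stride is selectable but spans far more than the nominal 96 days.)
#' @return The input with column `w_smoothed` added (`NA` where the window
#'   does not fit).
#' @export
moving_window <- function(anomalies, window = 6L, stride = 1L) {
  stopifnot("delta_evi" %in% names(anomalies), window >= 1L, stride >= 1L)
  window <- as.integer(window); stride <- as.integer(stride)
  anomalies$w_smoothed <- NA_real_
  for (cid in unique(anomalies$cell_id)) {
    sel <- which(anomalies$cell_id == cid)
    sel <- sel[order(anomalies$date[sel])]
    x <- anomalies$delta_evi[sel]
    m <- length(x)
    span <- (window - 1L) * stride
    if (span + 1L > m) {
      warning("window (", span + 1L, " composites) longer than series for cell ",
              cid, call. = FALSE)
      next
    }
    w <- vapply(seq_len(m - span), function(t) {
      mean(x[t + stride * (0:(window - 1L))])
    }, numeric(1))
    anomalies$w_smoothed[sel[seq_len(m - span)]] <- w
  }
  anomalies
}

#' Randomization test for a between-site median difference
#'
#' Compares the observed difference in medians (south minus north) with a
#' null distribution built by randomly reassigning values between the two
#' sites: `full_shuffle` pools all values and re-splits them at the
#' original sample sizes each iteration; `within_time_swap` flips the two
#' site labels independently at each time point (requires the two series
#' aligned on shared dates, equal length). The 2.5th and 97.5th
#' percentiles of the null draws give the interval consistent with
#' complete randomness; the two-sided p-value counts null draws at least
#' as extreme (in absolute value) as the observed difference, with the
#' observed case included in numerator and denominator.
#'
#' For tiny samples, `exhaustive = TRUE` (full_shuffle only) enumerates
#' every split of the pooled values at the original sizes instead of
#' sampling, giving the exact randomization p-value.
#'
#' @param south,north Numeric vectors of (anomaly) values per site.
#' @param n_iter Number of random reassignments.
#' @param seed Integer seed.
#' @param mode `"full_shuffle"` or `"within_time_swap"`.
#' @param exhaustive Enumerate all splits (full_shuffle, small n only).
#' @return Object of class `randomization_result`: `observed`,
#'   `null_draws`, `ci_low`, `ci_high`, `p`, `n_iter`, `seed`, `mode`.
#' @export
randomization_median_test <- function(south, north, n_iter = 10000L,
                                      seed = 1L,
                                      mode = c("full_shuffle",
                                               "within_time_swap"),
                                      exhaustive = FALSE) {
  mode <- match.arg(mode)
  south <- south[!is.na(south)]; north <- north[!is.na(north)]
  if (!length(south) || !length(north)) {
    stop("both sites need at least one value", call. = FALSE)
  }
  if (exhaustive) {
    if (mode != "full_shuffle") {
      stop("exhaustive enumeration is defined for full_shuffle only",
           call. = FALSE)
    }
    pool <- c(south, north)
    splits <- utils::combn(length(pool), length(south))
    null_draws <- apply(splits, 2, function(idx) {
      stats::median(pool[idx]) - stats::median(pool[-idx])
    })
    observed <- stats::median(south) - stats::median(north)
    ci <- stats::quantile(null_draws, c(0.025, 0.975), names = FALSE)
    p <- mean(abs(null_draws) >= abs(stats::median(south) -
                                       stats::median(north)))
    return(structure(
      list(observed = observed, null_draws = null_draws,
           ci_low = ci[1], ci_high = ci[2], p = p,
           n_iter = ncol(splits), seed = NA_integer_,
           mode = "exhaustive"),
      class = "randomization_result"))
  }
  if (n_iter < 100L) {
    warning("fewer than 100 iterations: percentile bounds are unstable",
            call. = FALSE)
  }
  observed <- stats::median(south) - stats::median(north)
  set.seed(as.integer(seed))
  ns <- length(south)
  if (mode == "within_time_swap") {
    if (length(south) != length(north)) {
      stop("within_time_swap requires series aligned on shared dates",
           call. = FALSE)
    }
    null_draws <- vapply(seq_len(n_iter), function(i) {
      flip <- stats::runif(ns) < 0.5
      s <- ifelse(flip, north, south)
      n_ <- ifelse(flip, south, north)
      stats::median(s) - stats::median(n_)
    }, numeric(1))
  } else {
    pool <- c(south, north)
    np <- length(pool)
    null_draws <- vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(np, ns)
      stats::median(pool[idx]) - stats::median(pool[-idx])
    }, numeric(1))
  }
  ci <- stats::quantile(null_draws, c(0.025, 0.975), names = FALSE)
  p <- (1 + sum(abs(null_draws) >= abs(observed))) / (n_iter + 1)
  structure(
    list(observed = observed, null_draws = null_draws,
         ci_low = ci[1], ci_high = ci[2], p = p,
         n_iter = as.integer(n_iter), seed = as.integer(seed), mode = mode),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "Randomization median-difference test (%s, %d iterations)\n  observed (south - north) = %.4g\n  null 2.5th/97.5th percentiles: [%.4g, %.4g]\n  two-sided p = %.4g\n",
    x$mode, x$n_iter, x$observed, x$ci_low, x$ci_high, x$p))
  invisible(x)
}
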