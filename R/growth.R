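#' Von Bertalanffy growth curve
#'
#' \deqn{L(t) = L_\infty (1 - e^{-k (t - t_0)})}
#' with asymptotic size `L_inf`, growth coefficient `k` (per year when ages
#' are in years), and `t0` the theoretical age at size zero.
#'
#' @param t Ages.
#' @param L_inf,k,t0 Curve parameters.
#' @return Sizes at `t`.
#' @export
vb_curve <- function(t, L_inf, k, t0) {
  L_inf * (1 - exp(-k * (t - t0)))
}

vb_start <- function(ages, sizes) {
  L0 <- 1.05 * max(sizes)
  # slope of log(1 - size/L0) vs age gives -k; guard against log of <= 0
  frac <- pmin(pmax(1 - sizes / L0, 1e-6), 1)
  sl <- stats::coef(stats::lm(log(frac) ~ ages))
  k0 <- max(-unname(sl[2]), 0.05)
  c(L_inf = L0, k = k0, t0 = 0)
}

vb_control <- function() {
  minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-8, ptol = 1e-8)
}

# Levenberg-Marquardt least squares with the package's convergence settings;
# returns estimates, standard errors and the usual fit summaries
lm_least_squares <- function(par, resid_fn) {
  out <- minpack.lm::nls.lm(par = par, fn = resid_fn,
                            control = vb_control())
  if (!out$info %in% 1:3) {
    stop("growth fit did not converge: ", out$message,
         " (best iterate: ", paste(signif(out$par, 6), collapse = ", "),
         "; gradient norm ", signif(sqrt(sum(out$fvec^2)), 6), ")",
         call. = FALSE)
  }
  rss <- stats::deviance(out)
  df <- length(out$fvec) - length(out$par)
  sigma2 <- rss / df
  # (J'J)^-1 via Cholesky; SVD pseudo-inverse when the fit is exact enough
  # to make the normal matrix numerically singular
  inv <- tryCatch(chol2inv(chol(out$hessian)), error = function(e) {
    sv <- svd(out$hessian)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  vcov <- sigma2 * inv
  dimnames(vcov) <- list(names(out$par), names(out$par))
  list(coef = out$par,
       se = stats::setNames(sqrt(pmax(diag(vcov), 0)), names(out$par)),
       vcov = vcov, residual_sd = sqrt(sigma2), df = df, rss = rss,
       iterations = out$niter, residuals = out$fvec)
}

#' Fit a von Bertalanffy growth curve to one group
#'
#' Least-squares fit of `size ~ L_inf (1 - exp(-k (age - t0)))` by damped
#' Gauss-Newton (Levenberg-Marquardt) with relative tolerance 1e-8 and at
#' most 200 iterations. Self-start: `L_inf0 = 1.05 max(size)`, `k0` from
#' the slope of `log(1 - size/L_inf0)` against age, `t0_0 = 0`.
#'
#' @param ages,sizes Numeric vectors (ages in years); `n >= 4` and positive
#'   age span required.
#' @param init Optional named start `c(L_inf=, k=, t0=)`.
#' @return Object of class `vb_fit`: `coef`, `se`, `vcov`, `residual_sd`,
#'   `df`, `n`, `converged`, `fitted`, `trait` (filled by callers).
#' @export
fit_vb <- function(ages, sizes, init = NULL) {
  stopifnot(length(ages) == length(sizes))
  if (length(ages) < 4L) stop("need n >= 4 observations", call. = FALSE)
  if (diff(range(ages)) <= 0) stop("ages must span a positive range",
                                   call. = FALSE)
  start <- if (is.null(init)) vb_start(ages, sizes) else init
  ls <- lm_least_squares(start, function(p) {
    sizes - vb_curve(ages, p[["L_inf"]], p[["k"]], p[["t0"]])
  })
  structure(
    list(
      coef = ls$coef, se = ls$se, vcov = ls$vcov,
      residual_sd = ls$residual_sd, df = ls$df, n = length(ages),
      converged = TRUE, iterations = ls$iterations,
      fitted = sizes - ls$residuals, rss = ls$rss
    ),
    class = "vb_fit"
  )
}

#' @export
print.vb_fit <- function(x, ...) {
  cat("Von Bertalanffy fit (n =", x$n, "):\n")
  print(round(rbind(estimate = x$coef, se = x$se), 4))
  cat(sprintf("residual sd %.4g, df %d, converged: %s\n",
              x$residual_sd, x$df, x$converged))
  invisible(x)
}

#' Compare von Bertalanffy parameters between two groups
#'
#' Joint fit parameterized as baseline + delta x indicator(group 2) for
#' each of `L_inf`, `k`, `t0` (six parameters). Contrasts are Wald t
#' statistics `delta / SE(delta)` with `df = n - 6` and two-sided p-values.
#'
#' @param records Specimen data frame (must contain `age_years`, the trait
#'   column, and the grouping column).
#' @param trait Trait column name: `"cranial_size"`, `"weight_kg"`, or
#'   `"pes_length_cm"` (any numeric column works).
#' @param grouping `"sex"` or `"property"` (any two-level column works).
#' @return Object of class `vb_group_fit`: per-group `coef`, `deltas`
#'   table (estimate, se, t, df, p per parameter), `groups`, `n`, `df`,
#'   `residual_sd`, `rss`, `converged`.
#' @export
compare_vb_groups <- function(records, trait, grouping = c("sex", "property")) {
  grouping <- if (length(grouping) == 1L) grouping else match.arg(grouping)
  stopifnot(is.data.frame(records), trait %in% names(records),
            grouping %in% names(records), "age_years" %in% names(records))
  keep <- stats::complete.cases(records[, c("age_years", trait, grouping)])
  records <- records[keep, , drop = FALSE]
  groups <- sort(unique(as.character(records[[grouping]])))
  if (length(groups) != 2L) stop("grouping must have exactly two levels",
                                 call. = FALSE)
  g <- as.numeric(records[[grouping]] == groups[2])
  if (min(table(g)) < 4L) stop("each group needs n >= 4", call. = FALSE)
  ages <- records$age_years
  sizes <- records[[trait]]

  base <- vb_start(ages, sizes)
  start <- c(L = base[["L_inf"]], dL = 0, k = base[["k"]], dk = 0,
             t0 = 0, dt0 = 0)
  ls <- lm_least_squares(start, function(p) {
    sizes - (p[["L"]] + p[["dL"]] * g) *
      (1 - exp(-(p[["k"]] + p[["dk"]] * g) *
                 (ages - (p[["t0"]] + p[["dt0"]] * g))))
  })
  cf <- ls$coef
  n <- length(ages)
  df <- n - 6L
  delta_names <- c(L_inf = "dL", k = "dk", t0 = "dt0")
  deltas <- do.call(rbind, lapply(names(delta_names), function(p) {
    dn <- delta_names[[p]]
    est <- cf[[dn]]
    se <- ls$se[[dn]]
    tt <- est / se
    data.frame(parameter = p, estimate = est, se = se, t = tt, df = df,
               p = 2 * stats::pt(-abs(tt), df), stringsAsFactors = FALSE)
  }))
  rownames(deltas) <- NULL
  per_group <- list(
    stats::setNames(cf[c("L", "k", "t0")], c("L_inf", "k", "t0")),
    stats::setNames(cf[c("L", "k", "t0")] + cf[c("dL", "dk", "dt0")],
                    c("L_inf", "k", "t0"))
  )
  names(per_group) <- groups
  structure(
    list(
      trait = trait, grouping = grouping, groups = groups,
      coef = per_group, deltas = deltas, n = n, df = df,
      residual_sd = ls$residual_sd, rss = ls$rss,
      converged = TRUE
    ),
    class = "vb_group_fit"
  )
}

#' @export
print.vb_group_fit <- function(x, ...) {
  cat(sprintf("Von Bertalanffy comparison: %s ~ age by %s (n = %d, df = %d)\n",
              x$trait, x$grouping, x$n, x$df))
  for (gname in x$groups) {
    cat(sprintf("  %s: L_inf = %.4g, k = %.4g, t0 = %.4g\n", gname,
                x$coef[[gname]]["L_inf"], x$coef[[gname]]["k"],
                x$coef[[gname]]["t0"]))
  }
  d <- x$deltas
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  delta %-5s t_%d = %.3f, p = %.4g\n",
                d$parameter[i], d$df[i], d$t[i], d$p[i]))
  }
  invisible(x)
}

#' Age at which two fitted growth curves diverge
#'
#' Smallest age at which the absolute difference between the two group
#' curves exceeds `threshold` (trait units), located by grid scan plus
#' bisection. Returns `Inf` when the curves never separate by more than the
#' threshold; a `non_monotone` flag is set when the difference drops back
#' below the threshold after the first crossing.
#'
#' @param fit A `vb_group_fit`.
#' @param threshold Divergence threshold, same units as the trait.
#' @param t_max Upper search bound in years.
#' @return List `age_years`, `non_monotone`.
#' @export
divergence_age <- function(fit, threshold, t_max = 50) {
  stopifnot(inherits(fit, "vb_group_fit"), threshold >= 0)
  p1 <- fit$coef[[1]]
  p2 <- fit$coef[[2]]
  dfun <- function(t) {
    abs(vb_curve(t, p1["L_inf"], p1["k"], p1["t0"]) -
        vb_curve(t, p2["L_inf"], p2["k"], p2["t0"]))
  }
  t_lo <- max(p1["t0"], p2["t0"])
  grid <- seq(t_lo, t_max, length.out = 4096L)
  vals <- dfun(grid)
  above <- vals > threshold
  if (!any(above)) return(list(age_years = Inf, non_monotone = FALSE))
  first <- which(above)[1]
  if (first == 1L) {
    age <- grid[1]
  } else {
    lo <- grid[first - 1L]; hi <- grid[first]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (dfun(mid) > threshold) hi <- mid else lo <- mid
    }
    age <- hi
  }
  # non-monotone: difference dips back under the threshold after crossing
  later <- vals[first:length(vals)]
  non_mono <- any(later <= threshold)
  list(age_years = unname(age), non_monotone = non_mono)
}
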