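#' Residual-randomization permutation linear model (RRPP)
#'
#' Sequential (type-I) sums of squares for an ordered model formula over a
#' possibly multivariate response, with permutation p-values obtained by
#' residual randomization under the reduced model: for each term, the
#' residuals of the model containing all preceding terms are randomly
#' permuted and added back to the reduced-model fitted values, and the
#' term's F statistic is recomputed on the pseudo-data. The observed
#' arrangement counts as one permutation, so
#' `p = (1 + #\{F_perm >= F_obs\}) / n_perm` and the smallest attainable p
#' is `1/n_perm`.
#'
#' @param Y Numeric response: length-n vector or n x p matrix.
#' @param formula Right-hand-side formula over columns of `data`, terms in
#'   the order they should enter (sequential SS).
#' @param data Data frame of covariates/factors.
#' @param n_perm Total permutations including the observed one.
#' @param seed Integer seed for the permutation schedule.
#' @param randomize `"residual"` (RRPP, default) or `"full"` (permute rows
#'   of `Y` directly).
#' @return Object of class `perm_lm`: data frame `aov_table` with per-term
#'   `df`, `SS`, `R2`, `F`, `p`, plus `SS_total`, `SS_residual`,
#'   `df_residual`, `R2_residual`, `n_perm`, `seed`.
#' @export
rrpp_lm <- function(Y, formula, data, n_perm = 1000L, seed = 1L,
                    randomize = c("residual", "full")) {
  randomize <- match.arg(randomize)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(nrow(data) == n, n_perm >= 1L)
  mt <- stats::terms(formula, data = data)
  term_labels <- attr(mt, "term.labels")
  if (length(term_labels) == 0L) stop("formula has no terms", call. = FALSE)
  X <- stats::model.matrix(mt, data)
  asn <- attr(X, "assign")
  qr_full <- qr(X)
  if (qr_full$rank < ncol(X)) {
    dropped <- colnames(X)[qr_full$pivot[(qr_full$rank + 1L):ncol(X)]]
    stop("rank-deficient design: column(s) ",
         paste(dropped, collapse = ", "), " aliased", call. = FALSE)
  }
  K <- length(term_labels)
  # nested QR decompositions: terms 0 (intercept only) .. K
  qrs <- lapply(0:K, function(j) qr(X[, asn <= j, drop = FALSE]))
  ranks <- vapply(qrs, `[[`, integer(1), "rank")
  df_terms <- diff(ranks)
  df_res <- n - ranks[K + 1L]
  if (df_res <= 0) stop("n must exceed the total model df", call. = FALSE)

  # squared norm of the projection of M onto the column space of each qr
  proj_ss <- function(qrj, M) sum(qr.fitted(qrj, M)^2)
  fit_ss <- vapply(qrs, proj_ss, numeric(1), M = Y)
  ss_y <- sum(Y^2)
  SS_terms <- pmax(diff(fit_ss), 0)
  SS_resid <- max(ss_y - fit_ss[K + 1L], 0)
  SS_total <- max(ss_y - fit_ss[1L], 0)    # corrected for the intercept
  # exact fits leave a residual SS of numerical-noise size; treat as zero
  eps <- 1e-12 * max(ss_y, 1)
  f_stat <- function(num_ss, num_df, den_ss) {
    num <- num_ss / num_df
    den <- den_ss / df_res          # scalar
    if (den <= eps) ifelse(num <= eps, 0, Inf) else num / den
  }
  F_obs <- f_stat(SS_terms, df_terms, SS_resid)

  fitted_red <- lapply(1:K, function(j) qr.fitted(qrs[[j]], Y))
  resid_red <- lapply(1:K, function(j) Y - fitted_red[[j]])

  exceed <- rep(0L, K)
  if (n_perm > 1L) {
    set.seed(as.integer(seed))
    perms <- replicate(n_perm - 1L, sample.int(n))
    for (i in seq_len(n_perm - 1L)) {
      idx <- perms[, i]
      for (j in 1:K) {
        Yp <- if (randomize == "residual") {
          fitted_red[[j]] + resid_red[[j]][idx, , drop = FALSE]
        } else {
          Y[idx, , drop = FALSE]
        }
        ss_fit_hi <- proj_ss(qrs[[j + 1L]], Yp)
        ss_fit_lo <- proj_ss(qrs[[j]], Yp)
        rss_p <- max(sum(Yp^2) - proj_ss(qrs[[K + 1L]], Yp), 0)
        Fp <- f_stat(max(ss_fit_hi - ss_fit_lo, 0), df_terms[j], rss_p)
        if (Fp >= F_obs[j]) exceed[j] <- exceed[j] + 1L
      }
    }
  }
  p <- (1L + exceed) / n_perm

  structure(
    list(
      aov_table = data.frame(
        term = term_labels, df = df_terms, SS = SS_terms,
        R2 = SS_terms / SS_total, F = F_obs, p = p,
        stringsAsFactors = FALSE
      ),
      SS_total = SS_total, SS_residual = SS_resid, df_residual = df_res,
      R2_residual = SS_resid / SS_total,
      n_perm = as.integer(n_perm), seed = as.integer(seed),
      randomize = randomize, formula = formula
    ),
    class = "perm_lm"
  )
}

#' @export
print.perm_lm <- function(x, ...) {
  cat(sprintf("Permutation linear model (%s randomization, %d permutations)\n",
              x$randomize, x$n_perm))
  tab <- x$aov_table
  tab$SS <- signif(tab$SS, 5); tab$R2 <- round(tab$R2, 3)
  tab$F <- round(tab$F, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("residual: df %d, R2 %.3f\n", x$df_residual, x$R2_residual))
  invisible(x)
}

#' Interpopulation tests per sex
#'
#' For each sex separately, fits permutation linear models
#' `response ~ age + population` for four responses: cranial shape
#' (multivariate Procrustes coordinates), cranial centroid size, body
#' weight, and pes length. The `age:population` interaction is then added
#' and retained in the report when its permutation p-value is at most
#' `alpha`. Records should already be trimmed to a common age range.
#'
#' @param records Specimen data frame with `sex`, `property`, `age_years`,
#'   `weight_kg`, `pes_length_cm`, `specimen_id`.
#' @param shapes Optional `aligned_shapes` object (see [gpa()] /
#'   [bilateral_symmetry()]); supplies the shape response and centroid
#'   sizes, matched to records by `specimen_id`. When `NULL` the shape and
#'   cranial-size rows are skipped.
#' @param shape_component `"symmetric"` (default) or `"full"`: which
#'   Procrustes coordinates enter the shape model.
#' @param n_perm,seed,alpha See [rrpp_lm()]; `alpha` is the interaction
#'   retention threshold.
#' @return Object of class `interpop_tests`: nested list `fits[[sex]]
#'   [[response]]` of `perm_lm`, logical `interaction_retained`, and a tidy
#'   `table` (sex, response, term, df, R2, F, p).
#' @export
interpopulation_tests <- function(records, shapes = NULL,
                                  shape_component = c("symmetric", "full"),
                                  n_perm = 1000L, seed = 1L, alpha = 0.05) {
  shape_component <- match.arg(shape_component)
  stopifnot(is.data.frame(records))
  tab <- table(records$sex, records$property)
  if (any(tab == 0)) stop("a sex x population cell is empty", call. = FALSE)
  fits <- list()
  rows <- list()
  retained <- list()
  seed_i <- as.integer(seed)
  for (sx in sort(unique(as.character(records$sex)))) {
    rs <- records[records$sex == sx, , drop = FALSE]
    dat <- data.frame(age = rs$age_years,
                      population = factor(rs$property))
    responses <- list(weight = rs$weight_kg, pes = rs$pes_length_cm)
    if (!is.null(shapes)) {
      m <- match(rs$specimen_id, shapes$specimen_ids)
      if (any(is.na(m))) stop("records without matching landmark data: ",
                              paste(rs$specimen_id[is.na(m)], collapse = ", "),
                              call. = FALSE)
      comp <- if (shape_component == "symmetric" &&
                  !is.null(shapes$symmetric_component))
        shapes$symmetric_component else shapes$procrustes_coords
      responses <- c(
        list(shape = flatten_shapes(comp)[m, , drop = FALSE],
             cranial_size = shapes$centroid_sizes[m]),
        responses
      )
    }
    for (resp in names(responses)) {
      seed_i <- seed_i + 1L
      main <- rrpp_lm(responses[[resp]], ~ age + population, dat,
                      n_perm = n_perm, seed = seed_i)
      seed_i <- seed_i + 1L
      inter <- rrpp_lm(responses[[resp]], ~ age + population + age:population,
                       dat, n_perm = n_perm, seed = seed_i)
      ip <- inter$aov_table$p[inter$aov_table$term == "age:population"]
      keep <- ip <= alpha
      retained[[paste(sx, resp, sep = ".")]] <- keep
      use <- if (keep) inter else main
      fits[[sx]][[resp]] <- use
      at <- use$aov_table
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sx, response = resp, term = at$term, df = at$df,
        R2 = at$R2, F = at$F, p = at$p, stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(fits = fits, interaction_retained = unlist(retained),
         table = do.call(rbind, rows), alpha = alpha, n_perm = n_perm,
         seed = as.integer(seed)),
    class = "interpop_tests"
  )
}

#' @export
print.interpop_tests <- function(x, ...) {
  cat("Interpopulation permutation linear model tests\n")
  tab <- x$table
  tab$R2 <- round(tab$R2, 3); tab$F <- round(tab$F, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

# n x k x 3 array -> n x 3k matrix
flatten_shapes <- function(arr) {
  stopifnot(length(dim(arr)) == 3L)
  n <- dim(arr)[1]
  matrix(arr, nrow = n)
}
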