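#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid — the standard size measure in geometric morphometrics.
#'
#' @param config A `landmark_config` or a k x 3 coordinate matrix.
#' @return Positive scalar.
#' @export
centroid_size <- function(config) {
  X <- if (inherits(config, "landmark_config")) config$coordinates else
    as.matrix(config)
  Xc <- sweep(X, 2, colMeans(X))
  cs <- sqrt(sum(Xc^2))
  if (cs == 0) stop("zero centroid size: all landmarks coincident",
                    call. = FALSE)
  cs
}

# optimal rotation (det +1) carrying X onto target C: argmin ||X R - C||
opa_rotation <- function(X, C) {
  M <- crossprod(X, C)
  sv <- svd(M)
  d <- det(sv$u %*% t(sv$v))
  sv$u %*% diag(c(1, 1, sign(d))) %*% t(sv$v)
}

center_scale <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  Xc / sqrt(sum(Xc^2))
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of landmark configurations: each is centered
#' at the origin, scaled to unit centroid size, and rotated onto the
#' current consensus by the orthogonal least-squares solution constrained
#' to determinant +1 (no reflections); the consensus is then updated.
#' Iteration stops when the summed squared change in the consensus falls
#' below `tol`.
#'
#' @param configs List of `landmark_config` (equal landmark count) or of
#'   k x 3 matrices.
#' @param tol Convergence tolerance on the consensus change.
#' @param max_iter Iteration cap.
#' @return Object of class `aligned_shapes`: `procrustes_coords`
#'   (n x k x 3), `centroid_sizes` (original units), `consensus` (k x 3,
#'   unit centroid size), `specimen_ids`, `labels`, `convergence`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (length(configs) < 2L) stop("need at least 2 configurations",
                                 call. = FALSE)
  ids <- vapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    if (inherits(cf, "landmark_config")) cf$specimen_id else paste0("spec", i)
  }, character(1))
  mats <- lapply(configs, function(cf) {
    if (inherits(cf, "landmark_config")) cf$coordinates else as.matrix(cf)
  })
  ks <- vapply(mats, nrow, integer(1))
  if (length(unique(ks)) != 1L) stop("configurations differ in landmark count",
                                     call. = FALSE)
  k <- ks[1]
  labels <- if (inherits(configs[[1]], "landmark_config"))
    configs[[1]]$labels else paste0("L", seq_len(k))
  css <- vapply(mats, centroid_size, numeric(1))
  for (i in seq_along(mats)) {
    sv <- svd(sweep(mats[[i]], 2, colMeans(mats[[i]])))
    if (sum(sv$d > 1e-10 * sv$d[1]) < 2L) {
      stop("alignment error: configuration '", ids[i],
           "' is degenerate (rank < 2)", call. = FALSE)
    }
  }
  scaled <- lapply(mats, center_scale)
  consensus <- scaled[[1]]
  iter <- 0L
  change <- Inf
  while (iter < max_iter && change > tol) {
    iter <- iter + 1L
    scaled <- lapply(scaled, function(X) X %*% opa_rotation(X, consensus))
    new_consensus <- Reduce(`+`, scaled) / length(scaled)
    new_consensus <- center_scale(new_consensus)
    change <- sum((new_consensus - consensus)^2)
    consensus <- new_consensus
  }
  # reported consensus is the plain coordinate-wise mean of the aligned set
  consensus <- Reduce(`+`, scaled) / length(scaled)
  arr <- array(NA_real_, dim = c(length(scaled), k, 3),
               dimnames = list(ids, labels, c("x", "y", "z")))
  for (i in seq_along(scaled)) arr[i, , ] <- scaled[[i]]
  structure(
    list(procrustes_coords = arr, centroid_sizes = stats::setNames(css, ids),
         consensus = consensus, specimen_ids = ids, labels = labels,
         convergence = list(iterations = iter, final_change = change)),
    class = "aligned_shapes"
  )
}

#' @export
print.aligned_shapes <- function(x, ...) {
  d <- dim(x$procrustes_coords)
  cat(sprintf("Aligned shapes: %d specimens, %d landmarks (GPA %d iterations, change %.2e)\n",
              d[1], d[2], x$convergence$iterations, x$convergence$final_change))
  if (!is.null(x$symmetric_component)) {
    cat("  bilateral symmetry components present\n")
  }
  invisible(x)
}

#' Reflect a configuration across the midsagittal plane and relabel
#'
#' Negates the x coordinate and swaps each bilateral pair's rows. Applying
#' it twice returns the original configuration. The choice of reflection
#' plane is immaterial once configurations are superimposed, because any
#' two mirror forms differ only by a rotation.
#'
#' @param X k x 3 coordinate matrix.
#' @param pairing A `landmark_pairing`.
#' @return Reflected, relabeled k x 3 matrix.
#' @export
reflect_relabel <- function(X, pairing) {
  Xm <- X
  Xm[, 1] <- -X[, 1]
  out <- Xm
  if (nrow(pairing$pairs)) {
    out[pairing$pairs[, 1], ] <- Xm[pairing$pairs[, 2], ]
    out[pairing$pairs[, 2], ] <- Xm[pairing$pairs[, 1], ]
  }
  out
}

#' Bilateral (object) symmetry decomposition
#'
#' For each specimen a mirrored copy is built with [reflect_relabel()];
#' originals and mirrored copies are jointly superimposed by [gpa()]. The
#' symmetric component of a specimen is the mean of its two aligned
#' copies, the asymmetric component half their difference, so
#' `symmetric + asymmetric` reconstructs the aligned original exactly.
#'
#' @param configs List of `landmark_config` (raw coordinates).
#' @param pairing A `landmark_pairing` covering all landmarks; defaults to
#'   the pairing attached to the first configuration.
#' @param midline_tol Warn when an aligned midline landmark lies farther
#'   than this fraction of (unit) centroid size from the least-squares
#'   midsagittal plane.
#' @return An `aligned_shapes` with `procrustes_coords` (aligned
#'   originals), `symmetric_component`, `asymmetric_component`,
#'   `consensus` (mean over originals and mirrored copies), and original
#'   `centroid_sizes`.
#' @export
bilateral_symmetry <- function(configs, pairing = NULL, midline_tol = 0.05) {
  if (is.null(pairing)) pairing <- configs[[1]]$pairing
  if (is.null(pairing)) stop("no pairing map supplied", call. = FALSE)
  k <- nrow(if (inherits(configs[[1]], "landmark_config"))
    configs[[1]]$coordinates else configs[[1]])
  check_pairing(pairing, k)
  n <- length(configs)
  mats <- lapply(configs, function(cf) {
    if (inherits(cf, "landmark_config")) cf$coordinates else as.matrix(cf)
  })
  ids <- vapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    if (inherits(cf, "landmark_config")) cf$specimen_id else paste0("spec", i)
  }, character(1))
  mirrored <- lapply(mats, reflect_relabel, pairing = pairing)
  joint <- gpa(c(mats, mirrored))
  arr <- joint$procrustes_coords
  orig <- arr[seq_len(n), , , drop = FALSE]
  mirr <- arr[n + seq_len(n), , , drop = FALSE]
  sym <- (orig + mirr) / 2
  asym <- (orig - mirr) / 2
  dimnames(orig)[[1]] <- dimnames(sym)[[1]] <- dimnames(asym)[[1]] <- ids

  # midsagittal plane check on the aligned originals
  if (length(pairing$midline) >= 3L) {
    for (i in seq_len(n)) {
      P <- orig[i, pairing$midline, , drop = TRUE]
      Pc <- sweep(P, 2, colMeans(P))
      nrm <- svd(Pc)$v[, 3]
      dist <- abs(Pc %*% nrm)
      if (any(dist > midline_tol)) {
        warning(sprintf(
          "specimen '%s': midline landmark(s) %s lie beyond %.0f%% of centroid size from the fitted midsagittal plane (max %.3g)",
          ids[i],
          paste(pairing$midline[dist > midline_tol], collapse = ", "),
          100 * midline_tol, max(dist)), call. = FALSE)
      }
    }
  }

  css <- vapply(mats, centroid_size, numeric(1))
  structure(
    list(procrustes_coords = orig, symmetric_component = sym,
         asymmetric_component = asym,
         centroid_sizes = stats::setNames(css, ids),
         consensus = joint$consensus, specimen_ids = ids,
         labels = joint$labels, pairing = pairing,
         convergence = joint$convergence),
    class = "aligned_shapes"
  )
}

#' Ontogenetic allometry model of shape on size
#'
#' Permutation linear model of the (by default symmetric-component)
#' Procrustes coordinates on the natural log of centroid size, sex, and
#' their interaction, with the observed multivariate regression retained
#' so predicted shapes can be evaluated at chosen sizes.
#'
#' @param shapes An `aligned_shapes` (from [bilateral_symmetry()] or
#'   [gpa()]).
#' @param records Specimen data frame with `specimen_id` and `sex`.
#' @param shape_component `"symmetric"` or `"full"`.
#' @param formula Model over `log_cs` and `sex` (default
#'   `~ log_cs * sex`); use `~ log_cs` when no sex structure is wanted.
#' @param n_perm,seed Passed to [rrpp_lm()].
#' @return Object of class `allometry_fit`: `perm` (the `perm_lm`),
#'   `coefficients` (model-matrix regression of the flattened shapes),
#'   `data`, `k`, plus the covariate ranges used for extrapolation
#'   warnings.
#' @export
allometry_model <- function(shapes, records,
                            shape_component = c("symmetric", "full"),
                            formula = ~ log_cs * sex,
                            n_perm = 1000L, seed = 1L) {
  shape_component <- match.arg(shape_component)
  m <- match(shapes$specimen_ids, records$specimen_id)
  if (any(is.na(m))) stop("shapes without matching specimen records",
                          call. = FALSE)
  comp <- if (shape_component == "symmetric" &&
              !is.null(shapes$symmetric_component))
    shapes$symmetric_component else shapes$procrustes_coords
  Y <- flatten_shapes(comp)
  dat <- data.frame(log_cs = log(shapes$centroid_sizes),
                    sex = factor(records$sex[m]))
  perm <- rrpp_lm(Y, formula, dat, n_perm = n_perm, seed = seed)
  mt <- stats::terms(formula, data = dat)
  X <- stats::model.matrix(mt, dat)
  B <- qr.coef(qr(X), Y)
  structure(
    list(perm = perm, coefficients = B, terms = mt, data = dat,
         k = dim(comp)[2], labels = shapes$labels,
         log_cs_range = range(dat$log_cs)),
    class = "allometry_fit"
  )
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("Allometry model of shape\n")
  print(x$perm)
  invisible(x)
}

#' Shape predicted by the allometry model at chosen covariates
#'
#' Evaluates the fitted multivariate regression at the supplied covariate
#' values and reshapes the result to a k x 3 configuration. Evaluating at
#' the column means of the design reproduces the consensus (regression
#' through the mean). Warns when `log_cs` lies beyond 1.2x the observed
#' range.
#'
#' @param fit An `allometry_fit`.
#' @param at Data frame (or list) with one row of covariate values, e.g.
#'   `list(log_cs = 2.5, sex = "female")`. When `NULL`, covariate means
#'   (and the first sex level) are used.
#' @return k x 3 predicted configuration.
#' @export
predicted_shape <- function(fit, at = NULL) {
  dat <- fit$data
  if (is.null(at)) {
    at <- data.frame(log_cs = mean(dat$log_cs), sex = levels(dat$sex)[1])
  }
  at <- as.data.frame(at)
  if ("sex" %in% names(at)) at$sex <- factor(at$sex, levels = levels(dat$sex))
  r <- fit$log_cs_range
  span <- diff(r)
  if ("log_cs" %in% names(at) &&
      (at$log_cs < r[1] - 0.2 * span || at$log_cs > r[2] + 0.2 * span)) {
    warning("predicting beyond 1.2x the observed log centroid size range",
            call. = FALSE)
  }
  Xnew <- stats::model.matrix(stats::delete.response(fit$terms), at)
  pred <- as.vector(Xnew %*% fit$coefficients)
  out <- matrix(pred, nrow = fit$k, ncol = 3)
  dimnames(out) <- list(fit$labels, c("x", "y", "z"))
  out
}
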