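test_that("centroid size matches its definition and scaling laws", {
  X <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(centroid_size(X), 2 * sqrt(2))  # hand computation
  set.seed(1)
  Y <- matrix(rnorm(30), 10, 3)
  expect_equal(centroid_size(2 * Y), 2 * centroid_size(Y))
  shift <- matrix(c(5, -3, 7), 10, 3, byrow = TRUE)
  expect_equal(centroid_size(Y + shift), centroid_size(Y))
  expect_error(centroid_size(matrix(1, 4, 3)), "coincident")
})

test_that("GPA is invariant to rigid motion and scaling of its inputs", {
  set.seed(2)
  base <- lapply(1:4, function(i) matrix(rnorm(30), 10, 3))
  al1 <- gpa(base)
  # Procrustes distance between a config and its scrambled copy is ~0
  scrambled <- c(base[1], list(rigid_scramble(base[[1]])))
  al_pair <- gpa(scrambled)
  expect_lt(sqrt(sum((al_pair$procrustes_coords[1, , ] -
                        al_pair$procrustes_coords[2, , ])^2)), 1e-8)
  # identical configs: distance exactly ~0
  al_same <- gpa(list(base[[2]], base[[2]]))
  expect_lt(sqrt(sum((al_same$procrustes_coords[1, , ] -
                        al_same$procrustes_coords[2, , ])^2)), 1e-12)
  # scrambling one input leaves the whole alignment unchanged within 1e-8
  base2 <- base
  base2[[3]] <- rigid_scramble(base[[3]])
  al2 <- gpa(base2)
  expect_equal(al1$procrustes_coords, al2$procrustes_coords,
               tolerance = 1e-8, ignore_attr = TRUE)
  # aligned configurations are centered with unit centroid size
  for (i in 1:4) {
    A <- al1$procrustes_coords[i, , ]
    expect_lt(max(abs(colMeans(A))), 1e-8)
    expect_equal(sqrt(sum(A^2)), 1, tolerance = 1e-8)
  }
  # consensus is the plain coordinate-wise mean of the aligned set
  expect_equal(al1$consensus,
               apply(al1$procrustes_coords, c(2, 3), mean),
               tolerance = 1e-12, ignore_attr = TRUE)
  # degenerate (collinear) configuration is rejected by name
  degen <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(gpa(list(base[[1]], landmark_config("bad", degen))), "bad")
})

test_that("GPA attains the brute-force optimum on a small instance", {
  # independent oracle: minimize the summed squared deviation from the mean
  # over per-config rotations parameterized by Euler angles (generic optim),
  # on centered unit-size configs - no SVD route shared with gpa()
  set.seed(3)
  configs <- lapply(1:3, function(i) matrix(rnorm(30), 10, 3))
  scaled <- lapply(configs, function(X) {
    Xc <- sweep(X, 2, colMeans(X))
    Xc / sqrt(sum(Xc^2))
  })
  rotmat <- function(a) {
    Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
                c(0, sin(a[1]), cos(a[1])))
    Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
                c(-sin(a[2]), 0, cos(a[2])))
    Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
                c(0, 0, 1))
    Rx %*% Ry %*% Rz
  }
  objective <- function(par) {
    rot <- lapply(0:2, function(j) scaled[[j + 1]] %*% rotmat(par[3 * j + 1:3]))
    cons <- Reduce(`+`, rot) / 3
    sum(vapply(rot, function(R) sum((R - cons)^2), numeric(1)))
  }
  best <- Inf
  for (trial in 1:8) {
    o <- optim(runif(9, -pi, pi), objective, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  al <- gpa(configs)
  cons <- apply(al$procrustes_coords, c(2, 3), mean)
  achieved <- sum(vapply(1:3, function(i) {
    sum((al$procrustes_coords[i, , ] - cons)^2)
  }, numeric(1)))
  expect_equal(achieved, best, tolerance = 1e-6)
})

test_that("bilateral decomposition splits symmetric and asymmetric variation", {
  # a perfectly symmetric configuration has a null asymmetric component
  cfgs <- lapply(1:3, function(i) {
    cf <- symmetric_config_8(paste0("s", i))
    cf$coordinates <- rigid_scramble(cf$coordinates)
    cf
  })
  shapes <- bilateral_symmetry(cfgs, symmetric_config_8()$pairing)
  expect_lt(max(abs(shapes$asymmetric_component)), 1e-9)
  # components always reconstruct the aligned coordinates
  expect_equal(shapes$symmetric_component + shapes$asymmetric_component,
               shapes$procrustes_coords, tolerance = 1e-12)
})

test_that("reflect-relabel is an involution and asymmetry scales linearly", {
  cf <- symmetric_config_8()
  p <- cf$pairing
  set.seed(4)
  X <- cf$coordinates + matrix(rnorm(24, 0, 0.05), 8, 3)
  expect_equal(reflect_relabel(reflect_relabel(X, p), p), X)

  # antisymmetric perturbation of size eps: asymmetric norm proportional to eps
  raw <- matrix(rnorm(24), 8, 3)
  anti <- (raw - reflect_relabel(raw, p)) / 2
  eps_grid <- c(0.01, 0.02, 0.04)
  norms <- vapply(eps_grid, function(eps) {
    cfgs <- lapply(1:3, function(i) {
      base <- symmetric_config_8(paste0("t", i))$coordinates +
        0.02 * ((m <- matrix(rnorm(24), 8, 3)) + reflect_relabel(m, p)) / 2
      landmark_config(paste0("t", i), base + if (i == 1) eps * anti else 0,
                      pairing = p)
    })
    sh <- bilateral_symmetry(cfgs, p)
    sqrt(sum(sh$asymmetric_component[1, , ]^2))
  }, numeric(1))
  ratios <- norms / eps_grid
  expect_lt(diff(range(ratios)) / mean(ratios), 0.02)
})

test_that("symmetric plus asymmetric squared norms give the total variance", {
  rec <- gen_specimens(seed = 13)[1:10, ]
  lm <- gen_landmarks(rec, asym_sd = 0.01, seed = 13)
  shapes <- bilateral_symmetry(lm$configs, lm$pairing)
  n <- length(lm$configs)
  cons <- shapes$consensus
  # over the joint original+mirrored set the cross terms cancel exactly
  total <- sum(vapply(1:n, function(i) {
    o <- shapes$procrustes_coords[i, , ]
    m <- 2 * shapes$symmetric_component[i, , ] - o  # the mirrored copy
    sum((o - cons)^2) + sum((m - cons)^2)
  }, numeric(1)))
  decomp <- 2 * sum(vapply(1:n, function(i) {
    sum((shapes$symmetric_component[i, , ] - cons)^2) +
      sum(shapes$asymmetric_component[i, , ]^2)
  }, numeric(1)))
  expect_equal(total, decomp, tolerance = 1e-8)
})

test_that("Procrustes distance behaves as a metric on aligned shapes", {
  set.seed(6)
  rec <- gen_specimens(seed = 6)[1:6, ]
  lm <- gen_landmarks(rec, seed = 6)
  shapes <- bilateral_symmetry(lm$configs, lm$pairing)
  d <- function(i, j) sqrt(sum((shapes$procrustes_coords[i, , ] -
                                  shapes$procrustes_coords[j, , ])^2))
  for (trip in list(c(1, 2, 3), c(2, 4, 6), c(1, 5, 3))) {
    expect_equal(d(trip[1], trip[2]), d(trip[2], trip[1]))
    expect_lte(d(trip[1], trip[3]),
               d(trip[1], trip[2]) + d(trip[2], trip[3]) + 1e-12)
  }
})

test_that("allometry model detects generated size-shape covariation", {
  rec <- gen_specimens(seed = 17)
  lm <- gen_landmarks(rec, allometric_vector_scale = 0.15, seed = 17)
  shapes <- bilateral_symmetry(lm$configs, lm$pairing)
  allo <- allometry_model(shapes, rec, n_perm = 199, seed = 17)
  tab <- allo$perm$aov_table
  expect_lte(tab$p[tab$term == "log_cs"], 0.05)
  # negative control: shuffling specimen ids destroys the association
  rec_shuf <- rec
  set.seed(99)
  rec_shuf$specimen_id <- sample(rec_shuf$specimen_id)
  shapes_shuf <- shapes
  shapes_shuf$specimen_ids <- rec_shuf$specimen_id[
    match(shapes$specimen_ids, rec$specimen_id)]
  shapes_shuf$centroid_sizes <- stats::setNames(
    sample(unname(shapes$centroid_sizes)), shapes$specimen_ids)
  allo_shuf <- allometry_model(shapes_shuf, rec, n_perm = 199, seed = 18)
  tab_shuf <- allo_shuf$perm$aov_table
  expect_gt(tab_shuf$p[tab_shuf$term == "log_cs"], 0.05)
})

test_that("predicted shapes interpolate the allometric trajectory", {
  rec <- gen_specimens(seed = 23)[1:40, ]
  lm <- gen_landmarks(rec, allometric_vector_scale = 0.2, asym_sd = 0,
                      ind_sd = 0, cs_noise_sd = 0, seed = 23)
  shapes <- bilateral_symmetry(lm$configs, lm$pairing)
  allo <- allometry_model(shapes, rec, formula = ~ log_cs, n_perm = 2,
                          seed = 1)
  # regression through the mean: prediction at the covariate mean is the
  # consensus (the mean symmetric shape)
  at_mean <- predicted_shape(allo,
                             data.frame(log_cs = mean(allo$data$log_cs)))
  expect_equal(at_mean, shapes$consensus, tolerance = 1e-9,
               ignore_attr = TRUE)
  # min-to-max displacement lies along the generating allometric field
  lo <- predicted_shape(allo, data.frame(log_cs = min(allo$data$log_cs)))
  hi <- predicted_shape(allo, data.frame(log_cs = max(allo$data$log_cs)))
  delta <- hi - lo
  # rotate the displacement back into the template frame before comparing
  R <- fenceroo:::opa_rotation(shapes$consensus / sqrt(sum(shapes$consensus^2)),
                               lm$truth$template)
  v1 <- as.vector(delta %*% R)
  v2 <- as.vector(lm$truth$allometric_field)
  cosine <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  expect_gt(abs(cosine), 0.9)
  # zero-allometry generator: predictions at min and max size coincide
  lm0 <- gen_landmarks(rec, allometric_vector_scale = 0, asym_sd = 0,
                       ind_sd = 0, cs_noise_sd = 0, seed = 23)
  shapes0 <- bilateral_symmetry(lm0$configs, lm0$pairing)
  allo0 <- allometry_model(shapes0, rec, formula = ~ log_cs, n_perm = 2,
                           seed = 1)
  lo0 <- predicted_shape(allo0, data.frame(log_cs = min(allo0$data$log_cs)))
  hi0 <- predicted_shape(allo0, data.frame(log_cs = max(allo0$data$log_cs)))
  expect_lt(max(abs(hi0 - lo0)), 1e-8)
  # extrapolation warning beyond 1.2x the observed covariate range
  expect_warning(
    predicted_shape(allo, data.frame(log_cs = max(allo$data$log_cs) +
                                       diff(range(allo$data$log_cs)))),
    "beyond")
})
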