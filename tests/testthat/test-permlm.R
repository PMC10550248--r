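test_that("a perfect fit gives R2 = 1 and the minimum attainable p", {
  set.seed(1)
  x <- rnorm(30)
  dat <- data.frame(x = x)
  res <- rrpp_lm(x, ~ x, dat, n_perm = 100, seed = 1)
  expect_equal(res$aov_table$R2, 1, tolerance = 1e-10)
  expect_equal(res$aov_table$p, 1 / 100)
  expect_equal(res$R2_residual, 0, tolerance = 1e-10)
})

test_that("univariate single-covariate F equals the classical regression F", {
  set.seed(2)
  dat <- data.frame(x = rnorm(40))
  y <- 1 + 0.5 * dat$x + rnorm(40)
  res <- rrpp_lm(y, ~ x, dat, n_perm = 2, seed = 1)
  classical <- summary(lm(y ~ x, dat))$fstatistic[["value"]]
  expect_equal(res$aov_table$F, classical, tolerance = 1e-10)
})

test_that("sequential R2 components sum to one", {
  set.seed(3)
  dat <- data.frame(x = rnorm(50), g = factor(rep(c("a", "b"), 25)))
  Y <- matrix(rnorm(50 * 4), 50)
  Y[, 1] <- Y[, 1] + dat$x
  res <- rrpp_lm(Y, ~ x + g + x:g, dat, n_perm = 50, seed = 2)
  expect_equal(sum(res$aov_table$R2) + res$R2_residual, 1,
               tolerance = 1e-10)
  expect_true(all(res$aov_table$F >= 0))
  expect_true(all(res$aov_table$p >= 1 / 50 & res$aov_table$p <= 1))
})

test_that("permutation p-values are reproducible and seed-sensitive only within MC error", {
  set.seed(4)
  dat <- data.frame(x = rnorm(40))
  y <- 0.4 * dat$x + rnorm(40)
  a <- rrpp_lm(y, ~ x, dat, n_perm = 500, seed = 7)
  b <- rrpp_lm(y, ~ x, dat, n_perm = 500, seed = 7)
  expect_identical(a$aov_table$p, b$aov_table$p)
  c_ <- rrpp_lm(y, ~ x, dat, n_perm = 500, seed = 8)
  # binomial Monte-Carlo error bound at 500 permutations
  pbar <- (a$aov_table$p + c_$aov_table$p) / 2
  expect_lt(abs(a$aov_table$p - c_$aov_table$p),
            4 * sqrt(pbar * (1 - pbar) / 500) + 2 / 500)
})

test_that("jointly permuting response and design rows changes nothing", {
  set.seed(5)
  dat <- data.frame(x = rnorm(35), g = factor(rep(c("a", "b", "c"), length.out = 35)))
  Y <- matrix(rnorm(35 * 3), 35) + dat$x
  res <- rrpp_lm(Y, ~ x + g, dat, n_perm = 200, seed = 3)
  ord <- sample(35)
  res2 <- rrpp_lm(Y[ord, ], ~ x + g, dat[ord, , drop = FALSE],
                  n_perm = 200, seed = 3)
  expect_equal(res$aov_table$SS, res2$aov_table$SS, tolerance = 1e-10)
  expect_equal(res$aov_table$F, res2$aov_table$F, tolerance = 1e-10)
})

test_that("a single-column multivariate response reduces to the univariate case", {
  set.seed(6)
  dat <- data.frame(x = rnorm(30))
  y <- 2 + dat$x + rnorm(30)
  uni <- rrpp_lm(y, ~ x, dat, n_perm = 50, seed = 9)
  multi <- rrpp_lm(matrix(y, ncol = 1), ~ x, dat, n_perm = 50, seed = 9)
  expect_identical(uni$aov_table$SS, multi$aov_table$SS)
  expect_identical(uni$aov_table$p, multi$aov_table$p)
})

test_that("rank-deficient designs fail with the aliased column named", {
  set.seed(7)
  dat <- data.frame(x = rnorm(20))
  dat$x2 <- 2 * dat$x
  y <- rnorm(20)
  expect_error(rrpp_lm(y, ~ x + x2, dat, n_perm = 10, seed = 1), "x2")
})

test_that("full randomization is exposed as an alternative scheme", {
  set.seed(8)
  dat <- data.frame(x = rnorm(40))
  y <- 0.8 * dat$x + rnorm(40)
  res <- rrpp_lm(y, ~ x, dat, n_perm = 200, seed = 2, randomize = "full")
  # single-term model: full randomization also gives a small p here
  expect_lt(res$aov_table$p, 0.05)
})

test_that("interpopulation tests find an injected weight-only effect", {
  specs <- default_population_specs(k_ratio_common = 1)  # identical growth
  # inject a population effect on weight only
  specs$dingoes_common$vb$female$weight_kg["L_inf"] <- 40
  specs$dingoes_common$vb$male$weight_kg["L_inf"] <- 80
  rec <- gen_specimens(specs, seed = 31)
  trimmed <- trim_to_common_age_range(rec)$kept
  res <- interpopulation_tests(trimmed, shapes = NULL, n_perm = 199,
                               seed = 31)
  tab <- res$table
  wgt_p <- tab$p[tab$response == "weight" & tab$term == "population"]
  expect_true(all(wgt_p <= 0.05))
  pes_p <- tab$p[tab$response == "pes" & tab$term == "population"]
  expect_true(all(pes_p > 0.05))
})

test_that("an age:population interaction is retained only where injected", {
  set.seed(33)
  n <- 60
  mk <- function(sex, prop, slope_shift) {
    age <- runif(n, 3, 10)
    data.frame(
      specimen_id = sprintf("%s_%s_%d", sex, prop, seq_len(n)),
      sex = sex, property = prop, age_years = age,
      weight_kg = 20 + 2 * age + rnorm(n),
      pes_length_cm = 25 + (1 + slope_shift) * age + rnorm(n, 0, 0.5),
      stringsAsFactors = FALSE
    )
  }
  rec <- rbind(
    mk("female", "dingoes_rare", 0), mk("female", "dingoes_common", 0),
    mk("male", "dingoes_rare", 0), mk("male", "dingoes_common", 0.6)
  )
  res <- interpopulation_tests(rec, shapes = NULL, n_perm = 199, seed = 3)
  expect_true(res$interaction_retained[["male.pes"]])
  expect_false(res$interaction_retained[["female.pes"]])
  # retained interaction appears in the male pes report rows
  male_pes <- res$table[res$table$sex == "male" & res$table$response == "pes", ]
  expect_true("age:population" %in% male_pes$term)
})

test_that("an empty sex-by-population cell is a precondition error", {
  rec <- counted_specimens(10, 10, 10, 0)
  expect_error(interpopulation_tests(rec, shapes = NULL, n_perm = 9, seed = 1),
               "cell")
})
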