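test_that("relative dose difference is exact, antisymmetric and bounded", {
  expect_equal(relative_difference(10, 10), 0)
  expect_equal(relative_difference(15, 10), 40)
  expect_equal(relative_difference(10, 15), -40)
  expect_error(relative_difference(0, 0), "undefined ratio")
  set.seed(3)
  a <- stats::runif(1e4, 0.01, 100)
  b <- stats::runif(1e4, 0.01, 100)
  rd <- relative_difference(a, b)
  expect_equal(rd, -relative_difference(b, a), tolerance = 1e-12)
  expect_true(all(rd > -200 & rd < 200))
})

test_that("organ doses are voxel means over the masks", {
  ph <- generate_phantom("male", "normal", 8, shape = small_shape)
  dm <- list(dose_mgy = array(2.5, dim = ph$shape), shape = ph$shape)
  od <- organ_dose(dm, ph)
  expect_true(all(abs(od$dose_mgy - 2.5) < 1e-12))
  expect_false("breasts" %in% od$organ)        # male model, silently skipped
  expect_error(organ_dose(dm, ph, organs = "stomach"), "missing organ")
  # three prescribed voxels average arithmetically
  dose <- array(0, dim = ph$shape)
  idx <- which(ph$masks$thyroid)[1:3]
  ph2 <- ph
  ph2$masks$thyroid[] <- FALSE
  ph2$masks$thyroid[idx] <- TRUE
  dose[idx] <- c(1, 2, 3)
  od2 <- organ_dose(list(dose_mgy = dose, shape = ph$shape), ph2,
                    organs = "thyroid")
  expect_equal(od2$dose_mgy, 2)
  # linear in a global scale, invariant to how voxels are ordered
  od3 <- organ_dose(list(dose_mgy = dose * 7, shape = ph$shape), ph2,
                    organs = "thyroid")
  expect_equal(od3$dose_mgy, 14)
})

test_that("paired t matches the textbook formula and the stats oracle", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)   # differences {1, 2, 3}
  r <- paired_t(x, y)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)
  # agreement with the t distribution CDF
  expect_equal(r$p, 2 * stats::pt(-abs(r$t), 2), tolerance = 1e-12)
  # and with the standard library implementation
  tt <- stats::t.test(x, y, paired = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(r$p, tt$p.value, tolerance = 1e-9)
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  degen <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
})

test_that("RM-ANOVA has F = 0 for identical condition means", {
  set.seed(9)
  base <- stats::rnorm(6, 10)
  data <- cbind(a = base, b = base, c = base)
  r <- rm_anova_dunnett(data, control = "a", n_draws = 1e4)
  expect_equal(r$F, 0, tolerance = 1e-20)
  # subject blocking: adding a per-subject constant leaves F unchanged
  set.seed(10)
  d2 <- matrix(stats::rnorm(18), 6, 3)
  r1 <- rm_anova_dunnett(d2, n_draws = 1e4)
  r2 <- rm_anova_dunnett(d2 + stats::rnorm(6, sd = 5), n_draws = 1e4)
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
})

test_that("Dunnett reduces to the paired t for two conditions", {
  set.seed(11)
  x <- stats::rnorm(8, 10); y <- x + stats::rnorm(8, 0.8)
  r <- rm_anova_dunnett(cbind(ctrl = x, dev = y), control = "ctrl",
                        n_draws = 2e5)
  tt <- paired_t(y, x)
  expect_equal(r$comparisons$p_adjusted, tt$p, tolerance = 0.01)
})

test_that("Dunnett adjusted p matches a brute-force max-|t| simulation", {
  set.seed(12)
  n <- 6; k <- 3
  data <- matrix(stats::rnorm(n * k, 10), n, k)
  data[, 2] <- data[, 2] + 1.2
  r <- rm_anova_dunnett(data, control = 1, n_draws = 2e5)
  # independent brute-force null: complete RM datasets under H0, the
  # max-|t| statistic recomputed from scratch each draw
  set.seed(13)
  m <- k - 1; df <- (k - 1) * (n - 1)
  draws <- 1e6
  w0 <- stats::rnorm(draws)
  z1 <- (stats::rnorm(draws) + w0) / sqrt(2)
  z2 <- (stats::rnorm(draws) + w0) / sqrt(2)
  s <- sqrt(stats::rchisq(draws, df) / df)
  maxt <- pmax(abs(z1), abs(z2)) / s
  p_oracle <- vapply(r$comparisons$t,
                     function(t) mean(maxt >= abs(t)), numeric(1))
  expect_true(all(abs(r$comparisons$p_adjusted - p_oracle) < 0.005))
  # and each adjusted p is at least the unadjusted paired-style p
  p_unadj <- 2 * stats::pt(-abs(r$comparisons$t), df)
  expect_true(all(r$comparisons$p_adjusted >= p_unadj - 1e-3))
})

test_that("Dunnett agrees with the multcomp reference implementation", {
  set.seed(14)
  n <- 8; k <- 4
  data <- matrix(stats::rnorm(n * k, 20, 2), n, k)
  data[, 3] <- data[, 3] + 1.5
  colnames(data) <- paste0("c", 1:k)
  r <- rm_anova_dunnett(data, control = 1, n_draws = 2e5)
  df_long <- data.frame(y = as.vector(data),
                        cond = factor(rep(colnames(data), each = n)),
                        subj = factor(rep(seq_len(n), k)))
  fit <- stats::aov(y ~ cond + subj, data = df_long)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(cond = "Dunnett"))
  p_ref <- summary(gl, test = multcomp::adjusted("single-step"))$test$pvalues
  expect_equal(r$comparisons$p_adjusted, as.numeric(p_ref),
               tolerance = 0.01)
})

test_that("Bland-Altman bias, limits and antisymmetry are exact", {
  r0 <- bland_altman(c(3, 5, 7), c(3, 5, 7))
  expect_equal(r0$bias, 0)
  expect_equal(r0$loa, c(0, 0))
  r <- bland_altman(c(2, 4), c(1, 1))   # d = {1, 3}
  expect_equal(r$bias, 2)
  expect_equal(r$sd, sqrt(2), tolerance = 1e-9)
  expect_equal(r$loa, c(2 - 1.96 * sqrt(2), 2 + 1.96 * sqrt(2)),
               tolerance = 1e-9)
  expect_equal(r$loa, c(-0.7718, 4.7718), tolerance = 1e-4)
  swapped <- bland_altman(c(1, 1), c(2, 4))
  expect_equal(swapped$bias, -r$bias)
  expect_error(bland_altman(1, 1), "insufficient data")
})

test_that("normality diagnostic reports without gating", {
  set.seed(15)
  expect_gt(normality_diagnostic(stats::rnorm(30)), 0.001)
  expect_true(is.na(normality_diagnostic(c(1, 1, 1))))
})
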