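test_that("identical differences give a degenerate fit at that value", {
  tab <- paired_from_diffs(list(A = c(2, 2), B = c(2, 2), C = c(2, 2)))
  fit <- fit_agreement(tab)
  expect_true(fit$degenerate)
  expect_equal(fit$mu, 2)
  expect_equal(fit$tau2, 0)
  expect_equal(fit$sigma2, 0)
  expect_equal(fit$loa_lower, 2)
  expect_equal(fit$loa_upper, 2)
})

test_that("fit refuses unusable layouts", {
  expect_error(fit_agreement(paired_from_diffs(list(A = c(1, 2)))),
               class = "hragree_estimation_error")
  expect_error(fit_agreement(paired_from_diffs(list(A = c(1, 2), B = 3))),
               class = "hragree_estimation_error")
})

test_that("balanced toy matches method-of-moments and grid REML oracles", {
  tab <- paired_from_diffs(list(A = c(1, 3), B = c(5, 7)))
  fit <- fit_agreement(tab)
  mom <- mom_oracle(tab)
  expect_equal(fit$mu, 4)
  expect_equal(fit$tau2, mom$tau2, tolerance = 1e-4)
  expect_equal(fit$sigma2, mom$sigma2, tolerance = 1e-4)

  grid <- grid_reml_oracle(tab)
  expect_equal(fit$mu, grid$mu, tolerance = 1e-3)
  expect_equal(fit$tau2, grid$tau2, tolerance = 1e-3)
  expect_equal(fit$sigma2, grid$sigma2, tolerance = 1e-3)
})

test_that("fit agrees with an independent mixed-model implementation on unbalanced data", {
  skip_if_not_installed("lme4")
  set.seed(21)
  tab <- dplyr::bind_rows(
    paired_from_diffs(list(A = rnorm(30, 1, 5), B = rnorm(55, -1, 5),
                           C = rnorm(12, 0.5, 5), D = rnorm(80, 2, 5)))
  )
  fit <- fit_agreement(tab)
  lf <- lme4::lmer(difference ~ 1 + (1 | participant_id), data = tab, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$mu, unname(lme4::fixef(lf)[1]), tolerance = 1e-5)
  expect_equal(fit$tau2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2, vc$vcov[2], tolerance = 1e-4)
})

test_that("AR(1) fit agrees with an independent implementation", {
  skip_if_not_installed("nlme")
  tab <- simulate_epoch_differences(10, 60, mu = 0.5, tau2 = 1, sigma2 = 20,
                                    phi = 0.5, seed = 14)
  fit <- fit_agreement(tab, with_ar1 = TRUE)
  lf <- nlme::lme(difference ~ 1, random = ~ 1 | participant_id, data = tab,
                  correlation = nlme::corAR1(form = ~ 1 | participant_id),
                  method = "REML")
  expect_equal(fit$mu, unname(nlme::fixef(lf)[1]), tolerance = 1e-4)
  expect_equal(fit$phi,
               unname(coef(lf$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
  expect_equal(fit$sigma2, lf$sigma^2, tolerance = 0.01)
  expect_equal(fit$tau2, as.numeric(nlme::VarCorr(lf)[1, 1]), tolerance = 0.01)
})

test_that("limits of agreement follow the closed form and are symmetric", {
  expect_equal(unlist(limits_of_agreement(0, 0, 1)),
               c(total_sd = 1, loa_lower = -1.96, loa_upper = 1.96))
  loa <- limits_of_agreement(1, 3, 1)
  expect_equal(loa$total_sd, 2)
  expect_equal(loa$loa_lower, -2.92)
  expect_equal(loa$loa_upper, 4.92)
  expect_error(limits_of_agreement(0, -1, 1), class = "hragree_domain_error")

  # midpoint of the limits is the bias, for fits too
  tab <- simulate_epoch_differences(6, 30, seed = 2)
  fit <- fit_agreement(tab)
  expect_equal((fit$loa_upper + fit$loa_lower) / 2, fit$mu)
  expect_equal(limits_of_agreement(fit)$total_sd, sqrt(fit$tau2 + fit$sigma2))
})

test_that("total_sd ignores epoch order when AR(1) is off", {
  tab <- simulate_epoch_differences(8, 40, phi = 0.4, seed = 31)
  fit1 <- fit_agreement(tab)
  set.seed(99)
  shuffled <- tab |>
    dplyr::group_by(participant_id) |>
    dplyr::slice_sample(prop = 1) |>
    dplyr::ungroup()
  fit2 <- fit_agreement(shuffled)
  expect_equal(fit2$total_sd, fit1$total_sd)
  expect_equal(fit2$mu, fit1$mu)
})

test_that("cluster bootstrap is deterministic under a fixed seed", {
  tab <- simulate_epoch_differences(8, 25, seed = 5)
  b1 <- cluster_bootstrap_loa(tab, n_replicates = 50, seed = 123)
  b2 <- cluster_bootstrap_loa(tab, n_replicates = 50, seed = 123)
  expect_identical(b1$loa_lower_ci, b2$loa_lower_ci)
  expect_identical(b1$loa_upper_ci, b2$loa_upper_ci)
  expect_identical(b1$replicates, b2$replicates)
})

test_that("cluster bootstrap collapses to a point on degenerate data", {
  tab <- paired_from_diffs(list(A = c(2, 2), B = c(2, 2)))
  b <- cluster_bootstrap_loa(tab, n_replicates = 30, seed = 1)
  expect_equal(b$loa_lower_ci, c(2, 2))
  expect_equal(b$loa_upper_ci, c(2, 2))
})

test_that("bootstrap does not disturb the global RNG stream", {
  tab <- simulate_epoch_differences(5, 20, seed = 8)
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(cluster_bootstrap_loa(tab, n_replicates = 20, seed = 9))
  expect_identical(runif(1), before)
})

test_that("proportional-bias slope is recovered and null when absent", {
  set.seed(61)
  n <- 600
  tab0 <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:12), each = 50),
    epoch_start = rep((0:49) * 5, 12),
    hr_criterion = runif(n, 70, 170)
  ) |>
    dplyr::mutate(hr_index = hr_criterion + rnorm(n, 0, 3),
                  difference = hr_index - hr_criterion)
  pb0 <- proportional_bias_check(tab0)
  expect_true(pb0$slope_ci_lower < 0 && pb0$slope_ci_upper > 0)

  tab1 <- tab0 |>
    dplyr::mutate(hr_index = hr_criterion + 0.1 * hr_criterion + rnorm(n, 0, 2),
                  difference = hr_index - hr_criterion)
  pb1 <- proportional_bias_check(tab1)
  # slope on the pair mean is close to the generative 0.1 on the criterion
  expect_equal(pb1$slope, 0.1, tolerance = 0.05)

  # dispersion rising with heart rate yields a positive statistic
  tab2 <- tab0 |>
    dplyr::mutate(hr_index = hr_criterion + rnorm(n, 0, 0.05 * hr_criterion),
                  difference = hr_index - hr_criterion)
  expect_gt(proportional_bias_check(tab2)$heteroscedasticity_stat, 0)
})

test_that("proportional-bias check validates its inputs", {
  small <- toy_paired()
  expect_error(proportional_bias_check(small), class = "hragree_domain_error")
  const <- paired_from_diffs(list(A = rnorm(10), B = rnorm(10)))
  expect_error(proportional_bias_check(
    dplyr::mutate(const, hr_index = 100, hr_criterion = 100)),
    class = "hragree_domain_error")
})

test_that("tidy and glance expose the fitted quantities", {
  tab <- simulate_epoch_differences(6, 30, seed = 12)
  fit <- fit_agreement(tab)
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("mean_bias", "tau2", "sigma2", "total_sd",
                             "loa_lower", "loa_upper"))
  expect_equal(td$estimate[td$term == "total_sd"], fit$total_sd)
  gl <- generics::glance(fit)
  expect_equal(gl$n_participants, 6)
  expect_false(gl$degenerate)
})
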