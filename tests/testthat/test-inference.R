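test_that("chi-squared equals hand-computed weighted residual sums", {
  d1 <- data.frame(observable = "a", time_days = 0, mean = 2, sd = 1, n = 3)
  p1 <- data.frame(observable = "a", time_days = 0, value = 1)
  expect_equal(chi_squared(d1, p1), 1.0)

  d2 <- data.frame(observable = c("a", "b"), time_days = c(0, 0),
                   mean = c(3, 5), sd = c(1, 3), n = 3)
  p2 <- data.frame(observable = c("a", "b"), time_days = c(0, 0),
                   value = c(1, 2))
  expect_equal(chi_squared(d2, p2), 4 + 1)        # (3-1)/1 and (5-2)/3

  p3 <- p2; p3$value <- d2$mean
  expect_equal(chi_squared(d2, p3), 0)

  expect_error(chi_squared(d2, p2[1, ]), "no prediction")
  d_bad <- d1; d_bad$sd <- 0
  expect_error(chi_squared(d_bad, p1), "sd must be > 0")
})

test_that("chi-squared agrees with the naive double-loop reference", {
  set.seed(99)
  for (i in 1:25) {
    rp <- random_dataset_pair(n_obs = sample(2:5, 1),
                              n_times = sample(2:5, 1))
    fast <- chi_squared(rp$data, rp$pred)
    slow <- chi_squared_naive(rp$data, rp$pred)
    expect_lt(abs(fast - slow), 1e-12 * max(1, slow))
  }
})

test_that("log10-scale prior penalty behaves as a Gaussian in decades", {
  pr <- ibd_prior(mean = 1e0, sigma = 1e1)
  p_at_mean <- c(a = 1, b = 1, c = 1)
  expect_equal(prior_penalty(p_at_mean, pr), 0)
  # one decade off with a one-decade width contributes exactly 1
  expect_equal(prior_penalty(c(a = 10, b = 1, c = 1), pr), 1)
  expect_equal(prior_penalty(c(a = 0.1, b = 1), pr), 1)
  # symmetric under reordering
  p <- c(a = 0.3, b = 2, c = 7)
  expect_equal(prior_penalty(p, pr), prior_penalty(rev(p), pr))
  # disabled prior contributes nothing
  expect_equal(prior_penalty(p, NULL), 0)
  expect_error(prior_penalty(c(a = -1), pr), "> 0")
  expect_error(prior_penalty(c(a = 1), ibd_prior(applies_to = "zz")),
               "missing parameter")
})

test_that("objective is chi-squared plus prior and reduces to chi-squared", {
  # additivity on the hand-composed cases
  expect_equal(5.0 + 1.0, 6.0)
  m <- ibd_model("core")
  d <- core_nf_data()$data
  p <- true_params_core()
  expect_equal(ibd_objective(m, p, d, frede_protocol(), prior = NULL),
               chi_squared(d, predict_obs_for_test(m, p, d)),
               tolerance = 1e-10)
  with_prior <- ibd_objective(m, p, d, frede_protocol(), prior = ibd_prior())
  expect_equal(with_prior,
               ibd_objective(m, p, d, frede_protocol(), prior = NULL) +
                 prior_penalty(p, ibd_prior()),
               tolerance = 1e-10)
})

test_that("multi-start fitting is deterministic and reports the ensemble", {
  d <- core_nf_data()$data
  f1 <- fit_ibd(ibd_model("core"), d, frede_protocol(), n_starts = 2,
                seed = 7)
  f2 <- fit_ibd(ibd_model("core"), d, frede_protocol(), n_starts = 2,
                seed = 7)
  expect_identical(f1, f2)
  expect_equal(nrow(f1$starts$start_par), 2)
  ok <- f1$starts$converged
  expect_true(any(ok))
  expect_true(all(f1$best_objective <= f1$starts$objective[ok] + 1e-12))
  expect_error(fit_ibd(ibd_model("core"), d[0, ], frede_protocol()),
               "empty")
})

test_that("simulate() draws reproducible replicate datasets from the fit", {
  fit <- core_nf_fit()
  s1 <- simulate(fit, nsim = 2, seed = 3)
  s2 <- simulate(fit, nsim = 2, seed = 3)
  expect_identical(s1, s2)
  expect_length(s1, 2)
  expect_s3_class(s1[[1]], "ibd_data")
  expect_false(identical(s1[[1]]$mean, s1[[2]]$mean))
})

test_that("waterfall summarizes the start ensemble", {
  fake <- structure(list(starts = list(objective = c(10, 10, 50),
                                       converged = rep(TRUE, 3))),
                    class = "ibd_fit")
  wf <- waterfall(fake, tol = 0.01)
  expect_equal(wf$objectives, c(10, 10, 50))
  expect_equal(wf$fraction_at_global, 2 / 3)
  # non-decreasing in tol, and 1 for a degenerate ensemble
  expect_gte(waterfall(fake, tol = 100)$fraction_at_global,
             wf$fraction_at_global)
  fake2 <- structure(list(starts = list(objective = rep(4, 5),
                                        converged = rep(TRUE, 5))),
                     class = "ibd_fit")
  expect_equal(waterfall(fake2)$fraction_at_global, 1)
  fake3 <- structure(list(starts = list(objective = 1,
                                        converged = FALSE)),
                     class = "ibd_fit")
  expect_error(waterfall(fake3), "no converged starts")
})

test_that("confidence thresholds come from the 1-dof chi-squared quantile", {
  expect_equal(chi2_threshold(0.95), 3.84, tolerance = 1e-3)
  expect_equal(chi2_threshold(0.6827), 1.0, tolerance = 1e-3)
  expect_error(chi2_threshold(1.2))
})

test_that("profile CI of a linear-Gaussian toy matches the analytic SE", {
  # constant model theta for heteroscedastic observations: the objective is
  # exactly quadratic with SE = 1 / sqrt(sum(1/sigma^2))
  set.seed(5)
  y <- c(4.1, 3.8, 4.4, 3.9, 4.3)
  sig <- c(0.5, 0.3, 0.8, 0.4, 0.6)
  resid_fn <- function(th) (y - th[1]) / sig
  w <- 1 / sig^2
  opt <- sum(w * y) / sum(w)
  se <- 1 / sqrt(sum(w))
  f0 <- sum(((y - opt) / sig)^2)
  cu <- colitisdyn:::profile_engine(resid_fn, c(theta = opt), 1L,
                                    f0 = f0, threshold = chi2_threshold(0.95),
                                    step_init = 0.01)
  half_lo <- unname(cu$optimum - cu$ci_lower_log10)
  half_hi <- unname(cu$ci_upper_log10 - cu$optimum)
  expected <- sqrt(chi2_threshold(0.95)) * se
  expect_equal(half_lo, expected, tolerance = 0.02)
  expect_equal(half_hi, expected, tolerance = 0.02)
  expect_equal(cu$status, "identifiable")
  # symmetric quadratic profile gives a symmetric interval
  expect_equal(half_lo, half_hi, tolerance = 0.02)
})

test_that("a parameter absent from the residuals profiles flat", {
  resid_fn <- function(th) (c(2.9, 3.1, 3.0) - th[1]) / 0.1
  cu <- colitisdyn:::profile_engine(resid_fn, c(a = 3, b = 0), 2L,
                                    f0 = sum(resid_fn(c(3, 0))^2),
                                    threshold = chi2_threshold(0.95))
  expect_equal(cu$status, "structurally_nonidentifiable")
  expect_equal(classify_identifiability(cu), "structurally_nonidentifiable")
})

test_that("identifiability classification follows the crossing pattern", {
  mk_curve <- function(grid, prof, opt, f0) {
    structure(list(parameter = "k", grid = grid, profile_objective = prof,
                   optimum = opt, best_objective = f0, level = 0.95,
                   threshold = f0 + chi2_threshold(0.95)),
              class = "ibd_profile_curve")
  }
  g <- seq(-1, 1, by = 0.1)
  both <- mk_curve(g, 20 * g^2, 0, 0)
  expect_equal(classify_identifiability(both), "identifiable")
  ci <- confint(both)
  expect_equal(unname(ci["upper"]), 10^sqrt(3.84 / 20), tolerance = 0.01)
  one_side <- mk_curve(g, ifelse(g < 0, 20 * g^2, 0.001 * g^2), 0, 0)
  expect_equal(classify_identifiability(one_side),
               "practically_nonidentifiable")
})

test_that("profile of a fitted model attains its minimum at the optimum", {
  fit <- core_nf_fit()
  pr <- profile(fit, which = "k_turnN")
  cu <- pr$k_turnN
  expect_gte(min(cu$profile_objective), fit$best_objective - 1e-6)
  expect_equal(cu$profile_objective[cu$grid == cu$optimum],
               fit$best_objective)
  expect_equal(cu$status, "identifiable")
  expect_true(cu$ci_lower <= 10^cu$optimum && 10^cu$optimum <= cu$ci_upper)
  # confint on the profile set returns one row per parameter
  cimat <- confint(pr)
  expect_equal(dim(cimat), c(1, 2))
})
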