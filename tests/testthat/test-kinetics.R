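# Mono-exponential kinetics fitting, replicate statistics and group
# comparison.

test_that("noiseless mono-exponential data are recovered to machine precision", {
  t <- seq(0, 200, length.out = 20)
  y <- 10 * exp(-0.03 * t) + 5
  fit <- fit_monoexp(kinetic_trace(t, y, "sub", "substrate"))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(10, 0.03, 5), tolerance = 1e-6)
  expect_length(fit$flags, 0)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-8)
})

test_that("the fitted rate brackets the truth under noise at its own standard error", {
  t <- seq(0, 200, length.out = 20)
  y0 <- 10 * exp(-0.03 * t) + 5
  set.seed(42)
  y <- y0 + rnorm(20, 0, 0.5)
  fit <- fit_monoexp(kinetic_trace(t, y, "sub", "substrate"))
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["k"]] - 0.03), 3 * fit$se[["k"]])
  # standard errors come from the covariance matrix of the fit
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(fit)))), tolerance = 1e-12)
})

test_that("a flat trace is reported with an unidentifiable rate", {
  t <- seq(0, 100, length.out = 10)
  fit <- fit_monoexp(kinetic_trace(t, rep(7, 10)))
  expect_true(fit$converged)
  expect_equal(coef(fit)[["a"]], 0)
  expect_equal(coef(fit)[["y0"]], 7)
  expect_true(is.na(coef(fit)[["k"]]))
  expect_true("k_unidentifiable" %in% fit$flags)
})

test_that("too-short or non-finite traces are rejected", {
  expect_error(fit_monoexp(kinetic_trace(1:4, c(4, 3, 2, 1))), "at least 5")
  expect_error(kinetic_trace(c(1, 2, 2.5, 2, 3), 1:5), "strictly increasing")
  expect_message(kinetic_trace(1:6, c(1, 2, NA, 4, 5, 6)), "dropping 1")
})

test_that("the shared-rate joint fit recovers an exact pair and reduces to the substrate fit", {
  t <- seq(0, 180, by = 92 / 60)
  pr <- synth_kinetic_pair(0.0561, 37.5, 6.5, -31, 31, t, noise_sd = 0)
  fit <- fit_shared_rate(pr$substrate, pr$product)
  expect_true(fit$converged)
  expect_equal(fit$k, 0.0561, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[c("a_s", "y0_s", "a_p", "y0_p")]),
               c(37.5, 6.5, -31, 31), tolerance = 1e-6)
  # product identically zero: shared k falls back to the substrate-only fit
  zero <- kinetic_trace(t, rep(0, length(t)), "prod", "product")
  fit0 <- fit_shared_rate(pr$substrate, zero)
  sub <- fit_monoexp(pr$substrate)
  expect_equal(fit0$k, coef(sub)[["k"]], tolerance = 1e-6)
  expect_lt(abs(coef(fit0)[["a_p"]]), 1e-8)
})

test_that("the joint fit is unbiased over seeded reference-noise simulations", {
  t <- seq(0, 180, by = 92 / 60)
  ks <- vapply(1:20, function(i) {
    pr <- synth_kinetic_pair(0.0561, 37.5, 6.5, -31, 31, t,
                             seed = derive_seed(11, i))
    fit_shared_rate(pr$substrate, pr$product)$k
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.0561), stats::sd(ks) / sqrt(length(ks)))
})

test_that("amplitude signs follow the substrate/product convention and are flagged otherwise", {
  t <- seq(0, 180, by = 5)
  pr <- synth_kinetic_pair(0.04, 30, 5, -20, 20, t, noise_sd = 0)
  fs <- fit_monoexp(pr$substrate)
  fp <- fit_monoexp(pr$product)
  expect_gt(coef(fs)[["a"]], 0)
  expect_lt(coef(fp)[["a"]], 0)
  expect_length(fs$flags, 0)
  expect_length(fp$flags, 0)
  # a rising trace declared as substrate is flagged
  wrong <- fit_monoexp(kinetic_trace(pr$product$times, pr$product$values,
                                     role = "substrate"))
  expect_true("sign_mismatch" %in% wrong$flags)
})

test_that("fits are invariant to uniform rescaling up to amplitude scaling", {
  t <- seq(0, 180, by = 5)
  set.seed(3)
  y <- 30 * exp(-0.04 * t) + 5 + rnorm(length(t), 0, 0.3)
  f1 <- fit_monoexp(kinetic_trace(t, y))
  f2 <- fit_monoexp(kinetic_trace(t, 1000 * y))
  expect_equal(coef(f2)[["k"]], coef(f1)[["k"]], tolerance = 1e-6)
  expect_equal(coef(f2)[["a"]] / coef(f1)[["a"]], 1000, tolerance = 1e-6)
  expect_equal(f2$se[["k"]], f1$se[["k"]], tolerance = 1e-6)
})

test_that("the shared fit never has a larger residual sum than a common-k compromise", {
  t <- seq(0, 180, by = 4)
  for (seed in 1:5) {
    pr <- synth_kinetic_pair(0.05, 37.5, 6.5, -31, 31, t, seed = seed)
    joint <- fit_shared_rate(pr$substrate, pr$product)
    kbar <- mean(c(coef(fit_monoexp(pr$substrate))[["k"]],
                   coef(fit_monoexp(pr$product))[["k"]]))
    # best amplitudes/asymptotes for the averaged rate are a linear fit
    rss_at <- function(tr) {
      X <- cbind(exp(-kbar * tr$times), 1)
      sum(stats::lm.fit(X, tr$values)$residuals^2)
    }
    expect_lte(joint$rss, rss_at(pr$substrate) + rss_at(pr$product) + 1e-9)
  }
})

test_that("replicate statistics give mean, SD and coefficient of variation", {
  rs <- replicate_stats(c(2, 4, 6))
  expect_equal(rs$mean, 4)
  expect_equal(rs$sd, 2)
  expect_equal(rs$cv_percent, 50)
  expect_equal(rs$n, 3)
  expect_equal(replicate_stats(rep(3, 4))$cv_percent, 0)
  expect_error(replicate_stats(1), "at least 2")
})

test_that("rate-group comparison behaves at the degenerate extremes", {
  expect_equal(compare_rates(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(compare_rates(c(1, 1, 1), c(1, 1, 1))$t, 0)
  set.seed(1)
  sep <- compare_rates(rnorm(3, 0, 1e-9), 1 + rnorm(3, 0, 1e-9))
  expect_lt(sep$p_value, 1e-6)
  expect_error(compare_rates(1, c(1, 2)), "at least 2")
})
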