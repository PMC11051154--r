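test_that("an exactly additive matrix gives zero residual variance", {
  a <- c(3.1, 2.8, 3.5, 3.0)
  b <- c(-0.2, 0, 0.2)
  lnrt <- outer(a, b, `-`)
  fit <- fit_lognormal_rt(lnrt)
  expect_equal(fit$residual_variance, 0, tolerance = 1e-16)
  expect_equal(unname(fit$speed), a, tolerance = 1e-10)
  expect_equal(unname(fit$time_intensity), b, tolerance = 1e-10)
})

test_that("with complete data tau equals the person row mean", {
  set.seed(4)
  lnrt <- matrix(rnorm(60, 3, 0.5), 10, 6)
  fit <- fit_lognormal_rt(lnrt)
  expect_equal(unname(fit$speed), rowMeans(lnrt), tolerance = 1e-8)
  expect_equal(mean(fit$time_intensity), 0, tolerance = 1e-10)
})

test_that("incomplete data match the least-squares oracle on the design matrix", {
  set.seed(8)
  lnrt <- matrix(rnorm(200, 3, 0.6), 20, 10)
  lnrt[sample(200, 20)] <- NA
  fit <- fit_lognormal_rt(lnrt)
  # oracle: lm on person/item factor codings, gamma recentered to mean zero
  d <- data.frame(y = as.vector(lnrt),
                  p = factor(rep(1:20, 10)), i = factor(rep(1:10, each = 20)))
  m <- lm(y ~ 0 + p + i, data = d, na.action = na.omit,
          contrasts = list(i = "contr.sum"))
  co <- coef(m)
  gam_lm <- -c(co[grep("^i", names(co))], -sum(co[grep("^i", names(co))]))
  tau_lm <- co[grep("^p", names(co))] - mean(gam_lm) * 0  # already centered
  gam_lm <- gam_lm - mean(gam_lm)
  expect_equal(unname(fit$time_intensity), unname(gam_lm), tolerance = 1e-6)
  expect_equal(unname(fit$speed), unname(tau_lm), tolerance = 1e-6)
  # sigma2 is the mean squared residual over observed cells
  expect_equal(fit$residual_variance,
               mean(residuals(m)^2), tolerance = 1e-6)
})

test_that("residuals subtract the person and item effects", {
  expect_equal(rt_residuals(matrix(3.0), list(speed = 3.2, time_intensity = 0.2,
                                              residual_variance = 1))$values[1, 1], 0)
  expect_equal(rt_residuals(matrix(4.0), list(speed = 3.0, time_intensity = 0,
                                              residual_variance = 1))$values[1, 1], 1)
  set.seed(2)
  lnrt <- matrix(rnorm(80, 3, 0.5), 10, 8)
  fit <- fit_lognormal_rt(lnrt)
  res <- rt_residuals(lnrt, fit)
  expect_equal(mean(res$values), 0, tolerance = 1e-8)
  # standardization uses the construct-state SD when state variances exist
  fit$state_variances <- c(0.25, 2)
  res2 <- rt_residuals(lnrt, fit)
  expect_equal(res2$standardized, res2$values / 0.5)
})

test_that("adding a constant to lnRT shifts tau and leaves residuals unchanged", {
  set.seed(6)
  lnrt <- matrix(rnorm(60, 3, 0.4), 10, 6)
  f0 <- fit_lognormal_rt(lnrt)
  f1 <- fit_lognormal_rt(lnrt + 0.7)
  expect_equal(unname(f1$speed), unname(f0$speed) + 0.7, tolerance = 1e-8)
  expect_equal(f1$time_intensity, f0$time_intensity, tolerance = 1e-8)
  expect_equal(rt_residuals(lnrt + 0.7, f1)$values,
               rt_residuals(lnrt, f0)$values, tolerance = 1e-8)
})

test_that("empty rows and columns are reported by name", {
  lnrt <- matrix(rnorm(12, 3, 0.3), 4, 3,
                 dimnames = list(paste0("p", 1:4), paste0("i", 1:3)))
  lnrt[2, ] <- NA
  expect_error(fit_lognormal_rt(lnrt), "p2")
})
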