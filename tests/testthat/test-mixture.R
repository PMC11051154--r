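test_that("a single-class fit reduces to the CML difficulties and AIC
           arithmetic holds", {
  fx <- make_rasch_fixture(80, seq(-1, 1, length.out = 6), seed = 19)
  f1 <- fit_mixture_rasch(fx$X, 1, n_starts = 1, seed = 1)
  cml <- fit_rasch_cml(fx$X)
  expect_equal(unname(f1$difficulties_by_class[1, ]),
               unname(cml$difficulties), tolerance = 1e-6)
  expect_equal(f1$n_params, (6 - 1) + 0 + 2)
  expect_equal(f1$aic, f1$minus2_loglik + 2 * f1$n_params)
  expect_equal(rowSums(f1$memberships), rep(1, 80))
})

test_that("EM log-likelihood is non-decreasing and memberships are proper", {
  sim <- simulate_mixture_rasch(scenario_library("two_class_mixture", seed = 23))
  fit <- fit_mixture_rasch(sim$dataset, 2, n_starts = 3, seed = 31)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_equal(rowSums(fit$memberships), rep(1, 300), tolerance = 1e-12)
  expect_true(all(fit$class_weights > 0 & fit$class_weights < 1))
  expect_equal(sum(fit$class_weights), 1, tolerance = 1e-12)
  # classes are reported in decreasing weight order
  expect_true(all(diff(fit$class_weights) <= 0))
  # parameter count: 32 additional parameters per added class on a 30-item test
  expect_equal(fit$n_params, 2 * 29 + 1 + 4)
})

test_that("opposed-difficulty classes are recovered", {
  sim <- simulate_mixture_rasch(scenario_library("two_class_mixture", seed = 21))
  fit <- fit_mixture_rasch(sim$dataset, 2, n_starts = 5, seed = 42)
  tab <- table(fit$hard_assignments, sim$truth$class)
  acc <- max(sum(diag(tab)), tab[1, 2] + tab[2, 1]) / sum(tab)
  expect_gte(acc, 0.9)
  # recovered class-1 difficulties correlate with one true ordering
  r <- cor(fit$difficulties_by_class[1, ], sim$truth$difficulties_by_class[1, ])
  expect_gt(abs(r), 0.9)
})

test_that("the likelihood-ratio test reproduces nested-fit arithmetic", {
  f_small <- structure(list(n_classes = 1L, minus2_loglik = 9664.96,
                            n_params = 31L), class = "mixture_rasch")
  f_large <- structure(list(n_classes = 2L, minus2_loglik = 9564.86,
                            n_params = 63L), class = "mixture_rasch")
  lr <- likelihood_ratio_test(f_small, f_large)
  expect_equal(lr$statistic, 100.10, tolerance = 1e-8)
  expect_equal(lr$df, 32L)
  expect_true(lr$approximate)
  f_same <- f_small
  f_same$n_classes <- 2L
  expect_equal(likelihood_ratio_test(f_small, f_same)$statistic, 0)
  expect_error(likelihood_ratio_test(f_large, f_small), "fewer classes")
  f_bad <- f_large; f_bad$minus2_loglik <- 9700
  expect_error(likelihood_ratio_test(f_small, f_bad), "negative")
})

test_that("class profiling reports descriptives, correlations and
           cognitive-model regressions", {
  sim <- simulate_mixture_rasch(scenario_library("two_class_mixture", seed = 29))
  fit <- fit_mixture_rasch(sim$dataset, 2, n_starts = 3, seed = 7)
  prof <- profile_classes(fit, sim$dataset)
  expect_equal(nrow(prof$class_table), 2)
  expect_true(all(abs(prof$class_table$r_trait_criterion) <= 1, na.rm = TRUE))
  regs <- prof$regressions
  expect_equal(nrow(regs), 4)  # 2 classes x (difficulty, mean lnRT)
  # multiple R never decreases when position is added
  ok <- !is.na(regs$R)
  expect_true(all(regs$R_position[ok] >= regs$R[ok] - 1e-12))
  # a response constructed as an exact linear function of memory load
  # has multiple R = 1
  ml <- sim$dataset$item_covariates$memory_load
  fit2 <- fit
  fit2$difficulties_by_class[1, ] <- 2 * ml - mean(2 * ml)
  prof2 <- profile_classes(fit2, sim$dataset)
  expect_equal(prof2$regressions$R[1], 1, tolerance = 1e-8)
  # regression coefficients match the closed-form least-squares oracle
  y <- scale(fit$difficulties_by_class[1, ])[, 1]
  Z <- scale(cbind(sim$dataset$item_covariates$memory_load,
                   sim$dataset$item_covariates$unique_elements))
  bh <- solve(crossprod(Z), crossprod(Z, y))
  expect_equal(regs$beta_memory_load[1], bh[1], tolerance = 1e-8)
  expect_equal(regs$beta_unique_elements[1], bh[2], tolerance = 1e-8)
})

test_that("the marginal-likelihood variant agrees with CML for one class", {
  fx <- make_rasch_fixture(100, seq(-1, 1, length.out = 6), seed = 47)
  fm <- fit_mixture_rasch(fx$X, 1, n_starts = 1, seed = 1,
                          likelihood = "mml", max_iter = 60)
  cml <- fit_rasch_cml(fx$X)
  expect_gt(cor(fm$difficulties_by_class[1, ], cml$difficulties), 0.98)
  expect_equal(mean(fm$difficulties_by_class[1, ]), 0, tolerance = 1e-8)
  # generalized EM: observed log-likelihood still non-decreasing
  expect_true(all(diff(fm$loglik_trace) > -1e-6))
})
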