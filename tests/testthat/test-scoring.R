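test_that("state-based masks retain construct-driven cells and count
           correctly", {
  st <- matrix(1L, 3, 30)
  expect_true(all(mask_from_states(st)$retain))
  st[2, 17:30] <- 2L   # change point after item 16
  msk <- mask_from_states(st)
  expect_equal(sum(msk$retain[2, ]), 16)
  set.seed(12)
  st3 <- matrix(sample(1:2, 600, replace = TRUE), 20, 30)
  expect_equal(sum(mask_from_states(st3)$retain), sum(st3 == 1L))
  expect_error(mask_from_states(matrix(3, 2, 2)), "only 1 and 2")
})

test_that("residual-threshold masks apply the one- and two-sided rules", {
  res <- structure(list(values = matrix(c(-2.6, -1.0, 3.0), 1, 3),
                        standardized = matrix(c(-2.6, -1.0, 3.0), 1, 3),
                        sd_reference = 1), class = "rt_residuals")
  neg <- mask_from_residual_threshold(res, -2.5, "negative")
  expect_equal(unname(neg$retain[1, ]), c(FALSE, TRUE, TRUE))
  both <- mask_from_residual_threshold(res, 2.5, "both")
  expect_equal(unname(both$retain[1, ]), c(FALSE, TRUE, FALSE))
  # nothing below -6 SD: full retain
  expect_true(all(mask_from_residual_threshold(res, -6, "negative")$retain))
})

test_that("EAP matches a fine-grid integration oracle", {
  set.seed(41)
  beta <- rnorm(30, 0, 1.2)
  X <- matrix(rbinom(100 * 30, 1, 0.5), 100, 30)
  est <- eap_abilities(X, beta)
  grid <- seq(-6, 6, length.out = 10001)
  P <- plogis(outer(grid, beta, `-`))
  w <- dnorm(grid)
  for (j in 1:100) {
    lik <- exp(colSums(X[j, ] * log(t(P)) + (1 - X[j, ]) * log(1 - t(P))))
    post <- w * lik
    eap_oracle <- sum(post * grid) / sum(post)   # trapezoid with equal steps
    expect_equal(est$eap[j], eap_oracle, tolerance = 1e-4)
  }
})

test_that("EAP symmetry, shrinkage and unscorable flagging", {
  beta <- c(-1.5, -0.5, 0.5, 1.5)
  half <- eap_abilities(matrix(c(1, 1, 0, 0), 1), beta)
  expect_equal(half$eap[1], 0, tolerance = 1e-10)
  allc <- eap_abilities(matrix(1, 1, 4), beta)
  expect_true(allc$eap[1] > 0 && allc$eap[1] < 4)
  msk <- suppressWarnings(new_trim_mask(matrix(FALSE, 1, 4), "none"))
  out <- suppressWarnings(eap_abilities(matrix(1, 1, 4), beta, msk))
  expect_true(out$unscorable[1])
  expect_true(is.na(out$eap[1]))
})

test_that("empirical reliability formula and simulation property", {
  est <- data.frame(eap = c(-1, 0, 1), posterior_sd = 1)
  expect_equal(empirical_reliability(est), 0.5, tolerance = 1e-10)
  est2 <- data.frame(eap = rnorm(50), posterior_sd = 1e-8)
  expect_gt(empirical_reliability(est2), 0.999)
  expect_error(empirical_reliability(data.frame(eap = c(1, 1), posterior_sd = 1)),
               "variance")
  # reliability approximates squared correlation with true ability
  fx <- make_rasch_fixture(301, rnorm(30, 0, 1), seed = 33)
  est3 <- eap_abilities(fx$X, fx$beta)
  rel <- empirical_reliability(est3)
  expect_equal(rel, cor(est3$eap, fx$theta)^2, tolerance = 0.05)
})

test_that("disattenuation arithmetic, caps and monotonicity", {
  expect_equal(disattenuate(0.5, 1), 0.5)
  expect_equal(disattenuate(0.5, 0.64), 0.625)
  expect_equal(round(disattenuate(0.628, 1)^2, 3), 0.394)
  expect_warning(adj <- disattenuate(0.9, 0.5), "capped")
  expect_equal(adj, 1)
  expect_error(disattenuate(0.5, 0), "reliability")
  expect_gt(disattenuate(0.6, 0.8), disattenuate(0.5, 0.8))
  expect_gt(disattenuate(0.5, 0.7), disattenuate(0.5, 0.9))
})

test_that("bootstrap gain test is deterministic, null under no trim, and
           powered on erratic contamination", {
  sim <- simulate_joint(scenario_library("paper_like_cp", seed = 2))
  msk <- mask_from_states(sim$truth$states)
  b1 <- bootstrap_gain_test(sim$dataset, msk, criterion = "criterion",
                            n_boot = 99, seed = 7)
  b2 <- bootstrap_gain_test(sim$dataset, msk, criterion = "criterion",
                            n_boot = 99, seed = 7)
  expect_identical(b1$p_value, b2$p_value)
  expect_identical(b1$null_gains, b2$null_gains)
  # identical mask and baseline: zero observed gain
  full <- new_trim_mask(!is.na(sim$dataset$responses), "none")
  b0 <- bootstrap_gain_test(sim$dataset, full, full, criterion = "criterion",
                            n_boot = 59, seed = 3)
  expect_equal(b0$observed_gain, 0)
  expect_warning(bootstrap_gain_test(sim$dataset, msk, criterion = "criterion",
                                     n_boot = 50, seed = 1), "n_boot")
})

test_that("validity table squares r exactly and empty trims equal no-trim", {
  # single-state data: no residual reaches -6 or -5 SD, so those trim rows
  # must coincide with the no-trim row
  sim <- simulate_joint(scenario_library("null_single_state", seed = 5))
  vt <- suppressWarnings(validity_table(sim$dataset, list(),
                                        criterion = "criterion"))
  expect_equal(vt$variance_explained, vt$adjusted_r^2)
  no_trim <- vt[vt$trim == "no_trim", ]
  for (lbl in c("residual<-6 SD", "residual<-5 SD")) {
    row <- vt[vt$trim == lbl, ]
    expect_equal(row$raw_r, no_trim$raw_r)
    expect_equal(row$adjusted_r, no_trim$adjusted_r)
  }
})

test_that("the bootstrap test detects genuine erratic contamination", {
  # trims that remove the truly erratic cells (9x residual variance, chance
  # accuracy) produce significant validity gains in the median replicate
  ps <- vapply(1:20, function(sd) {
    sim <- simulate_joint(scenario_library("paper_like_cp", seed = sd))
    msk <- mask_from_states(sim$truth$states)
    bootstrap_gain_test(sim$dataset, msk, criterion = "criterion",
                        n_boot = 199, seed = sd)$p_value
  }, 0)
  # under the null the p-values would be uniform on (0,1); genuine
  # contamination pulls the whole distribution toward zero
  expect_lt(median(ps), 0.15)
  expect_gt(mean(ps < 0.05), 0.3)
})
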