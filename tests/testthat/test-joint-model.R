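# reduced sampler settings keep these fits to a few seconds each
small_cfg <- function(...) joint_config(n_chains = 1, burnin = 300, iters = 300, ...)

test_that("stationary distribution solves pi P = pi and matches power
           iteration", {
  expect_equal(unname(stationary_distribution(matrix(0.5, 2, 2))), c(0.5, 0.5))
  P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)
  pi_hat <- stationary_distribution(P)
  expect_equal(unname(pi_hat), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(max(abs(pi_hat %*% P - pi_hat)), 0, tolerance = 1e-10)
  # power-iteration oracle
  v <- c(1, 0)
  for (i in 1:10000) v <- as.vector(v %*% P)
  expect_equal(unname(pi_hat), v, tolerance = 1e-10)
  expect_error(stationary_distribution(diag(2)), "stationary")
  expect_error(stationary_distribution(matrix(1, 3, 3)), "2x2")
})

test_that("convergence diagnostics separate mixed from disjoint chains", {
  set.seed(44)
  good <- list(matrix(rnorm(1000)), matrix(rnorm(1000)))
  d <- convergence_diagnostics(good)
  expect_lt(d$rhat, 1.02)
  expect_lt(abs(d$lag1_acf), 0.1)
  expect_gt(d$ess, 500)
  bad <- list(matrix(rnorm(1000, 0)), matrix(rnorm(1000, 10)))
  expect_gt(convergence_diagnostics(bad)$rhat, 3)
  expect_warning(convergence_diagnostics(matrix(rnorm(500))), "split-chain")
})

test_that("single-state data produce near-zero erratic occupancy", {
  sim <- simulate_joint(scenario_library("null_single_state", seed = 3))
  post <- suppressWarnings(gibbs_fit_markov(sim$dataset, small_cfg(seed = 9)))
  expect_lt(mean(post$state_prob), 0.05)
})

test_that("forced single-state configuration reproduces the Rasch and
           lognormal fits", {
  sim <- simulate_joint(scenario_library("null_single_state", seed = 13))
  post <- suppressWarnings(
    gibbs_fit_markov(sim$dataset, small_cfg(seed = 2, single_state = TRUE)))
  rt <- fit_lognormal_rt(log_transform(sim$dataset$response_times))
  s <- post$summary
  tau_eap <- s$mean[grep("^tau_", s$param)]
  gam_eap <- s$mean[grep("^gamma_", s$param)]
  expect_gt(cor(tau_eap, rt$speed), 0.999)
  expect_equal(mean(gam_eap), 0, tolerance = 1e-8)
  expect_gt(cor(gam_eap, rt$time_intensity), 0.99)
  expect_equal(unname(post$sigma2[1]), rt$residual_variance, tolerance = 0.05)
  cml <- fit_rasch_cml(sim$dataset$responses)
  b1 <- s$mean[grep("^beta1_", s$param)]
  expect_gt(cor(b1, cml$difficulties), 0.98)
})

test_that("change-point fits recover per-person transitions on a small
           late-shift simulation", {
  sim <- simulate_joint(sim_config(n_persons = 80, n_items = 20,
                                   sigma2 = c(0.187, 1.647),
                                   k_range = 14:20, no_transition_prob = 0,
                                   seed = 37))
  post <- gibbs_fit_changepoint(sim$dataset, small_cfg(seed = 21), "residual")
  expect_lte(mean(abs(post$changepoints$k_mode - sim$truth$k)), 2)
  # per-draw ordering constraint holds on every stored draw
  s2 <- post$chains[[1]]$sigma2
  expect_true(all(s2[, 1] < s2[, 2]))
  # a person simulated without a transition has posterior mode at n_items
  no_trans <- which(sim$truth$k == 20)
  expect_true(mean(post$changepoints$k_mode[no_trans] == 20) > 0.8)
  # reconstructed states follow the step pattern
  st <- modal_states(post)
  expect_true(all(apply(st, 1, function(r) all(diff(r) >= 0))))
})

test_that("occupancy curve is definitionally consistent and flat for
           single-state data", {
  sim <- simulate_joint(scenario_library("null_single_state", seed = 23))
  post <- suppressWarnings(gibbs_fit_markov(sim$dataset, small_cfg(seed = 31)))
  oc <- occupancy_curve(post)
  expect_equal(nrow(oc), 30)
  expect_true(all(oc$prop_erratic < 0.05))
  # column means of the per-cell state probabilities agree with the curve
  expect_equal(unname(colMeans(post$state_prob)), oc$prop_erratic,
               tolerance = 1e-10)
})

test_that("state characterization flags disengagement and the engaged-slow
           inversion", {
  sim <- simulate_joint(sim_config(n_persons = 100, n_items = 20,
                                   sigma2 = c(0.187, 1.647),
                                   erratic_accuracy = 0.26,
                                   k_range = 14:20, no_transition_prob = 0,
                                   seed = 51))
  post <- gibbs_fit_changepoint(sim$dataset, small_cfg(seed = 8), "residual")
  rep1 <- characterize_states(post, sim$dataset)
  expect_equal(rep1$disengaged_state, 2L)
  expect_gt(rep1$table$sigma2[2] / rep1$table$sigma2[1], 2)
  expect_lt(rep1$table$prop_correct[2], rep1$table$prop_correct[1])

  simi <- simulate_joint(scenario_library("early_engagement_inversion", seed = 4))
  posti <- suppressWarnings(gibbs_fit_markov(
    simi$dataset, joint_config(n_chains = 1, burnin = 500, iters = 500,
                               seed = 6, share_beta = TRUE)))
  repi <- characterize_states(posti, simi$dataset)
  expect_true(is.na(repi$disengaged_state))
  expect_match(paste(repi$notes, collapse = " "), "alternative interpretation")
})

test_that("preconditions and warnings: sparse persons rejected, single-state
           data warned", {
  sim <- simulate_joint(sim_config(n_persons = 20, n_items = 10, seed = 3))
  ds <- sim$dataset
  ds$responses[1, ] <- NA
  ds$response_times[1, ] <- NA
  expect_error(gibbs_fit_markov(ds, small_cfg()), "fewer than 5")
  simn <- simulate_joint(scenario_library("null_single_state", seed = 7))
  expect_warning(gibbs_fit_markov(simn$dataset, small_cfg(seed = 11)),
                 "single-state")
})
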