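test_that("generation is bit-exact given (config, seed)", {
  cfg <- scenario_library("paper_like_cp", seed = 9)
  a <- simulate_joint(cfg)
  b <- simulate_joint(cfg)
  expect_identical(a$dataset$responses, b$dataset$responses)
  expect_identical(a$dataset$response_times, b$dataset$response_times)
  expect_identical(a$truth, b$truth)
  cfg2 <- scenario_library("paper_like_cp", seed = 10)
  expect_false(identical(simulate_joint(cfg2)$dataset$responses,
                         a$dataset$responses))
})

test_that("accuracy margins concentrate around the model probabilities", {
  cfg <- sim_config(n_persons = 1000, n_items = 20, structure = "markov",
                    initial_probs = c(1, 0),
                    transition_matrix = diag(2), seed = 5)
  sim <- simulate_mixture_rasch(sim_config(n_persons = 300, n_items = 30,
                                           difficulties = rep(0, 30),
                                           ability_sd = 1e-9, seed = 5))
  # theta ~ 0, beta = 0: marginal proportion correct ~ .5
  expect_equal(mean(sim$dataset$responses), 0.5, tolerance = 0.02)
  simj <- simulate_joint(sim_config(n_persons = 1000, n_items = 20,
                                    structure = "markov",
                                    initial_probs = c(1, 0),
                                    transition_matrix = diag(2), seed = 6))
  p_theory <- plogis(outer(simj$truth$theta, simj$truth$beta, `-`))
  expect_lt(max(abs(colMeans(simj$dataset$responses) - colMeans(p_theory))), 0.06)
})

test_that("state dynamics and residual variances match their configuration", {
  simn <- simulate_joint(scenario_library("null_single_state", seed = 2))
  expect_true(all(simn$truth$states == 1L))
  lnrt <- log(simn$dataset$response_times)
  e <- lnrt - outer(simn$truth$tau, simn$truth$gamma, `-`)
  expect_equal(var(as.vector(e)), 0.187, tolerance = 0.07)

  simc <- simulate_joint(scenario_library("paper_like_cp", seed = 8))
  e2 <- log(simc$dataset$response_times) -
    outer(simc$truth$tau, simc$truth$gamma, `-`)
  ratio <- var(e2[simc$truth$states == 2L]) / var(e2[simc$truth$states == 1L])
  expect_gt(ratio, 7); expect_lt(ratio, 11)
  # change points all in the last third
  expect_true(all(simc$truth$k > 20))
  # criterion correlation near its target
  expect_lt(abs(cor(simc$dataset$person_covariates$criterion,
                    simc$truth$theta) - 0.63), 0.1)
})

test_that("markov preset matches the configured initial and long-run
           state distributions", {
  cfg <- scenario_library("paper_like_markov", seed = 14)
  sim <- simulate_joint(cfg)
  expect_lt(abs(mean(sim$truth$states[, 1] == 2L) - 0.052), 0.035)
  expect_equal(unname(stationary_distribution(cfg$transition_matrix)),
               c(0.70, 0.30), tolerance = 0.005)
  # occupancy at the final item is ~20% (the configured elbow pattern)
  expect_lt(abs(mean(sim$truth$states[, 30] == 2L) - 0.20), 0.06)
})

test_that("scenario presets are complete and serialize losslessly", {
  presets <- scenario_library()
  expect_setequal(names(presets),
                  c("paper_like_cp", "paper_like_markov", "two_class_mixture",
                    "early_engagement_inversion", "null_single_state"))
  expect_error(scenario_library("nope"), "paper_like_cp")
  dir <- withr::local_tempdir()
  for (nm in names(presets)) {
    pth <- file.path(dir, paste0(nm, ".yaml"))
    write_sim_config(presets[[nm]], pth)
    back <- read_sim_config(pth)
    expect_equal(back, presets[[nm]], tolerance = 1e-9)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(sigma2 = c(2, 1)), "sigma2")
  expect_error(sim_config(initial_probs = c(0.6, 0.6)), "summing to 1")
  expect_error(sim_config(erratic_accuracy = 1.5), "erratic_accuracy")
  expect_error(sim_config(class_weights = c(0.5, 0.6)), "class_weights")
  expect_error(simulate_mixture_rasch(sim_config(class_weights = c(0.5, 0.5))),
               "difficulties_by_class")
})
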