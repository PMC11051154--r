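test_that("rasch_probability is the logistic in theta - beta", {
  expect_equal(rasch_probability(0, 0), 0.5)
  # symmetry and the trait levels profiled for the three latent classes
  expect_equal(round(rasch_probability(-0.235, 0), 3), 0.442)
  expect_equal(round(rasch_probability(1.689, 0), 3), 0.844)
  expect_equal(round(rasch_probability(0.746, 0), 3), 0.678)
  expect_equal(rasch_probability(700, 0), 1)
  expect_equal(rasch_probability(-700, 0), 0)
  expect_error(rasch_probability(Inf, 0), "finite")
})

test_that("elementary symmetric functions match polynomial expansion and
           exhaustive enumeration", {
  expect_equal(elementary_symmetric(2), c(1, 2))
  expect_equal(elementary_symmetric(c(1, 2)), c(1, 3, 2))
  # brute force over all 2^8 subsets
  set.seed(3)
  eps <- rexp(8) + 0.1
  brute <- sapply(0:8, function(r) {
    subs <- utils::combn(8, r)
    if (r == 0) return(1)
    sum(apply(subs, 2, function(ix) prod(eps[ix])))
  })
  expect_equal(elementary_symmetric(eps), brute)
  expect_error(elementary_symmetric(c(1, -1)), "> 0")
})

test_that("CML estimates match a grid-search oracle on a small fixture", {
  fx <- make_rasch_fixture(20, c(-0.8, 0.2, 0.6), seed = 11)
  fit <- fit_rasch_cml(fx$X)
  expect_equal(mean(fit$difficulties), 0, tolerance = 1e-10)
  # oracle: direct maximization of the conditional likelihood on a fine grid
  # over the two free (anchored) difficulties
  st <- respshift:::.build_patterns(fx$X[rowSums(fx$X) %in% 1:2, ])
  grid <- seq(-3, 3, by = 0.005)
  best <- c(NA, NA); best_v <- Inf
  for (b1 in grid) {
    v <- vapply(grid, function(b2)
      respshift:::.cml_nll(c(b1, b2, 0), st$patterns, st$item_margins), 0)
    i <- which.min(v)
    if (v[i] < best_v) { best_v <- v[i]; best <- c(b1, grid[i]) }
  }
  oracle <- c(best, 0); oracle <- oracle - mean(oracle)
  expect_equal(unname(fit$difficulties), oracle, tolerance = 0.01)
})

test_that("identical item columns get identical difficulties", {
  set.seed(5)
  col <- rbinom(40, 1, 0.5)
  other <- rbinom(40, 1, 0.7)
  X <- cbind(col, col, other)
  fit <- fit_rasch_cml(X)
  expect_equal(fit$difficulties[[1]], fit$difficulties[[2]], tolerance = 1e-6)
})

test_that("the converged centered solution is invariant to the start", {
  fx <- make_rasch_fixture(60, c(-1, -0.2, 0.5, 0.7), seed = 9)
  f0 <- respshift:::.cml_optimize(fx$X)
  f1 <- respshift:::.cml_optimize(fx$X, start = fx$beta + 2.5)
  expect_equal(f0$difficulties, f1$difficulties, tolerance = 1e-5)
})

test_that("perfectly separated items and extreme-only samples are rejected", {
  X <- cbind(rep(1, 10), rbinom(10, 1, 0.5))
  X[1, 2] <- 1 - X[1, 2]  # ensure second item mixed
  expect_error(fit_rasch_cml(X), "separated")
  expect_error(fit_rasch_cml(rbind(c(1, 1, 1), c(0, 0, 0))), "non-extreme")
})

test_that("specific objectivity: difficulties agree across random halves", {
  fx <- make_rasch_fixture(500, seq(-2, 2, length.out = 24), seed = 13)
  set.seed(17)
  half <- sample(c(TRUE, FALSE), 500, replace = TRUE)
  f1 <- fit_rasch_cml(fx$X[half, ])
  f2 <- fit_rasch_cml(fx$X[!half, ])
  expect_gt(cor(f1$difficulties, f2$difficulties), 0.9)
})

test_that("ability estimation is finite everywhere and tracks raw score", {
  beta <- seq(-1, 1, length.out = 10)
  X <- rbind(rep(1, 10), rep(0, 10), c(rep(1, 5), rep(0, 5)))
  ab <- rasch_abilities(X, beta)
  expect_true(all(is.finite(ab$theta)))
  expect_true(ab$theta[1] > ab$theta[3] & ab$theta[3] > ab$theta[2])
  ml <- rasch_abilities(X, beta, method = "ml")
  expect_true(all(is.finite(ml$theta)))
  expect_true(all(ab$se > 0))
})
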