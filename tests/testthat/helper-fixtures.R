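# small Rasch fixture built directly from the model, independent of the
# simulate module, for oracle-based tests
make_rasch_fixture <- function(n_persons, difficulties, seed = 1,
                               theta_sd = 1) {
  set.seed(seed)
  theta <- stats::rnorm(n_persons, 0, theta_sd)
  p <- stats::plogis(outer(theta, difficulties, `-`))
  X <- matrix(stats::rbinom(length(p), 1, p), nrow(p), ncol(p))
  list(X = X, theta = theta, beta = difficulties)
}

# tiny complete test_dataset with RTs and covariates
make_tiny_dataset <- function(n_persons = 12, n_items = 6, seed = 2) {
  set.seed(seed)
  beta <- seq(-1, 1, length.out = n_items)
  fx <- make_rasch_fixture(n_persons, beta, seed = seed)
  tau <- stats::rnorm(n_persons, 3, 0.3)
  gam <- seq(-0.3, 0.3, length.out = n_items)
  lnrt <- outer(tau, gam, `-`) + matrix(stats::rnorm(n_persons * n_items, 0, 0.4),
                                        n_persons, n_items)
  test_dataset(fx$X, exp(lnrt),
               person_covariates = data.frame(person = paste0("p", 1:n_persons),
                                              criterion = fx$theta + stats::rnorm(n_persons, 0, 0.5)),
               item_covariates = data.frame(item = paste0("i", 1:n_items),
                                            memory_load = rep(1:3, length.out = n_items),
                                            unique_elements = rep(4:6, length.out = n_items),
                                            position = 1:n_items))
}
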