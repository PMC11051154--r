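#' Sampler configuration for the joint state model
#'
#' Defaults follow the long-run protocol (10,000 burn-in and 10,000 kept
#' iterations on 2 chains); reduced desk-scale settings (e.g., 1,000/1,000)
#' are appropriate for simulation studies and are what the test suite uses.
#'
#' @param n_chains number of independent chains.
#' @param burnin,iters burn-in and kept iterations per chain.
#' @param prior_var_ability prior variance of the logit-scale parameters
#'   theta and beta (normal, mean 0). The default 4 is weakly informative on
#'   the probability scale; much larger values make the erratic-state
#'   accuracy parameters degenerate for persons with no erratic responses.
#' @param prior_var_speed prior variance of tau and gamma (log-seconds
#'   scale).
#' @param gamma_shape,gamma_rate gamma prior on the RT residual precisions.
#' @param prior_var_erratic variance of the hierarchical prior on
#'   erratic-state abilities, `theta_j2 ~ N(mu2, prior_var_erratic)` with the
#'   common erratic level `mu2` estimated. Erratic responding (guessing,
#'   lapses) is modelled as a person-invariant success level; a small
#'   variance stops per-person erratic abilities from absorbing chance runs
#'   of incorrect answers.
#' @param min_variance_ratio identification floor on the residual-variance
#'   separation: the erratic state must satisfy
#'   `sigma2_2 >= min_variance_ratio * sigma2_1` on every draw. The two
#'   response states are defined by the size of the residual variance; with
#'   no floor, a second state whose variance hugs the first fits ordinary
#'   responses for free and absorbs arbitrary cells in data that have no
#'   erratic state at all (the motivating application has a ~9x separation).
#'   Data with genuinely milder heteroscedasticity than the floor are
#'   reported as indistinct states.
#' @param k_prior prior on the per-person change point: `"spike_slab"` (the
#'   default; no transition with estimated population probability omega ~
#'   Beta(1,1), otherwise uniform over 1..n_items) or `"uniform"` (flat over
#'   1..n_items). The flat prior attaches no cost to declaring a transition,
#'   which lets high-residual construct-driven tail responses leak into the
#'   erratic state; the spike-and-slab prior learns the no-transition rate
#'   from the data, exactly as the Markov structure learns its switch
#'   probability.
#' @param warmup number of initial burn-in sweeps during which all responses
#'   are held in the construct-driven state, so the accuracy and RT structure
#'   is well fit before state sampling is released (staged initialization;
#'   guards against a degenerate mode in which the two states split the
#'   population instead of separating erratic cells). Default: half the
#'   burn-in, capped at 500.
#' @param share_beta if `TRUE`, item difficulties are shared between the two
#'   states (only abilities are state-specific). With fully state-specific
#'   difficulties and a uniform change-point prior, the erratic state can act
#'   as a second complete measurement model and absorb ordinary responses, so
#'   sharing is the default under the change-point structures; the Markov
#'   structure, whose learned transition probabilities penalize spurious
#'   switching, uses state-specific difficulties by default (`NULL` = this
#'   structure-dependent default).
#' @param seed master seed; per-chain substreams are derived from it.
#' @param single_state if `TRUE`, all responses are forced into the
#'   construct-driven state (no transitions), which reduces the model to a
#'   Rasch accuracy model plus the homoscedastic lognormal RT model.
#' @param slice_w,slice_m slice-sampler step width and maximum step-out count.
#' @param max_rhat convergence threshold on the potential scale reduction.
#' @return a named list of class `joint_config`.
#' @export
joint_config <- function(n_chains = 2, burnin = 10000, iters = 10000,
                         prior_var_ability = 4, prior_var_speed = 100,
                         gamma_shape = 0.001, gamma_rate = 0.001,
                         prior_var_erratic = 0.25,
                         min_variance_ratio = 4,
                         k_prior = c("spike_slab", "uniform"),
                         warmup = NULL, share_beta = NULL,
                         seed = 1, single_state = FALSE,
                         slice_w = 1, slice_m = 20, max_rhat = 1.1) {
  if (is.null(warmup)) warmup <- min(500L, as.integer(burnin) %/% 2L)
  k_prior <- match.arg(k_prior)
  structure(list(n_chains = as.integer(n_chains), burnin = as.integer(burnin),
                 iters = as.integer(iters), warmup = as.integer(warmup),
                 share_beta = share_beta,
                 prior_var_ability = prior_var_ability,
                 prior_var_speed = prior_var_speed,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 prior_var_erratic = prior_var_erratic, k_prior = k_prior,
                 min_variance_ratio = min_variance_ratio,
                 seed = as.integer(seed), single_state = isTRUE(single_state),
                 slice_w = slice_w, slice_m = as.integer(slice_m),
                 max_rhat = max_rhat),
            class = "joint_config")
}

.joint_fit <- function(dataset, config, structure) {
  stopifnot(inherits(dataset, "test_dataset"))
  if (!inherits(config, "joint_config")) config <- do.call(joint_config, config)
  X <- dataset$responses
  if (is.null(dataset$response_times))
    stop("the joint state model requires response times")
  lnRT <- log_transform(dataset$response_times)
  nobs <- rowSums(!is.na(X) | !is.na(lnRT))
  if (any(nobs < 5))
    stop("person(s) with fewer than 5 observed items: ",
         paste(dataset$person_ids[nobs < 5], collapse = ", "))
  Xi <- X
  Xi[is.na(Xi)] <- -1
  storage.mode(Xi) <- "integer"
  struct_code <- match(structure, c("markov", "cp-residual", "cp-speed")) - 1L

  share_beta <- config$share_beta
  if (is.null(share_beta)) share_beta <- structure != "markov"
  k_init <- if (structure == "markov") rep(ncol(X), nrow(X))
            else .init_changepoints(X, lnRT)
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    chains[[ch]] <- joint_gibbs_cpp(Xi, unclass(lnRT), struct_code,
                                    config$single_state,
                                    config$burnin, config$iters,
                                    min(config$warmup, config$burnin),
                                    share_beta, as.integer(k_init),
                                    identical(config$k_prior, "spike_slab"),
                                    config$min_variance_ratio,
                                    config$prior_var_erratic,
                                    config$prior_var_ability,
                                    config$prior_var_speed,
                                    config$gamma_shape,
                                    config$gamma_rate, config$slice_w,
                                    config$slice_m)
  }
  .assemble_posterior(chains, dataset, config, structure)
}

.combine_draws <- function(chains, what) do.call(rbind, lapply(chains, `[[`, what))

# Per-person single change-in-variance scan on residuals from the
# homoscedastic lognormal fit: an interior change point is accepted only when
# the two-segment profile likelihood beats the one-segment fit by a BIC-style
# margin, so persons without a transition start at k = n_items.
.init_changepoints <- function(X, lnRT, penalty = 3 * log(ncol(lnRT))) {
  fit <- fit_lognormal_rt(lnRT)
  e2 <- (unclass(lnRT) - outer(fit$speed, fit$time_intensity, `-`))^2
  I <- ncol(e2)
  vapply(seq_len(nrow(e2)), function(j) {
    v <- e2[j, ]
    obs <- !is.na(v)
    n <- sum(obs)
    if (n < 6) return(I)
    cs <- cumsum(ifelse(obs, v, 0))
    cn <- cumsum(obs)
    tot <- cs[I]
    nll1 <- n * log(tot / n)
    ks <- which(cn >= 2 & (n - cn) >= 2 & seq_len(I) < I)
    if (!length(ks)) return(I)
    nll2 <- vapply(ks, function(k) {
      n1 <- cn[k]; n2 <- n - n1
      s1 <- cs[k]; s2 <- tot - s1
      n1 * log(max(s1, 1e-12) / n1) + n2 * log(max(s2, 1e-12) / n2)
    }, 0)
    best <- which.min(nll2)
    if (nll1 - nll2[best] > penalty) ks[best] else I
  }, 0L)
}

.assemble_posterior <- function(chains, dataset, config, structure) {
  J <- nrow(dataset$responses); I <- ncol(dataset$responses)
  cp <- structure != "markov"
  warnings <- character(0)

  state_prob <- Reduce(`+`, lapply(chains, `[[`, "state_prob")) / length(chains)
  dimnames(state_prob) <- dimnames(dataset$responses)

  sig <- .combine_draws(chains, "sigma2")
  sigma2 <- colMeans(sig)
  names(sigma2) <- c("sigma2_1", "sigma2_2")

  transition <- NULL
  if (!cp && !config$single_state) {
    tr <- colMeans(.combine_draws(chains, "trans"))
    ip <- colMeans(.combine_draws(chains, "initp"))
    transition <- list(
      initial_probs = stats::setNames(ip, c("state1", "state2")),
      transition_matrix = matrix(tr, 2, 2, byrow = TRUE,
                                 dimnames = list(c("from1", "from2"),
                                                 c("to1", "to2"))))
  }
  changepoints <- NULL
  if (cp) {
    kd <- .combine_draws(chains, "k")
    k_mode <- apply(kd, 2L, function(v) {
      tb <- tabulate(v, I)
      which.max(tb)
    })
    changepoints <- data.frame(person = dataset$person_ids,
                               k_mode = k_mode, k_mean = colMeans(kd))
  }

  # parameter summaries (EAP, posterior SD, central 95% interval)
  vec_summ <- function(mat, prefix) {
    q <- apply(mat, 2L, stats::quantile, probs = c(.025, .975))
    data.frame(param = paste0(prefix, seq_len(ncol(mat))),
               mean = colMeans(mat), sd = apply(mat, 2L, stats::sd),
               q025 = q[1, ], q975 = q[2, ], row.names = NULL)
  }
  summ <- rbind(
    data.frame(param = c("sigma2_1", "sigma2_2"), mean = colMeans(sig),
               sd = apply(sig, 2, stats::sd),
               q025 = apply(sig, 2, stats::quantile, .025),
               q975 = apply(sig, 2, stats::quantile, .975), row.names = NULL),
    vec_summ(.combine_draws(chains, "gamma"), "gamma_"),
    vec_summ(.combine_draws(chains, "tau"), "tau_"),
    vec_summ(.combine_draws(chains, "beta1"), "beta1_"),
    vec_summ(.combine_draws(chains, "beta2"), "beta2_"),
    vec_summ(.combine_draws(chains, "theta1"), "theta1_"),
    vec_summ(.combine_draws(chains, "theta2"), "theta2_"))
  if (!cp && !config$single_state)
    summ <- rbind(summ,
                  vec_summ(.combine_draws(chains, "initp"), "initp_"),
                  vec_summ(.combine_draws(chains, "trans"), "trans_"))

  post <- structure(list(
    structure = structure, chains = chains, config = config,
    summary = summ, sigma2 = sigma2, transition = transition,
    changepoints = changepoints, state_prob = state_prob,
    deviance = unlist(lapply(chains, `[[`, "deviance")),
    person_ids = dataset$person_ids, item_ids = dataset$item_ids,
    n_items = I, n_persons = J), class = "joint_posterior")

  diag <- convergence_diagnostics(post)
  post$diagnostics <- diag
  post$converged <- all(diag$rhat <= config$max_rhat, na.rm = TRUE)
  if (!post$converged)
    warnings <- c(warnings, sprintf(
      "convergence failure: %d parameter(s) with Rhat > %.2f (max %.3f)",
      sum(diag$rhat > config$max_rhat, na.rm = TRUE), config$max_rhat,
      max(diag$rhat, na.rm = TRUE)))
  occ2 <- mean(state_prob)
  if (!config$single_state && occ2 < 0.01)
    warnings <- c(warnings, "single-state data: erratic-state occupancy is ~0")
  post$warnings <- warnings
  for (w in warnings) warning(w, call. = FALSE)
  post
}

#' Fit the joint accuracy/response-time model with Markov state transitions
#'
#' Two latent response states per cell (construct-driven vs erratic) with
#' state-specific abilities/difficulties for accuracy and state-specific
#' residual variances for log response time; per-person state sequences follow
#' a time-homogeneous lag-1 Markov chain sampled by forward filtering /
#' backward sampling. See [joint_config()] for priors and sampler settings.
#' The constraint `sigma2_1 < sigma2_2` identifies state 1 as the
#' low-residual-variance (construct-driven) state on every stored draw.
#'
#' @param dataset a [test_dataset()] with response times.
#' @param config a [joint_config()] (or list of overrides).
#' @return object of class `joint_posterior`: posterior draws per chain,
#'   EAP `summary`, `sigma2`, `transition` (initial probabilities and 2x2
#'   transition matrix), `state_prob` (posterior probability of the erratic
#'   state per cell), `deviance` draws, `diagnostics`, `converged`.
#' @export
gibbs_fit_markov <- function(dataset, config = joint_config()) {
  .joint_fit(dataset, config, "markov")
}

#' Fit the joint model with a per-person change point
#'
#' Each person's state sequence is constrained to a single transition:
#' construct-driven for items `1..k_j`, erratic afterwards, with `k_j`
#' uniform over `1..n_items` a priori (`k_j = n_items` means no transition)
#' and sampled from its enumerated discrete full conditional. In
#' `mode = "residual"` the states switch the RT residual variance (and the
#' accuracy parameters); in `mode = "speed"` the states switch the person
#' speed parameter `tau_js` with a single residual variance, the
#' mean-shift alternative used to check whether a simple speed shift can
#' account for erratic responding.
#'
#' @inheritParams gibbs_fit_markov
#' @param mode `"residual"` or `"speed"`.
#' @return a `joint_posterior`; additionally carries `changepoints`
#'   (posterior mode and mean of `k_j` per person).
#' @export
gibbs_fit_changepoint <- function(dataset, config = joint_config(),
                                  mode = c("residual", "speed")) {
  mode <- match.arg(mode)
  .joint_fit(dataset, config, if (mode == "residual") "cp-residual" else "cp-speed")
}

#' @export
print.joint_posterior <- function(x, ...) {
  cat(sprintf("<joint_posterior> structure = %s; %d chains x %d kept draws\n",
              x$structure, length(x$chains), x$config$iters))
  cat(sprintf("  sigma2 (construct, erratic) = (%.3f, %.3f)\n",
              x$sigma2[1], x$sigma2[2]))
  if (!is.null(x$transition)) {
    cat(sprintf("  initial state probs = (%.3f, %.3f)\n",
                x$transition$initial_probs[1], x$transition$initial_probs[2]))
  }
  cat(sprintf("  erratic-state occupancy (posterior mean) = %.3f\n",
              mean(x$state_prob)))
  cat(sprintf("  converged: %s\n", x$converged))
  invisible(x)
}

#' Modal state classifications from a fitted joint model
#'
#' Returns the person x item matrix of most likely states (1 =
#' construct-driven, 2 = erratic). Under a change-point structure the states
#' are reconstructed from the posterior mode of `k_j`, so every row follows
#' the step pattern 1...1 2...2 exactly.
#'
#' @param posterior a `joint_posterior`.
#' @return integer matrix with entries in \{1, 2\}.
#' @export
modal_states <- function(posterior) {
  stopifnot(inherits(posterior, "joint_posterior"))
  if (!is.null(posterior$changepoints)) {
    k <- posterior$changepoints$k_mode
    st <- outer(seq_along(k), seq_len(posterior$n_items),
                function(j, i) ifelse(i <= k[j], 1L, 2L))
  } else {
    st <- ifelse(posterior$state_prob > 0.5, 2L, 1L)
  }
  dimnames(st) <- dimnames(posterior$state_prob)
  st
}

#' Stationary distribution of a two-state transition matrix
#'
#' Solves `pi P = pi`, `sum(pi) = 1` for a row-stochastic 2x2 matrix: the
#' long-run proportion of time spent in each response state if testing
#' continued indefinitely.
#'
#' @param transition_matrix row-stochastic 2x2 matrix (or a `joint_posterior`
#'   fitted with the Markov structure).
#' @return named probability pair `(state1, state2)`.
#' @export
stationary_distribution <- function(transition_matrix) {
  if (inherits(transition_matrix, "joint_posterior")) {
    if (is.null(transition_matrix$transition))
      stop("posterior has no transition matrix (change-point structure?)")
    transition_matrix <- transition_matrix$transition$transition_matrix
  }
  P <- as.matrix(transition_matrix)
  if (!all(dim(P) == c(2, 2)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition_matrix must be a row-stochastic 2x2 matrix")
  denom <- P[1, 2] + P[2, 1]
  if (denom < 1e-12)
    stop("no unique stationary distribution (reducible chain)")
  stats::setNames(c(P[2, 1], P[1, 2]) / denom, c("state1", "state2"))
}

#' Proportion of examinees in the erratic state by item position
#'
#' The posterior mean of the erratic-state indicator, averaged over persons,
#' at each serial item position: the curve that shows when during the test
#' erratic responding sets in.
#'
#' @param posterior a `joint_posterior`.
#' @return data.frame with `position`, `prop_erratic`, and Monte Carlo
#'   central 95% interval columns `q025`, `q975`.
#' @export
occupancy_curve <- function(posterior) {
  stopifnot(inherits(posterior, "joint_posterior"))
  occ <- .combine_draws(posterior$chains, "occupancy")
  data.frame(position = seq_len(ncol(occ)),
             prop_erratic = colMeans(occ),
             q025 = apply(occ, 2, stats::quantile, .025),
             q975 = apply(occ, 2, stats::quantile, .975))
}

.split_chains <- function(draws_list) {
  # split each chain's draw vector in half -> 2m sequences (split-Rhat)
  out <- list()
  for (v in draws_list) {
    n <- length(v)
    h <- n %/% 2L
    out[[length(out) + 1L]] <- v[seq_len(h)]
    out[[length(out) + 1L]] <- v[h + seq_len(h)]
  }
  out
}

.rhat <- function(draws_list) {
  sp <- .split_chains(draws_list)
  m <- length(sp); n <- length(sp[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(sp, mean, 0)
  vars <- vapply(sp, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess <- function(draws_list, max_lag = 100) {
  m <- length(draws_list); n <- length(draws_list[[1]])
  W <- mean(vapply(draws_list, stats::var, 0))
  if (W <= 0) return(NA_real_)
  max_lag <- min(max_lag, n - 2L)
  rho <- rep(0, max_lag)
  for (ch in draws_list) {
    a <- stats::acf(ch, lag.max = max_lag, plot = FALSE)$acf[-1]
    rho <- rho + a / m
  }
  s <- 0
  for (t in seq(1, max_lag - 1, by = 2)) {
    pair <- rho[t] + rho[t + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  m * n / (1 + 2 * s)
}

#' Convergence diagnostics for MCMC chains
#'
#' Split-chain potential scale reduction (Rhat), effective sample size, and
#' lag-1 autocorrelation per parameter. Accepts either a `joint_posterior`
#' (diagnostics are computed for the residual variances, transition/initial
#' probabilities, time intensities, speeds, and construct-state item and
#' person parameters) or a plain list of chains, each a matrix with one
#' column per parameter (or a bare vector for a single parameter).
#'
#' @param chains a `joint_posterior` or list of chains of equal length. A
#'   single chain is accepted and handled by the split-chain fallback, with a
#'   warning.
#' @param max_lag maximum lag used in the autocorrelation/ESS computation.
#' @return data.frame with `param`, `rhat`, `ess`, `lag1_acf`.
#' @export
convergence_diagnostics <- function(chains, max_lag = 100) {
  if (inherits(chains, "joint_posterior")) {
    post <- chains
    grab <- function(what, prefix) {
      mats <- lapply(post$chains, `[[`, what)
      if (is.null(mats[[1]])) return(NULL)
      cols <- ncol(mats[[1]])
      stats::setNames(lapply(seq_len(cols), function(i) lapply(mats, function(m) m[, i])),
                      paste0(prefix, seq_len(cols)))
    }
    sets <- c(grab("sigma2", "sigma2_"), grab("trans", "trans_"),
              grab("initp", "initp_"), grab("gamma", "gamma_"),
              grab("tau", "tau_"), grab("beta1", "beta1_"),
              grab("theta1", "theta1_"))
    chains <- sets
  } else {
    if (is.matrix(chains) || is.numeric(chains)) chains <- list(chains)
    chains <- lapply(chains, function(ch) if (is.null(dim(ch))) matrix(ch) else ch)
    if (length(chains) == 1L)
      warning("single chain supplied; using split-chain fallback")
    if (length(unique(vapply(chains, nrow, 0L))) != 1L)
      stop("chains must have equal length")
    cols <- ncol(chains[[1]])
    nm <- colnames(chains[[1]]) %||% paste0("param_", seq_len(cols))
    chains <- stats::setNames(
      lapply(seq_len(cols), function(i) lapply(chains, function(m) m[, i])), nm)
  }
  do.call(rbind, lapply(names(chains), function(nm) {
    dl <- chains[[nm]]
    data.frame(param = nm, rhat = .rhat(dl), ess = .ess(dl, max_lag),
               lag1_acf = mean(vapply(dl, function(v)
                 stats::acf(v, lag.max = 1, plot = FALSE)$acf[2], 0)),
               row.names = NULL)
  }))
}

#' Characterize the two response states of a fitted joint model
#'
#' Reports, per state, the EAP residual variance and the empirical proportion
#' of correct responses over the cells classified into that state, and flags
#' which state looks disengaged (high residual variance AND low accuracy).
#' A large residual variance alone does not imply disengagement: if the
#' high-variance state shows *higher* accuracy (e.g., examinees engaged only
#' for the first few, slow items, then guessing for the rest), the function
#' attaches an alternative-interpretation warning instead of the flag.
#' States whose residual variances differ by less than `distinct_ratio` are
#' reported as indistinct.
#'
#' @param posterior a `joint_posterior`.
#' @param dataset the [test_dataset()] the model was fitted to.
#' @param distinct_ratio minimum `sigma2_2 / sigma2_1` for the states to count
#'   as distinct.
#' @return object of class `state_report`: `table` (per-state data.frame),
#'   `disengaged_state` (2, or `NA` if none), `notes` (character).
#' @export
characterize_states <- function(posterior, dataset, distinct_ratio = 2) {
  stopifnot(inherits(posterior, "joint_posterior"))
  st <- modal_states(posterior)
  X <- dataset$responses
  tab <- do.call(rbind, lapply(1:2, function(s) {
    cells <- st == s & !is.na(X)
    data.frame(state = s,
               label = c("construct-driven", "erratic")[s],
               sigma2 = unname(posterior$sigma2[s]),
               prop_correct = if (any(cells)) mean(X[cells]) else NA_real_,
               n_cells = sum(cells))
  }))
  notes <- character(0)
  disengaged <- NA_integer_
  ratio <- tab$sigma2[2] / tab$sigma2[1]
  if (posterior$structure == "cp-speed" || !is.finite(ratio) || ratio < distinct_ratio) {
    notes <- c(notes, "states indistinct: residual variances do not separate the states")
  } else if (is.na(tab$prop_correct[2]) || tab$n_cells[2] == 0) {
    notes <- c(notes, "no cells classified erratic; single-state data")
  } else if (tab$prop_correct[2] < tab$prop_correct[1]) {
    disengaged <- 2L
  } else {
    notes <- c(notes, paste(
      "alternative interpretation: the high-residual-variance state has the",
      "HIGHER accuracy, so it may reflect engaged (e.g., early, slow) responding",
      "rather than disengagement; inspect the accuracy parameters"))
  }
  structure(list(table = tab, disengaged_state = disengaged, notes = notes),
            class = "state_report")
}

#' @export
print.state_report <- function(x, ...) {
  cat("<state_report>\n")
  print(x$table, digits = 3)
  if (!is.na(x$disengaged_state))
    cat(sprintf("  state %d flagged disengaged (high variance, low accuracy)\n",
                x$disengaged_state))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
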