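#' Rasch item-response probability
#'
#' Probability of a correct response under the one-parameter logistic model:
#' `plogis(theta - beta)`. For example, a person one logit above an item's
#' difficulty solves it with probability 0.731; at `theta = beta` the
#' probability is exactly one half.
#'
#' @param theta trait level(s).
#' @param beta item difficulty(ies).
#' @return probability in (0, 1); vectorized with the usual recycling.
#' @export
rasch_probability <- function(theta, beta) {
  if (!all(is.finite(theta)) || !all(is.finite(beta)))
    stop("rasch_probability requires finite theta and beta")
  stats::plogis(theta - beta)
}

#' Elementary symmetric functions of item easiness parameters
#'
#' Computes `gamma_r` for r = 0..n, where `gamma_r` is the sum over all
#' r-subsets of items of the product of their easiness values
#' `eps_i = exp(-beta_i)`. These are the normalizing constants of the Rasch
#' conditional likelihood given raw scores. Uses the stable summation
#' recursion (coefficients of `prod_i (1 + eps_i x)`).
#'
#' @param epsilons positive easiness values.
#' @return numeric vector of length `length(epsilons) + 1`, starting at
#'   `gamma_0 = 1`.
#' @export
elementary_symmetric <- function(epsilons) {
  if (length(epsilons) == 0L) return(1)
  if (!all(is.finite(epsilons)) || any(epsilons <= 0))
    stop("epsilons must be finite and > 0")
  g <- c(1, rep(0, length(epsilons)))
  for (i in seq_along(epsilons)) {
    r <- seq_len(i) + 1L
    g[r] <- g[r] + epsilons[i] * g[r - 1L]
  }
  g
}

# gamma_r^{(i)}: esf with item i removed, by deflation of the full table.
# Returns matrix (n_items x (n)) with [i, r+1] = gamma_r^{(i)}, r = 0..n-1.
esf_deflate <- function(epsilons, g = elementary_symmetric(epsilons)) {
  n <- length(epsilons)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    gi <- numeric(n)
    gi[1] <- 1
    for (r in seq_len(n - 1L))
      gi[r + 1L] <- g[r + 1L] - epsilons[i] * gi[r]
    out[i, ] <- gi
  }
  out
}

# Conditional log-likelihood and gradient for (possibly weighted) Rasch CML.
# Persons are grouped by missingness pattern; `patterns` is a list of
# list(items = integer index vector, counts = weighted score counts n_r for
# r = 0..length(items), margins = weighted item totals over the pattern).
.cml_nll <- function(beta, patterns, item_margins) {
  nll <- sum(item_margins * beta)
  for (p in patterns) {
    eps <- exp(-beta[p$items])
    g <- elementary_symmetric(eps)
    nz <- which(p$counts > 0)
    nll <- nll + sum(p$counts[nz] * log(g[nz]))
  }
  nll
}

.cml_grad <- function(beta, patterns, item_margins) {
  gr <- item_margins
  for (p in patterns) {
    eps <- exp(-beta[p$items])
    g <- elementary_symmetric(eps)
    defl <- esf_deflate(eps, g)
    n <- length(p$items)
    # expected score of item i given raw score r: eps_i * gamma_{r-1}^{(i)} / gamma_r
    for (r in seq_len(n)) {
      if (p$counts[r + 1L] == 0) next
      pir <- eps * defl[, r] / g[r + 1L]
      gr[p$items] <- gr[p$items] - p$counts[r + 1L] * pir
    }
  }
  # gradient of the *negative* conditional log-likelihood
  gr
}

.build_patterns <- function(X, weights = NULL) {
  J <- nrow(X)
  if (is.null(weights)) weights <- rep(1, J)
  obs <- !is.na(X)
  key <- apply(obs, 1L, function(z) paste(which(z), collapse = ","))
  patterns <- list()
  item_margins <- rep(0, ncol(X))
  for (k in unique(key)) {
    rows <- which(key == k)
    items <- which(obs[rows[1L], ])
    if (!length(items)) next
    sub <- X[rows, items, drop = FALSE]
    r <- rowSums(sub)
    counts <- vapply(0:length(items), function(s) sum(weights[rows][r == s]), 0)
    item_margins[items] <- item_margins[items] +
      colSums(sub * weights[rows])
    patterns[[length(patterns) + 1L]] <- list(items = items, counts = counts)
  }
  list(patterns = patterns, item_margins = item_margins)
}

# Weighted CML optimizer; the last item is anchored at 0 during optimization
# (the conditional likelihood depends only on difficulty differences) and the
# solution is centered to mean 0 afterwards.
.cml_optimize <- function(X, weights = NULL, start = NULL, reltol = 1e-12) {
  I <- ncol(X)
  st <- .build_patterns(X, weights)
  free2full <- function(b) c(b, 0)
  # beyond |beta| = 25 the likelihood is evaluated at the clamped value plus
  # a smooth quadratic penalty: exp(-beta) stays finite if a weighted
  # subsample is nearly separated for some item, and the optimum of the
  # penalized objective coincides with the CML optimum whenever it is interior
  fn <- function(b) {
    beta <- free2full(b)
    excess <- pmax(abs(beta) - 25, 0)
    .cml_nll(pmin(pmax(beta, -25), 25), st$patterns, st$item_margins) +
      1e4 * sum(excess^2)
  }
  gr <- function(b) {
    beta <- free2full(b)
    excess <- pmax(abs(beta) - 25, 0)
    g <- .cml_grad(pmin(pmax(beta, -25), 25), st$patterns, st$item_margins) +
      2e4 * excess * sign(beta)
    g[-I]
  }
  b0 <- if (is.null(start)) rep(0, I - 1L) else (start - start[I])[-I]
  opt <- stats::optim(b0, fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = reltol))
  # polish until successive solutions agree to 1e-6 in every coordinate
  for (k in 1:5) {
    opt2 <- stats::optim(opt$par, fn, gr, method = "BFGS",
                         control = list(maxit = 200, reltol = reltol))
    delta <- max(abs(opt2$par - opt$par))
    opt <- opt2
    if (delta < 1e-6) break
  }
  beta <- free2full(opt$par)
  beta <- beta - mean(beta)
  list(difficulties = beta, cond_loglik = -opt$value)
}

#' Fit the Rasch model by conditional maximum likelihood
#'
#' Item difficulties are estimated by maximizing the likelihood conditional on
#' each person's raw score, which removes the person parameters (specific
#' objectivity) and requires no assumption on the trait distribution.
#' Difficulties are centered to mean zero. Persons with extreme raw scores
#' (0 or all observed items correct) carry no conditional information and are
#' ignored by the estimator.
#'
#' @param responses person x item matrix in \{0,1,NA\}, or a [test_dataset()].
#' @return object of class `rasch_cml`: `difficulties` (mean-zero),
#'   `cond_loglik`, `n_persons_used`, `constraint_applied = TRUE`.
#' @export
fit_rasch_cml <- function(responses) {
  if (inherits(responses, "test_dataset")) responses <- responses$responses
  X <- as.matrix(responses)
  I <- ncol(X)
  if (I < 2L) stop("need at least 2 items")
  obs <- !is.na(X)
  nobs <- rowSums(obs)
  r <- rowSums(X, na.rm = TRUE)
  keep <- nobs > 0 & r > 0 & r < nobs       # non-extreme persons
  if (!any(keep)) stop("no persons with non-extreme raw scores; cannot estimate")
  Xk <- X[keep, , drop = FALSE]
  ncorr <- colSums(Xk == 1, na.rm = TRUE)
  nincorr <- colSums(Xk == 0, na.rm = TRUE)
  sep <- which(ncorr == 0 | nincorr == 0)
  if (length(sep)) {
    ids <- colnames(X) %||% as.character(seq_len(I))
    stop("perfectly separated item(s) among non-extreme persons: ",
         paste(ids[sep], collapse = ", "))
  }
  fit <- .cml_optimize(Xk)
  structure(list(difficulties = stats::setNames(fit$difficulties,
                                                colnames(X) %||% paste0("i", seq_len(I))),
                 cond_loglik = fit$cond_loglik,
                 n_persons_used = sum(keep),
                 constraint_applied = TRUE),
            class = "rasch_cml")
}

#' @export
print.rasch_cml <- function(x, ...) {
  cat(sprintf("<rasch_cml> %d items, conditional logLik %.3f (%d persons)\n",
              length(x$difficulties), x$cond_loglik, x$n_persons_used))
  invisible(x)
}

#' Person ability estimates given fixed item difficulties
#'
#' Warm's weighted likelihood estimator (`method = "wle"`, the default)
#' corrects the first-order bias of the ML estimator and remains finite at
#' extreme raw scores. `method = "ml"` solves the plain likelihood equation,
#' with extreme scores moved 0.3 score points inward so the estimate exists.
#'
#' @param responses person x item matrix in \{0,1,NA\}.
#' @param difficulties item difficulty vector (or `rasch_cml` object).
#' @param method `"wle"` or `"ml"`.
#' @return data.frame with `theta`, `se`, `raw_score`, `n_observed`.
#' @export
rasch_abilities <- function(responses, difficulties, method = c("wle", "ml")) {
  method <- match.arg(method)
  if (inherits(difficulties, "rasch_cml")) difficulties <- difficulties$difficulties
  X <- as.matrix(responses)
  out <- data.frame(theta = rep(NA_real_, nrow(X)), se = NA_real_,
                    raw_score = NA_real_, n_observed = NA_integer_)
  for (j in seq_len(nrow(X))) {
    items <- which(!is.na(X[j, ]))
    out$n_observed[j] <- length(items)
    if (!length(items)) next
    b <- difficulties[items]
    r <- sum(X[j, items])
    out$raw_score[j] <- r
    est <- .theta_solve(r, b, method)
    out$theta[j] <- est$theta
    out$se[j] <- est$se
  }
  out
}

.theta_solve <- function(r, b, method) {
  n <- length(b)
  if (method == "ml") {
    r_adj <- if (r <= 0) 0.3 else if (r >= n) n - 0.3 else r
    f <- function(th) sum(stats::plogis(th - b)) - r_adj
  } else {
    f <- function(th) {
      p <- stats::plogis(th - b)
      info <- sum(p * (1 - p))
      jj <- sum(p * (1 - p) * (1 - 2 * p))
      (r - sum(p)) + jj / (2 * info)
    }
  }
  lo <- -12; hi <- 12
  if (f(lo) * f(hi) > 0) {           # fall back to the boundary with smaller |f|
    th <- if (abs(f(lo)) < abs(f(hi))) lo else hi
  } else th <- stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  p <- stats::plogis(th - b)
  list(theta = th, se = 1 / sqrt(sum(p * (1 - p))))
}

# Standardized person log-likelihood fit index (Drasgow's l_z): the person's
# response log-likelihood Z-scored against its model-implied mean and variance.
person_fit_lz <- function(x, theta, beta) {
  ok <- !is.na(x)
  x <- x[ok]; beta <- beta[ok]
  p <- stats::plogis(theta - beta)
  l <- sum(x * log(p) + (1 - x) * log1p(-p))
  el <- sum(p * log(p) + (1 - p) * log1p(-p))
  vl <- sum(p * (1 - p) * (log(p / (1 - p)))^2)
  if (vl <= 0) return(NA_real_)
  (l - el) / sqrt(vl)
}
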