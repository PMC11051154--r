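#' Fit a mixture Rasch model by EM
#'
#' Latent classes of examinees differ in their item-difficulty vectors
#' `beta_ig` (mean zero within class) while sharing the Rasch response
#' function. Within each class the responses enter through the conditional
#' likelihood given raw scores, multiplied by a class-specific raw-score
#' distribution smoothed by a two-parameter (location/dispersion) log-linear
#' model. The free parameter count is therefore
#' `G*(n_items - 1) + (G - 1) + 2*G`, i.e., 32 additional parameters per
#' added class for a 30-item test.
#'
#' EM is restarted from `n_starts` random soft partitions (symmetric
#' Dirichlet); the best solution by log-likelihood is retained, with classes
#' relabelled in order of decreasing weight. With `n_classes = 1` the
#' difficulty estimates coincide with [fit_rasch_cml()].
#'
#' @param dataset a [test_dataset()] or a person x item 0/1 matrix.
#' @param n_classes number of latent classes G >= 1.
#' @param n_starts number of random EM starts.
#' @param seed integer seed for the random starts.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param ability_method passed to [rasch_abilities()].
#' @param likelihood `"cml"` (the default: within-class conditional
#'   likelihood with the two-parameter score distribution) or `"mml"`
#'   (marginal maximum likelihood with a class-specific normal ability
#'   distribution, integrated by Gauss-Hermite quadrature). Both have the
#'   same free-parameter count per class (I - 1 difficulties plus two
#'   ability-distribution/score-distribution parameters).
#' @return object of class `mixture_rasch` with elements `n_classes`,
#'   `class_weights`, `difficulties_by_class` (G x items), `memberships`
#'   (persons x G, rows sum to 1), `hard_assignments`, `abilities` (data.frame
#'   with `theta`, `se`, `class`), `minus2_loglik`, `n_params`, `aic`,
#'   `person_fit` (standardized log-likelihood index), `loglik_trace`,
#'   `score_params`, `n_starts_degenerate`.
#' @export
fit_mixture_rasch <- function(dataset, n_classes, n_starts = 20, seed = NULL,
                              max_iter = 300, tol = 1e-8,
                              ability_method = "wle",
                              likelihood = c("cml", "mml")) {
  likelihood <- match.arg(likelihood)
  X <- if (inherits(dataset, "test_dataset")) dataset$responses else as.matrix(dataset)
  J <- nrow(X); I <- ncol(X)
  G <- as.integer(n_classes)
  if (G < 1L) stop("n_classes must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  groups <- .pattern_groups(X)
  best <- NULL
  n_degenerate <- 0L
  for (s in seq_len(n_starts)) {
    W0 <- matrix(stats::rgamma(J * G, 1), J, G)
    W0 <- W0 / rowSums(W0)
    res <- try(.mixture_em(X, G, W0, groups, max_iter, tol, likelihood),
               silent = TRUE)
    if (inherits(res, "try-error") || res$degenerate) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best))
    stop("all ", n_starts, " EM starts degenerated (a class weight collapsed to 0)")

  ord <- order(best$pi, decreasing = TRUE)
  pi <- best$pi[ord]
  beta <- best$beta[ord, , drop = FALSE]
  W <- best$W[, ord, drop = FALSE]
  phi <- best$phi[ord, , drop = FALSE]
  hard <- max.col(W, ties.method = "first")
  small <- which(tabulate(hard, G) < 10)
  if (length(small))
    warning("class(es) ", paste(small, collapse = ", "),
            " have fewer than 10 assigned persons")

  colnames(beta) <- colnames(X) %||% paste0("i", seq_len(I))
  abil <- data.frame(theta = NA_real_, se = NA_real_, class = hard)
  pfit <- rep(NA_real_, J)
  for (g in seq_len(G)) {
    rows <- which(hard == g)
    if (!length(rows)) next
    a <- rasch_abilities(X[rows, , drop = FALSE], beta[g, ], method = ability_method)
    abil$theta[rows] <- a$theta
    abil$se[rows] <- a$se
    for (j in rows) pfit[j] <- person_fit_lz(X[j, ], abil$theta[j], beta[g, ])
  }

  n_params <- G * (I - 1L) + (G - 1L) + 2L * G
  m2ll <- -2 * best$loglik
  structure(list(
    n_classes = G, class_weights = pi, difficulties_by_class = beta,
    memberships = W, hard_assignments = hard, abilities = abil,
    minus2_loglik = m2ll, n_params = n_params, aic = m2ll + 2 * n_params,
    person_fit = pfit, loglik_trace = best$trace, score_params = phi,
    n_starts_degenerate = n_degenerate), class = "mixture_rasch")
}

#' @export
print.mixture_rasch <- function(x, ...) {
  cat(sprintf("<mixture_rasch> G = %d; -2lnL = %.2f; %d parameters; AIC = %.2f\n",
              x$n_classes, x$minus2_loglik, x$n_params, x$aic))
  cat("  class weights:", paste(sprintf("%.3f", x$class_weights), collapse = ", "), "\n")
  invisible(x)
}

# persons grouped by identical missingness pattern (items observed).
.pattern_groups <- function(X) {
  obs <- !is.na(X)
  key <- apply(obs, 1L, function(z) paste(which(z), collapse = ","))
  lapply(unique(key), function(k) {
    rows <- which(key == k)
    items <- which(obs[rows[1L], ])
    list(rows = rows, items = items,
         r = rowSums(X[rows, items, drop = FALSE]))
  })
}

# log score-distribution over r = 0..n under the 2-parameter log-linear model
.log_score_dist <- function(phi, n) {
  z <- ((0:n) - n / 2) / sqrt(n)
  lp <- phi[1] * z + phi[2] * z^2
  lp - log(sum(exp(lp - max(lp)))) - max(lp)
}

.fit_score_dist <- function(counts, n, start = c(0, 0)) {
  z <- ((0:n) - n / 2) / sqrt(n)
  tot <- sum(counts)
  if (tot <= 0) return(start)
  fn <- function(phi) {
    lp <- .log_score_dist(phi, n)
    -sum(counts * lp)
  }
  gr <- function(phi) {
    lp <- .log_score_dist(phi, n)
    p <- exp(lp)
    c(-sum(counts * z) + tot * sum(p * z),
      -sum(counts * z^2) + tot * sum(p * z^2))
  }
  stats::optim(start, fn, gr, method = "BFGS")$par
}

# per-person per-class log density under the conditional-likelihood mixture
.mixture_logf <- function(X, beta, phi, groups) {
  J <- nrow(X); G <- nrow(beta)
  logf <- matrix(NA_real_, J, G)
  for (grp in groups) {
    S <- grp$items; n <- length(S)
    Xs <- X[grp$rows, S, drop = FALSE]
    for (g in seq_len(G)) {
      eps <- exp(-beta[g, S])
      lg <- log(elementary_symmetric(eps))
      lsc <- .log_score_dist(phi[g, ], n)
      logf[grp$rows, g] <- -(Xs %*% beta[g, S]) - lg[grp$r + 1L] + lsc[grp$r + 1L]
    }
  }
  logf
}

.mixture_em <- function(X, G, W, groups, max_iter, tol, likelihood = "cml") {
  J <- nrow(X); I <- ncol(X)
  beta <- matrix(0, G, I)
  # under CML, phi holds the score-distribution parameters; under MML, the
  # class ability mean and log-SD
  phi <- matrix(0, G, 2)
  trace <- numeric(0)
  ll_old <- -Inf
  pi <- colMeans(W)
  for (iter in seq_len(max_iter)) {
    # M-step
    for (g in seq_len(G)) {
      if (likelihood == "cml") {
        fit <- .cml_optimize(X, weights = W[, g], start = beta[g, ])
        beta[g, ] <- fit$difficulties
        for (grp in groups) {
          n <- length(grp$items)
          counts <- vapply(0:n, function(s) sum(W[grp$rows, g][grp$r == s]), 0)
          phi[g, ] <- .fit_score_dist(counts, n, phi[g, ])
        }
      } else {
        upd <- .mml_mstep(X, W[, g], beta[g, ], phi[g, ])
        beta[g, ] <- upd$beta
        phi[g, ] <- upd$phi
      }
    }
    pi <- colMeans(W)
    if (any(pi < 1e-5))
      return(list(degenerate = TRUE))
    # E-step
    logf <- if (likelihood == "cml") .mixture_logf(X, beta, phi, groups)
            else .mml_logf(X, beta, phi)
    lw <- sweep(logf, 2, log(pi), `+`)
    mx <- apply(lw, 1, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    ll <- sum(lse)
    W <- exp(lw - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(degenerate = FALSE, loglik = ll, pi = colMeans(W), beta = beta,
       phi = phi, W = W, trace = trace)
}

# marginal log density of each person's pattern under a class with
# difficulties beta and ability ~ N(mu, sd), by Gauss-Hermite quadrature
.mml_logf_one <- function(X, beta, mu, sd, nodes = 31) {
  gh <- pracma::gaussHermite(nodes)
  th <- mu + sqrt(2) * sd * gh$x
  w <- gh$w / sqrt(pi)
  P <- stats::plogis(outer(th, beta, `-`))   # nodes x items
  obs <- !is.na(X)
  X0 <- ifelse(obs, X, 0)
  # persons x nodes pattern log-likelihoods, missing items contributing 0
  ll <- X0 %*% t(log(P)) + ((1 - X0) * obs) %*% t(log(1 - P))
  m <- apply(ll, 1L, max)
  m + log(exp(ll - m) %*% w)[, 1L]
}

.mml_logf <- function(X, beta, phi) {
  G <- nrow(beta)
  sapply(seq_len(G), function(g)
    .mml_logf_one(X, beta[g, ], phi[g, 1], exp(phi[g, 2])))
}

# generalized M-step for one class: a few quasi-Newton steps on the weighted
# marginal log-likelihood over (anchored difficulties, mu, log sd)
.mml_mstep <- function(X, w, beta, phi) {
  I <- length(beta)
  # anchoring the last difficulty at 0 shifts the ability scale with it
  par0 <- c((beta - beta[I])[-I], phi - c(beta[I], 0))
  fn <- function(par) {
    b <- c(par[seq_len(I - 1L)], 0)
    b <- pmin(pmax(b, -25), 25)
    -sum(w * .mml_logf_one(X, b, par[I], exp(min(par[I + 1L], 3))))
  }
  opt <- stats::optim(par0, fn, method = "BFGS",
                      control = list(maxit = 8, reltol = 1e-8))
  b <- c(opt$par[seq_len(I - 1L)], 0)
  # centering the anchored difficulties shifts the ability scale with them
  list(beta = b - mean(b), phi = opt$par[I:(I + 1L)] - c(mean(b), 0))
}

#' Likelihood-ratio comparison of nested mixture Rasch fits
#'
#' The statistic is the difference in `-2 lnL` between the smaller and larger
#' model, referred to a chi-square distribution with `df` equal to the
#' difference in free parameter counts. The p-value carries an `approximate`
#' caveat flag: the regularity conditions for the chi-square reference fail on
#' the boundary of a mixture (testing G vs G+1 classes), so the p-value is a
#' conventional approximation, not an exact test.
#'
#' @param fit_small,fit_large `mixture_rasch` fits of the same data with
#'   `fit_small$n_classes < fit_large$n_classes`.
#' @return list with `statistic`, `df`, `p_value`, `approximate = TRUE`.
#' @export
likelihood_ratio_test <- function(fit_small, fit_large) {
  if (fit_small$n_classes >= fit_large$n_classes)
    stop("fit_small must have fewer classes than fit_large")
  stat <- fit_small$minus2_loglik - fit_large$minus2_loglik
  if (stat < -1e-8)
    stop("negative LR statistic: fits are not nested or not converged")
  stat <- max(stat, 0)
  df <- fit_large$n_params - fit_small$n_params
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       approximate = TRUE)
}

#' Profile latent classes on persons, items, and cognitive covariates
#'
#' Produces the descriptive account of a mixture solution: per-class trait
#' and response-time summaries, within-class correlations of trait with mean
#' log RT and with the external criterion, and item-level regressions of
#' (a) class-specific item difficulty and (b) within-class item mean log RT
#' on the cognitive-complexity covariates (memory load, unique elements),
#' then with serial position added, reporting standardized coefficients,
#' multiple R, and the R-change F test for position.
#'
#' @param fit a `mixture_rasch` object.
#' @param dataset the [test_dataset()] it was fitted to; must carry
#'   `item_covariates` (`memory_load`, `unique_elements`, `position`) and,
#'   for criterion correlations, a numeric person covariate.
#' @param criterion name of the person-covariate column to use as the external
#'   criterion; default: the first numeric column other than `person`.
#' @return object of class `class_profile`: `class_table`, `item_table`,
#'   `regressions` data.frames.
#' @export
profile_classes <- function(fit, dataset, criterion = NULL) {
  stopifnot(inherits(fit, "mixture_rasch"), inherits(dataset, "test_dataset"))
  icov <- dataset$item_covariates
  if (is.null(icov) || !all(c("memory_load", "unique_elements", "position") %in% names(icov)))
    stop("item covariates memory_load, unique_elements, position are required")
  crit <- NULL
  if (!is.null(dataset$person_covariates)) {
    pc <- dataset$person_covariates
    if (is.null(criterion)) {
      num <- names(pc)[vapply(pc, is.numeric, TRUE) & names(pc) != "person"]
      criterion <- if (length(num)) num[1L] else NULL
    }
    if (!is.null(criterion)) crit <- pc[[criterion]]
  }
  lnrt <- if (!is.null(dataset$response_times)) log_transform(dataset$response_times) else NULL
  G <- fit$n_classes
  hard <- fit$hard_assignments
  theta <- fit$abilities$theta
  mn_lnrt <- if (!is.null(lnrt)) rowMeans(lnrt, na.rm = TRUE) else rep(NA_real_, length(hard))

  safe_cor <- function(a, b) {
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
    stats::cor(a[ok], b[ok])
  }
  class_table <- do.call(rbind, lapply(seq_len(G), function(g) {
    rows <- which(hard == g)
    data.frame(class = g, n = length(rows), weight = fit$class_weights[g],
               trait_mean = mean(theta[rows], na.rm = TRUE),
               trait_sd = stats::sd(theta[rows]),
               mean_lnrt = mean(mn_lnrt[rows], na.rm = TRUE),
               criterion_mean = if (is.null(crit)) NA_real_ else mean(crit[rows], na.rm = TRUE),
               criterion_sd = if (is.null(crit)) NA_real_ else stats::sd(crit[rows]),
               r_trait_lnrt = safe_cor(theta[rows], mn_lnrt[rows]),
               r_trait_criterion = if (is.null(crit)) NA_real_ else safe_cor(theta[rows], crit[rows]))
  }))

  item_table <- do.call(rbind, lapply(seq_len(G), function(g) {
    rows <- which(hard == g)
    ilnrt <- if (!is.null(lnrt) && length(rows))
      colMeans(lnrt[rows, , drop = FALSE], na.rm = TRUE) else rep(NA_real_, ncol(fit$difficulties_by_class))
    data.frame(class = g, item = colnames(fit$difficulties_by_class),
               difficulty = fit$difficulties_by_class[g, ],
               mean_lnrt = ilnrt,
               row.names = NULL)
  }))

  zz <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else rep(NA_real_, length(v))
  reg_one <- function(y, g, label) {
    d <- data.frame(y = zz(y), ml = zz(icov$memory_load),
                    ue = zz(icov$unique_elements), pos = zz(icov$position))
    if (anyNA(d$y) || all(is.na(d$ml)))
      return(data.frame(class = g, response = label, r_lnrt = NA, beta_memory_load = NA,
                        beta_unique_elements = NA, R = NA, R_position = NA,
                        F_change = NA, df1 = NA, df2 = NA, p_change = NA))
    m1 <- stats::lm(y ~ ml + ue, data = d)
    m2 <- stats::lm(y ~ ml + ue + pos, data = d)
    r2_1 <- summary(m1)$r.squared; r2_2 <- summary(m2)$r.squared
    an <- stats::anova(m1, m2)
    ilnrt <- item_table$mean_lnrt[item_table$class == g]
    data.frame(class = g, response = label,
               r_lnrt = safe_cor(y, ilnrt),
               beta_memory_load = unname(stats::coef(m1)["ml"]),
               beta_unique_elements = unname(stats::coef(m1)["ue"]),
               R = sqrt(r2_1), R_position = sqrt(r2_2),
               F_change = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
               p_change = an$`Pr(>F)`[2])
  }
  regressions <- do.call(rbind, lapply(seq_len(G), function(g) {
    rbind(reg_one(fit$difficulties_by_class[g, ], g, "difficulty"),
          reg_one(item_table$mean_lnrt[item_table$class == g], g, "mean_lnrt"))
  }))
  structure(list(class_table = class_table, item_table = item_table,
                 regressions = regressions, criterion = criterion),
            class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  cat("<class_profile>\n\nPer-class summaries:\n")
  print(x$class_table, digits = 3)
  cat("\nItem-covariate regressions (standardized):\n")
  print(x$regressions, digits = 3)
  invisible(x)
}
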