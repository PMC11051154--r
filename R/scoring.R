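#' Trim mask retaining construct-driven responses
#'
#' Converts a state classification (1 = construct-driven, 2 = erratic) into a
#' retain/discard mask: erratic responses are trimmed, i.e., treated as not
#' observed when rescoring. Persons left with no retained response are flagged
#' unscorable rather than dropped silently.
#'
#' @param states person x item matrix in \{1, 2\} (e.g., from
#'   [modal_states()]), or a `joint_posterior`.
#' @return object of class `trim_mask`: `retain` (logical matrix),
#'   `provenance`, `unscorable` (logical per person).
#' @export
mask_from_states <- function(states) {
  if (inherits(states, "joint_posterior")) states <- modal_states(states)
  states <- as.matrix(states)
  if (!all(states %in% c(1L, 2L))) stop("states must contain only 1 and 2")
  retain <- states == 1L
  new_trim_mask(retain, "state-based")
}

new_trim_mask <- function(retain, provenance) {
  unscorable <- rowSums(retain) == 0
  if (any(unscorable))
    warning(sum(unscorable), " person(s) have no retained responses (unscorable)")
  structure(list(retain = retain, provenance = provenance,
                 unscorable = unscorable), class = "trim_mask")
}

#' @export
print.trim_mask <- function(x, ...) {
  cat(sprintf("<trim_mask> %s: %d/%d cells retained; %d unscorable person(s)\n",
              x$provenance, sum(x$retain), length(x$retain), sum(x$unscorable)))
  invisible(x)
}

#' Trim mask from a response-time residual threshold
#'
#' Discards responses whose standardized RT residual falls below
#' `threshold_sd` (`side = "negative"`, targeting uncharacteristically fast
#' responses such as rapid guesses), or whose absolute standardized residual
#' exceeds `|threshold_sd|` (`side = "both"`, additionally targeting
#' uncharacteristically slow responses). Cells without an observed residual
#' are retained.
#'
#' @param residuals an `rt_residuals` object (see [rt_residuals()]).
#' @param threshold_sd threshold in residual SD units (negative for
#'   `side = "negative"`, e.g., -2.5).
#' @param side `"negative"` or `"both"`.
#' @return a `trim_mask`.
#' @export
mask_from_residual_threshold <- function(residuals, threshold_sd,
                                         side = c("negative", "both")) {
  side <- match.arg(side)
  z <- residuals$standardized
  discard <- if (side == "negative") !is.na(z) & z < threshold_sd
             else !is.na(z) & abs(z) > abs(threshold_sd)
  new_trim_mask(!discard, sprintf("residual-threshold(%s, %g SD)", side, threshold_sd))
}

#' EAP ability estimates with fixed item difficulties
#'
#' Expected a posteriori trait estimates under a normal prior, integrating the
#' Rasch likelihood over ability by Gauss-Hermite quadrature (61 nodes by
#' default). Item parameters are treated as fixed; a trim mask is applied as
#' induced missingness before scoring. Deterministic given its inputs, and
#' finite for every person including all-correct/all-incorrect patterns
#' (the prior supplies shrinkage).
#'
#' @param responses person x item 0/1 matrix (or [test_dataset()]).
#' @param difficulties item difficulty vector (or `rasch_cml` fit).
#' @param mask optional `trim_mask`; discarded cells are not scored.
#' @param prior_mean,prior_sd normal prior on ability (default standard
#'   normal).
#' @param nodes number of Gauss-Hermite quadrature nodes.
#' @return object of class `ability_estimates`, a data.frame with `eap`,
#'   `posterior_sd`, `n_items_used`, `unscorable`.
#' @export
eap_abilities <- function(responses, difficulties, mask = NULL,
                          prior_mean = 0, prior_sd = 1, nodes = 61) {
  if (inherits(responses, "test_dataset")) responses <- responses$responses
  if (inherits(difficulties, "rasch_cml")) difficulties <- difficulties$difficulties
  X <- as.matrix(responses)
  if (ncol(X) != length(difficulties)) stop("difficulty vector length mismatch")
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "trim_mask"))
    if (!all(dim(mask$retain) == dim(X))) stop("mask shape mismatch")
    X[!mask$retain] <- NA
  }
  gh <- pracma::gaussHermite(nodes)
  th <- prior_mean + sqrt(2) * prior_sd * gh$x     # nodes on the ability scale
  w <- gh$w / sqrt(pi)
  # log-likelihood of each response pattern at each node
  P <- stats::plogis(outer(th, difficulties, `-`))  # nodes x items
  out <- data.frame(eap = rep(NA_real_, nrow(X)), posterior_sd = NA_real_,
                    n_items_used = 0L, unscorable = FALSE)
  for (j in seq_len(nrow(X))) {
    items <- which(!is.na(X[j, ]))
    out$n_items_used[j] <- length(items)
    if (!length(items)) { out$unscorable[j] <- TRUE; next }
    x <- X[j, items]
    ll <- colSums(x * log(t(P[, items, drop = FALSE])) +
                  (1 - x) * log(1 - t(P[, items, drop = FALSE])))
    wl <- w * exp(ll - max(ll))
    wl <- wl / sum(wl)
    m <- sum(wl * th)
    v <- sum(wl * (th - m)^2)
    out$eap[j] <- m
    out$posterior_sd[j] <- sqrt(v)
  }
  class(out) <- c("ability_estimates", "data.frame")
  out
}

#' Empirical reliability of EAP ability estimates
#'
#' `var(EAP) / (var(EAP) + mean(posterior_sd^2))`: the proportion of observed
#' EAP variance attributable to true ability variance, with the average
#' posterior variance standing in for error variance. Used to disattenuate
#' validity coefficients for the (possibly reduced) post-trim test length.
#'
#' @param estimates an `ability_estimates` object (or data.frame with `eap`
#'   and `posterior_sd`).
#' @return reliability in (0, 1).
#' @export
empirical_reliability <- function(estimates) {
  ok <- !is.na(estimates$eap)
  if (sum(ok) < 2) stop("need at least 2 scored persons")
  v <- stats::var(estimates$eap[ok])
  if (v <= 0) stop("zero variance in EAP estimates; reliability undefined")
  v / (v + mean(estimates$posterior_sd[ok]^2))
}

#' Disattenuate a validity coefficient for score unreliability
#'
#' Single-variable correction for attenuation: `adjusted_r = raw_r /
#' sqrt(reliability)`. (Reconstructed procedure: the correction is applied to
#' the test-score side only, with the criterion treated as is.) Monotone
#' increasing in `raw_r` and decreasing in reliability; if `|raw_r|` exceeds
#' `sqrt(reliability)` the result is capped at +/-1 with a warning.
#'
#' @param raw_r observed correlation.
#' @param reliability reliability in (0, 1].
#' @return adjusted correlation.
#' @export
disattenuate <- function(raw_r, reliability) {
  if (!is.finite(reliability) || reliability <= 0)
    stop("reliability must be in (0, 1]")
  if (reliability > 1) stop("reliability cannot exceed 1")
  adj <- raw_r / sqrt(reliability)
  if (abs(adj) > 1) {
    warning("disattenuated correlation exceeds 1 in magnitude; capped")
    adj <- sign(adj)
  }
  adj
}

# shared machinery: EAP + validity summary for one mask
.validity_one <- function(X, difficulties, mask, criterion,
                          min_items = 3, prior_mean = 0, prior_sd = 1) {
  est <- eap_abilities(X, difficulties, mask, prior_mean, prior_sd)
  ok <- !is.na(est$eap) & est$n_items_used >= min_items & !is.na(criterion)
  n_excluded <- sum(!ok)
  raw_r <- stats::cor(est$eap[ok], criterion[ok])
  rel <- empirical_reliability(est[ok, , drop = FALSE])
  adj <- disattenuate(raw_r, rel)
  list(raw_r = raw_r, reliability = rel, adjusted_r = adj,
       variance_explained = adj^2, n = sum(ok), n_excluded = n_excluded,
       estimates = est)
}

#' Bootstrap test of the validity gain from a trim
#'
#' Observed statistic: disattenuated criterion correlation after the trim
#' minus the same quantity under the baseline (usually no-trim) mask. The
#' null distribution is built by re-trimming at random: in each replicate,
#' each person has the same *number* of responses discarded as under the
#' real trim, but the discarded cells are chosen uniformly at random among
#' that person's baseline-retained responses. The p-value is the proportion
#' of null gains at least as large as the observed gain. (Reconstructed
#' procedure; deterministic given `seed`.)
#'
#' @param dataset a [test_dataset()].
#' @param mask the trim under test (`trim_mask`).
#' @param baseline_mask baseline `trim_mask` (default: retain everything).
#' @param criterion numeric criterion vector, or the name of a person
#'   covariate column.
#' @param difficulties fixed item difficulties for rescoring; default: Rasch
#'   CML fit on the full responses.
#' @param n_boot number of bootstrap replicates (a warning is issued below
#'   100).
#' @param seed integer seed.
#' @return list with `observed_gain`, `p_value`, `null_gains`, `n_boot`.
#' @export
bootstrap_gain_test <- function(dataset, mask, baseline_mask = NULL,
                                criterion, difficulties = NULL,
                                n_boot = 1000, seed = 1) {
  stopifnot(inherits(dataset, "test_dataset"), inherits(mask, "trim_mask"))
  X <- dataset$responses
  if (is.character(criterion))
    criterion <- dataset$person_covariates[[criterion]]
  if (is.null(criterion) || anyNA(criterion))
    stop("criterion must be available for all persons")
  if (is.null(baseline_mask))
    baseline_mask <- new_trim_mask(!is.na(X), "none")
  if (is.null(difficulties)) difficulties <- fit_rasch_cml(X)
  if (inherits(difficulties, "rasch_cml")) difficulties <- difficulties$difficulties
  if (n_boot < 100) warning("n_boot < 100: p-value will be coarse")

  base <- .validity_one(X, difficulties, baseline_mask, criterion)
  obs <- .validity_one(X, difficulties, mask, criterion)
  observed_gain <- obs$adjusted_r - base$adjusted_r

  # per-person count of responses discarded relative to the baseline
  discarded <- baseline_mask$retain & !mask$retain & !is.na(X)
  n_disc <- rowSums(discarded)
  candidates <- lapply(seq_len(nrow(X)), function(j)
    which(baseline_mask$retain[j, ] & !is.na(X[j, ])))

  set.seed(seed)
  null_gains <- vapply(seq_len(n_boot), function(b) {
    retain <- baseline_mask$retain
    for (j in which(n_disc > 0)) {
      cand <- candidates[[j]]
      drop <- cand[sample.int(length(cand), min(n_disc[j], length(cand)))]
      retain[j, drop] <- FALSE
    }
    rmask <- suppressWarnings(new_trim_mask(retain, "bootstrap"))
    .validity_one(X, difficulties, rmask, criterion)$adjusted_r - base$adjusted_r
  }, 0)
  list(observed_gain = observed_gain,
       p_value = mean(null_gains >= observed_gain),
       null_gains = null_gains, n_boot = n_boot)
}

#' Validity table across trimming rules
#'
#' Recomputes the criterion-validity summary for the untrimmed data, for each
#' supplied fitted joint model (state-based trims, scored with that model's
#' construct-state difficulties), and for a ladder of negative-residual
#' threshold trims. Each row reports the raw correlation with the criterion,
#' the post-trim empirical reliability, the disattenuated correlation, and
#' the variance explained (`adjusted_r^2`, exactly).
#'
#' Residuals for the threshold trims come from the homoscedastic lognormal RT
#' fit; they are standardized by the construct-driven-state residual SD of
#' the `cp_residual` posterior when one is supplied (thresholds should
#' reference engaged behavior), else by the homoscedastic residual SD.
#'
#' @param dataset a [test_dataset()] with response times.
#' @param posteriors named list with any of `cp_residual`, `cp_speed`,
#'   `markov` (`joint_posterior` objects); may be empty.
#' @param criterion numeric vector or person-covariate column name.
#' @param thresholds negative-residual thresholds, in SD units.
#' @param min_items persons with fewer retained items are excluded from the
#'   correlations (reported in `n_excluded`).
#' @return object of class `validity_report`: data.frame with one row per
#'   trim rule.
#' @export
validity_table <- function(dataset, posteriors = list(), criterion = NULL,
                           thresholds = c(-6, -5, -3.5, -3, -2.5, -2, -1.5, -1, -0.5, 0),
                           min_items = 3) {
  stopifnot(inherits(dataset, "test_dataset"))
  X <- dataset$responses
  if (is.null(criterion)) {
    pc <- dataset$person_covariates
    num <- names(pc)[vapply(pc, is.numeric, TRUE) & names(pc) != "person"]
    if (!length(num)) stop("no numeric person covariate to use as criterion")
    criterion <- pc[[num[1]]]
  } else if (is.character(criterion) && length(criterion) == 1L) {
    criterion <- dataset$person_covariates[[criterion]]
  }

  cml <- fit_rasch_cml(X)
  no_trim <- new_trim_mask(!is.na(X), "none")
  rows <- list()
  add <- function(label, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      trim = label, raw_r = res$raw_r, reliability = res$reliability,
      adjusted_r = res$adjusted_r, variance_explained = res$variance_explained,
      n = res$n, n_excluded = res$n_excluded)
  }
  add("no_trim", .validity_one(X, cml, no_trim, criterion, min_items))

  post_beta1 <- function(post) {
    s <- post$summary
    b <- s$mean[grep("^beta1_", s$param)]
    b - mean(b)
  }
  labels <- c(cp_residual = "cp_residual", cp_speed = "cp_speed", markov = "markov")
  for (nm in intersect(names(labels), names(posteriors))) {
    post <- posteriors[[nm]]
    msk <- suppressWarnings(mask_from_states(post))
    msk$retain <- msk$retain & !is.na(X)
    add(labels[[nm]], .validity_one(X, post_beta1(post), msk, criterion, min_items))
  }

  rtfit <- fit_lognormal_rt(log_transform(dataset$response_times))
  if ("cp_residual" %in% names(posteriors))
    rtfit$state_variances <- unname(posteriors$cp_residual$sigma2)
  resid <- rt_residuals(log_transform(dataset$response_times), rtfit)
  for (thr in thresholds) {
    msk <- suppressWarnings(mask_from_residual_threshold(resid, thr, "negative"))
    add(sprintf("residual<%g SD", thr),
        .validity_one(X, cml, msk, criterion, min_items))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("validity_report", "data.frame")
  out
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report>\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}
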