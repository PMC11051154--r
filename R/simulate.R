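#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator, with defaults that
#' emulate a 301-examinee, 30-item multiple-choice reasoning test: abilities
#' and speeds drawn from normal distributions, item difficulties and time
#' intensities linked to cognitive-complexity covariates (memory load, unique
#' elements) plus noise, construct-driven log-RT residual SD around 0.43
#' (variance 0.187), an erratic state with ~9x inflated residual variance
#' (1.647) and near-chance accuracy, and a person-level criterion score
#' correlated with ability.
#'
#' @param n_persons,n_items dimensions.
#' @param ability_mean,ability_sd trait distribution.
#' @param difficulties optional fixed item difficulty vector (centered); if
#'   `NULL`, difficulties are built from the generated covariates plus noise.
#' @param class_weights,difficulties_by_class mixture structure for
#'   [simulate_mixture_rasch()]: class probabilities and a G x items matrix
#'   (or list of vectors).
#' @param tau_mean,tau_sd person speed distribution (log-seconds scale; the
#'   default 3.2 corresponds to ~25 s per item).
#' @param time_intensities optional fixed gamma vector (centered).
#' @param sigma2 ordered pair of residual variances (construct-driven,
#'   erratic).
#' @param rt_state_model `"residual"` (erratic state inflates the residual
#'   variance) or `"speed"` (erratic state shifts the person speed by
#'   `speed_shift` with a single residual variance).
#' @param speed_shift log-RT mean shift in the erratic state under the
#'   `"speed"` model (negative = faster, e.g., rapid guessing).
#' @param initial_probs,transition_matrix Markov state dynamics.
#' @param no_transition_prob,k_range change-point dynamics: with probability
#'   `no_transition_prob` a person never transitions (`k = n_items`),
#'   otherwise `k` is uniform on `k_range` (default: every examinee draws a
#'   change point uniformly from the last third of the test, `k = n_items`
#'   meaning no transition occurs).
#' @param structure `"markov"`, `"changepoint"`, or `"inversion"`: under
#'   inversion, a fraction of examinees engage items with a principled (slow,
#'   accurate) process for the first few items only and guess at a typical
#'   pace for the rest, while the remaining examinees guess throughout — the
#'   counter-example in which the high-residual-variance state is the
#'   *engaged* one.
#' @param inversion_items number of initial engaged items under
#'   `"inversion"`.
#' @param inversion_fraction fraction of examinees showing the engaged-early
#'   pattern.
#' @param inversion_shift log-RT elevation of the engaged early responses
#'   over the person's typical (guessing) pace.
#' @param erratic_accuracy fixed success probability in the erratic state
#'   (0.25 by default; 0.125 would be pure 8-option guessing).
#' @param criterion_cor,criterion_mean,criterion_sd criterion model: target
#'   correlation with ability and the reporting scale.
#' @param seed integer seed; generated data are bit-exact functions of
#'   (config, seed).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 301, n_items = 30,
                       ability_mean = 0, ability_sd = 1,
                       difficulties = NULL,
                       class_weights = NULL, difficulties_by_class = NULL,
                       tau_mean = 3.2, tau_sd = 0.45,
                       time_intensities = NULL,
                       sigma2 = c(0.187, 1.647),
                       rt_state_model = "residual",
                       speed_shift = -0.8,
                       initial_probs = c(0.948, 0.052),
                       transition_matrix = NULL,
                       no_transition_prob = 0, k_range = 21:30,
                       structure = "changepoint",
                       inversion_items = 3,
                       inversion_fraction = 0.25,
                       inversion_shift = 2.5,
                       erratic_accuracy = 0.25,
                       criterion_cor = 0.63,
                       criterion_mean = 215, criterion_sd = 16,
                       seed = 1) {
  if (is.list(transition_matrix))
    transition_matrix <- do.call(rbind, transition_matrix)
  if (is.null(transition_matrix))
    transition_matrix <- matrix(c(0.9907, 0.0093, 0.0216, 0.9784), 2, 2, byrow = TRUE)
  if (is.list(difficulties_by_class))
    difficulties_by_class <- do.call(rbind, difficulties_by_class)
  cfg <- list(n_persons = as.integer(n_persons), n_items = as.integer(n_items),
              ability_mean = as.numeric(ability_mean), ability_sd = as.numeric(ability_sd),
              difficulties = if (!is.null(difficulties)) as.numeric(difficulties),
              class_weights = if (!is.null(class_weights)) as.numeric(class_weights),
              difficulties_by_class = difficulties_by_class,
              tau_mean = as.numeric(tau_mean), tau_sd = as.numeric(tau_sd),
              time_intensities = if (!is.null(time_intensities)) as.numeric(time_intensities),
              sigma2 = as.numeric(sigma2),
              rt_state_model = match.arg(rt_state_model, c("residual", "speed")),
              speed_shift = as.numeric(speed_shift),
              initial_probs = as.numeric(initial_probs),
              transition_matrix = transition_matrix,
              no_transition_prob = as.numeric(no_transition_prob),
              k_range = as.integer(k_range),
              structure = match.arg(structure, c("changepoint", "markov", "inversion")),
              inversion_items = as.integer(inversion_items),
              inversion_fraction = as.numeric(inversion_fraction),
              inversion_shift = as.numeric(inversion_shift),
              erratic_accuracy = as.numeric(erratic_accuracy),
              criterion_cor = as.numeric(criterion_cor),
              criterion_mean = as.numeric(criterion_mean),
              criterion_sd = as.numeric(criterion_sd),
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_persons < 2 || n_items < 2) stop("need at least 2 persons and 2 items")
    if (length(sigma2) != 2 || any(sigma2 <= 0) || sigma2[1] >= sigma2[2])
      stop("sigma2 must be an increasing positive pair (sigma2_1 < sigma2_2)")
    if (any(initial_probs < 0) || abs(sum(initial_probs) - 1) > 1e-8)
      stop("initial_probs must be probabilities summing to 1")
    if (any(transition_matrix < 0) || any(abs(rowSums(transition_matrix) - 1) > 1e-8))
      stop("transition_matrix rows must be probabilities summing to 1")
    if (erratic_accuracy < 0 || erratic_accuracy > 1)
      stop("erratic_accuracy must be in [0, 1]")
    if (no_transition_prob < 0 || no_transition_prob > 1)
      stop("no_transition_prob must be in [0, 1]")
    if (abs(criterion_cor) > 1) stop("criterion_cor must be in [-1, 1]")
    if (!is.null(class_weights)) {
      if (abs(sum(class_weights) - 1) > 1e-8 || any(class_weights <= 0))
        stop("class_weights must be positive and sum to 1")
    }
  })
  invisible(cfg)
}

# item covariates and covariate-linked difficulties / time intensities
.sim_items <- function(cfg) {
  I <- cfg$n_items
  memory_load <- sample(1:3, I, replace = TRUE)
  unique_elements <- sample(4:9, I, replace = TRUE)
  beta <- cfg$difficulties
  if (is.null(beta)) {
    beta <- 0.7 * scale(memory_load)[, 1] + 0.35 * scale(unique_elements)[, 1] +
      stats::rnorm(I, 0, 0.5)
    beta <- beta - mean(beta)
  }
  gam <- cfg$time_intensities
  if (is.null(gam)) {
    gam <- -0.25 * scale(memory_load)[, 1] + stats::rnorm(I, 0, 0.15)
    gam <- gam - mean(gam)
  }
  list(covariates = data.frame(item = paste0("i", seq_len(I)),
                               memory_load = memory_load,
                               unique_elements = unique_elements,
                               position = seq_len(I)),
       beta = beta, gamma = gam)
}

.sim_criterion <- function(theta, cfg) {
  z <- (theta - mean(theta)) / stats::sd(theta)
  rho <- cfg$criterion_cor
  cz <- rho * z + sqrt(1 - rho^2) * stats::rnorm(length(theta))
  cfg$criterion_mean + cfg$criterion_sd * cz
}

#' Simulate responses from a mixture Rasch model
#'
#' Class labels are drawn from `class_weights`; each class has its own
#' difficulty vector and responses are Bernoulli under the Rasch model.
#' Response times are generated from the lognormal model (no erratic state)
#' so that class profiling has data to work with.
#'
#' @param config a [sim_config()]; `class_weights` and
#'   `difficulties_by_class` define the mixture (a single class with the
#'   shared difficulty vector is used when absent).
#' @return a list of class `sim_dataset`: `dataset` (a [test_dataset()]) and
#'   `truth` (`theta`, `class`, `difficulties_by_class`, `tau`, `gamma`).
#' @export
simulate_mixture_rasch <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  set.seed(cfg$seed)
  J <- cfg$n_persons; I <- cfg$n_items
  items <- .sim_items(cfg)
  if (is.null(cfg$class_weights)) {
    weights <- 1
    B <- matrix(items$beta, 1, I)
  } else {
    weights <- cfg$class_weights
    B <- cfg$difficulties_by_class
    if (is.null(B)) stop("difficulties_by_class required when class_weights given")
    if (ncol(B) != I) stop("difficulties_by_class must have n_items columns")
    B <- B - rowMeans(B)
  }
  cls <- sample.int(length(weights), J, replace = TRUE, prob = weights)
  theta <- stats::rnorm(J, cfg$ability_mean, cfg$ability_sd)
  P <- stats::plogis(theta - t(B[cls, , drop = FALSE]))  # I x J
  X <- matrix(as.numeric(stats::runif(I * J) < P), J, I, byrow = TRUE)
  tau <- stats::rnorm(J, cfg$tau_mean, cfg$tau_sd)
  lnRT <- outer(tau, items$gamma, `-`) +
    matrix(stats::rnorm(J * I, 0, sqrt(cfg$sigma2[1])), J, I)
  criterion <- .sim_criterion(theta, cfg)
  ds <- test_dataset(X, exp(lnRT),
                     person_covariates = data.frame(person = paste0("p", seq_len(J)),
                                                    criterion = criterion),
                     item_covariates = items$covariates)
  structure(list(dataset = ds,
                 truth = list(theta = theta, class = cls,
                              difficulties_by_class = B, weights = weights,
                              tau = tau, gamma = items$gamma),
                 config = cfg),
            class = "sim_dataset")
}

#' Simulate responses and response times with latent state dynamics
#'
#' States evolve by a lag-1 Markov chain, a per-person change point, or the
#' "inversion" counter-example (engaged, slow responding for the first few
#' items only). Construct-driven cells get Rasch accuracy and
#' `N(tau - gamma, sigma2_1)` log RTs; erratic cells get a fixed success
#' probability and either inflated residual variance (`rt_state_model =
#' "residual"`) or a shifted speed with common variance (`"speed"`). The
#' criterion score is generated at the person level with the configured
#' correlation with true ability.
#'
#' @param config a [sim_config()].
#' @return a `sim_dataset`: `dataset` plus `truth` (`theta`, `beta`, `tau`,
#'   `gamma`, `states` (1/2 matrix), `k` (when change-point), `sigma2`).
#' @export
simulate_joint <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  set.seed(cfg$seed)
  J <- cfg$n_persons; I <- cfg$n_items
  items <- .sim_items(cfg)
  theta <- stats::rnorm(J, cfg$ability_mean, cfg$ability_sd)
  tau <- stats::rnorm(J, cfg$tau_mean, cfg$tau_sd)

  k <- NULL
  if (cfg$structure == "markov") {
    states <- matrix(1L, J, I)
    for (j in seq_len(J)) {
      s <- 1L + (stats::runif(1) < cfg$initial_probs[2])
      states[j, 1] <- s
      for (i in 2:I) {
        s <- 1L + (stats::runif(1) < cfg$transition_matrix[s, 2])
        states[j, i] <- s
      }
    }
  } else if (cfg$structure == "changepoint") {
    k <- ifelse(stats::runif(J) < cfg$no_transition_prob, I,
                sample(cfg$k_range, J, replace = TRUE))
    states <- outer(k, seq_len(I), function(kk, i) ifelse(i <= kk, 1L, 2L))
  } else {  # inversion: some examinees engage (slowly) early, guess after
    engaged <- stats::runif(J) < cfg$inversion_fraction
    k <- ifelse(engaged, cfg$inversion_items, 0L)
    states <- outer(k, seq_len(I), function(kk, i) ifelse(i <= kk, 1L, 2L))
  }

  P1 <- stats::plogis(outer(theta, items$beta, `-`))
  pcorr <- ifelse(states == 1L, P1, cfg$erratic_accuracy)
  X <- matrix(as.numeric(matrix(stats::runif(J * I), J, I) < pcorr), J, I)

  mu <- outer(tau, items$gamma, `-`)
  if (cfg$structure == "inversion") {
    # engaged early items are protracted; everything else at typical speed
    mu <- mu + cfg$inversion_shift * (states == 1L)
    sdm <- matrix(sqrt(cfg$sigma2[1]), J, I)
  } else if (cfg$rt_state_model == "speed") {
    mu <- mu + cfg$speed_shift * (states == 2L)
    sdm <- matrix(sqrt(cfg$sigma2[1]), J, I)
  } else {
    sdm <- matrix(sqrt(cfg$sigma2[states]), J, I)
  }
  lnRT <- mu + matrix(stats::rnorm(J * I), J, I) * sdm
  criterion <- .sim_criterion(theta, cfg)
  ds <- test_dataset(X, exp(lnRT),
                     person_covariates = data.frame(person = paste0("p", seq_len(J)),
                                                    criterion = criterion),
                     item_covariates = items$covariates)
  structure(list(dataset = ds,
                 truth = list(theta = theta, beta = items$beta, tau = tau,
                              gamma = items$gamma, states = states, k = k,
                              sigma2 = cfg$sigma2),
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> generated with seed", x$config$seed, "\n")
  print(x$dataset)
  invisible(x)
}

#' Named library of simulation scenarios
#'
#' Presets covering the settings exercised throughout the package:
#' \describe{
#'   \item{paper_like_cp}{301 x 30, change points uniform over the last
#'     third of the test (k in 21..30; k = 30 means no transition), residual
#'     variances (0.187, 1.647), erratic accuracy .26.}
#'   \item{paper_like_markov}{Markov dynamics with initial state distribution
#'     (.948, .052) and a slow-mixing transition matrix whose stationary
#'     distribution is (.70, .30).}
#'   \item{two_class_mixture}{two equally weighted latent classes with
#'     opposed item-difficulty orderings.}
#'   \item{early_engagement_inversion}{engaged, slow responding for the first
#'     3 items only, then guessing at typical speed: the high-variance state
#'     is the engaged one.}
#'   \item{null_single_state}{no erratic state at all (transition probability
#'     zero).}
#' }
#'
#' @param name optional preset name; if omitted the full named list is
#'   returned.
#' @param seed seed stored in the returned config(s).
#' @return a `sim_config`, or a named list of them.
#' @export
scenario_library <- function(name = NULL, seed = 1) {
  I <- 30
  presets <- list(
    paper_like_cp = sim_config(
      structure = "changepoint", sigma2 = c(0.187, 1.647),
      erratic_accuracy = 0.26, no_transition_prob = 0, k_range = 21:30,
      seed = seed),
    paper_like_markov = sim_config(
      structure = "markov", sigma2 = c(0.187, 1.647), erratic_accuracy = 0.26,
      initial_probs = c(0.948, 0.052),
      transition_matrix = matrix(c(0.9907, 0.0093, 0.0216, 0.9784), 2, 2,
                                 byrow = TRUE),
      seed = seed),
    two_class_mixture = sim_config(
      n_persons = 300, class_weights = c(0.5, 0.5),
      difficulties_by_class = rbind(seq(-2, 2, length.out = I),
                                    seq(2, -2, length.out = I)),
      seed = seed),
    early_engagement_inversion = sim_config(
      n_persons = 150, structure = "inversion", inversion_items = 3,
      inversion_fraction = 0.25, inversion_shift = 2.5,
      sigma2 = c(0.187, 1.647), erratic_accuracy = 0.25, seed = seed),
    null_single_state = sim_config(
      n_persons = 150, structure = "markov",
      initial_probs = c(1, 0),
      transition_matrix = matrix(c(1, 0, 0, 1), 2, 2),
      seed = seed))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Write / read a simulation configuration as YAML
#'
#' Round-trips exactly: `read_sim_config(write_sim_config(cfg, path))`
#' reconstructs an identical `sim_config`.
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lst <- unclass(config)
  lst$transition_matrix <- lapply(seq_len(nrow(lst$transition_matrix)),
                                  function(r) as.numeric(lst$transition_matrix[r, ]))
  if (!is.null(lst$difficulties_by_class))
    lst$difficulties_by_class <- lapply(seq_len(nrow(lst$difficulties_by_class)),
                                        function(r) as.numeric(lst$difficulties_by_class[r, ]))
  yaml::write_yaml(lst[!vapply(lst, is.null, TRUE)], path, precision = 12)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(sim_config, lst)
}
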