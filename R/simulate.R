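# Simulated study datasets: four equicorrelated standard-normal "signal"
# variables (pairwise correlation rho), optionally twelve independent
# standard-normal "noise" variables with zero outcome coefficient, and a
# binary outcome drawn from a logistic model with four equal signal
# coefficients. The common coefficient and intercept are calibrated so the
# true linear predictor discriminates at a target AUROC with a target
# prevalence.

#' Weighted concordance (AUROC) of a score against case probabilities
#'
#' Computes P(score_case > score_control) where each observation is a case
#' with probability `p` and a control with probability `1 - p`. This is the
#' expected AUROC of the score against outcomes drawn from `p`, without
#' drawing them, which makes the calibration search smooth and
#' deterministic.
#'
#' @param score Numeric scores.
#' @param p Case probabilities, same length.
#' @return Scalar in \[0, 1\].
#' @keywords internal
weighted_auroc <- function(score, p) {
  ord <- order(score)
  w <- p[ord]          # case weight
  v <- 1 - p[ord]      # control weight
  # scores are continuous draws, so ties have negligible probability and the
  # same-observation pair contributes O(1/n); both are ignored
  conc <- sum(w * (cumsum(v) - v))
  conc / (sum(w) * sum(v))
}

#' Empirical AUROC of a score against binary outcomes
#'
#' Rank-based (Mann-Whitney) AUROC with tie correction.
#'
#' @param score Numeric scores.
#' @param y 0/1 outcomes (or two-level factor).
#' @return Scalar AUROC.
#' @export
empirical_auroc <- function(score, y) {
  y <- as_binary01(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibrate the outcome model of the simulated datasets
#'
#' Nested deterministic search on a fixed Monte-Carlo sample of the signal
#' sum `S ~ N(0, n_signal + n_signal*(n_signal-1)*rho)`: the inner root
#' finds the intercept giving the target expected prevalence for a
#' candidate coefficient, the outer root finds the common coefficient
#' giving the target expected AUROC of the true linear predictor.
#'
#' @param rho Pairwise signal correlation in \[0, 1).
#' @param target_auroc Target discrimination in (0.5, 1).
#' @param target_prevalence Target positive-class proportion in (0, 1).
#' @param n_signal Number of signal variables (default 4).
#' @param mc_size Monte-Carlo sample size for the search (default 2e5).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @return List with `beta` (common signal coefficient) and `intercept`.
#' @examples
#' calibrate_coefficients(rho = 0.1, target_auroc = 0.75, seed = 1)
#' @export
calibrate_coefficients <- function(rho, target_auroc = 0.75,
                                   target_prevalence = 0.20,
                                   n_signal = 4, mc_size = 2e5, seed = 1) {
  stopifnot(target_auroc > 0.5, target_auroc < 1,
            target_prevalence > 0, target_prevalence < 1, rho >= 0, rho < 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  s_var <- n_signal + n_signal * (n_signal - 1) * rho
  S <- stats::rnorm(mc_size, 0, sqrt(s_var))

  solve_intercept <- function(beta) {
    stats::uniroot(function(a) mean(stats::plogis(a + beta * S)) - target_prevalence,
                   interval = c(-30, 30), tol = 1e-8)$root
  }
  auroc_of <- function(beta) {
    a <- solve_intercept(beta)
    weighted_auroc(S, stats::plogis(a + beta * S))
  }
  fit <- stats::uniroot(function(b) auroc_of(b) - target_auroc,
                        interval = c(1e-6, 10), tol = 1e-6, extendInt = "upX")
  beta <- fit$root
  list(beta = beta, intercept = solve_intercept(beta))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a dataset of correlated signal variables with a binary outcome
#'
#' Signal variables `V1..Vk` are drawn from an equicorrelated multivariate
#' normal with standard-normal marginals; noise variables `N1..Nm` are
#' independent standard normal with zero outcome coefficient; the binary
#' `outcome` is Bernoulli(plogis(intercept + beta * (V1 + ... + Vk))).
#'
#' @param n Number of rows.
#' @param rho Pairwise signal correlation.
#' @param beta,intercept Outcome model parameters (see
#'   [calibrate_coefficients()]).
#' @param n_signal Number of signal variables (default 4).
#' @param n_noise Number of noise variables (default 0).
#' @param seed Optional integer seed.
#' @return Tibble with the signal columns, noise columns and an integer 0/1
#'   `outcome` column.
#' @export
simulate_dataset <- function(n, rho, beta, intercept, n_signal = 4,
                             n_noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Sigma <- matrix(rho, n_signal, n_signal)
  diag(Sigma) <- 1
  Z <- matrix(stats::rnorm(n * n_signal), n, n_signal)
  X <- Z %*% chol(Sigma)
  colnames(X) <- paste0("V", seq_len(n_signal))
  out <- tibble::as_tibble(X)
  if (n_noise > 0) {
    Nz <- matrix(stats::rnorm(n * n_noise), n, n_noise)
    colnames(Nz) <- paste0("N", seq_len(n_noise))
    out <- dplyr::bind_cols(out, tibble::as_tibble(Nz))
  }
  lp <- intercept + beta * rowSums(X)
  out$outcome <- stats::rbinom(n, 1, stats::plogis(lp))
  out
}

sim_preset_table <- tibble::tribble(
  ~preset,       ~target_auroc, ~rho, ~n_noise,
  "sim_75_1",    0.75,          0.1,  0L,
  "sim_75_7",    0.75,          0.7,  0L,
  "sim_90_1",    0.90,          0.1,  0L,
  "sim_90_7",    0.90,          0.7,  0L,
  # noise presets share the signal design of their base preset; the "_7
  # noise" design is equicorrelated at 0.7 like its base
  "sim_75_1_noise", 0.75,       0.1,  12L,
  "sim_75_7_noise", 0.75,       0.7,  12L,
  "sim_90_1_noise", 0.90,       0.1,  12L,
  "sim_90_7_noise", 0.90,       0.7,  12L
)

.calibration_cache <- new.env(parent = emptyenv())

#' Simulate one of the named study presets
#'
#' Presets `sim_<auroc>_<rho>` (e.g. `sim_75_7`: target AUROC 0.75,
#' pairwise correlation 0.7), with `_noise` variants adding twelve
#' independent noise variables. Calibrated coefficients are cached per
#' session, keyed on the design and calibration seed.
#'
#' @param preset Preset name (see `sim_presets()`).
#' @param n Number of rows (default 4000, the study condition).
#' @param seed Integer seed for the data draw.
#' @param calibration_seed Seed for the coefficient calibration (default 1;
#'   calibration is deterministic given this seed).
#' @return Tibble as in [simulate_dataset()].
#' @export
simulate_preset <- function(preset, n = 4000, seed = NULL, calibration_seed = 1) {
  row <- sim_preset_table[sim_preset_table$preset == preset, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown preset '", preset, "'; see sim_presets()"))
  }
  coefs <- preset_coefficients(preset, calibration_seed)
  simulate_dataset(n = n, rho = row$rho, beta = coefs$beta,
                   intercept = coefs$intercept, n_noise = row$n_noise,
                   seed = seed)
}

preset_coefficients <- function(preset, calibration_seed = 1) {
  row <- sim_preset_table[sim_preset_table$preset == preset, ]
  key <- paste(row$rho, row$target_auroc, calibration_seed, sep = "|")
  if (is.null(.calibration_cache[[key]])) {
    .calibration_cache[[key]] <- calibrate_coefficients(
      rho = row$rho, target_auroc = row$target_auroc, seed = calibration_seed)
  }
  .calibration_cache[[key]]
}

#' List the available simulation presets
#'
#' @return Tibble of preset names and their design parameters.
#' @export
sim_presets <- function() sim_preset_table

#' Drop the noise variables of a simulated dataset
#'
#' Returns the dataset restricted to signal variables and outcome, with the
#' exact same signal values and outcome draws.
#'
#' @param data A data frame with `N*` noise columns.
#' @return Tibble without the `N*` columns.
#' @export
drop_noise <- function(data) {
  keep <- !grepl("^N[0-9]+$", names(data))
  tibble::as_tibble(data[, keep, drop = FALSE])
}

signal_vars <- function(data) grep("^V[0-9]+$", names(data), value = TRUE)
noise_vars <- function(data) grep("^N[0-9]+$", names(data), value = TRUE)
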