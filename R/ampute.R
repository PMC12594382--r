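# Amputation: deliberate creation of missing values in complete data under
# a named missingness mechanism. Six mechanisms are provided; in every one,
# noise variables (if declared) receive MCAR missingness so they stay pure
# noise at all levels of the workflow, and the outcome is never amputed.
#
# "A random sample of size corresponding to X%" is implemented as
# exact-count sampling without replacement: size = round(rate * segment
# size). Segment membership (below/above the driver's sample mean) is frozen
# from the pre-amputation values of all drivers before any cell is deleted,
# so circular mechanisms never condition on already-deleted values.

#' MCAR amputation
#'
#' For each listed variable independently, an exact-count random sample of
#' `round(rate * n)` rows is set to missing.
#'
#' @param data A data frame.
#' @param vars Columns to ampute.
#' @param rate Missingness rate in (0, 1); default 0.30.
#' @return The data with `NA`s injected.
#' @export
ampute_mcar <- function(data, vars, rate = 0.3) {
  stopifnot(rate > 0, rate < 1, all(vars %in% names(data)))
  n <- nrow(data)
  k <- round(rate * n)
  if (k == 0) {
    warn("round(rate * n) is 0; no cells amputed")
    return(tibble::as_tibble(data))
  }
  data <- tibble::as_tibble(data)
  for (v in vars) data[[v]][sample.int(n, k)] <- NA
  data
}

#' Conditional (MAR / MNAR) amputation of one variable
#'
#' The driver's rows are split at its sample mean; an exact-count sample of
#' `round(low_rate * n_low)` rows is amputed in the below-mean segment and
#' `round(high_rate * n_high)` in the at-or-above-mean segment. With the
#' default rates 10% / 50% and a roughly symmetric driver this yields about
#' 30% marginal missingness. Self-driven amputation (`driver == target`) is
#' the MNAR mechanism: missingness depends on the unobserved value itself.
#'
#' @param data A data frame.
#' @param target Column to ampute.
#' @param driver Fully observed column whose mean splits the segments (may
#'   equal `target`).
#' @param low_rate,high_rate Segment missingness rates.
#' @return The data with `NA`s injected in `target`.
#' @export
ampute_conditional <- function(data, target, driver, low_rate = 0.1, high_rate = 0.5) {
  stopifnot(all(c(target, driver) %in% names(data)))
  d <- data[[driver]]
  if (anyNA(d)) abort("driver must be fully observed at amputation time")
  data <- tibble::as_tibble(data)
  high <- d >= mean(d)
  segments <- list(list(rows = which(!high), rate = low_rate),
                   list(rows = which(high), rate = high_rate))
  for (seg in segments) {
    if (length(seg$rows) == 0) {
      warn("empty driver segment contributes no amputations")
      next
    }
    k <- round(seg$rate * length(seg$rows))
    if (k > 0) data[[target]][seg$rows[sample.int(length(seg$rows), k)]] <- NA
  }
  data
}

#' Outcome-dependent conditional amputation of one variable
#'
#' As [ampute_conditional()] but with four strata: (driver segment) x
#' (binary outcome class), each with its own exact-count rate. The default
#' rates 10/36/20/30 percent yield about 30% marginal missingness at 20%
#' prevalence.
#'
#' @inheritParams ampute_conditional
#' @param outcome Name of the complete binary outcome column.
#' @param rates Named rates `low_pos`, `low_neg`, `high_pos`, `high_neg`.
#' @export
ampute_conditional_outcome <- function(data, target, driver, outcome,
                                       rates = c(low_pos = 0.10, low_neg = 0.36,
                                                 high_pos = 0.20, high_neg = 0.30)) {
  stopifnot(all(c(target, driver, outcome) %in% names(data)),
            all(c("low_pos", "low_neg", "high_pos", "high_neg") %in% names(rates)))
  d <- data[[driver]]
  if (anyNA(d) || anyNA(data[[outcome]])) {
    abort("driver and outcome must be fully observed")
  }
  y <- as_binary01(data[[outcome]])
  data <- tibble::as_tibble(data)
  high <- d >= mean(d)
  strata <- list(low_pos = which(!high & y == 1), low_neg = which(!high & y == 0),
                 high_pos = which(high & y == 1), high_neg = which(high & y == 0))
  for (s in names(strata)) {
    seg <- strata[[s]]
    if (length(seg) == 0) {
      warn(paste0("empty stratum '", s, "' contributes no amputations"))
      next
    }
    k <- round(rates[[s]] * length(seg))
    if (k > 0) data[[target]][seg[sample.int(length(seg), k)]] <- NA
  }
  data
}

#' Ampute a dataset under a named missingness mechanism
#'
#' Mechanisms over the ordered signal variables (canonically V1..V4):
#' \describe{
#'   \item{MCAR}{each signal variable amputed completely at random at
#'     `rate`.}
#'   \item{MAR_2}{V1 amputed in function of V2 and V3 in function of V4
#'     (10% below / 50% above the driver mean); V2 and V4 stay complete.}
#'   \item{MAR_2_out}{as MAR_2 but with segment-by-outcome rates
#'     10/36/20/30 percent.}
#'   \item{MAR_circ}{circular drivers: V1 by V2, V2 by V3, V3 by V4, V4 by
#'     V1, each 10%/50%.}
#'   \item{MAR_circ_out}{circular drivers with the outcome-dependent
#'     rates.}
#'   \item{MNAR}{each signal variable amputed in function of its own value
#'     (10% below its mean, 50% at or above).}
#' }
#' Driver segment membership is computed from the pre-amputation values of
#' all drivers before any cell is deleted. Noise variables always receive
#' MCAR at `rate`; the outcome is never amputed.
#'
#' @param data A complete data frame.
#' @param mechanism One of `"MCAR"`, `"MAR_2"`, `"MAR_2_out"`,
#'   `"MAR_circ"`, `"MAR_circ_out"`, `"MNAR"`.
#' @param signal_vars Ordered signal variable names (length 4 for the
#'   MAR/MNAR mechanisms).
#' @param noise_vars Optional noise variable names (always MCAR).
#' @param outcome Outcome column name (required for the `_out` variants).
#' @param rate Target marginal missingness rate, default 0.30.
#' @param seed Optional integer seed for reproducible masks.
#' @return The amputed tibble.
#' @examples
#' df <- simulate_dataset(n = 200, rho = 0.7, beta = 0.5, intercept = -1.7, seed = 1)
#' amp <- ampute(df, "MNAR", signal_vars = paste0("V", 1:4), seed = 1)
#' colMeans(is.na(amp))
#' @export
ampute <- function(data, mechanism, signal_vars, noise_vars = NULL,
                   outcome = NULL, rate = 0.3, seed = NULL) {
  mechanism <- match.arg(mechanism, c("MCAR", "MAR_2", "MAR_2_out",
                                      "MAR_circ", "MAR_circ_out", "MNAR"))
  stopifnot(all(signal_vars %in% names(data)))
  if (mechanism != "MCAR" && length(signal_vars) != 4) {
    abort("MAR/MNAR mechanisms require exactly 4 signal variables")
  }
  if (grepl("_out$", mechanism) && is.null(outcome)) {
    abort("outcome-dependent mechanisms require `outcome`")
  }
  if (!is.null(seed)) set.seed(seed)
  data <- tibble::as_tibble(data)
  pre <- data # segment memberships frozen pre-amputation

  ampute_pairs <- function(data, pairs, outcome_dep) {
    for (p in pairs) {
      if (outcome_dep) {
        mask <- is.na(ampute_conditional_outcome(pre, p[1], p[2], outcome)[[p[1]]])
      } else {
        mask <- is.na(ampute_conditional(pre, p[1], p[2])[[p[1]]])
      }
      data[[p[1]]][mask] <- NA
    }
    data
  }
  v <- signal_vars
  data <- switch(
    mechanism,
    MCAR = ampute_mcar(data, v, rate),
    MAR_2 = ampute_pairs(data, list(c(v[1], v[2]), c(v[3], v[4])), FALSE),
    MAR_2_out = ampute_pairs(data, list(c(v[1], v[2]), c(v[3], v[4])), TRUE),
    MAR_circ = ampute_pairs(
      data, list(c(v[1], v[2]), c(v[2], v[3]), c(v[3], v[4]), c(v[4], v[1])), FALSE),
    MAR_circ_out = ampute_pairs(
      data, list(c(v[1], v[2]), c(v[2], v[3]), c(v[3], v[4]), c(v[4], v[1])), TRUE),
    MNAR = ampute_pairs(data, lapply(v, function(x) c(x, x)), FALSE)
  )
  if (length(noise_vars) > 0) data <- ampute_mcar(data, noise_vars, rate)
  data
}
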