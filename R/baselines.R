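# Baseline imputers with the same fit/predict contract as the forest
# imputer, so the benchmark can swap them in interchangeably. Both are
# row-independent and never touch observed cells.

#' Mean/mode baseline imputer
#'
#' Stores the train-set mean (continuous) or mode (categorical) of each
#' variable, computed on complete cases, and fills every missing cell with
#' it at prediction time.
#'
#' @param data Training data frame with `NA`s marking missing cells.
#' @param outcome Optional outcome column to exclude.
#' @return Object of class `meanmode_imputer` with elements `fill_values`
#'   and `imputed` (the imputed training table).
#' @examples
#' fit <- meanmode_impute(data.frame(x = c(2, 4, NA)))
#' predict(fit, data.frame(x = NA_real_))
#' @export
meanmode_impute <- function(data, outcome = NULL) {
  data <- as_table(data)
  fills <- compute_initialization(data, "mean/mode", outcome = outcome)
  structure(list(fill_values = fills,
                 imputed = apply_initialization(data, fills),
                 config = list(outcome = outcome)),
            class = "meanmode_imputer")
}

#' @export
predict.meanmode_imputer <- function(object, new_data, ...) {
  apply_initialization(as_table(new_data), object$fill_values)
}

#' Linear-regression baseline imputer
#'
#' For each numeric variable, an ordinary least squares model is fit on the
#' rows observed for that variable, with all other variables as predictors
#' after mean initialization of their missing cells. Variables are imputed
#' independently from the initialized table (no chaining between imputed
#' variables). Categorical columns are not supported directly; dummy-code
#' them first with [dummy_encode()].
#'
#' @param data Training data frame (numeric columns only besides the
#'   outcome).
#' @param outcome Optional outcome column to exclude.
#' @return Object of class `linear_imputer` with elements `init_values`,
#'   `models` and `imputed`.
#' @export
linear_impute <- function(data, outcome = NULL) {
  data <- tibble::as_tibble(data)
  vars <- setdiff(names(data), outcome)
  if (!all(vapply(data[vars], is.numeric, logical(1)))) {
    abort("linear imputation supports numeric columns only; see dummy_encode()")
  }
  if (length(vars) < 2) abort("need at least 2 variables")
  fills <- compute_initialization(data[vars], "mean/mode")
  init <- apply_initialization(data[vars], fills)
  models <- list()
  out <- init
  for (v in vars) {
    obs <- !is.na(data[[v]])
    # models are fit even for complete variables so new data can be imputed
    df <- init
    df[[v]] <- data[[v]] # raw target with NAs
    fml <- stats::reformulate(setdiff(vars, v), response = v)
    fit <- stats::lm(fml, data = df[obs, , drop = FALSE])
    if (anyNA(stats::coef(fit))) {
      warn(paste0("rank-deficient design for '", v,
                  "'; collinear terms dropped"))
    }
    models[[v]] <- fit
    if (any(!obs)) {
      out[[v]][!obs] <- suppressWarnings(
        unname(stats::predict(fit, newdata = init[!obs, , drop = FALSE])))
    }
  }
  if (!is.null(outcome)) out[[outcome]] <- data[[outcome]]
  structure(list(init_values = fills, models = models,
                 imputed = tibble::as_tibble(out[names(data)]),
                 config = list(outcome = outcome)),
            class = "linear_imputer")
}

#' @export
predict.linear_imputer <- function(object, new_data, ...) {
  new_data <- tibble::as_tibble(new_data)
  vars <- names(object$models)
  stopifnot(all(vars %in% names(new_data)))
  init <- apply_initialization(new_data[vars], object$init_values)
  out <- new_data
  for (v in vars) {
    idx <- is.na(new_data[[v]])
    if (!any(idx)) next
    out[[v]][idx] <- suppressWarnings(
      unname(stats::predict(object$models[[v]],
                            newdata = init[idx, , drop = FALSE])))
  }
  out
}

#' Dummy-code the factor columns of a data frame
#'
#' Each factor column with L levels is replaced by L - 1 indicator columns
#' against the first (reference) level, named `<var>_<level>`. Missing
#' cells propagate to every indicator of that variable. Numeric columns and
#' the outcome pass through unchanged.
#'
#' @param data A data frame.
#' @param outcome Optional outcome column left untouched.
#' @return Tibble of numeric columns.
#' @export
dummy_encode <- function(data, outcome = NULL) {
  data <- as_table(data)
  cols <- purrr::map(names(data), function(v) {
    x <- data[[v]]
    if (!is.factor(x) || identical(v, outcome)) {
      return(rlang::set_names(tibble::tibble(x), v))
    }
    lv <- levels(x)[-1]
    m <- purrr::map(lv, function(l) as.numeric(x == l))
    rlang::set_names(tibble::as_tibble(m, .name_repair = "minimal"),
                     paste(v, lv, sep = "_"))
  })
  dplyr::bind_cols(cols)
}
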