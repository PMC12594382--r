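#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr %>%
NULL

# Variable kinds: numeric columns are continuous, factor (or character,
# promoted to factor on ingestion) columns are categorical. Ordinal data is
# expected as numeric codes and treated as continuous.

variable_kind <- function(x) {
  if (is.numeric(x)) "continuous" else if (is.factor(x)) "categorical" else
    abort(paste0("unsupported column type: ", paste(class(x), collapse = "/")))
}

as_table <- function(data) {
  data <- tibble::as_tibble(data)
  dplyr::mutate(data, dplyr::across(dplyr::where(is.character), as.factor))
}

#' Mode of a vector with a deterministic tie-break
#'
#' Highest observed frequency wins; ties are broken by declared level order
#' (first level wins). `NA` values are ignored.
#'
#' @param x A factor.
#' @return A length-1 character scalar, the modal level.
#' @keywords internal
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  counts <- table(x) # table() preserves level order
  names(counts)[which.max(counts)]
}

#' Summarize the variables of a data frame
#'
#' One row per variable: observed/missing counts, the mean (continuous) or
#' mode (categorical) computed on complete cases, the observed-part variance
#' for continuous variables and the observed class proportions for
#' categorical variables. A column that is entirely missing gets
#' `n_observed = 0` and an `NA` fill value rather than a silent number.
#'
#' @param data A data frame; numeric columns are treated as continuous,
#'   factor/character columns as categorical.
#' @param outcome Optional name of an outcome column to exclude from the
#'   summary (only predictor variables are summarized).
#' @return A tibble with columns `variable`, `kind`, `n_observed`,
#'   `n_missing`, `prop_missing`, `mean` , `mode`, `variance` and a
#'   `level_props` list-column (named numeric vector for categorical
#'   variables, `NULL` otherwise).
#' @examples
#' df <- data.frame(x = c(1, 2, NA), g = factor(c("a", "a", "b")))
#' summarize_variables(df)
#' @export
summarize_variables <- function(data, outcome = NULL) {
  stopifnot(nrow(data) >= 1)
  data <- as_table(data)
  vars <- setdiff(names(data), outcome)
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    kind <- variable_kind(x)
    n_miss <- sum(is.na(x))
    obs <- x[!is.na(x)]
    tibble::tibble(
      variable = v,
      kind = kind,
      n_observed = length(obs),
      n_missing = n_miss,
      prop_missing = n_miss / length(x),
      mean = if (kind == "continuous" && length(obs) > 0) mean(obs) else NA_real_,
      mode = if (kind == "categorical") stat_mode(x) else NA_character_,
      variance = if (kind == "continuous" && length(obs) > 1) stats::var(obs) else NA_real_,
      level_props = list(
        if (kind == "categorical" && length(obs) > 0)
          prop.table(table(obs)) else NULL
      )
    )
  })
}

#' Count rows that are missing on every listed variable
#'
#' Observations missing on all variables at once cannot be matched or
#' modelled from within-row information; imputers that rely on donors must
#' drop them, while initialization-based imputers fall back to their fill
#' values.
#'
#' @param data A data frame.
#' @param variables Character vector of column names (non-empty).
#' @return Integer count of rows with `NA` in every listed column.
#' @examples
#' df <- data.frame(a = c(NA, 1, NA), b = c(NA, NA, 2))
#' count_completely_missing(df, c("a", "b"))
#' @export
count_completely_missing <- function(data, variables) {
  if (length(variables) == 0) abort("`variables` must name at least one column")
  stopifnot(all(variables %in% names(data)))
  sum(rowSums(!is.na(data[variables])) == 0)
}

#' Drop rows that are missing on every listed variable
#'
#' Row order of the retained rows is preserved; applying the function twice
#' is the same as applying it once.
#'
#' @inheritParams count_completely_missing
#' @return A list with `data` (the filtered tibble) and `n_dropped`.
#' @export
drop_completely_missing <- function(data, variables) {
  if (length(variables) == 0) abort("`variables` must name at least one column")
  stopifnot(all(variables %in% names(data)))
  keep <- rowSums(!is.na(data[variables])) > 0
  list(data = tibble::as_tibble(data[keep, , drop = FALSE]),
       n_dropped = sum(!keep))
}

#' Fill values for initialization
#'
#' Computes mean/mode or median/mode fill values on complete cases of each
#' variable, or validates a user-supplied custom map.
#'
#' @param data A data frame.
#' @param method One of `"mean/mode"`, `"median/mode"`, `"custom"`.
#' @param custom_values Named list of fill values, required (for every
#'   variable with missing cells) when `method = "custom"`.
#' @param outcome Optional outcome column name to skip.
#' @return Named list of fill values (numeric for continuous, level label
#'   for categorical).
#' @export
compute_initialization <- function(data,
                                   method = c("mean/mode", "median/mode", "custom"),
                                   custom_values = NULL, outcome = NULL) {
  method <- match.arg(method)
  data <- as_table(data)
  vars <- setdiff(names(data), outcome)
  fills <- lapply(rlang::set_names(vars), function(v) {
    x <- data[[v]]
    obs <- x[!is.na(x)]
    if (method == "custom" && !is.null(custom_values[[v]])) {
      return(custom_values[[v]])
    }
    if (length(obs) == 0) {
      if (anyNA(x)) {
        abort(paste0("variable '", v, "' is entirely missing and has no custom fill value"))
      }
      return(NULL)
    }
    if (is.numeric(x)) {
      if (method == "median/mode") stats::median(obs) else mean(obs)
    } else {
      stat_mode(x)
    }
  })
  fills[!vapply(fills, is.null, logical(1))]
}

apply_initialization <- function(data, fills) {
  for (v in names(fills)) {
    if (!v %in% names(data)) next
    idx <- is.na(data[[v]])
    if (!any(idx)) next
    if (is.factor(data[[v]])) {
      data[[v]][idx] <- factor(fills[[v]], levels = levels(data[[v]]))
    } else {
      data[[v]][idx] <- fills[[v]]
    }
  }
  data
}
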