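# Iterative chained random-forest imputation with persisted per-iteration
# models.
#
# Fit: initialize missing cells (mean/mode by default), then impute each
# variable in sequence with a random forest trained on that variable's
# observed part, updating the working table on the fly so later variables
# in the same iteration see the fresh imputations. After each iteration the
# weighted global out-of-bag NMSE is compared with the previous iteration's
# value (the initialization itself has NMSE 1 by definition); when it no
# longer decreases the iteration is rejected, the previous table is
# returned and only the accepted iterations' models are kept for replay.
#
# Transform: initialize a new table with the stored fill values and replay
# the stored models in the stored sequence for the selected number of
# iterations. Rows are processed jointly but independently: no cross-row
# information is used at prediction time, so a single observation can be
# imputed.

new_seed <- function(master, i, s) {
  as.integer((as.double(master) * 48271 + i * 7919 + s * 104729) %% 2147483587) + 1L
}

#' Order variables for imputation
#'
#' Variables are imputed in increasing order of missingness by default (the
#' least missing first), with ties broken by original column order.
#' Imputation models are learned for all predictor variables, with or
#' without missing values.
#'
#' @param data A data frame.
#' @param outcome Optional outcome column to exclude.
#' @param order `"increasing"` (default) or `"decreasing"` missingness.
#' @return Character vector of variable names.
#' @export
determine_sequence <- function(data, outcome = NULL,
                               order = c("increasing", "decreasing")) {
  order <- match.arg(order)
  vars <- setdiff(names(data), outcome)
  stopifnot(length(vars) >= 1)
  miss <- vapply(data[vars], function(x) mean(is.na(x)), numeric(1))
  idx <- base::order(miss, seq_along(vars),
                     decreasing = c(order == "decreasing", FALSE),
                     method = "radix")
  vars[idx]
}

#' Screen candidate predictors for one imputation target
#'
#' A candidate `x` is removed when the proportion of missing `x` among
#' observed target rows exceeds `p_obs`, or the proportion of observed `x`
#' among missing target rows falls below `p_miss`. Both proportions are
#' computed on the original missingness mask, never the working imputed
#' table. With the defaults `p_obs = 1`, `p_miss = 0` nothing is excluded.
#' A `predictor_matrix` row (target) x column (candidate) of `FALSE`
#' removes a candidate unconditionally.
#'
#' @param target Target variable name.
#' @param mask Logical missingness matrix (`TRUE` = missing) of the
#'   original data.
#' @param candidates Candidate predictor names.
#' @param predictor_matrix Optional named logical matrix (rows = targets).
#' @param p_obs,p_miss Screening thresholds.
#' @return Character vector of retained predictors (may be empty).
#' @export
select_predictors <- function(target, mask, candidates,
                              predictor_matrix = NULL, p_obs = 1, p_miss = 0) {
  candidates <- setdiff(candidates, target)
  if (!is.null(predictor_matrix)) {
    allowed <- colnames(predictor_matrix)[predictor_matrix[target, ]]
    candidates <- intersect(candidates, allowed)
  }
  if (p_obs >= 1 && p_miss <= 0) return(candidates)
  y_obs <- !mask[, target]
  y_miss <- mask[, target]
  keep <- vapply(candidates, function(x) {
    prop_obs <- if (any(y_obs)) mean(mask[y_obs, x]) else 0
    prop_miss <- if (any(y_miss)) mean(!mask[y_miss, x]) else 1
    prop_obs <= p_obs && prop_miss >= p_miss
  }, logical(1))
  candidates[keep]
}

fit_forest <- function(y, x, num_trees, max_depth, mtry, seed) {
  categorical <- is.factor(y)
  ranger::ranger(
    x = x, y = if (categorical) droplevels(y) else y,
    num.trees = num_trees,
    mtry = mtry %||% max(1L, floor(sqrt(ncol(x)))),
    min.node.size = if (categorical) 10 else 5,
    max.depth = max_depth %||% 0,
    probability = categorical,
    respect.unordered.factors = "ignore",
    num.threads = 1, seed = seed, verbose = FALSE
  )
}

predict_forest <- function(model, x) {
  stats::predict(model, data = x, num.threads = 1, verbose = FALSE)$predictions
}

# class probabilities -> label, ties broken by first level order
prob_to_label <- function(prob, levels) {
  prob <- prob[, levels[levels %in% colnames(prob)], drop = FALSE]
  factor(colnames(prob)[max.col(prob, ties.method = "first")], levels = levels)
}

var_error_record <- function(target, y_obs, oob_pred, app_pred, levels) {
  if (is.factor(y_obs)) {
    props <- prop.table(table(y_obs))
    bsref <- brier_reference(as.numeric(props))
    keep <- !is.na(oob_pred[, 1])
    prob_oob <- oob_pred[keep, , drop = FALSE]
    truth_oob <- y_obs[keep]
    nmse_oob <- if (bsref > 0 && any(keep))
      nmse_categorical(prob_oob, truth_oob, as.numeric(props)[match(colnames(prob_oob), names(props))]) else NA_real_
    nmse_app <- if (bsref > 0)
      nmse_categorical(app_pred, y_obs, as.numeric(props)[match(colnames(app_pred), names(props))]) else NA_real_
    lab_oob <- prob_to_label(prob_oob, levels)
    tibble::tibble(
      variable = target, nmse_oob = nmse_oob, nmse_apparent = nmse_app,
      mse = if (any(keep)) brier_score(prob_oob, truth_oob) else NA_real_,
      mer = if (any(keep)) misclassification_error_rate(lab_oob, truth_oob) else NA_real_,
      f1 = if (any(keep)) f1_scores(lab_oob, truth_oob, levels) else NA_real_
    )
  } else {
    ybar <- mean(y_obs)
    denom_ok <- sum((y_obs - ybar)^2) > 0
    keep <- !is.na(oob_pred)
    tibble::tibble(
      variable = target,
      nmse_oob = if (denom_ok && any(keep))
        nmse_continuous(y_obs[keep], oob_pred[keep], ybar) else NA_real_,
      nmse_apparent = if (denom_ok)
        nmse_continuous(y_obs, app_pred, ybar) else NA_real_,
      mse = if (any(keep)) mean((y_obs[keep] - oob_pred[keep])^2) else NA_real_,
      mer = NA_real_, f1 = NA_real_
    )
  }
}

#' Fit an iterative random-forest imputer
#'
#' Implements chained random-forest imputation with persisted models. Each
#' variable is imputed in sequence by a forest trained on its observed
#' part; imputations are updated on the fly within an iteration. The
#' algorithm iterates until the weighted global NMSE (out-of-bag by
#' default) stops decreasing, then discards the rejected iteration, or runs
#' exactly `maxiter` iterations when `fixed_maxiter = TRUE`. Categorical
#' variables use probability forests internally; imputed labels are the
#' argmax class.
#'
#' @param data A data frame with `NA`s marking missing cells. Character
#'   columns are promoted to factors.
#' @param outcome Optional name of an outcome column; it is excluded from
#'   the imputation entirely (never a target, never a predictor) and must
#'   be complete if present.
#' @param initialization `"mean/mode"` (default), `"median/mode"` or
#'   `"custom"`.
#' @param custom_init Named list of fill values for
#'   `initialization = "custom"`.
#' @param num_trees Trees per forest (default 500).
#' @param max_depth Maximum tree depth; `NULL` (default) grows unlimited
#'   trees.
#' @param mtry Variables tried per split; default `floor(sqrt(p))`.
#' @param maxiter Maximum number of iterations (default 10).
#' @param fixed_maxiter If `TRUE`, run exactly `maxiter` iterations and
#'   accept them all, bypassing the convergence rule.
#' @param convergence `"oob"` (default) or `"apparent"`: which global NMSE
#'   drives the stopping rule and the returned iteration.
#' @param var_weights Optional named weights for the global NMSE; default
#'   is each variable's proportion of missing values (equal weights when no
#'   variable has missing values).
#' @param predictor_matrix Optional logical matrix (rows = targets,
#'   columns = candidates) restricting predictors per target.
#' @param p_obs,p_miss Proportion-of-usable-cases screening thresholds
#'   (defaults 1 and 0: no screening); see [select_predictors()].
#' @param order Imputation order over missingness, `"increasing"`
#'   (default) or `"decreasing"`.
#' @param seed Integer master seed; per-(iteration, variable) child seeds
#'   are derived from it so results do not depend on scheduling.
#' @param verbose Print per-iteration global NMSE.
#' @return An object of class `forest_imputer` with elements `imputed`
#'   (the training table imputed at the selected iteration), `models`,
#'   `initialization`, `sequence`, `n_iterations` (selected iterations
#'   replayed at prediction time), `n_iterations_ran`, `converged`,
#'   `error_history` (tibble of per-variable and global errors per
#'   iteration) and `config`.
#' @examples
#' d <- simulate_dataset(300, 0.7, beta = 0.5, intercept = -1.7, seed = 1)
#' amp <- ampute(d, "MCAR", paste0("V", 1:4), outcome = "outcome", seed = 2)
#' fit <- forest_impute(amp, outcome = "outcome", num_trees = 50, seed = 3)
#' fit$n_iterations
#' head(predict(fit, amp))
#' @export
forest_impute <- function(data, outcome = NULL,
                          initialization = c("mean/mode", "median/mode", "custom"),
                          custom_init = NULL,
                          num_trees = 500, max_depth = NULL, mtry = NULL,
                          maxiter = 10, fixed_maxiter = FALSE,
                          convergence = c("oob", "apparent"),
                          var_weights = NULL, predictor_matrix = NULL,
                          p_obs = 1, p_miss = 0,
                          order = c("increasing", "decreasing"),
                          seed = NULL, verbose = FALSE) {
  initialization <- match.arg(initialization)
  convergence <- match.arg(convergence)
  order <- match.arg(order)
  stopifnot(maxiter >= 1)
  if (is.null(seed)) abort("`seed` is required for reproducible imputation")
  data <- as_table(data)
  if (!is.null(outcome)) stopifnot(outcome %in% names(data))
  vars <- setdiff(names(data), outcome)
  if (length(vars) < 2) abort("need at least 2 predictor variables")

  mask <- is.na(as.matrix(data[vars])) # original missingness, frozen
  dimnames(mask) <- list(NULL, vars)
  fills <- compute_initialization(data, initialization, custom_init, outcome)
  sequence <- determine_sequence(data, outcome, order)
  levels_map <- lapply(data[vars], levels)

  weights <- var_weights %||% colMeans(mask)
  if (is.null(names(weights))) names(weights) <- vars
  skip_zero_var <- vapply(vars, function(v) {
    obs <- data[[v]][!mask[, v]]
    if (is.factor(data[[v]])) length(unique(droplevels(obs))) < 2 else
      length(obs) > 1 && stats::var(obs) == 0 || length(obs) <= 1
  }, logical(1))
  weights[vars[skip_zero_var]] <- 0

  working <- apply_initialization(data, fills)
  prev_table <- working
  models <- list()          # models[[iter]][[var]]
  history <- list()
  prev_global <- 1          # the initialization has NMSE 1 by definition
  n_selected <- 0L
  converged <- FALSE

  for (i in seq_len(maxiter)) {
    iter_models <- list()
    iter_errors <- list()
    for (s in seq_along(sequence)) {
      v <- sequence[s]
      if (skip_zero_var[v]) {
        iter_errors[[v]] <- tibble::tibble(
          variable = v, nmse_oob = NA_real_, nmse_apparent = NA_real_,
          mse = NA_real_, mer = NA_real_, f1 = NA_real_)
        next
      }
      preds <- select_predictors(v, mask, vars, predictor_matrix, p_obs, p_miss)
      if (length(preds) == 0) {
        # no usable predictors: this variable keeps its initialization
        iter_errors[[v]] <- tibble::tibble(
          variable = v, nmse_oob = NA_real_, nmse_apparent = NA_real_,
          mse = NA_real_, mer = NA_real_, f1 = NA_real_)
        weights[v] <- 0
        next
      }
      obs_rows <- !mask[, v]
      y_obs <- data[[v]][obs_rows]
      x_obs <- working[obs_rows, preds, drop = FALSE]
      model <- fit_forest(y_obs, x_obs, num_trees, max_depth, mtry,
                          seed = new_seed(seed, i, s))
      oob <- model$predictions
      app <- predict_forest(model, x_obs)
      iter_errors[[v]] <- var_error_record(v, y_obs, oob, app, levels_map[[v]])
      if (any(mask[, v])) {
        x_miss <- working[mask[, v], preds, drop = FALSE]
        pred <- predict_forest(model, x_miss)
        working[[v]][mask[, v]] <- if (is.factor(data[[v]]))
          prob_to_label(pred, levels_map[[v]]) else pred
      }
      iter_models[[v]] <- list(model = model, predictors = preds)
    }
    per_var <- dplyr::bind_rows(iter_errors)
    glob <- function(metric) {
      vals <- rlang::set_names(per_var[[metric]], per_var$variable)
      w <- weights[names(vals)]
      w[is.na(vals)] <- 0
      if (all(w == 0)) { # nothing missing anywhere: equal weights
        w[!is.na(vals)] <- 1
      }
      if (all(w == 0)) return(NA_real_)
      global_weighted_nmse(vals, w)
    }
    g_oob <- glob("nmse_oob")
    g_app <- glob("nmse_apparent")
    history[[i]] <- dplyr::mutate(per_var, iteration = i,
                                  global_nmse_oob = g_oob,
                                  global_nmse_apparent = g_app,
                                  .before = 1)
    g <- if (convergence == "oob") g_oob else g_app
    if (verbose) message(sprintf("iteration %d: global NMSE %.4f", i, g))
    if (!fixed_maxiter && (is.na(g) || g >= prev_global)) {
      # rejected: roll back to the previous accepted imputation
      working <- prev_table
      converged <- TRUE
      break
    }
    models[[i]] <- iter_models
    n_selected <- i
    prev_global <- g
    prev_table <- working
  }

  structure(list(
    imputed = working,
    models = models,
    initialization = fills,
    sequence = sequence,
    n_iterations = n_selected,
    n_iterations_ran = length(history),
    converged = converged,
    error_history = dplyr::bind_rows(history),
    config = list(outcome = outcome, initialization = initialization,
                  num_trees = num_trees, max_depth = max_depth, mtry = mtry,
                  maxiter = maxiter, fixed_maxiter = fixed_maxiter,
                  convergence = convergence, order = order,
                  p_obs = p_obs, p_miss = p_miss,
                  var_weights = weights, seed = seed,
                  levels = levels_map,
                  version = imputer_format_version)
  ), class = "forest_imputer")
}

imputer_format_version <- "forestfill-imputer-1"

#' Impute new observations with a fitted imputer
#'
#' Missing cells are filled with the stored initialization values, then
#' overwritten by replaying the stored forest models in the stored sequence
#' for the selected number of iterations. Observed cells never change, and
#' rows are imputed independently of one another, so a single new
#' observation can be imputed.
#'
#' @param object A `forest_imputer`.
#' @param new_data Data frame covering the fitted variables with matching
#'   kinds and levels.
#' @param unseen_levels `"error"` (default) refuses observed categorical
#'   levels unseen at fit time; `"missing"` coerces them to `NA` and
#'   imputes them.
#' @param ... Unused.
#' @return The imputed tibble (columns in `new_data` order; extra columns
#'   pass through untouched).
#' @export
predict.forest_imputer <- function(object, new_data,
                                   unseen_levels = c("error", "missing"), ...) {
  unseen_levels <- match.arg(unseen_levels)
  new_data <- tibble::as_tibble(new_data)
  vars <- object$sequence
  missing_cols <- setdiff(vars, names(new_data))
  if (length(missing_cols) > 0) {
    abort(paste0("new data lacks fitted variable(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (v in vars) {
    lv <- object$config$levels[[v]]
    if (is.null(lv)) {
      if (!is.numeric(new_data[[v]])) abort(paste0("variable '", v, "' must be numeric"))
      next
    }
    x <- as.character(new_data[[v]])
    bad <- !is.na(x) & !(x %in% lv)
    if (any(bad)) {
      if (unseen_levels == "error") {
        abort(paste0("unseen level(s) in variable '", v, "': ",
                     paste(unique(x[bad]), collapse = ", ")))
      }
      x[bad] <- NA
    }
    new_data[[v]] <- factor(x, levels = lv)
  }
  mask <- is.na(as.matrix(new_data[vars]))
  dimnames(mask) <- list(NULL, vars)
  out <- apply_initialization(new_data, object$initialization)
  if (object$n_iterations >= 1) {
    for (i in seq_len(object$n_iterations)) {
      for (v in vars) {
        m <- object$models[[i]][[v]]
        if (is.null(m) || !any(mask[, v])) next
        pred <- predict_forest(m$model, out[mask[, v], m$predictors, drop = FALSE])
        out[[v]][mask[, v]] <- if (is.factor(out[[v]]))
          prob_to_label(pred, object$config$levels[[v]]) else pred
      }
    }
  }
  out
}

#' @export
print.forest_imputer <- function(x, ...) {
  cat("Iterative random-forest imputer\n")
  cat("  variables:", length(x$sequence),
      "| iterations selected:", x$n_iterations,
      "| ran:", x$n_iterations_ran,
      if (x$converged) "(converged)" else "", "\n")
  g <- unique(x$error_history[, c("iteration", "global_nmse_oob")])
  cat("  global OOB NMSE by iteration:",
      paste(sprintf("%.4f", g$global_nmse_oob), collapse = ", "), "\n")
  invisible(x)
}

#' Save / load a fitted imputer
#'
#' RDS serialization with a format-version tag; loading refuses an object
#' written by an incompatible format version. The save/load round trip
#' preserves `predict()` output exactly.
#'
#' @param object A `forest_imputer` (or baseline imputer).
#' @param path File path.
#' @return `save_imputer` returns `path` invisibly; `load_imputer` returns
#'   the fitted object.
#' @export
save_imputer <- function(object, path) {
  stopifnot(inherits(object, c("forest_imputer", "meanmode_imputer", "linear_imputer")))
  saveRDS(list(version = imputer_format_version, object = object), path)
  invisible(path)
}

#' @rdname save_imputer
#' @export
load_imputer <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    abort(paste0("cannot read imputer file: ", conditionMessage(e))))
  if (!is.list(payload) || !identical(payload$version, imputer_format_version)) {
    abort("imputer file version mismatch or corrupt file")
  }
  payload$object
}
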