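# Benchmark harness: repeated 2:1 train/test splits; amputation of train
# and test separately; imputation of the train set and transform-based
# imputation of the test set; prediction models on the imputed train set
# evaluated on the matching imputed test set; per-variable test-set
# imputation error against the pre-amputation truth; and reference models
# on the original, unamputed data.

#' Split a data frame 2:1 into train and test
#'
#' The test set receives `round(n * prop_test)` randomly sampled rows, with
#' no stratification.
#'
#' @param data A data frame.
#' @param prop_test Test fraction (default 1/3).
#' @param seed Optional integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
split_train_test <- function(data, prop_test = 1 / 3, seed = NULL) {
  stopifnot(nrow(data) >= 3)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  test_idx <- sample.int(n, round(n * prop_test))
  list(train = tibble::as_tibble(data[-test_idx, , drop = FALSE]),
       test = tibble::as_tibble(data[test_idx, , drop = FALSE]))
}

#' Fit a prediction model on imputed training data
#'
#' `"ridge"`: L2-penalized (logistic) regression via [glmnet::cv.glmnet()],
#' penalty chosen by 5-fold cross-validation minimizing logloss (binomial
#' deviance) for binary outcomes or squared error for continuous outcomes.
#' `"rf"`: a 500-tree random forest with `mtry` tuned over
#' `{1, floor(sqrt(p)), floor(p/3), p}` by OOB logloss / OOB MSE.
#'
#' @param kind `"ridge"` or `"rf"`.
#' @param data Complete (imputed) training data.
#' @param outcome Outcome column name; a 0/1 or two-level factor column
#'   gives a binary model, numeric gives a continuous one.
#' @param seed Integer seed for fold assignment / forests.
#' @return Object of class `prediction_model`; `predict()` returns
#'   positive-class probabilities (binary) or numeric predictions.
#' @export
fit_prediction_model <- function(kind = c("ridge", "rf"), data, outcome, seed = 1) {
  kind <- match.arg(kind)
  data <- as_table(data)
  y_raw <- data[[outcome]]
  binary <- is.factor(y_raw) || all(y_raw %in% c(0, 1))
  x_df <- data[setdiff(names(data), outcome)]
  stopifnot(!anyNA(x_df), !anyNA(y_raw))
  set.seed(seed)
  if (kind == "ridge") {
    x <- as.matrix(dummy_encode(x_df))
    y <- if (binary) as_binary01(y_raw) else y_raw
    foldid <- make_stratified_folds(y, nfolds = 5, binary = binary)
    fit <- glmnet::cv.glmnet(
      x, y, family = if (binary) "binomial" else "gaussian",
      alpha = 0, foldid = foldid,
      type.measure = if (binary) "deviance" else "mse")
    model <- list(fit = fit, features = colnames(x))
  } else {
    p <- ncol(x_df)
    y <- if (binary) factor(as_binary01(y_raw), levels = c(0, 1)) else y_raw
    grid <- unique(pmax(1L, c(1L, floor(sqrt(p)), floor(p / 3), p)))
    fits <- lapply(grid, function(m)
      ranger::ranger(x = x_df, y = y, num.trees = 500, mtry = m,
                     probability = binary, respect.unordered.factors = "ignore",
                     num.threads = 1, seed = seed, verbose = FALSE))
    oob_loss <- vapply(fits, function(f) {
      if (binary) {
        pr <- pmin(pmax(f$predictions[, "1"], 1e-12), 1 - 1e-12)
        -mean(as_binary01(y) * log(pr) + (1 - as_binary01(y)) * log(1 - pr))
      } else {
        f$prediction.error
      }
    }, numeric(1))
    model <- list(fit = fits[[which.min(oob_loss)]], mtry = grid[which.min(oob_loss)])
  }
  structure(list(kind = kind, binary = binary, model = model, outcome = outcome),
            class = "prediction_model")
}

make_stratified_folds <- function(y, nfolds, binary) {
  n <- length(y)
  foldid <- integer(n)
  if (binary) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
  } else {
    foldid <- sample(rep_len(seq_len(nfolds), n))
  }
  foldid
}

#' @export
predict.prediction_model <- function(object, new_data, ...) {
  new_data <- as_table(new_data)
  x_df <- new_data[setdiff(names(new_data), object$outcome)]
  if (object$kind == "ridge") {
    x <- as.matrix(dummy_encode(x_df))[, object$model$features, drop = FALSE]
    as.numeric(stats::predict(object$model$fit, newx = x, s = "lambda.min",
                              type = if (object$binary) "response" else "link"))
  } else {
    pr <- stats::predict(object$model$fit, data = x_df, num.threads = 1,
                         verbose = FALSE)$predictions
    if (object$binary) pr[, "1"] else pr
  }
}

#' Per-variable test-set imputation error
#'
#' NMSE (continuous) or misclassification error rate (categorical) of the
#' imputed values against the pre-amputation truth, evaluated on the cells
#' that were amputed. The NMSE reference is the mean of the true values of
#' the evaluated cells, so imputing every cell with that mean scores
#' exactly 1, and imputing with a train-set mean that the missingness
#' mechanism has biased (as under MNAR) scores above 1.
#'
#' @param truth Pre-amputation test data.
#' @param amputed Amputed test data (defines which cells are evaluated).
#' @param imputed Imputed test data.
#' @param variables Variables to evaluate.
#' @return Tibble with `variable`, `metric`, `error`, `n_missing`.
#' @export
variablewise_error <- function(truth, amputed, imputed, variables) {
  purrr::map_dfr(variables, function(v) {
    idx <- is.na(amputed[[v]]) & !is.na(truth[[v]])
    if (!any(idx)) {
      return(tibble::tibble(variable = v, metric = NA_character_,
                            error = NA_real_, n_missing = 0L))
    }
    if (is.numeric(truth[[v]])) {
      ref <- mean(truth[[v]][idx])
      tibble::tibble(variable = v, metric = "nmse",
                     error = nmse_continuous(truth[[v]][idx], imputed[[v]][idx], ref),
                     n_missing = sum(idx))
    } else {
      tibble::tibble(variable = v, metric = "mer",
                     error = misclassification_error_rate(imputed[[v]][idx],
                                                          truth[[v]][idx]),
                     n_missing = sum(idx))
    }
  })
}

imputer_registry <- function(num_trees = 100, seed = 1) {
  list(
    missforest = function(data, outcome)
      forest_impute(data, outcome = outcome, num_trees = num_trees, seed = seed),
    missforest_md10 = function(data, outcome)
      forest_impute(data, outcome = outcome, num_trees = num_trees,
                    max_depth = 10, seed = seed),
    meanmode = function(data, outcome) meanmode_impute(data, outcome = outcome),
    linear = function(data, outcome) linear_impute(data, outcome = outcome)
  )
}

#' Run a split-ampute-impute-predict benchmark scenario
#'
#' For each replicate: split 2:1; ampute train and test separately (when a
#' mechanism is given); record completely-missing row counts; fit each
#' imputer on the amputed train set (outcome excluded from the imputation
#' models); impute the test set with the trained imputer; fit each
#' prediction model on the imputed train set and evaluate it on the
#' matching imputed test set (Brier skill score for binary outcomes,
#' R-squared for continuous); evaluate per-variable test-set imputation
#' error against the pre-amputation truth; and fit/evaluate the same
#' prediction models on the original unamputed split as a reference
#' (imputer `"original"`). A replicate that fails is recorded with the
#' error message and excluded from aggregation, never silently averaged
#' over.
#'
#' @param data The complete dataset (or a preset name for
#'   [simulate_preset()]).
#' @param outcome Outcome column name.
#' @param mechanism Amputation mechanism name or `NULL` for no amputation.
#' @param imputers Character subset of `missforest`, `missforest_md10`,
#'   `meanmode`, `linear`.
#' @param models Character subset of `ridge`, `rf`.
#' @param n_reps Number of replicates (default 10; the full study condition
#'   is 100).
#' @param num_trees Trees for forest imputers (default 100, the benchmark
#'   setting).
#' @param rate Amputation rate.
#' @param seed Master seed; replicate seeds are derived from it.
#' @return Tibble with one row per (replicate, imputer, model): `bss` or
#'   `r_squared`, completely-missing counts, convergence iterations, the
#'   per-variable error tibble as a list-column, and runtimes (logged
#'   only).
#' @examples
#' \donttest{
#' d <- simulate_preset("sim_75_7", n = 1200, seed = 1)
#' run_scenario(d, "outcome", mechanism = "MCAR", imputers = "meanmode",
#'              n_reps = 2, seed = 1)
#' }
#' @export
run_scenario <- function(data, outcome = "outcome", mechanism = NULL,
                         imputers = c("missforest", "meanmode"),
                         models = "ridge", n_reps = 10, num_trees = 100,
                         rate = 0.3, seed = 1) {
  if (is.character(data) && length(data) == 1) {
    data <- simulate_preset(data, seed = seed)
  }
  data <- as_table(data)
  sv <- signal_vars(data)
  nv <- noise_vars(data)
  pred_vars <- setdiff(names(data), outcome)
  binary <- is.factor(data[[outcome]]) || all(data[[outcome]] %in% c(0, 1))

  purrr::map_dfr(seq_len(n_reps), function(rep) {
    rep_seed <- new_seed(seed, rep, 0L)
    res <- tryCatch(
      run_one_rep(data, outcome, mechanism, imputers, models, num_trees,
                  rate, rep_seed, sv, nv, pred_vars, binary),
      error = function(e) tibble::tibble(imputer = NA_character_,
                                         model = NA_character_,
                                         failure = conditionMessage(e)))
    dplyr::mutate(res, rep_id = rep, .before = 1)
  })
}

run_one_rep <- function(data, outcome, mechanism, imputers, models, num_trees,
                        rate, rep_seed, sv, nv, pred_vars, binary) {
  split <- split_train_test(data, seed = rep_seed)
  train0 <- split$train
  test0 <- split$test
  if (!is.null(mechanism)) {
    train <- ampute(train0, mechanism, signal_vars = sv, noise_vars = nv,
                    outcome = outcome, rate = rate, seed = new_seed(rep_seed, 1, 1))
    test <- ampute(test0, mechanism, signal_vars = sv, noise_vars = nv,
                   outcome = outcome, rate = rate, seed = new_seed(rep_seed, 2, 1))
  } else {
    train <- train0
    test <- test0
  }
  cm_train <- count_completely_missing(train, pred_vars)
  cm_test <- count_completely_missing(test, pred_vars)

  registry <- imputer_registry(num_trees = num_trees, seed = new_seed(rep_seed, 3, 1))
  eval_models <- function(train_imp, test_imp, imputer_name, n_iter, t_fit, t_imp) {
    purrr::map_dfr(models, function(m) {
      fit <- fit_prediction_model(m, train_imp, outcome,
                                  seed = new_seed(rep_seed, 4, match(m, models)))
      preds <- stats::predict(fit, test_imp)
      row <- tibble::tibble(imputer = imputer_name, model = m,
                            cm_train = cm_train, cm_test = cm_test,
                            convergence_iterations = n_iter,
                            t_fit_impute_train = t_fit, t_impute_test = t_imp)
      if (binary) {
        row$bss <- evaluate_prediction_binary(
          pmin(pmax(preds, 0), 1), as_binary01(test_imp[[outcome]]),
          mean(as_binary01(train_imp[[outcome]])))
      } else {
        row$r_squared <- evaluate_prediction_continuous(
          preds, test_imp[[outcome]], mean(train_imp[[outcome]]))
      }
      row
    })
  }

  out <- purrr::map_dfr(imputers, function(im) {
    t0 <- proc.time()[["elapsed"]]
    fit <- registry[[im]](train, outcome)
    train_imp <- fit$imputed
    t1 <- proc.time()[["elapsed"]]
    test_imp <- stats::predict(fit, test)
    t2 <- proc.time()[["elapsed"]]
    rows <- eval_models(train_imp, test_imp, im,
                        if (inherits(fit, "forest_imputer")) fit$n_iterations else NA_integer_,
                        t1 - t0, t2 - t1)
    rows$var_errors <- replicate(nrow(rows), simplify = FALSE,
      variablewise_error(test0, test, test_imp, setdiff(pred_vars, nv)))
    rows
  })
  original <- eval_models(train0, test0, "original", NA_integer_, NA_real_, NA_real_)
  original$var_errors <- vector("list", nrow(original))
  dplyr::bind_rows(out, original)
}
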