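# Error metrics driving the imputer's convergence criterion and the
# benchmark evaluation. One unified scale for continuous and categorical
# variables: NMSE = error of the model / error of the reference imputation
# (mean for continuous, class proportions for categorical). NMSE 1 means
# "no better than the reference"; < 1 improvement; > 1 deterioration.

#' Normalized mean squared error for continuous variables
#'
#' \deqn{NMSE = \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2 = 1 - R^2}
#'
#' The reference mean \eqn{\bar y} is supplied by the caller: at training
#' time the mean of the observed part, at test time the train-set mean (the
#' imputer can only know the training distribution).
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @param reference_mean Scalar reference \eqn{\bar y}.
#' @return Non-negative scalar; errors when the reference denominator is 0
#'   (constant truth equal to the reference mean).
#' @examples
#' y <- rnorm(50)
#' nmse_continuous(y, rep(mean(y), 50), mean(y)) # == 1
#' @export
nmse_continuous <- function(y_true, y_pred, reference_mean) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  denom <- sum((y_true - reference_mean)^2)
  if (denom <= 0) abort("NMSE undefined: zero reference variance")
  sum((y_true - y_pred)^2) / denom
}

#' Multiclass Brier score
#'
#' Mean over observations of the squared probability error summed over all
#' classes. For a binary variable this is twice the single-class Brier score
#' because the sum runs over both classes.
#'
#' @param prob_matrix N x R matrix of predicted class probabilities (rows sum
#'   to 1); probabilities are clipped to \[0, 1\] first.
#' @param truth Either a factor of true labels with R levels matching
#'   `colnames(prob_matrix)`, or an N x R one-hot matrix.
#' @return Scalar in \[0, 2\].
#' @export
brier_score <- function(prob_matrix, truth) {
  prob_matrix <- pmin(pmax(as.matrix(prob_matrix), 0), 1)
  y <- one_hot(truth, colnames(prob_matrix))
  stopifnot(nrow(y) == nrow(prob_matrix), ncol(y) == ncol(prob_matrix))
  mean(rowSums((prob_matrix - y)^2))
}

one_hot <- function(truth, levels = NULL) {
  if (is.matrix(truth)) return(truth)
  f <- factor(as.character(truth), levels = levels %||% levels(as.factor(truth)))
  m <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

#' Reference Brier score of the class-proportion predictor
#'
#' \deqn{BS_{ref} = 1 - \sum_j p_j^2} for reference class proportions
#' \eqn{p_j}. Zero for a degenerate single-class variable, in which case any
#' downstream division is the caller's error case.
#'
#' @param class_props Non-negative proportions summing to 1.
#' @return Scalar in \[0, 1).
#' @export
brier_reference <- function(class_props) {
  stopifnot(all(class_props >= 0), abs(sum(class_props) - 1) < 1e-8)
  1 - sum(class_props^2)
}

#' Normalized mean squared error for categorical variables
#'
#' Brier score divided by the reference Brier score of the class-proportion
#' predictor; algebraically `1 - BSS` (one minus the Brier skill score).
#'
#' @inheritParams brier_score
#' @param class_props Reference class proportions (train-set observed-part
#'   proportions), ordered as `colnames(prob_matrix)`.
#' @return Non-negative scalar; errors for a single-class reference.
#' @export
nmse_categorical <- function(prob_matrix, truth, class_props) {
  bsref <- brier_reference(class_props)
  if (bsref <= 0) abort("NMSE undefined: single-class reference")
  brier_score(prob_matrix, truth) / bsref
}

#' Misclassification error rate
#'
#' @param pred_labels,true_labels Vectors of equal length.
#' @return Fraction of discordant positions in \[0, 1\].
#' @export
misclassification_error_rate <- function(pred_labels, true_labels) {
  stopifnot(length(pred_labels) == length(true_labels), length(true_labels) >= 1)
  mean(as.character(pred_labels) != as.character(true_labels))
}

#' F1 score (binary) or macro F1 (multiclass)
#'
#' For two levels, the second declared level is the positive class (a fixed
#' documented convention). For more than two levels, the unweighted mean of
#' per-class F1 is returned; a class with no predicted and no true positives
#' contributes an F1 of 0.
#'
#' @param pred_labels,true_labels Vectors of labels.
#' @param levels Character vector of declared levels (length >= 2).
#' @return Scalar in \[0, 1\].
#' @export
f1_scores <- function(pred_labels, true_labels, levels) {
  stopifnot(length(levels) >= 2)
  f1_one <- function(cls) {
    tp <- sum(pred_labels == cls & true_labels == cls)
    fp <- sum(pred_labels == cls & true_labels != cls)
    fn <- sum(pred_labels != cls & true_labels == cls)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  pred_labels <- as.character(pred_labels)
  true_labels <- as.character(true_labels)
  if (length(levels) == 2) f1_one(levels[2]) else mean(vapply(levels, f1_one, numeric(1)))
}

#' Weighted global NMSE
#'
#' The convergence statistic: \eqn{\sum_v w_v NMSE_v / \sum_v w_v}. By
#' default (in the imputer) each variable's weight is its proportion of
#' missing values; variables with an undefined NMSE must carry weight 0.
#'
#' @param per_var_nmse Named numeric vector of per-variable NMSE values.
#' @param weights Named non-negative weights; every weighted variable must
#'   appear in `per_var_nmse`.
#' @return Scalar within the range of the inputs.
#' @export
global_weighted_nmse <- function(per_var_nmse, weights) {
  stopifnot(all(weights >= 0))
  active <- names(weights)[weights > 0]
  if (length(active) == 0) abort("at least one weight must be positive")
  if (!all(active %in% names(per_var_nmse))) {
    abort("weighted variable missing from `per_var_nmse`")
  }
  w <- weights[active]
  sum(w * per_var_nmse[active]) / sum(w)
}

#' Brier skill score for binary outcome predictions
#'
#' `BSS = 1 - BS / BSref` with the two-class Brier score
#' `BS = mean(2 (p_i - y_i)^2)` and `BSref = 1 - p^2 - (1-p)^2` computed
#' from the train-set prevalence.
#'
#' @param pred_probs Predicted probabilities of the positive class.
#' @param outcomes 0/1 (or two-level factor) observed outcomes.
#' @param train_prevalence Positive-class proportion of the training set.
#' @return Scalar (1 = perfect, 0 = no better than the prevalence).
#' @export
evaluate_prediction_binary <- function(pred_probs, outcomes, train_prevalence) {
  if (train_prevalence <= 0 || train_prevalence >= 1) {
    abort("degenerate train prevalence")
  }
  y <- as_binary01(outcomes)
  stopifnot(all(pred_probs >= 0 & pred_probs <= 1))
  bs <- mean(2 * (pred_probs - y)^2)
  bsref <- 1 - train_prevalence^2 - (1 - train_prevalence)^2
  1 - bs / bsref
}

as_binary01 <- function(outcomes) {
  if (is.factor(outcomes)) {
    stopifnot(nlevels(outcomes) == 2)
    as.integer(outcomes) - 1L
  } else {
    stopifnot(all(outcomes %in% c(0, 1)))
    as.numeric(outcomes)
  }
}

#' R-squared of predictions against a train-set mean reference
#'
#' `1 - sum((y - yhat)^2) / sum((y - train_mean)^2)`.
#'
#' @param preds,outcomes Numeric vectors of equal length (>= 2).
#' @param train_mean Scalar mean of the training outcomes.
#' @return Scalar (can be negative for predictions worse than the mean).
#' @export
evaluate_prediction_continuous <- function(preds, outcomes, train_mean) {
  stopifnot(length(preds) == length(outcomes), length(outcomes) >= 2)
  denom <- sum((outcomes - train_mean)^2)
  if (denom <= 0) abort("zero outcome variance against the reference mean")
  1 - sum((outcomes - preds)^2) / denom
}
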