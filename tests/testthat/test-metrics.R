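test_that("continuous NMSE matches hand computations and the mean-imputation identity", {
  y <- c(0, 2)
  expect_equal(nmse_continuous(y, c(1, 1), 1), 1)
  expect_equal(nmse_continuous(y, y, 1), 0)
  set.seed(1)
  z <- rnorm(100)
  expect_equal(nmse_continuous(z, rep(mean(z), 100), mean(z)), 1)
  expect_error(nmse_continuous(c(1, 1), c(1, 1), 1), "zero reference")
})

test_that("continuous NMSE is invariant under a common location shift", {
  set.seed(2)
  y <- rnorm(30); p <- rnorm(30); m <- mean(y)
  expect_equal(nmse_continuous(y, p, m), nmse_continuous(y + 5, p + 5, m + 5))
})

test_that("Brier score and its reference match hand computations", {
  # one observation, truth class 1 of 2, prediction (0.8, 0.2)
  pm <- matrix(c(0.8, 0.2), 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(brier_score(pm, factor("a", levels = c("a", "b"))), 0.08)
  # constant (0.5, 0.5) predictions score 0.5 regardless of truth
  pm2 <- matrix(0.5, 4, 2, dimnames = list(NULL, c("a", "b")))
  truth <- factor(c("a", "b", "a", "b"))
  expect_equal(brier_score(pm2, truth), 0.5)
  # perfect one-hot
  expect_equal(brier_score(one_hot(truth), truth), 0)

  expect_equal(brier_reference(c(0.5, 0.5)), 0.5)
  expect_equal(brier_reference(1), 0)
  expect_equal(brier_reference(c(0.2, 0.3, 0.5)), 0.62)
})

test_that("categorical NMSE equals BS/BSref and is 1 for the proportion predictor", {
  pm <- matrix(c(0.8, 0.2), 1, dimnames = list(NULL, c("a", "b")))
  truth <- factor("a", levels = c("a", "b"))
  expect_equal(nmse_categorical(pm, truth, c(0.5, 0.5)), 0.16)
  # predicting the class proportions estimated on the same observations
  y <- factor(c("a", "a", "b", "b", "b"))
  props <- as.numeric(prop.table(table(y)))
  pm3 <- matrix(props, 5, 2, byrow = TRUE, dimnames = list(NULL, levels(y)))
  expect_equal(nmse_categorical(pm3, y, props), 1)
  expect_error(nmse_categorical(pm, truth, c(1, 0)), "single-class")
})

test_that("categorical NMSE plus BSS equals one on random inputs", {
  set.seed(3)
  for (i in 1:10) {
    n <- 50
    p <- runif(n)
    pm <- cbind(`0` = 1 - p, `1` = p)
    y <- factor(rbinom(n, 1, 0.4), levels = c(0, 1))
    props <- c(0.6, 0.4)
    nmse <- nmse_categorical(pm, y, props)
    bss <- 1 - brier_score(pm, y) / brier_reference(props)
    expect_equal(nmse + bss, 1)
  }
})

test_that("Brier score of the proportion predictor converges to the reference", {
  set.seed(4)
  props <- c(0.2, 0.3, 0.5)
  y <- factor(sample(letters[1:3], 2e4, TRUE, props), levels = letters[1:3])
  pm <- matrix(props, 2e4, 3, byrow = TRUE, dimnames = list(NULL, letters[1:3]))
  expect_equal(brier_score(pm, y), brier_reference(props), tolerance = 0.02)
})

test_that("misclassification rate and F1 scores match hand counts", {
  expect_equal(misclassification_error_rate(c("a", "b"), c("a", "b")), 0)
  expect_equal(misclassification_error_rate(c("a", "b"), c("b", "a")), 1)
  expect_equal(misclassification_error_rate(c("a", "a", "b", "b"),
                                            c("a", "b", "b", "b")), 0.25)
  # binary, positive class = second declared level
  expect_equal(f1_scores(c("a", "b", "b"), c("a", "b", "b"), c("a", "b")), 1)
  expect_equal(f1_scores(c("a", "a"), c("a", "b"), c("a", "b")), 0)
  # macro F1 with an absent class contributing zero
  expect_equal(f1_scores(c("a", "b", "c"), c("a", "b", "b"), c("a", "b", "c")),
               mean(c(1, 2 / 3, 0)))
})

test_that("global weighted NMSE is the weighted mean and stays within input range", {
  expect_equal(global_weighted_nmse(c(a = 0.7), c(a = 2)), 0.7)
  expect_equal(global_weighted_nmse(c(a = 1, b = 0.5), c(a = 0.3, b = 0.1)), 0.875)
  set.seed(5)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    vals <- rlang::set_names(runif(k, 0, 2), letters[1:k])
    w <- rlang::set_names(runif(k), letters[1:k])
    g <- global_weighted_nmse(vals, w)
    expect_equal(g, sum(vals * w) / sum(w)) # brute-force oracle
    expect_gte(g, min(vals))
    expect_lte(g, max(vals))
    expect_equal(global_weighted_nmse(vals, rlang::set_names(rep(1, k), names(vals))),
                 mean(vals))
  }
  expect_error(global_weighted_nmse(c(a = 1), c(a = 1, b = 1)), "missing from")
})

test_that("binary prediction evaluation matches the two-class Brier identity", {
  expect_equal(evaluate_prediction_binary(c(0.8, 0.2), c(1, 0), 0.5), 0.84)
  expect_equal(evaluate_prediction_binary(c(1, 0), c(1, 0), 0.5), 1)
  set.seed(6)
  y <- rbinom(500, 1, 0.3)
  expect_equal(evaluate_prediction_binary(rep(mean(y), 500), y, mean(y)), 0)
  expect_error(evaluate_prediction_binary(0.5, 1, 0), "degenerate")
})

test_that("continuous prediction evaluation is R-squared against the train mean", {
  y <- c(0, 2)
  expect_equal(evaluate_prediction_continuous(c(1, 1), y, 1), 0)
  expect_equal(evaluate_prediction_continuous(y, y, 1), 1)
})
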