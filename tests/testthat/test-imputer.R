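test_that("imputation sequence sorts by missingness with stable ties", {
  d <- tibble::tibble(a = c(1, NA, NA, 4, 5, NA, NA, NA, 9, 10), # 50%
                      b = c(1, 2, NA, 4, 5, 6, 7, 8, 9, 10),     # 10%
                      c = 1:10)                                   # 0%
  expect_equal(determine_sequence(d), c("c", "b", "a"))
  expect_equal(determine_sequence(d, order = "decreasing"), c("a", "b", "c"))
  expect_equal(determine_sequence(tibble::tibble(x = 1:3, y = 1:3)), c("x", "y"))
})

test_that("predictor screening honours the matrix and the usable-case thresholds", {
  mask <- cbind(y = c(FALSE, FALSE, TRUE, TRUE),
                x = c(TRUE, TRUE, FALSE, FALSE),
                z = c(FALSE, FALSE, FALSE, FALSE))
  # defaults exclude nothing
  expect_equal(select_predictors("y", mask, c("y", "x", "z")), c("x", "z"))
  # x is 100% missing among observed y -> dropped at p_obs 0.9
  expect_equal(select_predictors("y", mask, c("y", "x", "z"), p_obs = 0.9), "z")
  # x fully observed among missing y, z too; p_miss = 1 keeps both
  expect_equal(select_predictors("y", mask, c("y", "x", "z"), p_miss = 1),
               c("x", "z"))
  pm <- matrix(TRUE, 3, 3, dimnames = list(c("y", "x", "z"), c("y", "x", "z")))
  diag(pm) <- FALSE
  pm["y", "x"] <- FALSE
  expect_equal(select_predictors("y", mask, c("y", "x", "z"), predictor_matrix = pm),
               "z")
})

test_that("a strongly related predictor yields OOB NMSE below one at iteration 1", {
  d <- linked_pair(n = 800, r = 0.95, seed = 1)
  fit <- forest_impute(d, num_trees = 100, seed = 2)
  it1 <- fit$error_history[fit$error_history$iteration == 1 &
                             fit$error_history$variable == "y", ]
  expect_lt(it1$nmse_oob, 1)
  expect_gte(fit$n_iterations, 1)
})

test_that("a complete table is returned unchanged while models are still trained", {
  d <- tibble::tibble(x = rnorm(120), y = rnorm(120), z = rnorm(120))
  fit <- forest_impute(d, num_trees = 30, seed = 3)
  expect_equal(as.data.frame(fit$imputed), as.data.frame(d))
  it1 <- fit$error_history[fit$error_history$iteration == 1, ]
  expect_equal(sort(it1$variable), c("x", "y", "z"))
  expect_true(all(!is.na(it1$nmse_oob)))
})

test_that("transform replay reproduces the fit-time imputation exactly", {
  d <- sim_small(300, seed = 4)
  amp <- ampute(d, "MCAR", paste0("V", 1:4), outcome = "outcome", seed = 5)
  fit <- forest_impute(amp, outcome = "outcome", num_trees = 50, seed = 6)
  replay <- predict(fit, amp)
  expect_identical(as.data.frame(replay), as.data.frame(fit$imputed))
})

test_that("transform is row-independent and preserves observed cells", {
  d <- sim_small(250, seed = 7)
  amp <- ampute(d, "MCAR", paste0("V", 1:4), outcome = "outcome", seed = 8)
  fit <- forest_impute(amp, outcome = "outcome", num_trees = 40, seed = 9)
  new <- ampute(sim_small(40, seed = 10), "MCAR", paste0("V", 1:4),
                outcome = "outcome", seed = 11)
  whole <- predict(fit, new)
  by_row <- purrr::map_dfr(seq_len(nrow(new)),
                           function(i) predict(fit, new[i, , drop = FALSE]))
  expect_equal(as.data.frame(whole), as.data.frame(by_row))
  obs <- !is.na(new$V1)
  expect_identical(whole$V1[obs], new$V1[obs])
  # fully observed rows come back untouched
  complete_rows <- stats::complete.cases(new)
  expect_identical(as.data.frame(whole[complete_rows, ]),
                   as.data.frame(new[complete_rows, ]))
})

test_that("a row missing every variable is imputed from initialization plus replay", {
  d <- linked_pair(n = 400, seed = 12)
  fit <- forest_impute(d, num_trees = 40, seed = 13)
  allmiss <- tibble::tibble(x = NA_real_, y = NA_real_)
  out <- predict(fit, allmiss)
  expect_false(anyNA(out))
  # hand-step the replay loop with the stored models
  cur <- tibble::tibble(x = fit$initialization$x, y = fit$initialization$y)
  if (fit$n_iterations >= 1) {
    for (i in seq_len(fit$n_iterations)) {
      for (v in fit$sequence) {
        m <- fit$models[[i]][[v]]
        cur[[v]] <- as.numeric(predict(m$model, data = cur[m$predictors],
                                       num.threads = 1)$predictions)
      }
    }
  }
  expect_equal(out$x, cur$x)
  expect_equal(out$y, cur$y)
})

test_that("accepted-iteration global NMSE decreases strictly and matches the oracle", {
  d <- sim_small(400, rho = 0.7, seed = 14)
  amp <- ampute(d, "MCAR", paste0("V", 1:4), outcome = "outcome", seed = 15)
  fit <- forest_impute(amp, outcome = "outcome", num_trees = 60, seed = 16)
  h <- tidy(fit)
  gl <- unique(h[, c("iteration", "global_nmse_oob")])
  accepted <- gl$global_nmse_oob[gl$iteration <= fit$n_iterations]
  expect_true(all(diff(c(1, accepted)) < 0))
  # oracle: recompute each global value as the brute-force weighted mean
  w <- fit$config$var_weights
  for (i in gl$iteration) {
    per <- h[h$iteration == i, ]
    vals <- rlang::set_names(per$nmse_oob, per$variable)
    expect_equal(gl$global_nmse_oob[gl$iteration == i],
                 sum(w[names(vals)] * vals) / sum(w[names(vals)]))
  }
})

test_that("fixed_maxiter forces exactly maxiter accepted iterations", {
  d <- sim_small(200, seed = 17)
  amp <- ampute(d, "MCAR", paste0("V", 1:4), outcome = "outcome", seed = 18)
  fit <- forest_impute(amp, outcome = "outcome", num_trees = 20, maxiter = 3,
                       fixed_maxiter = TRUE, seed = 19)
  expect_equal(fit$n_iterations, 3)
  expect_equal(fit$n_iterations_ran, 3)
  expect_false(fit$converged)
  expect_equal(length(fit$models), 3)
})

test_that("with fixed maxiter 1 the pipeline is single-pass chained imputation", {
  d <- linked_pair(400, seed = 20)
  fit <- forest_impute(d, num_trees = 30, maxiter = 1, fixed_maxiter = TRUE,
                       seed = 21)
  expect_equal(fit$n_iterations, 1)
  expect_equal(length(fit$models[[1]]), 2)
})

test_that("categorical variables are imputed as argmax labels with probability forests", {
  set.seed(22)
  n <- 300
  x <- rnorm(n)
  g <- factor(ifelse(x + rnorm(n, 0, 0.4) > 0, "pos", "neg"),
              levels = c("neg", "pos"))
  d <- tibble::tibble(x = x, g = g)
  d$g[sample.int(n, 90)] <- NA
  fit <- forest_impute(d, num_trees = 80, seed = 23)
  expect_true(all(!is.na(fit$imputed$g)))
  expect_true(all(fit$imputed$g %in% c("neg", "pos")))
  h <- tidy(fit)
  g1 <- h[h$iteration == 1 & h$variable == "g", ]
  expect_lt(g1$nmse_oob, 1)     # signal present: beats class proportions
  expect_false(is.na(g1$mer))
  expect_false(is.na(g1$f1))
  # imputed labels mostly agree with the latent rule
  idx <- is.na(d$g)
  acc <- mean(fit$imputed$g[idx] == ifelse(x[idx] > 0, "pos", "neg"))
  expect_gt(acc, 0.7)
})

test_that("custom and median initialization feed the stored fills", {
  d <- tibble::tibble(a = c(1, 2, 100, NA), b = c(1, 2, 3, 4))
  fit <- forest_impute(d, initialization = "median/mode", num_trees = 10,
                       maxiter = 1, fixed_maxiter = TRUE, seed = 24)
  expect_equal(fit$initialization$a, 2)
  fit2 <- forest_impute(d, initialization = "custom",
                        custom_init = list(a = -5, b = 0), num_trees = 10,
                        maxiter = 1, fixed_maxiter = TRUE, seed = 24)
  expect_equal(fit2$initialization$a, -5)
})

test_that("a zero-variance variable keeps its initialization and weight zero", {
  d <- tibble::tibble(k = rep(1, 100),
                      x = rnorm(100), y = rnorm(100))
  d$x[1:30] <- NA
  fit <- forest_impute(d, num_trees = 20, seed = 25)
  expect_true(all(is.na(tidy(fit)$nmse_oob[tidy(fit)$variable == "k"])))
  expect_equal(unname(fit$config$var_weights["k"]), 0)
})

test_that("fit refuses a missing seed and transform refuses unseen levels", {
  d <- toy_mixed()
  expect_error(forest_impute(d), "seed")
  fit <- forest_impute(d, num_trees = 15, seed = 26)
  bad <- tibble::tibble(x = 1, y = 2, g = factor("zzz"))
  expect_error(predict(fit, bad), "unseen level")
  coerced <- predict(fit, bad, unseen_levels = "missing")
  expect_true(coerced$g %in% c("a", "b"))
  expect_error(predict(fit, tibble::tibble(x = 1)), "lacks fitted variable")
})

test_that("save/load round trip preserves transform output and refuses bad files", {
  d <- sim_small(150, seed = 27)
  amp <- ampute(d, "MCAR", paste0("V", 1:4), outcome = "outcome", seed = 28)
  fit <- forest_impute(amp, outcome = "outcome", num_trees = 20, seed = 29)
  path <- withr::local_tempfile(fileext = ".rds")
  save_imputer(fit, path)
  loaded <- load_imputer(path)
  expect_identical(as.data.frame(predict(loaded, amp)),
                   as.data.frame(predict(fit, amp)))
  # truncated file -> error, not a partial object
  raw <- readBin(path, "raw", n = file.size(path))
  half <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw[seq_len(length(raw) %/% 2)], half)
  expect_error(load_imputer(half), "cannot read|version mismatch")
  plain <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(version = "other"), plain)
  expect_error(load_imputer(plain), "version mismatch")
})

test_that("stored model size grows with the number of trees", {
  d <- linked_pair(300, seed = 30)
  f10 <- forest_impute(d, num_trees = 10, maxiter = 1, fixed_maxiter = TRUE, seed = 31)
  f100 <- forest_impute(d, num_trees = 100, maxiter = 1, fixed_maxiter = TRUE, seed = 31)
  p10 <- withr::local_tempfile(); p100 <- withr::local_tempfile()
  save_imputer(f10, p10); save_imputer(f100, p100)
  expect_gt(file.size(p100), file.size(p10))
})

test_that("tidy, glance and autoplot expose the error history", {
  d <- sim_small(200, seed = 32)
  amp <- ampute(d, "MCAR", paste0("V", 1:4), outcome = "outcome", seed = 33)
  fit <- forest_impute(amp, outcome = "outcome", num_trees = 20, seed = 34)
  h <- tidy(fit)
  expect_true(all(c("iteration", "variable", "nmse_oob", "nmse_apparent",
                    "global_nmse_oob") %in% names(h)))
  g <- glance(fit)
  expect_equal(g$n_variables, 4)
  expect_s3_class(autoplot(fit), "ggplot")
})
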