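# Small fixtures built in code.

toy_mixed <- function() {
  tibble::tibble(
    x = c(1, 2, NA, 4, 5),
    y = c(2.1, NA, 6.1, 8.2, 9.9),
    g = factor(c("a", "a", "b", NA, "a"), levels = c("a", "b"))
  )
}

# two strongly related continuous variables with MCAR missingness on one
linked_pair <- function(n = 600, r = 0.95, prop = 0.3, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- r * x + sqrt(1 - r^2) * rnorm(n)
  d <- tibble::tibble(x = x, y = y)
  d$y[sample.int(n, round(prop * n))] <- NA
  d
}

sim_small <- function(n = 400, rho = 0.7, seed = 1, n_noise = 0) {
  simulate_dataset(n, rho, beta = 0.45, intercept = -1.66,
                   n_noise = n_noise, seed = seed)
}
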