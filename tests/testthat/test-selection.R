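# Three-stage stepwise selection: OLS correctness against the
# normal-equations oracle, stepwise behaviour on simulated sparse truths,
# hierarchy preservation, and the PRESS/VIF diagnostics.

test_that("OLS matches exact cases and the normal-equations oracle", {
  x <- 1:20
  f <- ols_fit(cbind(`(Intercept)` = 0, x = x)[, 2, drop = FALSE], 2 * x)
  expect_equal(f$coefficients$estimate, 2)
  expect_equal(f$rss, 0, tolerance = 1e-20)
  y <- c(4, 6, 11)
  f0 <- ols_fit(matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)")), y)
  expect_equal(f0$coefficients$estimate, mean(y))
  set.seed(11)
  X <- cbind(1, matrix(rnorm(60), 20, 3))
  colnames(X) <- c("(Intercept)", "a", "b", "c")
  y <- rnorm(20)
  f <- ols_fit(X, y)
  oracle <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_lt(max(abs(f$coefficients$estimate - drop(oracle))), 1e-9)
  expect_error(ols_fit(cbind(X, dup = X[, "a"]), y), "singular")
})

test_that("stepwise main effects find a strong signal and ignore most noise", {
  hits_signal <- 0L; noise_picks <- 0L; n_seeds <- 25L
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    n <- 500
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("x", 1:6)))
    y <- X[, 1] + rnorm(n, sd = sqrt(1 / 10))
    ts <- stepwise_main_effects(y, X)
    if ("x1" %in% ts$mains) hits_signal <- hits_signal + 1L
    noise_picks <- noise_picks + length(setdiff(ts$mains, "x1"))
  }
  expect_equal(hits_signal, n_seeds)
  # each of the 5 noise covariates selected well under half the time
  expect_lt(noise_picks / (5 * n_seeds), 0.5)
})

test_that("all-noise candidates leave the intercept-only model most often", {
  sizes <- integer(20)
  for (s in seq_len(20)) {
    set.seed(100 + s)
    X <- matrix(rnorm(500 * 5), 500, 5,
                dimnames = list(NULL, paste0("x", 1:5)))
    y <- rnorm(500)
    sizes[s] <- length(stepwise_main_effects(y, X)$mains)
  }
  expect_equal(sort(unique(sizes))[1], 0L)
  expect_equal(as.integer(names(which.max(table(sizes)))), 0L)
})

test_that("stepwise search is deterministic", {
  set.seed(42)
  X <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 2] + rnorm(200)
  expect_identical(stepwise_main_effects(y, X),
                   stepwise_main_effects(y, X))
})

test_that("interaction stage recovers a product term and keeps hierarchy", {
  set.seed(7)
  n <- 500
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  sig <- X[, 1] * X[, 2] + X[, 1] + X[, 2]
  y <- sig + rnorm(n, sd = sqrt(var(sig) / 10))
  mains <- stepwise_main_effects(y, X)
  full <- add_interactions(y, X, mains)
  expect_true("x1:x2" %in% full$interactions)
  used <- unique(unlist(strsplit(full$interactions, ":")))
  expect_true(all(used %in% full$mains))
  # single main: no candidate pairs
  one <- term_set("x1")
  expect_identical(add_interactions(y, X, one), one)
})

test_that("backward pruning drops noise terms and never breaks hierarchy", {
  kept_sig <- 0L; dropped_noise <- 0L; n_seeds <- 30L
  for (s in seq_len(n_seeds)) {
    set.seed(200 + s)
    n <- 500
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "z")))
    y <- X[, "a"] + rnorm(n, sd = sqrt(1 / 10))
    ts <- term_set(c("a", "z"))
    pruned <- backward_prune(y, X, ts, p_exit = 0.05)
    if ("a" %in% pruned$mains) kept_sig <- kept_sig + 1L
    if (!("z" %in% pruned$mains)) dropped_noise <- dropped_noise + 1L
    used <- unique(unlist(strsplit(pruned$interactions, ":")))
    expect_true(all(used %in% pruned$mains))
  }
  expect_equal(kept_sig, n_seeds)
  expect_gte(dropped_noise / n_seeds, 0.85)
  expect_error(backward_prune(1, matrix(1), term_set(), p_exit = 2),
               "p_exit")
})

test_that("terms below the exit level survive pruning unchanged", {
  set.seed(13)
  n <- 300
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + 0.8 * X[, 2] + rnorm(n, sd = 0.3)
  ts <- term_set(c("a", "b"))
  expect_identical(backward_prune(y, X, ts, p_exit = 0.05), ts)
})

test_that("PRESS equals the explicit leave-one-out refit loop", {
  set.seed(14)
  n <- 25
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(n)
  dg <- diagnose(y, X, term_set(c("a", "b")))
  D <- cbind(1, X)
  press_loop <- sum(vapply(seq_len(n), function(i) {
    b <- solve(t(D[-i, ]) %*% D[-i, ]) %*% t(D[-i, ]) %*% y[-i]
    (y[i] - drop(D[i, ] %*% b))^2
  }, 0))
  expect_lt(abs(dg$press - press_loop), 1e-9)
})

test_that("orthonormal designs have unit VIFs and small condition numbers", {
  set.seed(15)
  Q <- qr.Q(qr(matrix(rnorm(100 * 3), 100, 3)))
  colnames(Q) <- c("a", "b", "c")
  dg <- diagnose(rnorm(100), Q, term_set(c("a", "b", "c")))
  expect_equal(unname(dg$vif), rep(1, 3), tolerance = 0.2)
  expect_false(dg$flags$vif)
})

test_that("the full three-stage procedure runs clean on random data", {
  # the AIC path monotonicity is asserted inside every stepwise move; this
  # exercises it over several random datasets
  for (s in 1:5) {
    set.seed(300 + s)
    X <- matrix(rnorm(300 * 6), 300, 6,
                dimnames = list(NULL, paste0("x", 1:6)))
    y <- X[, 1] - X[, 3] + rnorm(300, sd = 0.5)
    res <- select_terms(y, X)
    expect_s3_class(res$terms, "mob_term_set")
    used <- unique(unlist(strsplit(res$terms$interactions, ":")))
    expect_true(all(used %in% res$terms$mains))
  }
})
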