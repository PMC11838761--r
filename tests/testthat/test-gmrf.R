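# Structure matrices, constraint handling, and exactness of the Gaussian
# engine against an independent covariance-domain dense oracle.

test_that("ICAR structure matches its definition on a path graph", {
  adj <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"))
  blk <- icar_structure(adj)
  expect_equal(as.matrix(blk$structure),
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3),
               ignore_attr = TRUE)
  expect_equal(blk$rank_deficiency, 1L)
})

test_that("ICAR rows sum to zero and null space tracks graph components", {
  for (seed in 1:5) {
    adj <- random_connected_adjacency(8, seed = seed)
    # split into two components by removing node N01's edges beyond a subset
    ids <- sprintf("N%02d", 1:10)  # two extra isolated nodes
    blk <- icar_structure(adj, ids = ids)
    expect_true(all(abs(Matrix::rowSums(blk$structure)) < 1e-12))
    ev <- eigen(as.matrix(blk$structure), symmetric = TRUE,
                only.values = TRUE)$values
    nullity <- sum(abs(ev) < 1e-9 * max(abs(ev), 1))
    comp_oracle <- bfs_components(ids, adj)
    expect_equal(nullity, max(comp_oracle))
    expect_equal(blk$rank_deficiency, max(comp_oracle))
    expect_equal(unname(blk$components), unname(comp_oracle[blk$ids]))
  }
})

test_that("scaled ICAR has unit geometric-mean marginal variance per component", {
  adj <- random_connected_adjacency(7, seed = 3)
  blk <- scale_icar(icar_structure(adj))
  # pseudo-inverse oracle on the scaled structure
  S <- as.matrix(blk$structure)
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > 1e-9 * max(e$values)
  margvar <- rowSums(sweep(e$vectors[, pos]^2, 2, e$values[pos], "/"))
  expect_equal(exp(mean(log(margvar))), 1, tolerance = 1e-6)
  # idempotence
  blk2 <- scale_icar(blk)
  expect_lt(max(abs(blk2$structure - blk$structure)), 1e-10)
})

test_that("disconnected ICAR is scaled per component", {
  adj <- rbind(data.frame(id_a = c("a", "b"), id_b = c("b", "c")),
               data.frame(id_a = c("x", "y"), id_b = c("y", "z")))
  blk <- scale_icar(icar_structure(adj))
  S <- as.matrix(blk$structure)
  for (grp in list(1:3, 4:6)) {
    e <- eigen(S[grp, grp], symmetric = TRUE)
    pos <- e$values > 1e-9 * max(e$values)
    mv <- rowSums(sweep(e$vectors[, pos, drop = FALSE]^2, 2,
                        e$values[pos], "/"))
    expect_equal(exp(mean(log(mv))), 1, tolerance = 1e-6)
  }
})

test_that("BYM2 limits are exact and mid-phi marginal variance is 1/tau", {
  adj <- random_connected_adjacency(6, seed = 5)
  scaled <- scale_icar(icar_structure(adj))
  n <- nrow(scaled$structure)
  r0 <- bym2_effect(scaled, tau = 3, phi = 0)
  expect_equal(as.matrix(r0$precision), diag(3, n))
  r1 <- bym2_effect(scaled, tau = 3, phi = 1)
  expect_equal(as.matrix(r1$precision), 3 * as.matrix(scaled$structure))
  # sampling oracle: draw (b, u) from the joint under constraints by
  # conditioning the dense covariance, check var(b) ~ 1/tau
  rep_ <- bym2_effect(scaled, tau = 2, phi = 0.5)
  Q <- as.matrix(rep_$precision); C <- as.matrix(rep_$constraints)
  sv <- svd(C, nu = 0, nv = ncol(Q))
  V <- sv$v[, (sum(sv$d > 1e-10) + 1):ncol(Q)]
  Sig <- V %*% solve(crossprod(V, Q %*% V)) %*% t(V)
  mv <- mean(diag(Sig)[seq_len(n)])  # typical marginal variance of b
  expect_lt(abs(mv - 0.5), 0.1)      # 1/tau up to the geometric-mean scaling
  expect_error(bym2_effect(scaled, tau = -1, phi = 0.5), "tau")
  expect_error(bym2_effect(scaled, tau = 1, phi = 2), "phi")
})

test_that("AR1 precision is tridiagonal with inverse rho^|i-j|/tau", {
  blk <- ar1_precision(4, rho = 0.6, tau = 2.5)
  Qi <- solve(as.matrix(blk$structure))
  expect_equal(Qi, outer(1:4, 1:4, function(i, j) 0.6^abs(i - j)) / 2.5,
               tolerance = 1e-10, ignore_attr = TRUE)
  Q0 <- ar1_precision(5, rho = 0, tau = 3)
  expect_equal(as.matrix(Q0$structure), diag(3, 5))
  Q <- as.matrix(ar1_precision(9, rho = 0.7)$structure)
  expect_true(all(Q[abs(row(Q) - col(Q)) > 1] == 0))
  expect_error(ar1_precision(4, rho = 1.2), "rho")
})

test_that("interaction structures: identity (I) and Kronecker pattern (IV)", {
  adj <- random_connected_adjacency(5, seed = 2)
  scaled <- scale_icar(icar_structure(adj))
  ar <- ar1_precision(6, rho = 0.5)
  b1 <- interaction_block(scaled, ar, "I")
  expect_equal(as.matrix(b1$structure), diag(30))
  ar0 <- ar1_precision(6, rho = 0)
  b40 <- interaction_block(scaled, ar0, "IV")
  S <- as.matrix(scaled$structure)
  expect_equal(as.matrix(b40$structure),
               as.matrix(Matrix::bdiag(rep(list(S), 6))),
               ignore_attr = TRUE)
  b4 <- interaction_block(scaled, ar, "IV")
  kron_oracle <- kronecker(as.matrix(ar$structure) / ar$tau, S)
  expect_equal(as.matrix(b4$structure), kron_oracle, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(b4$rank_deficiency, 6L)
})

test_that("assembled latent dimension and prior bookkeeping are exact", {
  rs <- random_small_model(seed = 4, n_area = 5, n_time = 6, k = 3)
  m <- rs$model
  expect_equal(m$N, 3L + 2L * 5L + 6L + 30L)
  expect_equal(m$n_obs, length(rs$y))
  # no blocks: prior is the fixed-effect ridge only
  X <- cbind(`(Intercept)` = rep(1, 10), x = rnorm(10))
  m0 <- assemble_model(X)
  expect_equal(m0$N, 2L)
  expect_null(m0$C)
})

test_that("posterior matches the dense covariance-domain oracle", {
  for (seed in 1:4) {
    it <- if (seed %% 2 == 0) "IV" else "I"
    rs <- random_small_model(seed = seed, n_area = 6, n_time = 8, k = 3,
                             interaction = it, n_obs = 70)
    expect_lte(rs$model$N, 200)
    post <- posterior_given_hyper(rs$model, rs$y, rs$hyper)
    oracle <- oracle_dense_posterior(rs$model, rs$y, rs$hyper)
    expect_lt(max(abs(post$mean - oracle$mean)), 1e-8)
    expect_lt(max(abs(post$sd - oracle$sd)), 1e-8)
    expect_lt(abs(post$logml - oracle$logml) / max(1, abs(oracle$logml)),
              1e-8)
  }
})

test_that("with no random blocks the posterior equals the ridge closed form", {
  set.seed(9)
  n <- 40; k <- 4
  X <- cbind(1, matrix(rnorm(n * (k - 1)), n))
  colnames(X) <- c("(Intercept)", paste0("x", 1:(k - 1)))
  y <- rnorm(n)
  tau <- 3.7
  model <- assemble_model(X)
  post <- posterior_given_hyper(model, y, list(tau_eps = tau, blocks = list()))
  ridge <- solve(tau * crossprod(X) + diag(0.001, k), tau * crossprod(X, y))
  expect_lt(max(abs(post$mean - drop(ridge))), 1e-10)
})

test_that("posterior means respect the sum-to-zero constraints", {
  for (seed in 5:7) {
    rs <- random_small_model(seed = seed, interaction = "IV")
    post <- posterior_given_hyper(rs$model, rs$y, rs$hyper)
    resid <- as.matrix(rs$model$C %*% post$mean)
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("a directly observed cell's posterior mean approaches the datum as noise vanishes", {
  set.seed(11)
  blocks <- list(iid = latent_block_iid(6, "iid"))
  X <- matrix(0, 6, 1, dimnames = list(NULL, "(Intercept)"))
  model <- assemble_model(X, blocks, list(iid = 1:6))
  y <- rnorm(6)
  post <- posterior_given_hyper(
    model, y, list(tau_eps = 1e10, blocks = list(iid = list(tau = 2))))
  fitted <- drop(as.matrix(model$A %*% post$mean))
  expect_lt(max(abs(fitted - y)), 1e-6)
})

test_that("unobserved latent cells keep their prior marginals", {
  set.seed(21)
  # iid block of 6 cells, observe only cells 1..3
  blocks <- list(iid = latent_block_iid(6, "iid"))
  X <- matrix(0, 3, 1, dimnames = list(NULL, "(Intercept)"))
  model <- assemble_model(X, blocks, list(iid = 1:3))
  y <- rnorm(3)
  h <- list(tau_eps = 5, blocks = list(iid = list(tau = 2)))
  post <- posterior_given_hyper(model, y, h)
  expect_equal(post$mean[1 + 4:6], rep(0, 3))
  expect_equal(post$sd[1 + 4:6], rep(1 / sqrt(2), 3), tolerance = 1e-10)
})

test_that("empirical Bayes is deterministic, ascends, and recovers the noise precision", {
  set.seed(31)
  n <- 400
  X <- cbind(1, rnorm(n)); colnames(X) <- c("(Intercept)", "x")
  tau_true <- 25
  hits <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    y <- drop(X %*% c(0.3, 1)) + rnorm(n, sd = 1 / sqrt(tau_true))
    model <- assemble_model(X)
    f1 <- fit_empirical_bayes(model, y)
    f2 <- fit_empirical_bayes(model, y)
    expect_identical(f1$theta, f2$theta)
    init_val <- posterior_given_hyper(model, y, f1$init,
                                      need_sd = FALSE)$logml
    expect_gte(f1$logml, init_val - 1e-8)
    if (abs(f1$hyper$tau_eps - tau_true) / tau_true < 0.15) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
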