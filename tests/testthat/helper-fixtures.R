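# Shared fixtures: small geographies, random graphs, and a covariance-domain
# dense oracle for the latent-Gaussian engine. The oracle works entirely in
# the covariance domain (explicit inverses, marginal Gaussian density),
# independent of the engine's reduced-precision route.

tiny_geo <- function(seed = 7) generate_geography(1, 2, 4, seed = seed)

random_connected_adjacency <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  # random spanning tree plus extra random edges
  perm <- sample(n)
  edges <- cbind(perm[-1], perm[vapply(2:n, function(i) sample(i - 1, 1), 0L)])
  more <- cbind(sample(n, extra, replace = TRUE),
                sample(n, extra, replace = TRUE))
  e <- rbind(edges, more)
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  ids <- sprintf("N%02d", seq_len(n))
  data.frame(id_a = pmin(ids[e[, 1]], ids[e[, 2]]),
             id_b = pmax(ids[e[, 1]], ids[e[, 2]]),
             stringsAsFactors = FALSE)
}

# brute-force connected components by breadth-first search (test oracle)
bfs_components <- function(ids, adjacency) {
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  cc <- 0L
  for (s in ids) {
    if (!is.na(comp[s])) next
    cc <- cc + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cc
      nb <- c(adjacency$id_b[adjacency$id_a == v],
              adjacency$id_a[adjacency$id_b == v])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

# full prior precision + constraints of an assembled model at given
# hyperparameters, built from the concrete block constructors (not from the
# model's own parametrized pieces)
oracle_full_prior <- function(model, hyper) {
  N <- model$N
  Q <- matrix(0, N, N)
  Q[seq_len(model$k_fixed), seq_len(model$k_fixed)] <-
    diag(model$beta_prec, model$k_fixed)
  Crows <- list()
  for (nm in names(model$blocks)) {
    b <- model$blocks[[nm]]
    off <- model$offsets[[nm]]
    par <- hyper$blocks[[nm]]
    if (b$kind == "bym2") {
      ucols <- b$effect_dim + seq_len(b$effect_dim)
      scaled <- list(structure = b$pieces$uu_s[ucols, ucols, drop = FALSE],
                     constraints = b$constraints[, ucols, drop = FALSE])
      rep_ <- bym2_effect(scaled, par$tau, par$phi)
      Qb <- as.matrix(rep_$precision)
      Cb <- as.matrix(rep_$constraints)
    } else if (b$kind == "ar1") {
      Qb <- as.matrix(ar1_precision(b$size, par$rho, par$tau)$structure)
      Cb <- NULL
    } else if (b$kind %in% c("iid", "interaction1")) {
      Qb <- diag(par$tau, b$size)
      Cb <- NULL
    } else if (b$kind == "interaction4") {
      Qb <- par$tau * as.matrix(b$pieces$t0 +
                                  par$rho^2 * b$pieces$t1 -
                                  par$rho * b$pieces$t2) / (1 - par$rho^2)
      Cb <- as.matrix(b$constraints)
    } else stop("unknown block kind")
    idx <- off + seq_len(b$size)
    Q[idx, idx] <- Qb
    if (!is.null(Cb)) {
      Cfull <- matrix(0, nrow(Cb), N)
      Cfull[, idx] <- Cb
      Crows[[length(Crows) + 1L]] <- Cfull
    }
  }
  list(Q = Q, C = if (length(Crows)) do.call(rbind, Crows) else NULL)
}

# covariance-domain posterior: prior covariance from the SVD null space of
# the constraints, marginal likelihood from the observation covariance
oracle_dense_posterior <- function(model, y, hyper) {
  fp <- oracle_full_prior(model, hyper)
  N <- model$N
  V <- if (is.null(fp$C)) diag(N) else {
    sv <- svd(fp$C, nu = 0, nv = N)
    r <- sum(sv$d > max(sv$d) * 1e-10)
    sv$v[, (r + 1):N, drop = FALSE]
  }
  Sigma <- V %*% solve(crossprod(V, fp$Q %*% V)) %*% t(V)
  A <- as.matrix(model$A)
  Sy <- A %*% Sigma %*% t(A) + diag(1 / hyper$tau_eps, nrow(A))
  chy <- chol(Sy)
  alpha <- backsolve(chy, forwardsolve(t(chy), y))
  logml <- -0.5 * length(y) * log(2 * pi) - sum(log(diag(chy))) -
    0.5 * sum(y * alpha)
  SA <- Sigma %*% t(A)
  mean_post <- drop(SA %*% alpha)
  W <- backsolve(chy, forwardsolve(t(chy), t(SA)))
  cov_post <- Sigma - SA %*% W
  list(mean = mean_post, sd = sqrt(pmax(diag(cov_post), 0)), logml = logml)
}

# small random latent model over a random graph, with responses
random_small_model <- function(seed = 1, n_area = 6, n_time = 8, k = 3,
                               interaction = "IV", n_obs = 60) {
  set.seed(seed)
  adj <- random_connected_adjacency(n_area, seed = seed + 100)
  ids <- sprintf("N%02d", seq_len(n_area))
  scaled <- scale_icar(icar_structure(adj, ids = ids))
  blocks <- list(
    spatial = latent_block_bym2(scaled, "spatial"),
    temporal = latent_block_ar1(n_time, "temporal"),
    interaction = latent_block_interaction(scaled, n_time, interaction,
                                           "interaction"))
  cells_all <- expand.grid(a = seq_len(n_area), t = seq_len(n_time))
  pick <- sample(nrow(cells_all), n_obs, replace = TRUE)
  a <- cells_all$a[pick]; t <- cells_all$t[pick]
  X <- cbind(1, matrix(rnorm(n_obs * (k - 1)), n_obs, k - 1))
  colnames(X) <- c("(Intercept)", sprintf("x%d", seq_len(k - 1)))
  cells <- list(spatial = a, temporal = t,
                interaction = (t - 1L) * n_area + a)
  model <- assemble_model(X, blocks, cells)
  y <- rnorm(n_obs)
  hyper <- list(tau_eps = exp(runif(1, 0, 2)),
                blocks = list(
                  spatial = list(tau = exp(runif(1, 0, 2)),
                                 phi = runif(1, 0.2, 0.8)),
                  temporal = list(tau = exp(runif(1, 0, 2)),
                                  rho = runif(1, -0.7, 0.7)),
                  interaction = if (interaction == "IV")
                    list(tau = exp(runif(1, 0, 2)), rho = runif(1, -0.7, 0.7))
                  else list(tau = exp(runif(1, 0, 2)))))
  list(model = model, y = y, hyper = hyper)
}
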