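# Sparse-precision machinery for the random-effect blocks (ICAR/BYM2, AR1,
# space-time interaction) and the exact Gaussian latent posterior given
# hyperparameters. For a Gaussian response the latent posterior is exactly
# Gaussian, so empirical Bayes (modal hyperparameters + exact conditional
# posterior) replaces approximate integration.
#
# Sum-to-zero constraints are handled by exact null-space reparametrization:
# an orthonormal basis Z of {x : Cx = 0} is built once per model (block by
# block, since every constraint touches a single block), and all solves run
# on the reduced precision Z'QZ, which is proper even though ICAR and
# type-IV interaction priors are intrinsic. Prior precisions are linear
# combinations of constant sparse pieces, so the reduced pieces are
# precomputed once and each hyperparameter evaluation only reassembles small
# dense blocks.

#' Intrinsic CAR (ICAR) structure matrix from an adjacency
#'
#' Q = D - W (degree minus adjacency). Rows sum to zero; the null space is
#' spanned by the indicator of each connected component, so one sum-to-zero
#' constraint per component is attached.
#'
#' @param adjacency data.frame with columns \code{id_a}, \code{id_b}
#'   (undirected edges, no self-edges).
#' @param ids optional full node set (nodes without edges become singleton
#'   components); default: all ids appearing in edges.
#' @return object of class \code{mob_precision_block}: sparse
#'   \code{structure}, \code{constraints} (one row per component),
#'   \code{rank_deficiency}, \code{ids}, \code{components}.
#' @export
icar_structure <- function(adjacency, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(adjacency$id_a, adjacency$id_b)))
  if (!length(ids)) stop("empty graph", call. = FALSE)
  keep <- adjacency$id_a %in% ids & adjacency$id_b %in% ids
  adjacency <- adjacency[keep, , drop = FALSE]
  if (any(adjacency$id_a == adjacency$id_b))
    stop("self-edges are not allowed", call. = FALSE)
  n <- length(ids)
  i <- match(adjacency$id_a, ids); j <- match(adjacency$id_b, ids)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n))
  W@x[] <- 1  # collapse duplicate edges
  Q <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[i], to = ids[j]), directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  k <- max(comp)
  C <- Matrix::sparseMatrix(i = comp, j = seq_len(n), x = 1, dims = c(k, n))
  structure(list(label = "spatial", structure = methods::as(Q, "CsparseMatrix"),
                 constraints = C, rank_deficiency = k, ids = ids,
                 components = unname(comp), scaled = FALSE),
            class = "mob_precision_block")
}

#' Scale an ICAR structure to unit typical marginal variance
#'
#' Multiplies each connected component's structure by the geometric mean of
#' its constrained generalized-inverse marginal variances, the convention
#' the BYM2 reparametrization requires so the mixing parameter is
#' interpretable. Idempotent.
#'
#' @param block an ICAR \code{mob_precision_block}.
#' @return the block with scaled structure and \code{scaled = TRUE}.
#' @export
scale_icar <- function(block) {
  Q <- as.matrix(block$structure)
  comp <- block$components
  for (cc in unique(comp)) {
    sel <- which(comp == cc)
    if (length(sel) == 1L) next  # singleton pinned at zero; nothing to scale
    e <- eigen(Q[sel, sel, drop = FALSE], symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-9
    margvar <- rowSums(sweep(e$vectors[, pos, drop = FALSE]^2, 2,
                             e$values[pos], "/"))
    s <- exp(mean(log(margvar)))
    Q[sel, sel] <- Q[sel, sel] * s
  }
  block$structure <- methods::as(Matrix::Matrix(Q, sparse = TRUE),
                                 "CsparseMatrix")
  block$scaled <- TRUE
  block
}

#' Evaluate the BYM2 joint representation at given hyperparameters
#'
#' The area effect is b = (sqrt(1 - phi) v + sqrt(phi) u) / sqrt(tau) with v
#' iid standard normal and u the unit-scaled ICAR component, so b has
#' marginal variance ~ 1/tau for every phi. For 0 < phi < 1 the returned
#' representation is the joint precision of (b, u) with the observation map
#' touching b only; the limits are exact: phi = 0 is a pure iid effect with
#' precision tau, phi = 1 the pure scaled ICAR.
#'
#' @param scaled a scaled ICAR block (\code{\link{scale_icar}}).
#' @param tau total precision (> 0).
#' @param phi mixing parameter in [0, 1].
#' @return list: \code{precision} (latent), \code{effect_map} (effect cells x
#'   latent), \code{constraints}, \code{size}.
#' @export
bym2_effect <- function(scaled, tau, phi) {
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (!is.numeric(phi) || phi < 0 || phi > 1)
    stop("`phi` must lie in [0, 1]", call. = FALSE)
  n <- nrow(scaled$structure)
  if (phi == 0) {
    return(list(precision = Matrix::Diagonal(n, tau),
                effect_map = Matrix::Diagonal(n), constraints = NULL,
                size = n))
  }
  if (phi == 1) {
    return(list(precision = tau * scaled$structure,
                effect_map = Matrix::Diagonal(n),
                constraints = scaled$constraints, size = n))
  }
  I <- Matrix::Diagonal(n)
  Qbb <- (tau / (1 - phi)) * I
  Qbu <- (-sqrt(tau * phi) / (1 - phi)) * I
  Quu <- scaled$structure + (phi / (1 - phi)) * I
  Q <- rbind(cbind(Qbb, Qbu), cbind(Matrix::t(Qbu), Quu))
  C <- cbind(Matrix::Matrix(0, nrow(scaled$constraints), n, sparse = TRUE),
             scaled$constraints)
  list(precision = methods::as(Q, "CsparseMatrix"),
       effect_map = cbind(I, Matrix::Matrix(0, n, n, sparse = TRUE)),
       constraints = C, size = 2L * n)
}

#' Stationary AR1 precision matrix
#'
#' Tridiagonal precision of the stationary first-order autoregression with
#' lag-1 correlation rho and marginal precision tau (marginal variance
#' 1/tau): the inverse has entries rho^|i-j| / tau.
#'
#' @param n number of time points (>= 2).
#' @param rho lag-1 correlation, |rho| < 1.
#' @param tau marginal precision (> 0).
#' @return a \code{mob_precision_block} with fields \code{tau}, \code{rho}.
#' @export
ar1_precision <- function(n, rho, tau = 1) {
  if (n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  d <- c(1, rep(1 + rho^2, n - 2L), 1)
  Q <- Matrix::bandSparse(
    n, k = c(0, 1),
    diagonals = list(d, rep(-rho, n - 1L)), symmetric = TRUE)
  structure(list(label = "temporal",
                 structure = methods::as((tau / (1 - rho^2)) * Q,
                                         "CsparseMatrix"),
                 constraints = NULL, rank_deficiency = 0L,
                 ids = seq_len(n), tau = tau, rho = rho),
            class = "mob_precision_block")
}

#' Space-time interaction structure
#'
#' Type I is exchangeable: an identity structure over the (area, time)
#' cells. Type IV is the fully structured interaction: the Kronecker product
#' of the AR1 structure (unit marginal variance) and the ICAR structure,
#' with one induced sum-over-areas constraint per (time point, spatial
#' component). Cells are ordered time-major: cell index = (t - 1) *
#' n_area + a.
#'
#' @param spatial an ICAR \code{mob_precision_block} (scaled for type IV).
#' @param temporal an AR1 \code{mob_precision_block}.
#' @param type \code{"I"} or \code{"IV"}.
#' @return a \code{mob_precision_block} over the n_area * n_time cells.
#' @export
interaction_block <- function(spatial, temporal, type = c("I", "IV")) {
  type <- match.arg(type)
  nA <- nrow(spatial$structure); nT <- nrow(temporal$structure)
  if (type == "I") {
    return(structure(list(label = "interaction",
                          structure = Matrix::Diagonal(nA * nT),
                          constraints = NULL, rank_deficiency = 0L,
                          n_area = nA, n_time = nT, type = "I"),
                     class = "mob_precision_block"))
  }
  Tunit <- temporal$structure / temporal$tau  # unit-marginal-variance AR1
  Q <- Matrix::kronecker(Tunit, spatial$structure)
  comp <- spatial$components
  k <- max(comp)
  # sum over areas of each component, at each time point
  ii <- as.vector(outer(comp, (seq_len(nT) - 1L) * k, `+`))
  jj <- as.vector(outer(seq_len(nA), (seq_len(nT) - 1L) * nA, `+`))
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nT * k, nA * nT))
  structure(list(label = "interaction",
                 structure = methods::as(Q, "CsparseMatrix"),
                 constraints = C, rank_deficiency = nT * k,
                 n_area = nA, n_time = nT, type = "IV",
                 rho = temporal$rho),
            class = "mob_precision_block")
}

# ---- parametrized latent blocks (precision = sum of coef(par) * pieces) ----

latent_block <- function(label, kind, size, effect_dim, pieces, coef,
                         par_names, constraints, effect_map, ids = NULL) {
  list(label = label, kind = kind, size = as.integer(size),
       effect_dim = as.integer(effect_dim),
       pieces = lapply(pieces, function(p) methods::as(p, "CsparseMatrix")),
       coef = coef, par_names = par_names, constraints = constraints,
       effect_map = methods::as(effect_map, "CsparseMatrix"), ids = ids)
}

#' Parametrized BYM2 latent block for model assembly
#' @param scaled a scaled ICAR block.
#' @param label block label (must be unique within a model).
#' @return a latent block whose precision is assembled at fit time from
#'   (tau, phi).
#' @export
latent_block_bym2 <- function(scaled, label = "spatial") {
  n <- nrow(scaled$structure)
  I <- Matrix::Diagonal(n)
  Z0 <- Matrix::Matrix(0, n, n, sparse = TRUE)
  pieces <- list(
    bb = rbind(cbind(I, Z0), cbind(Z0, Z0)),
    bu = rbind(cbind(Z0, I), cbind(I, Z0)),
    uu_s = rbind(cbind(Z0, Z0), cbind(Z0, scaled$structure)),
    uu_i = rbind(cbind(Z0, Z0), cbind(Z0, I)))
  C <- cbind(Matrix::Matrix(0, nrow(scaled$constraints), n, sparse = TRUE),
             scaled$constraints)
  latent_block(label, "bym2", 2L * n, n, pieces,
               coef = function(par) {
                 tau <- par$tau; phi <- par$phi
                 c(tau / (1 - phi), -sqrt(tau * phi) / (1 - phi), 1,
                   phi / (1 - phi))
               },
               par_names = c("tau", "phi"), constraints = C,
               effect_map = cbind(I, Z0), ids = scaled$ids)
}

#' Parametrized stationary AR1 latent block
#' @param n_time number of time points.
#' @param label block label.
#' @return a latent block assembled at fit time from (tau, rho).
#' @export
latent_block_ar1 <- function(n_time, label = "temporal") {
  I <- Matrix::Diagonal(n_time)
  Dint <- Matrix::Diagonal(n_time, c(0, rep(1, n_time - 2L), 0))
  Off <- Matrix::bandSparse(n_time, k = 1,
                            diagonals = list(rep(1, n_time - 1L)),
                            symmetric = TRUE)
  latent_block(label, "ar1", n_time, n_time,
               pieces = list(I = I, interior = Dint, off = Off),
               coef = function(par) {
                 tau <- par$tau; rho <- par$rho
                 (tau / (1 - rho^2)) * c(1, rho^2, -rho)
               },
               par_names = c("tau", "rho"), constraints = NULL,
               effect_map = I, ids = seq_len(n_time))
}

#' Parametrized iid latent block
#' @param n block size.
#' @param label block label.
#' @export
latent_block_iid <- function(n, label = "iid") {
  I <- Matrix::Diagonal(n)
  latent_block(label, "iid", n, n, pieces = list(I = I),
               coef = function(par) par$tau, par_names = "tau",
               constraints = NULL, effect_map = I)
}

#' Parametrized space-time interaction latent block
#'
#' Type I is iid over the (area, time) cells (precision tau * I); type IV
#' assembles tau/(1 - rho^2) times the Kronecker of the AR1 structure with
#' the scaled ICAR structure, with the induced per-time sum-to-zero
#' constraints. Cells are time-major.
#'
#' @param scaled scaled ICAR block over the areas.
#' @param n_time number of time points.
#' @param type "I" or "IV".
#' @param label block label.
#' @export
latent_block_interaction <- function(scaled, n_time, type = c("I", "IV"),
                                     label = "interaction") {
  type <- match.arg(type)
  nA <- nrow(scaled$structure)
  N <- nA * n_time
  if (type == "I") {
    blk <- latent_block_iid(N, label)
    blk$kind <- "interaction1"
    return(blk)
  }
  I_T <- Matrix::Diagonal(n_time)
  Dint <- Matrix::Diagonal(n_time, c(0, rep(1, n_time - 2L), 0))
  Off <- Matrix::bandSparse(n_time, k = 1,
                            diagonals = list(rep(1, n_time - 1L)),
                            symmetric = TRUE)
  S <- scaled$structure
  comp <- scaled$components
  k <- max(comp)
  ii <- as.vector(outer(comp, (seq_len(n_time) - 1L) * k, `+`))
  jj <- as.vector(outer(seq_len(nA), (seq_len(n_time) - 1L) * nA, `+`))
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n_time * k, N))
  latent_block(label, "interaction4", N, N,
               pieces = list(t0 = Matrix::kronecker(I_T, S),
                             t1 = Matrix::kronecker(Dint, S),
                             t2 = Matrix::kronecker(Off, S)),
               coef = function(par) {
                 tau <- par$tau; rho <- par$rho
                 (tau / (1 - rho^2)) * c(1, rho^2, -rho)
               },
               par_names = c("tau", "rho"), constraints = C,
               effect_map = Matrix::Diagonal(N))
}

#' Assemble a latent Gaussian model
#'
#' Joins the fixed-effect design (independent zero-mean Gaussian prior with
#' precision 0.001 per coefficient) with the random-effect blocks into one
#' latent vector, and builds the sparse observation matrix mapping the
#' latent field to each observed response. Missing responses never enter the
#' likelihood; they are reached through prediction functionals.
#'
#' @param X dense fixed-effect design (n_obs x k), intercept included.
#' @param blocks named list of latent blocks.
#' @param cells named list (same names as \code{blocks}) of integer vectors,
#'   length n_obs: which effect cell of each block an observation touches.
#' @param beta_prec prior precision of the fixed effects (default 0.001).
#' @return object of class \code{mob_latent_model}.
#' @export
assemble_model <- function(X, blocks = list(), cells = list(),
                           beta_prec = 0.001) {
  k <- ncol(X); n_obs <- nrow(X)
  if (!identical(sort(names(blocks)), sort(names(cells))) &&
      (length(blocks) || length(cells)))
    stop("`blocks` and `cells` must share names", call. = FALSE)
  sizes <- vapply(blocks, `[[`, 0L, "size")
  offsets <- c(fixed = 0L,
               stats::setNames(k + c(0L, cumsum(sizes))[seq_along(blocks)],
                               names(blocks)))
  N <- k + sum(sizes)
  Aparts <- list(methods::as(Matrix::Matrix(X, sparse = TRUE),
                             "CsparseMatrix"))
  Cparts <- list()
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    idx <- cells[[nm]]
    if (length(idx) != n_obs || any(idx < 1L | idx > b$effect_dim))
      stop("cell index mismatch while assembling block '", nm, "'",
           call. = FALSE)
    sel <- Matrix::sparseMatrix(i = seq_len(n_obs), j = idx, x = 1,
                                dims = c(n_obs, b$effect_dim))
    Aparts[[length(Aparts) + 1L]] <- sel %*% b$effect_map
    if (!is.null(b$constraints)) {
      pad_l <- offsets[nm]
      Cparts[[length(Cparts) + 1L]] <- cbind(
        Matrix::Matrix(0, nrow(b$constraints), pad_l, sparse = TRUE),
        b$constraints,
        Matrix::Matrix(0, nrow(b$constraints), N - pad_l - b$size,
                       sparse = TRUE))
    }
  }
  A <- do.call(cbind, Aparts)
  C <- if (length(Cparts)) do.call(rbind, Cparts) else NULL
  structure(list(X = X, blocks = blocks, A = methods::as(A, "CsparseMatrix"),
                 C = C, k_fixed = k, N = N, offsets = offsets,
                 beta_prec = beta_prec, n_obs = n_obs,
                 cache = new.env(parent = emptyenv())),
            class = "mob_latent_model")
}

#' @exportS3Method base::print
print.mob_latent_model <- function(x, ...) {
  cat(sprintf("<mob_latent_model> %d latent (%d fixed + %d random in %d blocks), %d observations, %d constraints\n",
              x$N, x$k_fixed, x$N - x$k_fixed, length(x$blocks), x$n_obs,
              if (is.null(x$C)) 0L else nrow(x$C)))
  invisible(x)
}

# per-block orthonormal null-space bases and reduced constant pieces
reduce_model <- function(model) {
  cache <- model$cache
  if (!is.null(cache$Z)) return(invisible(cache))
  Zb <- list(); red_pieces <- list()
  for (nm in names(model$blocks)) {
    b <- model$blocks[[nm]]
    if (is.null(b$constraints)) {
      Zb[[nm]] <- NULL  # identity
      red_pieces[[nm]] <- lapply(b$pieces, function(p) as.matrix(p))
    } else {
      Ct <- t(as.matrix(b$constraints))
      qq <- qr(Ct)
      Zi <- qr.Q(qq, complete = TRUE)[, -(seq_len(qq$rank)), drop = FALSE]
      Zb[[nm]] <- Zi
      red_pieces[[nm]] <- lapply(b$pieces, function(p) {
        crossprod(Zi, as.matrix(p %*% Zi))
      })
    }
  }
  m_b <- vapply(names(model$blocks), function(nm) {
    if (is.null(Zb[[nm]])) model$blocks[[nm]]$size else ncol(Zb[[nm]])
  }, 0L)
  m <- model$k_fixed + sum(m_b)
  # global sparse Z = blockdiag(I_k, Z_1, ..., Z_K)
  parts <- list(Matrix::Diagonal(model$k_fixed))
  for (nm in names(model$blocks)) {
    parts[[length(parts) + 1L]] <-
      if (is.null(Zb[[nm]])) Matrix::Diagonal(model$blocks[[nm]]$size) else
        Matrix::Matrix(Zb[[nm]], sparse = TRUE)
  }
  Z <- methods::as(Matrix::bdiag(parts), "CsparseMatrix")
  roff <- c(fixed = 0L,
            stats::setNames(model$k_fixed +
                              c(0L, cumsum(m_b))[seq_along(m_b)],
                            names(model$blocks)))
  AZ <- as.matrix(model$A %*% Z)
  cache$Z <- Z; cache$Zb <- Zb; cache$red_pieces <- red_pieces
  cache$m <- m; cache$m_b <- m_b; cache$roff <- roff
  cache$AZ <- AZ; cache$G <- crossprod(AZ)
  invisible(cache)
}

# reduced prior precision blocks at given hyperparameters
reduced_prior_blocks <- function(model, hyper) {
  cache <- reduce_model(model)
  out <- list(fixed = diag(model$beta_prec, model$k_fixed))
  for (nm in names(model$blocks)) {
    b <- model$blocks[[nm]]
    par <- hyper$blocks[[nm]]
    if (is.null(par)) stop("hyperparameters missing for block '", nm, "'",
                           call. = FALSE)
    co <- b$coef(par)
    ps <- cache$red_pieces[[nm]]
    M <- co[1] * ps[[1]]
    if (length(ps) > 1L) for (q in 2:length(ps)) M <- M + co[q] * ps[[q]]
    out[[nm]] <- M
  }
  out
}

check_hyper <- function(model, hyper) {
  if (!is.numeric(hyper$tau_eps) || hyper$tau_eps <= 0)
    stop("`tau_eps` must be > 0", call. = FALSE)
  for (nm in names(model$blocks)) {
    par <- hyper$blocks[[nm]]
    pn <- model$blocks[[nm]]$par_names
    if ("tau" %in% pn && (is.null(par$tau) || par$tau <= 0))
      stop("block '", nm, "': tau must be > 0", call. = FALSE)
    if ("phi" %in% pn && (is.null(par$phi) || par$phi <= 0 || par$phi >= 1))
      stop("block '", nm, "': phi must lie in (0, 1) for assembled models",
           call. = FALSE)
    if ("rho" %in% pn && (is.null(par$rho) || abs(par$rho) >= 1))
      stop("block '", nm, "': |rho| must be < 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Exact Gaussian latent posterior at fixed hyperparameters
#'
#' Posterior precision is the prior precision plus tau_eps * A'A, reduced to
#' the constraint subspace; means, marginal standard deviations, and the log
#' marginal likelihood of the observations are exact.
#'
#' @param model a \code{mob_latent_model}.
#' @param y observed responses (length = rows of the observation matrix).
#' @param hyper list: \code{tau_eps}, \code{blocks} (named: tau and
#'   phi/rho as the block requires).
#' @param need_sd compute latent marginal standard deviations (skippable
#'   inside optimization loops).
#' @return object of class \code{mob_posterior}: \code{mean}, \code{sd},
#'   \code{logml}, plus solve handles for linear functionals.
#' @export
posterior_given_hyper <- function(model, y, hyper, need_sd = TRUE) {
  check_hyper(model, hyper)
  if (length(y) != model$n_obs) stop("response length mismatch", call. = FALSE)
  if (!model$n_obs) stop("need at least one observation", call. = FALSE)
  cache <- reduce_model(model)
  pb <- reduced_prior_blocks(model, hyper)
  m <- cache$m
  Mprior_logdet <- 0
  for (nm in names(pb)) {
    ch <- tryCatch(chol(pb[[nm]]), error = function(e)
      stop("non-positive-definite prior block '", nm,
           "'; condition: ", conditionMessage(e), call. = FALSE))
    Mprior_logdet <- Mprior_logdet + 2 * sum(log(diag(ch)))
  }
  Mpost <- hyper$tau_eps * cache$G
  off <- cache$roff; sizes <- c(fixed = model$k_fixed, cache$m_b)
  for (nm in names(pb)) {
    i <- off[[nm]] + seq_len(sizes[[nm]])
    Mpost[i, i] <- Mpost[i, i] + pb[[nm]]
  }
  chM <- tryCatch(chol(Mpost), error = function(e)
    stop("numerical failure: reduced posterior precision not positive ",
         "definite (", conditionMessage(e), ")", call. = FALSE))
  b <- hyper$tau_eps * drop(crossprod(cache$AZ, y))
  alpha <- backsolve(chM, forwardsolve(t(chM), b))
  mean_latent <- drop(cache$Z %*% alpha)
  logml <- -0.5 * model$n_obs * log(2 * pi) +
    0.5 * model$n_obs * log(hyper$tau_eps) +
    0.5 * Mprior_logdet - sum(log(diag(chM))) -
    0.5 * hyper$tau_eps * sum(y^2) + 0.5 * sum(b * alpha)
  sd_latent <- NULL
  Minv <- NULL
  if (need_sd) {
    Minv <- chol2inv(chM)
    ZM <- as.matrix(cache$Z %*% Minv)
    sd_latent <- sqrt(pmax(rowSums(ZM * cache$Z), 0))
  }
  structure(list(mean = mean_latent, sd = sd_latent, logml = logml,
                 alpha = alpha, chol = chM, Minv = Minv, Z = cache$Z,
                 hyper = hyper, model = model),
            class = "mob_posterior")
}

#' Posterior of linear functionals of the latent field
#'
#' @param post a \code{mob_posterior}.
#' @param L sparse or dense matrix (rows = functionals) over the latent
#'   vector, e.g. prediction rows built like the observation matrix.
#' @return data.frame with \code{mean} and \code{sd} per functional (no
#'   observation noise included).
#' @export
posterior_functionals <- function(post, L) {
  L <- methods::as(Matrix::Matrix(L, sparse = TRUE), "CsparseMatrix")
  mu <- drop(L %*% post$mean)
  Minv <- post$Minv
  if (is.null(Minv)) Minv <- chol2inv(post$chol)
  LZ <- as.matrix(L %*% post$Z)
  v <- rowSums((LZ %*% Minv) * LZ)
  data.frame(mean = mu, sd = sqrt(pmax(v, 0)))
}

# ---- empirical Bayes hyperparameter estimation ----

# theta packing: log(tau_eps), then per block: log tau, logit phi / atanh rho
pack_theta <- function(model, hyper) {
  th <- log(hyper$tau_eps)
  for (nm in names(model$blocks)) {
    pn <- model$blocks[[nm]]$par_names
    par <- hyper$blocks[[nm]]
    for (p in pn)
      th <- c(th, switch(p, tau = log(par$tau),
                         phi = stats::qlogis(par$phi), rho = atanh(par$rho)))
  }
  th
}

unpack_theta <- function(model, theta) {
  hyper <- list(tau_eps = exp(theta[1]), blocks = list())
  i <- 1L
  for (nm in names(model$blocks)) {
    pn <- model$blocks[[nm]]$par_names
    par <- list()
    for (p in pn) {
      i <- i + 1L
      par[[p]] <- switch(p, tau = exp(theta[i]),
                         phi = stats::plogis(theta[i]), rho = tanh(theta[i]))
    }
    hyper$blocks[[nm]] <- par
  }
  hyper
}

#' Default hyperpriors for empirical-Bayes fitting
#'
#' Gamma(shape 1, rate 5e-5) on every precision (evaluated on the log scale
#' with its Jacobian) and Normal(0, precision 0.15) on the internal logit
#' mixing and Fisher-z correlation parameters — the conventional defaults of
#' latent-Gaussian software, kept configurable.
#'
#' @param gamma_shape,gamma_rate Gamma hyperprior on precisions.
#' @param z_prec Gaussian precision on internal logit/Fisher-z parameters.
#' @return list of settings.
#' @export
default_hyperpriors <- function(gamma_shape = 1, gamma_rate = 5e-5,
                                z_prec = 0.15) {
  list(gamma_shape = gamma_shape, gamma_rate = gamma_rate, z_prec = z_prec)
}

log_hyperprior <- function(model, theta, hp) {
  # precisions: Gamma on tau, density in theta = log tau includes Jacobian
  lp <- 0
  i <- 1L
  add_tau <- function(th) stats::dgamma(exp(th), shape = hp$gamma_shape,
                                        rate = hp$gamma_rate, log = TRUE) + th
  lp <- lp + add_tau(theta[1])
  for (nm in names(model$blocks)) {
    for (p in model$blocks[[nm]]$par_names) {
      i <- i + 1L
      lp <- lp + if (p == "tau") add_tau(theta[i]) else
        stats::dnorm(theta[i], 0, 1 / sqrt(hp$z_prec), log = TRUE)
    }
  }
  lp
}

default_init <- function(model, y) {
  v <- stats::var(y)
  if (!is.finite(v) || v <= 0) v <- 1
  hyper <- list(tau_eps = 2 / v, blocks = list())
  for (nm in names(model$blocks)) {
    pn <- model$blocks[[nm]]$par_names
    par <- list(tau = 4 / v)
    if ("phi" %in% pn) par$phi <- 0.5
    if ("rho" %in% pn) par$rho <- 0.5
    hyper$blocks[[nm]] <- par[pn]
  }
  hyper
}

#' Empirical-Bayes fit of a latent Gaussian model
#'
#' Maximizes the exact log marginal likelihood plus log hyperpriors over
#' internally transformed hyperparameters (log precisions, logit mixing,
#' Fisher-z correlation) with Nelder-Mead, then returns the exact Gaussian
#' posterior at the mode. Deterministic given data and init. Credible
#' intervals condition on the modal hyperparameters and so slightly
#' understate hyperparameter uncertainty; this is the classical
#' empirical-Bayes trade-off.
#'
#' @param model a \code{mob_latent_model}.
#' @param y response vector.
#' @param init optional initial hyperparameter list (as in
#'   \code{\link{posterior_given_hyper}}).
#' @param control list: \code{maxit} (default 1000), \code{reltol} (default 1e-8).
#' @param hyperpriors see \code{\link{default_hyperpriors}}.
#' @return object of class \code{mob_eb_fit}: \code{hyper} (modal),
#'   \code{posterior}, \code{logml}, \code{convergence} metadata,
#'   \code{boundary} flag.
#' @export
fit_empirical_bayes <- function(model, y, init = NULL,
                                control = list(),
                                hyperpriors = default_hyperpriors()) {
  maxit <- control$maxit %||% 1000L
  reltol <- control$reltol %||% 1e-8
  init <- init %||% default_init(model, y)
  check_hyper(model, init)
  th0 <- pack_theta(model, init)
  reduce_model(model)
  negobj <- function(th) {
    if (any(!is.finite(th)) || any(abs(th) > 40)) return(1e12)
    h <- unpack_theta(model, th)
    val <- tryCatch(
      posterior_given_hyper(model, y, h, need_sd = FALSE)$logml +
        log_hyperprior(model, th, hyperpriors),
      error = function(e) -Inf)
    if (!is.finite(val)) 1e12 else -val
  }
  restarts <- control$restarts %||% 1L
  opt <- if (length(th0) == 1L) {
    stats::optim(th0, negobj, method = "Brent", lower = -40, upper = 40,
                 control = list(maxit = maxit))
  } else {
    o <- stats::optim(th0, negobj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
    # fresh-simplex restarts from the incumbent optimum escape collapsed
    # simplices; still deterministic
    for (r in seq_len(restarts)) {
      o2 <- stats::optim(o$par, negobj, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = reltol))
      if (o2$value <= o$value) o <- o2
    }
    o
  }
  f0 <- negobj(th0)
  if (opt$value > f0) { # never return worse than the init
    opt$par <- th0; opt$value <- f0
  }
  hyper <- unpack_theta(model, opt$par)
  post <- posterior_given_hyper(model, y, hyper, need_sd = TRUE)
  conv <- list(code = opt$convergence, evaluations = opt$counts[["function"]],
               converged = opt$convergence == 0L)
  if (!conv$converged)
    warning("hyperparameter optimization did not converge within maxit = ",
            maxit)
  boundary <- any(abs(opt$par) > 12)
  if (boundary)
    warning("modal hyperparameters near the boundary of their range")
  structure(list(hyper = hyper, posterior = post, logml = post$logml,
                 objective = -opt$value, convergence = conv,
                 boundary = boundary, theta = opt$par, init = init),
            class = "mob_eb_fit")
}
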