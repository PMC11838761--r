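# Three-stage stepwise OLS term selection: bidirectional AIC over main
# effects, bidirectional AIC over two-way interactions of the selected
# mains, then backward pruning on p-values, with collinearity/conditioning
# cleanup. The selected term set feeds the Bayesian spatiotemporal models.

#' Ordinary least squares fit on an explicit design
#'
#' Gaussian-likelihood AIC is \code{n log(RSS/n) + 2k} with the additive
#' constant dropped (the convention of stepwise-selection AIC in R); only
#' AIC differences are ever used.
#'
#' @param X design matrix including the intercept column.
#' @param y response vector.
#' @return list of class \code{mob_ols}: coefficient table (term, estimate,
#'   se, t, p), residuals, fitted, rss, sigma2, aic, n, k.
#' @export
ols_fit <- function(X, y) {
  keep <- is.finite(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y); k <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < k)
    stop("singular design: columns are linearly dependent", call. = FALSE)
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / (n - k)
  XtXi <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(diag(XtXi), 0) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = unname(beta),
                              se = unname(se), t = unname(tval),
                              p = unname(pval), stringsAsFactors = FALSE),
    residuals = res, fitted = fitted, rss = rss, sigma2 = sigma2,
    aic = n * log(rss / n) + 2 * k, n = n, k = k, qr = qrX
  ), class = "mob_ols")
}

# design for a term list over the centred candidate-mains matrix
design_from_terms <- function(X_mains, terms) {
  n <- nrow(X_mains)
  D <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  for (tm in terms) {
    col <- if (grepl(":", tm, fixed = TRUE)) {
      p <- strsplit(tm, ":", fixed = TRUE)[[1]]
      X_mains[, p[1]] * X_mains[, p[2]]
    } else X_mains[, tm]
    D <- cbind(D, structure(col, dim = c(n, 1L), dimnames = list(NULL, tm)))
  }
  D
}

term_aic <- function(X_mains, y, terms) {
  ols_fit(design_from_terms(X_mains, terms), y)$aic
}

# greedy bidirectional AIC search over `movable` terms; `forced` always in.
# Ties between an addition and a removal of equal AIC go to the removal
# (smaller model). The accepted-path AIC is checked to be non-increasing.
step_bidirectional <- function(X_mains, y, movable, forced = character(0),
                               start = character(0)) {
  cur <- start
  cur_aic <- term_aic(X_mains, y, c(forced, cur))
  path <- cur_aic
  repeat {
    best_aic <- cur_aic; best_move <- NULL
    for (d in cur) { # removals considered first so ties favour them
      v <- try(term_aic(X_mains, y, c(forced, setdiff(cur, d))), silent = TRUE)
      if (!inherits(v, "try-error") && v < best_aic - 1e-10) {
        best_aic <- v; best_move <- list(op = "drop", term = d)
      }
    }
    for (a in setdiff(movable, cur)) {
      v <- try(term_aic(X_mains, y, c(forced, cur, a)), silent = TRUE)
      if (!inherits(v, "try-error") && v < best_aic - 1e-10) {
        best_aic <- v; best_move <- list(op = "add", term = a)
      }
    }
    if (is.null(best_move)) break
    cur <- if (best_move$op == "add") c(cur, best_move$term) else
      setdiff(cur, best_move$term)
    cur_aic <- best_aic
    path <- c(path, cur_aic)
  }
  if (any(diff(path) > 1e-8))
    stop("internal error: AIC increased along an accepted stepwise path")
  list(terms = cur, aic = cur_aic, path = path)
}

#' Stage 1: bidirectional AIC stepwise over candidate main effects
#'
#' @param y response vector.
#' @param X_mains matrix of centred candidate main-effect columns (one per
#'   covariate code, no intercept).
#' @param candidates candidate codes (default all columns).
#' @return a \code{\link{term_set}} of selected mains.
#' @export
stepwise_main_effects <- function(y, X_mains, candidates = colnames(X_mains)) {
  if (!length(candidates)) stop("need at least one candidate", call. = FALSE)
  if (length(y) <= length(candidates) + 2L)
    warning("few observations relative to candidate count; selection unstable")
  res <- step_bidirectional(X_mains, y, movable = candidates)
  term_set(mains = res$terms)
}

#' Stage 2: add two-way interactions of the selected mains
#'
#' Candidate interactions are all unordered pairs of the stage-1 mains; the
#' mains are forced into every model while the interactions are searched
#' bidirectionally by AIC, so the term hierarchy always holds.
#'
#' @param y,X_mains as in \code{\link{stepwise_main_effects}}.
#' @param mains a \code{\link{term_set}} (interactions ignored).
#' @return a \code{\link{term_set}} with mains plus selected interactions.
#' @export
add_interactions <- function(y, X_mains, mains) {
  if (!inherits(mains, "mob_term_set")) stop("`mains` must be a term_set",
                                             call. = FALSE)
  m <- mains$mains
  if (length(m) < 2L) return(mains)
  pairs <- utils::combn(sort(m), 2)
  cand <- paste(pairs[1, ], pairs[2, ], sep = ":")
  res <- step_bidirectional(X_mains, y, movable = cand, forced = m)
  term_set(mains = m, interactions = res$terms)
}

#' Stage 3: backward pruning of marginally significant terms
#'
#' Iteratively refits and drops the droppable term with the largest p-value
#' above \code{p_exit}, until every surviving term is significant at
#' \code{p_exit} or only the intercept remains. A main effect is droppable
#' only once it appears in no surviving interaction, so the hierarchy is
#' preserved. The default exit level matches the significance level at which
#' final model terms are reported (p < .05), so marginal terms are removed
#' and the simplified model has higher overall estimate significance.
#'
#' @param y,X_mains as above.
#' @param terms a \code{\link{term_set}}.
#' @param p_exit exit p-value threshold in (0, 1).
#' @return the pruned \code{\link{term_set}}.
#' @export
backward_prune <- function(y, X_mains, terms, p_exit = 0.05) {
  if (!(is.numeric(p_exit) && p_exit > 0 && p_exit < 1))
    stop("`p_exit` must lie in (0, 1)", call. = FALSE)
  cur <- c(terms$mains, terms$interactions)
  repeat {
    if (!length(cur)) break
    fit <- ols_fit(design_from_terms(X_mains, cur), y)
    ct <- fit$coefficients
    ct <- ct[ct$term != "(Intercept)", ]
    ints <- cur[grepl(":", cur, fixed = TRUE)]
    in_int <- unique(unlist(strsplit(ints, ":", fixed = TRUE)))
    droppable <- ct$term[grepl(":", ct$term, fixed = TRUE) |
                           !(ct$term %in% in_int)]
    cand <- ct[ct$term %in% droppable & ct$p > p_exit, ]
    if (!nrow(cand)) break
    cur <- setdiff(cur, cand$term[which.max(cand$p)])
  }
  term_set(mains = cur[!grepl(":", cur, fixed = TRUE)],
           interactions = cur[grepl(":", cur, fixed = TRUE)])
}

#' OLS diagnostics for a selected model
#'
#' Predictive R-squared uses the leave-one-out PRESS statistic computed via
#' the hat-matrix identity; VIFs come from the inverse correlation matrix of
#' the non-intercept columns; the condition number is that of the design
#' with columns scaled to unit norm. Flags are raised at VIF > 10 and
#' condition number > 30.
#'
#' @param y,X_mains as above.
#' @param terms a \code{\link{term_set}}.
#' @param vif_limit,cond_limit flag thresholds.
#' @return list of class \code{mob_ols_diagnostics}.
#' @export
diagnose <- function(y, X_mains, terms, vif_limit = 10, cond_limit = 30) {
  tl <- c(terms$mains, terms$interactions)
  D <- design_from_terms(X_mains, tl)
  fit <- ols_fit(D, y)
  keep <- is.finite(y)
  yv <- y[keep]; Dv <- D[keep, , drop = FALSE]
  h <- rowSums(qr.Q(fit$qr)[, seq_len(fit$k), drop = FALSE]^2)
  press <- sum((fit$residuals / (1 - h))^2)
  tss <- sum((yv - mean(yv))^2)
  r2 <- 1 - fit$rss / tss
  adj_r2 <- 1 - (1 - r2) * (fit$n - 1) / (fit$n - fit$k)
  pred_r2 <- 1 - press / tss
  vif <- if (length(tl) >= 2L) {
    R <- stats::cor(Dv[, tl, drop = FALSE])
    stats::setNames(diag(solve(R)), tl)
  } else if (length(tl) == 1L) stats::setNames(1, tl) else numeric(0)
  Ds <- sweep(Dv, 2, sqrt(colSums(Dv^2)), "/")
  sv <- svd(Ds, nu = 0, nv = 0)$d
  cond <- sv[1] / sv[length(sv)]
  structure(list(
    aic = fit$aic, r2 = r2, adj_r2 = adj_r2, predictive_r2 = pred_r2,
    vif = vif, condition_number = cond, coefficients = fit$coefficients,
    press = press,
    flags = list(vif = any(vif > vif_limit), condition = cond > cond_limit)
  ), class = "mob_ols_diagnostics")
}

#' Full three-stage term selection with conditioning cleanup
#'
#' Runs the bidirectional main-effect search, the interaction search, and
#' the backward prune, then — automating the manual practice of dropping
#' least significant terms from ill-conditioned or overfit models — removes
#' the least significant droppable term while any VIF exceeds
#' \code{vif_limit} or the condition number exceeds \code{cond_limit}, up to
#' \code{max_clean} times.
#'
#' @param y response (log relative mobility).
#' @param X_mains centred candidate main-effect matrix.
#' @param p_exit backward-prune exit p-value.
#' @param vif_limit,cond_limit,max_clean cleanup settings.
#' @return list with \code{terms} (a \code{\link{term_set}}) and
#'   \code{diagnostics}.
#' @export
select_terms <- function(y, X_mains, p_exit = 0.05, vif_limit = 10,
                         cond_limit = 30, max_clean = 10L) {
  mains <- stepwise_main_effects(y, X_mains)
  if (!length(mains$mains))
    return(list(terms = mains, diagnostics = diagnose(y, X_mains, mains)))
  full <- add_interactions(y, X_mains, mains)
  pruned <- backward_prune(y, X_mains, full, p_exit = p_exit)
  for (i in seq_len(max_clean)) {
    if (!length(c(pruned$mains, pruned$interactions))) break
    dg <- diagnose(y, X_mains, pruned, vif_limit, cond_limit)
    if (!dg$flags$vif && !dg$flags$condition) break
    ct <- dg$coefficients
    ct <- ct[ct$term != "(Intercept)", ]
    ints <- pruned$interactions
    in_int <- unique(unlist(strsplit(ints, ":", fixed = TRUE)))
    droppable <- ct$term[grepl(":", ct$term, fixed = TRUE) |
                           !(ct$term %in% in_int)]
    ct <- ct[ct$term %in% droppable, ]
    if (!nrow(ct)) break
    worst <- ct$term[which.max(ct$p)]
    pruned <- term_set(
      mains = setdiff(pruned$mains, worst),
      interactions = setdiff(pruned$interactions, worst))
  }
  list(terms = pruned, diagnostics = diagnose(y, X_mains, pruned))
}
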