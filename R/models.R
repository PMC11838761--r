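# Country-level and regional-level spatiotemporal models: one BYM2 spatial
# block (country pathway) or three nested spatial blocks (regional pathway),
# an AR1 block over the 24 concatenated study months, a space-time
# interaction, and the selected fixed effects. Fitting is empirical Bayes on
# the exact Gaussian marginal likelihood; predictions cover every in-scope
# (unit, month), observed or not.

#' Specification of one mobility model
#'
#' @param scope a country id (country pathway) or region id (regional
#'   pathway).
#' @param direction "FR" (outflow) or "TO" (inflow).
#' @param terms a \code{\link{term_set}} of fixed-effect terms.
#' @param interaction_type "I" (exchangeable) or "IV" (structured
#'   Kronecker).
#' @param retain_january keep the January anchor rows (logR = 0) in the
#'   likelihood; they inform the noise level. Set FALSE to drop them.
#' @param domestic optional data.frame (unit, year, month, value) with a
#'   domestic-travel covariate derived from the flow data; it enters the fit
#'   as an extra fixed effect but is forced to zero in prediction rows,
#'   since it cannot be computed for units whose mobility is being
#'   predicted.
#' @param beta_prec fixed-effect prior precision.
#' @return list of class \code{mob_model_spec}.
#' @export
model_spec <- function(scope, direction = c("FR", "TO"),
                       terms = term_set(), interaction_type = c("I", "IV"),
                       retain_january = TRUE, domestic = NULL,
                       beta_prec = 0.001) {
  structure(list(scope = scope, direction = match.arg(direction),
                 terms = terms,
                 interaction_type = match.arg(interaction_type),
                 retain_january = retain_january, domestic = domestic,
                 beta_prec = beta_prec),
            class = "mob_model_spec")
}

# observed rows of the series for a set of units, as keys + response
series_obs <- function(series, units, spec, years) {
  s <- series[series$unit %in% units & series$direction == spec$direction &
                series$observed, , drop = FALSE]
  if (!spec$retain_january) s <- s[s$month != 1L, , drop = FALSE]
  s$mi <- month_index(s$year, s$month, min(years))
  s
}

design_with_domestic <- function(covs, spec, keys, prediction = FALSE) {
  X <- build_design(covs, spec$terms, keys)
  if (!is.null(spec$domestic)) {
    v <- if (prediction) numeric(nrow(keys)) else {
      dk <- paste(spec$domestic$unit, spec$domestic$year, spec$domestic$month)
      kk <- paste(keys$unit, keys$year, keys$month)
      val <- spec$domestic$value[match(kk, dk)]
      val[is.na(val)] <- 0
      val
    }
    X <- cbind(X, DOMESTIC = v)
  }
  X
}

#' Build a country-level latent model
#'
#' One BYM2 block over the country's provinces, one AR1 block over the 24
#' concatenated study months, one space-time interaction block, plus the
#' fixed-effect design.
#'
#' @param geo a \code{mob_geography}.
#' @param covs centred covariate table covering the country's provinces.
#' @param series a relative-mobility series (\code{\link{compute_relative_mobility}}).
#' @param spec a \code{\link{model_spec}} whose scope is a country id.
#' @param years study years.
#' @return list of class \code{mob_model}: the assembled latent model, the
#'   response, prediction scaffolding, and metadata.
#' @export
build_country_model <- function(geo, covs, series, spec,
                                years = c(2018L, 2019L)) {
  prov <- provinces_of(geo, spec$scope)
  if (length(prov) < 2L)
    stop("single-province country '", spec$scope,
         "': the spatial block is degenerate; fit an iid effect instead",
         call. = FALSE)
  n_time <- 12L * length(years)
  obs <- series_obs(series, prov, spec, years)
  if (length(unique(obs$mi)) < 2L)
    stop("fewer than 2 observed months in scope '", spec$scope, "'",
         call. = FALSE)
  scaled <- scale_icar(icar_structure(geo$adjacency, ids = prov))
  blocks <- list(
    spatial = latent_block_bym2(scaled, "spatial"),
    temporal = latent_block_ar1(n_time, "temporal"),
    interaction = latent_block_interaction(scaled, n_time,
                                           spec$interaction_type,
                                           "interaction"))
  keys <- obs[, c("unit", "year", "month")]
  X <- design_with_domestic(covs, spec, keys)
  ai <- match(obs$unit, prov)
  cells <- list(spatial = ai, temporal = obs$mi,
                interaction = (obs$mi - 1L) * length(prov) + ai)
  latent <- assemble_model(X, blocks, cells, beta_prec = spec$beta_prec)

  pred_keys <- data.frame(
    unit = rep(prov, times = n_time),
    year = rep(rep(years, each = 12L), each = length(prov)),
    month = rep(rep(1:12, times = length(years)), each = length(prov)),
    stringsAsFactors = FALSE)
  pmi <- month_index(pred_keys$year, pred_keys$month, min(years))
  pai <- match(pred_keys$unit, prov)
  pred_cells <- list(spatial = pai, temporal = pmi,
                     interaction = (pmi - 1L) * length(prov) + pai)
  Xp <- design_with_domestic(covs, spec, pred_keys, prediction = TRUE)

  structure(list(latent = latent, y = obs$logR, obs_keys = keys,
                 pred_keys = pred_keys, pred_cells = pred_cells,
                 Xpred = Xp, spec = spec, units = prov, years = years,
                 pathway = "country"),
            class = "mob_model")
}

#' Build a regional-level latent model
#'
#' Three nested spatial BYM2 blocks — (1) over the region's country
#' adjacency graph, each province mapped to its country's effect (large
#' scale, regional extent); (2) over provinces using within-country edges
#' only (small scale, country extent); (3) over provinces using the full
#' regional province graph including cross-border edges (small scale,
#' regional extent) — plus AR1, interaction, and fixed effects. Provinces of
#' data-missing countries are latent nodes with no likelihood contribution
#' and are predicted through the spatial structure. Countries disconnected
#' from the region's country graph are excluded with a message.
#'
#' @inheritParams build_country_model
#' @param spec a \code{\link{model_spec}} whose scope is a region id.
#' @return a \code{mob_model}; if the region holds a single country, the
#'   country model is returned with a warning.
#' @export
build_regional_model <- function(geo, covs, series, spec,
                                 years = c(2018L, 2019L)) {
  prov_all <- provinces_of(geo, spec$scope)
  countries <- unique(geo$country_of[prov_all])
  if (length(countries) < 2L) {
    warning("region '", spec$scope,
            "' holds a single country; falling back to the country model")
    cspec <- spec; cspec$scope <- countries
    return(build_country_model(geo, covs, series, cspec, years))
  }
  cadj <- geo$country_adjacency
  cadj <- cadj[cadj$id_a %in% countries & cadj$id_b %in% countries, ,
               drop = FALSE]
  g <- igraph::graph_from_data_frame(
    cadj[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = countries))
  memb <- igraph::components(g)$membership[countries]
  main_comp <- which.max(tabulate(memb))
  dropped <- countries[memb != main_comp]
  if (length(dropped)) {
    message("excluding countries disconnected from the regional graph: ",
            paste(dropped, collapse = ", "))
    countries <- countries[memb == main_comp]
    cadj <- cadj[cadj$id_a %in% countries & cadj$id_b %in% countries, ,
                 drop = FALSE]
  }
  prov <- prov_all[geo$country_of[prov_all] %in% countries]
  n_time <- 12L * length(years)
  obs <- series_obs(series, prov, spec, years)
  if (length(unique(obs$mi)) < 2L)
    stop("fewer than 2 observed months in scope '", spec$scope, "'",
         call. = FALSE)

  ctry_scaled <- scale_icar(icar_structure(cadj, ids = countries))
  within <- geo$adjacency[
    geo$adjacency$id_a %in% prov & geo$adjacency$id_b %in% prov &
      geo$country_of[geo$adjacency$id_a] ==
        geo$country_of[geo$adjacency$id_b], , drop = FALSE]
  regional <- geo$adjacency[
    geo$adjacency$id_a %in% prov & geo$adjacency$id_b %in% prov, ,
    drop = FALSE]
  within_scaled <- scale_icar(icar_structure(within, ids = prov))
  regional_scaled <- scale_icar(icar_structure(regional, ids = prov))

  blocks <- list(
    spatial_country = latent_block_bym2(ctry_scaled, "spatial_country"),
    spatial_within = latent_block_bym2(within_scaled, "spatial_within"),
    spatial_regional = latent_block_bym2(regional_scaled, "spatial_regional"),
    temporal = latent_block_ar1(n_time, "temporal"),
    interaction = latent_block_interaction(regional_scaled, n_time,
                                           spec$interaction_type,
                                           "interaction"))
  keys <- obs[, c("unit", "year", "month")]
  X <- design_with_domestic(covs, spec, keys)
  ai <- match(obs$unit, prov)
  ci <- match(geo$country_of[obs$unit], countries)
  cells <- list(spatial_country = ci, spatial_within = ai,
                spatial_regional = ai, temporal = obs$mi,
                interaction = (obs$mi - 1L) * length(prov) + ai)
  latent <- assemble_model(X, blocks, cells, beta_prec = spec$beta_prec)

  pred_keys <- data.frame(
    unit = rep(prov, times = n_time),
    year = rep(rep(years, each = 12L), each = length(prov)),
    month = rep(rep(1:12, times = length(years)), each = length(prov)),
    stringsAsFactors = FALSE)
  pmi <- month_index(pred_keys$year, pred_keys$month, min(years))
  pai <- match(pred_keys$unit, prov)
  pci <- match(geo$country_of[pred_keys$unit], countries)
  pred_cells <- list(spatial_country = pci, spatial_within = pai,
                     spatial_regional = pai, temporal = pmi,
                     interaction = (pmi - 1L) * length(prov) + pai)
  Xp <- design_with_domestic(covs, spec, pred_keys, prediction = TRUE)

  structure(list(latent = latent, y = obs$logR, obs_keys = keys,
                 pred_keys = pred_keys, pred_cells = pred_cells,
                 Xpred = Xp, spec = spec, units = prov, years = years,
                 countries = countries, excluded = dropped,
                 pathway = "regional"),
            class = "mob_model")
}

# observation-style matrix over the latent vector for arbitrary rows
functional_rows <- function(latent, X, cells) {
  n <- nrow(X)
  parts <- list(methods::as(Matrix::Matrix(X, sparse = TRUE),
                            "CsparseMatrix"))
  for (nm in names(latent$blocks)) {
    b <- latent$blocks[[nm]]
    sel <- Matrix::sparseMatrix(i = seq_len(n), j = cells[[nm]], x = 1,
                                dims = c(n, b$effect_dim))
    parts[[length(parts) + 1L]] <- sel %*% b$effect_map
  }
  methods::as(do.call(cbind, parts), "CsparseMatrix")
}

#' Fit a mobility model and predict every in-scope unit-month
#'
#' Runs the empirical-Bayes engine, then evaluates the linear-predictor
#' posterior for every (unit, month) cell in scope. Reported prediction
#' intervals come in two flavours: the linear predictor (for mapping the
#' latent relative-mobility surface) and the posterior predictive including
#' observation noise (for calibration against observed values). Relative
#' mobility is the monotone back-transform 10^q of each log-scale quantile.
#'
#' @param model a \code{mob_model}.
#' @param init,control,hyperpriors passed to
#'   \code{\link{fit_empirical_bayes}}.
#' @return object of class \code{mob_fit_result}: \code{fixed} (posterior
#'   summaries per term), \code{hyper}, \code{predictions} (per unit-month:
#'   logR and R means and 95\% intervals, observed flag), \code{logml},
#'   \code{convergence}.
#' @export
fit_mobility_model <- function(model, init = NULL, control = list(),
                               hyperpriors = default_hyperpriors()) {
  eb <- fit_empirical_bayes(model$latent, model$y, init = init,
                            control = control, hyperpriors = hyperpriors)
  post <- eb$posterior
  k <- model$latent$k_fixed
  terms <- colnames(model$latent$X)
  z <- stats::qnorm(0.975)
  fixed <- data.frame(
    term = terms, mean = post$mean[seq_len(k)], sd = post$sd[seq_len(k)],
    lower = post$mean[seq_len(k)] - z * post$sd[seq_len(k)],
    upper = post$mean[seq_len(k)] + z * post$sd[seq_len(k)],
    stringsAsFactors = FALSE)
  fixed$significant <- fixed$lower > 0 | fixed$upper < 0
  fixed$type <- ifelse(fixed$term == "(Intercept)", "intercept",
                       ifelse(grepl(":", fixed$term, fixed = TRUE),
                              "interaction", "main"))

  L <- functional_rows(model$latent, model$Xpred, model$pred_cells)
  lin <- posterior_functionals(post, L)
  sd_pred <- sqrt(lin$sd^2 + 1 / eb$hyper$tau_eps)
  pred <- data.frame(
    model$pred_keys,
    logR_mean = lin$mean, logR_sd = lin$sd,
    logR_lower = lin$mean - z * lin$sd, logR_upper = lin$mean + z * lin$sd,
    pred_lower = lin$mean - z * sd_pred, pred_upper = lin$mean + z * sd_pred,
    stringsAsFactors = FALSE)
  pred$R_mean <- 10^pred$logR_mean
  pred$R_lower <- 10^pred$logR_lower
  pred$R_upper <- 10^pred$logR_upper
  ok <- paste(model$obs_keys$unit, model$obs_keys$year, model$obs_keys$month)
  pk <- paste(pred$unit, pred$year, pred$month)
  pred$observed <- pk %in% ok
  pred$logR_obs <- model$y[match(pk, ok)]

  structure(list(fixed = fixed, hyper = eb$hyper, predictions = pred,
                 logml = eb$logml, convergence = eb$convergence,
                 boundary = eb$boundary, posterior = post, model = model),
            class = "mob_fit_result")
}

#' @exportS3Method base::print
print.mob_fit_result <- function(x, ...) {
  cat(sprintf("<mob_fit_result> %s pathway, scope %s, direction %s: %d terms, %d predictions (%d observed), logML %.2f\n",
              x$model$pathway, x$model$spec$scope, x$model$spec$direction,
              nrow(x$fixed), nrow(x$predictions), sum(x$predictions$observed),
              x$logml))
  invisible(x)
}

#' Predicted relative mobility for selected units
#'
#' Extracts the back-transformed linear-predictor posterior (no observation
#' noise) for the requested units: posterior mean-quantile and central 95\%
#' interval of R per month. The back-transform is monotone, so interval
#' ordering is preserved.
#'
#' @param fit a \code{mob_fit_result}.
#' @param units unit ids inside the fitted model's scope.
#' @return data.frame (unit, year, month, R, R_lower, R_upper, observed).
#' @export
predict_missing <- function(fit, units) {
  outside <- setdiff(units, fit$model$units)
  if (length(outside))
    stop("unit(s) outside model scope: ", paste(outside, collapse = ", "),
         call. = FALSE)
  p <- fit$predictions[fit$predictions$unit %in% units, ]
  out <- data.frame(unit = p$unit, year = p$year, month = p$month,
                    R = p$R_mean, R_lower = p$R_lower, R_upper = p$R_upper,
                    observed = p$observed, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fixed-effect summary table with significance flags
#'
#' Terms are flagged significant when 0 lies outside the central 95\%
#' credible interval; simple main effects are listed before interactions.
#'
#' @param fit a \code{mob_fit_result}.
#' @return data.frame of per-term posterior summaries.
#' @export
summarize_fixed_effects <- function(fit) {
  f <- fit$fixed
  f[order(match(f$type, c("intercept", "main", "interaction")), f$term), ]
}
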