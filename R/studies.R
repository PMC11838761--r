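# Seeded simulation studies quantifying the pipeline's statistical
# properties: fixed-effect coverage and noise-precision recovery, predictive
# interval calibration, stepwise-selection support recovery, and hold-out
# prediction of a fully missing country. The analysis scripts and the
# acceptance report all run these.

#' Draw the latent field of an assembled model from its prior
#'
#' Samples each random-effect block from its (constrained) prior at the
#' given hyperparameters; the fixed-effect part is set to \code{beta}
#' (default zero).
#'
#' @param model a \code{mob_latent_model}.
#' @param hyper hyperparameters as in \code{\link{posterior_given_hyper}}.
#' @param beta fixed-effect values (length = number of design columns).
#' @return latent vector of length \code{model$N}.
#' @export
sample_latent <- function(model, hyper, beta = NULL) {
  check_hyper(model, hyper)
  cache <- reduce_model(model)
  pb <- reduced_prior_blocks(model, hyper)
  z <- numeric(cache$m)
  off <- cache$roff; sizes <- c(fixed = model$k_fixed, cache$m_b)
  for (nm in names(pb)) {
    if (nm == "fixed") next
    i <- off[[nm]] + seq_len(sizes[[nm]])
    z[i] <- backsolve(chol(pb[[nm]]), stats::rnorm(length(i)))
  }
  x <- drop(cache$Z %*% z)
  x[seq_len(model$k_fixed)] <- beta %||% numeric(model$k_fixed)
  x
}

recovery_model <- function(n_provinces = 20, seed = 2) {
  geo <- generate_geography(1, 1, n_provinces, seed = seed)
  covs <- center_and_scale(
    generate_covariates(geo, codes = c("TEMP", "GDPC"), seed = seed))
  prov <- provinces_of(geo)
  series0 <- data.frame(unit = rep(prov, 24),
                        direction = "FR",
                        year = rep(rep(c(2018L, 2019L), each = 12),
                                   each = length(prov)),
                        month = rep(rep(1:12, 2), each = length(prov)),
                        R = 1, logR = 0, observed = TRUE,
                        stringsAsFactors = FALSE)
  spec <- model_spec(unique(geo$country_of), "FR",
                     term_set(c("GDPC", "TEMP")), interaction_type = "IV")
  build_country_model(geo, covs, series0, spec)
}

#' Parameter-recovery study for the country-level model
#'
#' Replicates a country model (default 20 provinces x 24 months) with known
#' fixed effects and hyperparameters: each replicate draws the latent field
#' and Gaussian noise, refits by empirical Bayes, and records whether each
#' true coefficient lies in its 95\% credible interval and the relative
#' error of the modal noise precision. The structured (type IV) interaction
#' is used so every variance component is identifiable from a single
#' observation per cell.
#'
#' @param n_reps number of replicates.
#' @param seed root seed.
#' @param n_provinces provinces in the synthetic country.
#' @param beta true fixed effects (intercept, GDPC, TEMP).
#' @param hyper true hyperparameters.
#' @param maxit optimizer budget per replicate.
#' @return data.frame per replicate: coverage count, number of
#'   coefficients, tau_eps relative error.
#' @export
study_parameter_recovery <- function(n_reps = 50, seed = 1,
                                     n_provinces = 20,
                                     beta = c(0.05, 0.2, 0.05),
                                     hyper = list(
                                       tau_eps = 100,
                                       blocks = list(
                                         spatial = list(tau = 25, phi = 0.5),
                                         temporal = list(tau = 25, rho = 0.6),
                                         interaction = list(tau = 100,
                                                            rho = 0.6))),
                                     maxit = 400) {
  model <- recovery_model(n_provinces, seed = 2)
  lat <- model$latent
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, paste0("recovery", r)))
    x <- sample_latent(lat, hyper, beta = beta)
    y <- drop(as.matrix(lat$A %*% x)) +
      stats::rnorm(lat$n_obs, sd = 1 / sqrt(hyper$tau_eps))
    fit <- fit_empirical_bayes(lat, y, control = list(maxit = maxit))
    k <- lat$k_fixed
    est <- fit$posterior$mean[seq_len(k)]
    sd <- fit$posterior$sd[seq_len(k)]
    covered <- abs(est - beta) <= stats::qnorm(0.975) * sd
    out[[r]] <- data.frame(rep = r, covered = sum(covered), k = k,
                           tau_eps_rel_err =
                             abs(fit$hyper$tau_eps - hyper$tau_eps) /
                               hyper$tau_eps)
  }
  do.call(rbind, out)
}

#' Predictive-interval calibration study
#'
#' Each replicate draws a latent field from a known model, generates
#' observations, computes the exact posterior at the true hyperparameters,
#' and evaluates 95\% posterior predictive intervals against an independent
#' replicate set of observations of the same cells (capture on the training
#' observations themselves is mildly conservative because the intervals
#' were fitted to them). Under the true model the capture probability is
#' exactly 95\%.
#'
#' @param n_reps replicates.
#' @param n_obs observations per replicate.
#' @param n_cells latent cells.
#' @param seed root seed.
#' @return data.frame per replicate: capture_95, n.
#' @export
study_coverage_calibration <- function(n_reps = 50, n_obs = 1000,
                                       n_cells = 100, seed = 1) {
  blocks <- list(field = latent_block_iid(n_cells, "field"))
  X <- matrix(1, n_obs, 1, dimnames = list(NULL, "(Intercept)"))
  hyper <- list(tau_eps = 25, blocks = list(field = list(tau = 4)))
  z <- stats::qnorm(0.975)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, paste0("calib", r)))
    cells <- sample.int(n_cells, n_obs, replace = TRUE)
    model <- assemble_model(X, blocks, list(field = cells))
    x <- sample_latent(model, hyper, beta = 0.2)
    eta <- drop(as.matrix(model$A %*% x))
    y <- eta + stats::rnorm(n_obs, sd = 1 / sqrt(hyper$tau_eps))
    post <- posterior_given_hyper(model, y, hyper)
    lin <- posterior_functionals(post, model$A)
    spd <- sqrt(lin$sd^2 + 1 / hyper$tau_eps)
    y_rep <- eta + stats::rnorm(n_obs, sd = 1 / sqrt(hyper$tau_eps))
    met <- compute_metrics(model_residuals(y_rep, lin$mean),
                           lower = lin$mean - z * spd,
                           upper = lin$mean + z * spd, observed = y_rep)
    out[[r]] <- data.frame(rep = r, capture_95 = met$capture_95, n = met$n)
  }
  do.call(rbind, out)
}

#' Stepwise-selection support-recovery study
#'
#' Sparse truth (two mains and their interaction among \code{n_candidates}
#' standard-normal candidates) at signal-to-noise ratio \code{snr}; each
#' seed runs the full three-stage procedure and records whether the
#' selected support is exactly the truth and whether it contains it.
#'
#' @param n_seeds number of simulated datasets.
#' @param n,n_candidates,snr design of each dataset.
#' @param p_exit backward-prune exit level.
#' @param seed root seed.
#' @return data.frame per seed: exact, superset, n_terms.
#' @export
study_selection_recovery <- function(n_seeds = 100, n = 500,
                                     n_candidates = 10, snr = 10,
                                     p_exit = 0.05, seed = 1) {
  out <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(derive_seed(seed, paste0("select", s)))
    X <- matrix(stats::rnorm(n * n_candidates), n, n_candidates)
    colnames(X) <- sprintf("x%02d", seq_len(n_candidates))
    signal <- X[, 1] + X[, 2] + X[, 1] * X[, 2]
    y <- signal + stats::rnorm(n, sd = sqrt(stats::var(signal) / snr))
    sel <- select_terms(y, X, p_exit = p_exit)$terms
    got <- c(sel$mains, sel$interactions)
    truth <- c("x01", "x02", "x01:x02")
    out[[s]] <- data.frame(seed = s,
                           exact = setequal(got, truth),
                           superset = all(truth %in% got),
                           n_terms = length(got))
  }
  do.call(rbind, out)
}

holdout_region_model <- function(geo, covs, series, direction = "FR") {
  spec <- model_spec("R1", direction, term_set(c("GDPC", "TEMP")),
                     interaction_type = "I")
  build_regional_model(geo, covs, series, spec)
}

#' Hold-out prediction study for the regional model
#'
#' Each seed draws a regional latent field with strong spatial structure
#' (country-level and cross-border province-level effects) plus seasonal
#' covariate effects, withholds one entire country's observations, refits,
#' and compares the held-out country's predicted linear predictor with the
#' truth (Spearman correlation), also recording whether the held-out
#' units' mean 95\% interval width exceeds the observed units' width.
#'
#' @param n_seeds number of replicates.
#' @param seed root seed.
#' @param n_countries,provinces_per_country regional geography.
#' @param beta true fixed effects for (Intercept, GDPC, TEMP).
#' @param hyper true hyperparameters of the regional model.
#' @param maxit optimizer budget.
#' @return data.frame per seed: spearman, width_missing, width_observed,
#'   wider (logical).
#' @export
study_holdout_prediction <- function(n_seeds = 20, seed = 1,
                                     n_countries = 4,
                                     provinces_per_country = 4,
                                     beta = c(0, 0.3, 0.06),
                                     hyper = list(
                                       tau_eps = 400,
                                       blocks = list(
                                         spatial_country = list(tau = 16,
                                                                phi = 0.7),
                                         spatial_within = list(tau = 100,
                                                               phi = 0.5),
                                         spatial_regional = list(tau = 25,
                                                                 phi = 0.7),
                                         temporal = list(tau = 25,
                                                         rho = 0.7),
                                         interaction = list(tau = 2500))),
                                     maxit = 300) {
  geo <- generate_geography(1, n_countries, provinces_per_country, seed = 5)
  prov <- provinces_of(geo)
  covs <- center_and_scale(
    generate_covariates(geo, codes = c("TEMP", "GDPC"), seed = 5),
    scale = TRUE)
  keys <- data.frame(unit = rep(prov, 24),
                     year = rep(rep(c(2018L, 2019L), each = 12),
                                each = length(prov)),
                     month = rep(rep(1:12, 2), each = length(prov)),
                     stringsAsFactors = FALSE)
  series_all <- data.frame(keys, direction = "FR", R = 1, logR = 0,
                           observed = TRUE, stringsAsFactors = FALSE)
  full <- holdout_region_model(geo, covs, series_all)
  countries <- sort(unique(geo$country_of))
  out <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(derive_seed(seed, paste0("holdout", s)))
    x <- sample_latent(full$latent, hyper, beta = beta)
    eta <- drop(as.matrix(full$latent$A %*% x))
    y <- eta + stats::rnorm(length(eta), sd = 1 / sqrt(hyper$tau_eps))
    held <- countries[1 + (s - 1) %% length(countries)]
    series <- series_all
    # y is ordered like the full model's observation rows; map it onto the
    # series rows by key
    sk <- paste(series$unit, series$year, series$month)
    fk0 <- paste(full$obs_keys$unit, full$obs_keys$year,
                 full$obs_keys$month)
    series$logR <- y[match(sk, fk0)]
    series$observed <- unname(geo$country_of[series$unit] != held)
    model <- holdout_region_model(geo, covs, series)
    fit <- fit_mobility_model(model, control = list(maxit = maxit))
    p <- fit$predictions
    pk <- paste(p$unit, p$year, p$month)
    fk <- paste(full$obs_keys$unit, full$obs_keys$year,
                full$obs_keys$month)
    truth_eta <- eta[match(pk, fk)]
    miss <- geo$country_of[p$unit] == held
    sp <- stats::cor(p$logR_mean[miss], truth_eta[miss], method = "spearman")
    w_miss <- mean(p$logR_upper[miss] - p$logR_lower[miss])
    w_obs <- mean(p$logR_upper[!miss] - p$logR_lower[!miss])
    out[[s]] <- data.frame(seed = s, heldout = held, spearman = sp,
                           width_missing = w_miss, width_observed = w_obs,
                           wider = w_miss > w_obs,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
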