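# Country-level and regional-level model assembly, fitting, prediction of
# missing units, and the fixed-effect summaries.

model_fixture <- function(seed = 1) {
  geo <- tiny_geo()
  covs <- center_and_scale(
    generate_covariates(geo, codes = c("TEMP", "GDPC"), seed = seed))
  sim <- simulate_flows(geo, covs, truth = list(
    beta = c(GDPC = 0.1),
    hyper = list(tau_eps = 400,
                 spatial = list(tau = 50, phi = 0.5),
                 temporal = list(tau = 25, rho = 0.6))), seed = seed)
  ser <- compute_relative_mobility(
    directional_totals(sim$flows, "FR"), "FR", min_january = 100)
  list(geo = geo, covs = covs, ser = ser, sim = sim)
}

test_that("country model bookkeeping: latent dimension audit", {
  fx <- model_fixture()
  spec <- model_spec("R1.C01", "FR", term_set("GDPC"))
  m <- build_country_model(fx$geo, fx$covs, fx$ser, spec)
  n_prov <- 4; n_month <- 24
  expect_equal(m$latent$N, 2L + 2L * n_prov + n_month + n_prov * n_month)
  expect_equal(nrow(m$pred_keys), n_prov * n_month)
  # empty term set: intercept plus the three random blocks
  m0 <- build_country_model(fx$geo, fx$covs, fx$ser,
                            model_spec("R1.C01", "FR", term_set()))
  expect_equal(m0$latent$k_fixed, 1L)
  expect_equal(length(m0$latent$blocks), 3L)
})

test_that("single-province countries are rejected with advice", {
  geo1 <- generate_geography(1, 2, 1, seed = 1)
  covs <- center_and_scale(generate_covariates(geo1, codes = "TEMP",
                                               seed = 1))
  ser <- data.frame(unit = provinces_of(geo1), direction = "FR",
                    year = 2018L, month = 1L, R = 1, logR = 0,
                    observed = TRUE)
  expect_error(build_country_model(geo1, covs, ser,
                                   model_spec("R1.C01", "FR", term_set())),
               "iid")
})

test_that("noise-free data are interpolated exactly in the limit", {
  fx <- model_fixture()
  spec <- model_spec("R1.C01", "FR", term_set("GDPC"))
  m <- build_country_model(fx$geo, fx$covs, fx$ser, spec)
  hyper <- list(tau_eps = 1e12,
                blocks = list(spatial = list(tau = 1, phi = 0.5),
                              temporal = list(tau = 1, rho = 0.5),
                              interaction = list(tau = 1)))
  post <- posterior_given_hyper(m$latent, m$y, hyper)
  fitted <- drop(as.matrix(m$latent$A %*% post$mean))
  expect_lt(max(abs(fitted - m$y)), 1e-6)
})

test_that("fitting is deterministic and summaries are complete", {
  fx <- model_fixture()
  spec <- model_spec("R1.C01", "FR", term_set("GDPC"))
  m <- build_country_model(fx$geo, fx$covs, fx$ser, spec)
  f1 <- suppressWarnings(fit_mobility_model(m, control = list(maxit = 150)))
  f2 <- suppressWarnings(fit_mobility_model(m, control = list(maxit = 150)))
  expect_identical(f1$hyper, f2$hyper)
  expect_identical(f1$predictions, f2$predictions)
  expect_equal(nrow(f1$fixed), 2L)
  expect_equal(nrow(summarize_fixed_effects(f1)), 2L)
  # predictions exist for every in-scope unit-month
  expect_equal(nrow(f1$predictions), 4L * 24L)
  expect_true(all(f1$predictions$R_mean > 0))
  expect_true(all(f1$predictions$R_lower <= f1$predictions$R_mean &
                    f1$predictions$R_mean <= f1$predictions$R_upper))
})

test_that("predict_missing back-transforms monotonically and guards scope", {
  fx <- model_fixture()
  spec <- model_spec("R1.C01", "FR", term_set())
  m <- build_country_model(fx$geo, fx$covs, fx$ser, spec)
  fit <- suppressWarnings(fit_mobility_model(m, control = list(maxit = 100)))
  pm <- predict_missing(fit, m$units[1:2])
  expect_setequal(unique(pm$unit), m$units[1:2])
  expect_true(all(pm$R_lower <= pm$R & pm$R <= pm$R_upper))
  expect_true(all(pm$R > 0))
  expect_error(predict_missing(fit, "ELSEWHERE"), "outside model scope")
  # a posterior log-mean of zero is relative mobility one
  expect_equal(10^0, 1)
})

test_that("single-country regions fall back to the country model", {
  geo <- generate_geography(1, 1, 4, seed = 3)
  covs <- center_and_scale(generate_covariates(geo, codes = "TEMP", seed = 3))
  sim <- simulate_flows(geo, covs, truth = list(
    hyper = list(tau_eps = 400, temporal = list(tau = 25, rho = 0.5))),
    seed = 3)
  ser <- compute_relative_mobility(directional_totals(sim$flows, "FR"), "FR",
                                   min_january = 100)
  spec <- model_spec("R1", "FR", term_set())
  expect_warning(mr <- build_regional_model(geo, covs, ser, spec),
                 "single country")
  mc <- build_country_model(geo, covs, ser,
                            model_spec("R1.C01", "FR", term_set()))
  expect_equal(mr$latent$N, mc$latent$N)
  pr <- posterior_given_hyper(mr$latent, mr$y, list(
    tau_eps = 100, blocks = list(spatial = list(tau = 10, phi = 0.5),
                                 temporal = list(tau = 10, rho = 0.5),
                                 interaction = list(tau = 100))))
  pc <- posterior_given_hyper(mc$latent, mc$y, list(
    tau_eps = 100, blocks = list(spatial = list(tau = 10, phi = 0.5),
                                 temporal = list(tau = 10, rho = 0.5),
                                 interaction = list(tau = 100))))
  expect_lt(max(abs(pr$mean[1] - pc$mean[1])), 1e-6)
})

test_that("regional model structure: three spatial scales, nested graphs", {
  fx <- model_fixture()
  spec <- model_spec("R1", "FR", term_set("GDPC"))
  m <- build_regional_model(fx$geo, fx$covs, fx$ser, spec)
  expect_setequal(names(m$latent$blocks),
                  c("spatial_country", "spatial_within", "spatial_regional",
                    "temporal", "interaction"))
  # country-level block dimension = 2 countries (BYM2 doubles it)
  expect_equal(m$latent$blocks$spatial_country$size, 4L)
  expect_equal(m$latent$blocks$spatial_country$effect_dim, 2L)
})

test_that("without cross-border edges the regional province graphs coincide", {
  fx <- model_fixture()
  geo <- fx$geo
  # strip cross-country province edges
  same <- geo$country_of[geo$adjacency$id_a] == geo$country_of[geo$adjacency$id_b]
  geo$adjacency <- geo$adjacency[same, ]
  spec <- model_spec("R1", "FR", term_set())
  m <- build_regional_model(geo, fx$covs, fx$ser, spec)
  expect_equal(as.matrix(m$latent$blocks$spatial_regional$pieces$uu_s),
               as.matrix(m$latent$blocks$spatial_within$pieces$uu_s))
})

test_that("provinces of data-missing countries are still predicted", {
  fx <- model_fixture()
  ser <- fx$ser
  miss <- provinces_of(fx$geo, "R1.C02")
  ser$observed[ser$unit %in% miss] <- FALSE
  spec <- model_spec("R1", "FR", term_set())
  m <- build_regional_model(fx$geo, fx$covs, ser, spec)
  fit <- suppressWarnings(fit_mobility_model(m, control = list(maxit = 100)))
  pm <- predict_missing(fit, miss)
  expect_equal(nrow(pm), length(miss) * 24L)
  expect_false(any(pm$observed))
  # unobserved units carry wider linear-predictor intervals
  p <- fit$predictions
  w_miss <- mean(p$logR_upper[p$unit %in% miss] -
                   p$logR_lower[p$unit %in% miss])
  w_obs <- mean(p$logR_upper[!(p$unit %in% miss)] -
                  p$logR_lower[!(p$unit %in% miss)])
  expect_gt(w_miss, w_obs)
})

test_that("more observed months shrink the fixed-effect posterior", {
  fx <- model_fixture()
  spec <- model_spec("R1.C01", "FR", term_set("GDPC"))
  hyper <- list(tau_eps = 200,
                blocks = list(spatial = list(tau = 25, phi = 0.5),
                              temporal = list(tau = 25, rho = 0.5),
                              interaction = list(tau = 200)))
  sds <- vapply(c(6L, 24L), function(nm) {
    ser <- fx$ser
    ser$observed <- ser$observed & month_index(ser$year, ser$month) <= nm
    m <- build_country_model(fx$geo, fx$covs, ser, spec)
    post <- posterior_given_hyper(m$latent, m$y, hyper)
    mean(post$sd[seq_len(m$latent$k_fixed)])
  }, 0)
  expect_lt(sds[2], sds[1])
})

test_that("a domestic-travel covariate enters the fit but not predictions", {
  fx <- model_fixture()
  dom <- data.frame(unit = fx$ser$unit, year = fx$ser$year,
                    month = fx$ser$month,
                    value = stats::rnorm(nrow(fx$ser), 0, 0.1))
  spec <- model_spec("R1.C01", "FR", term_set(), domestic = dom)
  m <- build_country_model(fx$geo, fx$covs, fx$ser, spec)
  expect_true("DOMESTIC" %in% colnames(m$latent$X))
  expect_true(all(m$Xpred[, "DOMESTIC"] == 0))
})
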