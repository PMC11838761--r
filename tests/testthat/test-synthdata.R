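# Generator invariants: hierarchy and connectivity of the synthetic
# geography, covariate ranges, count process anchoring, the privacy
# mechanism, and country-block missingness.

test_that("minimal hierarchy is generated with connected adjacency", {
  geo <- generate_geography(1, 1, 3, seed = 7)
  expect_equal(sum(geo$units$level == "province"), 3L)
  expect_equal(sum(geo$units$level == "country"), 1L)
  prov <- provinces_of(geo)
  comp <- bfs_components(prov, geo$adjacency)
  expect_equal(max(comp), 1L)
  expect_error(generate_geography(0, 1, 1), "positive integer")
})

test_that("geography generation is deterministic and hierarchically valid", {
  g1 <- generate_geography(2, 2, 4, seed = 1)
  g2 <- generate_geography(2, 2, 4, seed = 1)
  expect_identical(g1, g2)
  prov <- provinces_of(g1)
  # every province has exactly one country parent; country one region
  expect_true(all(g1$units$parent[match(prov, g1$units$id)] %in%
                    g1$units$id[g1$units$level == "country"]))
  # adjacency has no self-edges and is stored symmetrically (a < b)
  expect_true(all(g1$adjacency$id_a != g1$adjacency$id_b))
  expect_true(all(g1$adjacency$id_a < g1$adjacency$id_b))
})

test_that("each country's province subgraph is connected (BFS oracle)", {
  geo <- generate_geography(1, 2, 5, seed = 3)
  for (cid in unique(geo$country_of)) {
    prov <- provinces_of(geo, cid)
    within <- geo$adjacency[geo$adjacency$id_a %in% prov &
                              geo$adjacency$id_b %in% prov, ]
    expect_equal(max(bfs_components(prov, within)), 1L)
  }
})

test_that("generated covariates stay inside the catalogue ranges", {
  geo <- tiny_geo()
  covs <- generate_covariates(geo, codes = c("GDPC", "HOLS", "TEMP"),
                              seed = 4)
  gdpc <- covs$value[covs$code == "GDPC"]
  expect_true(all(gdpc >= 2.88 & gdpc <= 6.59))
  hols <- covs$value[covs$code == "HOLS"]
  expect_true(all(hols == floor(hols) & hols >= 0 & hols <= 5))
  expect_identical(covs, generate_covariates(geo, codes = c("GDPC", "HOLS",
                                                            "TEMP"),
                                             seed = 4))
  expect_error(generate_covariates(geo, codes = "NOPE"), "unknown covariate")
})

test_that("degenerate generator (no variance, zero beta) anchors every month at January", {
  geo <- tiny_geo()
  covs <- center_and_scale(generate_covariates(geo, codes = "TEMP", seed = 1))
  sim <- simulate_flows(geo, covs, truth = list(hyper = list(tau_eps = Inf)),
                        seed = 2)
  tot <- directional_totals(sim$flows, "FR")
  for (u in unique(tot$unit)) for (y in unique(tot$year)) {
    v <- tot$total[tot$unit == u & tot$year == y]
    expect_true(all(v == v[1]))
  }
  ser <- compute_relative_mobility(tot, "FR")
  expect_true(all(ser$R[ser$observed] == 1))
})

test_that("a pure covariate effect reproduces beta * x in the realized response", {
  geo <- generate_geography(1, 1, 3, seed = 9)
  covs <- center_and_scale(generate_covariates(geo, codes = "TEMP", seed = 9))
  # Monte-Carlo over replicate count processes; only integer rounding noise.
  # The effect size keeps the response within about half a decade so count
  # rounding stays negligible.
  beta_true <- 0.05
  reps <- lapply(1:30, function(r) {
    sim <- simulate_flows(geo, covs, truth = list(
      beta = c(TEMP = beta_true), hyper = list(tau_eps = Inf)),
      seed = 100 + r)
    tot <- directional_totals(sim$flows, "FR")
    ser <- compute_relative_mobility(tot, "FR")
    merge(ser[ser$observed & ser$month != 1, ],
          sim$truth$logR, by = c("unit", "year", "month"))
  })
  ser <- do.call(rbind, reps)
  keys <- paste(ser$unit, ser$year, ser$month)
  x <- covariate_matrix(covs, data.frame(unit = ser$unit, year = ser$year,
                                         month = ser$month), "TEMP")[, 1]
  err <- ser$logR.x - beta_true * x
  se <- stats::sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 3 * se + 1e-4)
  expect_lt(max(abs(err)), 0.01)  # rounding error only
})

test_that("flow simulation is seed-deterministic", {
  geo <- tiny_geo()
  covs <- center_and_scale(generate_covariates(geo, codes = "TEMP", seed = 1))
  tr <- list(beta = c(TEMP = 0.1),
             hyper = list(tau_eps = 400, temporal = list(tau = 25, rho = 0.5)))
  s1 <- simulate_flows(geo, covs, tr, seed = 5)
  s2 <- simulate_flows(geo, covs, tr, seed = 5)
  expect_identical(s1, s2)
})

test_that("weekly mode conserves monthly totals exactly", {
  geo <- tiny_geo()
  covs <- center_and_scale(generate_covariates(geo, codes = "TEMP", seed = 1))
  sm <- simulate_flows(geo, covs, seed = 3, weekly = FALSE)
  sw <- simulate_flows(geo, covs, seed = 3, weekly = TRUE)
  agg <- aggregate_weekly_to_monthly(sw$flows)
  expect_equal(sum(agg$count), sum(sm$flows$count))
})

test_that("privacy mechanism has the advertised Laplace moments", {
  set.seed(1)
  eps <- 0.66
  n <- 1e5
  flows <- data.frame(origin = "a", dest = "b", year = 2018L,
                      month = rep(1:12, length.out = n),
                      count = rep(1e6, n))
  out <- apply_privacy(flows, privacy_params(epsilon = eps,
                                             suppression_threshold = 100),
                       seed = 3)
  noise <- out$count - 1e6
  expect_equal(nrow(out), n)  # counts far above threshold: nothing removed
  expect_lt(abs(mean(noise)), 3 * sqrt(2 / eps^2 / n))
  expect_lt(abs(stats::var(noise) - 2 / eps^2) / (2 / eps^2), 0.05)
})

test_that("noisy counts below the suppression threshold are removed, others rounded", {
  flows <- data.frame(origin = "a", dest = c("b", "c"), year = 2018L,
                      month = 1L, count = c(99, 150))
  # enormous epsilon: negligible noise, so the decision is driven by count
  out <- apply_privacy(flows, privacy_params(epsilon = 1e6), seed = 1)
  expect_equal(out$dest, "c")
  expect_equal(out$count, 150)
  expect_true(all(out$count >= 100))
  expect_error(privacy_params(epsilon = -1), "epsilon")
})

test_that("country-block missingness hits the nearest achievable fraction", {
  geo <- generate_geography(1, 10, 1, seed = 2)
  prov <- provinces_of(geo)
  flows <- data.frame(origin = rep(prov, each = length(prov)),
                      dest = rep(prov, length(prov)),
                      year = 2018L, month = 1L, count = 1000)
  out0 <- apply_missingness(flows, geo, c(R1 = 0), seed = 1)
  expect_equal(nrow(out0), nrow(flows))
  out1 <- apply_missingness(flows, geo, c(R1 = 1), seed = 1)
  expect_equal(nrow(out1), 0L)
  out <- apply_missingness(flows, geo, c(R1 = 0.726), seed = 1)
  removed <- attr(out, "removed_countries")
  expect_true(length(removed) %in% c(7L, 8L))
  rm_prov <- prov[geo$country_of[prov] %in% removed]
  expect_false(any(out$origin %in% rm_prov | out$dest %in% rm_prov))
})
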