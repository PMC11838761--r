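# Configuration, orchestration and file I/O for the two modelling pathways
# (country-level and regional-level) plus the descriptive exports. Every run
# is reproducible end to end from (config, seed): all randomness flows from
# the root seed through per-stage derived streams.

#' Build a run configuration
#'
#' Returns the default configuration, with any supplied element overriding
#' the default. Sections: \code{simulate} (geography sizes, covariate codes,
#' generating truth, privacy, missingness), \code{selection} (candidate
#' codes, p_exit, VIF/condition limits), \code{engine} (interaction type,
#' optimizer control, coverage gates), \code{directions}, \code{seed},
#' \code{out_dir}.
#'
#' @param ... named overrides, nested lists merged one level deep.
#' @return list of class \code{mob_run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    directions = c("FR", "TO"),
    simulate = list(
      n_regions = 2L, countries_per_region = 2L, provinces_per_country = 4L,
      codes = c("TEMP", "PREC", "GDPC", "ACCS"),
      beta = c(TEMP = 0.02, GDPC = 0.15),
      hyper = list(tau_eps = 400,
                   spatial = list(tau = 50, phi = 0.5),
                   temporal = list(tau = 25, rho = 0.6),
                   interaction = list(tau = 400)),
      privacy = list(epsilon = 0.66, delta = 2.1e-29,
                     suppression_threshold = 100L),
      missing_fractions = NULL,
      weekly = FALSE,
      years = c(2018L, 2019L)),
    selection = list(candidates = NULL, p_exit = 0.05, vif_limit = 10,
                     cond_limit = 30),
    engine = list(interaction_type = "I", maxit = 300L,
                  min_months = 6L, min_provinces = 2L, min_january = 100)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      for (sub in names(over[[nm]])) cfg[[nm]][[sub]] <- over[[nm]][[sub]]
    } else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "mob_run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file whose top-level keys match \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Simulate a full synthetic study dataset
#'
#' Geography, covariates, ground-truth flows, the privacy mechanism, and
#' (optionally) country-block missingness, all from the configuration's root
#' seed.
#'
#' @param config a \code{\link{run_config}}.
#' @return list: geo, covs, flows_raw, flows (privatized, post-missingness),
#'   truth, removed_countries.
#' @export
simulate_study <- function(config = run_config()) {
  sc <- config$simulate
  geo <- generate_geography(sc$n_regions, sc$countries_per_region,
                            sc$provinces_per_country,
                            seed = derive_seed(config$seed, "geo"))
  covs <- generate_covariates(geo, years = sc$years, codes = sc$codes,
                              seed = derive_seed(config$seed, "covs"))
  ccovs <- center_and_scale(covs)
  sim <- simulate_flows(geo, ccovs,
                        truth = list(beta = sc$beta, hyper = sc$hyper),
                        seed = derive_seed(config$seed, "sim"),
                        weekly = isTRUE(sc$weekly), years = sc$years)
  flows <- sim$flows
  if (isTRUE(sc$weekly)) flows <- aggregate_weekly_to_monthly(flows)
  flows <- apply_privacy(flows, do.call(privacy_params, sc$privacy),
                         seed = derive_seed(config$seed, "priv"))
  removed <- character(0)
  if (!is.null(sc$missing_fractions)) {
    flows <- apply_missingness(flows, geo,
                               fractions = unlist(sc$missing_fractions),
                               seed = derive_seed(config$seed, "miss"))
    removed <- attr(flows, "removed_countries")
  }
  list(geo = geo, covs = covs, flows_raw = sim$flows, flows = flows,
       truth = sim$truth, removed_countries = removed)
}

prepare_series <- function(flows, direction, min_january) {
  totals <- directional_totals(flows, direction = direction,
                               include_self = TRUE)
  compute_relative_mobility(totals, direction = direction,
                            min_january = min_january)
}

select_for_scope <- function(series, covs, geo, scope, direction, config,
                             scale = FALSE) {
  prov <- provinces_of(geo, scope)
  obs <- series[series$unit %in% prov & series$direction == direction &
                  series$observed & series$month != 1L, ]
  cand <- config$selection$candidates %||% sort(unique(covs$code))
  scoped <- covs[covs$unit %in% prov & covs$code %in% cand, , drop = FALSE]
  scoped <- center_and_scale(scoped, scale = scale)
  keys <- obs[, c("unit", "year", "month")]
  Xm <- covariate_matrix(scoped, keys, cand)
  sel <- select_terms(obs$logR, Xm, p_exit = config$selection$p_exit,
                      vif_limit = config$selection$vif_limit,
                      cond_limit = config$selection$cond_limit)
  list(terms = sel$terms, diagnostics = sel$diagnostics, covs = scoped,
       centering = attr(scoped, "centering"))
}

#' Run the country-level modelling pathway
#'
#' For every country meeting the coverage gate (at least
#' \code{engine$min_provinces} provinces with a usable January baseline and
#' \code{engine$min_months} observed months) and every direction: prepare
#' the response, select terms, fit the country model, summarize and
#' calibrate. Countries failing the gate are skipped with a recorded
#' reason. Artifacts are written under \code{out_dir} when set.
#'
#' @param config a \code{\link{run_config}}.
#' @param study optional pre-simulated study (\code{\link{simulate_study}});
#'   simulated from the config when absent.
#' @return list of class \code{mob_pathway_result}: \code{fits} (per
#'   country x direction), \code{skipped}, \code{manifest}.
#' @export
run_country_pathway <- function(config = run_config(), study = NULL) {
  study <- study %||% simulate_study(config)
  fits <- list(); skipped <- list()
  for (direction in config$directions) {
    series <- prepare_series(study$flows, direction,
                             config$engine$min_january)
    for (cid in sort(unique(study$geo$country_of))) {
      key <- paste(cid, direction, sep = ".")
      prov <- provinces_of(study$geo, cid)
      obs <- series[series$unit %in% prov & series$observed, ]
      n_months <- length(unique(paste(obs$year, obs$month)))
      n_prov <- length(unique(obs$unit))
      if (n_prov < config$engine$min_provinces ||
          n_months < config$engine$min_months) {
        skipped[[key]] <- sprintf(
          "coverage below gate: %d provinces, %d observed months",
          n_prov, n_months)
        next
      }
      res <- tryCatch({
        sel <- select_for_scope(series, study$covs, study$geo, cid,
                                direction, config, scale = FALSE)
        spec <- model_spec(cid, direction, sel$terms,
                           interaction_type = config$engine$interaction_type)
        model <- build_country_model(study$geo, sel$covs, series, spec,
                                     years = config$simulate$years)
        fit <- fit_mobility_model(model,
                                  control = list(maxit = config$engine$maxit))
        list(fit = fit, terms = sel$terms, diagnostics = sel$diagnostics,
             coefficients = summarize_fixed_effects(fit),
             calibration = calibrate_fit(fit))
      }, error = function(e) e)
      if (inherits(res, "error")) skipped[[key]] <- conditionMessage(res)
      else fits[[key]] <- res
    }
  }
  out <- structure(list(pathway = "country", fits = fits, skipped = skipped,
                        config = config, manifest = NULL),
                   class = "mob_pathway_result")
  if (!is.null(config$out_dir))
    out$manifest <- write_pathway(out, file.path(config$out_dir, "country"))
  out
}

#' Run the regional-level modelling pathway
#'
#' Per region and direction: pool the region's observed responses, select
#' terms region-wide (covariates centred and scaled), fit the three-scale
#' regional model, predict relative mobility for every in-scope province
#' and month (including provinces of data-missing countries), and calibrate
#' on the observed cells.
#'
#' @inheritParams run_country_pathway
#' @return a \code{mob_pathway_result} whose elements carry a
#'   \code{predictions} long table per fit.
#' @export
run_regional_pathway <- function(config = run_config(), study = NULL) {
  study <- study %||% simulate_study(config)
  fits <- list(); skipped <- list()
  regions <- sort(unique(study$geo$region_of))
  for (direction in config$directions) {
    series <- prepare_series(study$flows, direction,
                             config$engine$min_january)
    for (rid in regions) {
      key <- paste(rid, direction, sep = ".")
      res <- tryCatch({
        sel <- select_for_scope(series, study$covs, study$geo, rid,
                                direction, config, scale = TRUE)
        spec <- model_spec(rid, direction, sel$terms,
                           interaction_type = config$engine$interaction_type)
        model <- build_regional_model(study$geo, sel$covs, series, spec,
                                      years = config$simulate$years)
        fit <- fit_mobility_model(model,
                                  control = list(maxit = config$engine$maxit))
        list(fit = fit, terms = sel$terms, diagnostics = sel$diagnostics,
             coefficients = summarize_fixed_effects(fit),
             predictions = predict_missing(fit, model$units),
             calibration = calibrate_fit(fit))
      }, error = function(e) e)
      if (inherits(res, "error")) skipped[[key]] <- conditionMessage(res)
      else fits[[key]] <- res
    }
  }
  out <- structure(list(pathway = "regional", fits = fits, skipped = skipped,
                        config = config, manifest = NULL),
                   class = "mob_pathway_result")
  if (!is.null(config$out_dir))
    out$manifest <- write_pathway(out, file.path(config$out_dir, "regional"))
  out
}

#' Descriptive exports: month-rank table and country-to-country flow matrix
#'
#' The rank table gives each country's months ranked 1..12 by outflow
#' volume within each year; the flow matrix holds log10(total + 1) of
#' country-aggregated counts over the whole record, self-flows on the
#' diagonal.
#'
#' @param flows monthly flow table.
#' @param geo a \code{mob_geography}.
#' @return list: \code{ranks} (country, year, month, rank),
#'   \code{annual_ratio} (country, year, month, ratio), \code{log_matrix}
#'   (country x country).
#' @export
export_descriptives <- function(flows, geo) {
  validate_flows(flows, weekly = FALSE)
  f <- flows
  f$origin <- unname(geo$country_of[f$origin])
  f$dest <- unname(geo$country_of[f$dest])
  totals <- directional_totals(f, "FR", include_self = TRUE)
  countries <- sort(unique(geo$country_of))
  agg <- stats::aggregate(count ~ origin + dest, data = f, FUN = sum)
  M <- matrix(0, length(countries), length(countries),
              dimnames = list(countries, countries))
  M[cbind(match(agg$origin, countries), match(agg$dest, countries))] <-
    agg$count
  list(ranks = stats::setNames(rank_months(totals),
                               c("country", "year", "month", "rank")),
       annual_ratio = stats::setNames(relative_to_annual_mean(totals),
                                      c("country", "year", "month", "ratio")),
       log_matrix = log10(M + 1))
}

# ---- file I/O ----

#' Write a flow table as long CSV
#' @param flows flow table.
#' @param path output file.
#' @export
write_flows_csv <- function(flows, path) {
  utils::write.csv(flows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flow table from long CSV
#' @param path CSV with columns origin,dest,year,month[,week],count.
#' @export
read_flows_csv <- function(path) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_flows(f)
  f
}

#' Write a geography as GeoJSON (centroids) plus an adjacency edge list
#'
#' The GeoJSON carries one Point feature per unit with level and parent in
#' the properties; the adjacency goes to a two-column CSV next to it.
#'
#' @param geo a \code{mob_geography}.
#' @param path output .geojson path; the edge list is written with suffix
#'   \code{_adjacency.csv}.
#' @export
write_geography_json <- function(geo, path) {
  feats <- lapply(seq_len(nrow(geo$units)), function(i) {
    u <- geo$units[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(u$x, u$y)),
         properties = list(id = u$id, level = u$level,
                           parent = if (is.na(u$parent)) NULL else u$parent))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(geo$adjacency,
                   sub("\\.geojson$|\\.json$", "_adjacency.csv", path),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_pathway <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (key in names(result$fits)) {
    r <- result$fits[[key]]
    co <- file.path(dir, paste0(key, "_coefficients.csv"))
    utils::write.csv(r$coefficients, co, row.names = FALSE)
    pr <- file.path(dir, paste0(key, "_predictions.csv"))
    utils::write.csv(r$fit$predictions, pr, row.names = FALSE)
    me <- file.path(dir, paste0(key, "_metrics.json"))
    jsonlite::write_json(unclass(r$calibration), me, auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, co, pr, me)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
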