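# Seeded synthetic geography, covariates, and privatized OD flow generator.
# Every downstream stage of the pipeline is testable against the known ground
# truth these functions record.

#' Catalogue of supported covariate codes
#'
#' The covariate dictionary used across the package: code, long name, units,
#' the transform applied on the model scale, the plausible range of per-unit
#' means on that scale, and the generator class (climatic codes vary smoothly
#' and 12-month periodically; socioeconomic codes are constant within a year;
#' calendar codes are integer day counts per month).
#'
#' @return data.frame with columns \code{code}, \code{name}, \code{units},
#'   \code{transform} (one of \code{none}, \code{log10}, \code{log10p1}),
#'   \code{lo}, \code{hi}, \code{class}, \code{integer}.
#' @export
covariate_codes <- function() {
  tab <- rbind(
    c("DWPT", "2m Dewpoint Temperature",      "C",                 "none",    -10.43, 25.21, "climatic", FALSE),
    c("TEMP", "2m Surface Temperature",       "C",                 "none",      2.71, 37.49, "climatic", FALSE),
    c("EVAP", "Evaporation",                  "log10(mm/day + 1)", "log10p1",   0.02,  6.46, "climatic", FALSE),
    c("LAIH", "LAI High Vegetation",          "m2/m2",             "none",      0.00,  5.98, "climatic", FALSE),
    c("LAIL", "LAI Low Vegetation",           "m2/m2",             "none",      0.00,  4.05, "climatic", FALSE),
    c("PREC", "Precipitation",                "log10(mm/day + 1)", "log10p1",   0.00, 37.37, "climatic", FALSE),
    c("SKRC", "Skin Reservoir Content",       "log10(mm/day + 1)", "log10p1",   0.00,  0.55, "climatic", FALSE),
    c("PRES", "Surface Pressure",             "kPa",               "none",     74.72, 102.12, "climatic", FALSE),
    c("ROFF", "Total Runoff",                 "log10(mm/day + 1)", "log10p1",   0.00, 32.07, "climatic", FALSE),
    c("WINU", "Wind U (Eastward)",            "m/s",               "none",     -5.53,  6.82, "climatic", FALSE),
    c("WINV", "Wind V (Northward)",           "m/s",               "none",     -7.45,  8.33, "climatic", FALSE),
    c("ACCS", "Accessibility",                "log10(minutes)",    "log10",    -1.36,  3.58, "socioeconomic", FALSE),
    c("INFM", "Infant Mortality Rate",        "percent",           "none",      1.04, 20.23, "socioeconomic", FALSE),
    c("NPRF", "No Primary Education, Female", "percent",           "none",      1.39, 49.74, "socioeconomic", FALSE),
    c("NPRM", "No Primary Education, Male",   "percent",           "none",      1.11, 49.08, "socioeconomic", FALSE),
    c("SECF", "Secondary Education, Female",  "percent",           "none",      0.13, 61.10, "socioeconomic", FALSE),
    c("SECM", "Secondary Education, Male",    "percent",           "none",      1.16, 64.22, "socioeconomic", FALSE),
    c("UWCH", "Underweight Children",         "percent",           "none",      1.13, 54.70, "socioeconomic", FALSE),
    c("GDPC", "Mean GDP Per Capita",          "log10(USD per capita)", "log10", 2.88,  6.59, "socioeconomic", FALSE),
    c("NTLS", "VIIRS Night-time Lights",      "log10(nW/cm2/sr + 1)", "log10p1", -0.01, 1.70, "socioeconomic", FALSE),
    c("URBN", "Urban Extent",                 "percent",           "none",      0.00, 99.74, "socioeconomic", FALSE),
    c("HOLS", "Public Holidays",              "days",              "none",      0, 5,  "calendar", TRUE),
    c("HSCH", "School Holidays",              "days",              "none",      0, 31, "calendar", TRUE)
  )
  out <- data.frame(
    code = tab[, 1], name = tab[, 2], units = tab[, 3], transform = tab[, 4],
    lo = as.numeric(tab[, 5]), hi = as.numeric(tab[, 6]), class = tab[, 7],
    integer = as.logical(tab[, 8]), stringsAsFactors = FALSE
  )
  out
}

#' Generate a synthetic administrative hierarchy
#'
#' Builds a region > country > province hierarchy on a jittered planar grid.
#' Provinces of a country sit on a rook-contiguous grid (so each country's
#' province subgraph is connected by construction); countries are laid out on
#' a grid within their region, adjacent when their layout cells touch;
#' cross-border province edges join mutually nearest centroids of adjacent
#' countries, and consecutive regions are stitched through their nearest
#' country pair so the continental graph is connected.
#'
#' @param n_regions,countries_per_region,provinces_per_country positive
#'   integers; up to five regions mirrors the subregional partition used in
#'   continental analyses.
#' @param seed integer seed; output is deterministic given the seed.
#' @return an object of class \code{mob_geography}: list with \code{units}
#'   (id, level, parent, x, y), \code{adjacency} (id_a, id_b, undirected,
#'   province level), \code{country_of}, \code{region_of} lookup vectors.
#' @export
generate_geography <- function(n_regions, countries_per_region,
                               provinces_per_country, seed = 1L) {
  stopifnot_scalar_count(n_regions, "n_regions")
  stopifnot_scalar_count(countries_per_region, "countries_per_region")
  stopifnot_scalar_count(provinces_per_country, "provinces_per_country")
  set.seed(derive_seed(seed, "geography"))

  p <- provinces_per_country
  nc_grid <- ceiling(sqrt(p))
  nr_grid <- ceiling(p / nc_grid)
  ccols <- ceiling(sqrt(countries_per_region))
  crows <- ceiling(countries_per_region / ccols)
  cw <- nc_grid + 1.5  # country box width
  ch <- nr_grid + 1.5
  rw <- ccols * cw + 3 # region width

  units <- list(); adj <- list(); k <- 0L
  country_pos <- list()
  for (r in seq_len(n_regions)) {
    rid <- sprintf("R%d", r)
    for (co in seq_len(countries_per_region)) {
      cid <- sprintf("%s.C%02d", rid, co)
      gi <- (co - 1) %/% ccols; gj <- (co - 1) %% ccols
      ox <- (r - 1) * rw + gj * cw
      oy <- gi * ch
      country_pos[[cid]] <- c(r, gi, gj)
      cells <- seq_len(p) - 1L
      ci <- cells %/% nc_grid; cj <- cells %% nc_grid
      x <- ox + cj + 0.5 + stats::runif(p, -0.2, 0.2)
      y <- oy + ci + 0.5 + stats::runif(p, -0.2, 0.2)
      pid <- sprintf("%s.P%02d", cid, seq_len(p))
      k <- k + 1L
      units[[k]] <- data.frame(
        id = c(pid), level = "province", parent = cid,
        x = x, y = y, stringsAsFactors = FALSE
      )
      # rook adjacency on the province grid
      for (a in seq_len(p)) for (b in seq_len(p)) {
        if (a < b && abs(ci[a] - ci[b]) + abs(cj[a] - cj[b]) == 1L)
          adj[[length(adj) + 1L]] <- c(pid[a], pid[b])
      }
    }
  }
  prov <- do.call(rbind, units)
  country_of <- stats::setNames(prov$parent, prov$id)
  region_of_country <- stats::setNames(
    sub("^(R[0-9]+)\\..*$", "\\1", names(country_pos)), names(country_pos))
  region_of <- stats::setNames(region_of_country[country_of], prov$id)

  # country adjacency within region from the layout grid, plus a chain link
  # between consecutive regions
  cids <- names(country_pos)
  cadj <- list()
  for (a in seq_along(cids)) for (b in seq_along(cids)) {
    if (a >= b) next
    pa <- country_pos[[a]]; pb <- country_pos[[b]]
    if (pa[1] == pb[1] && abs(pa[2] - pb[2]) + abs(pa[3] - pb[3]) == 1L)
      cadj[[length(cadj) + 1L]] <- c(cids[a], cids[b])
  }
  cent <- function(cid) {
    m <- prov[prov$parent == cid, c("x", "y")]
    c(mean(m$x), mean(m$y))
  }
  if (n_regions > 1L) {
    for (r in seq_len(n_regions - 1L)) {
      ca <- cids[region_of_country[cids] == sprintf("R%d", r)]
      cb <- cids[region_of_country[cids] == sprintf("R%d", r + 1L)]
      d <- outer(ca, cb, Vectorize(function(i, j) {
        sum((cent(i) - cent(j))^2)
      }))
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      cadj[[length(cadj) + 1L]] <- c(ca[ij[1]], cb[ij[2]])
    }
  }

  # cross-border province edges: mutual nearest centroids across each
  # adjacent country pair (always at least the overall nearest pair)
  for (e in cadj) {
    pa <- prov[prov$parent == e[1], ]; pb <- prov[prov$parent == e[2], ]
    d <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), Vectorize(function(i, j) {
      (pa$x[i] - pb$x[j])^2 + (pa$y[i] - pb$y[j])^2
    }))
    near_b <- apply(d, 1, which.min); near_a <- apply(d, 2, which.min)
    added <- FALSE
    for (i in seq_len(nrow(pa))) {
      j <- near_b[i]
      if (near_a[j] == i) {
        adj[[length(adj) + 1L]] <- c(pa$id[i], pb$id[j]); added <- TRUE
      }
    }
    if (!added) {
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      adj[[length(adj) + 1L]] <- c(pa$id[ij[1]], pb$id[ij[2]])
    }
  }

  amat <- do.call(rbind, adj)
  adjacency <- unique(data.frame(id_a = pmin(amat[, 1], amat[, 2]),
                                 id_b = pmax(amat[, 1], amat[, 2]),
                                 stringsAsFactors = FALSE))
  adjacency <- adjacency[order(adjacency$id_a, adjacency$id_b), ]
  rownames(adjacency) <- NULL

  countries <- data.frame(
    id = cids, level = "country", parent = region_of_country[cids],
    x = vapply(cids, function(i) cent(i)[1], 0),
    y = vapply(cids, function(i) cent(i)[2], 0), stringsAsFactors = FALSE
  )
  regions <- data.frame(
    id = sprintf("R%d", seq_len(n_regions)), level = "region", parent = NA,
    x = vapply(seq_len(n_regions), function(r) {
      mean(prov$x[region_of == sprintf("R%d", r)])
    }, 0),
    y = vapply(seq_len(n_regions), function(r) {
      mean(prov$y[region_of == sprintf("R%d", r)])
    }, 0), stringsAsFactors = FALSE
  )
  all_units <- rbind(regions, countries, prov)
  rownames(all_units) <- NULL

  structure(list(
    units = all_units, adjacency = adjacency,
    country_of = country_of, region_of = region_of,
    country_adjacency = unique(data.frame(
      id_a = vapply(cadj, function(e) min(e), ""),
      id_b = vapply(cadj, function(e) max(e), ""),
      stringsAsFactors = FALSE)),
    seed = seed
  ), class = "mob_geography")
}

#' @exportS3Method base::print
print.mob_geography <- function(x, ...) {
  np <- sum(x$units$level == "province")
  cat(sprintf("<mob_geography> %d regions, %d countries, %d provinces, %d province edges\n",
              sum(x$units$level == "region"), sum(x$units$level == "country"),
              np, nrow(x$adjacency)))
  invisible(x)
}

#' Province ids of a geography, optionally restricted to a scope
#' @param geo a \code{mob_geography}.
#' @param scope a region id, country id, or NULL for all provinces.
#' @return character vector of province ids.
#' @export
provinces_of <- function(geo, scope = NULL) {
  ids <- names(geo$country_of)
  if (is.null(scope)) return(ids)
  if (scope %in% unique(geo$region_of)) return(ids[geo$region_of[ids] == scope])
  if (scope %in% unique(geo$country_of)) return(ids[geo$country_of[ids] == scope])
  stop(sprintf("scope '%s' is not a region or country of this geography", scope),
       call. = FALSE)
}

#' Generate synthetic monthly covariates on the model scale
#'
#' Values are drawn directly on the (already transformed) model scale so that
#' every generated value — and hence every per-code mean — lies inside the
#' catalogue range for that code. Climatic codes follow a smooth 12-month
#' periodic seasonal curve with a region-level phase; socioeconomic codes are
#' constant across months within a year; calendar codes are integer day
#' counts drawn per country-month and shared by its provinces.
#'
#' @param geo a \code{mob_geography}.
#' @param years integer vector of study years.
#' @param codes covariate codes (subset of \code{covariate_codes()$code}).
#' @param seed integer seed.
#' @return data.frame (unit, year, month, code, value) with attribute
#'   \code{transforms}; class \code{mob_covariates}.
#' @export
generate_covariates <- function(geo, years = c(2018L, 2019L),
                                codes = c("TEMP", "PREC", "GDPC", "ACCS"),
                                seed = 1L) {
  cat_tab <- covariate_codes()
  unknown <- setdiff(codes, cat_tab$code)
  if (length(unknown))
    stop("unknown covariate code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  set.seed(derive_seed(seed, "covariates"))
  prov <- provinces_of(geo)
  months <- 1:12
  out <- list()
  for (code in codes) {
    row <- cat_tab[cat_tab$code == code, ]
    lo <- row$lo; hi <- row$hi; mid <- (lo + hi) / 2; half <- (hi - lo) / 2
    if (row$class == "climatic") {
      base <- stats::runif(length(prov), mid - 0.5 * half, mid + 0.5 * half)
      phase <- stats::setNames(
        sample(0:11, length(unique(geo$region_of)), replace = TRUE),
        unique(geo$region_of))
      amp <- pmin(base - lo, hi - base) * stats::runif(length(prov), 0.3, 0.9)
      for (y in years) {
        v <- outer(seq_along(prov), months, function(i, m) {
          base[i] + amp[i] * sin(2 * pi * (m - phase[geo$region_of[prov[i]]]) / 12)
        })
        out[[length(out) + 1L]] <- data.frame(
          unit = rep(prov, times = 12), year = y,
          month = rep(months, each = length(prov)),
          code = code, value = as.vector(v), stringsAsFactors = FALSE)
      }
    } else if (row$class == "socioeconomic") {
      for (y in years) {
        v <- stats::runif(length(prov), mid - 0.9 * half, mid + 0.9 * half)
        out[[length(out) + 1L]] <- data.frame(
          unit = rep(prov, times = 12), year = y,
          month = rep(months, each = length(prov)),
          code = code, value = rep(v, times = 12), stringsAsFactors = FALSE)
      }
    } else { # calendar: integer days per country-month
      ctry <- unique(geo$country_of)
      for (y in years) {
        v <- matrix(sample(seq(lo, hi), length(ctry) * 12, replace = TRUE),
                    length(ctry), 12, dimnames = list(ctry, NULL))
        out[[length(out) + 1L]] <- data.frame(
          unit = rep(prov, times = 12), year = y,
          month = rep(months, each = length(prov)),
          code = code,
          value = as.vector(v[cbind(match(geo$country_of[rep(prov, 12)], ctry),
                                    rep(months, each = length(prov)))]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$code, res$year, res$month, res$unit), ]
  rownames(res) <- NULL
  attr(res, "transforms") <- cat_tab[cat_tab$code %in% codes,
                                     c("code", "transform")]
  class(res) <- c("mob_covariates", "data.frame")
  res
}

#' Covariate lookup matrix for a set of observation keys
#'
#' Arranges a long covariate table into a numeric matrix with one row per
#' requested (unit, year, month) key and one column per code — the shape
#' the stepwise selection takes its candidate main effects in.
#'
#' @param covs covariate table (unit, year, month, code, value).
#' @param keys data.frame with columns unit, year, month.
#' @param codes covariate codes to extract.
#' @return numeric matrix, \code{nrow(keys)} x \code{length(codes)}.
#' @export
covariate_matrix <- function(covs, keys, codes) {
  X <- matrix(NA_real_, nrow(keys), length(codes),
              dimnames = list(NULL, codes))
  ck <- paste(covs$unit, covs$year, covs$month)
  kk <- paste(keys$unit, keys$year, keys$month)
  for (code in codes) {
    sel <- covs$code == code
    X[, code] <- covs$value[sel][match(kk, ck[sel])]
  }
  if (anyNA(X)) stop("covariate table does not cover all requested keys",
                     call. = FALSE)
  X
}

# ---- ground-truth samplers (eigen-based; independent of the fitting engine)

sample_icar_scaled <- function(struct_block) {
  S <- as.matrix(struct_block$structure)
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  drop(e$vectors[, pos, drop = FALSE] %*%
         (stats::rnorm(sum(pos)) / sqrt(e$values[pos])))
}

sample_bym2_truth <- function(adj_block_scaled, tau, phi) {
  n <- nrow(adj_block_scaled$structure)
  if (!is.finite(tau)) return(numeric(n))
  v <- stats::rnorm(n)
  u <- if (phi > 0) sample_icar_scaled(adj_block_scaled) else numeric(n)
  (sqrt(1 - phi) * v + sqrt(phi) * u) / sqrt(tau)
}

sample_ar1_truth <- function(n, tau, rho) {
  if (!is.finite(tau)) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  for (t in seq_len(n - 1)) x[t + 1] <- rho * x[t] + stats::rnorm(1, sd = sqrt(1 - rho^2))
  x / sqrt(tau)
}

#' Simulate privat-izable OD flows with recorded ground truth
#'
#' Draws log relative mobility per (province, month) from the additive
#' spatiotemporal model — BYM2 spatial effect, AR1 temporal effect,
#' space-time interaction, fixed covariate effects, Gaussian noise — then
#' converts it to integer OD counts against a log-uniform January baseline.
#' January months are the anchor: their log relative mobility is 0 by
#' construction, so each unit's January total equals its baseline. A
#' distance-decay mixture allocates each province's outflow mostly to itself
#' and nearby provinces.
#'
#' @param geo a \code{mob_geography}.
#' @param covs a \code{mob_covariates} table covering the study window.
#' @param truth list with \code{beta} (named by covariate code; optional) and
#'   \code{hyper} (list with \code{tau_eps} and optional \code{spatial}
#'   (tau, phi), \code{temporal} (tau, rho), \code{interaction} (tau));
#'   \code{tau = Inf} or an absent block means that variance component is 0.
#' @param seed integer seed.
#' @param direction which marginal carries the signal: \code{"FR"} scales all
#'   flows out of a unit by its relative mobility, \code{"TO"} scales inflows.
#' @param weekly if TRUE, monthly counts are split 4/5-wise into weekly rows
#'   (months with 31 days get 5 weeks) so the weekly-to-monthly aggregation
#'   path is exercised; totals are conserved exactly.
#' @param years study years.
#' @return list with \code{flows} (origin, dest, year, month[, week], count)
#'   and \code{truth} (class \code{mob_ground_truth}: beta, hyper, latent
#'   effects per country, realized logR table, baseline counts).
#' @export
simulate_flows <- function(geo, covs, truth = list(), seed = 1L,
                           direction = c("FR", "TO"), weekly = FALSE,
                           years = c(2018L, 2019L)) {
  direction <- match.arg(direction)
  set.seed(derive_seed(seed, "flows"))
  beta <- truth$beta %||% numeric(0)
  hyper <- truth$hyper %||% list(tau_eps = Inf)
  prov <- provinces_of(geo)
  n_time <- 12L * length(years)
  if (length(beta)) {
    if (!all(names(beta) %in% unique(covs$code)))
      stop("truth$beta names must be covariate codes present in `covs`",
           call. = FALSE)
  }

  keys <- data.frame(unit = rep(prov, times = n_time),
                     year = rep(rep(years, each = 12L), each = length(prov)),
                     month = rep(rep(1:12, times = length(years)),
                                 each = length(prov)),
                     stringsAsFactors = FALSE)
  xb <- if (length(beta)) {
    drop(covariate_matrix(covs, keys, names(beta)) %*% beta)
  } else numeric(nrow(keys))

  countries <- unique(geo$country_of)
  latent <- list()
  logR <- numeric(nrow(keys))
  for (cid in countries) {
    cp <- provinces_of(geo, cid)
    A <- C <- NULL
    if (!is.null(hyper$spatial) && is.finite(hyper$spatial$tau)) {
      blk <- scale_icar(icar_structure(geo$adjacency, ids = cp))
      A <- stats::setNames(
        sample_bym2_truth(blk, hyper$spatial$tau, hyper$spatial$phi %||% 0.5), cp)
    } else A <- stats::setNames(numeric(length(cp)), cp)
    B <- if (!is.null(hyper$temporal) && is.finite(hyper$temporal$tau)) {
      sample_ar1_truth(n_time, hyper$temporal$tau, hyper$temporal$rho %||% 0.5)
    } else numeric(n_time)
    Ct <- if (!is.null(hyper$interaction) && is.finite(hyper$interaction$tau)) {
      matrix(stats::rnorm(length(cp) * n_time,
                          sd = 1 / sqrt(hyper$interaction$tau)),
             length(cp), n_time, dimnames = list(cp, NULL))
    } else matrix(0, length(cp), n_time, dimnames = list(cp, NULL))
    latent[[cid]] <- list(spatial = A, temporal = B, interaction = Ct)

    sel <- which(keys$unit %in% cp)
    mi <- month_index(keys$year[sel], keys$month[sel], min(years))
    eps <- if (is.finite(hyper$tau_eps %||% Inf)) {
      stats::rnorm(length(sel), sd = 1 / sqrt(hyper$tau_eps))
    } else numeric(length(sel))
    logR[sel] <- A[keys$unit[sel]] + B[mi] +
      Ct[cbind(match(keys$unit[sel], cp), mi)] + xb[sel] + eps
  }
  logR[keys$month == 1L] <- 0  # January anchors the response

  # January baseline OD allocation with distance decay
  xy <- geo$units[match(prov, geo$units$id), c("x", "y")]
  D <- as.matrix(stats::dist(xy))
  lambda <- 2 * mean(apply(D + diag(Inf, nrow(D)), 1, min))
  mass <- 10^stats::runif(length(prov), 3, 5)
  W <- exp(-D / lambda); diag(W) <- 0
  W <- W / rowSums(W)
  base <- 0.6 * diag(mass) + 0.4 * mass * W  # row a = outflow of province a
  dimnames(base) <- list(prov, prov)
  base <- round_half_away(base)

  lr <- matrix(logR, nrow = length(prov),
               dimnames = list(prov, NULL))  # prov x time (keys are unit-major)
  rows <- list()
  for (t in seq_len(n_time)) {
    scalef <- 10^lr[, t]
    cnt <- if (direction == "FR") base * scalef else t(t(base) * scalef)
    cnt <- round_half_away(cnt)
    nz <- which(cnt > 0, arr.ind = TRUE)
    rows[[t]] <- data.frame(
      origin = prov[nz[, 1]], dest = prov[nz[, 2]],
      year = years[(t - 1) %/% 12 + 1], month = (t - 1) %% 12 + 1,
      count = cnt[nz], stringsAsFactors = FALSE)
  }
  flows <- do.call(rbind, rows)
  flows <- flows[order(flows$year, flows$month, flows$origin, flows$dest), ]
  rownames(flows) <- NULL

  if (weekly) flows <- split_monthly_to_weekly(flows)

  gt <- structure(list(
    beta = beta, hyper = hyper, latent = latent,
    logR = data.frame(keys, logR = logR, stringsAsFactors = FALSE),
    baseline = base, direction = direction
  ), class = "mob_ground_truth")
  list(flows = flows, truth = gt)
}

# deterministic 4/5-wise split preserving monthly totals exactly
split_monthly_to_weekly <- function(flows) {
  days31 <- c(1, 3, 5, 7, 8, 10, 12)
  nweek <- ifelse(flows$month %in% days31, 5L, 4L)
  idx <- rep(seq_len(nrow(flows)), nweek)
  wk <- sequence(nweek)
  base <- flows$count[idx] %/% rep(nweek, nweek)
  extra <- as.integer(wk <= (flows$count[idx] %% rep(nweek, nweek)))
  out <- data.frame(flows[idx, c("origin", "dest", "year", "month")],
                    week = wk, count = base + extra,
                    stringsAsFactors = FALSE)
  out <- out[out$count > 0, ]
  rownames(out) <- NULL
  out
}

#' Privacy-mechanism parameters
#'
#' @param epsilon Laplace parameter (noise scale is \code{1/epsilon});
#'   default 0.66.
#' @param delta privacy-accounting slack, carried as metadata only.
#' @param suppression_threshold counts whose noisy value falls below this are
#'   removed; default 100.
#' @return list of class \code{mob_privacy_params}.
#' @export
privacy_params <- function(epsilon = 0.66, delta = 2.1e-29,
                           suppression_threshold = 100L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("`epsilon` must be a single positive number", call. = FALSE)
  if (!is.numeric(delta) || delta < 0 || delta >= 1)
    stop("`delta` must lie in [0, 1)", call. = FALSE)
  stopifnot_scalar_count(suppression_threshold, "suppression_threshold")
  structure(list(epsilon = epsilon, delta = delta,
                 suppression_threshold = as.integer(suppression_threshold)),
            class = "mob_privacy_params")
}

#' Apply the Laplace-noise + suppression privacy mechanism
#'
#' Adds zero-mean Laplace noise of scale \code{1/epsilon} to every count,
#' removes cells whose noisy value is below the suppression threshold, and
#' rounds retained noisy counts half-away-from-zero (published counts are
#' user counts). Removed cells are absent from the output, not zero.
#'
#' @param flows flow table with a \code{count} column.
#' @param params a \code{\link{privacy_params}} object.
#' @param seed integer seed.
#' @return the privatized flow table.
#' @export
apply_privacy <- function(flows, params = privacy_params(), seed = 1L) {
  if (!inherits(params, "mob_privacy_params")) params <- do.call(privacy_params, params)
  if (any(flows$count < 0)) stop("raw counts must be non-negative", call. = FALSE)
  set.seed(derive_seed(seed, "privacy"))
  noisy <- flows$count + rlaplace(nrow(flows), scale = 1 / params$epsilon)
  keep <- noisy >= params$suppression_threshold
  out <- flows[keep, , drop = FALSE]
  out$count <- round_half_away(noisy[keep])
  rownames(out) <- NULL
  attr(out, "privacy") <- params
  attr(out, "n_suppressed") <- sum(!keep)
  out
}

#' Remove whole-country blocks of flows to emulate missing coverage
#'
#' For each region, countries are removed (all flows touching any of their
#' provinces) until the fraction of the region's provinces belonging to
#' removed countries is as close as achievable to the requested fraction —
#' coverage gaps in aggregated mobility data are country-shaped, not
#' row-shaped.
#'
#' @param flows flow table.
#' @param geo a \code{mob_geography}.
#' @param fractions named numeric vector (names = region ids) of target
#'   missing-province fractions in [0, 1]; unnamed regions default to 0.
#' @param seed integer seed (order in which countries are considered).
#' @return flow table with attributes \code{removed_countries} and
#'   \code{achieved_fractions}.
#' @export
apply_missingness <- function(flows, geo, fractions = numeric(0), seed = 1L) {
  if (length(fractions) && (any(fractions < 0) || any(fractions > 1)))
    stop("`fractions` must lie in [0, 1]", call. = FALSE)
  set.seed(derive_seed(seed, "missingness"))
  removed <- character(0)
  achieved <- stats::setNames(numeric(0), character(0))
  for (rid in names(fractions)) {
    f <- fractions[[rid]]
    ctries <- unique(geo$country_of[provinces_of(geo, rid)])
    sizes <- vapply(ctries, function(cc) length(provinces_of(geo, cc)), 0L)
    ord <- sample(seq_along(ctries))
    cum <- cumsum(sizes[ord]) / sum(sizes)
    k <- which.min(abs(c(0, cum) - f)) - 1L
    sel <- if (k > 0) ctries[ord[seq_len(k)]] else character(0)
    removed <- c(removed, sel)
    achieved[rid] <- if (k > 0) cum[k] else 0
  }
  rm_prov <- names(geo$country_of)[geo$country_of %in% removed]
  out <- flows[!(flows$origin %in% rm_prov) & !(flows$dest %in% rm_prov), ,
               drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_countries") <- removed
  attr(out, "achieved_fractions") <- achieved
  out
}
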