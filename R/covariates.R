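# Covariate preparation: zonal statistics over gridded fields, unit
# transforms, centring/scaling, and interaction-safe design matrices.

#' Construct a zonal grid
#'
#' @param raster numeric matrix of pixel values.
#' @param zones same-shape matrix of zone labels (character or integer).
#' @param nodata value in \code{raster} to treat as missing (or NA).
#' @return list of class \code{mob_zonal_grid}.
#' @export
zonal_grid <- function(raster, zones, nodata = NA) {
  if (!is.matrix(raster) || !is.matrix(zones) ||
      !all(dim(raster) == dim(zones)))
    stop("`raster` and `zones` must be matrices of identical shape",
         call. = FALSE)
  mask <- if (is.na(nodata)) is.na(raster) else raster == nodata | is.na(raster)
  structure(list(raster = raster, zones = zones, mask = mask),
            class = "mob_zonal_grid")
}

#' Zonal statistics over an administrative raster
#'
#' Computes the requested statistics of pixel values per zone, over
#' non-missing pixels only. The median of an even pixel count is the mean of
#' the two middle values.
#'
#' @param g a \code{\link{zonal_grid}}.
#' @param stats_req subset of mean, median, min, max, sum.
#' @return data.frame with one row per zone and one column per statistic.
#' @export
zonal_statistics <- function(g, stats_req = c("mean", "median", "min", "max",
                                              "sum")) {
  stats_req <- match.arg(stats_req, several.ok = TRUE)
  z <- g$zones[!g$mask]
  v <- g$raster[!g$mask]
  all_zones <- sort(unique(as.vector(g$zones)))
  empty <- setdiff(all_zones, unique(z))
  if (length(empty))
    stop("zone(s) with no valid pixels: ", paste(empty, collapse = ", "),
         call. = FALSE)
  fns <- list(mean = mean, median = stats::median, min = min, max = max,
              sum = sum)
  out <- data.frame(zone = all_zones, stringsAsFactors = FALSE)
  for (s in stats_req)
    out[[s]] <- as.numeric(tapply(v, z, fns[[s]])[as.character(all_zones)])
  out
}

covariate_transform_of <- function(code) {
  tab <- covariate_codes()
  i <- match(code, tab$code)
  if (is.na(i)) stop("unknown covariate code: ", code, call. = FALSE)
  tab$transform[i]
}

#' Apply a covariate's unit transform
#'
#' Maps raw covariate values to the model scale according to the covariate
#' dictionary: \code{log10} (e.g. GDP per capita, accessibility minutes),
#' \code{log10(x + 1)} (e.g. runoff or precipitation sums, night-time
#' lights), or identity for codes modelled in native units.
#'
#' @param values numeric vector on the raw scale.
#' @param code covariate code.
#' @return transformed values.
#' @export
transform_covariate <- function(values, code) {
  tr <- covariate_transform_of(code)
  if (tr == "log10") {
    bad <- which(values <= 0)
    if (length(bad))
      stop(sprintf("%s requires positive values for log10; offending value %g",
                   code, values[bad[1]]), call. = FALSE)
    log10(values)
  } else if (tr == "log10p1") {
    bad <- which(values < 0)
    if (length(bad))
      stop(sprintf("%s requires non-negative values for log10(x+1); offending value %g",
                   code, values[bad[1]]), call. = FALSE)
    log10(values + 1)
  } else values
}

#' Invert a covariate's unit transform
#' @inheritParams transform_covariate
#' @export
inverse_transform_covariate <- function(values, code) {
  tr <- covariate_transform_of(code)
  if (tr == "log10") 10^values
  else if (tr == "log10p1") 10^values - 1
  else values
}

#' Mean-centre (and optionally scale) covariates within a model scope
#'
#' Subtracts the per-code mean computed over the table's observed rows at
#' the declared level (the whole table for a single country model, or
#' region-wide with additional scaling for regional models). The constants
#' are recorded so prediction designs for data-missing units are built with
#' the same centring, and so the operation is invertible.
#'
#' @param covs a covariate table (unit, year, month, code, value).
#' @param scale divide by the per-code standard deviation as well.
#' @param constants optional centring table from a previous call (code,
#'   center, scale) to reuse frozen constants.
#' @return the table with centred values and attribute \code{centering}.
#' @export
center_and_scale <- function(covs, scale = FALSE, constants = NULL) {
  codes <- sort(unique(covs$code))
  if (is.null(constants)) {
    constants <- data.frame(code = codes, center = NA_real_, scale = 1,
                            stringsAsFactors = FALSE)
    for (i in seq_along(codes)) {
      v <- covs$value[covs$code == codes[i]]
      constants$center[i] <- mean(v)
      if (scale) {
        s <- stats::sd(v)
        if (!is.finite(s) || s == 0)
          stop("degenerate covariate (zero variance): ", codes[i],
               call. = FALSE)
        constants$scale[i] <- s
      }
    }
  }
  i <- match(covs$code, constants$code)
  if (anyNA(i)) stop("centring constants missing for some codes", call. = FALSE)
  covs$value <- (covs$value - constants$center[i]) / constants$scale[i]
  attr(covs, "centering") <- constants
  covs
}

#' A set of fixed-effect model terms
#'
#' Main effects plus unordered pairwise interactions. Every interaction's
#' codes must appear among the mains (hierarchy); duplicates are dropped
#' with a warning.
#'
#' @param mains character vector of covariate codes.
#' @param interactions character vector of "A:B" pairs (order within a pair
#'   irrelevant).
#' @return object of class \code{mob_term_set}.
#' @export
term_set <- function(mains = character(0), interactions = character(0)) {
  if (anyDuplicated(mains)) {
    warning("duplicate main effects dropped")
    mains <- unique(mains)
  }
  ints <- vapply(strsplit(interactions, ":", fixed = TRUE), function(p) {
    if (length(p) != 2L) stop("interactions must be 'A:B' pairs", call. = FALSE)
    paste(sort(p), collapse = ":")
  }, "")
  if (anyDuplicated(ints)) {
    warning("duplicate interactions dropped")
    ints <- unique(ints)
  }
  used <- unique(unlist(strsplit(ints, ":", fixed = TRUE)))
  if (!all(used %in% mains))
    stop("interaction terms must be built from selected main effects: ",
         paste(setdiff(used, mains), collapse = ", "), call. = FALSE)
  structure(list(mains = sort(mains), interactions = sort(ints)),
            class = "mob_term_set")
}

#' @exportS3Method base::print
print.mob_term_set <- function(x, ...) {
  cat("<mob_term_set> mains:", if (length(x$mains)) paste(x$mains, collapse = ", ") else "(none)",
      "\n  interactions:", if (length(x$interactions)) paste(x$interactions, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Build a fixed-effect design matrix from a term set
#'
#' Columns are the intercept, main effects in alphabetical order, then
#' interactions in alphabetical order. Interaction columns are elementwise
#' products of the (already centred) mains and are not re-centred, keeping
#' main-effect interpretation at covariate means.
#'
#' @param covs centred covariate table.
#' @param terms a \code{\link{term_set}}.
#' @param keys data.frame (unit, year, month) giving the observation rows.
#' @return numeric design matrix, first column the intercept.
#' @export
build_design <- function(covs, terms, keys) {
  if (!inherits(terms, "mob_term_set")) stop("`terms` must be a term_set",
                                             call. = FALSE)
  missing_codes <- setdiff(terms$mains, unique(covs$code))
  if (length(missing_codes))
    stop("unknown term(s) not in covariate table: ",
         paste(missing_codes, collapse = ", "), call. = FALSE)
  X <- matrix(1, nrow(keys), 1L, dimnames = list(NULL, "(Intercept)"))
  if (length(terms$mains)) {
    M <- covariate_matrix(covs, keys, terms$mains)
    X <- cbind(X, M)
    for (int in terms$interactions) {
      p <- strsplit(int, ":", fixed = TRUE)[[1]]
      X <- cbind(X, structure(M[, p[1]] * M[, p[2]],
                              dim = c(nrow(keys), 1L),
                              dimnames = list(NULL, int)))
    }
  }
  X
}
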