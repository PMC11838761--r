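# From OD flow tables to the model response: directional January-baseline
# relative mobility, plus the descriptive month-rank and annual-mean views.

validate_flows <- function(flows, weekly = NA) {
  need <- c("origin", "dest", "year", "month", "count")
  if (!all(need %in% names(flows)))
    stop("flow table must have columns origin, dest, year, month, count",
         call. = FALSE)
  if (any(flows$count < 0)) stop("counts must be non-negative", call. = FALSE)
  has_week <- "week" %in% names(flows)
  if (isTRUE(weekly) && !has_week)
    stop("expected weekly flows (a `week` column)", call. = FALSE)
  if (identical(weekly, FALSE) && has_week)
    stop("expected monthly flows but found a `week` column", call. = FALSE)
  invisible(flows)
}

#' Aggregate weekly flow records to a monthly timescale
#'
#' Sums weekly counts within each (origin, dest, year, month) cell. Total
#' counts are conserved exactly. Weekly rows must already carry their month
#' assignment; for calendar ISO weeks use \code{\link{iso_week_month}} first.
#'
#' @param flows weekly flow table (origin, dest, year, month, week, count).
#' @return monthly flow table (origin, dest, year, month, count).
#' @export
aggregate_weekly_to_monthly <- function(flows) {
  validate_flows(flows, weekly = TRUE)
  if (nrow(flows) == 0L)
    return(flows[, c("origin", "dest", "year", "month", "count")])
  agg <- stats::aggregate(count ~ origin + dest + year + month, data = flows,
                          FUN = sum)
  agg <- agg[order(agg$year, agg$month, agg$origin, agg$dest), ]
  rownames(agg) <- NULL
  agg[, c("origin", "dest", "year", "month", "count")]
}

#' Month containing the Thursday of an ISO week
#'
#' Assignment rule for calendar weekly data whose source does not state a
#' week-month mapping: a week belongs to the month containing its Thursday
#' (the ISO-8601 majority rule — at least four of the week's days fall in
#' that month).
#'
#' @param year ISO week-based year.
#' @param week ISO week number (1..53).
#' @return list with \code{year} and \code{month} of the Thursday.
#' @export
iso_week_month <- function(year, week) {
  jan4 <- as.Date(sprintf("%d-01-04", year))
  # back up to the Monday of week 1, then forward to the requested Thursday
  monday1 <- jan4 - (as.integer(format(jan4, "%u")) - 1L)
  thu <- monday1 + (week - 1L) * 7L + 3L
  list(year = as.integer(format(thu, "%Y")),
       month = as.integer(format(thu, "%m")))
}

#' Directional unit-by-month mobility totals
#'
#' Outflow (FR) totals sum a unit's counts over all destinations; inflow
#' (TO) totals sum over all origins. Self-flows (origin = destination) carry
#' substantial internal movement and are included by default.
#'
#' @param flows monthly flow table.
#' @param direction \code{"FR"} (outflow) or \code{"TO"} (inflow).
#' @param include_self include the origin = destination diagonal.
#' @return data.frame (unit, year, month, total).
#' @export
directional_totals <- function(flows, direction = c("FR", "TO"),
                               include_self = TRUE) {
  direction <- match.arg(direction)
  validate_flows(flows, weekly = FALSE)
  if (!include_self) flows <- flows[flows$origin != flows$dest, , drop = FALSE]
  if (nrow(flows) == 0L)
    return(data.frame(unit = character(0), year = integer(0),
                      month = integer(0), total = numeric(0)))
  flows$unit <- if (direction == "FR") flows$origin else flows$dest
  agg <- stats::aggregate(count ~ unit + year + month, data = flows, FUN = sum)
  names(agg)[names(agg) == "count"] <- "total"
  agg <- agg[order(agg$unit, agg$year, agg$month), ]
  rownames(agg) <- NULL
  agg
}

#' January-baseline relative mobility series
#'
#' The model response: for each (unit, year), R_m = x_m / x_Jan, so January
#' is exactly 1 (log10 R = 0). Unit-years whose January total is absent or
#' below \code{min_january} get all 12 months emitted with
#' \code{observed = FALSE} (the response is missing, but the unit remains
#' predictable by the regional models).
#'
#' @param totals unit-by-month totals from \code{\link{directional_totals}}.
#' @param direction label recorded on the series ("FR" or "TO").
#' @param min_january minimum January total for a usable baseline.
#' @return data.frame (unit, direction, year, month, R, logR, observed);
#'   class \code{mob_relative_series}.
#' @export
compute_relative_mobility <- function(totals, direction = "FR",
                                      min_january = 1) {
  if (any(totals$total < 0)) stop("totals must be non-negative", call. = FALSE)
  uy <- unique(totals[, c("unit", "year")])
  out <- list()
  for (i in seq_len(nrow(uy))) {
    u <- uy$unit[i]; y <- uy$year[i]
    sel <- totals$unit == u & totals$year == y
    x <- stats::setNames(rep(NA_real_, 12L), 1:12)
    x[as.character(totals$month[sel])] <- totals$total[sel]
    jan <- x["1"]
    ok <- !is.na(jan) && jan >= min_january && jan > 0
    R <- if (ok) x / jan else rep(NA_real_, 12L)
    if (ok) R[1] <- 1
    out[[i]] <- data.frame(
      unit = u, direction = direction, year = y, month = 1:12,
      R = unname(R), logR = unname(log10(R)),
      observed = ok & !is.na(R), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$logR[res$observed & res$month == 1L] <- 0  # exact anchor
  res <- res[order(res$unit, res$year, res$month), ]
  rownames(res) <- NULL
  class(res) <- c("mob_relative_series", "data.frame")
  res
}

#' Normality diagnostics for the transformed response
#'
#' QQ points against the standard normal plus a straightness statistic (the
#' correlation of the QQ plot) and a Shapiro-Wilk test where sample size
#' permits. Purely descriptive; no filtering is applied.
#'
#' @param x numeric vector of log relative mobility values (NA dropped).
#' @return list with \code{qq} (theoretical, sample), \code{correlation},
#'   \code{shapiro_w}, \code{shapiro_p}, \code{degenerate}, \code{n}.
#' @export
check_gaussian <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("need at least 3 finite values", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(list(qq = NULL, correlation = NA_real_, shapiro_w = NA_real_,
                shapiro_p = NA_real_, degenerate = TRUE, n = length(x)))
  }
  s <- sort(x)
  q <- stats::qnorm(stats::ppoints(length(x)))
  sh <- if (length(x) <= 5000L) stats::shapiro.test(x) else NULL
  list(qq = data.frame(theoretical = q, sample = s),
       correlation = stats::cor(q, s),
       shapiro_w = if (is.null(sh)) NA_real_ else unname(sh$statistic),
       shapiro_p = if (is.null(sh)) NA_real_ else sh$p.value,
       degenerate = FALSE, n = length(x))
}

#' Rank months by mobility volume within each unit-year
#'
#' Dense ranks 1..12 with the highest volume ranked 12; ties are broken by
#' the earlier month taking the lower rank. Unit-years without all 12 months
#' are skipped.
#'
#' @param totals unit-by-month totals.
#' @return data.frame (unit, year, month, rank).
#' @export
rank_months <- function(totals) {
  uy <- unique(totals[, c("unit", "year")])
  out <- list()
  for (i in seq_len(nrow(uy))) {
    sel <- totals$unit == uy$unit[i] & totals$year == uy$year[i]
    if (sum(sel) != 12L) next
    sub <- totals[sel, ]
    sub <- sub[order(sub$month), ]
    out[[length(out) + 1L]] <- data.frame(
      unit = uy$unit[i], year = uy$year[i], month = 1:12,
      rank = rank(sub$total, ties.method = "first"),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(unit = character(0), year = integer(0), month = integer(0),
               rank = integer(0))
  rownames(res) <- NULL
  res
}

#' Monthly mobility relative to the annual mean
#'
#' For each unit-year with 12 observed months, value_m divided by the mean
#' of the 12 values; the 12 ratios average to exactly 1.
#'
#' @param totals unit-by-month totals.
#' @return data.frame (unit, year, month, ratio).
#' @export
relative_to_annual_mean <- function(totals) {
  uy <- unique(totals[, c("unit", "year")])
  out <- list()
  for (i in seq_len(nrow(uy))) {
    sel <- totals$unit == uy$unit[i] & totals$year == uy$year[i]
    if (sum(sel) != 12L) next
    sub <- totals[sel, ]
    sub <- sub[order(sub$month), ]
    mu <- mean(sub$total)
    if (mu == 0) stop("zero annual mean for unit-year ",
                      uy$unit[i], "/", uy$year[i], call. = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      unit = uy$unit[i], year = uy$year[i], month = 1:12,
      ratio = sub$total / mu, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(unit = character(0), year = integer(0), month = integer(0),
               ratio = numeric(0))
  rownames(res) <- NULL
  res
}
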