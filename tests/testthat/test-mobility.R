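# Response construction: aggregation, directional totals, the January
# baseline, normality diagnostics, and the descriptive month summaries.

weekly_fixture <- function(seed = 1, n = 60) {
  set.seed(seed)
  data.frame(origin = sample(letters[1:3], n, TRUE),
             dest = sample(letters[1:3], n, TRUE),
             year = sample(c(2018L, 2019L), n, TRUE),
             month = sample(1:3, n, TRUE),
             week = sample(1:4, n, TRUE),
             count = sample(50:500, n, TRUE))
}

test_that("weekly-to-monthly aggregation sums weeks and conserves totals", {
  f <- data.frame(origin = "a", dest = "b", year = 2018L, month = 2L,
                  week = 1:4, count = rep(100, 4))
  agg <- aggregate_weekly_to_monthly(f)
  expect_equal(agg$count, 400)
  empty <- f[0, ]
  expect_equal(nrow(aggregate_weekly_to_monthly(empty)), 0L)
  # brute-force group-and-sum oracle on a random fixture
  wf <- weekly_fixture()
  agg <- aggregate_weekly_to_monthly(wf)
  for (i in seq_len(nrow(agg))) {
    sel <- wf$origin == agg$origin[i] & wf$dest == agg$dest[i] &
      wf$year == agg$year[i] & wf$month == agg$month[i]
    expect_equal(agg$count[i], sum(wf$count[sel]))
  }
  expect_equal(sum(agg$count), sum(wf$count))
  expect_error(aggregate_weekly_to_monthly(agg), "week")
})

test_that("ISO week-month rule assigns the month containing the Thursday", {
  # ISO week 1 of 2018 has Thursday 2018-01-04; week 5 Thursday 2018-02-01
  expect_equal(iso_week_month(2018, 1)$month, 1L)
  expect_equal(iso_week_month(2018, 5)$month, 2L)
})

test_that("directional totals: definitions, symmetry, brute-force oracle", {
  f <- data.frame(origin = "a", dest = "b", year = 2018L, month = 1L,
                  count = 5)
  fr <- directional_totals(f, "FR", include_self = FALSE)
  to <- directional_totals(f, "TO", include_self = FALSE)
  expect_equal(fr$total[fr$unit == "a"], 5)
  expect_equal(to$total[to$unit == "b"], 5)
  expect_false("a" %in% to$unit)

  set.seed(2)
  g <- expand.grid(origin = letters[1:4], dest = letters[1:4],
                   stringsAsFactors = FALSE)
  g$year <- 2018L; g$month <- 1L; g$count <- sample(1:100, nrow(g))
  # symmetric tensor: FR equals TO
  sym <- g
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m[cbind(g$origin, g$dest)] <- g$count
  ms <- m + t(m)
  sym$count <- ms[cbind(sym$origin, sym$dest)]
  expect_equal(directional_totals(sym, "FR")$total,
               directional_totals(sym, "TO")$total)
  # brute-force double loop
  fr <- directional_totals(g, "FR")
  for (u in letters[1:4]) {
    expect_equal(fr$total[fr$unit == u], sum(g$count[g$origin == u]))
  }
})

test_that("relative mobility anchors January at exactly 1", {
  tot <- data.frame(unit = "a", year = 2018L, month = 1:3,
                    total = c(100, 200, 50))
  ser <- compute_relative_mobility(tot, "FR")
  expect_equal(ser$R[ser$month == 2 & ser$observed], 2)
  expect_equal(ser$logR[ser$month == 2 & ser$observed], log10(2),
               tolerance = 1e-12)
  expect_identical(ser$R[ser$month == 1 & ser$observed], 1)
  expect_identical(ser$logR[ser$month == 1 & ser$observed], 0)
})

test_that("unit-years without a usable January are emitted unobserved", {
  tot <- data.frame(unit = "a", year = 2018L, month = 2:12, total = 100)
  ser <- compute_relative_mobility(tot, "FR")
  expect_equal(nrow(ser), 12L)
  expect_false(any(ser$observed))
  low <- data.frame(unit = "a", year = 2018L, month = 1:12, total = 50)
  expect_false(any(compute_relative_mobility(low, "FR",
                                             min_january = 100)$observed))
  expect_error(compute_relative_mobility(
    data.frame(unit = "a", year = 2018L, month = 1L, total = -1), "FR"),
    "non-negative")
})

test_that("gaussianity diagnostics separate normal from exponential samples", {
  set.seed(5)
  gn <- check_gaussian(rnorm(1000))
  expect_gt(gn$correlation, 0.99)
  ge <- check_gaussian(rexp(1000))
  expect_lt(ge$correlation, gn$correlation - 0.01)
  expect_true(check_gaussian(rep(1, 10))$degenerate)
  expect_error(check_gaussian(c(1, 2)), "at least 3")
})

test_that("month ranks: order, ties, argsort oracle, permutation property", {
  inc <- data.frame(unit = "a", year = 2018L, month = 1:12, total = 1:12)
  expect_equal(rank_months(inc)$rank, 1:12)
  tie <- data.frame(unit = "a", year = 2018L, month = 1:12, total = 7)
  expect_equal(rank_months(tie)$rank, 1:12)  # earlier month gets lower rank
  set.seed(3)
  for (i in 1:5) {
    v <- sample(100, 12)
    rnd <- data.frame(unit = "a", year = 2018L, month = 1:12, total = v)
    r <- rank_months(rnd)$rank
    expect_equal(r, order(order(v)))  # argsort-of-argsort oracle
    expect_setequal(r, 1:12)
  }
})

test_that("annual-mean ratios average to one", {
  const <- data.frame(unit = "a", year = 2018L, month = 1:12, total = 40)
  expect_equal(relative_to_annual_mean(const)$ratio, rep(1, 12))
  set.seed(4)
  rnd <- data.frame(unit = "a", year = 2018L, month = 1:12,
                    total = runif(12, 1, 100))
  expect_equal(mean(relative_to_annual_mean(rnd)$ratio), 1,
               tolerance = 1e-12)
  spike <- data.frame(unit = "a", year = 2018L, month = 1:12,
                      total = c(2, rep(0, 11)))
  expect_equal(relative_to_annual_mean(spike)$ratio[1], 12)
  zero <- data.frame(unit = "a", year = 2018L, month = 1:12, total = 0)
  expect_error(relative_to_annual_mean(zero), "zero annual mean")
})
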