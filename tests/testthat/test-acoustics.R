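test_that("energetic mean matches direct evaluation and is a fixed point on equal inputs", {
  expect_equal(energetic_mean(c(60, 60, 60)), 60)
  expect_equal(energetic_mean(c(0, 0)), 0)
  # direct evaluation of 10*log10((10^5 + 10^6)/2)
  expect_equal(energetic_mean(c(50, 60)), 57.4036268949424, tolerance = 1e-12)
  expect_error(energetic_mean(numeric(0)), "no measurements in period")
  expect_error(energetic_mean(c(50, NA)), "finite")
})

test_that("energetic mean dominates the arithmetic mean and respects bounds", {
  set.seed(1)
  for (i in 1:50) {
    x <- runif(sample(2:10, 1), 30, 90)
    em <- energetic_mean(x)
    expect_gte(em, mean(x) - 1e-12)
    expect_gte(em, min(x) - 1e-12)
    expect_lte(em, max(x) + 1e-12)
  }
  # equality only when all inputs are equal
  expect_gt(energetic_mean(c(40, 60)) - mean(c(40, 60)), 1)
})

test_that("intervals are split over analysis periods, with midnight wrap", {
  expect_equal(assign_period("07:00", "10:00"),
               c(day = 3, evening = 0, night = 0))
  expect_equal(assign_period("13:00", "16:00"),
               c(day = 3, evening = 0, night = 0))
  expect_equal(assign_period("22:00", "01:00"),
               c(day = 0, evening = 1, night = 2))
  expect_equal(assign_period("19:00", "23:00"),
               c(day = 0, evening = 4, night = 0))
  expect_equal(assign_period("23:00", "07:00"),
               c(day = 0, evening = 0, night = 8))
  expect_equal(assign_period("04:00", "07:00"),
               c(day = 0, evening = 0, night = 3))
  # a full day of coverage sums to the period durations
  expect_equal(sum(assign_period("06:30", "20:15")), 13.75)
  expect_error(assign_period("10:00", "10:00"), "zero-duration")
  expect_error(assign_period("25:00", "10:00"), "clock time")
  expect_error(assign_period("1000", "12:00"), "invalid clock")
})

test_that("Lden reduces to L when the period levels cancel the penalties", {
  set.seed(2)
  for (L in c(runif(25, 20, 90), 0, 85)) {
    expect_equal(as.numeric(compute_lden(L, L - 5, L - 10)), L, tolerance = 1e-9)
  }
  expect_equal(as.numeric(compute_lden(60, 55, 50)), 60, tolerance = 1e-12)
})

test_that("Lden matches direct formula evaluation and is strictly monotone", {
  # 10*log10((12*10^5 + 4*10^5.5 + 8*10^6)/24), evaluated independently
  expect_equal(as.numeric(compute_lden(50, 50, 50)), 56.3952430013186,
               tolerance = 1e-9)
  expect_equal(attr(compute_lden(50, 50, 50), "hours"),
               c(day = 12, evening = 4, night = 8))
  set.seed(3)
  for (i in 1:25) {
    pl <- runif(3, 30, 80)
    base <- as.numeric(compute_lden(pl[1], pl[2], pl[3]))
    for (k in 1:3) {
      up <- pl
      up[k] <- up[k] + runif(1, 0.1, 10)
      expect_gt(as.numeric(compute_lden(up[1], up[2], up[3])), base)
    }
    # bounded by the loudest penalised period
    expect_lte(base, max(pl[1], pl[2] + 5, pl[3] + 10) + 1e-12)
  }
  expect_error(compute_lden(Inf, 50, 50), "finite")
  expect_error(compute_lden(NA_real_, 50, 50), "finite")
})

test_that("period levels aggregate a log by overlap-weighted energetic means", {
  log1 <- data.frame(start = c("07:00", "19:00", "23:00"),
                     end = c("19:00", "23:00", "07:00"),
                     leq_db = c(60, 55, 50))
  expect_equal(period_levels_from_log(log1),
               c(l_day = 60, l_evening = 55, l_night = 50))
  # two equal-duration day measurements pool energetically
  log2 <- data.frame(start = c("07:00", "13:00", "19:00", "23:00"),
                     end = c("13:00", "19:00", "23:00", "07:00"),
                     leq_db = c(50, 60, 55, 50))
  pl <- period_levels_from_log(log2)
  expect_equal(pl[["l_day"]], 57.4036268949424, tolerance = 1e-9)
  expect_equal(pl[["l_evening"]], 55)
  # straddling interval feeds both evening and night
  log3 <- data.frame(start = c("07:00", "19:00", "22:00", "01:00"),
                     end = c("19:00", "22:00", "01:00", "07:00"),
                     leq_db = c(60, 56, 53, 48))
  pl3 <- period_levels_from_log(log3)
  expect_equal(pl3[["l_evening"]], energetic_mean(c(56, 53), c(3, 1)))
  expect_equal(pl3[["l_night"]], energetic_mean(c(53, 48), c(2, 6)))
  expect_error(
    period_levels_from_log(data.frame(start = "07:00", end = "19:00", leq_db = 60)),
    "no measurements in period: evening")
})

test_that("per-location Lden reporting reads the packaged example log", {
  log <- read_noise_log(system.file("extdata", "example_noise_log.csv",
                                    package = "noisebn"))
  tab <- lden_by_location(log)
  expect_equal(tab$location_id, c("ward_internal", "ward_ccu"))
  ward1 <- log[log$location_id == "ward_internal", ]
  expect_equal(tab$lden_db[1],
               round(as.numeric(compute_lden(period_levels_from_log(ward1))), 2))
  expect_true(all(tab$lden_db > tab$l_night))
})
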