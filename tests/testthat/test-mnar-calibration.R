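# SGA-ratio MNAR calibration: hand-computed ratios, the target-prevalence
# product, aggregation with skip reasons, scale equivariance.

ratio_fixture <- function() {
  # known: 200 records, 20 SGA (10%); unknown: 100 records, 12 SGA (12%)
  d <- make_records(300, smoker = rep(c(TRUE, FALSE), c(50, 250)), year = 2003)
  d$smoking[201:300] <- "unknown"
  d$sga10 <- FALSE
  d$sga10[c(1:20, 201:212)] <- TRUE
  d
}

test_that("the SGA ratio matches hand-computed group prevalences", {
  d <- ratio_fixture()
  r <- sga_ratio(d, 2003)
  expect_equal(r$sga_known, 0.10)
  expect_equal(r$sga_unknown, 0.12)
  expect_equal(r$ratio, 1.2)
  expect_equal(c(r$n_known, r$n_unknown), c(200L, 100L))
})

test_that("degenerate ratio inputs error or warn as appropriate", {
  d <- ratio_fixture()
  expect_error(sga_ratio(d, 1990), "no records")
  expect_error(sga_ratio(d[d$smoking != "unknown", ], 2003), "unknown-status group is empty")
  d0 <- d; d0$sga10[1:20] <- FALSE
  expect_error(sga_ratio(d0, 2003), "pool")
  dz <- d; dz$sga10[201:212] <- FALSE
  expect_warning(r <- sga_ratio(dz, 2003), "no SGA births")
  expect_equal(r$ratio, 0)
  expect_error(sga_ratio(make_records(3, smoker = FALSE), 2005), "sga10")
})

test_that("records with unknown gestational age are excluded from the prevalences", {
  d <- ratio_fixture()
  extra <- make_records(50, smoker = FALSE, year = 2003, ga = NA)
  extra$sga10 <- FALSE
  r0 <- sga_ratio(d, 2003)
  r1 <- suppressMessages(sga_ratio(rbind(d, extra), 2003))
  expect_equal(r1$ratio, r0$ratio)
  expect_equal(r1$n_known, r0$n_known)
})

test_that("mnar_target is the clamped product of prevalence and ratio", {
  expect_equal(mnar_target(0.256, 1.06), 0.27136)
  expect_equal(mnar_target(0.3, 1), 0.3)              # ratio 1 is the identity
  expect_equal(suppressWarnings(mnar_target(0.5, 1.5)), 0.75)
  expect_equal(mnar_target(0.9, 1.5), 0.999)          # clamp keeps weighting defined
  expect_warning(mnar_target(0.2, 0.8), "below the observed")
  expect_error(mnar_target(0, 1.1), "p_obs")
  expect_error(mnar_target(1, 1.1), "p_obs")
  expect_error(mnar_target(0.2, -1), "ratio")
})

test_that("calibrate_all_years yields one definitionally consistent row per year", {
  reg <- small_registry()
  cal <- calibrate_all_years(reg)
  expect_equal(cal$year, sort(unique(reg$year)))
  ok <- !is.na(cal$p_target)
  expect_true(all(ok))
  expect_equal(cal$p_target[ok], pmin(cal$p_obs[ok] * cal$ratio[ok], 0.999))
  # p_obs is the combined daily+occasional share among known records
  y <- cal$year[1]
  d <- reg[reg$year == y & is_known(reg$smoking), ]
  expect_equal(cal$p_obs[1], mean(d$smoking %in% c("daily", "occasional")))
})

test_that("years whose ratio cannot be formed are kept with a skip reason", {
  d <- ratio_fixture()
  allknown <- make_records(80, smoker = TRUE, year = 2004)
  allknown$sga10 <- rep(c(TRUE, FALSE), c(8, 72))
  cal <- calibrate_all_years(rbind(d, allknown))
  expect_equal(nrow(cal), 2L)
  expect_true(is.na(cal$p_target[cal$year == 2004]))
  expect_match(cal$note[cal$year == 2004], "skipped")
  expect_false(is.na(cal$p_target[cal$year == 2003]))
})

test_that("the calibration is invariant to duplicating every record", {
  d <- ratio_fixture()
  cal1 <- calibrate_all_years(d)
  cal2 <- calibrate_all_years(rbind(d, d))
  expect_equal(cal2$ratio, cal1$ratio)
  expect_equal(cal2$p_target, cal1$p_target)
  expect_equal(cal2$n_known, 2L * cal1$n_known)
})
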