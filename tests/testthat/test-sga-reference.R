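# SGA-10 reference: quantile rule, pooling, monotone rearrangement, strict
# flagging rule, self-consistency of the empirical decile.

test_that("stratum cutoff follows the linear-interpolation quantile rule", {
  # 100 weights 1000, 1100, ..., 10900: the interpolated 10th percentile is
  # x_(10) + 0.9 * (x_(11) - x_(10)) = 1900 + 0.9 * 100 = 1990
  rec <- make_records(100, smoker = FALSE, bw = seq(1000, 10900, by = 100), ga = 39)
  ref <- build_sga_reference(rec, min_stratum_n = 50)
  expect_equal(ref$cutoffs$cutoff_g, 1990)
  expect_equal(ref$cutoffs$stratum_n, 100L)
})

test_that("degenerate stratum (all weights equal) returns that weight", {
  rec <- make_records(60, smoker = FALSE, bw = 3000, ga = 40)
  ref <- build_sga_reference(rec, min_stratum_n = 50)
  expect_equal(ref$cutoffs$cutoff_g, 3000)
})

test_that("cutoffs are monotone-rearranged nondecreasing in gestational week", {
  # week 36 built heavier than week 37: pre-rearrangement cutoffs decrease
  rec <- rbind(make_records(100, smoker = FALSE, bw = seq(3001, 3100), ga = 36),
               make_records(100, smoker = FALSE, bw = seq(2001, 2100), ga = 37))
  ref <- build_sga_reference(rec, min_stratum_n = 50)
  expect_true(all(diff(ref$cutoffs$cutoff_g) >= 0))
  # the two empirical deciles are preserved, only reassigned
  expect_setequal(ref$cutoffs$cutoff_g,
                  c(stats::quantile(seq(2001, 2100), 0.1, type = 7, names = FALSE),
                    stats::quantile(seq(3001, 3100), 0.1, type = 7, names = FALSE)))
})

test_that("undersized strata pool toward week 39 and hopeless sexes error", {
  rec <- rbind(make_records(10, smoker = FALSE, bw = seq(2000, 2900, 100), ga = 38),
               make_records(90, smoker = FALSE, bw = seq(3000, 3890, 10), ga = 39))
  ref <- build_sga_reference(rec, min_stratum_n = 50)
  # week 38 pooled with 39: identical pooled cutoff and pooled stratum n
  expect_equal(ref$cutoffs$stratum_n, c(100L, 100L))
  expect_equal(length(unique(ref$cutoffs$cutoff_g)), 1L)
  expect_error(build_sga_reference(make_records(20, smoker = FALSE, bw = 3000, ga = 39),
                                   min_stratum_n = 50),
               "min_stratum_n")
})

test_that("flagging is strictly below the cutoff and unknown weeks are unflagged", {
  base <- make_records(100, smoker = FALSE, bw = seq(1000, 10900, by = 100), ga = 39)
  ref <- build_sga_reference(base, min_stratum_n = 50)      # cutoff 1990
  probe <- make_records(4, smoker = FALSE, bw = c(1990, 1989, 5000, 1000),
                        ga = c(39, 39, 39, NA))
  expect_equal(suppressMessages(flag_sga(probe, ref)), c(FALSE, TRUE, FALSE, FALSE))
  # monotone nonincreasing in weight at fixed sex and week
  w <- seq(1500, 2500, by = 10)
  probe2 <- make_records(length(w), smoker = FALSE, bw = w, ga = 39)
  fl <- flag_sga(probe2, ref)
  expect_true(all(diff(as.integer(fl)) <= 0))
})

test_that("weeks outside the reference range borrow the nearest covered week", {
  base <- make_records(200, smoker = FALSE, bw = rep(seq(2010, 4000, 10), len = 200),
                       ga = rep(c(38, 39), each = 100))
  ref <- build_sga_reference(base, min_stratum_n = 50)
  probe <- make_records(2, smoker = FALSE, bw = c(600, 5000), ga = c(30, 44))
  expect_equal(flag_sga(probe, ref),
               c(600 < min(ref$cutoffs$cutoff_g), FALSE))
  expect_error(flag_sga(make_records(1, smoker = FALSE, sex = "male"), ref), "male")
})

test_that("empirical decile is self-consistent on the population that built it", {
  cfg <- registry_config(births_per_year = 30000, years = 2005)
  reg <- exclude_nonviable(generate_registry(cfg, seed = 9), quiet = TRUE)
  base <- reg[reg$smoking == "nonsmoker" & !is.na(reg$ga_weeks), ]
  ref <- suppressMessages(build_sga_reference(base))
  frac <- mean(flag_sga(base, ref, quiet = TRUE))
  expect_lt(abs(frac - 0.10), 0.01)
})

test_that("references survive a CSV round trip", {
  base <- make_records(100, smoker = FALSE, bw = seq(1000, 10900, by = 100), ga = 39)
  ref <- build_sga_reference(base, min_stratum_n = 50)
  f <- tempfile(fileext = ".csv")
  write_sga_reference(ref, f)
  back <- read_sga_reference(f)
  expect_equal(back$cutoffs$cutoff_g, ref$cutoffs$cutoff_g)
  probe <- make_records(2, smoker = FALSE, bw = c(1989, 1990), ga = 39)
  expect_equal(flag_sga(probe, back), c(TRUE, FALSE))
  expect_error(read_sga_reference({f2 <- tempfile(); write.csv(data.frame(a = 1), f2); f2}),
               "columns")
})
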