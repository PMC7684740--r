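# Synthetic registry generator: determinism, calibration to the configured
# trends, MAR/MNAR behaviour of the missingness link, viability filtering.

test_that("generation is deterministic given (config, seed) down to the CSV bytes", {
  cfg <- registry_config(births_per_year = 500, years = 2005:2006)
  r1 <- generate_registry(cfg, seed = 7)
  r2 <- generate_registry(cfg, seed = 7)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_registry(r1, f1, with_truth = TRUE)
  write_registry(r2, f2, with_truth = TRUE)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  r3 <- generate_registry(cfg, seed = 8)
  expect_false(identical(r1$birth_weight_g, r3$birth_weight_g))
})

test_that("invalid configurations are rejected with the offending cell named", {
  expect_error(registry_config(births_per_year = 50), "births_per_year")
  expect_error(registry_config(bw_sd_g = 0), "bw_sd_g")
  expect_error(registry_config(smoking_trend = c(0.3, 1.2), years = 2000:2001),
               "smoking_trend")
  expect_error(registry_config(region_probs = c(nordic = 0.5, europe_non_nordic = 0.2,
                                                asia = 0.2, africa = 0.05, other = 0.1)),
               "sum to 1")
  expect_error(
    registry_config(unknown_trend = 0.6, years = 2007,
                    missingness_effects = list(
                      form = c(paper = 0, electronic = log(0.58)),
                      region = c(nordic = 0, europe_non_nordic = 0, asia = 0,
                                 africa = log(30), other = 0),
                      hospital = c(small_hospitals = 0,
                                   stats::setNames(rep(0, 16), sprintf("hosp_%02d", 1:16))))),
    "africa")
})

test_that("annual smoking prevalence tracks the configured 26% -> 7% trend", {
  cfg <- registry_config(births_per_year = 10000, years = c(1999, 2014))
  reg <- generate_registry(cfg, seed = 1)
  p99 <- mean(is_smoker(reg$smoking[reg$year == 1999]), na.rm = TRUE)
  p14 <- mean(is_smoker(reg$smoking[reg$year == 2014]), na.rm = TRUE)
  expect_lt(abs(p99 - 0.26), 0.02)
  expect_lt(abs(p14 - 0.07), 0.02)
  # latent truth has no sampling filter, so it should track even closer
  q99 <- mean(reg$true_smoking[reg$year == 1999] != "nonsmoker")
  expect_lt(abs(q99 - 0.26), 0.02)
})

test_that("mnar_delta = 0 gives equal missingness for smokers and non-smokers", {
  cfg <- registry_config(births_per_year = 5000, years = 2003, mnar_delta = 0,
                         # shut the covariate channel shared by the two models
                         missingness_effects = list(
                           form = c(paper = 0, electronic = 0),
                           region = c(nordic = 0, europe_non_nordic = 0, asia = 0,
                                      africa = 0, other = 0),
                           hospital = c(small_hospitals = 0,
                                        stats::setNames(rep(0, 16), sprintf("hosp_%02d", 1:16)))))
  reg <- generate_registry(cfg, seed = 3)
  smoker <- reg$true_smoking != "nonsmoker"
  unk <- !is_known(reg$smoking)
  p1 <- mean(unk[smoker]); p0 <- mean(unk[!smoker])
  se <- sqrt(p1 * (1 - p1) / sum(smoker) + p0 * (1 - p0) / sum(!smoker))
  expect_lt(abs(p1 - p0), 3 * se)
})

test_that("positive mnar_delta raises missingness risk for smokers accordingly", {
  cfg <- registry_config(births_per_year = 20000, years = 2000,
                         mnar_delta = log(1.5))
  reg <- generate_registry(cfg, seed = 5)
  smoker <- reg$true_smoking != "nonsmoker"
  unk <- !is_known(reg$smoking)
  rr <- mean(unk[smoker]) / mean(unk[!smoker])
  expect_gt(rr, 1.3)
  expect_lt(rr, 1.7)
})

test_that("birth-weight means follow the configured dose structure", {
  cfg <- registry_config(births_per_year = 50000, years = 1999)
  reg <- generate_registry(cfg, seed = 11)
  m <- tapply(reg$birth_weight_g, reg$true_smoking, mean)
  expect_gt(m[["nonsmoker"]], m[["occasional"]])
  expect_gt(m[["occasional"]], m[["daily"]])
  # daily deficit vs non-smokers is the configured 3428 - 3536 = -108 g
  n_d <- sum(reg$true_smoking == "daily"); n_n <- sum(reg$true_smoking == "nonsmoker")
  se <- 450 * sqrt(1 / n_d + 1 / n_n)
  expect_lt(abs((m[["daily"]] - m[["nonsmoker"]]) - (-108)), 3 * se)
})

test_that("exclude_nonviable drops exactly the sub-viability records, preserving order", {
  rec <- make_records(5, smoker = FALSE,
                      bw = c(499, 500, 3500, 3400, 700),
                      ga = c(30, 22, 21, 39, 40))
  out <- suppressMessages(exclude_nonviable(rec))
  expect_equal(out$record_id, rec$record_id[c(2, 4, 5)])   # 499 g out, ga 21 out
  expect_equal(unname(attr(out, "n_removed")[["removed"]]), 2)
  # unknown gestational age is retained on the gestational criterion
  rec$ga_weeks <- NA_integer_
  out2 <- suppressMessages(exclude_nonviable(rec))
  expect_equal(nrow(out2), 4)  # only the 499 g record goes
  expect_equal(nrow(suppressMessages(exclude_nonviable(rec[0, ]))), 0)
})

test_that("mothers repeat across cohorts and ground truth stays recoverable", {
  reg <- small_registry()
  births_per_mother <- table(reg$mother_id)
  expect_gt(mean(births_per_mother > 1), 0.1)
  # parity increments with successive births of the same mother
  rep_m <- names(births_per_mother)[births_per_mother > 1][1]
  d <- reg[reg$mother_id == rep_m, ]
  d <- d[order(d$year), ]
  expect_true(all(diff(d$parity) > 0))
  # latent truth among unknown-status records is present and computable
  unk <- reg[!is_known(reg$smoking), ]
  expect_true(all(unk$true_smoking %in% c("nonsmoker", "occasional", "daily")))
  expect_true(is.finite(mean(unk$true_smoking != "nonsmoker")))
})

test_that("registry round-trips through CSV, with truth only when requested", {
  reg <- small_registry()[1:50, ]
  f <- tempfile(fileext = ".csv")
  write_registry(reg, f)
  back <- read_registry(f)
  expect_false("true_smoking" %in% names(back))
  expect_equal(back$birth_weight_g, reg$birth_weight_g)
  write_registry(reg, f, with_truth = TRUE)
  expect_equal(read_registry(f)$true_smoking, reg$true_smoking)
})
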