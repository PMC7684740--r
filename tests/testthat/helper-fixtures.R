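# Fixtures built in code: small hand-constructed record sets plus cached
# synthetic registries shared across tests.

# A minimal record table with every column the pipeline touches.
make_records <- function(n, smoker, education = NULL, region = "nordic",
                         marital = NULL, year = 2005, bw = NULL, ga = 39,
                         hospital = "small_hospitals", form = "paper",
                         sex = "female", age = 30, parity = 1,
                         mother = NULL) {
  smoker <- rep_len(smoker, n)
  data.frame(
    record_id = sprintf("r%05d", seq_len(n)),
    mother_id = if (is.null(mother)) sprintf("m%05d", seq_len(n)) else rep_len(mother, n),
    year = rep_len(year, n),
    maternal_age_years = rep_len(age, n),
    parity = rep_len(parity, n),
    marital_status = if (is.null(marital)) ifelse(smoker, "single", "partnered")
                     else rep_len(marital, n),
    education = if (is.null(education)) ifelse(smoker, "primary", "high")
                else rep_len(education, n),
    region = rep_len(region, n),
    hospital_id = rep_len(hospital, n),
    form = rep_len(form, n),
    infant_sex = rep_len(sex, n),
    ga_weeks = rep_len(as.integer(ga), n),
    birth_weight_g = if (is.null(bw)) ifelse(smoker, 3300, 3600) + seq_len(n) %% 7
                     else rep_len(bw, n),
    smoking = ifelse(smoker, "daily", "nonsmoker"),
    stringsAsFactors = FALSE
  )
}

# Cache one small default-config registry per session (4 cohorts).
.fixture_env <- new.env(parent = emptyenv())

small_registry <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- registry_config(births_per_year = 2500, years = 2004:2007)
    reg <- exclude_nonviable(generate_registry(cfg, seed = 42), quiet = TRUE)
    .fixture_env$small <- suppressMessages(add_sga_flags(reg))
  }
  .fixture_env$small
}
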