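# Shared fixtures.  Expensive simulations are built lazily and cached for
# the whole test run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# single unselected-reporting country: reported value == first visit, so the
# measurement distribution is exactly the generator's closed-form law
unselected_countries <- function() {
  data.frame(country = "FR", group = "France", weight = 1,
             reporting = "unselected", stringsAsFactors = FALSE)
}

# small hand-built registry records table
toy_records <- function() {
  data.frame(
    patient_id = paste0("P", 1:5),
    country = "FR", year = 2005L,
    sex = c("M", "M", "F", "F", "M"),
    age_years = c(10, 45, 6.0, 40.0, 20),
    height_cm = c(140, 175, 115, 160, 178),
    weight_kg = c(32, 70, 20, 52, 65),
    fev1_l = c(1.8, 2.5, 1.1, 1.9, 3.2),
    measurement_type = "unselected",
    transplanted = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    genotype_class = "F508del_hom",
    stringsAsFactors = FALSE)
}

# registry with a deterministic outcome (y an exact function of age):
# useful for zero-noise bootstrap checks
deterministic_registry <- function(n = 400) {
  age <- seq(6, 40, length.out = n)
  cf_registry(data.frame(
    patient_id = paste0("D", seq_len(n)), country = "FR", year = 2005L,
    sex = "M", age_years = age, height_cm = 160, weight_kg = 55,
    fev1_l = 1 + 0.05 * age, measurement_type = "unselected",
    transplanted = FALSE, genotype_class = "other",
    stringsAsFactors = FALSE))
}

# mid-size filtered FEV1 registry reused across chart tests
chart_fixture <- function() {
  fixture("chart_reg", function() {
    cfg <- sim_config(n_patients_per_sex = 2000, age_range = c(6, 40),
                      countries = unselected_countries(), seed = 777L)
    list(config = cfg,
         registry = filter_registry(simulate_registry(cfg), "fev1"))
  })
}

expect_close <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
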