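# Shared fixtures for the test suite. Everything is built in code; the
# only on-disk inputs are the packaged published tables.

ref_calibration <- function() fit_load_cell_calibration(100000, 30, 400000)

# A hand-consistent composition for round-trip tests: free fields chosen
# near the obese group's published means, derived fields computed through
# the forward equations.
consistent_composition <- function(profile, weight_kg = 43.501,
                                   ffm_kg = 27.473, tbw_kg = 18.919,
                                   mm_kg = 23.255) {
  bmi_v <- bmi(weight_kg, profile$height_cm / 100)
  suppressWarnings(body_composition(
    weight_kg = weight_kg,
    bmi = bmi_v,
    bf_pct = bf_percent(bmi_v, profile$age_years, profile$sex_code),
    ffm_kg = ffm_kg,
    tbw_kg = tbw_kg,
    mm_kg = mm_kg,
    bm_kg = bm(weight_kg, profile$height_cm, mm_kg)
  ))
}

obese_profile <- function(id = "S1") {
  subject_profile(id, age_years = 8.441, sex_code = 1,
                  height_cm = 126.511, group_label = "obese")
}

# Small deterministic cohort for pipeline tests.
small_cohort <- function(n = 5, seed = 11) {
  generate_cohort(cohort_spec(n_obese = n, n_normal = n, seed = seed))
}
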