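# shared fixtures, built once per test run
.memo_env <- new.env()
memo <- function(key, expr) {
  if (is.null(.memo_env[[key]])) .memo_env[[key]] <- expr
  .memo_env[[key]]
}

ref_adult <- function() build_reference_adult(70, 180, 30, "male")
ref_model <- function() memo("ref_model", pbpk_model(ref_adult()))

# dense healthy reference profile, 2000 mg / 30 min, with full state
ref_profile <- function() memo("ref_profile", {
  simulate(ref_model(), regimen = dose_regimen(2000, 30),
           times = seq(0, 12, by = 0.05), full_state = TRUE)
})

# small single-arm scenario for end-to-end tests
tiny_scenario <- function(n = 3L, disease = "healthy") {
  structure(list(
    name = "tiny",
    population = list(n_subjects = n, n_observed = n, age = c(25, 35),
                      weight = c(65, 80), n_females = 1L, disease = disease),
    regimen = list(dose_mg = 1000, infusion_min = 30),
    simulation = list(horizon_h = 12, dt_h = 0.1)
  ), class = "pbpk_scenario")
}
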