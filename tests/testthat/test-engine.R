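test_that("dose regimens validate", {
  expect_error(dose_regimen(-1), "dose_mg")
  expect_error(dose_regimen(1000, infusion_min = 0), "infusion_min")
  expect_error(dose_regimen(1000, n_doses = 2), "interval_h")
  expect_error(dose_regimen(1000, infusion_min = 120, n_doses = 2, interval_h = 1),
               "overlap|exceed")
})

test_that("zero dose leaves the system at rest and mass balance guards 0/0", {
  prof <- simulate(ref_model(), regimen = dose_regimen(0),
                   times = seq(0, 4, 0.5), full_state = TRUE)
  expect_true(all(prof$conc == 0))
  expect_identical(mass_balance(prof), 0)
})

test_that("mass is conserved to solver tolerance on every run", {
  expect_lt(mass_balance(ref_profile()), 1e-6)
  sev <- pbpk_model(apply_severe_ckd(ref_adult()))
  prof <- simulate(sev, regimen = dose_regimen(1000, 30),
                   times = seq(0, 48, 0.5), full_state = TRUE)
  expect_lt(mass_balance(prof), 1e-6)
})

test_that("without elimination the infused amount stays in the body", {
  mod0 <- pbpk_model(ref_adult(), cefepime_defaults(cl_r_specific = 0))
  expect_equal(mod0$cl_plasma, 0)
  prof <- simulate(mod0, regimen = dose_regimen(500, 30),
                   times = seq(0, 12, 0.5), full_state = TRUE)
  state <- attr(prof, "state")
  in_body <- rowSums(state[, !colnames(state) %in% c("time", "eliminated"), drop = FALSE])
  expect_equal(max(state[, "eliminated"]), 0)
  post <- state[, "time"] > 0.5
  expect_equal(in_body[post], rep(500, sum(post)), tolerance = 1e-6)
})

test_that("constant-rate infusion approaches the closed-form steady state", {
  mod <- ref_model()
  # 100 mg/h for 60 h (>> 10 half-lives): Css = rate / CL_plasma
  prof <- simulate(mod, regimen = dose_regimen(6000, infusion_min = 3600),
                   times = seq(0, 60, 1))
  css <- 100 / mod$cl_plasma
  expect_equal(prof$conc[prof$time == 60], css, tolerance = 0.005)
})

test_that("dose/AUC0-inf equals the model plasma clearance within 2%", {
  mod <- ref_model()
  for (dose in c(62.5, 500, 2000)) {
    prof <- simulate(mod, regimen = dose_regimen(dose, 30), times = seq(0, 12, 0.05))
    res <- nca(prof$time[-1], prof$conc[-1], dose_mg = dose)
    expect_equal(res$cl, mod$cl_plasma, tolerance = 0.02)
  }
})

test_that("the system is linear: superposition and dose-independent slope", {
  mod <- ref_model()
  t <- seq(0, 12, 0.1)
  p1 <- simulate(mod, regimen = dose_regimen(500, 30), times = t)
  p2 <- simulate(mod, regimen = dose_regimen(1000, 30), times = t)
  expect_equal(p2$conc[-1], 2 * p1$conc[-1], tolerance = 1e-6)
  lz1 <- terminal_slope(p1$time[-1], p1$conc[-1])$lambda_z
  lz2 <- terminal_slope(p2$time[-1], p2$conc[-1])$lambda_z
  expect_equal(lz1, lz2, tolerance = 1e-4)
})

test_that("shorter infusions of the same dose give strictly higher Cmax", {
  mod <- ref_model()
  cmax <- vapply(c(3, 5, 10, 15, 30), function(dur) {
    max(simulate(mod, regimen = dose_regimen(2000, dur),
                 times = seq(0, 3, 0.01))$conc)
  }, numeric(1))
  expect_true(all(diff(cmax) < 0)) # decreasing in duration
})

test_that("collapsed to one compartment the engine matches the analytic infusion", {
  mod <- collapse_model(ref_model())
  t <- seq(0.05, 12, 0.05)
  num <- simulate(mod, regimen = dose_regimen(2000, 30), times = t)$conc
  ana <- solve_infusion_1cmt(t, 2000, 0.5, mod$v_collapsed, mod$cl_plasma)
  expect_lt(max(abs(num - ana) / ana), 0.001)
})

test_that("multiple-dose regimens superpose single doses", {
  mod <- ref_model()
  t <- seq(0, 16, 0.1)
  two <- simulate(mod, regimen = dose_regimen(1000, 30, n_doses = 2, interval_h = 8),
                  times = t)
  one <- simulate(mod, regimen = dose_regimen(1000, 30), times = t)$conc
  shifted <- c(rep(0, sum(t < 8)), one[seq_len(sum(t >= 8))])
  expect_equal(two$conc, one + shifted, tolerance = 1e-5)
})
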