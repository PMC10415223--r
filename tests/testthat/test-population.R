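test_that("demographics validate before sampling", {
  expect_error(population_demographics(0, c(20, 40), c(60, 80)), "n must be")
  expect_error(population_demographics(5, c(20, 40), c(60, 80), n_females = 6),
               "n_females")
})

test_that("sampled populations honor the study demographics and the seed", {
  demo <- population_demographics(12, c(25.2, 27.8), c(66.5, 80.3),
                                  n_females = 6, disease = "healthy")
  pop <- sample_population(demo, seed = 7)
  expect_length(pop$subjects, 12)
  sexes <- vapply(pop$subjects, function(s) s$sex, character(1))
  expect_equal(sum(sexes == "female"), 6)
  w <- vapply(pop$subjects, function(s) s$body_weight, numeric(1))
  a <- vapply(pop$subjects, function(s) s$age, numeric(1))
  expect_true(all(w >= 66.5 & w <= 80.3))
  expect_true(all(a >= 25.2 & a <= 27.8))
  expect_identical(pop, sample_population(demo, seed = 7)) # bitwise reproducible
  expect_false(identical(pop, sample_population(demo, seed = 8)))
})

test_that("point-range demographics give a deterministic single subject", {
  demo <- population_demographics(1, 30, 70, disease = "healthy",
                                  bmi_range = c(23.5, 23.5))
  s <- sample_population(demo, seed = 1)$subjects[[1]]
  expect_equal(s$body_weight, 70)
  expect_equal(s$age, 30)
  expect_equal(s$height, sqrt(70 / 23.5) * 100)
})

test_that("disease transforms are applied during sampling", {
  mk <- function(disease) {
    demo <- population_demographics(2, c(30, 50), c(65, 90), disease = disease)
    sample_population(demo, seed = 3)$subjects[[1]]
  }
  expect_equal(mk("moderate_ckd")$hct, 0.433)
  expect_equal(mk("severe_ckd")$rbf, 0.17)
  ob <- {
    demo <- population_demographics(2, c(31, 74), c(106.8, 163.2), disease = "obese")
    sample_population(demo, seed = 3)$subjects[[1]]
  }
  expect_identical(ob$disease, "obese")
  expect_equal(sum(ob$organs$volume), ob$body_weight, tolerance = 0.05 * ob$body_weight)
  ped <- {
    demo <- population_demographics(2, c(0.175, 16.4), c(3.5, 75), disease = "pediatric")
    sample_population(demo, seed = 3)$subjects[[1]]
  }
  expect_identical(ped$disease, "pediatric")
})

test_that("population simulation is per-subject consistent", {
  demo <- population_demographics(4, c(25, 35), c(60, 90), disease = "healthy",
                                  bmi_range = c(23.5, 23.5))
  pop <- sample_population(demo, seed = 11)
  sim <- simulate_population(pop, regimen = dose_regimen(1000, 30),
                             times = seq(0, 12, 0.05))
  expect_true(all(sim$conc >= 0))
  tab <- nca_population(sim)
  # engine identity per subject
  expect_true(all(abs(tab$cl - tab$model_cl) / tab$model_cl < 0.02))
  # with a fixed BMI, larger subjects clear faster (BSA-scaled GFR)
  ord <- order(tab$weight)
  expect_true(all(diff(tab$model_cl[ord]) > 0))
})

test_that("per-kilogram dosing scales the administered amount", {
  demo <- population_demographics(3, c(2, 10), c(10, 40), disease = "pediatric")
  pop <- sample_population(demo, seed = 5)
  sim <- simulate_population(pop, regimen = dose_regimen(1, 30),
                             times = seq(0, 8, 0.1), dose_mg_per_kg = 50)
  w <- vapply(pop$subjects, function(s) s$body_weight, numeric(1))
  expect_equal(sim$doses, 50 * w)
})

test_that("percentile bands are ordered and degenerate correctly", {
  base <- 50 * exp(-0.5 * seq(0, 12, 0.5))
  m_same <- cbind(base, base, base)
  b <- summarize_bands(m_same, times = seq(0, 12, 0.5))
  expect_equal(b$mean, base)
  expect_equal(b$p5, base)
  expect_equal(b$p95, base)
  expect_equal(b$min, base)
  expect_equal(b$max, base)

  set.seed(99)
  m <- sapply(1:25, function(i) base * exp(rnorm(length(base), 0, 0.2)))
  b2 <- summarize_bands(m, times = seq(0, 12, 0.5))
  expect_true(all(b2$min <= b2$p5 & b2$p5 <= b2$p95 & b2$p95 <= b2$max))
  expect_true(all(b2$mean >= b2$min & b2$mean <= b2$max))
  expect_error(summarize_bands(m[, 1, drop = FALSE], times = seq(0, 12, 0.5)),
               "at least 2")
  expect_error(summarize_bands(m, times = 1:3), "common time grid")
})

test_that("bands cover ~90% of held-out points generated by the same process", {
  t <- seq(0, 12, 0.5)
  base <- 60 * exp(-0.45 * t)
  gen <- function(n) sapply(seq_len(n), function(i)
    base * exp(rnorm(length(t), 0, sqrt(log(1 + 0.2^2)))))
  set.seed(123)
  bands <- summarize_bands(gen(100), times = t)
  held_out <- gen(20)
  inside <- held_out >= bands$p5 & held_out <= bands$p95
  expect_gt(mean(inside), 0.80)
  expect_lt(mean(inside), 0.98)
})

test_that("population-mean clearance is stable across seeds", {
  demo <- population_demographics(100, c(25.2, 27.8), c(66.5, 80.3),
                                  n_females = 6, disease = "healthy")
  means <- vapply(1:10, function(s) {
    pop <- sample_population(demo, seed = s)
    mean(vapply(pop$subjects, function(p) pbpk_model(p)$cl_plasma, numeric(1)))
  }, numeric(1))
  expect_lt(stats::sd(means) / mean(means), 0.02)
})
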