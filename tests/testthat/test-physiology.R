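test_that("reference adult carries the stated defaults and closes volume", {
  phys <- ref_adult()
  expect_equal(phys$gfr, 120, tolerance = 1e-10)
  expect_equal(phys$pbf, 1.0)
  expect_equal(phys$hct, 0.45)
  expect_equal(build_reference_adult(70, 180, 30, "female")$hct, 0.40)
  expect_equal(sum(phys$organs$volume), 70, tolerance = 0.05)
  expect_equal(phys$cardiac_output,
               sum(phys$organs$blood_flow[phys$organs$name != "lung"], na.rm = TRUE))
  expect_error(build_reference_adult(10, 180, 30), "weight")
  expect_error(build_reference_adult(70, 100, 30), "height")
  expect_error(build_reference_adult(70, 180, 10), "age")
})

test_that("volumes scale linearly with body weight, flows allometrically", {
  p70 <- ref_adult()
  p140 <- build_reference_adult(140, 180, 30, "male")
  expect_equal(p140$organs$volume, 2 * p70$organs$volume, tolerance = 1e-12)
  expect_equal(p140$organs$blood_flow, 2^0.75 * p70$organs$blood_flow,
               tolerance = 1e-12)
})

test_that("Du Bois body surface area matches the closed formula", {
  expect_equal(du_bois_bsa(70, 180), 1.886, tolerance = 5e-4)
  expect_equal(du_bois_bsa(1, 1), 0.007184)
  expect_equal(du_bois_bsa(130, 170), 0.007184 * 130^0.425 * 170^0.725)
  # strictly increasing in both arguments over a grid
  w <- seq(40, 150, by = 10)
  h <- seq(140, 200, by = 10)
  for (hh in h) expect_true(all(diff(du_bois_bsa(w, hh)) > 0))
  for (ww in w) expect_true(all(diff(du_bois_bsa(ww, h)) > 0))
  expect_error(du_bois_bsa(0, 170))
})

test_that("moderate CKD sets GET/PBF/HCT and leaves the rest untouched", {
  phys <- ref_adult()
  ckd <- apply_moderate_ckd(phys)
  expect_equal(ckd$get, 20.625)
  expect_equal(ckd$pbf, 0.9265)
  expect_equal(ckd$hct, 0.433)
  expect_equal(ckd$gfr, 45.5)
  expect_identical(ckd$rbf, phys$rbf)         # renal flow unchanged in moderate
  expect_identical(ckd$organs$volume, phys$organs$volume)
  expect_identical(phys$disease, "healthy")   # input is not mutated
  expect_error(apply_moderate_ckd(ckd), "already")
  expect_error(apply_moderate_ckd(ref_adult(), gfr = 80), "gfr")
})

test_that("severe CKD sets the full modifier set including renal/hepatic flows", {
  phys <- ref_adult()
  sev <- apply_severe_ckd(phys)
  expect_equal(sev$get, 24.375)
  expect_equal(sev$hct, 0.398)
  expect_equal(sev$pbf, 0.837)
  expect_equal(sev$rbf, 0.17)
  expect_equal(sev$habf, 0.16)
  expect_equal(sev$gfr, 20.5)
  expect_equal(sev$organs$blood_flow[sev$organs$name == "kidney"], 0.17)
  expect_equal(sev$organs$blood_flow[sev$organs$name == "liver"], 0.16)
  expect_error(apply_severe_ckd(sev), "already")
})

test_that("hematocrit is ordered by disease severity", {
  healthy <- ref_adult()
  mod <- apply_moderate_ckd(ref_adult())
  sev <- apply_severe_ckd(ref_adult())
  expect_true(sev$hct < mod$hct && mod$hct < healthy$hct)
  expect_equal(c(sev$hct, mod$hct, healthy$hct), c(0.398, 0.433, 0.45))
})

test_that("obesity rescales GFR with surface area and spares HCT and PBF", {
  # weight chosen so Du Bois BSA is ~2.20 m^2 at 180 cm
  w <- (2.20 / (0.007184 * 180^0.725))^(1 / 0.425)
  phys <- build_reference_adult(w, 180, 40, "male")
  ob <- apply_obesity(phys)
  expect_equal(ob$gfr, 143 * du_bois_bsa(w, 180) / 1.73)
  expect_equal(ob$gfr, 181.8, tolerance = 1e-3)
  expect_identical(ob$hct, phys$hct)  # bit-identical, untouched by the transform
  expect_identical(ob$pbf, phys$pbf)
  # BSA exactly 1.73 m^2 normalizes to 143 mL/min
  w173 <- (1.73 / (0.007184 * 165^0.725))^(1 / 0.425)
  ob173 <- suppressWarnings(apply_obesity(build_reference_adult(w173, 165, 40)))
  expect_equal(ob173$gfr, 143, tolerance = 1e-9)
})

test_that("obesity adds excess mass to adipose and keeps unit-density closure", {
  lean <- build_reference_adult(76, 180, 40, "male") # BMI 23.5
  ob <- apply_obesity(lean, target_weight = 120)     # BMI 37
  expect_equal(sum(ob$organs$volume), 120, tolerance = 0.05 * 120)
  gained <- ob$organs$volume - lean$organs$volume
  expect_equal(sum(gained[ob$organs$name != "adipose"]), 0)
  expect_equal(gained[ob$organs$name == "adipose"], 44)
  expect_warning(apply_obesity(build_reference_adult(70, 180, 40)), "BMI")
})

test_that("pediatric transform applies the published flows with allometric scaling", {
  adol <- apply_pediatric(ref_adult(), age = 17, weight = 70)
  flow <- function(p, o) p$organs$blood_flow[p$organs$name == o]
  expect_equal(flow(adol, "brain"), 1.85)
  expect_equal(flow(adol, "kidney"), 1.4)
  expect_equal(flow(adol, "small_intestine"), 1.4)
  child <- apply_pediatric(ref_adult(), age = 10, weight = 35)
  expect_equal(flow(child, "kidney"), 1.4 * 0.5^0.75, tolerance = 1e-12)
  expect_equal(flow(child, "muscle"), 0.88 * 0.5^0.75, tolerance = 1e-12)
  expect_equal(sum(child$organs$volume), 35, tolerance = 0.05 * 35)
  expect_equal(child$gfr, 120 * 0.5^0.75)
  expect_equal(child$cardiac_output,
               sum(child$organs$blood_flow[child$organs$name != "lung"], na.rm = TRUE))
  expect_error(apply_pediatric(ref_adult(), age = 0.1, weight = 3.5), "age")
  expect_error(apply_pediatric(ref_adult(), age = 5, weight = 120), "weight")
})

test_that("disease transforms are pure functions", {
  phys <- ref_adult()
  snapshot <- unserialize(serialize(phys, NULL))
  invisible(apply_moderate_ckd(phys))
  invisible(apply_severe_ckd(phys))
  invisible(suppressWarnings(apply_obesity(phys, target_weight = 110)))
  invisible(apply_pediatric(phys, 10, 35))
  expect_identical(phys, snapshot)
})

test_that("organ volume closure survives every transform", {
  for (p in list(apply_moderate_ckd(ref_adult()),
                 apply_severe_ckd(ref_adult()),
                 suppressWarnings(apply_obesity(build_reference_adult(76, 180, 40),
                                                target_weight = 115)),
                 apply_pediatric(ref_adult(), 6, 20))) {
    expect_equal(sum(p$organs$volume), p$body_weight,
                 tolerance = 0.05 * p$body_weight)
  }
})
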