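# Seeded virtual populations matched to study demographics, population
# simulation, and percentile-band summaries.

#' Population demographics for a virtual study arm
#'
#' @param n Number of virtual subjects (>= 1).
#' @param age_range Length-2 numeric, years (min, max; may be a point value).
#' @param weight_range Length-2 numeric, kg.
#' @param n_females Number of female subjects (<= n).
#' @param disease One of `"healthy"`, `"moderate_ckd"`, `"severe_ckd"`,
#'   `"obese"`, `"pediatric"`.
#' @param bmi_range Adult body-mass-index sampling range used to back-compute
#'   height from weight (Table-style study reports omit height). Defaults:
#'   20-27 for lean adults, 31-45 for obese.
#' @param gfr Optional within-band GFR override for the CKD states, mL/min.
#' @return An object of class `pbpk_demographics`.
#' @export
population_demographics <- function(n, age_range, weight_range, n_females = 0,
                                    disease = c("healthy", "moderate_ckd",
                                                "severe_ckd", "obese", "pediatric"),
                                    bmi_range = NULL, gfr = NULL) {
  disease <- match.arg(disease)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  age_range <- sort(as.numeric(rep(age_range, length.out = 2)))
  weight_range <- sort(as.numeric(rep(weight_range, length.out = 2)))
  if (n_females > n) stop("n_females cannot exceed n", call. = FALSE)
  if (is.null(bmi_range)) {
    bmi_range <- if (disease == "obese") c(31, 45) else c(20, 27)
  }
  structure(list(n = n, age_range = age_range, weight_range = weight_range,
                 n_females = as.integer(n_females), disease = disease,
                 bmi_range = bmi_range, gfr = gfr),
            class = "pbpk_demographics")
}

.build_subject <- function(demo, age, weight, sex) {
  switch(demo$disease,
    healthy = {
      bmi <- stats::runif(1, demo$bmi_range[1], demo$bmi_range[2])
      height <- min(max(sqrt(weight / bmi) * 100, 120), 220)
      build_reference_adult(weight, height, age, sex)
    },
    moderate_ckd = {
      bmi <- stats::runif(1, demo$bmi_range[1], demo$bmi_range[2])
      height <- min(max(sqrt(weight / bmi) * 100, 120), 220)
      ref <- build_reference_adult(weight, height, age, sex)
      if (is.null(demo$gfr)) apply_moderate_ckd(ref) else apply_moderate_ckd(ref, demo$gfr)
    },
    severe_ckd = {
      bmi <- stats::runif(1, demo$bmi_range[1], demo$bmi_range[2])
      height <- min(max(sqrt(weight / bmi) * 100, 120), 220)
      ref <- build_reference_adult(weight, height, age, sex)
      if (is.null(demo$gfr)) apply_severe_ckd(ref) else apply_severe_ckd(ref, demo$gfr)
    },
    obese = {
      bmi <- stats::runif(1, demo$bmi_range[1], demo$bmi_range[2])
      height <- min(max(sqrt(weight / bmi) * 100, 120), 220)
      lean_weight <- max(23.5 * (height / 100)^2, 20)
      ref <- build_reference_adult(min(lean_weight, weight), height, age, sex)
      suppressWarnings(apply_obesity(ref, target_weight = weight))
    },
    pediatric = {
      ref <- build_reference_adult(70, 180, 30, sex)
      apply_pediatric(ref, age, weight)
    }
  )
}

#' Sample a seeded virtual population
#'
#' Ages and weights are drawn uniformly within the reported study ranges, sex
#' is assigned to match the reported female count, height is back-computed
#' from weight and a cohort-appropriate BMI draw, and the disease transform is
#' applied per subject. The draw is fully reproducible for a fixed seed.
#'
#' @param demo A [population_demographics()] object.
#' @param seed Integer RNG seed.
#' @return An object of class `virtual_population` (list of `physiology`
#'   subjects plus the generating demographics and seed).
#' @export
sample_population <- function(demo, seed = 1L) {
  stopifnot(inherits(demo, "pbpk_demographics"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  sexes <- c(rep("female", demo$n_females), rep("male", demo$n - demo$n_females))
  subjects <- vector("list", demo$n)
  for (i in seq_len(demo$n)) {
    age <- stats::runif(1, demo$age_range[1], demo$age_range[2])
    weight <- stats::runif(1, demo$weight_range[1], demo$weight_range[2])
    subjects[[i]] <- .build_subject(demo, age, weight, sexes[i])
  }
  structure(list(subjects = subjects, demographics = demo, seed = as.integer(seed)),
            class = "virtual_population")
}

#' @export
print.virtual_population <- function(x, ...) {
  w <- vapply(x$subjects, function(s) s$body_weight, numeric(1))
  cat(sprintf("<virtual_population> %d subjects (%s), seed %d\n",
              length(x$subjects), x$demographics$disease, x$seed))
  cat(sprintf("  weight %.1f-%.1f kg, %d female\n",
              min(w), max(w), x$demographics$n_females))
  invisible(x)
}

#' Simulate every subject of a virtual population
#'
#' One venous-plasma profile per subject on a common time grid; each subject's
#' partition coefficients are recomputed from its disease-adjusted fraction
#' unbound. Doses may be fixed or per-kilogram.
#'
#' @param pop A `virtual_population`.
#' @param drug A `drug_params` object.
#' @param regimen A [dose_regimen()]; its `dose_mg` is used for every subject
#'   unless `dose_mg_per_kg` is given.
#' @param times Common output grid, h.
#' @param dose_mg_per_kg Optional weight-based dose (mg/kg), overriding the
#'   regimen amount per subject.
#' @return An object of class `population_profiles`: `time`, concentration
#'   matrix (times x subjects), per-subject doses and model clearances.
#' @export
simulate_population <- function(pop, drug = cefepime_defaults(),
                                regimen = dose_regimen(1000),
                                times = seq(0, 12, by = 0.05),
                                dose_mg_per_kg = NULL) {
  stopifnot(inherits(pop, "virtual_population"))
  if (!length(pop$subjects)) stop("population is empty", call. = FALSE)
  times <- sort(unique(times))
  n <- length(pop$subjects)
  conc <- matrix(NA_real_, nrow = length(times), ncol = n)
  doses <- numeric(n)
  cls <- numeric(n)
  weights <- numeric(n)
  for (i in seq_len(n)) {
    phys <- pop$subjects[[i]]
    reg <- regimen
    if (!is.null(dose_mg_per_kg)) reg$dose_mg <- dose_mg_per_kg * phys$body_weight
    model <- pbpk_model(phys, drug)
    prof <- tryCatch(simulate(model, regimen = reg, times = times),
                     error = function(e) stop(sprintf("subject %d: %s", i,
                                                      conditionMessage(e)),
                                              call. = FALSE))
    conc[, i] <- prof$conc
    doses[i] <- reg$dose_mg
    cls[i] <- model$cl_plasma
    weights[i] <- phys$body_weight
  }
  structure(list(time = times, conc = conc, doses = doses,
                 cl_plasma = cls, weights = weights, population = pop,
                 regimen = regimen),
            class = "population_profiles")
}

#' @export
print.population_profiles <- function(x, ...) {
  cat(sprintf("<population_profiles> %d subjects x %d time points\n",
              ncol(x$conc), nrow(x$conc)))
  invisible(x)
}

#' Percentile-band summary of a population simulation
#'
#' Pointwise arithmetic mean, empirical 5th and 95th percentiles (linear
#' interpolation definition, `stats::quantile` type 7), minimum and maximum of
#' the simulated concentrations, the summary drawn as shaded bands in visual
#' predictive checks.
#'
#' @param x A `population_profiles` object (>= 2 subjects on a common grid),
#'   or a numeric matrix (times x subjects) with `times` supplied.
#' @param times Time grid when `x` is a bare matrix.
#' @return A data.frame of class `percentile_bands` with columns `time`,
#'   `mean`, `p5`, `p95`, `min`, `max`.
#' @export
summarize_bands <- function(x, times = NULL) {
  if (inherits(x, "population_profiles")) {
    times <- x$time
    m <- x$conc
  } else {
    m <- as.matrix(x)
    if (is.null(times) || length(times) != nrow(m)) {
      stop("profiles must share a common time grid", call. = FALSE)
    }
  }
  if (ncol(m) < 2) stop("need at least 2 profiles", call. = FALSE)
  bands <- data.frame(
    time = times,
    mean = rowMeans(m),
    p5 = apply(m, 1, stats::quantile, probs = 0.05, type = 7, names = FALSE),
    p95 = apply(m, 1, stats::quantile, probs = 0.95, type = 7, names = FALSE),
    min = apply(m, 1, min),
    max = apply(m, 1, max)
  )
  stopifnot(all(bands$min <= bands$p5 + 1e-12),
            all(bands$p5 <= bands$p95 + 1e-12),
            all(bands$p95 <= bands$max + 1e-12),
            all(bands$mean >= bands$min - 1e-12 & bands$mean <= bands$max + 1e-12))
  class(bands) <- c("percentile_bands", "data.frame")
  bands
}

#' @export
plot.percentile_bands <- function(x, log = "", xlab = "time (h)",
                                  ylab = expression(paste("plasma conc (", mu, "g/mL)")),
                                  ...) {
  graphics::matplot(x$time, cbind(x$mean, x$p5, x$p95, x$min, x$max),
                    type = "l", lty = c(1, 3, 3, 2, 2),
                    col = c("black", "grey40", "grey40", "grey70", "grey70"),
                    log = log, xlab = xlab, ylab = ylab, ...)
  graphics::legend("topright", c("mean", "5th/95th pct", "min/max"),
                   lty = c(1, 3, 2), col = c("black", "grey40", "grey70"), bty = "n")
  invisible(x)
}
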