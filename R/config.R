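# Scenario configuration (YAML), bundled study-arm library, one-shot scenario
# runs and the two-column profile text format.

.SCENARIO_KEYS <- c("name", "population", "regimen", "simulation")
.POP_KEYS <- c("n_subjects", "n_observed", "age", "weight", "n_females", "disease",
               "bmi", "gfr")
.REG_KEYS <- c("dose_mg", "dose_mg_per_kg", "infusion_min")
.SIM_KEYS <- c("horizon_h", "dt_h")

#' Read and validate a scenario configuration
#'
#' A scenario file is a YAML document with four blocks: `name`, `population`
#' (n_subjects, n_observed, age \[min, max\], weight \[min, max\], n_females, disease,
#' optional bmi range and CKD gfr override), `regimen` (`dose_mg`, scalar or
#' list, or `dose_mg_per_kg`; `infusion_min`, scalar or list) and `simulation`
#' (`horizon_h`, `dt_h`). Unknown keys are rejected before any computation.
#'
#' @param path Path to a YAML scenario file.
#' @return An object of class `pbpk_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  .reject_unknown(cfg, .SCENARIO_KEYS, "scenario")
  for (blk in c("population", "regimen", "simulation")) {
    if (is.null(cfg[[blk]])) stop("scenario block missing: ", blk, call. = FALSE)
  }
  .reject_unknown(cfg$population, .POP_KEYS, "population")
  .reject_unknown(cfg$regimen, .REG_KEYS, "regimen")
  .reject_unknown(cfg$simulation, .SIM_KEYS, "simulation")
  if (is.null(cfg$regimen$dose_mg) && is.null(cfg$regimen$dose_mg_per_kg)) {
    stop("regimen needs dose_mg or dose_mg_per_kg", call. = FALSE)
  }
  # validate the demographics eagerly so config errors surface here
  .scenario_demographics(structure(cfg, class = "pbpk_scenario"))
  structure(cfg, class = "pbpk_scenario")
}

.reject_unknown <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
}

#' @export
print.pbpk_scenario <- function(x, ...) {
  p <- x$population; r <- x$regimen
  dose <- if (!is.null(r$dose_mg_per_kg)) sprintf("%g mg/kg", r$dose_mg_per_kg)
          else paste(r$dose_mg, collapse = "/")
  cat(sprintf("<pbpk_scenario> %s: n=%d %s, %s mg IV / %s min\n",
              x$name %||% "(unnamed)", p$n_subjects, p$disease, dose,
              paste(r$infusion_min, collapse = "/")))
  invisible(x)
}

#' Bundled scenario files
#'
#' The package ships one scenario per study arm of the source clinical
#' comparison (six healthy arms, one pediatric, moderate and severe renal
#' impairment, one obese).
#'
#' @param name Scenario name (file base name without extension); when missing,
#'   all available names are listed.
#' @return A file path (or a character vector of names).
#' @export
scenario_file <- function(name = NULL) {
  dir <- system.file("extdata", "scenarios", package = "cefepbpk")
  if (is.null(name)) {
    return(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
  }
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path)) {
    stop("no bundled scenario named '", name, "'; see scenario_file()", call. = FALSE)
  }
  path
}

.resolve_scenario <- function(scenario) {
  if (inherits(scenario, "pbpk_scenario")) return(scenario)
  if (is.character(scenario) && length(scenario) == 1L) {
    path <- if (file.exists(scenario)) scenario else scenario_file(scenario)
    return(read_scenario(path))
  }
  stop("scenario must be a pbpk_scenario, a file path or a bundled name",
       call. = FALSE)
}

.scenario_demographics <- function(scenario, n = NULL) {
  p <- scenario$population
  n <- n %||% p$n_subjects
  n_f <- p$n_females %||% 0L
  if (!is.null(n) && n != p$n_subjects) {
    # sub-sampled arm (e.g. the observed subjects): keep the female fraction
    n_f <- round(n_f * n / p$n_subjects)
  }
  population_demographics(
    n = n,
    age_range = unlist(p$age),
    weight_range = unlist(p$weight),
    n_females = n_f,
    disease = p$disease,
    bmi_range = if (!is.null(p$bmi)) unlist(p$bmi) else NULL,
    gfr = p$gfr
  )
}

.scenario_regimen <- function(scenario, dose_mg = NULL, infusion_min = NULL) {
  r <- scenario$regimen
  infusion <- infusion_min %||% unlist(r$infusion_min)[1]
  per_kg <- r$dose_mg_per_kg
  dose <- dose_mg %||% unlist(r$dose_mg)[1] %||% 0
  list(regimen = dose_regimen(dose, infusion_min = infusion),
       dose_mg_per_kg = per_kg)
}

#' Run one scenario end to end
#'
#' Samples the scenario's virtual population, simulates every subject on the
#' configured grid, summarizes percentile bands, runs per-subject NCA, and
#' returns a manifest (scenario name, seed, package version) sufficient to
#' regenerate the outputs bit-for-bit.
#'
#' @param scenario A `pbpk_scenario`, file path or bundled scenario name.
#' @param seed Integer RNG seed.
#' @param dose_mg,infusion_min Optional overrides of the scenario's first
#'   listed dose/infusion duration (for multi-dose or multi-duration arms).
#' @param n Optional override of the number of simulated subjects.
#' @return A list of class `pbpk_run`: `profiles` (`population_profiles`),
#'   `bands`, `nca` (per-subject table), `manifest`.
#' @export
run_scenario <- function(scenario, seed = 1L, dose_mg = NULL,
                         infusion_min = NULL, n = NULL) {
  scenario <- .resolve_scenario(scenario)
  demo <- .scenario_demographics(scenario, n = n %||% scenario$population$n_subjects)
  reg <- .scenario_regimen(scenario, dose_mg = dose_mg, infusion_min = infusion_min)
  times <- seq(0, scenario$simulation$horizon_h, by = scenario$simulation$dt_h)
  pop <- sample_population(demo, seed = seed)
  sim <- simulate_population(pop, regimen = reg$regimen, times = times,
                             dose_mg_per_kg = reg$dose_mg_per_kg)
  per_kg <- !is.null(reg$dose_mg_per_kg)
  structure(list(
    profiles = sim,
    bands = summarize_bands(sim),
    nca = nca_population(sim, per_kg = per_kg),
    manifest = list(scenario = scenario$name, seed = as.integer(seed),
                    package_version = as.character(utils::packageVersion("cefepbpk")),
                    dose_mg = dose_mg, infusion_min = infusion_min, n = n)
  ), class = "pbpk_run")
}

#' @export
print.pbpk_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<pbpk_run> scenario '%s', seed %d (v%s)\n",
              m$scenario, m$seed, m$package_version))
  cat(sprintf("  %d subjects; mean NCA CL %.3f %s; mean Cmax %.2f ug/mL\n",
              nrow(x$nca), mean(x$nca$cl), x$nca$cl_units[1], mean(x$nca$cmax)))
  invisible(x)
}

#' Write / read a concentration-time profile as two-column text
#'
#' The interchange format is tab-separated `time_h`, `conc_ug_ml` with `#`
#' comment headers carrying metadata; readable by any NCA tool and by
#' [read_profile()].
#'
#' @param profile A data.frame with `time` and `conc` columns.
#' @param path Output file path.
#' @param metadata Named character vector written as `# key: value` headers.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) {
    writeLines(sprintf("# %s: %s", names(metadata), metadata), con)
  }
  writeLines("time_h\tconc_ug_ml", con)
  utils::write.table(data.frame(profile$time, profile$conc), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @return For `read_profile()`: a data.frame with columns `time`, `conc`.
#' @export
read_profile <- function(path) {
  d <- utils::read.delim(path, comment.char = "#")
  stats::setNames(d[, 1:2], c("time", "conc"))
}
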