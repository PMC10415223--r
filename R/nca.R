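# Non-compartmental analysis of concentration-time profiles: Cmax/Tmax,
# linear-up/log-down trapezoidal AUC, best-adjusted-R-squared terminal slope,
# extrapolation to infinity and clearance.

.check_profile <- function(time, conc, min_points = 1L) {
  if (length(time) != length(conc)) stop("time and conc lengths differ", call. = FALSE)
  if (length(time) < min_points) {
    stop(sprintf("profile needs at least %d point(s)", min_points), call. = FALSE)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

#' Maximum concentration and its time
#'
#' @param time Sampling times, h, strictly increasing.
#' @param conc Concentrations, ug/mL.
#' @return Named vector `c(cmax, tmax)`; the earliest time wins on ties.
#' @export
cmax_tmax <- function(time, conc) {
  .check_profile(time, conc, 1L)
  i <- which.max(conc) # which.max returns the first (earliest) maximum
  c(cmax = conc[i], tmax = time[i])
}

#' Trapezoidal area under the curve
#'
#' Linear-up/log-down by default: the logarithmic trapezoid
#' `(c1 - c2) * dt / log(c1/c2)` is used on strictly decreasing segments with
#' positive endpoints, the linear trapezoid elsewhere (and as fallback when a
#' log segment touches zero). `method = "linear"` forces linear throughout.
#'
#' @param time Sampling times, h, strictly increasing (>= 2 points).
#' @param conc Concentrations, ug/mL.
#' @param method `"lin-log"` (default) or `"linear"`.
#' @return AUC from the first to the last sampling time, ug/mL*h.
#' @export
auc_trapezoidal <- function(time, conc, method = c("lin-log", "linear")) {
  method <- match.arg(method)
  .check_profile(time, conc, 2L)
  dt <- diff(time)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  lin <- (c1 + c2) / 2 * dt
  if (method == "linear") return(sum(lin))
  use_log <- c2 < c1 & c2 > 0
  seg <- lin
  seg[use_log] <- (c1[use_log] - c2[use_log]) * dt[use_log] /
    log(c1[use_log] / c2[use_log])
  sum(seg)
}

#' Terminal log-linear slope
#'
#' Fits log(conc) ~ time over candidate terminal point sets (the last 3 points
#' up to all points strictly after Tmax) and keeps the fit with the best
#' adjusted R-squared; ties within 1e-4 prefer the longer tail, the common
#' convention of NCA software.
#'
#' @param time,conc The profile (>= `min_points` positive points after the
#'   peak).
#' @param min_points Minimum number of tail points (default 3).
#' @return List with `lambda_z` (1/h), `t_half` (h), `n_points`, `adj_r2`,
#'   `intercept` (log scale).
#' @export
terminal_slope <- function(time, conc, min_points = 3L) {
  .check_profile(time, conc, min_points)
  i_max <- which.max(conc)
  idx <- seq_along(time) > i_max & conc > 0
  tt <- time[idx]; cc <- conc[idx]
  if (length(tt) < min_points) {
    stop("terminal phase not identifiable: too few post-peak points", call. = FALSE)
  }
  best <- NULL
  n_avail <- length(tt)
  for (k in min_points:n_avail) {
    sel <- seq.int(n_avail - k + 1L, n_avail)
    fit <- stats::lm.fit(cbind(1, tt[sel]), log(cc[sel]))
    slope <- unname(fit$coefficients[2])
    if (!is.finite(slope) || slope >= 0) next
    res <- fit$residuals
    y <- log(cc[sel])
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj_r2 + 1e-4 ||
        (adj > best$adj_r2 - 1e-4 && k > best$n_points)) {
      best <- list(lambda_z = -slope, t_half = log(2) / -slope,
                   n_points = k, adj_r2 = adj,
                   intercept = unname(fit$coefficients[1]))
    }
  }
  if (is.null(best)) stop("terminal phase not identifiable: no decreasing tail",
                          call. = FALSE)
  best
}

#' Non-compartmental analysis of one profile
#'
#' Computes Cmax/Tmax, AUC(0-tlast) by linear-up/log-down trapezoid, the
#' terminal slope, AUC(0-Inf) = AUC(0-tlast) + Clast/lambda_z with its
#' extrapolated fraction (a warning is raised above 20%), half-life
#' ln(2)/lambda_z, and clearance dose/AUC(0-Inf) when a dose is given.
#'
#' @param time,conc The profile.
#' @param dose_mg Administered dose, mg (optional; enables `cl`).
#' @param method AUC method, see [auc_trapezoidal()].
#' @param min_points Minimum terminal points, see [terminal_slope()].
#' @return An object of class `nca`: a list of PK parameters.
#' @examples
#' t <- seq(0.5, 8, by = 0.5)
#' nca(t, 100 * exp(-0.35 * t), dose_mg = 1000)
#' @export
nca <- function(time, conc, dose_mg = NULL, method = c("lin-log", "linear"),
                min_points = 3L) {
  method <- match.arg(method)
  .check_profile(time, conc, 2L)
  cm <- cmax_tmax(time, conc)
  auc_t <- auc_trapezoidal(time, conc, method)
  ts <- terminal_slope(time, conc, min_points)
  c_last <- conc[length(conc)]
  auc_inf <- auc_t + c_last / ts$lambda_z
  extrap <- 100 * (c_last / ts$lambda_z) / auc_inf
  if (extrap >= 20) {
    warning(sprintf("extrapolated AUC fraction is %.1f%% (>= 20%%)", extrap),
            call. = FALSE)
  }
  out <- list(cmax = unname(cm["cmax"]), tmax = unname(cm["tmax"]),
              auc_0_t = auc_t, auc_0_inf = auc_inf,
              lambda_z = ts$lambda_z, t_half = ts$t_half,
              lambda_z_n_points = ts$n_points, lambda_z_adj_r2 = ts$adj_r2,
              extrapolated_fraction = extrap,
              dose_mg = dose_mg,
              cl = if (!is.null(dose_mg)) clearance(dose_mg, auc_inf) else NA_real_)
  class(out) <- "nca"
  out
}

#' Clearance from dose and extrapolated AUC
#'
#' `CL = dose / AUC(0-Inf)`; mg per ug/mL*h is numerically L/h.
#'
#' @param dose_mg Dose, mg.
#' @param auc_0_inf AUC(0-Inf), ug/mL*h (> 0).
#' @return Clearance, L/h (0 for a zero dose).
#' @examples
#' clearance(1000, 113.6)
#' @export
clearance <- function(dose_mg, auc_0_inf) {
  if (auc_0_inf <= 0) stop("auc_0_inf must be positive", call. = FALSE)
  dose_mg / auc_0_inf
}

#' @export
print.nca <- function(x, ...) {
  cat("<nca>\n")
  cat(sprintf("  Cmax %.3f ug/mL at %.2f h\n", x$cmax, x$tmax))
  cat(sprintf("  AUC(0-t) %.2f | AUC(0-Inf) %.2f ug/mL*h (%.1f%% extrapolated)\n",
              x$auc_0_t, x$auc_0_inf, x$extrapolated_fraction))
  cat(sprintf("  lambda_z %.4f 1/h (n=%d, adjR2 %.4f) | t1/2 %.2f h\n",
              x$lambda_z, x$lambda_z_n_points, x$lambda_z_adj_r2, x$t_half))
  if (!is.na(x$cl)) cat(sprintf("  CL %.3f L/h (dose %g mg)\n", x$cl, x$dose_mg))
  invisible(x)
}

#' @export
coef.nca <- function(object, ...) {
  c(cmax = object$cmax, tmax = object$tmax, auc_0_t = object$auc_0_t,
    auc_0_inf = object$auc_0_inf, lambda_z = object$lambda_z,
    t_half = object$t_half, cl = object$cl)
}

#' NCA parameter table for a simulated population
#'
#' Runs [nca()] on every subject of a [simulate_population()] result.
#'
#' @param sim A `population_profiles` object.
#' @param per_kg Report clearance per kilogram (L/h/kg), the convention for
#'   weight-based pediatric dosing.
#' @param ... Passed to [nca()].
#' @return A data.frame, one row per subject.
#' @export
nca_population <- function(sim, per_kg = FALSE, ...) {
  stopifnot(inherits(sim, "population_profiles"))
  rows <- lapply(seq_len(ncol(sim$conc)), function(i) {
    res <- nca(sim$time, sim$conc[, i], dose_mg = sim$doses[i], ...)
    data.frame(subject = i, weight = sim$weights[i], dose_mg = sim$doses[i],
               cmax = res$cmax, auc_0_inf = res$auc_0_inf,
               lambda_z = res$lambda_z, t_half = res$t_half,
               cl = if (per_kg) res$cl / sim$weights[i] else res$cl,
               cl_units = if (per_kg) "L/h/kg" else "L/h",
               model_cl = sim$cl_plasma[i])
  })
  do.call(rbind, rows)
}
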