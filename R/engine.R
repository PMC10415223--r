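# Whole-body ODE engine: perfusion-limited organs, venous/arterial pools,
# lung in series with cardiac output, IV-infusion input into the venous pool,
# renal elimination by filtration of the arterial plasma entering the kidney.
#
# Unit conventions (package-wide): time h, amounts mg, volumes L,
# concentrations ug/mL (= mg/L); physiology flows are L/min and are converted
# to L/h once, at assembly.

#' Intravenous infusion dosing regimen
#'
#' @param dose_mg Dose per administration, mg (> 0, or 0 for a null run).
#' @param infusion_min Infusion duration, minutes (> 0).
#' @param start_h Start time of the first infusion, h.
#' @param n_doses Number of administrations.
#' @param interval_h Interdose interval, h (required when `n_doses > 1`; must
#'   exceed the infusion duration so infusions do not overlap).
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen(1000, infusion_min = 30)
#' @export
dose_regimen <- function(dose_mg, infusion_min = 30, start_h = 0,
                         n_doses = 1L, interval_h = NULL) {
  if (dose_mg < 0) stop("dose_mg must be non-negative", call. = FALSE)
  if (infusion_min <= 0) stop("infusion_min must be positive", call. = FALSE)
  if (n_doses > 1) {
    if (is.null(interval_h)) stop("interval_h required for multiple doses", call. = FALSE)
    if (interval_h <= infusion_min / 60) {
      stop("interdose interval must exceed the infusion duration", call. = FALSE)
    }
  }
  structure(list(dose_mg = dose_mg, infusion_min = infusion_min,
                 start_h = start_h, n_doses = as.integer(n_doses),
                 interval_h = interval_h),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("<dose_regimen> %g mg IV over %g min x %d, start %g h\n",
              x$dose_mg, x$infusion_min, x$n_doses, x$start_h))
  invisible(x)
}

# infusion windows as a matrix (start, end, rate mg/h)
.infusion_windows <- function(regimen) {
  starts <- regimen$start_h +
    (seq_len(regimen$n_doses) - 1L) * (regimen$interval_h %||% 0)
  dur <- regimen$infusion_min / 60
  cbind(start = starts, end = starts + dur,
        rate = rep(regimen$dose_mg / dur, length(starts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a whole-body PBPK model for one individual
#'
#' Couples an individual physiology, the drug parameters and a tissue:plasma
#' partition-coefficient set into an ODE model with perfusion-limited organs.
#' Per organ, `dA/dt = Q * (C_art - C_tissue / (Kp/BP))` in blood
#' concentrations; splanchnic organs drain through the liver; the lung sits in
#' series with the (effective) cardiac output, taken as the sum of the
#' arterial-side organ flows so the flow matrix balances by construction.
#' Renal plasma clearance is
#' `CL_plasma = CL_R,specific * 70 kg * 0.06 * GFR/120` L/h — the specific
#' clearance anchored at the reference adult and carried across individuals by
#' their glomerular filtration rate — and is applied to the arterial plasma
#' entering the kidney, which preserves the linear-elimination identity
#' `dose / AUC(0-Inf) = CL_plasma` exactly.
#'
#' @param physiology A `physiology` object.
#' @param drug A `drug_params` object (default [cefepime_defaults()]).
#' @param kp Optional named Kp vector; computed via [compute_kp_set()] with
#'   the disease-adjusted fraction unbound when omitted.
#' @return An object of class `pbpk_model`.
#' @examples
#' mod <- pbpk_model(build_reference_adult(70, 180, 30))
#' coef(mod)
#' @export
pbpk_model <- function(physiology, drug = cefepime_defaults(), kp = NULL) {
  validate_physiology(physiology)
  fu <- fu_adjusted(drug, physiology)
  if (is.null(kp)) kp <- compute_kp_set(drug, physiology, fu = fu)
  org <- physiology$organs
  perfused <- org$name[!org$name %in% c("arterial_blood", "venous_blood")]
  missing_kp <- setdiff(perfused, names(kp))
  if (length(missing_kp)) {
    stop("incomplete Kp set; missing: ", paste(missing_kp, collapse = ", "),
         call. = FALSE)
  }
  bp <- (1 - physiology$hct) + physiology$hct * drug$kp_rbc
  cl_plasma <- drug$cl_r_specific * 70 * 0.06 * physiology$gfr / 120

  structure(list(
    physiology = physiology,
    drug = drug,
    kp = kp[perfused],
    bp = bp,
    fu = fu,
    cl_plasma = cl_plasma,
    vss = vss_l_per_kg(physiology, kp)
  ), class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat("<pbpk_model> cefepime whole-body PBPK\n")
  print(x$physiology)
  cat(sprintf("  CL_plasma %.3f L/h | Vss %.3f L/kg | B:P %.3f | fu %.4f\n",
              x$cl_plasma, x$vss, x$bp, x$fu))
  invisible(x)
}

#' @export
coef.pbpk_model <- function(object, ...) {
  c(cl_plasma_l_h = object$cl_plasma,
    vss_l_kg = object$vss,
    blood_plasma_ratio = object$bp,
    fu_plasma = object$fu,
    gfr_ml_min = object$physiology$gfr,
    body_weight_kg = object$physiology$body_weight)
}

# internal: build state layout + derivative closure
.build_ode <- function(model, flow_scale = 1) {
  org <- model$physiology$organs
  blood <- c("arterial_blood", "venous_blood")
  tis <- org[!org$name %in% blood, , drop = FALSE]
  v_art <- org$volume[org$name == "arterial_blood"]
  v_ven <- org$volume[org$name == "venous_blood"]

  q <- tis$blood_flow * 60 * flow_scale          # L/h
  names(q) <- tis$name
  v <- tis$volume
  names(v) <- tis$name
  kpb <- model$kp[tis$name] / model$bp           # tissue:blood partition
  splanchnic <- tis$name[!is.na(tis$drains_to) & tis$drains_to == "liver"]
  direct <- setdiff(tis$name, c("lung", "liver", splanchnic))
  q_liver_out <- q[["liver"]] + sum(q[splanchnic])
  co <- sum(q[setdiff(tis$name, "lung")])        # effective cardiac output, L/h
  cl <- model$cl_plasma
  bp <- model$bp

  state_names <- c(tis$name, "venous", "arterial", "eliminated")
  n_tis <- nrow(tis)

  deriv <- function(t, A, rate) {
    a_tis <- A[seq_len(n_tis)]
    c_out <- (a_tis / v) / kpb                   # blood conc leaving each organ
    c_ven <- A[[n_tis + 1L]] / v_ven
    c_art <- A[[n_tis + 2L]] / v_art

    dA <- q * (c_art - c_out)
    dA[["lung"]] <- co * (c_ven - c_out[["lung"]])
    dA[["liver"]] <- q[["liver"]] * c_art + sum(q[splanchnic] * c_out[splanchnic]) -
      q_liver_out * c_out[["liver"]]
    elim <- cl * c_art / bp
    dA[["kidney"]] <- dA[["kidney"]] - elim

    d_ven <- sum(q[direct] * c_out[direct]) + q_liver_out * c_out[["liver"]] -
      co * c_ven + rate
    d_art <- co * c_out[["lung"]] - co * c_art
    list(c(dA, d_ven, d_art, elim))
  }

  list(deriv = deriv, state_names = state_names, n_tis = n_tis,
       v_ven = v_ven, v_art = v_art, v = v, co = co)
}

#' Simulate a concentration-time profile
#'
#' Integrates the whole-body ODE system for a dosing regimen, restarting the
#' solver at every infusion on/off boundary (stiff-capable `deSolve::lsoda`,
#' relative tolerance 1e-8, absolute tolerance 1e-10 mg).
#'
#' @param object A `pbpk_model`.
#' @param nsim,seed Ignored (the model is deterministic); present for
#'   compatibility with [stats::simulate()].
#' @param regimen A [dose_regimen()].
#' @param times Output times, h, starting at or after 0.
#' @param full_state Keep the full amount-per-compartment trajectory (needed
#'   by [mass_balance()]).
#' @param ... Unused.
#' @return A data.frame of class `pbpk_profile` with columns `time` (h) and
#'   `conc` (venous plasma concentration, ug/mL).
#' @examples
#' mod <- pbpk_model(build_reference_adult(70, 180, 30))
#' prof <- simulate(mod, regimen = dose_regimen(1000), times = seq(0, 12, 0.1))
#' head(prof)
#' @export
simulate.pbpk_model <- function(object, nsim = 1, seed = NULL,
                                regimen = dose_regimen(1000),
                                times = seq(0, 12, by = 0.05),
                                full_state = FALSE, ...) {
  stopifnot(inherits(regimen, "dose_regimen"))
  times <- sort(unique(times))
  if (times[1] < 0) stop("output times must be non-negative", call. = FALSE)

  ode <- .build_ode(object)
  win <- .infusion_windows(regimen)
  horizon <- max(times)
  bounds <- sort(unique(c(0, pmin(c(win[, "start"], win[, "end"]), horizon), horizon)))
  bounds <- bounds[bounds <= horizon]

  state <- stats::setNames(numeric(length(ode$state_names)), ode$state_names)
  out_rows <- NULL
  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    mid <- (t0 + t1) / 2
    rate <- sum(win[win[, "start"] <= mid & mid < win[, "end"], "rate"])
    seg_times <- sort(unique(c(t0, times[times >= t0 & times <= t1], t1)))
    sol <- deSolve::lsoda(
      y = state, times = seg_times,
      func = function(t, y, parms) ode$deriv(t, y, parms), parms = rate,
      rtol = 1e-8, atol = 1e-10
    )
    if (attr(sol, "istate")[1L] < 0) {
      stop(sprintf("ODE integration failed near t = %.3f h", t1), call. = FALSE)
    }
    state <- sol[nrow(sol), -1L]
    keep <- sol[, "time"] %in% times & (i == 1L | sol[, "time"] > t0)
    out_rows <- rbind(out_rows, sol[keep, , drop = FALSE])
  }

  conc <- (out_rows[, "venous"] / ode$v_ven) / object$bp
  prof <- data.frame(time = out_rows[, "time"], conc = pmax(conc, 0))
  class(prof) <- c("pbpk_profile", "data.frame")
  attr(prof, "regimen") <- regimen
  attr(prof, "cl_plasma") <- object$cl_plasma
  attr(prof, "bp") <- object$bp
  attr(prof, "subject_weight") <- object$physiology$body_weight
  if (full_state) {
    attr(prof, "state") <- out_rows
    attr(prof, "windows") <- win
  }
  prof
}

#' Predict venous plasma concentrations
#'
#' Thin wrapper over [simulate.pbpk_model()] returning the concentration
#' vector at the requested times.
#'
#' @inheritParams simulate.pbpk_model
#' @param newdata Optional data.frame with a `time` column.
#' @return Numeric vector of concentrations, ug/mL.
#' @export
predict.pbpk_model <- function(object, newdata = NULL,
                               regimen = dose_regimen(1000),
                               times = seq(0, 12, by = 0.05), ...) {
  if (!is.null(newdata)) times <- newdata$time
  simulate(object, regimen = regimen, times = times)$conc
}

#' @export
print.pbpk_profile <- function(x, ...) {
  reg <- attr(x, "regimen")
  cat(sprintf("<pbpk_profile> %d points over %g h (%g mg / %g min IV)\n",
              nrow(x), max(x$time), reg$dose_mg, reg$infusion_min))
  cat(sprintf("  Cmax %.2f ug/mL at %.2f h\n", max(x$conc), x$time[which.max(x$conc)]))
  invisible(x)
}

#' @export
plot.pbpk_profile <- function(x, log = "", xlab = "time (h)",
                              ylab = expression(paste("plasma conc (", mu, "g/mL)")),
                              type = "l", ...) {
  graphics::plot(x$time, x$conc, type = type, log = log, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Mass-balance check for a simulated profile
#'
#' Relative error `|infused - (amount in body + eliminated)| / infused` at the
#' final simulation time. Requires a profile simulated with
#' `full_state = TRUE`. A zero-dose run returns 0.
#'
#' @param profile A `pbpk_profile` carrying the full state trajectory.
#' @return Relative mass-balance error (dimensionless).
#' @export
mass_balance <- function(profile) {
  state <- attr(profile, "state")
  if (is.null(state)) stop("profile must be simulated with full_state = TRUE", call. = FALSE)
  win <- attr(profile, "windows")
  t_end <- state[nrow(state), "time"]
  infused <- sum(pmax(pmin(t_end, win[, "end"]) - win[, "start"], 0) * win[, "rate"])
  if (infused == 0) return(0)
  in_body_plus_elim <- sum(state[nrow(state), -1L])
  abs(infused - in_body_plus_elim) / infused
}

#' Closed-form one-compartment infusion solution
#'
#' Analytic venous concentration for a single constant-rate infusion into a
#' well-stirred volume `v_l` with linear clearance `cl_l_h`:
#' `C(t) = R0/CL * (1 - exp(-k t))` during the infusion and exponential
#' washout afterwards, `k = CL/V`. Used as an independent oracle for the ODE
#' engine.
#'
#' @param times Times, h.
#' @param dose_mg Dose, mg.
#' @param duration_h Infusion duration, h.
#' @param v_l Volume of distribution, L.
#' @param cl_l_h Clearance, L/h.
#' @return Concentrations, ug/mL.
#' @export
solve_infusion_1cmt <- function(times, dose_mg, duration_h, v_l, cl_l_h) {
  k <- cl_l_h / v_l
  r0 <- dose_mg / duration_h
  cend <- r0 / cl_l_h * (1 - exp(-k * duration_h))
  ifelse(times <= duration_h,
         r0 / cl_l_h * (1 - exp(-k * times)),
         cend * exp(-k * (times - duration_h)))
}

#' Collapse a PBPK model to a single well-stirred compartment
#'
#' Numerical-verification device: sets every partition coefficient and the
#' blood:plasma ratio to 1 and scales all blood flows by a large factor, so
#' the whole body behaves as one well-stirred volume equal to total body
#' volume with the model's plasma clearance. The result can be compared
#' against [solve_infusion_1cmt()].
#'
#' @param model A `pbpk_model`.
#' @param flow_scale Multiplier applied to all blood flows (default 1e4;
#'   the residual mixing error decays as `1/flow_scale`).
#' @return A modified `pbpk_model` (with attribute `flow_scale`) plus fields
#'   `v_collapsed` (L).
#' @export
collapse_model <- function(model, flow_scale = 1e4) {
  model$kp[] <- 1
  model$bp <- 1
  model$physiology$organs$blood_flow <-
    model$physiology$organs$blood_flow * flow_scale
  model$physiology$cardiac_output <- model$physiology$cardiac_output * flow_scale
  model$v_collapsed <- sum(model$physiology$organs$volume)
  model
}
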