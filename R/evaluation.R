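# Model-qualification statistics: observed/predicted fold ratios, arithmetic
# mean ratio with 95% CI, average fold error (geometric mean), and the
# two-fold acceptance criterion, recomputed from packaged comparison tables.

#' Observed/predicted fold ratio
#'
#' `R = observed / predicted`, kept at full precision; rounding is a display
#' concern only.
#'
#' @param observed,predicted Positive PK parameter values.
#' @return The fold ratio.
#' @examples
#' fold_ratio(8.21, 9.16)
#' @export
fold_ratio <- function(observed, predicted) {
  if (any(observed <= 0) || any(predicted <= 0)) {
    stop("observed and predicted values must be positive", call. = FALSE)
  }
  observed / predicted
}

#' Average fold error
#'
#' `AFE = 10^(mean(log10(ratios)))`, the geometric mean of the fold ratios.
#'
#' @param ratios Positive fold ratios (N >= 1).
#' @return The average fold error.
#' @examples
#' afe(c(1.46 / 2.4, 3.44 / 6.57))
#' @export
afe <- function(ratios) {
  if (!length(ratios)) stop("ratios must be non-empty", call. = FALSE)
  if (any(ratios <= 0)) stop("ratios must be positive", call. = FALSE)
  10^mean(log10(ratios))
}

#' Arithmetic mean fold ratio with 95% confidence interval
#'
#' @param ratios Fold ratios (N >= 1; the normal-approximation CI
#'   `mean +/- 1.96 * sd/sqrt(N)` requires N >= 2 and is `NA` otherwise).
#' @return Named vector `c(mean, ci_lower, ci_upper)`.
#' @export
mean_ratio <- function(ratios) {
  if (!length(ratios)) stop("ratios must be non-empty", call. = FALSE)
  m <- mean(ratios)
  if (length(ratios) < 2) {
    return(c(mean = m, ci_lower = NA_real_, ci_upper = NA_real_))
  }
  half <- 1.96 * stats::sd(ratios) / sqrt(length(ratios))
  c(mean = m, ci_lower = m - half, ci_upper = m + half)
}

#' Two-fold acceptance criterion
#'
#' @param r Positive fold ratio(s).
#' @return Logical: `TRUE` iff `0.5 <= r <= 2` (boundaries inclusive).
#' @export
twofold_flag <- function(r) {
  if (any(r <= 0)) stop("ratios must be positive", call. = FALSE)
  r >= 0.5 & r <= 2.0
}

#' Packaged observed/predicted PK comparison table
#'
#' Loads the bundled table of observed and model-predicted Cmax, AUC(0-Inf)
#' and clearance values per study arm (healthy at 62.5-2000 mg, pediatric at
#' 50 mg/kg, moderate/severe renal impairment and obese), as printed in the
#' source publication, with the fold ratio recomputed from the unrounded
#' pair. The healthy 1000 mg Cmax block that duplicates clearance values in
#' the printed source carries `anomaly = 1` and is preserved as printed;
#' `ratio_mismatch = 1` marks the two cells whose printed ratio disagrees with
#' the recomputed quotient by more than one unit in the last printed digit.
#'
#' @return A data.frame with columns `population`, `parameter`, `dose_mg`,
#'   `observed`, `predicted`, `ratio` (recomputed), `printed_ratio`
#'   (character, as displayed in the source), `anomaly`, `ratio_mismatch`,
#'   `study`.
#' @export
observed_predicted_pk <- function() {
  path <- system.file("extdata", "observed_predicted_pk.tsv", package = "cefepbpk")
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(printed_ratio = "character"))
  d$ratio <- fold_ratio(d$observed, d$predicted)
  d[, c("population", "parameter", "dose_mg", "observed", "predicted",
        "ratio", "printed_ratio", "anomaly", "ratio_mismatch", "study")]
}

#' Grouped qualification report
#'
#' Summarizes evaluation records per population and parameter: record count,
#' column means of the observed and predicted values, arithmetic mean fold
#' ratio with 95% CI, average fold error and the number of records inside the
#' two-fold range.
#'
#' @param records A data.frame with columns `population`, `parameter`,
#'   `observed`, `predicted` (e.g. from [observed_predicted_pk()]); a `ratio`
#'   column is recomputed if absent.
#' @return A data.frame of class `pbpk_eval_report`, one row per group;
#'   empty groups are excluded.
#' @export
build_report <- function(records) {
  if (!nrow(records)) stop("no evaluation records", call. = FALSE)
  need <- c("population", "parameter", "observed", "predicted")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  records$ratio <- fold_ratio(records$observed, records$predicted)
  groups <- split(records, list(records$population, records$parameter), drop = TRUE)
  rows <- lapply(groups, function(g) {
    mr <- mean_ratio(g$ratio)
    data.frame(population = g$population[1], parameter = g$parameter[1],
               n = nrow(g),
               mean_observed = mean(g$observed),
               mean_predicted = mean(g$predicted),
               mean_ratio = unname(mr["mean"]),
               ci_lower = unname(mr["ci_lower"]),
               ci_upper = unname(mr["ci_upper"]),
               afe = afe(g$ratio),
               n_within_twofold = sum(twofold_flag(g$ratio)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$population, out$parameter), ]
  class(out) <- c("pbpk_eval_report", "data.frame")
  out
}

#' @export
print.pbpk_eval_report <- function(x, digits = 3, ...) {
  cat("<pbpk_eval_report> observed/predicted qualification summary\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Headline qualification statistics from the packaged tables
#'
#' Recomputes, from the packaged observed/predicted comparison table, the
#' summary statistics used to qualify the model: healthy-adult mean fold
#' ratios for clearance and Cmax, the average fold error of the healthy
#' AUC(0-Inf) ratios, the healthy column means of observed/predicted Cmax and
#' observed AUC(0-Inf), the pediatric and CKD clearance fold ratios, the
#' moderate-CKD AUC ratio, and the average fold error of the renal-impairment
#' clearance ratios (moderate + severe pooled).
#'
#' @return A named list of statistics plus the full grouped report
#'   (`$report`).
#' @export
qualification_summary <- function() {
  d <- observed_predicted_pk()
  healthy <- d[d$population == "healthy", ]
  pick <- function(pop, par) d[d$population == pop & d$parameter == par, ]
  renal_cl <- d[d$population %in% c("moderate_ckd", "severe_ckd") & d$parameter == "cl", ]
  list(
    healthy_cl_mean_ratio = unname(mean_ratio(healthy$ratio[healthy$parameter == "cl"])["mean"]),
    healthy_cmax_mean_ratio = unname(mean_ratio(healthy$ratio[healthy$parameter == "cmax"])["mean"]),
    healthy_auc_afe = afe(healthy$ratio[healthy$parameter == "auc_0_inf"]),
    healthy_cmax_afe = afe(healthy$ratio[healthy$parameter == "cmax"]),
    healthy_cmax_mean_observed = mean(healthy$observed[healthy$parameter == "cmax"]),
    healthy_cmax_mean_predicted = mean(healthy$predicted[healthy$parameter == "cmax"]),
    healthy_auc_mean_observed = mean(healthy$observed[healthy$parameter == "auc_0_inf"]),
    pediatric_cl_ratio = pick("pediatric", "cl")$ratio,
    severe_ckd_cl_ratio = pick("severe_ckd", "cl")$ratio,
    moderate_ckd_cl_ratio = pick("moderate_ckd", "cl")$ratio,
    moderate_ckd_auc_ratio = pick("moderate_ckd", "auc_0_inf")$ratio,
    obese_cl_ratio = pick("obese", "cl")$ratio,
    renal_cl_afe = afe(renal_cl$ratio),
    report = build_report(d)
  )
}
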