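# Reference-adult physiology and disease/age transforms.
#
# Organ volumes (L) and blood flows (L/min) for a 70 kg, 180 cm reference adult,
# assembled from ICRP-style published reference tables. Splanchnic organs drain
# into the liver (portal vein); everything else returns to the venous pool.
# Volumes sum to ~70 L so that unit tissue density closes the mass balance.
.reference_organs <- function() {
  data.frame(
    name = c("lung", "arterial_blood", "venous_blood",
             "heart", "brain", "muscle", "skin", "adipose", "bone",
             "kidney", "gonads", "rest_of_body",
             "liver", "spleen", "stomach", "small_intestine",
             "large_intestine", "pancreas"),
    volume = c(0.5, 1.7, 3.9,
               0.33, 1.45, 28.0, 3.3, 15.0, 10.5,
               0.31, 0.035, 1.74,
               1.8, 0.15, 0.15, 0.65,
               0.35, 0.14),
    # lung flow is cardiac output and is resolved at model assembly; blood pools
    # carry no perfusion of their own. Liver flow is the hepatic ARTERIAL flow;
    # portal inflow is the sum of the splanchnic outflows.
    blood_flow = c(NA, NA, NA,
                   0.24, 0.70, 1.10, 0.30, 0.32, 0.29,
                   1.24, 0.003, 0.99,
                   0.30, 0.08, 0.04, 0.60,
                   0.24, 0.06),
    composition = c("lung", NA, NA,
                    "heart", "brain", "muscle", "skin", "adipose", "bone",
                    "kidney", "gonads", "rest_of_body",
                    "liver", "spleen", "gut", "gut",
                    "gut", "pancreas"),
    drains_to = c(NA, NA, NA,
                  "venous", "venous", "venous", "venous", "venous", "venous",
                  "venous", "venous", "venous",
                  "venous", "liver", "liver", "liver",
                  "liver", "liver"),
    stringsAsFactors = FALSE
  )
}

.REF_WEIGHT <- 70
.REF_HEIGHT <- 180
.REF_GFR <- 120 # mL/min for the reference adult

#' Body surface area by the Du Bois formula
#'
#' @param weight Body weight in kg.
#' @param height Height in cm.
#' @return Body surface area in m^2: `0.007184 * weight^0.425 * height^0.725`.
#' @examples
#' du_bois_bsa(70, 180)
#' @export
du_bois_bsa <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    stop("du_bois_bsa: 'weight' and 'height' must be positive", call. = FALSE)
  }
  0.007184 * weight^0.425 * height^0.725
}

.REF_BSA <- 0.007184 * 70^0.425 * 180^0.725

#' Construct a reference adult physiology
#'
#' Builds an individual physiology from a baked-in published reference organ
#' table. Organ volumes are scaled linearly so that their sum equals body
#' weight at unit density; blood flows are scaled allometrically with exponent
#' 0.75. The glomerular filtration rate is indexed to body surface area so the
#' (70 kg, 180 cm) reference has exactly 120 mL/min.
#'
#' @param weight Body weight, kg (20-250).
#' @param height Height, cm (120-220).
#' @param age Age, years (18-100).
#' @param sex `"male"` or `"female"`; sets the default hematocrit
#'   (0.45 male, 0.40 female).
#' @return An object of class `physiology`: organ table plus whole-body fields
#'   (hematocrit `hct`, `gfr` mL/min, protein binding factor `pbf`, gastric
#'   emptying time `get` min, renal and hepatic-arterial blood flow `rbf`,
#'   `habf` L/min, `cardiac_output` L/min).
#' @examples
#' ref <- build_reference_adult(70, 180, 30, "male")
#' sum(ref$organs$volume) # ~70 L
#' @export
build_reference_adult <- function(weight, height, age, sex = c("male", "female")) {
  sex <- match.arg(sex)
  .check_range(weight, 20, 250, "weight")
  .check_range(height, 120, 220, "height")
  .check_range(age, 18, 100, "age")

  organs <- .reference_organs()
  organs$volume <- organs$volume * weight / sum(organs$volume)
  fscale <- (weight / .REF_WEIGHT)^0.75
  organs$blood_flow <- organs$blood_flow * fscale

  phys <- structure(list(
    organs = organs,
    body_weight = weight,
    height = height,
    age = age,
    sex = sex,
    hct = if (sex == "male") 0.45 else 0.40,
    gfr = .REF_GFR * du_bois_bsa(weight, height) / .REF_BSA,
    pbf = 1.0,
    get = 15.0,
    rbf = organs$blood_flow[organs$name == "kidney"],
    habf = organs$blood_flow[organs$name == "liver"],
    cardiac_output = sum(organs$blood_flow, na.rm = TRUE),
    disease = "healthy"
  ), class = "physiology")
  validate_physiology(phys)
  phys
}

.check_range <- function(x, lo, hi, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a single number in [%g, %g]", field, lo, hi),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a physiology object
#'
#' Checks the structural invariants: positive organ volumes, unique organ
#' names, hematocrit in (0, 1), non-negative GFR, positive protein binding
#' factor, and that the summed tissue blood flows do not exceed cardiac output
#' by more than 5%.
#'
#' @param phys A `physiology` object.
#' @return `phys`, invisibly; errors on violation.
#' @export
validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "physiology"))
  org <- phys$organs
  if (anyDuplicated(org$name)) stop("organ names must be unique", call. = FALSE)
  if (any(org$volume <= 0)) stop("organ volumes must be positive", call. = FALSE)
  if (any(org$blood_flow < 0, na.rm = TRUE)) {
    stop("organ blood flows must be non-negative", call. = FALSE)
  }
  if (phys$hct <= 0 || phys$hct >= 1) stop("hematocrit must be in (0,1)", call. = FALSE)
  if (phys$gfr < 0) stop("GFR must be non-negative", call. = FALSE)
  if (phys$pbf <= 0) stop("protein binding factor must be positive", call. = FALSE)
  qsum <- sum(org$blood_flow[org$name != "lung"], na.rm = TRUE)
  if (qsum > phys$cardiac_output * 1.05) {
    stop("summed organ blood flows exceed cardiac output by more than 5%", call. = FALSE)
  }
  invisible(phys)
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> %s, %s\n", x$disease, x$sex))
  cat(sprintf("  weight %.1f kg, height %.0f cm, age %.2f y\n",
              x$body_weight, x$height, x$age))
  cat(sprintf("  HCT %.3f | GFR %.1f mL/min | PBF %.4f | GET %.3f min\n",
              x$hct, x$gfr, x$pbf, x$get))
  cat(sprintf("  cardiac output %.2f L/min | RBF %.3f | HABF %.3f L/min\n",
              x$cardiac_output, x$rbf, x$habf))
  cat(sprintf("  %d organs, total volume %.1f L\n",
              nrow(x$organs), sum(x$organs$volume)))
  invisible(x)
}

.assert_untransformed <- function(phys, what) {
  if (!identical(phys$disease, "healthy")) {
    stop(sprintf("%s: physiology already carries disease state '%s'",
                 what, phys$disease), call. = FALSE)
  }
}

.set_flow <- function(phys, organ, value) {
  i <- match(organ, phys$organs$name)
  if (is.na(i)) stop(sprintf("unknown organ '%s'", organ), call. = FALSE)
  phys$organs$blood_flow[i] <- value
  phys
}

#' Transform a healthy adult physiology to moderate chronic kidney disease
#'
#' Sets gastric emptying time to 20.625 min, plasma protein binding factor to
#' 0.9265 and hematocrit to 0.433; GFR is placed inside the moderate band
#' (31-60 mL/min), at the band midpoint by default. All other fields are
#' unchanged. A pure function: the input is not modified.
#'
#' @param phys A healthy adult `physiology`.
#' @param gfr GFR in mL/min, must lie in \[31, 60\]. Default 45.5 (midpoint).
#' @return A new `physiology` with `disease = "moderate_ckd"`.
#' @export
apply_moderate_ckd <- function(phys, gfr = 45.5) {
  .assert_untransformed(phys, "apply_moderate_ckd")
  .check_range(gfr, 31, 60, "gfr")
  phys$get <- 20.625
  phys$pbf <- 0.9265
  phys$hct <- 0.433
  phys$gfr <- gfr
  phys$disease <- "moderate_ckd"
  validate_physiology(phys)
}

#' Transform a healthy adult physiology to severe chronic kidney disease
#'
#' Sets gastric emptying time 24.375 min, hematocrit 0.398, plasma protein
#' binding factor 0.837, renal blood flow 0.17 L/min and hepatic arterial blood
#' flow 0.16 L/min; the kidney and hepatic-arterial organ flows are set to RBF
#' and HABF. GFR is placed inside the severe band (11-30 mL/min), at the band
#' midpoint by default.
#'
#' @inheritParams apply_moderate_ckd
#' @param gfr GFR in mL/min, must lie in \[11, 30\]. Default 20.5 (midpoint).
#' @return A new `physiology` with `disease = "severe_ckd"`.
#' @export
apply_severe_ckd <- function(phys, gfr = 20.5) {
  .assert_untransformed(phys, "apply_severe_ckd")
  .check_range(gfr, 11, 30, "gfr")
  phys$get <- 24.375
  phys$hct <- 0.398
  phys$pbf <- 0.837
  phys$rbf <- 0.17
  phys$habf <- 0.16
  phys <- .set_flow(phys, "kidney", 0.17)
  phys <- .set_flow(phys, "liver", 0.16)
  phys$gfr <- gfr
  phys$disease <- "severe_ckd"
  validate_physiology(phys)
}

#' Transform a healthy adult physiology to an obese subject
#'
#' Sets GFR to 143 mL/min per 1.73 m^2 of Du Bois body surface area
#' (i.e. `143 * BSA / 1.73` mL/min absolute). Hematocrit and the plasma
#' protein binding factor are left untouched. When `target_weight` exceeds the
#' current body weight, the excess mass is added to adipose volume so total
#' organ volume continues to match body weight at unit density; this supports
#' building an obese subject from a lean reference of the same height.
#'
#' @param phys A healthy adult `physiology`.
#' @param target_weight Final body weight in kg; default keeps the current
#'   weight.
#' @return A new `physiology` with `disease = "obese"`.
#' @export
apply_obesity <- function(phys, target_weight = NULL) {
  .assert_untransformed(phys, "apply_obesity")
  if (is.null(target_weight)) target_weight <- phys$body_weight
  if (target_weight < phys$body_weight) {
    stop("target_weight must not be below the current body weight", call. = FALSE)
  }
  extra <- target_weight - phys$body_weight
  i <- match("adipose", phys$organs$name)
  phys$organs$volume[i] <- phys$organs$volume[i] + extra
  phys$body_weight <- target_weight
  bmi <- target_weight / (phys$height / 100)^2
  if (bmi <= 30) {
    warning(sprintf("apply_obesity: BMI %.1f kg/m^2 is not in the obese range", bmi),
            call. = FALSE)
  }
  phys$gfr <- 143 * du_bois_bsa(target_weight, phys$height) / 1.73
  phys$disease <- "obese"
  validate_physiology(phys)
}

#' Transform a reference physiology to a pediatric subject
#'
#' Organ volumes are scaled by `(weight/70)^vol_exponent` (default linear);
#' the eleven organ blood flows with published pediatric reference values
#' (large intestine 0.43, heart 0.35, hepatic artery 0.53, spleen 0.29, skin
#' 0.23, small intestine 1.4, stomach 0.10, pancreas 0.08, muscle 0.88, kidney
#' 1.4, brain 1.85 L/min, given at a 70 kg equivalent) are set and then scaled
#' by `(weight/70)^flow_exponent`, as are the remaining organ flows and GFR.
#' Cardiac output is recomputed as the sum of the arterial-side flows.
#'
#' @param phys A healthy adult `physiology` (the scaling reference).
#' @param age Age in years, 2 months to 18 years.
#' @param weight Body weight in kg (3-80).
#' @param height Height in cm; estimated from an age-typical body-mass index
#'   when omitted.
#' @param vol_exponent,flow_exponent Allometric exponents for volumes (1.0)
#'   and for flows and GFR (0.75).
#' @return A new `physiology` with `disease = "pediatric"`.
#' @export
apply_pediatric <- function(phys, age, weight, height = NULL,
                            vol_exponent = 1.0, flow_exponent = 0.75) {
  .assert_untransformed(phys, "apply_pediatric")
  .check_range(age, 2 / 12, 18, "age")
  .check_range(weight, 3, 80, "weight")
  if (is.null(height)) {
    bmi <- 15 + 0.35 * age # crude age-typical BMI, cosmetic only
    height <- sqrt(weight / bmi) * 100
  }

  wfrac <- weight / .REF_WEIGHT
  fscale <- wfrac^flow_exponent

  ped_flows <- c(large_intestine = 0.43, heart = 0.35, liver = 0.53,
                 spleen = 0.29, skin = 0.23, small_intestine = 1.4,
                 stomach = 0.10, pancreas = 0.08, muscle = 0.88,
                 kidney = 1.4, brain = 1.85)

  org <- phys$organs
  org$volume <- org$volume * (weight / phys$body_weight)^vol_exponent *
    (phys$body_weight / .REF_WEIGHT)^(vol_exponent - 1) # anchor at 70 kg reference
  org$volume <- org$volume * weight / sum(org$volume)   # unit-density closure

  # flows: listed organs take the published pediatric values; the rest keep
  # their reference values; all are then allometrically down-scaled
  base_flow <- .reference_organs()$blood_flow
  names(base_flow) <- .reference_organs()$name
  for (nm in names(base_flow)) {
    if (is.na(base_flow[[nm]])) next
    v <- if (nm %in% names(ped_flows)) ped_flows[[nm]] else base_flow[[nm]]
    org$blood_flow[org$name == nm] <- v * fscale
  }

  phys$organs <- org
  phys$body_weight <- weight
  phys$height <- height
  phys$age <- age
  phys$gfr <- .REF_GFR * fscale
  phys$rbf <- org$blood_flow[org$name == "kidney"]
  phys$habf <- org$blood_flow[org$name == "liver"]
  phys$cardiac_output <- sum(org$blood_flow, na.rm = TRUE)
  phys$disease <- "pediatric"
  validate_physiology(phys)
}
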