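# Cefepime drug parameters, ionization, binding and Rodgers-Rowland
# tissue:plasma partition coefficients.

# plasma neutral-lipid / neutral-phospholipid fractions used by the
# partition equations; plasma water is treated as fully accessible (1.0)
.PLASMA_F_NL <- 0.0023
.PLASMA_F_NP <- 0.0013
.PLASMA_PH <- 7.4

#' Default cefepime drug parameters
#'
#' Physicochemistry, plasma binding and renal clearance of cefepime
#' hydrochloride: molecular weight 517 g/mol, log P 0.6914, pKa 13.2
#' (quaternary/basic center) and 4.06 (carboxylic acid), fraction unbound in
#' plasma 0.55, and a specific renal clearance of 2.1 mL/min/kg referenced to
#' the 70 kg reference adult. Cefepime is a zwitterion whose permanent cation
#' is charge-paired with the carboxylate; for tissue partitioning the
#' anionic/acid form of the Rodgers-Rowland equations is used
#' (`ionization = "acid"`), and the erythrocyte partition coefficient is taken
#' as zero so the blood:plasma ratio is `1 - hematocrit`.
#'
#' @param ... Named overrides of any field (e.g. `fu_plasma = 0.60` for
#'   sensitivity runs over the reported 51.6-99.2% binding range).
#' @return An object of class `drug_params`.
#' @examples
#' cefepime_defaults()
#' @export
cefepime_defaults <- function(...) {
  drug <- structure(list(
    name = "cefepime",
    molecular_weight = 517,
    log_p = 0.6914,
    pka_acid = 4.06,
    pka_base = 13.2,
    ionization = "acid",
    fu_plasma = 0.55,
    cl_r_specific = 2.1,   # mL/min/kg at the 70 kg reference adult
    kp_rbc = 0             # no erythrocyte partitioning (polar zwitterion)
  ), class = "drug_params")
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(drug))
    if (length(bad)) stop("unknown drug parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    drug[names(dots)] <- dots
  }
  if (drug$fu_plasma <= 0 || drug$fu_plasma > 1) {
    stop("fu_plasma must be in (0, 1]", call. = FALSE)
  }
  if (drug$molecular_weight <= 0) stop("molecular_weight must be positive", call. = FALSE)
  if (drug$cl_r_specific < 0) stop("cl_r_specific must be non-negative", call. = FALSE)
  drug
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("<drug_params> %s\n", x$name))
  cat(sprintf("  MW %.0f g/mol | logP %.4f | pKa(acid) %.2f | pKa(base) %.2f [%s form]\n",
              x$molecular_weight, x$log_p, x$pka_acid, x$pka_base, x$ionization))
  cat(sprintf("  fu %.3f | CL_R %.2f mL/min/kg (70 kg reference) | Kp,RBC %.2f\n",
              x$fu_plasma, x$cl_r_specific, x$kp_rbc))
  invisible(x)
}

#' Henderson-Hasselbalch ionized fraction
#'
#' @param pka Acid dissociation constant (pKa units).
#' @param ph Medium pH, in (0, 14).
#' @param kind `"acid"` (ionized above its pKa) or `"base"` (ionized below).
#' @return The ionized fraction in \[0, 1\]:
#'   `1/(1 + 10^(pka - ph))` for acids, `1/(1 + 10^(ph - pka))` for bases.
#' @examples
#' ionized_fraction(4.06, 7.4, "acid")
#' @export
ionized_fraction <- function(pka, ph, kind = c("acid", "base")) {
  kind <- match.arg(kind)
  if (any(ph <= 0) || any(ph >= 14)) stop("ph must be in (0, 14)", call. = FALSE)
  if (kind == "acid") 1 / (1 + 10^(pka - ph)) else 1 / (1 + 10^(ph - pka))
}

#' Unbound plasma fraction under disease scaling of binding protein
#'
#' Scales the plasma binding-protein concentration by the physiology's protein
#' binding factor (PBF): `fu' = 1 / (1 + PBF * (1 - fu) / fu)`. At PBF = 1 the
#' healthy fraction unbound is returned; PBF < 1 (reduced binding protein, as
#' in chronic kidney disease) raises the unbound fraction.
#'
#' @param drug A `drug_params` object.
#' @param phys A `physiology` object (or a bare PBF value).
#' @return Adjusted fraction unbound in (0, 1\].
#' @examples
#' fu_adjusted(cefepime_defaults(), build_reference_adult(70, 180, 30))
#' @export
fu_adjusted <- function(drug, phys) {
  pbf <- if (inherits(phys, "physiology")) phys$pbf else as.numeric(phys)
  if (pbf <= 0) stop("PBF must be positive", call. = FALSE)
  fu <- drug$fu_plasma
  1 / (1 + pbf * (1 - fu) / fu)
}

#' Tissue composition table for the partition-coefficient equations
#'
#' Reads the packaged table of per-tissue water, lipid and phospholipid
#' fractions, tissue:plasma albumin ratios and intracellular pH.
#'
#' @return A data.frame with one row per tissue composition class.
#' @export
tissue_compositions <- function() {
  path <- system.file("extdata", "tissue_composition.tsv", package = "cefepbpk")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Rodgers-Rowland tissue:plasma partition coefficients
#'
#' Computes one Kp per perfused organ from the unified distribution equations.
#' For an acid (or an anion-dominated zwitterion such as cefepime) the
#' unbound-referenced coefficient is
#' \deqn{Kpu = f_{EW} + \frac{X}{Y} f_{IW}
#'   + \frac{P f_{NL} + (0.3P + 0.7) f_{NP}}{Y}
#'   + \left(\frac{1}{fu} - 1 - \frac{P f_{NL,p} + (0.3P + 0.7) f_{NP,p}}{Y}\right) RA}
#' with \eqn{X = 1 + 10^{pH_{IW} - pKa}}, \eqn{Y = 1 + 10^{pH_p - pKa}},
#' P the octanol:water partition of the neutral species and RA the
#' tissue:plasma albumin ratio; `Kp = fu * Kpu`. Neutral compounds use
#' \eqn{X/Y = 1}, \eqn{Y = 1}.
#'
#' @param drug A `drug_params` object.
#' @param phys A `physiology` object whose organs are to be covered.
#' @param fu Fraction unbound in plasma; defaults to the disease-adjusted
#'   value [fu_adjusted()] for `phys`.
#' @param compositions Tissue-composition table; defaults to
#'   [tissue_compositions()].
#' @return Named numeric vector of Kp values, one per perfused organ.
#' @export
compute_kp_set <- function(drug, phys, fu = fu_adjusted(drug, phys),
                           compositions = tissue_compositions()) {
  if (fu <= 0 || fu > 1) stop("fu must be in (0, 1]", call. = FALSE)
  org <- phys$organs
  perfused <- org[!is.na(org$composition), , drop = FALSE]
  idx <- match(perfused$composition, compositions$tissue)
  if (anyNA(idx)) {
    stop("missing tissue composition for organ(s): ",
         paste(perfused$name[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  comp <- compositions[idx, , drop = FALSE]

  p <- 10^drug$log_p
  if (identical(drug$ionization, "neutral")) {
    y <- 1
    xy <- rep(1, nrow(comp))
  } else if (identical(drug$ionization, "acid")) {
    y <- 1 + 10^(.PLASMA_PH - drug$pka_acid)
    xy <- (1 + 10^(comp$ph_iw - drug$pka_acid)) / y
  } else {
    stop("unsupported ionization class: ", drug$ionization, call. = FALSE)
  }

  lipid_t <- (p * comp$f_nl + (0.3 * p + 0.7) * comp$f_np) / y
  lipid_p <- (p * .PLASMA_F_NL + (0.3 * p + 0.7) * .PLASMA_F_NP) / y
  kpu <- comp$f_ew + xy * comp$f_iw + lipid_t +
    (1 / fu - 1 - lipid_p) * comp$albumin_ratio
  kp <- fu * kpu
  names(kp) <- perfused$name
  if (any(!is.finite(kp)) || any(kp <= 0)) {
    stop("partition coefficients must be finite and positive", call. = FALSE)
  }
  kp
}

#' Steady-state volume of distribution from a Kp set
#'
#' `Vss = (sum(V_organ * Kp) + V_plasma) / body_weight`, plasma-referenced,
#' with `V_plasma = (1 - HCT) * blood volume` (no erythrocyte partitioning).
#'
#' @param phys A `physiology` object.
#' @param kp Named Kp vector from [compute_kp_set()].
#' @return Vss in L/kg.
#' @export
vss_l_per_kg <- function(phys, kp) {
  org <- phys$organs
  blood <- org$name %in% c("arterial_blood", "venous_blood")
  v_plasma <- sum(org$volume[blood]) * (1 - phys$hct)
  tis <- org[!blood, , drop = FALSE]
  (sum(tis$volume * kp[tis$name]) + v_plasma) / phys$body_weight
}
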