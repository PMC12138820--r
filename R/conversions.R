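# Matrix and unit conversions ------------------------------------------------

#' Molar mass of L-ergothioneine (C9H15N3O2S), g/mol
#' @export
EGT_MOLAR_MASS <- 229.30

#' Whole-blood / plasma / RBC concentration conversions
#'
#' Whole blood is the hematocrit-weighted mixture of red cells and plasma,
#' \eqn{C_{Blood} = Hct \cdot C_{RBC} + (1 - Hct) \cdot C_{Plasma}}.
#' \code{egt_blood_to_rbc} inverts this to recover the RBC concentration
#' from measured blood and plasma concentrations;
#' \code{egt_rbc_plasma_to_blood} reconstructs whole blood.  The two are
#' exact inverses.
#'
#' @param C_Blood,C_Plasma,C_RBC concentrations, uM (vectorized).
#' @param Hct hematocrit, a fraction strictly between 0 and 1.
#' @return concentration in uM.
#' @examples
#' egt_blood_to_rbc(286, 3.42, 2.29 / 5.20)    # 5 mg/day blanks -> 645 uM
#' egt_rbc_plasma_to_blood(594, 3.16, 2.29 / 5.20)
#' @export
egt_blood_to_rbc <- function(C_Blood, C_Plasma, Hct) {
  .check_hct(Hct)
  if (any(C_Blood < 0) || any(C_Plasma < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  out <- (C_Blood - C_Plasma * (1 - Hct)) / Hct
  if (any(out < 0)) {
    warning("negative RBC concentration implied; blood/plasma/Hct combination ",
            "is physically inconsistent")
  }
  out
}

#' @rdname egt_blood_to_rbc
#' @export
egt_rbc_plasma_to_blood <- function(C_RBC, C_Plasma, Hct) {
  .check_hct(Hct)
  Hct * C_RBC + (1 - Hct) * C_Plasma
}

.check_hct <- function(Hct) {
  if (any(Hct <= 0) || any(Hct >= 1)) {
    stop("Hct must lie strictly between 0 and 1", call. = FALSE)
  }
}

#' Dose and rate unit conversions
#'
#' Conversions between mass and molar units for ergothioneine using its
#' molar mass 229.30 g/mol, and between the model's hourly molar intake
#' rate and the reported daily mass intake.
#'
#' @param mg dose in milligrams.
#' @param umol amount in micromoles.
#' @param rate intake rate in umol/h.
#' @return converted quantity.
#' @examples
#' egt_dose_mg_to_umol(8)             # 34.89 umol
#' egt_rate_umol_h_to_mg_day(1.36)    # 7.48 mg/day dietary intake
#' @export
egt_dose_mg_to_umol <- function(mg) {
  if (any(mg < 0)) stop("dose must be non-negative", call. = FALSE)
  mg * 1000 / EGT_MOLAR_MASS
}

#' @rdname egt_dose_mg_to_umol
#' @export
egt_umol_to_mg <- function(umol) {
  if (any(umol < 0)) stop("amount must be non-negative", call. = FALSE)
  umol * EGT_MOLAR_MASS / 1000
}

#' @rdname egt_dose_mg_to_umol
#' @export
egt_rate_umol_h_to_mg_day <- function(rate) {
  if (any(rate < 0)) stop("rate must be non-negative", call. = FALSE)
  egt_umol_to_mg(rate * 24)
}
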