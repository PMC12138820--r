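# Steady-state initialization ------------------------------------------------

#' Initial conditions from observed blank plasma and RBC concentrations
#'
#' Computes the full model state at \code{t = 0} given measured pre-dose
#' ("blank") plasma and circulating-RBC concentrations, solving every other
#' compartment for local steady state under continuous dietary intake:
#' \itemize{
#'   \item gut lumen \code{A_g = R / k_a};
#'   \item liver extracellular (all tandem units)
#'     \code{C_he = C_p0 + R / Q_h} — the dietary throughput raises the
#'     portal stream above plasma;
#'   \item peripheral extracellular \code{C_Te = C_p0};
#'   \item every intracellular space at transport/efflux balance,
#'     \code{C_T = K_p K_m C_Te / (K_m + C_Te)};
#'   \item renal duct at the positive root of the filtration–reabsorption–
#'     urine balance
#'     \code{Q_u C_d^2 + (V_maxD + Q_u K_m - GFR C_p0) C_d - GFR C_p0 K_m = 0};
#'   \item RBC precursor \code{A_pre = v_up,P(C_p0) / k_1}.
#' }
#' Plasma and RBC are pinned to the supplied observations, so the global
#' system is not forced to an exact whole-body steady state; feeding the
#' result into [egt_rhs()] gives (numerically) zero derivatives for every
#' compartment except plasma and circulating RBC.
#'
#' @param C_p0 blank plasma concentration, uM (> 0).
#' @param C_RBC0 blank RBC concentration, uM (>= 0).
#' @param params an \code{egt_parameters} object.
#' @param derived derived transport parameters (recomputed by default).
#' @return an object of class \code{egt_init}: the named state vector with
#'   attribute \code{fixed} naming the pinned entries.
#' @examples
#' y0 <- egt_initialize(3.16, 594, egt_parameters())
#' y0[["C_d"]]    # 5.03 uM duct concentration
#' @export
egt_initialize <- function(C_p0, C_RBC0, params, derived = egt_derive(params)) {
  stopifnot(inherits(params, "egt_parameters"))
  if (!is.numeric(C_p0) || length(C_p0) != 1L || C_p0 <= 0) {
    stop("C_p0 must be a single positive concentration", call. = FALSE)
  }
  if (!is.numeric(C_RBC0) || length(C_RBC0) != 1L || C_RBC0 < 0) {
    stop("C_RBC0 must be a single non-negative concentration", call. = FALSE)
  }
  p <- params
  n <- as.integer(p$n_liver_units)

  A_g  <- p$R / p$k_a
  C_he <- rep(C_p0 + p$R / p$Q_h, n)
  part <- function(Kp, Ce) Kp * p$K_m * Ce / (p$K_m + Ce)
  C_h  <- part(p$K_pH, C_he)
  C_ae <- C_p0; C_a <- part(p$K_pA, C_ae)
  C_se <- C_p0; C_s <- part(p$K_pS, C_se)
  C_me <- C_p0; C_m <- part(p$K_pM, C_me)
  C_d  <- egt_duct_root(C_p0, p)
  A_pre <- egt_mm_flux(p$V_maxP, p$K_m, C_p0) / p$k_1

  state <- stats::setNames(
    c(A_g, C_he, C_h, C_ae, C_a, C_se, C_s, C_me, C_m,
      C_d, A_pre, C_RBC0, C_p0, 0),
    egt_state_names(params))
  structure(state, fixed = c("C_p", "C_RBC"), class = "egt_init")
}

# positive root of the duct filtration/reabsorption/urine balance
# GFR*C_p = V_maxD*C_d/(K_m + C_d) + Q_u*C_d
egt_duct_root <- function(C_p0, params) {
  a <- params$Q_u
  b <- params$V_maxD + params$Q_u * params$K_m - params$GFR * C_p0
  cc <- -params$GFR * C_p0 * params$K_m
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no real duct steady state (should be impossible)", call. = FALSE)
  root <- (-b + sqrt(disc)) / (2 * a)
  if (root <= 0) stop("no positive duct steady state", call. = FALSE)
  root
}

#' @export
print.egt_init <- function(x, ...) {
  cat("PBPK initial condition (pinned:", paste(attr(x, "fixed"), collapse = ", "), ")\n")
  print(signif(unclass(x), 4))
  invisible(x)
}
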