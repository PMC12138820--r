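# Mass-balance right-hand side -----------------------------------------------

#' Michaelis-Menten transport flux
#'
#' Saturable carrier-mediated flux \eqn{v = V_{max} C / (K_m + C)}; monotone
#' non-decreasing in \code{C} and bounded above by \code{V_max}.
#'
#' @param V_max maximal transport rate, umol/h (> 0).
#' @param K_m Michaelis constant, uM (> 0).
#' @param C substrate concentration, uM (>= 0); vectorized.
#' @return flux in umol/h.
#' @examples
#' egt_mm_flux(11.1, 21.0, 3.16)   # baseline RBC-precursor uptake, 1.4518
#' egt_mm_flux(10, 5, 5)           # half saturation: V_max/2
#' @export
egt_mm_flux <- function(V_max, K_m, C) {
  if (any(V_max <= 0) || any(K_m <= 0)) {
    stop("V_max and K_m must be strictly positive", call. = FALSE)
  }
  if (any(C < 0)) stop("substrate concentration must be non-negative", call. = FALSE)
  V_max * C / (K_m + C)
}

# names of the state vector, in the layout shared with the compiled code
egt_state_names <- function(params) {
  n <- as.integer(params$n_liver_units)
  c("A_g",
    paste0("C_he", seq_len(n)), paste0("C_h", seq_len(n)),
    "C_ae", "C_a", "C_se", "C_s", "C_me", "C_m",
    "C_d", "A_pre", "C_RBC", "C_p", "A_u")
}

# compartment "volumes" used to convert the state to amounts; entries of 1
# are already amounts (A_g, A_pre, A_u)
egt_state_volumes <- function(params) {
  n <- as.integer(params$n_liver_units)
  stats::setNames(
    c(1, rep(params$V_he / n, n), rep(params$V_h / n, n),
      params$V_ae, params$V_a, params$V_se, params$V_s, params$V_me, params$V_m,
      params$V_d, 1, params$V_RBC, params$V_p, 1),
    egt_state_names(params))
}

# pack parameters (+ derived transport constants) into the fixed-order
# numeric vector consumed by the compiled derivative function
.egt_pack_parms <- function(params, derived = egt_derive(params)) {
  c(params$R, params$k_a, params$V_p, params$V_RBC,
    params$V_a, params$V_ae, params$V_h, params$V_he,
    params$V_s, params$V_se, params$V_m, params$V_me, params$V_d,
    params$Q_a, params$Q_h, params$Q_s, params$Q_m, params$Q_u, params$GFR,
    params$k_1, params$k_b,
    params$V_maxH, params$V_maxD, params$V_maxP, params$K_m,
    as.numeric(params$n_liver_units),
    derived$V_max[["adipose"]], derived$V_max[["skin"]], derived$V_max[["muscle"]],
    derived$PS_eff[["liver"]], derived$PS_eff[["adipose"]],
    derived$PS_eff[["skin"]], derived$PS_eff[["muscle"]],
    as.numeric(params$absorption_route == "portal"))
}

#' Time derivatives of the PBPK state (reference implementation)
#'
#' Pure-R mass balance of the 21-compartment system plus a cumulative
#' urinary-excretion bookkeeping state.  The production integration path
#' uses the compiled equivalent; this function is the transparent reference
#' used for inspection, property tests and the fixed-step oracle.  Its
#' signature is the one \pkg{deSolve} expects.
#'
#' Structure: dietary intake \code{R} enters the gut lumen continuously;
#' absorbed gut flux \code{k_a * A_g} enters the first liver extracellular
#' sub-unit (portal route, configurable); plasma perfuses the tandem liver
#' in series and each peripheral tissue in parallel; every cellular uptake
#' is Michaelis-Menten in the local extracellular concentration with efflux
#' clearance \code{PS_eff} back out; plasma is filtered into the renal duct
#' at GFR with saturable reabsorption (\code{V_maxD}) and urinary loss
#' \code{Q_u * C_d} — the only elimination route; the RBC precursor pool
#' takes EGT up from plasma (\code{V_maxP}), matures into circulating RBC at
#' rate \code{k_1}, and RBC turnover (\code{k_b}) returns EGT to plasma.
#'
#' @param t time, h (unused; the system is autonomous).
#' @param state named numeric state vector in the layout of
#'   [egt_initialize()].
#' @param params an \code{egt_parameters} object.
#' @param derived derived transport parameters; recomputed from
#'   \code{params} by default.
#' @return a list whose first element is the derivative vector.
#' @export
egt_rhs <- function(t, state, params, derived = egt_derive(params)) {
  if (any(!is.finite(state))) {
    bad <- egt_state_names(params)[!is.finite(state)]
    stop("non-finite state in compartment(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- params
  n <- as.integer(p$n_liver_units)
  A_g  <- state[[1]]
  C_he <- state[1 + seq_len(n)]
  C_h  <- state[1 + n + seq_len(n)]
  o <- 1 + 2 * n
  C_ae <- state[[o + 1]]; C_a <- state[[o + 2]]
  C_se <- state[[o + 3]]; C_s <- state[[o + 4]]
  C_me <- state[[o + 5]]; C_m <- state[[o + 6]]
  C_d  <- state[[o + 7]]
  A_pre <- state[[o + 8]]
  C_RBC <- state[[o + 9]]
  C_p   <- state[[o + 10]]

  mm <- function(vmax, c) vmax * c / (p$K_m + c)
  absflux <- p$k_a * A_g
  portal <- identical(p$absorption_route, "portal")

  dA_g <- p$R - absflux

  up_h   <- mm(p$V_maxH / n, C_he)
  inflow <- c(C_p, C_he[-n])
  influx <- c(if (portal) absflux else 0, rep(0, n - 1))
  dC_he <- (p$Q_h * (inflow - C_he) + influx - up_h + (derived$PS_eff[["liver"]] / n) * C_h) /
    (p$V_he / n)
  dC_h <- (up_h - (derived$PS_eff[["liver"]] / n) * C_h) / (p$V_h / n)

  up_a <- mm(derived$V_max[["adipose"]], C_ae)
  up_s <- mm(derived$V_max[["skin"]], C_se)
  up_m <- mm(derived$V_max[["muscle"]], C_me)
  dC_ae <- (p$Q_a * (C_p - C_ae) - up_a + derived$PS_eff[["adipose"]] * C_a) / p$V_ae
  dC_a  <- (up_a - derived$PS_eff[["adipose"]] * C_a) / p$V_a
  dC_se <- (p$Q_s * (C_p - C_se) - up_s + derived$PS_eff[["skin"]] * C_s) / p$V_se
  dC_s  <- (up_s - derived$PS_eff[["skin"]] * C_s) / p$V_s
  dC_me <- (p$Q_m * (C_p - C_me) - up_m + derived$PS_eff[["muscle"]] * C_m) / p$V_me
  dC_m  <- (up_m - derived$PS_eff[["muscle"]] * C_m) / p$V_m

  up_d <- mm(p$V_maxD, C_d)
  up_p <- mm(p$V_maxP, C_p)
  dC_d   <- (p$GFR * C_p - up_d - p$Q_u * C_d) / p$V_d
  dA_pre <- up_p - p$k_1 * A_pre
  dC_RBC <- (p$k_1 * A_pre - p$k_b * p$V_RBC * C_RBC) / p$V_RBC
  dC_p <- (p$Q_h * (C_he[n] - C_p) +
             p$Q_a * (C_ae - C_p) + p$Q_s * (C_se - C_p) + p$Q_m * (C_me - C_p) -
             p$GFR * C_p + up_d - up_p + p$k_b * p$V_RBC * C_RBC +
             if (portal) 0 else absflux) / p$V_p
  dA_u <- p$Q_u * C_d

  list(stats::setNames(
    c(dA_g, dC_he, dC_h, dC_ae, dC_a, dC_se, dC_s, dC_me, dC_m,
      dC_d, dA_pre, dC_RBC, dC_p, dA_u),
    egt_state_names(params)))
}

#' Total amount of ergothioneine in the body
#'
#' Sums amounts over all model compartments (gut, tissue sub-compartments,
#' duct, RBC precursor, circulating RBC, plasma), excluding the cumulative
#' urine bookkeeping state.  Used by the mass-conservation checks: along
#' any trajectory the body total changes only by dietary/bolus input minus
#' urinary output.
#'
#' @param state state vector or matrix of states (rows = time points) in the
#'   layout of [egt_initialize()].
#' @param params an \code{egt_parameters} object.
#' @return total amount, umol (vector if \code{state} is a matrix).
#' @export
egt_total_amount <- function(state, params) {
  vols <- egt_state_volumes(params)
  body <- setdiff(names(vols), "A_u")
  if (is.matrix(state)) {
    as.numeric(state[, body, drop = FALSE] %*% vols[body])
  } else {
    sum(state[body] * vols[body])
  }
}
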