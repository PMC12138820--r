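# Model parameterization -----------------------------------------------------

# canonical parameter symbols and their fixed 70-kg adult defaults
.egt_defaults <- list(
  R       = 1.36,     # dietary EGT ingestion rate, umol/h (optimized value)
  k_a     = 6.00,     # absorption rate constant (gastric emptying), /h
  V_p     = 3.00,     # plasma volume, L
  V_RBC   = 2.29,     # red-blood-cell volume, L
  V_a     = 10.0,     # adipose intracellular volume, L
  V_ae    = 2.00,     # adipose extracellular volume, L
  V_h     = 1.69,     # liver intracellular volume, L
  V_he    = 0.338,    # liver extracellular volume, L
  V_s     = 7.8,      # skin intracellular volume, L
  V_se    = 1.56,     # skin extracellular volume, L
  V_m     = 35.0,     # muscle intracellular volume, L
  V_me    = 7.00,     # muscle extracellular volume, L
  V_d     = 0.127,    # renal proximal tubular duct volume, L
  Q_a     = 8.74,     # adipose plasma flow, L/h
  Q_h     = 48.7,     # liver plasma flow, L/h
  Q_s     = 18.0,     # skin plasma flow, L/h
  Q_m     = 45.0,     # muscle plasma flow, L/h
  Q_u     = 0.0583,   # urinary flow, L/h
  GFR     = 7.50,     # glomerular filtration rate, L/h
  k_1     = 0.0104,   # RBC-precursor differentiation rate, /h
  k_b     = 0.000963, # RBC degradation rate, /h
  V_maxH  = 10227,    # hepatic uptake maximum, umol/h (= 10 * Q_h * K_m)
  V_maxD  = 121,      # renal-duct reabsorption maximum, umol/h (optimized)
  V_maxP  = 11.1,     # RBC-precursor uptake maximum, umol/h (optimized)
  K_m     = 21.0,     # OCTN1 Michaelis constant, uM
  K_pH    = 80.1,     # liver-to-plasma concentration ratio
  K_pM    = 5.06,     # muscle-to-plasma concentration ratio
  K_pA    = 17.5,     # adipose-to-plasma concentration ratio
  K_pS    = 20.8,     # skin-to-plasma concentration ratio
  e_H     = 0.147,    # relative OCTN1 mRNA expression, liver (per gram)
  e_M     = 0.464,    # muscle
  e_A     = 0.209,    # adipose
  e_S     = 0.131,    # skin
  Hct     = 2.29 / 5.20,  # hematocrit = RBC volume / blood volume
  n_liver_units = 5L,     # tandem liver sub-units
  absorption_route = "portal"  # absorbed flux enters liver unit 1 ("plasma" alternative)
)

.egt_numeric_parms <- setdiff(names(.egt_defaults),
                              c("n_liver_units", "absorption_route"))

#' Model parameters for the ergothioneine PBPK model
#'
#' Constructs a validated parameter set for the whole-body ergothioneine
#' (EGT) model.  Defaults are the fixed 70-kg adult physiology (organ
#' volumes and plasma flows, renal filtration and urine flow, RBC turnover
#' rates), the OCTN1 Michaelis constant \eqn{K_m = 21} uM, the murine
#' tissue-to-plasma partition ratios \eqn{K_p}, per-gram OCTN1 mRNA
#' expression weights used to scale tissue transport maxima, and the
#' calibrated triple (dietary intake rate \code{R}, renal reabsorption
#' maximum \code{V_maxD}, erythroid precursor uptake maximum
#' \code{V_maxP}).  The hepatic maximum \code{V_maxH} is anchored to
#' flow-limited uptake: \code{V_maxH / K_m = 10 * Q_h}.
#'
#' @param ... named parameter overrides.  Unknown names are an error.
#' @return an object of class \code{egt_parameters}: a named list with all
#'   model symbols.
#' @examples
#' p <- egt_parameters()
#' p$V_maxH / p$K_m / p$Q_h   # flow-limited anchor: 10
#' egt_parameters(R = 2.0)$R
#' @export
egt_parameters <- function(...) {
  override <- list(...)
  if (length(override) == 1L && is.list(override[[1]]) && is.null(names(override))) {
    override <- override[[1]]
  }
  unknown <- setdiff(names(override), names(.egt_defaults))
  if (length(unknown)) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- utils::modifyList(.egt_defaults, override)
  validate_egt_parameters(p)
  structure(p, class = "egt_parameters")
}

validate_egt_parameters <- function(p) {
  for (nm in .egt_numeric_parms) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  # R may be zero (no dietary intake); everything else strictly positive
  pos <- setdiff(.egt_numeric_parms, c("Hct", "R"))
  if (p$R < 0) stop("R must be non-negative", call. = FALSE)
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad)) {
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (p$Hct <= 0 || p$Hct >= 1) {
    stop("Hct must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- p$n_liver_units
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("n_liver_units must be a positive integer", call. = FALSE)
  }
  if (!p$absorption_route %in% c("portal", "plasma")) {
    stop("absorption_route must be 'portal' or 'plasma'", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.egt_parameters <- function(x, ...) {
  cat("Ergothioneine PBPK model parameters (70-kg adult)\n")
  cat(sprintf("  dietary intake R        : %.4g umol/h (%.3g mg/day)\n",
              x$R, egt_rate_umol_h_to_mg_day(x$R)))
  cat(sprintf("  transport: V_maxH %.5g, V_maxD %.4g, V_maxP %.4g umol/h; K_m %.3g uM\n",
              x$V_maxH, x$V_maxD, x$V_maxP, x$K_m))
  cat(sprintf("  hematocrit %.4f; %d tandem liver units; absorption -> %s\n",
              x$Hct, as.integer(x$n_liver_units), x$absorption_route))
  cat(sprintf("  K_p (liver/muscle/adipose/skin): %.3g / %.3g / %.3g / %.3g\n",
              x$K_pH, x$K_pM, x$K_pA, x$K_pS))
  invisible(x)
}

#' Derived transport parameters
#'
#' Scales the peripheral-tissue transport maxima from the hepatic anchor
#' using per-gram OCTN1 mRNA expression and organ mass (intracellular
#' volume at unit density as mass proxy),
#' \deqn{V_{max,T} = V_{maxH} \frac{e_T W_T}{e_H W_H},}
#' and fixes each tissue's intrinsic efflux clearance from the
#' steady-state, linear-condition partitioning identity
#' \deqn{PS_{eff,T} = \frac{V_{max,T}/K_m}{K_{p,T}}.}
#'
#' @param params an \code{egt_parameters} object.
#' @return an object of class \code{egt_derived}: a list with named vectors
#'   \code{V_max} and \code{PS_eff} over tissues
#'   \code{c("liver","adipose","skin","muscle")}.
#' @examples
#' d <- egt_derive(egt_parameters())
#' d$PS_eff[["liver"]]    # (10227/21)/80.1 = 6.079 L/h
#' @export
egt_derive <- function(params) {
  stopifnot(inherits(params, "egt_parameters"))
  p <- params
  e  <- c(liver = p$e_H, adipose = p$e_A, skin = p$e_S, muscle = p$e_M)
  W  <- c(liver = p$V_h, adipose = p$V_a, skin = p$V_s, muscle = p$V_m)
  Kp <- c(liver = p$K_pH, adipose = p$K_pA, skin = p$K_pS, muscle = p$K_pM)
  if (any(e <= 0) || any(Kp <= 0)) {
    stop("expression weights and partition ratios must be positive", call. = FALSE)
  }
  V_max <- p$V_maxH * (e * W) / (e[["liver"]] * W[["liver"]])
  PS_eff <- (V_max / p$K_m) / Kp
  structure(list(V_max = V_max, PS_eff = PS_eff), class = "egt_derived")
}

#' @export
print.egt_derived <- function(x, ...) {
  cat("Derived transport parameters\n")
  m <- rbind(`V_max (umol/h)` = x$V_max, `PS_eff (L/h)` = x$PS_eff)
  print(signif(m, 4))
  invisible(x)
}

# Parameter configuration files ----------------------------------------------

#' Read and write parameter configuration files
#'
#' Parameter sets are stored as flat YAML or JSON maps keyed by the model
#' symbols (see [egt_parameters()]); the format is chosen by file
#' extension.  Unknown keys are rejected.  A fixture with all defaults is
#' shipped at \code{system.file("extdata", "params_default.yaml",
#' package = "egtpbpk")}.
#'
#' @param path file path ending in \code{.yaml}, \code{.yml} or \code{.json}.
#' @param params an \code{egt_parameters} object (for writing).
#' @return \code{egt_read_params} returns an \code{egt_parameters} object.
#' @export
egt_read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter file extension: .", ext, call. = FALSE))
  do.call(egt_parameters, raw)
}

#' @rdname egt_read_params
#' @export
egt_write_params <- function(params, path) {
  stopifnot(inherits(params, "egt_parameters"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  x$n_liver_units <- as.integer(x$n_liver_units)
  switch(ext,
    yaml = ,
    yml  = yaml::write_yaml(x, path, precision = 15),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported parameter file extension: .", ext, call. = FALSE))
  invisible(path)
}
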