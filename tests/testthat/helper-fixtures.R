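# shared fixtures: default parameterization and the repeated-dose study layout

test_params <- function(...) egt_parameters(...)

# dose arms with their blank-derived initial values: two arms from the
# two-arm 8-week study plus the historical 4-week 20 mg/day arm
study_arms <- function() {
  data.frame(dose_mg_per_day = c(5, 10, 20),
             C_p0 = c(3.42, 3.51, 2.97),
             C_RBC0 = c(624, 562, 594))
}

study_days <- function(dose) {
  if (dose == 20) c(0, 7, 14, 21, 28) else c(0, 8, 14, 21, 28, 56)
}

# noise-free arm-mean profiles generated by the model itself at the supplied
# parameters (self-consistency input for the calibration tests)
noise_free_means <- function(params, arms = study_arms(), ...) {
  do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    days <- study_days(arms$dose_mg_per_day[i])
    init <- egt_initialize(arms$C_p0[i], arms$C_RBC0[i], params)
    sim <- egt_simulate(egt_regimen(arms$dose_mg_per_day[i],
                                    weeks = max(days) / 7),
                        init, params, output_times = days * 24, ...)
    d <- as.data.frame(sim[sim$matrix %in% c("plasma", "rbc"), ])
    data.frame(dose_mg_per_day = arms$dose_mg_per_day[i],
               time_h = d$time_h, matrix = d$matrix,
               mean_concentration_uM = d$concentration_uM)
  }))
}

# random plausible model states for derivative-level property tests
random_states <- function(params, n, seed = 1) {
  set.seed(seed)
  nm <- egtpbpk:::egt_state_names(params)
  lapply(seq_len(n), function(i) {
    stats::setNames(stats::rlnorm(length(nm), meanlog = log(c(
      0.2,                       # A_g
      rep(3, 2 * params$n_liver_units),  # liver (scaled up below for intracellular)
      3, 50, 3, 60, 3, 15,       # tissue extra/intracellular
      5, 140, 590, 3.2, 1        # duct, precursor, RBC, plasma, urine
    )), sdlog = 0.5), nm)
  })
}
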