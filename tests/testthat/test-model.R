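test_that("Michaelis-Menten flux obeys its defining identities", {
  expect_identical(egt_mm_flux(11.1, 21, 0), 0)
  expect_equal(egt_mm_flux(10, 5, 5), 5)          # half saturation
  expect_equal(egt_mm_flux(11.1, 21.0, 3.16), 11.1 * 3.16 / (21 + 3.16),
               tolerance = 1e-12)                  # baseline precursor uptake 1.4518
  cs <- seq(0, 500, by = 7)
  v <- egt_mm_flux(11.1, 21, cs)
  expect_true(all(diff(v) > 0))                    # strictly increasing
  expect_true(all(v <= 11.1))                      # bounded by V_max
  expect_error(egt_mm_flux(11.1, 21, -1), "non-negative")
  expect_error(egt_mm_flux(-1, 21, 1), "strictly positive")
})

test_that("empty system with no intake has identically zero derivatives", {
  p <- test_params(R = 0)
  y <- stats::setNames(numeric(22), egtpbpk:::egt_state_names(p))
  expect_equal(unlist(egt_rhs(0, y, p)), stats::setNames(numeric(22), names(y)))
})

test_that("mass balance closes: body gain equals intake minus urinary loss at any state", {
  p <- test_params()
  vols <- egtpbpk:::egt_state_volumes(p)
  body <- setdiff(names(vols), "A_u")
  for (y in random_states(p, 25, seed = 42)) {
    dy <- unlist(egt_rhs(0, y, p))
    net <- sum(dy[body] * vols[body])
    # only dietary input and urine cross the system boundary
    expect_equal(net, p$R - p$Q_u * y[["C_d"]], tolerance = 1e-9)
    # the urine bookkeeping state closes the balance exactly
    expect_equal(net + dy[["A_u"]], p$R, tolerance = 1e-9)
  }
})

test_that("compiled derivative agrees with the R reference pointwise", {
  p <- test_params()
  pv <- egtpbpk:::.egt_pack_parms(p)
  for (y in random_states(p, 20, seed = 7)) {
    d_c <- deSolve::DLLfunc(func = "egt_derivs", dllname = "egtpbpk",
                            initfunc = "egt_initparms",
                            times = 0, y = y, parms = pv)$dy
    d_r <- unlist(egt_rhs(0, y, p))
    expect_equal(unname(d_c), unname(d_r), tolerance = 1e-12)
  }
  # and with absorbed flux routed to plasma instead of the portal stream
  p2 <- test_params(absorption_route = "plasma")
  pv2 <- egtpbpk:::.egt_pack_parms(p2)
  y <- random_states(p2, 1, seed = 9)[[1]]
  d_c <- deSolve::DLLfunc(func = "egt_derivs", dllname = "egtpbpk",
                          initfunc = "egt_initparms",
                          times = 0, y = y, parms = pv2)$dy
  expect_equal(unname(d_c), unname(unlist(egt_rhs(0, y, p2))), tolerance = 1e-12)
})

test_that("non-finite states are rejected with the compartment named", {
  p <- test_params()
  y <- random_states(p, 1)[[1]]
  y[["C_p"]] <- NaN
  expect_error(egt_rhs(0, y, p), "C_p")
})

test_that("transporter fluxes stay below their maxima along a dosed trajectory", {
  p <- test_params()
  d <- egt_derive(p)
  sim <- egt_simulate(egt_regimen(20, weeks = 1), egt_initialize(3.16, 594, p), p,
                      output_times = seq(0, 168, by = 2), keep_state = TRUE)
  st <- attr(sim, "state")
  expect_true(all(st[, -1] >= -1e-10))     # non-negative trajectory
  n <- p$n_liver_units
  for (j in seq_len(n)) {
    expect_true(all(egt_mm_flux(p$V_maxH / n, p$K_m, st[, paste0("C_he", j)]) <=
                      p$V_maxH / n))
  }
  expect_true(all(egt_mm_flux(d$V_max[["muscle"]], p$K_m, st[, "C_me"]) <=
                    d$V_max[["muscle"]]))
  expect_true(all(egt_mm_flux(p$V_maxD, p$K_m, st[, "C_d"]) <= p$V_maxD))
  expect_true(all(egt_mm_flux(p$V_maxP, p$K_m, st[, "C_p"]) <= p$V_maxP))
})
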