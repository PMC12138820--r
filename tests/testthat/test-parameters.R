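test_that("default parameterization satisfies its structural identities", {
  p <- test_params()
  # extracellular space is 20% of intracellular space in each tissue
  expect_equal(p$V_ae, 0.2 * p$V_a)
  expect_equal(p$V_he, 0.2 * p$V_h)
  expect_equal(p$V_se, 0.2 * p$V_s)
  expect_equal(p$V_me, 0.2 * p$V_m)
  # flow-limited hepatic anchor: uptake clearance is ten times liver plasma flow
  expect_equal(p$V_maxH, 10 * p$Q_h * p$K_m)
  expect_true(p$Hct > 0 && p$Hct < 1)
  expect_equal(p$Hct, p$V_RBC / 5.20)
})

test_that("parameter validation rejects malformed input", {
  expect_error(egt_parameters(bogus = 1), "unknown parameter")
  expect_error(egt_parameters(V_p = -1), "strictly positive")
  expect_error(egt_parameters(K_m = 0), "strictly positive")
  expect_error(egt_parameters(Hct = 1.2), "between 0 and 1")
  expect_error(egt_parameters(R = -0.1), "non-negative")
  expect_error(egt_parameters(n_liver_units = 2.5), "positive integer")
  expect_error(egt_parameters(absorption_route = "lymph"), "portal")
  # zero dietary intake is a legitimate degenerate configuration
  expect_silent(p0 <- egt_parameters(R = 0))
  expect_identical(p0$R, 0)
})

test_that("derived transport parameters match hand arithmetic", {
  p <- test_params()
  d <- egt_derive(p)
  # liver efflux clearance from the partitioning identity
  expect_equal(d$PS_eff[["liver"]], (10227 / 21) / 80.1, tolerance = 1e-12)
  # muscle maximum from expression-weight/organ-mass scaling
  expect_equal(d$V_max[["muscle"]], 10227 * (0.464 * 35.0) / (0.147 * 1.69),
               tolerance = 1e-12)
  expect_equal(d$V_max[["liver"]], p$V_maxH)
  # remaining tissues, same rules
  expect_equal(unname(d$V_max[c("adipose", "skin")]),
               10227 * c(0.209 * 10.0, 0.131 * 7.8) / (0.147 * 1.69),
               tolerance = 1e-12)
  expect_equal(unname(d$PS_eff), unname((d$V_max / 21) / c(80.1, 17.5, 20.8, 5.06)),
               tolerance = 1e-12)
})

test_that("equal expression and equal mass collapse all tissue maxima to the liver value", {
  p <- egt_parameters(e_H = 0.2, e_M = 0.2, e_A = 0.2, e_S = 0.2,
                      V_a = 1.69, V_ae = 0.338, V_s = 1.69, V_se = 0.338,
                      V_m = 1.69, V_me = 0.338)
  d <- egt_derive(p)
  expect_equal(unname(d$V_max), rep(p$V_maxH, 4))
})

test_that("parameter configs round-trip through YAML and JSON and reject unknown keys", {
  p <- egt_parameters(R = 1.5, V_maxD = 100)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    egt_write_params(p, f)
    q <- egt_read_params(f)
    expect_equal(unclass(q)[.egt_num <- names(q) != "absorption_route"],
                 unclass(p)[.egt_num], tolerance = 1e-12)
    expect_identical(q$absorption_route, p$absorption_route)
    unlink(f)
  }
  f <- tempfile(fileext = ".yaml")
  writeLines(c("R: 1.0", "not_a_parameter: 3"), f)
  expect_error(egt_read_params(f), "unknown parameter")
  unlink(f)
})

test_that("shipped default config reproduces the built-in defaults", {
  f <- system.file("extdata", "params_default.yaml", package = "egtpbpk")
  expect_true(nzchar(f))
  q <- egt_read_params(f)
  p <- egt_parameters()
  for (nm in names(unclass(p))) expect_equal(q[[nm]], p[[nm]], tolerance = 1e-12)
})
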