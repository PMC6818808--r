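test_that("internodal time constant is k1*k2 and independent of geometry", {
  pc <- physical_constants()
  for (d in c(0.5, 1, 4)) {
    for (g in c(0.3, 0.6, 0.85)) {
      cab <- derive_cable_parameters(axon_geometry(d = d, g = g), pc)
      expect_equal(cab$tau, 0.468, tolerance = 1e-12)   # = 3.6 pF/cm * 130 MOhm cm
      expect_equal(cab$tau, cab$C_m * cab$R_m)
    }
  }
})

test_that("length constant matches its closed form and scales with d and g", {
  pc <- physical_constants()
  # coefficient sqrt(k2 * pi / (4 rho_ax)) in um per (um diameter)
  coef <- sqrt(130e6 * pi / (4 * 110))
  cab <- derive_cable_parameters(axon_geometry(d = 1, g = 0.6), pc)
  expect_equal(cab$lam, coef * sqrt(log(1 / 0.6)), tolerance = 1e-10)
  expect_equal(cab$lam, 688.7, tolerance = 1e-3)
  # linear in d at fixed g
  cab2 <- derive_cable_parameters(axon_geometry(d = 3, g = 0.6), pc)
  expect_equal(cab2$lam, 3 * cab$lam, tolerance = 1e-12)
  # monotone decreasing in g
  lams <- vapply(seq(0.1, 0.9, by = 0.1), function(g)
    derive_cable_parameters(axon_geometry(d = 1, g = g), pc)$lam, numeric(1))
  expect_true(all(diff(lams) < 0))
})

test_that("implied medium constants match the published values", {
  med <- derive_medium_constants(physical_constants())
  expect_equal(med[["permittivity"]], 5.7e-11, tolerance = 0.01)
  expect_equal(med[["resistivity"]], 8.16e6, tolerance = 0.01)
  med2 <- derive_medium_constants(physical_constants(k1_pF_per_cm = 7.2))
  expect_equal(med2[["permittivity"]], 2 * med[["permittivity"]])
})

test_that("nodal parameters: time constant, patch resistance, beta limits", {
  pc <- physical_constants()
  geo <- axon_geometry(d = 1, g = 0.6, l = 1)
  cab <- derive_cable_parameters(geo, pc)
  nd <- derive_node_parameters(geo, pc, cab)
  expect_equal(nd$tau_node, 0.033, tolerance = 1e-12)     # 33 us
  expect_equal(nd$R_node, 33e-6 * 1e8 / pi, tolerance = 1e-12)  # ~1.05e3 MOhm
  expect_equal(nd$lam_node, 38.9)
  # derived (first-principles) nodal length constant ~ 27.4 um at d = 1
  nd_der <- derive_node_parameters(geo, pc, cab, lam_node_method = "derived")
  expect_equal(nd_der$lam_node, sqrt(33e2 / (4 * 1.1)), tolerance = 1e-12)
  # a vanishing node has nowhere to leak: beta -> 1; a very long node leaks
  # almost everything back across its membrane: beta -> 0 (Eq for the
  # current division against R_node = R_n/(pi d l))
  beta_of_l <- function(l) {
    g2 <- axon_geometry(d = 1, g = 0.6, l = l)
    derive_node_parameters(g2, pc, cab)$beta
  }
  expect_lt(beta_of_l(1e4), 1e-3)
  expect_gt(beta_of_l(1e-4), 0.999)
  ls <- c(0.25, 0.5, 1, 2, 4, 8)
  betas <- vapply(ls, beta_of_l, numeric(1))
  expect_true(all(diff(betas) < 0))
  expect_true(all(betas > 0 & betas < 1))
})

test_that("cable current saturates with node length while channel current is linear", {
  pc <- physical_constants()
  cab <- derive_cable_parameters(axon_geometry(1, 0.6), pc)
  ls <- seq(0.25, 6, by = 0.25)
  chan <- pi * 1 * ls * pc$i_Na
  cable_cur <- vapply(seq_along(ls), function(i) {
    nd <- derive_node_parameters(axon_geometry(1, 0.6, l = ls[i]), pc, cab)
    chan[i] * nd$beta
  }, numeric(1))
  # channel current exactly linear
  expect_equal(diff(chan, differences = 2), rep(0, length(ls) - 2))
  # cable current concave (saturating)
  expect_true(all(diff(cable_cur, differences = 2) <= 1e-12))
})

test_that("unit conversion round-trips are identities", {
  u <- sds_units()
  vals <- c(3.6, 130, 110, 33, 1, 50, 3.75)
  for (i in seq_along(u)) {
    expect_equal(vals[[1]] * u[[i]] / u[[i]], vals[[1]])
  }
  pc <- physical_constants()
  expect_equal(pc$k1 / u[["pF_per_cm"]], 3.6)
  expect_equal(pc$k2 / u[["MOhm_cm"]], 130)
  expect_equal(pc$rho_ax / u[["Ohm_cm"]], 110)
  expect_equal(pc$R_n / u[["Ohm_cm2"]], 33)
  expect_equal(pc$C_n / u[["uF_per_cm2"]], 1)
})

test_that("packaged parameter columns reproduce the published sets", {
  u <- sds_units()
  ps <- std_params()
  expect_equal(ps$geometry$d, 1)
  expect_equal(ps$geometry$g, 0.6)
  expect_equal(ps$geometry$L, 100)
  expect_equal(ps$geometry$l, 1)
  expect_equal(ps$V_thr, 15)
  expect_equal(ps$current$I0 / u[["pA_per_um2"]], 50)
  expect_equal(ps$current$tau_m / u[["us"]], 20)
  expect_equal(ps$current$tau_h / u[["us"]], 40)
  # derivable standard values agree with the printed ones to 0.5%
  expect_equal(ps$cable$tau, 0.47, tolerance = 0.005)
  expect_equal(ps$cable$lam / (1 * sqrt(log(1 / 0.6))), 965, tolerance = 0.005)

  pf <- fit_params()
  expect_equal(pf$geometry$d, 0.73)
  expect_equal(pf$geometry$g, 0.81)
  expect_equal(pf$geometry$L, 73)
  expect_equal(pf$cable$tau, 1.45)
  expect_equal(pf$cable$lam, 1200 * 0.73 * sqrt(log(1 / 0.81)))
  expect_equal(pf$node$lam_node, 48.1 * sqrt(0.73))
  expect_equal(pf$node$tau_node / u[["us"]], 20)
  expect_equal(pf$current$tau_m / u[["us"]], 70)
  expect_equal(pf$current$tau_h / u[["us"]], 160)
  expect_equal(pf$current$I0 / u[["pA_per_um2"]], 200)
  expect_equal(pf$V_thr, 4)
  # the two nodal time scales (node constant vs K activation) are distinct
  expect_equal(ps$current$tau_nK / u[["us"]], 150)
  expect_false(isTRUE(all.equal(ps$node$tau_node, ps$current$tau_nK)))
})

test_that("geometry re-derivation tracks overrides and invalidates caches", {
  ps <- std_params()
  p2 <- set_geometry(ps, d = 2)
  expect_equal(p2$geometry$L, 200)            # L tracks 100 d
  expect_equal(p2$cable$lam, 2 * ps$cable$lam, tolerance = 1e-12)
  expect_equal(p2$cable$tau, ps$cable$tau)    # tau unaffected by geometry
  pf <- fit_params()
  pf2 <- set_geometry(pf, g = 0.6)
  expect_equal(pf2$cable$tau, 1.45)           # fitted override preserved
  expect_equal(pf2$cable$lam, 1200 * 0.73 * sqrt(log(1 / 0.6)))
})

test_that("config files round-trip a parameter set", {
  ps <- parameter_set("standard", scenario = "B", d = 2, g = 0.7, l = 1.5,
                      V_thr = 12, delta_us = 25)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_sds_config(ps, path, rho_density = 0.5)
  back <- read_sds_config(path)
  expect_equal(back$rho_density, 0.5)
  p2 <- back$params
  for (fld in c("d", "g", "L", "l", "N")) {
    expect_equal(p2$geometry[[fld]], ps$geometry[[fld]])
  }
  expect_equal(p2$V_thr, ps$V_thr)
  expect_equal(p2$current$scenario, "B")
  expect_equal(p2$current$delta, ps$current$delta)
  expect_equal(p2$cable$lam, ps$cable$lam)
  # unknown keys are rejected by name
  writeLines(c("d_um = 1", "frobnicate = 2"), path)
  expect_error(read_sds_config(path), "frobnicate")
})

test_that("geometry validation rejects unphysical inputs", {
  expect_error(axon_geometry(d = -1), "diameter")
  expect_error(axon_geometry(d = 1, g = 1.2), "g-ratio")
  expect_error(axon_geometry(d = 1, g = 0), "g-ratio")
  expect_error(physical_constants(k1_pF_per_cm = -3), "positive")
})
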