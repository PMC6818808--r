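test_that("node contributions decompose the membrane potential exactly", {
  p <- std_params(N = 50L)
  prob <- propagation_problem(p)
  t_sp <- 0.0162
  t <- c(0.01, 0.05, 0.2)
  m <- node_contributions(0, t, prob, t_sp)
  expect_equal(rowSums(m), membrane_potential(0, t, prob, t_sp),
               tolerance = 1e-10)
  # at the threshold-crossing instant only already-fired (backward) nodes
  # contribute; the reference node and all forward nodes are silent
  m0 <- node_contributions(0, 0, prob, t_sp)
  expect_true(all(m0[, as.character(0:50)] == 0))
  expect_gt(sum(m0[, as.character(-50:-1)]), 0)
})

test_that("threshold residual: decay limit, continuity, scenario-B shift", {
  p <- std_params()
  prob <- propagation_problem(p)
  expect_equal(threshold_residual(50, prob), -p$V_thr, tolerance = 1e-6)
  # continuity in t_sp for the gated current
  ts <- seq(0.01, 0.03, length.out = 40)
  r <- threshold_residual(ts, prob)
  expect_true(all(abs(diff(r)) < 5))
  # scenario B with a single neighbour: root is the scenario-A root plus the delay
  pa <- std_params("A")
  pb <- std_params("B")
  ra <- solve_tsp(propagation_problem(pa, N = 1))
  rb <- solve_tsp(propagation_problem(pb, N = 1))
  expect_equal(rb$t_sp, ra$t_sp + pb$current$delta, tolerance = 1e-6)
})

test_that("time-to-spike decreases monotonically with lower threshold", {
  p <- std_params()
  tsps <- vapply(c(5, 10, 15, 20), function(v)
    solve_tsp(propagation_problem(p, V_thr = v))$t_sp, numeric(1))
  expect_true(all(diff(tsps) > 0))
})

test_that("threshold root is the unique up-crossing on the rising phase", {
  p <- std_params()
  prob <- propagation_problem(p)
  sol <- solve_tsp(prob)
  expect_true(sol$converged)
  expect_lt(abs(sol$residual), 1e-9)
  ts <- exp(seq(log(1e-5), log(5), length.out = 300))
  r <- threshold_residual(ts, prob)
  crossings <- sum(r[-1] > 0 & r[-length(r)] <= 0)
  expect_equal(crossings, 1)
})

test_that("propagation failure is reported, not raised", {
  p <- std_params()
  res <- conduction_velocity(propagation_problem(p, V_thr = 500))
  expect_false(res$converged)
  expect_true(is.na(res$v_corrected_mps))
})

test_that("delayed release bounds the single-neighbour velocity by (L+l)/Delta", {
  pb <- std_params("B")
  res <- conduction_velocity(propagation_problem(pb, N = 1), corrected = FALSE)
  geo <- pb$geometry
  v_bound <- (geo$L + geo$l) / pb$current$delta * 1e-3   # m/s
  expect_lt(res$v_internode_mps, v_bound)
  # with many neighbours the threshold can be crossed before the delay,
  # so the full solve may exceed the single-neighbour bound
  res_full <- conduction_velocity(propagation_problem(pb), corrected = FALSE)
  expect_gt(res_full$v_internode_mps, v_bound)
})

test_that("the nodal sum saturates quickly with N", {
  p <- std_params()
  t20 <- solve_tsp(propagation_problem(p, N = 20))$t_sp
  t1000 <- std_tsp_D()$t_sp
  expect_lt(abs(t20 - t1000) / t1000, 5e-3)
})

test_that("time-to-spike is invariant under joint electrotonic rescaling", {
  p <- std_params()
  prob <- propagation_problem(p)
  sol <- solve_tsp(prob)
  # scale all lengths (L, l, lam, lam_node) by c while holding R_lambda and
  # beta fixed: the dimensionless threshold problem is unchanged
  for (c_scale in c(0.5, 3)) {
    k <- prob$kernel
    k$lam <- k$lam * c_scale
    k$x_spacing <- k$x_spacing * c_scale
    prob2 <- prob
    prob2$kernel <- k
    sol2 <- solve_tsp(prob2)
    expect_equal(sol2$t_sp, sol$t_sp, tolerance = 1e-8)
  }
})

test_that("myelinated velocity grows approximately linearly with diameter", {
  p <- std_params()
  sw <- sweep_velocity(p, d = c(2, 4, 6, 8, 10))
  expect_true(all(sw$converged))
  fit <- stats::lm(v_mps ~ d_um, data = sw)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("unmyelinated axon: sqrt-diameter scaling and discretisation control", {
  p <- std_params()
  v1 <- unmyelinated_velocity(p, rho = 1, refine_check = TRUE)
  expect_true(v1$converged)
  expect_true(v1$disc_converged)
  expect_lt(v1$disc_rel_change, 0.02)
  p4 <- set_geometry(p, d = 4)
  v4 <- unmyelinated_velocity(p4, rho = 1, refine_check = FALSE)
  expect_equal(v4$v_mps / v1$v_mps, 2, tolerance = 0.1)
})

test_that("low channel density slows or blocks unmyelinated conduction", {
  p <- std_params()
  v1 <- unmyelinated_velocity(p, rho = 1, refine_check = FALSE)
  v01 <- unmyelinated_velocity(p, rho = 0.1, refine_check = FALSE)
  # the depolarisation scales with sqrt(rho): at this diameter and the
  # standard threshold a tenfold density reduction blocks conduction
  # entirely (the limiting case of slower propagation)
  expect_true(!v01$converged || v01$v_mps < v1$v_mps)
})

test_that("corrected velocity combines internodal and nodal transit times", {
  p <- std_params()
  res <- conduction_velocity(propagation_problem(p))
  geo <- p$geometry
  v_raw <- (geo$L + geo$l) / res$t_sp * 1e-3
  expect_equal(res$v_internode_mps, v_raw, tolerance = 1e-12)
  vn <- res$v_node_mps
  expect_equal(res$v_corrected_mps,
               (geo$L + geo$l) / (geo$L / (v_raw * 1e3) + geo$l / (vn * 1e3)) * 1e-3,
               tolerance = 1e-12)
  expect_lt(res$v_corrected_mps, res$v_internode_mps)
  # an infinitely fast node leaves only the internodal transit time
  res_inf <- conduction_velocity(propagation_problem(p), v_node = 1e12)
  expect_equal(res_inf$v_corrected_mps,
               res_inf$v_internode_mps * (geo$L + geo$l) / geo$L,
               tolerance = 1e-6)
})

test_that("action-potential shape with potassium shows after-hyperpolarisation", {
  p <- parameter_set("standard", scenario = "D", include_potassium = TRUE,
                     N = 300L)
  prob <- propagation_problem(p)
  t_sp <- std_tsp_D()$t_sp
  tr <- membrane_potential(0, seq(1e-3, 3, by = 2e-3), prob, t_sp)
  i_peak <- which.max(tr)
  expect_gt(max(tr), 50)               # depolarisation peak
  expect_lt(min(tr[i_peak:length(tr)]), 0)  # later hyperpolarising trough
})
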