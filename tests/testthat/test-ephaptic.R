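test_that("decoupling of identical axons: modes, coefficients, limits", {
  p <- std_params()
  b <- ephaptic_bundle(p)
  expect_equal(b$alpha, 1 / sum(b$R_ax_inv))        # R_ex^-1 = 0 limit
  dec <- decouple(b)
  expect_equal(dec$c1, 1)
  expect_equal(dec$c2, -1)
  expect_equal(dec$lam_tilde1, sqrt(2) * p$cable$lam, tolerance = 1e-12)
  expect_equal(dec$lam_tilde2, p$cable$lam, tolerance = 1e-12)
  # continuity: alpha -> 1/sum(Rax^-1) as R_ex^-1 -> 0+
  b_eps <- ephaptic_bundle(p, R_ex_inv = 1e-9)
  expect_equal(decouple(b_eps)$lam_tilde1, dec$lam_tilde1, tolerance = 1e-6)
  # decoupled limit: a highly conductive extracellular space removes coupling
  b0 <- ephaptic_bundle(p, R_ex_inv = 1e9)
  dec0 <- decouple(b0)
  expect_equal(dec0$lam_tilde1, p$cable$lam, tolerance = 1e-6)
  expect_equal(dec0$lam_tilde2, p$cable$lam, tolerance = 1e-6)
})

test_that("closed-form decoupling diagonalises the coupling matrix (general axons)", {
  p1 <- std_params()
  p2 <- set_geometry(std_params(), d = 2, L = 100)   # different diameter
  b <- ephaptic_bundle(p1, p2)
  dec <- decouple(b)
  ev <- eigen(dec$A)$values
  expect_equal(sort(c(dec$lam_tilde1^2, dec$lam_tilde2^2)), sort(ev),
               tolerance = 1e-10)
  # the rows (1, c1), (1, c2) are left eigenvectors of the coupling matrix
  for (cc in c(dec$c1, dec$c2)) {
    v <- c(1, cc) %*% dec$A
    expect_equal(v[2] / v[1], cc, tolerance = 1e-10)
  }
})

test_that("mode transformation round-trips to machine precision", {
  set.seed(1)
  P <- matrix(rnorm(20), 2)
  c1 <- 1
  c2 <- -1
  Pt1 <- P[1, ] + c1 * P[2, ]
  Pt2 <- P[1, ] + c2 * P[2, ]
  P1 <- -(c2 * Pt1 - c1 * Pt2) / (c1 - c2)
  P2 <- (Pt1 - Pt2) / (c1 - c2)
  expect_equal(P1, P[1, ], tolerance = 1e-14)
  expect_equal(P2, P[2, ], tolerance = 1e-14)
})

test_that("pair response: symmetry and the uncoupled limit", {
  p <- std_params(N = 200L)
  b <- ephaptic_bundle(p)
  t <- seq(0.005, 0.5, by = 0.005)
  firing <- data.frame(node = -5:0, time = (-5:0) * 0.0162)
  sym <- pair_response(b, firing, firing, x = 30, t = t)
  expect_equal(sym$P1_mV, sym$P2_mV, tolerance = 1e-12)
  # alpha -> 0: axon 1 recovers the uncoupled trace, silent axon 2 stays flat
  b0 <- ephaptic_bundle(p, R_ex_inv = 1e12)
  silent <- data.frame(node = integer(), time = numeric())
  one <- pair_response(b0, firing, silent, x = 30, t = t)
  k <- response_kernel(p)
  ref <- rowSums(vapply(seq_len(nrow(firing)), function(j)
    single_node_response(abs(30 - firing$node[j] * k$x_spacing),
                         t - firing$time[j], k), numeric(length(t))))
  expect_equal(one$P1_mV, ref, tolerance = 1e-4)
  expect_lt(max(abs(one$P2_mV)), 1e-4 * max(one$P1_mV))
})

test_that("difference mode propagates with the uncoupled length constant", {
  p <- std_params()
  b <- ephaptic_bundle(p)
  mk <- sdspike:::.mode_kernels(b)
  k <- response_kernel(p)
  expect_equal(mk$k2$lam, k$lam)
  expect_equal(mk$k2$R_lambda, k$R_lambda)
  expect_equal(mk$k2$x_spacing, k$x_spacing)
  t <- seq(0.01, 0.5, by = 0.01)
  expect_equal(single_node_response(100, t, mk$k2),
               single_node_response(100, t, k))
})

test_that("mode machinery agrees with a direct PDE solve of the coupled pair", {
  # method-of-lines integration of the coupled system
  # tau dPi/dt = lam^2 Pi'' + a lam^2 (P1'' + P2'') - Pi + Rm Ii delta(x)
  p <- std_params()
  tau <- p$cable$tau
  lam <- p$cable$lam
  Rm <- p$cable$R_m
  beta <- p$node$beta
  I0 <- p$current$I0 * pi
  terms <- p$current$terms
  Ifun <- function(t) if (t <= 0) 0 else I0 * sum(terms$A * exp(-t / terms$tau_s))
  h <- 25
  xg <- seq(-6000, 6000, by = h)
  nx <- length(xg)
  i0 <- which(xg == 0)
  lap <- function(v) (c(v[-1], 0) - 2 * v + c(0, v[-nx])) / h^2
  a <- 0.5
  dt <- 5e-5
  nt <- 800L   # 0.04 ms, the rise-time scale of the AP at a node
  run <- function(pair) {
    P1 <- numeric(nx)
    P2 <- numeric(nx)
    for (kk in seq_len(nt)) {
      t <- kk * dt
      Icab <- beta * Ifun(t) / h
      L1 <- lap(P1)
      L2 <- lap(P2)
      d1 <- (lam^2 * L1 + a * lam^2 * (L1 + L2) - P1) / tau
      d2 <- (lam^2 * L2 + a * lam^2 * (L1 + L2) - P2) / tau
      d1[i0] <- d1[i0] + Rm * Icab / tau
      if (pair) d2[i0] <- d2[i0] + Rm * Icab / tau
      P1 <- P1 + dt * d1
      P2 <- P2 + dt * d2
    }
    list(P1 = P1, P2 = P2)
  }
  xob <- which.min(abs(xg - 125))
  x <- xg[xob]
  t_end <- nt * dt
  b <- ephaptic_bundle(p)
  mk <- sdspike:::.mode_kernels(b)
  U1 <- response_multi_exponential(x, t_end, mk$k1)
  U2 <- response_multi_exponential(x, t_end, mk$k2)
  r_one <- run(pair = FALSE)
  r_par <- run(pair = TRUE)
  expect_equal(r_one$P1[xob], (U1 + U2) / 2, tolerance = 0.02)
  expect_equal(r_one$P2[xob], (U1 - U2) / 2, tolerance = 0.05)
  expect_equal(r_par$P1[xob], U1, tolerance = 0.02)
  # pointwise ordering at internodal distance: the synchronous pair
  # depolarises less than a single active axon, which depolarises less than
  # an uncoupled axon (what the published depolarisation curves display)
  expect_lt(r_par$P1[xob], r_one$P1[xob])
  expect_lt(r_one$P1[xob], U2)
})

test_that("entrainment: a symmetric pair stays synchronous, offsets contract", {
  p <- std_params(N = 400L)
  b <- ephaptic_bundle(p)
  st0 <- entrainment_step(b, 0)
  expect_true(st0$converged)
  expect_equal(st0$dt_out, 0, tolerance = 1e-10)
  st <- entrainment_step(b, 0.02)
  expect_true(st$converged)
  expect_lt(abs(st$dt_out), 0.02)
  expect_gte(st$dt_out, 0)           # sign is preserved
  # smaller offsets also contract
  st2 <- entrainment_step(b, 0.005)
  expect_lt(abs(st2$dt_out), 0.005)
})

test_that("paired velocity: uncoupled limit and coupling dependence", {
  p <- std_params(N = 400L)
  b0 <- ephaptic_bundle(p, R_ex_inv = 1e12)
  pv0 <- paired_velocity(b0)
  expect_equal(pv0$v_pair_mps, pv0$v_single_mps, tolerance = 1e-4)
  # the velocity change grows monotonically with the coupling strength
  rex <- c(1e-2, 3e-3, 1e-3, 3e-4, 0)   # decreasing R_ex^-1 = increasing alpha
  gaps <- vapply(rex, function(r) {
    pv <- paired_velocity(ephaptic_bundle(p, R_ex_inv = r))
    abs(pv$v_pair_mps - pv$v_single_mps)
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("passive axon next to a propagating action potential is perturbed biphasically", {
  p <- std_params(N = 400L)
  b <- ephaptic_bundle(p)
  tr <- passive_pair_trace(b, t = seq(-0.4, 1, by = 2e-3))
  expect_gt(max(tr$P1_mV), 50)       # the active axon carries a full AP
  expect_lt(min(tr$P2_mV), -1)       # hyperpolarised phase
  expect_gt(max(tr$P2_mV), 1)        # depolarised phase
  expect_lt(max(abs(tr$P2_mV)), 0.2 * max(tr$P1_mV))  # a weak perturbation
})
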