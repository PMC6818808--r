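#' Ephaptically coupled fibre bundle
#'
#' Two (or more) axons sharing a restricted extracellular space interact
#' through the extracellular potential: the trans-membrane potentials obey
#' coupled cable equations in which each axon's effective diffusion term
#' picks up a contribution `alpha lam_n^2 sum_m R_ax,m^-1 P_m''` with
#' coupling parameter `alpha = 1/(R_ex^-1 + sum_m R_ax,m^-1)`.  The default
#' `R_ex_inv = 0` describes a tightly packed bundle whose extracellular
#' return path is negligible, the regime explored in the published results.
#'
#' @param params1 an `sds_params` for the first axon.
#' @param params2 an `sds_params` for the second axon (defaults to the
#'   first: identical axons).
#' @param R_ex_inv extracellular axial conductance per unit length
#'   (1/(MOhm um) in internal units).
#' @return Object of class `sds_bundle`.
#' @export
ephaptic_bundle <- function(params1, params2 = params1, R_ex_inv = 0) {
  stopifnot(R_ex_inv >= 0)
  if (abs(params1$cable$tau - params2$cable$tau) > 1e-12)
    stop("the decoupling transformation requires equal cable time constants")
  R_ax_inv <- c(1 / params1$cable$R_c, 1 / params2$cable$R_c)
  if (any(!is.finite(R_ax_inv)) || any(R_ax_inv <= 0))
    stop("degenerate axial conductances")
  alpha <- 1 / (R_ex_inv + sum(R_ax_inv))
  structure(list(params = list(params1, params2), R_ex_inv = R_ex_inv,
                 R_ax_inv = R_ax_inv, alpha = alpha),
            class = "sds_bundle")
}

#' Decouple a two-fibre bundle into independent cable modes
#'
#' The coupled pair is diagonalised by `P~_1,2 = P_1 + c_1,2 P_2` with
#' \deqn{c_{1,2} = -\frac{\lambda_1^2(\alpha R_{ax,1}^{-1}+1) -
#'   \lambda_2^2(\alpha R_{ax,2}^{-1}+1)}{2\lambda_2^2\alpha R_{ax,1}^{-1}}
#'   \pm \sqrt{(\cdot)^2 + \frac{\lambda_1^2 R_{ax,2}^{-1}}
#'   {\lambda_2^2 R_{ax,1}^{-1}}},}
#' each mode obeying a single-axon cable equation with effective length
#' constants `lam1~^2 = lam1^2 + alpha R_ax1^-1 (lam1^2 + c1 lam2^2)` and
#' `lam2~^2 = lam2^2 + alpha R_ax2^-1 (lam2^2 + lam1^2/c2)`.  For identical
#' axons `c_1,2 = +/-1`; with a fully restricted extracellular space the
#' common mode then has `lam1~ = sqrt(2) lam` and the difference mode keeps
#' the uncoupled `lam`.
#'
#' @param bundle an `sds_bundle`.
#' @return List with `c1`, `c2`, `lam_tilde1`, `lam_tilde2`, `alpha`, and
#'   the coupling matrix `A` whose eigenvalues are the squared effective
#'   length constants.
#' @export
decouple <- function(bundle) {
  p1 <- bundle$params[[1]]
  p2 <- bundle$params[[2]]
  l1 <- p1$cable$lam
  l2 <- p2$cable$lam
  A1 <- bundle$alpha * bundle$R_ax_inv[1]
  A2 <- bundle$alpha * bundle$R_ax_inv[2]
  identical_axons <- isTRUE(all.equal(l1, l2)) &&
    isTRUE(all.equal(bundle$R_ax_inv[1], bundle$R_ax_inv[2]))
  if (identical_axons) {
    c1 <- 1
    c2 <- -1
  } else {
    m <- (l1^2 * (A1 + 1) - l2^2 * (A2 + 1)) / (2 * l2^2 * A1)
    rad <- sqrt(m^2 + (l1^2 * bundle$R_ax_inv[2]) /
                  (l2^2 * bundle$R_ax_inv[1]))
    c1 <- -m + rad
    c2 <- -m - rad
  }
  lt1 <- sqrt(l1^2 + A1 * (l1^2 + c1 * l2^2))
  lt2 <- sqrt(l2^2 + A2 * (l2^2 + l1^2 / c2))
  A <- matrix(c(l1^2 * (1 + A1), l1^2 * A2,
                l2^2 * A1,       l2^2 * (1 + A2)),
              nrow = 2, byrow = TRUE)
  list(c1 = c1, c2 = c2, lam_tilde1 = lt1, lam_tilde2 = lt2,
       alpha = bundle$alpha, A = A)
}

# mode kernel: the single-axon kernel of axon 1 with the cable length
# constant replaced by the mode's effective value (R_lambda = R_m/lam~ and
# the electrotonic node correction follow; beta is the physical current
# division at the node and is unchanged).
.mode_kernel <- function(bundle, lam_tilde) {
  p <- bundle$params[[1]]
  cable <- p$cable
  cable$lam <- lam_tilde
  cable$R_lambda <- cable$R_m / lam_tilde
  response_kernel(p, cable = cable)
}

.mode_kernels <- function(bundle) {
  dec <- decouple(bundle)
  list(k1 = .mode_kernel(bundle, dec$lam_tilde1),
       k2 = .mode_kernel(bundle, dec$lam_tilde2),
       dec = dec)
}

#' Trans-membrane potentials of an ephaptically coupled pair
#'
#' Evaluates `P_1(x, t)` and `P_2(x, t)` for identical coupled axons given
#' the firing history of each axon, by solving each decoupled mode with the
#' single-axon response machinery and inverting the transformation
#' (`P1 = (P~1 + P~2)/2`, `P2 = (P~1 - P~2)/2`).
#'
#' @param bundle an `sds_bundle` of identical axons.
#' @param firing1,firing2 data frames with columns `node` (integer index)
#'   and `time` (ms): the firing history of each axon.  Use a zero-row data
#'   frame for a silent axon.
#' @param x observation coordinate (um) on the effective internodal cable;
#'   0 is the reference node.
#' @param t time grid (ms).
#' @return Data frame with columns `t_ms`, `P1_mV`, `P2_mV`.
#' @export
pair_response <- function(bundle, firing1, firing2, x = 0, t) {
  mk <- .mode_kernels(bundle)
  t_max <- max(t)
  mode_sum <- function(kernel, c_mode) {
    out <- numeric(length(t))
    add <- function(firing, weight) {
      if (is.null(firing) || nrow(firing) == 0) return(invisible())
      for (j in seq_len(nrow(firing))) {
        age_max <- t_max - firing$time[j]
        if (age_max <= 0) next
        xn <- abs(x - firing$node[j] * kernel$x_spacing)
        if (xn^2 * kernel$tau / (4 * kernel$lam^2 * age_max) > 400) next
        out <<- out + weight *
          single_node_response(xn, t - firing$time[j], kernel)
      }
      invisible()
    }
    add(firing1, 1)
    add(firing2, c_mode)
    out
  }
  M1 <- mode_sum(mk$k1, mk$dec$c1)
  M2 <- mode_sum(mk$k2, mk$dec$c2)
  data.frame(t_ms = t, P1_mV = (M1 + M2) / 2, P2_mV = (M1 - M2) / 2)
}

# residual of the threshold condition for axon 1 of a coupled pair in steady
# synchronous propagation: P1 at the next node equals
# (1/2) sum_n [U~1(n x1, n t) + U~2(n x2, n t)] when both axons fire, and
# the same expression for a single active axon (the silent axon contributes
# equally to both modes).
.pair_residual <- function(t_sp, mk, N, V_thr, both_active = TRUE) {
  n <- seq_len(N)
  s1 <- sum(single_node_response(n * mk$k1$x_spacing, n * t_sp, mk$k1))
  s2 <- sum(single_node_response(n * mk$k2$x_spacing, n * t_sp, mk$k2))
  if (both_active) {
    # axon 2 fires identically: mode i is driven with weight (1 + c_i)
    0.5 * ((1 + mk$dec$c1) * s1 + (1 + mk$dec$c2) * s2) - V_thr
  } else {
    0.5 * (s1 + s2) - V_thr
  }
}

#' Velocity of a synchronous action-potential pair
#'
#' Solves the threshold condition for two identical axons firing in
#' synchrony (the difference mode vanishes; the common mode propagates on
#' the `sqrt(2) lam` cable) and compares with the uncoupled single-axon
#' velocity.
#'
#' @param bundle an `sds_bundle` of identical axons.
#' @param corrected apply the node-velocity correction to both velocities.
#' @return List with `v_pair_mps`, `v_single_mps`, `t_sp_pair`,
#'   `t_sp_single`.
#' @export
paired_velocity <- function(bundle, corrected = TRUE) {
  p <- bundle$params[[1]]
  mk <- .mode_kernels(bundle)
  geo <- p$geometry
  u <- sds_units()
  sol_pair <- .find_threshold_root(function(ts)
    .pair_residual(ts, mk, geo$N, p$V_thr, both_active = TRUE))
  sol_single <- solve_tsp(propagation_problem(p))
  to_v <- function(t_sp) {
    v_raw <- (geo$L + geo$l) / t_sp
    if (!corrected) return(v_raw * u[["um_per_ms"]])
    vn_int <- .vnode_for(p) / u[["um_per_ms"]]
    (geo$L + geo$l) / (geo$L / v_raw + geo$l / vn_int) * u[["um_per_ms"]]
  }
  list(v_pair_mps = if (sol_pair$converged) to_v(sol_pair$t_sp) else NA_real_,
       v_single_mps = if (sol_single$converged) to_v(sol_single$t_sp) else NA_real_,
       t_sp_pair = sol_pair$t_sp, t_sp_single = sol_single$t_sp)
}

#' One entrainment step of an offset action-potential pair
#'
#' Both axons have been propagating in near-synchrony: axon 1 fired its
#' nodes `n <= 0` at times `n t_pair` and axon 2 at `n t_pair + dt_in`,
#' where `t_pair` is the synchronous-pair time-to-spike.  The
#' threshold-crossing times `T1`, `T2` of the two axons at the next node are
#' solved from the coupled potentials, and the new offset `dt_out = T2 - T1`
#' is returned.  Ephaptic coupling is entraining when `|dt_out| < |dt_in|`.
#'
#' @param bundle an `sds_bundle` of identical axons.
#' @param dt_in initial firing offset (ms).
#' @param t_pair synchronous-pair time-to-spike (ms); solved if missing.
#' @return List with `dt_in`, `dt_out`, `T1`, `T2`, `t_pair`, `converged`.
#' @export
entrainment_step <- function(bundle, dt_in, t_pair = NULL) {
  p <- bundle$params[[1]]
  mk <- .mode_kernels(bundle)
  geo <- p$geometry
  if (is.null(t_pair)) {
    sol <- .find_threshold_root(function(ts)
      .pair_residual(ts, mk, geo$N, p$V_thr))
    if (!sol$converged) stop("synchronous pair does not propagate")
    t_pair <- sol$t_sp
  }
  k <- 0:geo$N
  # potential of axon i at its node 1 (distance (k+1) spacings from the node
  # that fired at -k t_pair [+ dt for axon 2])
  axon_potential <- function(T, own_offset, other_offset) {
    ages_own <- T + k * t_pair - own_offset
    ages_oth <- T + k * t_pair - other_offset
    x1 <- (k + 1) * mk$k1$x_spacing
    x2 <- (k + 1) * mk$k2$x_spacing
    own <- 0.5 * (sum(single_node_response(x1, ages_own, mk$k1)) +
                    sum(single_node_response(x2, ages_own, mk$k2)))
    oth <- 0.5 * (sum(single_node_response(x1, ages_oth, mk$k1)) -
                    sum(single_node_response(x2, ages_oth, mk$k2)))
    own + oth
  }
  f1 <- function(T) axon_potential(T, 0, dt_in) - p$V_thr
  f2 <- function(T) axon_potential(T, dt_in, 0) - p$V_thr
  rng <- c(1e-6, max(10 * t_pair, t_pair + 4 * abs(dt_in), 1e-3))
  s1 <- .find_threshold_root(f1, t_range = rng)
  s2 <- .find_threshold_root(f2, t_range = rng)
  T1 <- s1$t_sp
  T2 <- s2$t_sp    # absolute time: the offset is already in axon 2's history
  list(dt_in = dt_in, dt_out = T2 - T1, T1 = T1, T2 = T2, t_pair = t_pair,
       converged = s1$converged && s2$converged)
}

#' Trace of a passive axon next to a propagating action potential
#'
#' Convenience wrapper around [pair_response()]: axon 1 carries a steadily
#' propagating action potential (time-to-spike solved self-consistently in
#' the coupled system), axon 2 is silent, and both trans-membrane potentials
#' are evaluated at the reference node.
#'
#' @param bundle an `sds_bundle` of identical axons.
#' @param t time grid (ms); default covers the passage of the action
#'   potential.
#' @return Data frame from [pair_response()], with attribute `t_sp`.
#' @export
passive_pair_trace <- function(bundle, t = NULL) {
  p <- bundle$params[[1]]
  mk <- .mode_kernels(bundle)
  geo <- p$geometry
  sol <- .find_threshold_root(function(ts)
    .pair_residual(ts, mk, geo$N, p$V_thr, both_active = FALSE))
  if (!sol$converged) stop("single action potential does not propagate in the coupled system")
  t_sp <- sol$t_sp
  if (is.null(t)) t <- seq(1e-3, 1.5, by = 1e-3)
  firing1 <- data.frame(node = -geo$N:geo$N,
                        time = (-geo$N:geo$N) * t_sp)
  out <- pair_response(bundle, firing1,
                       data.frame(node = integer(), time = numeric()),
                       x = 0, t = t)
  attr(out, "t_sp") <- t_sp
  out
}
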