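#' Define a propagation problem
#'
#' Bundles a parameter set with the number of contributing nodes per side and
#' the firing threshold into the implicit problem for the internodal
#' time-to-spike `t_sp`: node `n = 0` (at `x = 0`) reaches `V_thr` at
#' `t = 0` given that every preceding node fired `t_sp` apart,
#' \deqn{V_{thr} = \sum_{n=1}^{N} U(n(L + l\lambda/\lambda_n),\, n t_{sp}).}
#'
#' @param params an `sds_params`.
#' @param N nodes per side (defaults to the geometry's `N`).
#' @param V_thr firing threshold (mV, defaults to the set's).
#' @return Object of class `sds_problem`.
#' @export
propagation_problem <- function(params, N = params$geometry$N,
                                V_thr = params$V_thr) {
  stopifnot(N >= 1, V_thr > 0)
  structure(list(params = params, kernel = response_kernel(params),
                 N = as.integer(N), V_thr = V_thr),
            class = "sds_problem")
}

#' Membrane potential of a propagating action potential
#'
#' Superposition of single-node responses,
#' `V(x,t) = sum_n U(|x - n x_sp|, t - n t_sp)` over `n = -N..N`, where
#' `x_sp = L + l lam/lam_node` is the effective internodal spacing and node
#' `n = 0` crosses threshold at `t = 0`.  Nodes whose spatial attenuation
#' makes their contribution vanish at double precision are skipped.
#'
#' @param x observation point (um, scalar).
#' @param t time (ms), vectorised.
#' @param problem an `sds_problem`.
#' @param t_sp internodal time-to-spike (ms), e.g. from [solve_tsp()].
#' @return Membrane potential (mV) at each `t`.
#' @export
membrane_potential <- function(x, t, problem, t_sp) {
  k <- problem$kernel
  out <- numeric(length(t))
  t_max <- max(t)
  for (n in -problem$N:problem$N) {
    age_max <- t_max - n * t_sp
    if (age_max <= 0) next
    xn <- abs(x - n * k$x_spacing)
    # skip nodes beyond any representable contribution
    if (xn^2 * k$tau / (4 * k$lam^2 * age_max) > 400) next
    out <- out + single_node_response(xn, t - n * t_sp, k)
  }
  out
}

#' Per-node contributions to the membrane potential
#'
#' The decomposition of [membrane_potential()] by source node: column `n` of
#' the returned matrix is the depolarisation contributed by the node at
#' `x = n x_sp` firing at `t = n t_sp`.  Columns sum to the total membrane
#' potential.
#'
#' @inheritParams membrane_potential
#' @return Numeric matrix, `length(t)` rows and `2N + 1` columns named by
#'   node index.
#' @export
node_contributions <- function(x, t, problem, t_sp) {
  k <- problem$kernel
  idx <- -problem$N:problem$N
  m <- matrix(0, nrow = length(t), ncol = length(idx),
              dimnames = list(NULL, idx))
  for (j in seq_along(idx)) {
    n <- idx[j]
    xn <- abs(x - n * k$x_spacing)
    m[, j] <- single_node_response(xn, t - n * t_sp, k)
  }
  m
}

#' Threshold-condition residual
#'
#' `sum_{n=1..N} U(n x_sp, n t_sp) - V_thr`: zero at the self-consistent
#' time-to-spike.  Negative both for very small `t_sp` (currents have not
#' arrived) and very large `t_sp` (responses have decayed), positive between
#' whenever propagation is possible.
#'
#' @param t_sp candidate time-to-spike (ms), vectorised.
#' @param problem an `sds_problem`.
#' @return Residual (mV) for each `t_sp`.
#' @export
threshold_residual <- function(t_sp, problem) {
  k <- problem$kernel
  n <- seq_len(problem$N)
  vapply(t_sp, function(ts) {
    sum(single_node_response(n * k$x_spacing, n * ts, k)) - problem$V_thr
  }, numeric(1))
}

#' Solve the implicit threshold condition for the time-to-spike
#'
#' Locates the smallest positive root of [threshold_residual()] by a
#' geometric bracketing scan followed by safeguarded Newton iteration
#' (numerical central-difference derivative, with bisection fallback
#' whenever a Newton step leaves the bracket -- scenario B's causal cutoffs
#' make the residual only piecewise smooth).
#'
#' @param problem an `sds_problem`.
#' @param t_range search range for the bracketing scan (ms).
#' @param tol residual tolerance (mV).
#' @param max_iter iteration cap.
#' @return Object of class `sds_result`: `t_sp` (ms), `residual` (mV),
#'   `iterations`, `converged`.  If the threshold is never reached the result
#'   has `converged = FALSE` and `t_sp = NA` (propagation failure), not an
#'   error.
#' @export
solve_tsp <- function(problem, t_range = c(1e-6, 10), tol = 1e-9,
                      max_iter = 200L) {
  .find_threshold_root(function(ts) threshold_residual(ts, problem),
                       t_range, tol, max_iter)
}

# smallest positive up-crossing of f (negative -> positive), by geometric
# bracketing scan + Newton with bisection safeguard; shared by the
# single-axon, unmyelinated and ephaptic solvers.
.find_threshold_root <- function(f, t_range = c(1e-6, 10), tol = 1e-9,
                                 max_iter = 200L, n_scan = 160L) {
  grid <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = n_scan))
  fg <- vapply(grid, f, numeric(1))
  up <- which(fg[-1] > 0 & fg[-length(fg)] <= 0)
  if (!length(up)) {
    return(structure(list(t_sp = NA_real_, residual = max(fg),
                          iterations = length(grid), converged = FALSE),
                     class = "sds_result"))
  }
  lo <- grid[up[1]]
  hi <- grid[up[1] + 1]
  flo <- fg[up[1]]
  t <- 0.5 * (lo + hi)
  ft <- f(t)
  iter <- 0L
  while (abs(ft) > tol && iter < max_iter && (hi - lo) > 1e-15) {
    h <- max(1e-6 * t, 1e-9)
    fp <- (f(t + h) - f(t - h)) / (2 * h)
    t_new <- if (is.finite(fp) && fp != 0) t - ft / fp else NA_real_
    if (!is.finite(t_new) || t_new <= lo || t_new >= hi) {
      t_new <- 0.5 * (lo + hi)   # bisection safeguard
    }
    ft_new <- f(t_new)
    if ((ft_new > 0) == (flo > 0)) {
      lo <- t_new
      flo <- ft_new
    } else {
      hi <- t_new
    }
    t <- t_new
    ft <- ft_new
    iter <- iter + 1L
  }
  structure(list(t_sp = t, residual = ft, iterations = iter,
                 converged = abs(ft) <= tol),
            class = "sds_result")
}

#' @export
print.sds_result <- function(x, ...) {
  cat("<sds_result>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v) || is.logical(v))
      cat(sprintf("  %s: %s\n", nm, paste(signif(v, 6), collapse = ", ")))
  }
  invisible(x)
}

# cache of nodal conduction velocities, keyed by the parameters they depend on
.vnode_cache <- new.env(parent = emptyenv())

# nodal current model used for the within-node (unmyelinated) velocity: the
# gated sodium profile of the parameter set.  For the impulse scenarios A/B
# the set's I0 is an impulse calibration, not a sustained current density, so
# the first-principles peak sodium density i_Na is used instead.
.node_current <- function(params) {
  cur <- params$current
  I0 <- if (cur$scenario %in% c("C", "D")) cur$I0 else params$constants$i_Na
  current_model(scenario = "D", I0 = I0, gamma = cur$gamma,
                tau_m = cur$tau_m, tau_h = cur$tau_h,
                tau_nK = cur$tau_nK, tau_k = cur$tau_k,
                i_K = params$constants$i_K, include_potassium = FALSE)
}

.vnode_for <- function(params) {
  if (!is.na(params$node$v_node)) return(params$node$v_node)
  cur <- .node_current(params)
  key <- paste(params$geometry$d, params$geometry$l, params$node$lam_node,
               params$node$tau_node, cur$I0, params$V_thr, cur$tau_m,
               cur$tau_h, cur$gamma, sep = "|")
  if (!is.null(.vnode_cache[[key]])) return(.vnode_cache[[key]])
  v <- unmyelinated_velocity(params, rho = 1, l_disc = params$geometry$l,
                             refine_check = FALSE)$v_mps
  .vnode_cache[[key]] <- v
  v
}

#' Conduction velocity of a myelinated axon
#'
#' Solves for the time-to-spike and returns both the internode velocity
#' `v = (L + l)/t_sp` and the node-corrected velocity
#' `v = (L + l) / (L/v + l/v_n)`, where the within-node velocity `v_n` is
#' the action-potential velocity of an unmyelinated axon with the nodal
#' membrane properties at full channel density ([unmyelinated_velocity()]),
#' computed once per parameter set and cached.
#'
#' @param problem an `sds_problem`.
#' @param corrected logical; apply the finite node-velocity correction
#'   (default TRUE, used throughout the published analysis).
#' @param v_node optional within-node velocity (m/s) to use instead of the
#'   cached unmyelinated solve.
#' @return `sds_result` with `t_sp` (ms), `v_internode_mps`,
#'   `v_corrected_mps`, `v_node_mps`, `residual`, `iterations`, `converged`.
#' @examples
#' \donttest{
#' p <- parameter_set("standard", scenario = "D")
#' conduction_velocity(propagation_problem(p))
#' }
#' @export
conduction_velocity <- function(problem, corrected = TRUE, v_node = NULL) {
  sol <- solve_tsp(problem)
  geo <- problem$params$geometry
  u <- sds_units()
  if (!sol$converged || is.na(sol$t_sp)) {
    sol$v_internode_mps <- NA_real_
    sol$v_corrected_mps <- NA_real_
    sol$v_node_mps <- NA_real_
    return(sol)
  }
  v_raw <- (geo$L + geo$l) / sol$t_sp          # um/ms
  sol$v_internode_mps <- v_raw * u[["um_per_ms"]]
  if (corrected) {
    vn <- if (is.null(v_node)) .vnode_for(problem$params) else v_node
    vn_int <- vn / u[["um_per_ms"]]            # m/s -> um/ms
    sol$v_node_mps <- vn
    sol$v_corrected_mps <- (geo$L + geo$l) /
      (geo$L / v_raw + geo$l / vn_int) * u[["um_per_ms"]]
  } else {
    sol$v_node_mps <- NA_real_
    sol$v_corrected_mps <- sol$v_internode_mps
  }
  sol
}

#' Conduction velocity of an unmyelinated axon
#'
#' The axon is treated as a chain of firing sites spaced `l_disc` apart on a
#' cable whose constants derive from the nodal membrane: relative channel
#' density `rho` scales the membrane conductance, so the time constant is
#' `tau_node/rho`, the length constant `lam_node/sqrt(rho)`, and the
#' threshold-triggered current density of each site scales with `rho`.  At
#' low densities the depolarisation (proportional to `sqrt(rho)`) can fail
#' to reach threshold in thin axons: conduction block, reported as a
#' non-converged result.  The velocity is `l_disc / t_sp`; `l_disc` is a
#' discretisation choice, and a refinement check at `l_disc/2` verifies it
#' does not control the result.
#'
#' @param params an `sds_params` (supplies nodal constants, the gated sodium
#'   current and the threshold).
#' @param rho relative ion channel density in (0, 1].
#' @param l_disc discretisation length (um); defaults to the node length.
#' @param N contributing sites per side.
#' @param refine_check logical; re-solve at `l_disc/2` and report the
#'   relative velocity change.
#' @return `sds_result` with `v_mps`, `t_sp`, `converged`, and (if checked)
#'   `v_half_mps`, `disc_rel_change`, `disc_converged`.
#' @export
unmyelinated_velocity <- function(params, rho = 1, l_disc = NULL, N = 1000L,
                                  refine_check = TRUE) {
  stopifnot(rho > 0, rho <= 1)
  if (is.null(l_disc)) l_disc <- params$geometry$l
  stopifnot(l_disc > 0)
  u <- sds_units()
  solve_unmyel <- function(l_d, N_d) {
    d <- params$geometry$d
    tau_u <- params$node$tau_node / rho
    lam_u <- params$node$lam_node / sqrt(rho)
    R_m_u <- params$constants$R_n / (pi * d * rho)   # MOhm um, per length
    R_node_u <- params$constants$R_n / (rho * pi * d * l_d)
    R_lambda_u <- R_m_u / lam_u
    beta_u <- 1 / (1 + R_lambda_u / (2 * R_node_u))
    cur <- .node_current(params)
    area <- pi * d * l_d
    terms <- cur$terms
    terms$w <- cur$I0 * rho * area * terms$A
    kernel <- structure(list(
      scenario = "D", tau = tau_u, lam = lam_u, R_lambda = R_lambda_u,
      beta = beta_u, Q = cur$I0 * rho * area * tau_u, delta = 0,
      terms = terms, x_spacing = l_d
    ), class = "sds_kernel")
    prob <- structure(list(params = params, kernel = kernel,
                           N = as.integer(N_d), V_thr = params$V_thr),
                      class = "sds_problem")
    sol <- solve_tsp(prob)
    sol$v_mps <- if (sol$converged) l_d / sol$t_sp * u[["um_per_ms"]] else NA_real_
    sol
  }
  sol <- solve_unmyel(l_disc, N)
  if (refine_check && sol$converged) {
    sol2 <- solve_unmyel(l_disc / 2, 2L * N)
    sol$v_half_mps <- sol2$v_mps
    sol$disc_rel_change <- abs(sol2$v_mps - sol$v_mps) / sol$v_mps
    sol$disc_converged <- is.finite(sol$disc_rel_change) &&
      sol$disc_rel_change < 0.02
  }
  sol
}

#' Action-potential voltage trace
#'
#' Evaluates `V(x, t)` for a steadily propagating action potential at a fixed
#' observation point.  The default time grid has 1 us resolution: the
#' delta-impulse scenarios have an integrable `1/sqrt(t)` singularity at the
#' firing instant of the local node, so peak amplitudes are reported at
#' physiological sampling resolution.
#'
#' @param problem an `sds_problem`.
#' @param x observation point (um); 0 is the reference node.
#' @param t time grid (ms); default `seq(dt, t_end, dt)`.
#' @param t_sp time-to-spike; solved from the problem if missing.
#' @param dt,t_end default grid resolution and extent (ms).
#' @return Data frame with columns `x_um`, `t_ms`, `V_mV` (ready to write as
#'   a trace CSV) plus attribute `t_sp`.
#' @export
action_potential_trace <- function(problem, x = 0, t = NULL, t_sp = NULL,
                                   dt = 1e-3, t_end = 1.5) {
  if (is.null(t_sp)) {
    sol <- solve_tsp(problem)
    if (!sol$converged) stop("no propagating solution: threshold not reached")
    t_sp <- sol$t_sp
  }
  if (is.null(t)) t <- seq(dt, t_end, by = dt)
  v <- membrane_potential(x, t, problem, t_sp)
  out <- data.frame(x_um = x, t_ms = t, V_mV = v)
  attr(out, "t_sp") <- t_sp
  out
}
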