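#' Dimensionless inflection constant
#'
#' Small-distance limit of the rising-phase inflection time of the impulse
#' response: `t_i = zeta x^2 tau / lam^2` with
#' `zeta = (1 - sqrt(2/3))/2` (about 0.09175).
#'
#' @return The constant `zeta`.
#' @export
sds_zeta <- function() (1 - sqrt(2 / 3)) / 2

#' Inflection time of the impulse-response rising phase (scenario A)
#'
#' Smallest positive root of the truncated second-derivative condition for
#' `U(x, t) = const * t^(-1/2) exp(-x^2 tau/(4 lam^2 t) - t/tau)`:
#' \deqn{t_i = \frac{3 x^2 \tau}{2\lambda^2(3 - 2x^2/\lambda^2)}
#'   \left(1 - \sqrt{1 - \tfrac{1}{9}(3 - 2x^2/\lambda^2)}\right),}
#' reducing to `zeta x^2 tau / lam^2` for `x << lam`.
#'
#' @param x distance from the firing node (um).
#' @param cable an `sds_cable`.
#' @param small_x logical; use the small-distance limit instead of the full
#'   quadratic root.
#' @return Inflection time (ms); `NA` with a warning if the discriminant is
#'   negative (no rising-phase inflection in the truncated expansion).
#' @export
inflection_scenarioA <- function(x, cable, small_x = FALSE) {
  stopifnot(x > 0)
  tau <- cable$tau
  lam <- cable$lam
  if (small_x) return(sds_zeta() * x^2 * tau / lam^2)
  q <- 3 - 2 * x^2 / lam^2
  disc <- 1 - q / 9
  if (disc < 0) {
    warning("negative discriminant: no inflection point in the expansion")
    return(NA_real_)
  }
  3 * x^2 * tau / (2 * lam^2 * q) * (1 - sqrt(disc))
}

#' Inflection time for the exponential current (scenario C)
#'
#' Closed-form approximations of the rising-phase inflection of the
#' exponential-current response, with the branch chosen by the decay
#' constant: for `tau_c < tau` the quadratic root
#' `t_i = (1 - sqrt(1 - 2 x^2 tau/lam^2 (1/tau - 2/tau_c))) /
#' (2(1/tau - 2/tau_c))` (whose `tau_c << tau` limit is
#' `tau_c/4 (sqrt(1 + 4x^2 tau/(lam^2 tau_c)) - 1)`), and for
#' `tau_c > tau` the cable-dominated root
#' `t_i = tau/2 (sqrt(1 + 2x^2/lam^2) - 1)`.
#'
#' @param x distance (um).
#' @param cable an `sds_cable`.
#' @param tau_c current decay constant (ms).
#' @param branch `"auto"` (default, selected by `tau_c` vs `tau`),
#'   `"quadratic"`, `"fast_limit"` or `"slow"`.
#' @return Inflection time (ms).
#' @export
inflection_scenarioC <- function(x, cable, tau_c,
                                 branch = c("auto", "quadratic", "fast_limit",
                                            "slow")) {
  branch <- match.arg(branch)
  stopifnot(x > 0, tau_c > 0)
  tau <- cable$tau
  lam <- cable$lam
  if (branch == "auto") branch <- if (tau_c < tau) "quadratic" else "slow"
  switch(branch,
    quadratic = {
      c0 <- 1 / tau - 2 / tau_c
      disc <- 1 - 2 * x^2 * tau / lam^2 * c0
      if (disc < 0) {
        warning("negative discriminant in scenario-C inflection")
        return(NA_real_)
      }
      (1 - sqrt(disc)) / (2 * c0)
    },
    fast_limit = tau_c / 4 * (sqrt(1 + 4 * x^2 * tau / (lam^2 * tau_c)) - 1),
    slow = tau / 2 * (sqrt(1 + 2 * x^2 / lam^2) - 1)
  )
}

#' Inflection time for the gated current (scenario D)
#'
#' Additive approximation `t_i = t_i,cab + t_i,chan`: the cable part is the
#' large-distance limit of the impulse-response inflection,
#' `t_i,cab = sqrt(2) x tau / (4 lam)`, and the channel part is the
#' inflection of the rising phase of the gated current profile
#' `(1 - e^(-t/tau_m))^gamma e^(-t/tau_h)` (independent of distance).  The
#' channel inflection solves a quadratic in `y = q/(1-q)`, `q = e^(-t/tau_m)`;
#' for `gamma = 1` it reduces to `t_i,chan = 2 tau_m ln(1 + tau_h/tau_m)`.
#'
#' @param x distance (um).
#' @param cable an `sds_cable`.
#' @param model an `sds_current` (supplies `gamma`, `tau_m`, `tau_h`).
#' @return List with `t_i`, `t_i_cab`, `t_i_chan` (ms).
#' @export
inflection_scenarioD <- function(x, cable, model) {
  stopifnot(x > 0)
  t_cab <- sqrt(2) * x * cable$tau / (4 * cable$lam)
  t_chan <- .channel_inflection(model$gamma, model$tau_m, model$tau_h)
  list(t_i = t_cab + t_chan, t_i_cab = t_cab, t_i_chan = t_chan)
}

# inflection of (1-q)^gamma e^{-t/tau2}, q = e^{-t/tau1}: quadratic
# gamma(gamma-1)/tau1^2 y^2 - gamma(1/tau1^2 + 2/(tau1 tau2)) y + 1/tau2^2 = 0
# in y = q/(1-q); the larger y (earlier time) root is the rising-phase
# inflection.
.channel_inflection <- function(gamma, tau1, tau2) {
  if (gamma == 1L) return(2 * tau1 * log(1 + tau2 / tau1))
  A <- gamma * (gamma - 1) / tau1^2
  B <- gamma * (1 / tau1^2 + 2 / (tau1 * tau2))
  C <- 1 / tau2^2
  disc <- B^2 - 4 * A * C
  if (disc < 0) {
    warning("negative discriminant in channel inflection")
    return(NA_real_)
  }
  y <- (B + sqrt(disc)) / (2 * A)
  q <- y / (1 + y)
  -tau1 * log(q)
}

#' Linearised time-to-spike
#'
#' Tangent-line extrapolation of the single-node depolarisation at its
#' rising-phase inflection point:
#' `t_sp = t_i + (V_thr - V(t_i)) / V'(t_i)`.  For scenario A the published
#' closed-form approximations are used for `V(t_i)` and `V'(t_i)`
#' (`V(t_i) = R_lam beta I0 /sqrt(4 pi zeta) * (lam/x) * exp(-1/(4 zeta))`,
#' `V'(t_i) = (2/sqrt(6)) lam^2/(4 zeta^2 x^2 tau) V(t_i)`); scenarios C and
#' D evaluate the exact closed-form response and a central-difference
#' derivative at `t_i`.
#'
#' @param x distance from the firing node (um); typically the effective
#'   internodal spacing.
#' @param params an `sds_params`.
#' @param V_thr firing threshold (mV); defaults to the set's.
#' @param exact_slope logical; for scenario A use numerical `V(t_i)`,
#'   `V'(t_i)` instead of the closed-form approximations.
#' @return Object of class `sds_linear`: `t_i`, `V_i`, `dVdt_i`, `t_sp_lin`,
#'   `zeta`, and a flag `reachable` (FALSE when the tangent line cannot reach
#'   `V_thr`, i.e. `dVdt_i <= 0`).
#' @export
linear_tsp <- function(x, params, V_thr = params$V_thr, exact_slope = FALSE) {
  kernel <- response_kernel(params)
  scen <- params$current$scenario
  cable <- params$cable
  if (scen == "B") scen <- "A"   # same response, shifted; shift added below
  t_i <- switch(scen,
    A = inflection_scenarioA(x, cable),
    C = inflection_scenarioC(x, cable, params$current$tau_c),
    D = inflection_scenarioD(x, cable, params$current)$t_i
  )
  if (is.na(t_i)) {
    return(structure(list(t_i = NA_real_, V_i = NA_real_, dVdt_i = NA_real_,
                          t_sp_lin = NA_real_, zeta = sds_zeta(),
                          reachable = FALSE), class = "sds_linear"))
  }
  U <- function(t) {
    if (params$current$scenario %in% c("A", "B")) response_delta(x, t, kernel)
    else response_multi_exponential(x, t, kernel)
  }
  if (params$current$scenario %in% c("A", "B") && !exact_slope) {
    zeta <- sds_zeta()
    I0_eff <- kernel$Q / kernel$tau   # impulse charge expressed as current
    V_i <- kernel$R_lambda * kernel$beta * I0_eff / sqrt(4 * pi * zeta) *
      (cable$lam / x) * exp(-1 / (4 * zeta))
    dVdt_i <- (2 / sqrt(6)) * cable$lam^2 / (4 * zeta^2 * x^2 * cable$tau) * V_i
  } else {
    h <- 1e-4 * t_i
    V_i <- U(t_i)
    dVdt_i <- (U(t_i + h) - U(t_i - h)) / (2 * h)
  }
  t_sp <- t_i + (V_thr - V_i) / dVdt_i
  if (params$current$scenario == "B") t_sp <- t_sp + params$current$delta
  structure(list(t_i = t_i, V_i = V_i, dVdt_i = dVdt_i, t_sp_lin = t_sp,
                 zeta = sds_zeta(),
                 # the tangent line only extrapolates meaningfully while it
                 # predicts a positive crossing time on a rising branch
                 reachable = dVdt_i > 0 && t_sp > 0),
            class = "sds_linear")
}
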