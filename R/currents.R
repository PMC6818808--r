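#' Threshold-triggered ion channel current model
#'
#' Defines the prescribed current released at a node of Ranvier once the
#' membrane potential crosses threshold.  Four scenarios are supported:
#' \describe{
#'   \item{A}{instantaneous release, a delta impulse at the crossing;}
#'   \item{B}{delta impulse released after a hard delay `delta`;}
#'   \item{C}{instantaneous onset with exponential decay (constant `tau_c`);}
#'   \item{D}{gated profile `(1 - e^(-t/tau_m))^gamma e^(-t/tau_h)`
#'     normalised so its peak equals `I0`, approximating measured sodium
#'     currents; optionally a gated potassium current
#'     `(1 - e^(-t/tau_nK))^4 e^(-t/tau_k)` of opposite sign with peak
#'     density `i_K`.}
#' }
#' Gated profiles are expanded into signed sums of exponentials
#' ([expand_to_exponentials()]), for which the cable equation has closed-form
#' responses.
#'
#' @param scenario one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param I0 peak current density (nA/um^2, internal units).
#' @param delta scenario-B delay (ms).
#' @param tau_c scenario-C decay constant (ms).
#' @param gamma scenario-D activation exponent (integer >= 1).
#' @param tau_m,tau_h sodium activation / inactivation constants (ms).
#' @param tau_nK,tau_k potassium activation / decay constants (ms).
#' @param i_K peak potassium current density (nA/um^2).
#' @param include_potassium logical; add the potassium current (used for
#'   action-potential shapes, not for threshold/velocity computations).
#' @return Object of class `sds_current`.  For scenarios C and D the field
#'   `terms` is a data frame with columns `A` (dimensionless weight,
#'   normalisation included) and `tau_s` (ms) such that the current density
#'   is `I0 * sum(A_s exp(-t/tau_s))` (potassium terms carry `i_K` scaling
#'   and negative sign folded into `A`).
#' @export
current_model <- function(scenario = c("D", "A", "B", "C"),
                          I0, delta = 0.03, tau_c = 0.04,
                          gamma = 1L, tau_m = 0.02, tau_h = 0.04,
                          tau_nK = 0.15, tau_k = 0.3,
                          i_K = 3.75e-3, include_potassium = FALSE) {
  scenario <- match.arg(as.character(scenario), c("D", "A", "B", "C"))
  gamma <- as.integer(gamma)
  stopifnot(gamma >= 1L, I0 > 0, tau_m > 0, tau_h > 0, tau_nK > 0, tau_k > 0)
  terms <- NULL
  if (scenario == "C") {
    terms <- data.frame(A = 1, tau_s = tau_c)
  } else if (scenario == "D") {
    na <- expand_to_exponentials(gamma, tau_m, tau_h)
    C_na <- normalization_na(gamma, tau_m, tau_h)$C
    terms <- data.frame(A = na$A / C_na, tau_s = na$tau_s)
    if (include_potassium) {
      kk <- expand_to_exponentials(4L, tau_nK, tau_k)
      C_k <- normalization_k(tau_nK, tau_k)$C
      terms <- rbind(terms,
                     data.frame(A = -(i_K / I0) * kk$A / C_k, tau_s = kk$tau_s))
    }
  }
  structure(list(scenario = scenario, I0 = I0, delta = delta, tau_c = tau_c,
                 gamma = gamma, tau_m = tau_m, tau_h = tau_h,
                 tau_nK = tau_nK, tau_k = tau_k, i_K = i_K,
                 include_potassium = include_potassium, terms = terms),
            class = "sds_current")
}

# peak value and peak time of the unnormalised gated profile
# (1 - exp(-t/tau1))^gamma * exp(-t/tau2)
.gating_peak <- function(gamma, tau1, tau2) {
  r <- gamma * tau2 / tau1
  t_max <- tau1 * log(r + 1)
  C <- (r / (r + 1))^gamma * (1 / (r + 1))^(tau1 / tau2)
  list(C = C, t_max = t_max)
}

#' Normalisation of the gated sodium current
#'
#' The profile `(1 - e^(-t/tau_m))^gamma e^(-t/tau_h)` peaks at
#' `t_max = tau_m ln(gamma tau_h/tau_m + 1)` with value `C_Na`; dividing by
#' `C_Na` makes the peak current density equal `I0`.
#'
#' @param gamma activation exponent (integer >= 1).
#' @param tau_m,tau_h activation and inactivation constants (ms).
#' @return List with elements `C` (peak value of the unnormalised profile)
#'   and `t_max` (ms).
#' @export
normalization_na <- function(gamma, tau_m, tau_h) {
  stopifnot(gamma >= 1, tau_m > 0, tau_h > 0)
  .gating_peak(gamma, tau_m, tau_h)
}

#' Normalisation of the gated potassium current
#'
#' Same as [normalization_na()] for the fourth-power activation profile
#' `(1 - e^(-t/tau_nK))^4 e^(-t/tau_k)`.
#'
#' @param tau_nK,tau_k potassium activation and decay constants (ms).
#' @return List with elements `C` and `t_max` (ms).
#' @export
normalization_k <- function(tau_nK, tau_k) {
  stopifnot(tau_nK > 0, tau_k > 0)
  .gating_peak(4L, tau_nK, tau_k)
}

#' Expand a gated profile into a signed sum of exponentials
#'
#' Binomial expansion of `(1 - e^(-t/tau_rise))^gamma e^(-t/tau_fall)` into
#' `sum_s A_s exp(-t/tau_s)` with `A_s = choose(gamma, s) (-1)^s` and
#' `tau_s = (s/tau_rise + 1/tau_fall)^(-1)`, `s = 0..gamma`.
#'
#' @param gamma activation exponent (integer >= 1).
#' @param tau_rise,tau_fall rise and fall time constants (ms).
#' @return Data frame with columns `A` and `tau_s`.
#' @export
expand_to_exponentials <- function(gamma, tau_rise, tau_fall) {
  gamma <- as.integer(gamma)
  stopifnot(gamma >= 1L, tau_rise > 0, tau_fall > 0)
  s <- 0:gamma
  data.frame(A = choose(gamma, s) * (-1)^s,
             tau_s = 1 / (s / tau_rise + 1 / tau_fall))
}

#' Evaluate a continuous channel-current profile
#'
#' Returns the current density released by a node that crossed threshold at
#' `t = 0`, for the continuous scenarios C and D (zero for `t < 0`; the
#' delta-impulse scenarios A and B have no pointwise density and raise an
#' error).  For scenario D with `include_potassium = TRUE` the (outward)
#' potassium current is subtracted.
#'
#' @param model an `sds_current`.
#' @param t time since threshold crossing (ms), vectorised.
#' @return Current density in the units of `model$I0` (nA/um^2 internally).
#' @export
current_profile <- function(model, t) {
  if (model$scenario %in% c("A", "B"))
    stop("scenario ", model$scenario,
         " is a delta impulse and has no pointwise density; ",
         "it is handled symbolically by the response functions")
  out <- numeric(length(t))
  pos <- t > 0
  if (!any(pos)) return(out)
  tp <- t[pos]
  if (model$scenario == "C") {
    out[pos] <- model$I0 * exp(-tp / model$tau_c)
  } else {
    v <- numeric(length(tp))
    for (j in seq_len(nrow(model$terms)))
      v <- v + model$terms$A[j] * exp(-tp / model$terms$tau_s[j])
    out[pos] <- model$I0 * v
  }
  out
}
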