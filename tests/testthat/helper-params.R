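# shared fixtures; expensive solves are memoised for the whole run
.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

std_params <- function(scenario = "D", ...) {
  parameter_set("standard", scenario = scenario, ...)
}

fit_params <- function(scenario = "D", ...) {
  parameter_set("fitted", scenario = scenario, ...)
}

std_tsp_D <- function() memo("tsp_D", solve_tsp(propagation_problem(std_params())))

# direct numerical convolution of an exponential cable current with the
# Green's function: independent quadrature oracle for the closed forms
quad_response <- function(x, t, tau_s, kernel, I_term = 1) {
  f <- function(s) {
    exp(-(t - s) / tau_s) / sqrt(4 * pi * kernel$tau * s) *
      exp(-x^2 * kernel$tau / (4 * kernel$lam^2 * s) - s / kernel$tau)
  }
  kernel$R_lambda * kernel$beta * I_term *
    stats::integrate(f, 0, t, rel.tol = 1e-12, abs.tol = 1e-16)$value
}
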