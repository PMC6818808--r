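#' Electrophysiological constants
#'
#' First-principles constants of the model: the capacitance and resistance
#' coefficients of the myelin sheath (treated as a cylindrical capacitor),
#' the axoplasm resistivity, the specific membrane resistance and capacitance
#' of a node of Ranvier, and the peak sodium and potassium current densities.
#' Values are supplied in the units they are usually published in and stored
#' in the internal unit system (see [sds_units()]).
#'
#' @param k1_pF_per_cm myelin capacitance coefficient (pF/cm).
#' @param k2_MOhm_cm myelin resistance coefficient (MOhm cm).
#' @param rho_ax_Ohm_cm axoplasm resistivity (Ohm cm).
#' @param R_n_Ohm_cm2 nodal specific membrane resistance (Ohm cm^2).
#' @param C_n_uF_per_cm2 nodal specific membrane capacitance (uF/cm^2).
#' @param i_Na_pA_per_um2 peak sodium current density (pA/um^2).
#' @param i_K_pA_per_um2 peak potassium current density (pA/um^2).
#' @return Object of class `sds_constants`: internal-unit fields `k1`
#'   (nF/um), `k2` (MOhm um), `rho_ax` (MOhm um), `R_n` (MOhm um^2), `C_n`
#'   (nF/um^2), `i_Na`, `i_K` (nA/um^2).
#' @export
physical_constants <- function(k1_pF_per_cm = 3.6, k2_MOhm_cm = 130,
                               rho_ax_Ohm_cm = 110, R_n_Ohm_cm2 = 33,
                               C_n_uF_per_cm2 = 1, i_Na_pA_per_um2 = 50,
                               i_K_pA_per_um2 = 3.75) {
  vals <- c(k1_pF_per_cm, k2_MOhm_cm, rho_ax_Ohm_cm, R_n_Ohm_cm2,
            C_n_uF_per_cm2, i_Na_pA_per_um2, i_K_pA_per_um2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physical constants must be strictly positive")
  u <- sds_units()
  structure(list(
    k1     = k1_pF_per_cm * u[["pF_per_cm"]],
    k2     = k2_MOhm_cm * u[["MOhm_cm"]],
    rho_ax = rho_ax_Ohm_cm * u[["Ohm_cm"]],
    R_n    = R_n_Ohm_cm2 * u[["Ohm_cm2"]],
    C_n    = C_n_uF_per_cm2 * u[["uF_per_cm2"]],
    i_Na   = i_Na_pA_per_um2 * u[["pA_per_um2"]],
    i_K    = i_K_pA_per_um2 * u[["pA_per_um2"]]
  ), class = "sds_constants")
}

#' Axon geometry
#'
#' @param d axon diameter (um).
#' @param g g-ratio (axon diameter / fibre diameter), in (0, 1).
#' @param L internode length (um); defaults to the standard allometry
#'   `100 * d`.
#' @param l node of Ranvier length (um).
#' @param N number of contributing nodes on each side of the reference node.
#' @return Object of class `sds_geometry` with fields `d`, `g`, `L`, `l`,
#'   `N` and the fibre diameter `D = d/g`.
#' @export
axon_geometry <- function(d = 1, g = 0.6, L = 100 * d, l = 1, N = 1000L) {
  if (!is.finite(d) || d <= 0) stop("axon diameter d must be positive")
  if (!is.finite(g) || g <= 0 || g >= 1) stop("g-ratio must lie in (0, 1)")
  if (!is.finite(L) || L < 0) stop("internode length L must be >= 0")
  if (!is.finite(l) || l <= 0) stop("node length l must be positive")
  N <- as.integer(N)
  if (N < 1L) stop("N must be at least 1")
  structure(list(d = d, g = g, L = L, l = l, N = N, D = d / g),
            class = "sds_geometry")
}

#' Derive internodal cable parameters from geometry and constants
#'
#' The myelinated internode is a passive cable with radial capacitance
#' `C_m = k1 / ln(1/g)`, radial resistance `R_m = k2 * ln(1/g)`, and axial
#' resistance `R_c = 4 rho_ax / (pi d^2)`.  The membrane time constant
#' `tau = C_m R_m = k1 k2` is independent of both diameter and g-ratio, and
#' the electrotonic length constant is `lam = sqrt(R_m / R_c)`.
#'
#' @param geometry an [axon_geometry()].
#' @param constants a [physical_constants()].
#' @param lam_coef optional length-constant coefficient (um per um of
#'   diameter per sqrt-log unit); when supplied, `lam = lam_coef * d *
#'   sqrt(ln(1/g))` replaces the first-principles value (used by the fitted
#'   parameter set).
#' @param tau optional override of the time constant (ms), likewise for the
#'   fitted set.
#' @return Object of class `sds_cable` with fields `tau` (ms), `lam` (um),
#'   `R_m` (MOhm um), `C_m` (nF/um), `R_c` (MOhm/um) and `R_lambda = R_m /
#'   lam` (MOhm).
#' @export
derive_cable_parameters <- function(geometry, constants = physical_constants(),
                                    lam_coef = NULL, tau = NULL) {
  g <- geometry$g
  d <- geometry$d
  lg <- log(1 / g)
  C_m <- constants$k1 / lg
  R_m <- constants$k2 * lg
  R_c <- 4 * constants$rho_ax / (pi * d^2)
  lam <- if (is.null(lam_coef)) sqrt(R_m / R_c) else lam_coef * d * sqrt(lg)
  tau <- if (is.null(tau)) C_m * R_m else tau
  structure(list(tau = tau, lam = lam, R_m = R_m, C_m = C_m, R_c = R_c,
                 R_lambda = R_m / lam),
            class = "sds_cable")
}

#' Medium constants implied by the cable coefficients
#'
#' Inverts the cylindrical-capacitor relations `C_m = 2 pi eps / ln(1/g)`
#' and `R_m = rho ln(1/g) / (2 pi)` to recover the permittivity and
#' resistivity of the myelin from the published coefficients `k1`, `k2`.
#'
#' @param constants a [physical_constants()].
#' @return Named numeric vector: `permittivity` (s Ohm^-1 m^-1) and
#'   `resistivity` (Ohm m).
#' @export
derive_medium_constants <- function(constants = physical_constants()) {
  u <- sds_units()
  k1_pF_cm <- constants$k1 / u[["pF_per_cm"]]
  k2_MOhm_cm <- constants$k2 / u[["MOhm_cm"]]
  # pF/cm -> F/m: 1e-12 F / 1e-2 m = 1e-10;  MOhm cm -> Ohm m: 1e6 * 1e-2
  c(permittivity = k1_pF_cm * 1e-10 / (2 * pi),
    resistivity = 2 * pi * k2_MOhm_cm * 1e4)
}

#' Derive nodal parameters
#'
#' A node of Ranvier of length `l` on an axon of diameter `d` has membrane
#' area `pi d l`, giving a total radial resistance `R_node = R_n / (pi d l)`
#' and a time constant `tau_node = R_n C_n` independent of geometry.  The
#' fraction of nodal channel current that enters the axial cable (rather than
#' leaking back across the nodal membrane) is
#' `beta = 1 / (1 + R_lambda / (2 R_node))`.
#'
#' The nodal length constant defaults to the published tabulated scaling
#' `lam_node = 38.9 sqrt(d / um) um`; `lam_node_method = "derived"` uses the
#' first-principles value `sqrt(R_n d / (4 rho_ax))` instead (about a factor
#' sqrt(2) smaller), and `lam_node_coef` overrides the tabulated coefficient
#' (the fitted parameter set uses 48.1).
#'
#' @param geometry an [axon_geometry()].
#' @param constants a [physical_constants()].
#' @param cable an `sds_cable` from [derive_cable_parameters()].
#' @param lam_node_coef coefficient of `sqrt(d)` in um (default 38.9).
#' @param lam_node_method `"table"` (default) or `"derived"`.
#' @param tau_node optional override of the nodal time constant (ms).
#' @return Object of class `sds_node` with fields `tau_node` (ms),
#'   `lam_node` (um), `R_node` (MOhm), `beta`, and `v_node` (m/s, `NA` until
#'   computed by [unmyelinated_velocity()] / [conduction_velocity()]).
#' @export
derive_node_parameters <- function(geometry, constants, cable,
                                   lam_node_coef = 38.9,
                                   lam_node_method = c("table", "derived"),
                                   tau_node = NULL) {
  lam_node_method <- match.arg(lam_node_method)
  d <- geometry$d
  l <- geometry$l
  lam_node <- switch(lam_node_method,
    table = lam_node_coef * sqrt(d),
    derived = sqrt(constants$R_n * d / (4 * constants$rho_ax))
  )
  R_node <- constants$R_n / (pi * d * l)
  structure(list(
    tau_node = if (is.null(tau_node)) constants$R_n * constants$C_n else tau_node,
    lam_node = lam_node,
    R_node = R_node,
    beta = 1 / (1 + cable$R_lambda / (2 * R_node)),
    v_node = NA_real_
  ), class = "sds_node")
}

# label-specific defaults (times in ms, current densities in nA/um^2 after
# conversion); fitted values override the first-principles derivations.
.set_defaults <- function(label) {
  u <- sds_units()
  if (label == "standard") {
    list(d = 1, g = 0.6, lam_coef = NULL, tau = NULL,
         lamn_coef = 38.9, tau_node = NULL,
         tau_m = 20 * u[["us"]], tau_h = 40 * u[["us"]],
         tau_nK = 150 * u[["us"]], tau_k = 300 * u[["us"]],
         I0 = 50 * u[["pA_per_um2"]], V_thr = 15)
  } else {
    list(d = 0.73, g = 0.81, lam_coef = 1200, tau = 1.45,
         lamn_coef = 48.1, tau_node = 20 * u[["us"]],
         tau_m = 70 * u[["us"]], tau_h = 160 * u[["us"]],
         tau_nK = 150 * u[["us"]], tau_k = 300 * u[["us"]],
         I0 = 200 * u[["pA_per_um2"]], V_thr = 4)
  }
}

#' Assemble a full model parameter set
#'
#' Packages the two published parameter columns: `"standard"`
#' (first-principles electrophysiological constants, d = 1 um, g = 0.6,
#' V_thr = 15 mV, gated-current constants tau_m = 20 us, tau_h = 40 us,
#' I0 = 50 pA/um^2) and `"fitted"` (calibrated against a biophysically
#' detailed cortex model: d = 0.73 um, g = 0.81, tau = 1.45 ms,
#' lam = 1200 d sqrt(ln(1/g)) um, lam_node = 48.1 sqrt(d) um, tau_node =
#' 20 us, tau_m = 70 us, tau_h = 160 us, I0 = 200 pA/um^2, V_thr = 4 mV).
#' Geometry, scenario and current parameters can be overridden; derived
#' cable and node parameters are recomputed accordingly.
#'
#' @param label `"standard"` or `"fitted"`.
#' @param scenario ion-current scenario, see [current_model()].
#' @param d,g,L,l,N geometry overrides (um; `N` nodes per side).
#' @param V_thr firing threshold (mV).
#' @param I0_pA_per_um2 peak channel current density (pA/um^2); defaults to
#'   the label value for scenario C/D and to the instantaneous-current
#'   calibration 6.6 pA/um^2 for scenarios A and B.
#' @param delta_us scenario-B release delay (us).
#' @param tau_c_us scenario-C decay constant (us).  Default `NULL`: matched
#'   so the exponential current carries the same total charge as the gated
#'   sodium current at equal peak density (about 69 us for the standard
#'   constants), making scenarios C and D comparable.
#' @param gamma scenario-D activation exponent (integer >= 1).
#' @param include_potassium add the gated potassium current to scenario-D
#'   voltage traces (excluded from threshold computations by default).
#' @param constants a [physical_constants()].
#' @param lam_node_method see [derive_node_parameters()].
#' @return Object of class `sds_params`, a list with elements `label`,
#'   `constants`, `geometry`, `cable`, `node`, `current` and `V_thr`.
#' @examples
#' p <- parameter_set("standard")
#' p$cable$tau          # 0.468 ms
#' @export
parameter_set <- function(label = c("standard", "fitted"),
                          scenario = "D",
                          d = NULL, g = NULL, L = NULL, l = 1, N = 1000L,
                          V_thr = NULL, I0_pA_per_um2 = NULL,
                          delta_us = 30, tau_c_us = NULL, gamma = 1L,
                          include_potassium = FALSE,
                          constants = physical_constants(),
                          lam_node_method = "table") {
  label <- match.arg(label)
  def <- .set_defaults(label)
  d <- if (is.null(d)) def$d else d
  g <- if (is.null(g)) def$g else g
  L <- if (is.null(L)) 100 * d else L
  V_thr <- if (is.null(V_thr)) def$V_thr else V_thr
  geometry <- axon_geometry(d = d, g = g, L = L, l = l, N = N)
  cable <- derive_cable_parameters(geometry, constants,
                                   lam_coef = def$lam_coef, tau = def$tau)
  node <- derive_node_parameters(geometry, constants, cable,
                                 lam_node_coef = def$lamn_coef,
                                 lam_node_method = lam_node_method,
                                 tau_node = def$tau_node)
  u <- sds_units()
  if (is.null(I0_pA_per_um2)) {
    I0 <- if (scenario %in% c("A", "B")) 6.6 * u[["pA_per_um2"]] else def$I0
  } else {
    I0 <- I0_pA_per_um2 * u[["pA_per_um2"]]
  }
  if (is.null(tau_c_us)) {
    # charge-matched exponential: same total charge as the gated Na current
    ex <- expand_to_exponentials(gamma, def$tau_m, def$tau_h)
    tau_c <- sum(ex$A * ex$tau_s) / normalization_na(gamma, def$tau_m, def$tau_h)$C
  } else {
    tau_c <- tau_c_us * u[["us"]]
  }
  current <- current_model(
    scenario = scenario, I0 = I0,
    delta = delta_us * u[["us"]], tau_c = tau_c,
    gamma = gamma, tau_m = def$tau_m, tau_h = def$tau_h,
    tau_nK = def$tau_nK, tau_k = def$tau_k,
    i_K = constants$i_K, include_potassium = include_potassium
  )
  structure(list(label = label, constants = constants, geometry = geometry,
                 cable = cable, node = node, current = current,
                 V_thr = V_thr,
                 lam_coef = def$lam_coef, lamn_coef = def$lamn_coef,
                 tau_override = def$tau, tau_node_override = def$tau_node,
                 lam_node_method = lam_node_method),
            class = "sds_params")
}

#' Re-derive a parameter set for new geometry
#'
#' Changes any of `d`, `g`, `L`, `l`, `N` and recomputes the cable and node
#' parameters, preserving the label-specific overrides (fitted lam
#' coefficient and time constants).  The cached nodal conduction velocity is
#' invalidated when `d` or `l` changes.
#'
#' @param params an `sds_params`.
#' @param d,g,L,l,N new geometry values (unchanged if missing; `L` tracks
#'   `100 d` if `d` changes and `L` is not given explicitly).
#' @return Updated `sds_params`.
#' @export
set_geometry <- function(params, d = NULL, g = NULL, L = NULL, l = NULL,
                         N = NULL) {
  geo <- params$geometry
  new_d <- if (is.null(d)) geo$d else d
  new_g <- if (is.null(g)) geo$g else g
  new_L <- if (!is.null(L)) L else if (!is.null(d)) 100 * new_d else geo$L
  new_l <- if (is.null(l)) geo$l else l
  new_N <- if (is.null(N)) geo$N else N
  geometry <- axon_geometry(new_d, new_g, new_L, new_l, new_N)
  cable <- derive_cable_parameters(geometry, params$constants,
                                   lam_coef = params$lam_coef,
                                   tau = params$tau_override)
  node <- derive_node_parameters(geometry, params$constants, cable,
                                 lam_node_coef = params$lamn_coef,
                                 lam_node_method = params$lam_node_method,
                                 tau_node = params$tau_node_override)
  if (new_d == geo$d && new_l == geo$l) node$v_node <- params$node$v_node
  params$geometry <- geometry
  params$cable <- cable
  params$node <- node
  params
}

#' @export
print.sds_params <- function(x, ...) {
  u <- sds_units()
  cat(sprintf("<sds_params '%s'> scenario %s\n", x$label, x$current$scenario))
  cat(sprintf("  geometry: d=%.3g um, g=%.3g, L=%.4g um, l=%.3g um, N=%d\n",
              x$geometry$d, x$geometry$g, x$geometry$L, x$geometry$l,
              x$geometry$N))
  cat(sprintf("  cable:    tau=%.4g ms, lambda=%.4g um, R_lambda=%.4g MOhm\n",
              x$cable$tau, x$cable$lam, x$cable$R_lambda))
  cat(sprintf("  node:     tau_n=%.3g us, lambda_n=%.4g um, beta=%.4g\n",
              x$node$tau_node / u[["us"]], x$node$lam_node, x$node$beta))
  cat(sprintf("  threshold: V_thr=%.3g mV, I0=%.4g pA/um^2\n",
              x$V_thr, x$current$I0 / u[["pA_per_um2"]]))
  invisible(x)
}

# --- flat key-value config ---------------------------------------------------

.config_keys <- c("label", "d_um", "g_ratio", "L_um", "l_um", "N_nodes",
                  "V_thr_mV", "I0_pA_per_um2", "tau_m_us", "tau_h_us",
                  "tau_nK_us", "tau_k_us", "scenario", "delta_us",
                  "tau_c_us", "gamma", "include_potassium", "rho_density")

#' Write a parameter set to a flat key-value config file
#'
#' @param params an `sds_params`.
#' @param path output file path.
#' @param rho_density relative channel density for unmyelinated-axon runs.
#' @return `path`, invisibly.
#' @export
write_sds_config <- function(params, path, rho_density = 1) {
  u <- sds_units()
  cur <- params$current
  kv <- c(
    label = params$label,
    d_um = params$geometry$d, g_ratio = params$geometry$g,
    L_um = params$geometry$L, l_um = params$geometry$l,
    N_nodes = params$geometry$N,
    V_thr_mV = params$V_thr,
    I0_pA_per_um2 = cur$I0 / u[["pA_per_um2"]],
    tau_m_us = cur$tau_m / u[["us"]], tau_h_us = cur$tau_h / u[["us"]],
    tau_nK_us = cur$tau_nK / u[["us"]], tau_k_us = cur$tau_k / u[["us"]],
    scenario = cur$scenario, delta_us = cur$delta / u[["us"]],
    tau_c_us = cur$tau_c / u[["us"]], gamma = cur$gamma,
    include_potassium = tolower(as.character(cur$include_potassium)),
    rho_density = rho_density
  )
  writeLines(paste(names(kv), unname(kv), sep = " = "), path)
  invisible(path)
}

#' Read a parameter set from a flat key-value config file
#'
#' @param path config file with one `key = value` pair per line; `#` starts
#'   a comment.  Unknown keys raise an error naming them.
#' @return List with elements `params` (an `sds_params`) and `rho_density`.
#' @export
read_sds_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(parts, `[`, "", 1))
  vals <- trimws(vapply(parts, `[`, "", 2))
  unknown <- setdiff(keys, .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  kv <- stats::setNames(as.list(vals), keys)
  num <- function(key, default = NULL) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  label <- if (is.null(kv$label)) "standard" else kv$label
  params <- parameter_set(
    label = label,
    scenario = if (is.null(kv$scenario)) "D" else kv$scenario,
    d = num("d_um"), g = num("g_ratio"), L = num("L_um"),
    l = num("l_um", 1), N = as.integer(num("N_nodes", 1000)),
    V_thr = num("V_thr_mV"), I0_pA_per_um2 = num("I0_pA_per_um2"),
    delta_us = num("delta_us", 30), tau_c_us = num("tau_c_us"),
    gamma = as.integer(num("gamma", 1)),
    include_potassium = isTRUE(tolower(kv$include_potassium %||% "false") == "true")
  )
  # current-model time-constant overrides, if present
  u <- sds_units()
  cur <- params$current
  if (!is.null(kv$tau_m_us)) cur$tau_m <- num("tau_m_us") * u[["us"]]
  if (!is.null(kv$tau_h_us)) cur$tau_h <- num("tau_h_us") * u[["us"]]
  if (!is.null(kv$tau_nK_us)) cur$tau_nK <- num("tau_nK_us") * u[["us"]]
  if (!is.null(kv$tau_k_us)) cur$tau_k <- num("tau_k_us") * u[["us"]]
  params$current <- current_model(
    scenario = cur$scenario, I0 = cur$I0, delta = cur$delta,
    tau_c = cur$tau_c, gamma = cur$gamma, tau_m = cur$tau_m,
    tau_h = cur$tau_h, tau_nK = cur$tau_nK, tau_k = cur$tau_k,
    i_K = params$constants$i_K, include_potassium = cur$include_potassium
  )
  list(params = params, rho_density = num("rho_density", 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
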