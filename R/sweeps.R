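#' Velocity sweep over geometry and scenario grids
#'
#' Computes the conduction velocity on the Cartesian grid of the supplied
#' parameter values.  Solver failures (threshold never reached) are recorded
#' as rows with `converged = FALSE`, not dropped.  The within-node velocity
#' is cached per unique `(d, l)` pair, so g-ratio and internode-length
#' sweeps re-use it.
#'
#' @param params base `sds_params`; each grid point re-derives the dependent
#'   cable and node parameters via [set_geometry()].
#' @param d,g,L,l,N grid values (vectors); defaults are the base set's
#'   single values.  `L = NA` tracks `100 d`.
#' @param scenario scenario values to sweep (character vector).
#' @param corrected apply the node-velocity correction.
#' @return Data frame with columns `d_um`, `g_ratio`, `L_um`, `l_um`, `N`,
#'   `scenario`, `t_sp_ms`, `v_mps`, `converged`.
#' @export
sweep_velocity <- function(params, d = params$geometry$d,
                           g = params$geometry$g, L = NA,
                           l = params$geometry$l, N = params$geometry$N,
                           scenario = params$current$scenario,
                           corrected = TRUE) {
  grid <- expand.grid(d = d, g = g, L = L, l = l, N = N,
                      scenario = scenario, stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gi <- grid[i, ]
    Li <- if (is.na(gi$L)) 100 * gi$d else gi$L
    p <- set_geometry(params, d = gi$d, g = gi$g, L = Li, l = gi$l,
                      N = gi$N)
    if (gi$scenario != params$current$scenario) {
      cur <- p$current
      p$current <- current_model(scenario = gi$scenario, I0 = cur$I0,
                                 delta = cur$delta, tau_c = cur$tau_c,
                                 gamma = cur$gamma, tau_m = cur$tau_m,
                                 tau_h = cur$tau_h, tau_nK = cur$tau_nK,
                                 tau_k = cur$tau_k, i_K = p$constants$i_K,
                                 include_potassium = cur$include_potassium)
    }
    res <- conduction_velocity(propagation_problem(p), corrected = corrected)
    out[[i]] <- data.frame(d_um = gi$d, g_ratio = gi$g, L_um = Li,
                           l_um = gi$l, N = gi$N, scenario = gi$scenario,
                           t_sp_ms = res$t_sp, v_mps = res$v_corrected_mps,
                           converged = res$converged)
  }
  do.call(rbind, out)
}

#' Fit the g-ratio power law of the conduction velocity
#'
#' The length constant of the internodal cable scales with `sqrt(ln(1/g))`;
#' classical theory assumed the velocity follows the same square-root law.
#' This fits the generalised power law `v = kappa (ln(1/g))^alpha` to
#' velocities computed at fixed axon diameter over a grid of g-ratios, by
#' nonlinear least squares with deterministic initialisation (`alpha = 0.5`,
#' `kappa` from the first grid point).
#'
#' @param params base `sds_params` (fixed axon diameter taken from it).
#' @param g_grid g-ratio grid (at least 5 points in (0, 1)); default 26
#'   points on \[0.5, 0.9\].
#' @param fit_mode `"fit_both"` (fit `kappa` and `alpha`) or `"fixed_half"`
#'   (classical `alpha = 0.5`, fit `kappa` only).
#' @param corrected apply the node-velocity correction to the sweep.
#' @param v_mps optional pre-computed velocities matching `g_grid`; when
#'   supplied the sweep is skipped and only the fit is performed.
#' @return Object of class `sds_gfit`: `kappa` (m/s), `alpha_exp`,
#'   `fit_mode`, `g_grid`, `v_mps`, `residual_norm`.
#' @export
fit_gratio_exponent <- function(params, g_grid = seq(0.5, 0.9, length.out = 26),
                                fit_mode = c("fit_both", "fixed_half"),
                                corrected = TRUE, v_mps = NULL) {
  fit_mode <- match.arg(fit_mode)
  if (length(g_grid) < 5 || any(g_grid <= 0) || any(g_grid >= 1))
    stop("g_grid must contain at least 5 values in (0, 1)")
  if (length(unique(g_grid)) < 5) stop("degenerate g grid")
  if (is.null(v_mps)) {
    sweep <- sweep_velocity(params, g = g_grid, L = params$geometry$L,
                            corrected = corrected)
    if (any(!sweep$converged)) stop("velocity solve failed on the g grid")
    v <- sweep$v_mps
    s <- log(1 / sweep$g_ratio)
  } else {
    if (length(v_mps) != length(g_grid)) stop("v_mps must match g_grid")
    v <- v_mps
    s <- log(1 / g_grid)
  }
  if (fit_mode == "fixed_half") {
    basis <- sqrt(s)
    kappa <- sum(v * basis) / sum(basis^2)
    alpha <- 0.5
    resid <- v - kappa * basis
  } else {
    kappa0 <- v[1] / sqrt(s[1])
    fit <- minpack.lm::nlsLM(v ~ kappa * s^alpha,
                             data = data.frame(v = v, s = s),
                             start = list(kappa = kappa0, alpha = 0.5),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    kappa <- stats::coef(fit)[["kappa"]]
    alpha <- stats::coef(fit)[["alpha"]]
    resid <- stats::residuals(fit)
  }
  structure(list(kappa = kappa, alpha_exp = alpha, fit_mode = fit_mode,
                 g_grid = g_grid, v_mps = v,
                 residual_norm = sqrt(sum(resid^2))),
            class = "sds_gfit")
}

#' @export
print.sds_gfit <- function(x, ...) {
  cat(sprintf("<sds_gfit> v = kappa (ln(1/g))^alpha: kappa = %.4g m/s, alpha = %.4g (%s)\n",
              x$kappa, x$alpha_exp, x$fit_mode))
  invisible(x)
}

#' Run a computation described by a key-value config file
#'
#' Reads a flat config file (see [read_sds_config()], plus the dispatch keys
#' `command` -- one of `velocity`, `sweep`, `ephaptic`, `fit_g`, `profile` --
#' and, for sweeps, comma-separated grid keys `sweep_d_um`, `sweep_g_ratio`,
#' `sweep_L_um`, `sweep_l_um`; for ephaptic runs `dt_in_ms`), executes the
#' corresponding analysis and writes a CSV result plus a JSON provenance
#' sidecar (inputs echoed, package version, timestamp) next to it.
#'
#' @param config_file path to the config file.
#' @param out_dir output directory (created if needed).
#' @param stem basename for the outputs (default: config file name).
#' @return Invisible list with `result` (data frame), `csv`, `sidecar`.
#' @export
run_config <- function(config_file, out_dir = ".",
                       stem = sub("\\.[^.]*$", "", basename(config_file))) {
  lines <- readLines(config_file, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(parts, `[`, "", 1))
  vals <- trimws(vapply(parts, `[`, "", 2))
  kv <- stats::setNames(as.list(vals), keys)
  extra_keys <- c("command", "sweep_d_um", "sweep_g_ratio", "sweep_L_um",
                  "sweep_l_um", "dt_in_ms")
  unknown <- setdiff(keys, c(.config_keys, extra_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  command <- kv$command %||% "velocity"
  # parameter keys go through the config reader
  base_lines <- lines[keys %in% .config_keys]
  tmp <- tempfile(fileext = ".cfg")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(base_lines, tmp)
  cfg <- read_sds_config(tmp)
  params <- cfg$params
  splitnum <- function(key) as.numeric(strsplit(kv[[key]], ",")[[1]])
  result <- switch(command,
    velocity = {
      res <- conduction_velocity(propagation_problem(params))
      data.frame(d_um = params$geometry$d, g_ratio = params$geometry$g,
                 L_um = params$geometry$L, l_um = params$geometry$l,
                 N = params$geometry$N, t_sp_ms = res$t_sp,
                 v_mps = res$v_corrected_mps,
                 v_internode_mps = res$v_internode_mps,
                 converged = res$converged)
    },
    sweep = sweep_velocity(params,
      d = if (!is.null(kv$sweep_d_um)) splitnum("sweep_d_um") else params$geometry$d,
      g = if (!is.null(kv$sweep_g_ratio)) splitnum("sweep_g_ratio") else params$geometry$g,
      L = if (!is.null(kv$sweep_L_um)) splitnum("sweep_L_um") else NA,
      l = if (!is.null(kv$sweep_l_um)) splitnum("sweep_l_um") else params$geometry$l),
    ephaptic = {
      dt_in <- as.numeric(kv$dt_in_ms %||% "0.02")
      b <- ephaptic_bundle(params)
      st <- entrainment_step(b, dt_in)
      pv <- paired_velocity(b)
      data.frame(dt_in_ms = dt_in, dt_out_ms = st$dt_out,
                 t_pair_ms = st$t_pair, v_pair_mps = pv$v_pair_mps,
                 v_single_mps = pv$v_single_mps)
    },
    fit_g = {
      fit <- fit_gratio_exponent(params)
      data.frame(kappa_mps = fit$kappa, alpha = fit$alpha_exp,
                 fit_mode = fit$fit_mode, residual_norm = fit$residual_norm)
    },
    profile = {
      prob <- propagation_problem(params)
      action_potential_trace(prob)
    },
    stop("unknown command: ", command)
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, paste0(stem, ".csv"))
  utils::write.csv(result, csv, row.names = FALSE)
  sidecar <- file.path(out_dir, paste0(stem, ".json"))
  jsonlite::write_json(list(
    inputs = kv,
    command = command,
    package = "sdspike",
    version = as.character(utils::packageVersion("sdspike")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(result = result, csv = csv, sidecar = sidecar))
}
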