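# Transfer function: semi-analytic population input -> output rate map
# F(nu_e, nu_i, W) for RS and FS AdEx cells. The mean conductances and mean
# membrane potential follow the analytic formulas; the membrane-potential SD
# sigma_V and autocorrelation time tau_V follow the shot-noise expressions of
# the mean-field lineage this model belongs to; the output rate is
#   nu_out = 1/(2 tau_V) * erfc((V_thr_eff - mu_V) / (sqrt(2) sigma_V)),
# with V_thr_eff a fitted second-order polynomial (10 coefficients) in the
# rescaled (mu_V, sigma_V, tau_V g_L / c_m). The polynomial is calibrated
# against single-neuron AdEx simulations under Poisson bombardment, so small
# inaccuracies of the auxiliary moment formulas are absorbed by the fit.

tf_cpp_list <- function(tf) {
  p <- tf$params
  list(g_L = p$g_L, c_m = p$c_m,
       E_L = if (tf$population == "FS") p$E_L_i else p$E_L_e,
       E_e = p$E_e, E_i = p$E_i, Q_e = p$Q_e, Q_i = p$Q_i,
       u_e = p$u_e, u_i = p$u_i, K_e = tf$K_e, K_i = tf$K_i,
       T_refr = p$T_refr, P = tf$P)
}

#' Mean synaptic conductances and membrane-potential moments
#'
#' Computes, for given presynaptic rates and adaptation current, the mean
#' excitatory/inhibitory synaptic conductances
#' `mu_Ge = nu_e K_e u_e Q_e` (rates in kHz internally), the total input
#' conductance, the mean membrane potential
#' `mu_V = (mu_Ge E_e + mu_Gi E_i + g_L E_L - W) / (mu_Ge + mu_Gi + g_L)`
#' (adaptation enters as a subtractive current), and the fluctuation
#' statistics `sigma_V` and `tau_V` used by the transfer function.
#'
#' @param nu_e,nu_i presynaptic excitatory/inhibitory rates, Hz (vectors
#'   recycled to common length).
#' @param W adaptation current, pA.
#' @param params an [adex_params()] object.
#' @param population `"RS"` or `"FS"` (selects the leak reversal).
#' @param K_e,K_i synapse counts per neuron (defaults 400 and 100, i.e.
#'   `p * N_e` and `p * N_i` at network defaults).
#' @return data.frame with columns `mu_Ge`, `mu_Gi`, `mu_G` (nS), `mu_V`,
#'   `sigma_V` (mV), `tau_V` (ms), plus `K_e`, `K_i`.
#' @examples
#' conductance_moments(nu_e = 4, nu_i = 0, W = 0)$mu_Ge  # = 12 nS
#' @export
conductance_moments <- function(nu_e, nu_i, W = 0, params = adex_params(),
                                population = c("RS", "FS"), K_e = 400,
                                K_i = 100) {
  population <- match.arg(population)
  if (any(nu_e < 0) || any(nu_i < 0)) stop("rates must be non-negative")
  n <- max(length(nu_e), length(nu_i), length(W))
  nu_e <- rep_len(nu_e, n); nu_i <- rep_len(nu_i, n); W <- rep_len(W, n)
  tf <- list(params = params, population = population, K_e = K_e, K_i = K_i,
             P = numeric(10))
  out <- voltage_moments_cpp(hz2khz(nu_e), hz2khz(nu_i), W, tf_cpp_list(tf))
  # report exact zero-input limit without the internal rate floor
  zero <- nu_e == 0 & nu_i == 0 & W == 0
  if (any(zero)) {
    out$mu_Ge[zero] <- 0; out$mu_Gi[zero] <- 0
    out$mu_G[zero] <- params$g_L
    out$mu_V[zero] <- if (population == "FS") params$E_L_i else params$E_L_e
  }
  out$K_e <- K_e; out$K_i <- K_i
  out
}

new_tf <- function(population, params, K_e, K_i, P, fit = NULL) {
  structure(list(population = population, params = params, K_e = K_e,
                 K_i = K_i, P = as.numeric(P), fit = fit),
            class = "adex_tf")
}

#' @export
print.adex_tf <- function(x, ...) {
  cat(sprintf("adex_tf: %s population, K_e = %g, K_i = %g\n",
              x$population, x$K_e, x$K_i))
  cat("  P =", signif(x$P, 4), "\n")
  if (!is.null(x$fit))
    cat(sprintf("  fit: %d grid points, residual RMS %.3f Hz\n",
                x$fit$n_points, x$fit$rms_hz))
  invisible(x)
}

#' Evaluate a fitted transfer function
#'
#' @param tf an `adex_tf` object (from [fit_tf()] or [default_tf()]).
#' @param nu_e,nu_i input rates, Hz.
#' @param W adaptation current, pA.
#' @return Output rate(s), Hz, clipped to `[0, 1000 / T_refr]`.
#' @export
evaluate_tf <- function(tf, nu_e, nu_i, W = 0) {
  stopifnot(inherits(tf, "adex_tf"))
  if (all(tf$P == 0)) stop("transfer function has not been fitted")
  n <- max(length(nu_e), length(nu_i), length(W))
  khz2hz(tf_rate_cpp(hz2khz(rep_len(nu_e, n)), hz2khz(rep_len(nu_i, n)),
                     rep_len(W, n), tf_cpp_list(tf)))
}

erfcinv <- function(y) -qnorm(y / 2) / sqrt(2)

#' Fit a transfer function against single-neuron AdEx simulations
#'
#' For each point of a (nu_e, nu_i, W) grid, one AdEx neuron is bombarded by
#' `K_e` and `K_i` independent Poisson trains with the adaptation current
#' frozen at W, and its stationary output rate is measured (averaged over
#' `n_rep` repetitions). The effective-threshold polynomial is initialized
#' by linear inversion of the rate formula at points with measurable output
#' and refined by weighted least squares on the predicted-vs-measured
#' rates; the weights (`1 / (1 + (rate / weight_scale)^2)`) emphasize the
#' fluctuation-driven operating region over the mean-driven corner that
#' the coupled model never visits. The stored residual RMS refers to the
#' operating region (measured output below 30 Hz).
#'
#' @param params an [adex_params()] object.
#' @param population `"RS"` (excitatory, adaptation levels matter) or
#'   `"FS"` (inhibitory, fitted at W = 0).
#' @param nu_e_grid,nu_i_grid input-rate grids, Hz.
#' @param W_grid adaptation levels, pA (default `c(0, 50, 100)` for RS,
#'   `0` for FS).
#' @param sim_time simulated time per grid point, ms.
#' @param transient discarded onset per point, ms.
#' @param n_rep neurons averaged per point.
#' @param dt integration step, ms.
#' @param seed integer seed.
#' @param rms_tol operating-region residual-RMS tolerance, Hz; a worse fit
#'   triggers a warning with diagnostics (never silent).
#' @param weight_scale rate scale of the loss weights, Hz.
#' @param K_e,K_i synapse counts per neuron (as in
#'   [conductance_moments()]).
#' @return An `adex_tf` object with fitted coefficients and fit metadata
#'   (grid, measured rates, residual RMS, seed).
#' @export
fit_tf <- function(params = adex_params(), population = c("RS", "FS"),
                   nu_e_grid = c(0, 0.5, 1, 2, 3, 4, 6, 8, 10, 13, 17, 25,
                                 40),
                   nu_i_grid = c(0, 1, 2, 4, 6, 9, 12, 16, 20, 25, 30, 35,
                                 40),
                   W_grid = NULL, sim_time = 10000, transient = 1000,
                   n_rep = 20, dt = 0.1, seed = 1, rms_tol = 1,
                   weight_scale = 20, K_e = 400, K_i = 100) {
  population <- match.arg(population)
  W_grid <- W_grid %||% (if (population == "RS") c(0, 50, 100) else 0)
  grid <- expand.grid(nu_e = nu_e_grid, nu_i = nu_i_grid, W = W_grid)
  set.seed(seed)
  rates <- sim_single_neuron_rates_cpp(unclass(params),
                                       population == "FS",
                                       hz2khz(grid$nu_e), hz2khz(grid$nu_i),
                                       grid$W, K_e, K_i, sim_time, transient,
                                       dt, as.integer(n_rep))
  if (all(rates == 0))
    stop("degenerate fit: all simulated grid rates are zero")
  tf0 <- new_tf(population, params, K_e, K_i, numeric(10))
  mom <- voltage_moments_cpp(hz2khz(grid$nu_e), hz2khz(grid$nu_i), grid$W,
                             tf_cpp_list(tf0))
  x1 <- (mom$mu_V + 60) / 10
  x2 <- (mom$sigma_V - 4) / 6
  x3 <- (mom$tau_V * params$g_L / params$c_m - 0.5) / 1
  X <- cbind(1, x1, x2, x3, x1^2, x1 * x2, x1 * x3, x2^2, x2 * x3, x3^2)

  cap <- 1 / params$T_refr  # kHz
  inv <- rates > 1e-5 & rates < 0.95 * cap &
    2 * mom$tau_V * rates < 1.98  # erfc inversion must stay in range
  if (sum(inv) < 12) inv <- rates > 0 & 2 * mom$tau_V * rates < 1.98
  vthr_star <- mom$mu_V[inv] +
    sqrt(2) * mom$sigma_V[inv] * erfcinv(2 * mom$tau_V[inv] * rates[inv])
  P0 <- qr.solve(X[inv, , drop = FALSE], vthr_star)

  # inverse-rate-squared weights keep the fluctuation-driven operating
  # region (low tens of Hz) from being swamped by the mean-driven corner
  wts <- 1 / (1 + (khz2hz(rates) / weight_scale)^2)
  obj <- function(P) {
    pred <- tf_rate_cpp(hz2khz(grid$nu_e), hz2khz(grid$nu_i), grid$W,
                        tf_cpp_list(new_tf(population, params, K_e, K_i, P)))
    sum(wts * (pred - rates)^2) / sum(wts)
  }
  opt <- stats::optim(P0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  P <- opt$par
  pred <- tf_rate_cpp(hz2khz(grid$nu_e), hz2khz(grid$nu_i), grid$W,
                      tf_cpp_list(new_tf(population, params, K_e, K_i, P)))
  op <- rates < hz2khz(30)  # fluctuation-driven operating region
  if (!any(op)) op <- rep(TRUE, length(rates))
  rms_hz <- khz2hz(sqrt(mean((pred[op] - rates[op])^2)))
  if (rms_hz > rms_tol)
    warning(sprintf(
      "transfer-function fit residual RMS %.2f Hz exceeds %.2f Hz (%s, %d points; max |resid| %.2f Hz)",
      rms_hz, rms_tol, population, nrow(grid),
      khz2hz(max(abs(pred - rates)))))
  new_tf(population, params, K_e, K_i, P,
         fit = list(grid = grid, measured_hz = khz2hz(rates),
                    predicted_hz = khz2hz(pred), n_points = nrow(grid),
                    rms_hz = rms_hz, seed = seed, sim_time = sim_time,
                    n_rep = n_rep))
}

#' Default fitted transfer functions shipped with the package
#'
#' Coefficients fitted by `scripts/fit_default_tf.R` (single-neuron AdEx
#' simulations at the default parameters) and stored as JSON under
#' `inst/extdata/`.
#'
#' @param population `"RS"` or `"FS"`.
#' @return An `adex_tf` object.
#' @export
default_tf <- function(population = c("RS", "FS")) {
  population <- match.arg(population)
  path <- system.file("extdata",
                      sprintf("tf_%s_default.json", tolower(population)),
                      package = "adexbrain", mustWork = TRUE)
  read_tf_json(path)
}

#' Serialize a transfer function to JSON / read it back
#' @param tf an `adex_tf` object.
#' @param path file path.
#' @return `write_tf_json` returns `path` invisibly; `read_tf_json` an
#'   `adex_tf`.
#' @export
write_tf_json <- function(tf, path) {
  stopifnot(inherits(tf, "adex_tf"))
  meta <- tf$fit
  meta$grid <- NULL; meta$measured_hz <- NULL; meta$predicted_hz <- NULL
  jsonlite::write_json(
    list(population = tf$population, K_e = tf$K_e, K_i = tf$K_i, P = tf$P,
         params = unclass(tf$params), fit = meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tf_json
#' @export
read_tf_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_tf(x$population, do.call(adex_params, as.list(x$params)),
         x$K_e, x$K_i, x$P, fit = x$fit)
}
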