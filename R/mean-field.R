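# Single-region two-population mean field with adaptation.
#
# First order:  T dnu_mu/dt = F_mu - nu_mu, plus the adaptation current
#   dW/dt = -W/u_w + b nu_e + a (mu_V - E_L).
# Second order (Master Equation): rates carry the covariance correction
#   (1/2) c_lam.eta d2F/dnu2, and the 2x2 covariance c evolves with a
#   finite-size source term F_lam (1/T - F_eta) / N_lam, a drift term, and
#   relaxation. The external drive nu_drive is an Ornstein-Uhlenbeck process
#   entering the excitatory-input argument of both transfer functions by
#   default, consistent with the network-level coupling convention and the
#   spiking model (the drive reaches every neuron there); the variant where
#   only F_e is driven is available via drive_to_inhibitory = FALSE.

#' Parameters of the single-region mean-field model
#'
#' @param tf_e,tf_i fitted transfer functions ([default_tf()] or
#'   [fit_tf()]) for the RS and FS populations.
#' @param T_ms population relaxation timescale T, ms.
#' @param N_e,N_i population sizes (finite-size covariance source scales as
#'   1/N).
#' @param b,a,u_w adaptation parameters (pA, nS, ms); default from `tf_e`'s
#'   neuron parameters.
#' @param E_L leak reversal used in the adaptation equation, mV.
#' @param drive_mean,drive_sd,drive_tau Ornstein-Uhlenbeck drive: mean and
#'   SD in Hz, correlation time in ms.
#' @param nu_aff afferent (thalamic) rate, Hz.
#' @param drive_to_inhibitory logical; when TRUE (default) the OU drive
#'   enters the excitatory-input argument of both populations' transfer
#'   functions, consistent with the network-level coupling and with the
#'   spiking model; FALSE drives only the excitatory population.
#' @return An object of class `mf_params`.
#' @export
mf_params <- function(tf_e = default_tf("RS"), tf_i = default_tf("FS"),
                      T_ms = 18, N_e = 8000, N_i = 2000, b = NULL, a = NULL,
                      u_w = NULL, E_L = NULL, drive_mean = 0.3,
                      drive_sd = 0.1, drive_tau = 5, nu_aff = 0,
                      drive_to_inhibitory = TRUE) {
  stopifnot(inherits(tf_e, "adex_tf"), inherits(tf_i, "adex_tf"),
            T_ms > 0, N_e > 0, N_i > 0, drive_sd >= 0, drive_tau > 0)
  p <- tf_e$params
  structure(list(tf_e = tf_e, tf_i = tf_i, T_ms = T_ms, N_e = N_e,
                 N_i = N_i, b = b %||% p$b, a = a %||% p$a,
                 u_w = u_w %||% p$u_w, E_L = E_L %||% p$E_L_e,
                 drive_mean = drive_mean, drive_sd = drive_sd,
                 drive_tau = drive_tau, nu_aff = nu_aff,
                 drive_to_inhibitory = drive_to_inhibitory),
            class = "mf_params")
}

sim_mf <- function(params, duration, dt, seed, order, record_dt, init) {
  stopifnot(inherits(params, "mf_params"))
  if (dt > params$T_ms / 10)
    stop("dt must be <= T/10 for a stable integration")
  init <- init %||% list()
  fe0 <- hz2khz(init$nu_e %||% 10)
  fi0 <- hz2khz(init$nu_i %||% 20)
  W0 <- init$W %||% 0
  c0 <- init$c %||% c(0, 0, 0)
  if (length(c0) == 4) {  # full 2x2 supplied: must be symmetric
    cm <- matrix(c0, 2, 2)
    if (abs(cm[1, 2] - cm[2, 1]) > 1e-12)
      stop("initial covariance matrix must be symmetric")
    c0 <- c(cm[1, 1], cm[1, 2], cm[2, 2])
  }
  set.seed(seed)
  res <- sim_mean_field_cpp(tf_cpp_list(params$tf_e),
                            tf_cpp_list(params$tf_i), params$T_ms,
                            params$N_e, params$N_i, params$a, params$b,
                            params$u_w, params$E_L,
                            hz2khz(params$drive_mean),
                            hz2khz(params$drive_sd), params$drive_tau,
                            hz2khz(params$nu_aff), duration, dt,
                            as.integer(order),
                            as.integer(max(1, round(record_dt / dt))),
                            fe0, fi0, W0, hz2khz(hz2khz(c0)),
                            isTRUE(params$drive_to_inhibitory))
  out <- data.frame(time = res$time, nu_e = khz2hz(res$nu_e),
                    nu_i = khz2hz(res$nu_i), W = res$W,
                    drive = khz2hz(res$drive))
  if (order == 2) {
    out$c_ee <- khz2hz(khz2hz(res$c_ee))
    out$c_ei <- khz2hz(khz2hz(res$c_ei))
    out$c_ii <- khz2hz(khz2hz(res$c_ii))
  }
  attr(out, "params") <- params
  attr(out, "order") <- order
  out
}

#' Integrate the single-region mean field
#'
#' `simulate_first_order()` integrates the rate + adaptation system;
#' `simulate_second_order()` additionally evolves the 2x2 rate covariance
#' of the Master Equation (its source term vanishes as 1/N, so large
#' populations recover the first-order trajectory). Both use a stochastic
#' Heun scheme with the OU drive discretized exactly.
#'
#' @param params an [mf_params()] object.
#' @param duration simulated time, ms.
#' @param dt integration step, ms (<= T/10).
#' @param seed integer seed (OU path determinism).
#' @param record_dt output sampling interval, ms.
#' @param init optional list with `nu_e`, `nu_i` (Hz), `W` (pA), and for
#'   second order `c` (covariances, Hz^2; length-3 `(ee, ei, ii)` or a
#'   symmetric 2x2 matrix).
#' @return data.frame time series: `time` (ms), `nu_e`, `nu_i` (Hz), `W`
#'   (pA), `drive` (Hz), and for second order `c_ee`, `c_ei`, `c_ii`
#'   (Hz^2).
#' @export
simulate_first_order <- function(params, duration = 10000, dt = 0.1,
                                 seed = 1, record_dt = 1, init = NULL) {
  sim_mf(params, duration, dt, seed, 1L, record_dt, init)
}

#' @rdname simulate_first_order
#' @export
simulate_second_order <- function(params, duration = 10000, dt = 0.1,
                                  seed = 1, record_dt = 1, init = NULL) {
  sim_mf(params, duration, dt, seed, 2L, record_dt, init)
}

#' Fixed points of the two-population mean field
#'
#' For each candidate excitatory rate, the inhibitory population is solved
#' to self-consistency (`nu_i = F_i(nu_e, nu_i)`), then crossings of
#' `F_e(nu_e, nu_i*(nu_e))` with the identity are located by a sign-change
#' scan refined with bisection. Crossings from above to below the identity
#' are tagged stable. The adaptation current is either frozen at `W` or
#' solved self-consistently (`W* = u_w (b nu_e + a (mu_V - E_L))`).
#'
#' @param tf_e,tf_i fitted transfer functions.
#' @param W_mode `"frozen"` or `"self-consistent"`.
#' @param W frozen adaptation current, pA (ignored if self-consistent).
#' @param b,a,u_w adaptation parameters for the self-consistent mode.
#' @param nu_drive constant drive offset added to the excitatory input, Hz.
#' @param bracket search interval for rates, Hz.
#' @param scan_step scan resolution, Hz.
#' @return data.frame with `nu_e`, `nu_i`, `W`, `stable` and `type`
#'   (`"crossing"` for identity crossings; `"boundary"` for a zero-rate
#'   equilibrium without sign change, as when the transfer function
#'   vanishes at zero input). Zero rows if the curve never crosses the
#'   identity and zero is not an equilibrium.
#' @export
find_fixed_points <- function(tf_e, tf_i, W_mode = c("frozen",
                                                     "self-consistent"),
                              W = 0, b = NULL, a = NULL, u_w = NULL,
                              nu_drive = 0, bracket = c(0, 200),
                              scan_step = 0.1) {
  W_mode <- match.arg(W_mode)
  stopifnot(inherits(tf_e, "adex_tf"), inherits(tf_i, "adex_tf"))
  p <- tf_e$params
  b <- b %||% p$b; a <- a %||% p$a; u_w <- u_w %||% p$u_w

  W_of <- function(nu_e, nu_i) {
    if (W_mode == "frozen") return(rep_len(W, length(nu_e)))
    # a = 0 makes this closed-form; otherwise iterate mu_V a few times
    Ws <- u_w * b * hz2khz(nu_e)
    if (a != 0) {
      for (it in 1:20) {
        mom <- conductance_moments(nu_e, nu_i, Ws, p, "RS",
                                   tf_e$K_e, tf_e$K_i)
        Ws_new <- u_w * (b * hz2khz(nu_e) + a * (mom$mu_V - p$E_L_e))
        if (max(abs(Ws_new - Ws)) < 1e-8) { Ws <- Ws_new; break }
        Ws <- Ws_new
      }
    }
    Ws
  }

  nu_i_star <- function(nu_e) {
    # g(x) = F_i(nu_e, x) - x decreases from g(0) >= 0 to g(max) <= 0
    # (F_i is capped at 1/T_refr), so the balance root is unique
    vapply(nu_e, function(ne) {
      g <- function(x) evaluate_tf(tf_i, ne, x, 0) - x
      g0 <- g(0)
      if (g0 <= 0) return(0)
      stats::uniroot(g, c(0, bracket[2] + 1), tol = 1e-8)$root
    }, numeric(1))
  }

  h <- function(nu_e) {
    ni <- nu_i_star(nu_e)
    Ws <- W_of(nu_e, ni)
    fe <- evaluate_tf(tf_e, nu_e + nu_drive, ni, Ws)
    list(h = fe - nu_e, nu_i = ni, W = Ws)
  }

  grid <- seq(bracket[1], bracket[2], by = scan_step)
  hg <- h(grid)$h
  sgn <- sign(hg)
  cross <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  out <- data.frame(nu_e = numeric(0), nu_i = numeric(0), W = numeric(0),
                    stable = logical(0), type = character(0))
  if (length(cross) > 0) {
    roots <- vapply(cross, function(i) {
      stats::uniroot(function(x) h(x)$h, c(grid[i], grid[i + 1]),
                     tol = 1e-6)$root
    }, numeric(1))
    info <- h(roots)
    out <- data.frame(nu_e = roots, nu_i = info$nu_i, W = info$W,
                      stable = hg[cross] > 0, type = "crossing")
  }
  # nu_e = 0 can be an equilibrium without a sign change (F(0, .) = 0):
  # report it as a boundary fixed point, distinct from identity crossings
  if (abs(hg[1]) < 1e-9 && (length(cross) == 0 || grid[cross[1]] > 0)) {
    i0 <- h(0)
    out <- rbind(data.frame(nu_e = 0, nu_i = i0$nu_i, W = i0$W,
                            stable = hg[2] <= 0, type = "boundary"), out)
  }
  rownames(out) <- NULL
  out
}
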