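#' Single-neuron and synapse parameters of the AdEx model
#'
#' Bundles every constant of the conductance-based adaptive exponential
#' integrate-and-fire (AdEx) neuron pair used throughout the package:
#' regular-spiking (RS) excitatory cells, which carry spike-frequency
#' adaptation, and fast-spiking (FS) inhibitory cells, which do not
#' (`a = b = 0` is imposed for FS cells at simulation time).
#'
#' Defaults are the standard values for this model family; the spike-
#' triggered adaptation increment `b` (pA) is the knob that moves the
#' network between wake-like asynchronous-irregular firing (`b = 0`) and
#' sleep-like Up/Down alternation (`b = 60`).
#'
#' @param c_m membrane capacitance, pF.
#' @param g_L leak conductance, nS.
#' @param E_L_e,E_L_i leak reversal potential of excitatory/inhibitory
#'   cells, mV.
#' @param Delta_e,Delta_i spike-initiation sharpness, mV.
#' @param v_thr exponential-term threshold, mV.
#' @param v_peak_e,v_peak_i spike-detection voltage, mV.
#' @param v_reset post-spike reset voltage, mV.
#' @param T_refr refractory period, ms.
#' @param a subthreshold adaptation conductance (RS cells), nS.
#' @param b spike-triggered adaptation increment (RS cells), pA.
#' @param u_w adaptation time constant, ms.
#' @param Q_e,Q_i excitatory/inhibitory quantal synaptic conductance, nS.
#' @param E_e,E_i excitatory/inhibitory synaptic reversal potential, mV.
#' @param u_e,u_i synaptic conductance decay time, ms.
#'
#' @return An object of class `adex_params` (a validated named list).
#' @examples
#' p <- adex_params()        # wake-like defaults (b = 0)
#' p60 <- adex_params(b = 60) # sleep-like adaptation level
#' @export
adex_params <- function(c_m = 200, g_L = 10, E_L_e = -63, E_L_i = -65,
                        Delta_e = 2, Delta_i = 0.5, v_thr = -50,
                        v_peak_e = -40, v_peak_i = -47.5, v_reset = -65,
                        T_refr = 5, a = 0, b = 0, u_w = 500,
                        Q_e = 1.5, Q_i = 5, E_e = 0, E_i = -80,
                        u_e = 5, u_i = 5) {
  p <- list(c_m = c_m, g_L = g_L, E_L_e = E_L_e, E_L_i = E_L_i,
            Delta_e = Delta_e, Delta_i = Delta_i, v_thr = v_thr,
            v_peak_e = v_peak_e, v_peak_i = v_peak_i, v_reset = v_reset,
            T_refr = T_refr, a = a, b = b, u_w = u_w, Q_e = Q_e, Q_i = Q_i,
            E_e = E_e, E_i = E_i, u_e = u_e, u_i = u_i)
  stopifnot(vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                     is.finite(x), logical(1)))
  if (c_m <= 0) stop("c_m must be positive")
  if (g_L <= 0) stop("g_L must be positive")
  if (u_w <= 0 || u_e <= 0 || u_i <= 0)
    stop("time constants u_w, u_e, u_i must be positive")
  if (!(E_i < E_L_i && E_i < E_L_e))
    stop("E_i must lie below both leak reversals")
  if (!(E_L_e < v_thr && E_L_i < v_thr))
    stop("leak reversals must lie below v_thr")
  if (!(v_thr < v_peak_e && v_thr < v_peak_i))
    stop("v_thr must lie below the spike-detection voltages")
  structure(p, class = "adex_params")
}

#' @export
print.adex_params <- function(x, ...) {
  cat("AdEx parameters (RS excitatory / FS inhibitory)\n")
  cat(sprintf("  c_m = %g pF, g_L = %g nS, E_L = %g/%g mV, Delta = %g/%g mV\n",
              x$c_m, x$g_L, x$E_L_e, x$E_L_i, x$Delta_e, x$Delta_i))
  cat(sprintf("  v_thr = %g mV, v_peak = %g/%g mV, v_reset = %g mV, T_refr = %g ms\n",
              x$v_thr, x$v_peak_e, x$v_peak_i, x$v_reset, x$T_refr))
  cat(sprintf("  adaptation: a = %g nS, b = %g pA, u_w = %g ms\n",
              x$a, x$b, x$u_w))
  cat(sprintf("  synapses: Q = %g/%g nS, E = %g/%g mV, u = %g/%g ms\n",
              x$Q_e, x$Q_i, x$E_e, x$E_i, x$u_e, x$u_i))
  invisible(x)
}
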