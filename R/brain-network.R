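# Connectome-coupled network of mean-field regions with axonal delays.
# Excitatory input of region k:
#   nu_input(k, t) = nu_drive(k, t) + nu_e(k, t)
#                    + S * sum_{j != k} C_jk nu_e(j, t - d_jk),
# with the self term (C_kk = 1) unscaled by S, and d_jk = tract length /
# v_c rounded to the integration step. Both populations' transfer functions
# receive nu_input + nu_aff; a square-wave stimulus adds its amplitude to
# the excitatory-population TF input of the target region only.

#' Configuration of a whole-brain simulation
#'
#' @param connectome a [connectome()].
#' @param tf_e,tf_i fitted transfer functions.
#' @param T_ms region relaxation timescale, ms.
#' @param b,a,u_w adaptation parameters (default from `tf_e`'s neuron
#'   parameters; `b` is the wake/sleep knob).
#' @param E_L leak reversal in the adaptation equation, mV.
#' @param S dimensionless inter-region coupling strength (>= 0).
#' @param v_c axonal propagation speed, mm/ms.
#' @param drive_mean,drive_sd,drive_tau per-region OU drive (Hz, Hz, ms);
#'   regions receive independent realizations.
#' @param nu_aff afferent rate added to every region, Hz.
#' @param duration,dt simulated time and step, ms.
#' @param transient initial discard used by downstream analysis, ms.
#' @param record_dt output sampling interval, ms.
#' @param seed integer master seed.
#' @return a `brain_config` object.
#' @export
brain_config <- function(connectome, tf_e = default_tf("RS"),
                         tf_i = default_tf("FS"), T_ms = 18, b = NULL,
                         a = NULL, u_w = NULL, E_L = NULL, S = 0.15,
                         v_c = 3, drive_mean = 0.3, drive_sd = 0.1,
                         drive_tau = 5, nu_aff = 0, duration = 10000,
                         dt = 0.1, transient = 2000, record_dt = 1,
                         seed = 1) {
  stopifnot(inherits(connectome, "connectome"), S >= 0, v_c > 0,
            duration > transient)
  p <- tf_e$params
  structure(list(connectome = connectome, tf_e = tf_e, tf_i = tf_i,
                 T_ms = T_ms, b = b %||% p$b, a = a %||% p$a,
                 u_w = u_w %||% p$u_w, E_L = E_L %||% p$E_L_e, S = S,
                 v_c = v_c, drive_mean = drive_mean, drive_sd = drive_sd,
                 drive_tau = drive_tau, nu_aff = nu_aff,
                 duration = duration, dt = dt, transient = transient,
                 record_dt = record_dt, seed = seed),
            class = "brain_config")
}

#' Square-wave stimulus specification
#'
#' @param region target region label (matched against connectome labels,
#'   partial matches allowed) or 1-based index.
#' @param amplitude added excitatory-input rate, Hz.
#' @param duration pulse length, ms.
#' @param onset pulse onset, ms.
#' @param waveform only `"square"` is implemented.
#' @return a `stimulus_spec` object.
#' @export
stimulus_spec <- function(region, amplitude = 0.1, duration = 50,
                          onset = 3000, waveform = "square") {
  stopifnot(amplitude >= 0, duration > 0, identical(waveform, "square"))
  structure(list(region = region, amplitude = amplitude,
                 duration = duration, onset = onset, waveform = waveform),
            class = "stimulus_spec")
}

resolve_region <- function(conn, region) {
  if (is.numeric(region)) {
    idx <- as.integer(region)
    if (idx < 1 || idx > conn$n_regions) stop("region index out of range")
    return(idx)
  }
  hit <- which(conn$labels == region)
  if (length(hit) == 0) hit <- grep(region, conn$labels, fixed = TRUE)
  if (length(hit) == 0)
    stop(sprintf("unknown target region label '%s'", region))
  if (length(hit) > 1)
    stop(sprintf("region label '%s' is ambiguous (%d matches)", region,
                 length(hit)))
  hit
}

#' Delayed coupling input to one region (reference implementation)
#'
#' Computes `nu_e(k, t) + S * sum_{j != k} C_jk nu_e(j, t - d_jk)` from an
#' explicit rate history. Drive and afferent terms are not included. This
#' mirrors what the simulator does internally and exists for direct
#' verification of the delay handling.
#'
#' @param k target region (1-based).
#' @param t time, ms (must be representable on the history grid).
#' @param history matrix (steps x regions) of excitatory rates, Hz, with
#'   row i holding time `(i - 1) * dt`.
#' @param conn a [connectome()].
#' @param delays delay matrix, ms (see [compute_delays()]).
#' @param S coupling strength.
#' @param dt history time step, ms.
#' @return scalar input rate, Hz.
#' @export
coupling_input <- function(k, t, history, conn, delays, S, dt) {
  n <- conn$n_regions
  step <- round(t / dt)
  val <- history[step + 1, k]
  for (j in seq_len(n)) {
    if (j == k) next
    lag <- round(delays[j, k] / dt)
    if (step - lag < 0) stop("requested lag beyond history buffer")
    val <- val + S * conn$weights[j, k] * history[step - lag + 1, j]
  }
  val
}

#' Simulate a connectome-coupled network of mean-field regions
#'
#' Heun integration of all regions with delayed excitatory coupling,
#' independent per-region OU drives, and an optional square-wave stimulus.
#' The delay buffer is warmed up with the initial state.
#'
#' @param config a [brain_config()].
#' @param stimulus a [stimulus_spec()] or NULL.
#' @param init optional list with vectors `nu_e`, `nu_i` (Hz) and `W` (pA)
#'   per region; defaults to a low-rate state (nu_e = 2 Hz, nu_i = 10 Hz,
#'   W = b * u_w * nu_e).
#' @return a `regional_ts` object: `time` (ms) and matrices `nu_e`,
#'   `nu_i` (Hz), `W` (pA) of shape steps x regions, plus labels and the
#'   config.
#' @export
simulate_brain <- function(config, stimulus = NULL, init = NULL) {
  stopifnot(inherits(config, "brain_config"))
  if (config$dt > config$T_ms / 10)
    stop("dt must be <= T/10 for a stable integration")
  conn <- config$connectome
  delays <- compute_delays(conn, config$v_c)
  dsteps <- matrix(as.integer(round(delays / config$dt)), conn$n_regions)
  n <- conn$n_regions
  init <- init %||% list()
  fe0 <- hz2khz(rep_len(init$nu_e %||% 2, n))
  fi0 <- hz2khz(rep_len(init$nu_i %||% 10, n))
  W0 <- rep_len(init$W %||% (config$b * config$u_w * hz2khz(2)), n)
  stim_target <- -1L; stim_amp <- 0; stim_onset <- 0; stim_dur <- 1
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "stimulus_spec"))
    stim_target <- resolve_region(conn, stimulus$region) - 1L
    stim_amp <- hz2khz(stimulus$amplitude)
    stim_onset <- stimulus$onset
    stim_dur <- stimulus$duration
  }
  set.seed(config$seed)
  res <- sim_brain_cpp(tf_cpp_list(config$tf_e), tf_cpp_list(config$tf_i),
                       config$T_ms, config$a, config$b, config$u_w,
                       config$E_L, conn$weights, dsteps, config$S,
                       hz2khz(config$drive_mean), hz2khz(config$drive_sd),
                       config$drive_tau, hz2khz(config$nu_aff),
                       config$duration, config$dt,
                       as.integer(max(1, round(config$record_dt /
                                                 config$dt))),
                       fe0, fi0, W0, stim_target, stim_amp, stim_onset,
                       stim_dur)
  structure(list(time = res$time, nu_e = khz2hz(res$nu_e),
                 nu_i = khz2hz(res$nu_i), W = res$W, labels = conn$labels,
                 record_dt = config$record_dt,
                 transient = config$transient, config = config,
                 stimulus = stimulus),
            class = "regional_ts")
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf(
    "regional_ts: %d regions x %d samples (%.1f s at %g ms), b = %g pA\n",
    ncol(x$nu_e), nrow(x$nu_e), max(x$time) / 1000, x$record_dt,
    x$config$b))
  invisible(x)
}

#' Drop the transient from a regional time series
#' @param ts a `regional_ts`.
#' @param transient override, ms (default: the config's).
#' @return a `regional_ts` restricted to `time >= transient`.
#' @export
discard_transient <- function(ts, transient = NULL) {
  stopifnot(inherits(ts, "regional_ts"))
  transient <- transient %||% ts$transient
  keep <- ts$time >= transient
  ts$time <- ts$time[keep]
  ts$nu_e <- ts$nu_e[keep, , drop = FALSE]
  ts$nu_i <- ts$nu_i[keep, , drop = FALSE]
  ts$W <- ts$W[keep, , drop = FALSE]
  ts$transient <- 0
  ts
}

#' Export a regional time series to CSV
#' @param ts a `regional_ts`.
#' @param path output file.
#' @param what `"nu_e"`, `"nu_i"` or `"W"`.
#' @return `path`, invisibly.
#' @export
write_regional_csv <- function(ts, path, what = c("nu_e", "nu_i", "W")) {
  what <- match.arg(what)
  df <- data.frame(time = ts$time, ts[[what]])
  names(df) <- c("time_ms", ts$labels)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
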