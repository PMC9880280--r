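#' Build a random AdEx network architecture
#'
#' Draws a directed Erdos-Renyi graph over `N` neurons (no self-connections):
#' each ordered pair is connected independently with probability `p`. The
#' last `frac_inh * N` neurons are inhibitory (FS), the rest excitatory (RS).
#'
#' @param N number of neurons.
#' @param frac_inh inhibitory fraction.
#' @param p connection probability.
#' @param seed integer seed; identical seeds give identical adjacency.
#' @return An `adex_network` object: CSR adjacency over presynaptic neurons
#'   (`adj_ptr`, `adj_idx`, both 0-based for the C++ core), neuron types
#'   (`is_inh`), and the generating parameters.
#' @examples
#' net <- build_network(N = 200, p = 0.05, seed = 1)
#' mean(diff(net$adj_ptr))  # mean out-degree, ~ p * (N - 1)
#' @export
build_network <- function(N = 10000, frac_inh = 0.2, p = 0.05, seed = 1) {
  if (length(N) != 1 || N < 2) stop("N must be a single integer >= 2")
  if (p < 0 || p >= 1) stop("p must lie in [0, 1)")
  if (frac_inh <= 0 || frac_inh >= 1) stop("frac_inh must lie in (0, 1)")
  set.seed(seed)
  N <- as.integer(N)
  n_inh <- as.integer(round(frac_inh * N))
  is_inh <- c(rep(0L, N - n_inh), rep(1L, n_inh))
  targets <- vector("list", N)
  if (p > 0) {
    k <- rbinom(N, N - 1L, p)
    for (i in seq_len(N)) {
      if (k[i] == 0L) { targets[[i]] <- integer(0); next }
      # sample without replacement from {1..N} \ {i}
      tr <- sample.int(N - 1L, k[i])
      tr <- ifelse(tr >= i, tr + 1L, tr)
      targets[[i]] <- tr - 1L  # 0-based
    }
  } else {
    targets <- replicate(N, integer(0), simplify = FALSE)
  }
  lens <- lengths(targets)
  structure(list(N = N, frac_inh = frac_inh, p = p, seed = seed,
                 is_inh = is_inh,
                 adj_ptr = c(0L, cumsum(lens)),
                 adj_idx = unlist(targets, use.names = FALSE) %||% integer(0)),
            class = "adex_network")
}

#' In-degrees of an AdEx network, split by presynaptic type
#'
#' @param net an `adex_network`.
#' @return data.frame with excitatory and inhibitory in-degree per neuron.
#' @export
in_degrees <- function(net) {
  src <- rep.int(seq_len(net$N), diff(net$adj_ptr))
  tgt <- net$adj_idx + 1L
  exc <- tabulate(tgt[net$is_inh[src] == 0L], nbins = net$N)
  inh <- tabulate(tgt[net$is_inh[src] == 1L], nbins = net$N)
  data.frame(neuron = seq_len(net$N), k_e = exc, k_i = inh)
}

#' Simulate a network of conductance-based AdEx neurons
#'
#' Forward-Euler integration (dt <= 0.1 ms) of the AdEx membrane equation
#' with exponential spike initiation, spike-triggered adaptation, and
#' exponentially decaying conductance synapses. Each neuron additionally
#' receives an independent Poisson excitatory drive through `Q_e` synapses,
#' standing in for background ("miniature") synaptic activity; its rate is
#' expressed per synapse, with `K_drive` synapses per neuron.
#'
#' @param net an `adex_network` from [build_network()].
#' @param params an [adex_params()] object (set `b` there).
#' @param duration simulation length, ms.
#' @param dt integration step, ms (must be <= 0.1).
#' @param drive_rate external Poisson rate per drive synapse, Hz.
#' @param K_drive number of drive synapses per neuron (default: the mean
#'   recurrent excitatory in-degree, `p * N * (1 - frac_inh)`).
#' @param seed integer seed.
#' @param monitor indices (1-based) of neurons whose state traces
#'   (v, w, G_e, G_i) are recorded.
#' @param record_every trace recording stride, in steps.
#' @param v_init `"uniform"` (between the cell's leak reversal and `v_thr`,
#'   kick-starting recurrent activity) or a numeric vector of length `N`.
#' @return A `spike_data` object: per-spike `neuron` (1-based) and `time`
#'   (ms), plus metadata and any monitored traces.
#' @export
simulate_spiking <- function(net, params = adex_params(), duration = 5000,
                             dt = 0.1, drive_rate = 0.5, K_drive = NULL,
                             seed = 1, monitor = integer(0),
                             record_every = 10L, v_init = "uniform") {
  stopifnot(inherits(net, "adex_network"), inherits(params, "adex_params"))
  if (dt > 0.1 + 1e-12) stop("dt must be <= 0.1 ms")
  if (duration < dt) stop("duration must be >= dt")
  if (drive_rate < 0) stop("drive_rate must be >= 0")
  K_drive <- K_drive %||% (net$p * net$N * (1 - net$frac_inh))
  set.seed(seed)
  EL <- ifelse(net$is_inh == 1L, params$E_L_i, params$E_L_e)
  if (identical(v_init, "uniform")) {
    v0 <- runif(net$N, EL, params$v_thr)
  } else {
    stopifnot(is.numeric(v_init), length(v_init) == net$N)
    v0 <- v_init
  }
  res <- sim_adex_network_cpp(net$adj_ptr, net$adj_idx, net$is_inh,
                              unclass(params), duration, dt,
                              hz2khz(drive_rate * K_drive), v0,
                              rep(0, net$N), as.integer(monitor) - 1L,
                              as.integer(record_every))
  out <- list(neuron = res$neuron + 1L, time = res$time, N = net$N,
              is_inh = net$is_inh, duration = duration, dt = dt,
              params = params, drive_rate = drive_rate, seed = seed)
  if (length(monitor) > 0) {
    out$traces <- list(time = res$trace_time, v = res$trace_v,
                       w = res$trace_w, G_e = res$trace_ge,
                       G_i = res$trace_gi, neuron = as.integer(monitor))
  }
  structure(out, class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("spike_data: %d neurons, %g ms, %d spikes (%.2f Hz mean rate)\n",
              x$N, x$duration, length(x$time),
              1000 * length(x$time) / (x$N * x$duration)))
  invisible(x)
}

#' Binned population firing rate
#'
#' Spike counts of one population per time bin, divided by bin length and
#' population size; reported in Hz.
#'
#' @param spikes a `spike_data` object.
#' @param bin bin width, ms (default 0.5).
#' @param population `"e"` or `"i"`.
#' @return data.frame with `time` (bin start, ms) and `rate` (Hz).
#' @export
population_rate <- function(spikes, bin = 0.5, population = c("e", "i")) {
  population <- match.arg(population)
  stopifnot(inherits(spikes, "spike_data"), bin > 0)
  keep <- if (population == "e") spikes$is_inh[spikes$neuron] == 0L
          else spikes$is_inh[spikes$neuron] == 1L
  n_pop <- sum(spikes$is_inh == (population == "i"))
  edges <- seq(0, spikes$duration + bin, by = bin)
  n_bins <- length(edges) - 1L
  idx <- findInterval(spikes$time[keep], edges, rightmost.closed = FALSE)
  idx <- idx[idx >= 1 & idx <= n_bins]
  counts <- tabulate(idx, nbins = n_bins)
  keep_bins <- edges[-length(edges)] < spikes$duration
  data.frame(time = edges[-length(edges)][keep_bins],
             rate = khz2hz(counts[keep_bins] / (bin * n_pop)))
}

#' Classify a population-rate series as asynchronous or Up/Down
#'
#' A series is labelled `"UpDown"` when the fraction of silent 20-ms windows
#' (mean rate below 1 Hz) exceeds 0.1 after discarding the transient, and
#' `"AI"` (asynchronous irregular) otherwise. The silent-window criterion
#' operationalizes the near-silent Down periods of slow-wave activity; the
#' accompanying rate SD rises sharply at the transition.
#'
#' @param rate data.frame from [population_rate()] (or any `time`/`rate`
#'   pair, ms and Hz), or a numeric rate vector with `bin` given.
#' @param bin bin width in ms (taken from `rate$time` when omitted).
#' @param transient initial period to discard, ms.
#' @param window silent-window length, ms.
#' @param silent_rate silence threshold, Hz.
#' @param silent_frac Up/Down classification threshold on the silent
#'   fraction.
#' @return list with `label` ("AI" or "UpDown"), `mean_rate`, `sd_rate`
#'   (Hz) and `silent_fraction`.
#' @export
classify_state <- function(rate, bin = NULL, transient = 1000, window = 20,
                           silent_rate = 1, silent_frac = 0.1) {
  if (is.data.frame(rate)) {
    bin <- bin %||% (rate$time[2] - rate$time[1])
    keep <- rate$time >= transient
    x <- rate$rate[keep]
  } else {
    if (is.null(bin)) stop("bin must be given for a bare rate vector")
    x <- rate[-seq_len(min(length(rate), floor(transient / bin)))]
  }
  if (length(x) * bin < 1000)
    stop("need at least 1 s of post-transient rate series")
  per_win <- max(1L, round(window / bin))
  n_win <- floor(length(x) / per_win)
  wmean <- colMeans(matrix(x[seq_len(n_win * per_win)], nrow = per_win))
  sf <- mean(wmean < silent_rate)
  list(label = if (sf > silent_frac) "UpDown" else "AI",
       mean_rate = mean(x), sd_rate = sd(x), silent_fraction = sf)
}

#' Write / read spikes as two-column TSV (neuron_id, time_ms)
#' @param spikes a `spike_data` object.
#' @param path output file.
#' @return `write_spikes_tsv` returns `path` invisibly; `read_spikes_tsv`
#'   returns a data.frame with `neuron` and `time`.
#' @export
write_spikes_tsv <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_data"))
  write.table(data.frame(neuron_id = spikes$neuron, time_ms = spikes$time),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes_tsv
#' @export
read_spikes_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  data.frame(neuron = df$neuron_id, time = df$time_ms)
}
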