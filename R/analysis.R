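# Spectral, correlation, phase and distance-profile characterization of
# regional rate series. The Welch periodogram and the Hilbert analytic
# signal are built directly on stats::fft.

#' Welch power spectrum with peak detection
#'
#' Hann-windowed, 50%-overlapping segment-averaged periodogram of a rate
#' series (by default the region-averaged excitatory rate of a
#' `regional_ts`, transient removed). The peak frequency is the argmax of
#' power over `peak_range`.
#'
#' @param x numeric series, or a `regional_ts` (region-averaged `nu_e` is
#'   used).
#' @param fs sampling rate, Hz (derived from the object's `record_dt` for
#'   a `regional_ts`).
#' @param window_s segment length, s (default 4: 0.25 Hz resolution,
#'   stable delta-band estimates).
#' @param overlap segment overlap fraction.
#' @param peak_range frequency band searched for the peak, Hz.
#' @return list with `freq` (Hz), `power`, and `peak_frequency` (Hz).
#' @export
power_spectrum <- function(x, fs = NULL, window_s = 4, overlap = 0.5,
                           peak_range = c(0.1, 100)) {
  if (inherits(x, "regional_ts")) {
    fs <- fs %||% (1000 / x$record_dt)
    x <- rowMeans(discard_transient(x)$nu_e)
  }
  if (is.null(fs)) stop("fs must be given for a bare series")
  nseg <- round(window_s * fs)
  if (length(x) < nseg)
    stop(sprintf("series (%d samples) shorter than one %g-s window",
                 length(x), window_s))
  hop <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  scale <- sum(win^2) * fs
  nfreq <- floor(nseg / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(fft(seg)[seq_len(nfreq)])^2 / scale
    acc <- acc + sp
  }
  power <- acc / length(starts)
  # one-sided density: fold the negative frequencies in
  interior <- 2:(nfreq - if (nseg %% 2 == 0) 1 else 0)
  power[interior] <- 2 * power[interior]
  freq <- (seq_len(nfreq) - 1) * fs / nseg
  band <- freq >= peak_range[1] & freq <= peak_range[2]
  peak <- if (any(band)) freq[band][which.max(power[band])] else NA_real_
  list(freq = freq, power = power, peak_frequency = peak)
}

get_pop_matrix <- function(ts, population, transient = TRUE) {
  if (inherits(ts, "regional_ts")) {
    if (transient) ts <- discard_transient(ts)
    if (population == "e") ts$nu_e else ts$nu_i
  } else {
    as.matrix(ts)
  }
}

#' Pearson functional connectivity matrix
#'
#' Pairwise Pearson correlation of post-transient regional rate series.
#' Zero-variance regions yield NA rows/columns (flagged, excluded from
#' summaries).
#'
#' @param ts a `regional_ts`, or a samples x regions matrix.
#' @param population `"e"` or `"i"`.
#' @return an `fc_matrix`: the correlation matrix with attributes
#'   `metric = "pearson"` and `population`.
#' @export
fc_pearson <- function(ts, population = c("e", "i")) {
  population <- match.arg(population)
  m <- get_pop_matrix(ts, population)
  if (ncol(m) < 2) stop("need at least 2 regions")
  v <- apply(m, 2, sd)
  fc <- suppressWarnings(cor(m))
  fc[v == 0, ] <- NA; fc[, v == 0] <- NA
  diag(fc) <- 1
  structure(fc, metric = "pearson", population = population,
            class = c("fc_matrix", "matrix", "array"))
}

#' Phase of the analytic signal (Hilbert transform via FFT)
#' @param x numeric series (demeaned internally).
#' @return instantaneous phase, radians.
#' @export
hilbert_phase <- function(x) {
  n <- length(x)
  X <- fft(x - mean(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Arg(fft(X * h, inverse = TRUE) / n)
}

#' Phase-lag index matrix
#'
#' PLI_ij = |< sign(psi_i(t) - psi_j(t)) >| per epoch, averaged over
#' epochs, where psi is the Hilbert phase of the (post-transient) rate
#' series and the sign is taken of the wrapped phase difference. Values
#' range from 0 (random phase relations or zero-lag synchrony) to 1
#' (perfect constant lag).
#'
#' @param ts a `regional_ts`, or a samples x regions matrix with `fs`.
#' @param population `"e"` or `"i"`.
#' @param epoch_s epoch length, s (>= 1).
#' @param fs sampling rate, Hz (for bare matrices).
#' @return an `fc_matrix` with `metric = "pli"` and zero diagonal.
#' @export
pli <- function(ts, population = c("e", "i"), epoch_s = 1, fs = NULL) {
  population <- match.arg(population)
  if (inherits(ts, "regional_ts")) fs <- fs %||% (1000 / ts$record_dt)
  if (is.null(fs)) stop("fs must be given for a bare matrix")
  if (epoch_s < 1) stop("epoch length must be >= 1 s")
  m <- get_pop_matrix(ts, population)
  n <- ncol(m)
  if (any(apply(m, 2, sd) == 0))
    warning("constant series: phase undefined for some regions")
  len <- round(epoch_s * fs)
  n_ep <- floor(nrow(m) / len)
  if (n_ep < 1) stop("series shorter than one epoch")
  acc <- matrix(0, n, n)
  for (ep in seq_len(n_ep)) {
    rows <- ((ep - 1) * len + 1):(ep * len)
    ph <- apply(m[rows, , drop = FALSE], 2, hilbert_phase)
    p <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      p[i, j] <- p[j, i] <- abs(mean(sign(sin(ph[, i] - ph[, j]))))
    }
    acc <- acc + p
  }
  out <- acc / n_ep
  diag(out) <- 0
  structure(out, metric = "pli", population = population,
            class = c("fc_matrix", "matrix", "array"))
}

offdiag_upper <- function(m) m[upper.tri(m)]

#' Distance profile of a functional-connectivity matrix
#'
#' Subdivides inter-region distances into equal-width bins, summarizes the
#' FC values per bin, runs a Kruskal-Wallis omnibus test across bins,
#' Mann-Whitney U tests of the middle bin against every other bin, and a
#' least-squares linear fit of value against distance. Empty bins are
#' merged with their left neighbor (with a message).
#'
#' @param fc an `fc_matrix` (or plain symmetric matrix).
#' @param distances symmetric distance matrix, mm (e.g. Euclidean
#'   inter-centre distances).
#' @param n_bins number of equal-width distance bins.
#' @return list with `bins` (per-bin n, mean, median, mid-distance),
#'   `values`/`distances`/`bin` vectors over region pairs, `kruskal`
#'   (htest), `pairwise` (data.frame: bin, U, p vs the middle bin), and
#'   `slope` (per mm) with its p-value.
#' @export
distance_profile <- function(fc, distances, n_bins = 5) {
  distances <- as.matrix(distances)
  if (!all(dim(fc) == dim(distances))) stop("shape mismatch")
  vals <- offdiag_upper(unclass(fc))
  d <- offdiag_upper(distances)
  ok <- is.finite(vals) & is.finite(d)
  vals <- vals[ok]; d <- d[ok]
  br <- seq(min(d), max(d), length.out = n_bins + 1)
  bin <- findInterval(d, br, rightmost.closed = TRUE)
  bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
  # merge empty bins leftward
  for (bb in seq_len(n_bins)) {
    if (sum(bin == bb) == 0) {
      message(sprintf("distance bin %d empty; merged with neighbor", bb))
      bin[bin > bb] <- bin[bin > bb] - 1L
    }
  }
  bins_present <- sort(unique(bin))
  bin <- match(bin, bins_present)
  k <- length(bins_present)
  mid <- ceiling(k / 2)
  bins <- data.frame(
    bin = seq_len(k),
    mid_distance = vapply(seq_len(k), function(bb)
      mean(range(d[bin == bb])), numeric(1)),
    n = as.integer(table(factor(bin, levels = seq_len(k)))),
    mean = vapply(seq_len(k), function(bb) mean(vals[bin == bb]),
                  numeric(1)),
    median = vapply(seq_len(k), function(bb) median(vals[bin == bb]),
                    numeric(1)))
  kw <- kruskal.test(vals, factor(bin))
  pw <- do.call(rbind, lapply(setdiff(seq_len(k), mid), function(bb) {
    wt <- wilcox.test(vals[bin == mid], vals[bin == bb], exact = FALSE)
    data.frame(bin = bb, U = unname(wt$statistic), p = wt$p.value)
  }))
  fit <- lm(vals ~ d)
  slope <- coef(fit)[2]
  slope_p <- summary(fit)$coefficients[2, 4]
  list(bins = bins, values = vals, distances = d, bin = bin,
       middle_bin = mid, kruskal = kw, pairwise = pw,
       slope = unname(slope), slope_p = unname(slope_p))
}

#' Compare excitatory vs inhibitory functional connectivity
#'
#' Independent two-sample t-test over the flattened off-diagonal entries,
#' with the excitatory-minus-inhibitory sign convention (inhibitory
#' correlations exceeding excitatory ones give a negative t).
#'
#' @param fc_e,fc_i `fc_matrix` objects of matching shape.
#' @return list with `t`, `p`, `mean_e`, `mean_i`, and per-pair
#'   differences `diff` (e minus i).
#' @export
compare_populations <- function(fc_e, fc_i) {
  if (!all(dim(fc_e) == dim(fc_i))) stop("shape mismatch")
  e <- offdiag_upper(unclass(fc_e))
  i <- offdiag_upper(unclass(fc_i))
  ok <- is.finite(e) & is.finite(i)
  tt <- t.test(e[ok], i[ok], var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_e = mean(e[ok]),
       mean_i = mean(i[ok]), diff = e[ok] - i[ok])
}
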