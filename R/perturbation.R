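# Stimulus-response machinery: trial ensembles, significance binarization
# against a shuffled pre-stimulus null, onset maps, Lempel-Ziv complexity,
# source entropy, and the perturbational complexity index (PCI).

#' Run a stimulus-response trial ensemble
#'
#' Each trial is an independent whole-brain simulation (fresh noise) with
#' the same square-wave stimulus delivered to the same region at a
#' randomized onset inside the steady-state window; trials are aligned on
#' return, keeping `window` ms before and after onset.
#'
#' @param config a [brain_config()]; its `transient` defines the start of
#'   the steady-state window.
#' @param stimulus a [stimulus_spec()]; its `onset` is ignored
#'   (randomized per trial).
#' @param n_trials number of trials.
#' @param seed master seed (per-trial seeds derive from it).
#' @param window pre/post window, ms.
#' @param onset_jitter width of the uniform onset randomization, ms.
#' @return a `trial_ensemble`: array `rates` (trials x regions x samples,
#'   Hz, sampled at `config$record_dt`), `onset_index` (first
#'   post-stimulus sample), metadata.
#' @export
run_trials <- function(config, stimulus, n_trials = 40, seed = 1,
                       window = 300, onset_jitter = 500) {
  stopifnot(inherits(config, "brain_config"),
            inherits(stimulus, "stimulus_spec"))
  if (config$transient < window)
    stop("config$transient must leave a full pre-stimulus window")
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1, n_trials)
  onsets <- config$transient + window +
    runif(n_trials, 0, onset_jitter)
  dt_rec <- config$record_dt
  wlen <- round(window / dt_rec)
  n <- config$connectome$n_regions
  rates <- array(NA_real_, c(n_trials, n, 2 * wlen))
  for (tr in seq_len(n_trials)) {
    onset <- round(onsets[tr] / dt_rec) * dt_rec  # align to record grid
    cfg <- config
    cfg$seed <- trial_seeds[tr]
    cfg$duration <- onset + window + 10 * dt_rec
    st <- stimulus
    st$onset <- onset
    ts <- simulate_brain(cfg, st)
    i0 <- which.min(abs(ts$time - onset))
    rows <- (i0 - wlen):(i0 + wlen - 1)
    rates[tr, , ] <- t(ts$nu_e[rows, , drop = FALSE])
  }
  structure(list(rates = rates, onset_index = wlen + 1L, dt = dt_rec,
                 window = window, n_trials = n_trials,
                 labels = config$connectome$labels, stimulus = stimulus,
                 seed = seed),
            class = "trial_ensemble")
}

#' Significance-binarize a trial ensemble against a shuffled null
#'
#' Rates are z-scored per trial with the pre-stimulus mean and SD averaged
#' over regions. The null distribution is built by shuffling every
#' pre-stimulus sample across time bins (`n_shuffles` repetitions); within
#' each series of `series_len` trials, the significance threshold `T_sig`
#' is the one-tail `percentile` of the per-repetition maximum absolute
#' value. Post-stimulus bins with z > T_sig are marked 1.
#'
#' @param trials a `trial_ensemble`.
#' @param n_shuffles null repetitions.
#' @param percentile one-tail percentile for the threshold (0-1).
#' @param series_len trials per threshold series.
#' @return a `binarized_response`: `s` (trials x regions x post bins in
#'   {0,1}), `S` (matrix trials x regions*bins, each row the concatenated
#'   significance vector), `threshold` per series, `z` scores.
#' @export
binarize_response <- function(trials, n_shuffles = 500, percentile = 0.99,
                              series_len = 20) {
  stopifnot(inherits(trials, "trial_ensemble"))
  on <- trials$onset_index
  pre_idx <- seq_len(on - 1)
  post_idx <- on:dim(trials$rates)[3]
  n_trials <- trials$n_trials
  n_reg <- dim(trials$rates)[2]
  z <- trials$rates
  for (tr in seq_len(n_trials)) {
    pre <- trials$rates[tr, , pre_idx, drop = TRUE]
    m <- mean(apply(pre, 1, mean))
    s <- mean(apply(pre, 1, sd))
    if (s == 0) stop("zero pre-stimulus SD: cannot binarize")
    z[tr, , ] <- (trials$rates[tr, , ] - m) / s
  }
  series <- split(seq_len(n_trials),
                  ceiling(seq_len(n_trials) / series_len))
  thr <- numeric(length(series))
  s_arr <- array(0L, c(n_trials, n_reg, length(post_idx)))
  epoch_size <- n_reg * length(pre_idx)
  for (si in seq_along(series)) {
    ids <- series[[si]]
    # null: the series' pre-stimulus samples, randomized across time bins
    # and trials, reassembled into surrogate epochs; the threshold is the
    # one-tail percentile of the surrogate-epoch maximum absolute value
    # (max-statistic control over regions x bins)
    pool <- abs(as.vector(z[ids, , pre_idx, drop = FALSE]))
    maxima <- vapply(seq_len(n_shuffles), function(r)
      max(pool[sample.int(length(pool), epoch_size)]), numeric(1))
    thr[si] <- quantile(maxima, percentile, names = FALSE)
    for (tr in ids)
      s_arr[tr, , ] <- (z[tr, , post_idx, drop = TRUE] > thr[si]) + 0L
  }
  # concatenate per-region significance vectors (region-major: each
  # region's full post-stimulus course, then the next region's)
  S <- t(vapply(seq_len(n_trials),
                function(tr) as.vector(t(s_arr[tr, , , drop = TRUE]))
                , numeric(n_reg * length(post_idx))))
  structure(list(s = s_arr, S = S, threshold = thr, z = z,
                 onset_index = on, dt = trials$dt,
                 labels = trials$labels),
            class = "binarized_response")
}

#' Earliest significant response time per region
#'
#' Per trial and region, the first post-stimulus bin whose significance is
#' sustained for at least `sustain` consecutive bins (NA when absent). The
#' aggregate map reports, per region, the fraction of trials with a finite
#' onset and the median onset over those trials (NA when fewer than
#' `min_frac` of the trials respond).
#'
#' @param binarized a `binarized_response`.
#' @param sustain consecutive significant bins required.
#' @param min_frac minimal responding-trial fraction for the aggregate.
#' @return list with `onset` (trials x regions, ms after stimulus) and
#'   `map` (data.frame: region, frac_responding, median_onset_ms).
#' @export
onset_map <- function(binarized, sustain = 2, min_frac = 0.25) {
  stopifnot(inherits(binarized, "binarized_response"))
  s <- binarized$s
  n_trials <- dim(s)[1]; n_reg <- dim(s)[2]; n_bins <- dim(s)[3]
  onset <- matrix(NA_real_, n_trials, n_reg)
  for (tr in seq_len(n_trials)) for (k in seq_len(n_reg)) {
    run <- 0L
    for (bb in seq_len(n_bins)) {
      run <- if (s[tr, k, bb] == 1L) run + 1L else 0L
      if (run >= sustain) {
        onset[tr, k] <- (bb - sustain + 1) * binarized$dt
        break
      }
    }
  }
  frac <- colMeans(!is.na(onset))
  med <- vapply(seq_len(n_reg), function(k) {
    if (frac[k] >= min_frac) median(onset[, k], na.rm = TRUE) else NA_real_
  }, numeric(1))
  list(onset = onset,
       map = data.frame(region = binarized$labels,
                        frac_responding = frac, median_onset_ms = med))
}

#' Lempel-Ziv complexity of a binary vector
#'
#' Sequential dictionary parse: the vector is sectioned into consecutive
#' words, each extending a previously seen word by one symbol; every new
#' word enters the dictionary, whose final size (the trailing incomplete
#' word included) is returned.
#'
#' @param S binary vector (0/1, or logical).
#' @return integer dictionary size.
#' @examples
#' lempel_ziv(c(0)) # 1
#' @export
lempel_ziv <- function(S) {
  S <- as.integer(S)
  if (length(S) == 0) stop("S must be nonempty")
  if (!all(S %in% c(0L, 1L))) stop("S must be binary")
  dict <- new.env(hash = TRUE, parent = emptyenv())
  count <- 0L
  word <- ""
  for (ch in S) {
    word <- paste0(word, ch)
    if (is.null(dict[[word]])) {
      assign(word, TRUE, envir = dict)
      count <- count + 1L
      word <- ""
    }
  }
  # trailing word (already in dictionary) counts as a word of the parse
  if (nzchar(word)) count <- count + 1L
  count
}

#' Source entropy of a binary vector
#'
#' Plug-in binary entropy `H = -p0 log2 p0 - p1 log2 p1` of the empirical
#' symbol frequencies, with `0 log 0 = 0`.
#'
#' @param S binary vector.
#' @return entropy in bits, in `[0, 1]`.
#' @export
source_entropy <- function(S) {
  S <- as.integer(S)
  if (length(S) == 0) stop("S must be nonempty")
  p <- mean(S)
  plog <- function(q) if (q <= 0) 0 else q * log2(q)
  -plog(p) - plog(1 - p)
}

#' Perturbational complexity index of a binary significance vector
#'
#' `PCI(S) = LZ(S) / H(S)`; a vector with zero entropy (no significant
#' response, or saturation) carries no complexity and returns 0 by
#' convention.
#'
#' @param S binary vector.
#' @return non-negative ratio.
#' @export
pci <- function(S) {
  H <- source_entropy(S)
  if (H == 0) return(0)
  lempel_ziv(S) / H
}

#' Full PCI experiment over adaptation levels and stimulus amplitudes
#'
#' For every combination of `b_values` and `amplitudes`, runs a trial
#' ensemble, binarizes it, and computes the per-trial PCI; per amplitude, a
#' one-way Kruskal-Wallis omnibus test across adaptation levels and a
#' Conover post-hoc comparison are reported.
#'
#' @param config a [brain_config()] (its `b` is overridden per condition).
#' @param stimulus_region target region label or index.
#' @param b_values adaptation levels, pA.
#' @param amplitudes stimulus amplitudes, Hz.
#' @param n_trials trials per condition.
#' @param seed master seed.
#' @param ... passed to [binarize_response()].
#' @return list with `table` (data.frame: b, amplitude, trial, pci),
#'   `tests` (per amplitude: kruskal htest, conover p-value matrix).
#' @export
pci_experiment <- function(config, stimulus_region,
                           b_values = c(0, 20, 40, 60),
                           amplitudes = c(0.01, 0.1, 1.0), n_trials = 40,
                           seed = 1, ...) {
  rows <- list(); tests <- list()
  for (amp in amplitudes) {
    per_b <- list()
    for (b in b_values) {
      cfg <- config
      cfg$b <- b
      st <- stimulus_spec(stimulus_region, amplitude = amp)
      tr <- run_trials(cfg, st, n_trials = n_trials,
                       seed = seed + round(1000 * amp) + b)
      bn <- binarize_response(tr, ...)
      pcis <- apply(bn$S, 1, pci)
      per_b[[as.character(b)]] <- pcis
      rows[[length(rows) + 1]] <-
        data.frame(b = b, amplitude = amp, trial = seq_along(pcis),
                   pci = pcis)
    }
    vals <- unlist(per_b, use.names = FALSE)
    grp <- factor(rep(b_values, vapply(per_b, length, integer(1))))
    tests[[as.character(amp)]] <-
      list(kruskal = kruskal.test(vals, grp),
           conover = conover_test(vals, grp))
  }
  list(table = do.call(rbind, rows), tests = tests)
}

#' Conover-Iman all-pairs rank comparison after Kruskal-Wallis
#'
#' Rank-based pairwise t statistics with the pooled rank variance corrected
#' by the Kruskal-Wallis statistic; two-sided p-values on N - k degrees of
#' freedom, optionally multiplicity-adjusted.
#'
#' @param x numeric values.
#' @param g grouping factor.
#' @param p_adjust adjustment method for [stats::p.adjust()].
#' @return list with matrices `t` and `p` (groups x groups).
#' @export
conover_test <- function(x, g, p_adjust = "holm") {
  g <- factor(g)
  k <- nlevels(g)
  N <- length(x)
  r <- rank(x)
  n_i <- tabulate(g)
  Rbar <- tapply(r, g, mean)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- unname(kruskal.test(x, g)$statistic)
  denom_scale <- S2 * (N - 1 - H) / (N - k)
  tmat <- matrix(NA_real_, k, k, dimnames = list(levels(g), levels(g)))
  pmat <- tmat
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(denom_scale * (1 / n_i[i] + 1 / n_i[j]))
    tij <- (Rbar[i] - Rbar[j]) / se
    pij <- 2 * pt(abs(tij), df = N - k, lower.tail = FALSE)
    tmat[i, j] <- tmat[j, i] <- tij
    pmat[i, j] <- pmat[j, i] <- pij
  }
  pv <- pmat[upper.tri(pmat)]
  pmat[upper.tri(pmat)] <- p.adjust(pv, method = p_adjust)
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  list(t = tmat, p = pmat)
}
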