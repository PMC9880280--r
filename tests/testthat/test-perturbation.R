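# synthetic trial ensemble built directly from noise (no simulation):
# trials x regions x (2 * wlen) rates around a known baseline
make_ensemble <- function(n_trials = 6, n_reg = 10, wlen = 100,
                          stim_effect = 0, seed = 1) {
  set.seed(seed)
  rates <- array(5 + rnorm(n_trials * n_reg * 2 * wlen, sd = 0.5),
                 c(n_trials, n_reg, 2 * wlen))
  if (stim_effect > 0)
    rates[, 1, (wlen + 1):(wlen + 20)] <-
      rates[, 1, (wlen + 1):(wlen + 20)] + stim_effect
  structure(list(rates = rates, onset_index = wlen + 1L, dt = 1,
                 window = wlen, n_trials = n_trials,
                 labels = paste0("r", seq_len(n_reg)),
                 stimulus = NULL, seed = seed),
            class = "trial_ensemble")
}

test_that("Lempel-Ziv parse matches a brute-force oracle exhaustively", {
  for (n in 1:12) {
    for (bits in all_bitstrings(n)) {
      expect_identical(lempel_ziv(bits), lz_bruteforce(bits))
    }
  }
})

test_that("Lempel-Ziv matches the oracle on random strings up to 64 bits", {
  set.seed(42)
  for (k in 1:200) {
    n <- sample(1:64, 1)
    bits <- sample(0:1, n, replace = TRUE)
    expect_identical(lempel_ziv(bits), lz_bruteforce(bits))
  }
})

test_that("Lempel-Ziv basics: single word, growth, input contract", {
  expect_identical(lempel_ziv(0L), 1L)
  set.seed(7)
  s1 <- sample(0:1, 40, replace = TRUE)
  s2 <- sample(0:1, 40, replace = TRUE)
  expect_gte(lempel_ziv(c(s1, s2)), lempel_ziv(s1))
  expect_error(lempel_ziv(c(0, 2)), "binary")
  expect_error(lempel_ziv(integer(0)), "nonempty")
})

test_that("source entropy evaluates its closed forms", {
  expect_equal(source_entropy(c(0, 1, 0, 1)), 1)
  expect_equal(source_entropy(c(1, 0, 0, 0)),
               -0.25 * log2(0.25) - 0.75 * log2(0.75))
  expect_equal(source_entropy(c(1, 0, 0, 0)), 0.8112781, tolerance = 1e-6)
  expect_equal(source_entropy(rep(0, 10)), 0)
})

test_that("PCI composes its two ingredients and handles degeneracy", {
  expect_equal(pci(rep(0, 50)), 0)
  s <- rep(c(0L, 1L), 32)
  expect_equal(pci(s), lz_bruteforce(s) / 1)
  expect_gte(pci(sample(0:1, 100, replace = TRUE)), 0)
})

test_that("binarization controls false positives under a null ensemble", {
  tr <- make_ensemble(n_trials = 8, seed = 10)
  bn <- binarize_response(tr, n_shuffles = 300, series_len = 8)
  expect_lte(mean(bn$s), 0.01)  # far below 1 - percentile
  expect_true(all(bn$s %in% c(0L, 1L)))
  expect_equal(ncol(bn$S), 10 * 100)
})

test_that("a separating stimulus marks the stimulated region's early bins", {
  tr <- make_ensemble(n_trials = 6, stim_effect = 30, seed = 11)
  bn <- binarize_response(tr, n_shuffles = 300, series_len = 6)
  expect_true(all(bn$s[, 1, 1:20] == 1L))
  expect_lt(mean(bn$s[, -1, ]), 0.01)
  om <- onset_map(bn)
  expect_true(all(om$onset[, 1] == 1))
  # the stimulated region responds no later than any other region
  expect_true(all(om$onset[, 1] <= apply(om$onset, 1, min, na.rm = TRUE)))
  expect_equal(om$map$frac_responding[1], 1)
})

test_that("flat rates abort binarization with a diagnostic", {
  tr <- make_ensemble(n_trials = 4, seed = 12)
  tr$rates[] <- 5
  expect_error(binarize_response(tr, n_shuffles = 10, series_len = 4),
               "zero pre-stimulus SD")
})

test_that("onset_map requires sustained significance and handles silence", {
  s <- array(0L, c(2, 3, 30))
  s[1, 2, c(5, 10, 11)] <- 1L   # isolated bin at 5, sustained pair at 10
  bn <- structure(list(s = s, S = NULL, threshold = 1, z = NULL,
                       onset_index = 1L, dt = 2,
                       labels = c("a", "b", "c")),
                  class = "binarized_response")
  om <- onset_map(bn, sustain = 2, min_frac = 0.25)
  expect_equal(om$onset[1, 2], 20)  # bin 10 at dt = 2 ms
  expect_true(is.na(om$onset[1, 1]))
  expect_true(all(is.na(om$onset[2, ])))
  expect_true(is.na(om$map$median_onset_ms[1]))
})

test_that("trial ensembles are reproducible and aligned", {
  conn <- small_conn()
  cfg <- brain_config(conn, transient = 1500, duration = 3000, seed = 1)
  st <- stimulus_spec(2, amplitude = 20)
  a <- run_trials(cfg, st, n_trials = 3, seed = 21)
  b <- run_trials(cfg, st, n_trials = 3, seed = 21)
  expect_identical(a$rates, b$rates)
  expect_equal(dim(a$rates), c(3, 8, 600))
  # ERP: the stimulated region's mean response rises right after onset
  erp <- colMeans(a$rates[, 2, ])
  pre <- mean(erp[250:300]); post <- max(erp[301:360])
  expect_gt(post, pre + 1)
  expect_error(run_trials(brain_config(conn, transient = 100,
                                       duration = 1000, seed = 1),
                          st, n_trials = 2, seed = 1),
               "full pre-stimulus")
})

test_that("Conover post-hoc statistics behave like rank-based t tests", {
  set.seed(30)
  x <- c(rnorm(15, 0), rnorm(15, 0), rnorm(15, 3))
  g <- rep(c("a", "b", "c"), each = 15)
  ct <- conover_test(x, g, p_adjust = "none")
  expect_true(isSymmetric(ct$p))
  expect_gt(ct$p["a", "b"], 0.05)   # same distribution
  expect_lt(ct$p["a", "c"], 1e-4)   # separated group
  expect_lt(ct$p["b", "c"], 1e-4)
  expect_equal(sign(ct$t["a", "c"]), -1)  # group c has larger ranks
  expect_true(all(ct$p[upper.tri(ct$p)] >= 0 &
                    ct$p[upper.tri(ct$p)] <= 1))
})
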