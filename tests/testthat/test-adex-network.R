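test_that("parameter validation enforces the physical orderings", {
  p <- adex_params()
  expect_equal(p$c_m, 200)
  expect_equal(p$Q_i, 5)
  expect_error(adex_params(c_m = -1), "c_m")
  expect_error(adex_params(E_i = -60), "E_i")
  expect_error(adex_params(v_thr = -30), "v_thr")
  expect_error(adex_params(u_e = 0), "time constants")
})

test_that("build_network produces a seeded Erdos-Renyi graph", {
  expect_length(build_network(N = 10, p = 0, seed = 1)$adj_idx, 0)
  expect_error(build_network(N = 1), "N")
  expect_error(build_network(p = 1.2), "p")

  a <- build_network(N = 500, p = 0.05, seed = 7)
  b <- build_network(N = 500, p = 0.05, seed = 7)
  expect_identical(a, b)

  src <- rep.int(seq_len(a$N), diff(a$adj_ptr))
  expect_false(any(a$adj_idx + 1L == src))  # no self-connections
})

test_that("realized in-degrees stay within 5 SD of the binomial moments", {
  net <- default_net()
  deg <- in_degrees(net)
  n_e <- sum(net$is_inh == 0L)
  n_i <- sum(net$is_inh == 1L)
  sd_e <- sqrt(n_e * net$p * (1 - net$p))
  sd_i <- sqrt(n_i * net$p * (1 - net$p))
  expect_lt(abs(mean(deg$k_e) - net$p * n_e), 5 * sd_e / sqrt(net$N))
  expect_lt(abs(mean(deg$k_i) - net$p * n_i), 5 * sd_i / sqrt(net$N))
  expect_true(all(abs(deg$k_e - net$p * n_e) <= 5 * sd_e))
  expect_true(all(abs(deg$k_i - net$p * n_i) <= 5 * sd_i))
  expect_equal(mean(deg$k_e + deg$k_i), 500, tolerance = 0.02)
})

test_that("an isolated neuron settles at the subthreshold fixed point", {
  p <- adex_params()
  net <- build_network(N = 2, frac_inh = 0.5, p = 0, seed = 1)
  sp <- simulate_spiking(net, p, duration = 500, drive_rate = 0, seed = 1,
                         monitor = 1, v_init = rep(p$E_L_e, 2))
  expect_length(sp$time, 0)
  # oracle: root of g_L (E_L - v) + g_L Delta exp((v - v_thr)/Delta) = 0
  f <- function(v) p$g_L * (p$E_L_e - v) +
    p$g_L * p$Delta_e * exp((v - p$v_thr) / p$Delta_e)
  v_fix <- uniroot(f, c(-70, -51))$root
  v_end <- tail(sp$traces$v[, 1], 1)
  expect_lt(abs(v_end - v_fix), 0.01)
  expect_lt(abs(v_fix - p$E_L_e), 0.5)
})

test_that("spiking simulation honors refractoriness and conductance signs", {
  net <- build_network(N = 400, p = 0.05, seed = 11)
  sp <- simulate_spiking(net, adex_params(), duration = 1000, seed = 2,
                         monitor = c(1, 300))
  isi_ok <- tapply(sp$time, sp$neuron, function(tt)
    length(tt) < 2 || min(diff(tt)) >= sp$params$T_refr - 1e-9)
  expect_true(all(unlist(isi_ok)))
  expect_true(all(sp$traces$G_e >= 0))
  expect_true(all(sp$traces$G_i >= 0))
})

test_that("identical seeds give identical spike data", {
  net <- build_network(N = 400, p = 0.05, seed = 11)
  a <- simulate_spiking(net, adex_params(), duration = 500,
                        drive_rate = 30, seed = 5, monitor = 1)
  b <- simulate_spiking(net, adex_params(), duration = 500,
                        drive_rate = 30, seed = 5, monitor = 1)
  expect_identical(a$time, b$time)
  expect_identical(a$neuron, b$neuron)
  expect_identical(a$traces$v, b$traces$v)
  c <- simulate_spiking(net, adex_params(), duration = 500,
                        drive_rate = 30, seed = 6, monitor = 1)
  expect_false(identical(a$traces$G_e, c$traces$G_e))
  expect_gt(length(a$time), 0)
})

test_that("population_rate implements the counting identity", {
  sp <- structure(list(neuron = rep(1L, 10),
                       time = seq(50, 950, by = 100), N = 1,
                       is_inh = 0L, duration = 1000, dt = 0.1),
                  class = "spike_data")
  r <- population_rate(sp, bin = 100, population = "e")
  expect_equal(r$rate, rep(10, 10))
  empty <- structure(list(neuron = integer(0), time = numeric(0), N = 5,
                          is_inh = rep(0L, 5), duration = 200, dt = 0.1),
                     class = "spike_data")
  expect_true(all(population_rate(empty)$rate == 0))
})

test_that("classify_state separates constructed AI and Up-Down series", {
  const <- data.frame(time = seq(0, 4999.5, by = 0.5), rate = 10)
  expect_equal(classify_state(const, transient = 0)$label, "AI")
  sq <- data.frame(time = seq(0, 4999.5, by = 0.5),
                   rate = rep(rep(c(0, 20), each = 500), 5))
  cls <- classify_state(sq, transient = 0)
  expect_equal(cls$label, "UpDown")
  expect_equal(cls$silent_fraction, 0.5, tolerance = 0.05)
  expect_error(classify_state(const[1:100, ], transient = 0), "1 s")
})

test_that("spike TSV round trip preserves the data", {
  sp <- structure(list(neuron = c(3L, 1L, 7L, 3L),
                       time = c(0.5, 1.25, 2, 10.75), N = 10,
                       is_inh = rep(0L, 10), duration = 20, dt = 0.1),
                  class = "spike_data")
  path <- tempfile(fileext = ".tsv")
  write_spikes_tsv(sp, path)
  back <- read_spikes_tsv(path)
  expect_equal(back$neuron, sp$neuron)
  expect_equal(back$time, sp$time)
})
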