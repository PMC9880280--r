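test_that("conductance moments match the closed-form identities", {
  m0 <- conductance_moments(0, 0, 0)
  expect_equal(m0$mu_Ge, 0)
  expect_equal(m0$mu_Gi, 0)
  expect_equal(m0$mu_V, adex_params()$E_L_e)

  # mu_Ge = nu_e K_e u_e Q_e = 0.004 * 400 * 5 * 1.5 = 12 nS
  expect_equal(conductance_moments(4, 0, 0)$mu_Ge, 12, tolerance = 1e-6)

  # mu_V decreases monotonically with the adaptation current
  mv <- conductance_moments(rep(5, 4), rep(10, 4), c(0, 50, 150, 400))$mu_V
  expect_true(all(diff(mv) < 0))

  expect_error(conductance_moments(-1, 0), "non-negative")
})

test_that("mu_V stays within the synaptic reversal bounds on the grid", {
  p <- adex_params()
  g <- expand.grid(nu_e = c(0, 1, 5, 20, 40), nu_i = c(0, 1, 5, 20, 40),
                   W = c(0, 50, 100))
  m <- conductance_moments(g$nu_e, g$nu_i, g$W)
  expect_true(all(m$mu_V >= p$E_i - 1e-9))
  expect_true(all(m$mu_V <= p$E_e + 1e-9))
  expect_true(all(m$sigma_V >= 0))
  expect_true(all(m$mu_G >= p$g_L))
})

test_that("the default evaluators respect bounds and population ordering", {
  tfe <- default_tf("RS")
  tfi <- default_tf("FS")
  g <- expand.grid(nu_e = seq(0, 40, by = 4), nu_i = seq(0, 40, by = 4))
  fe <- evaluate_tf(tfe, g$nu_e, g$nu_i, 0)
  fi <- evaluate_tf(tfi, g$nu_e, g$nu_i, 0)
  expect_true(all(fe >= 0 & fe <= 200))
  expect_true(all(fi >= 0 & fi <= 200))
  # FS cells lack adaptation and have a sharper spike initiation: at
  # identical input the inhibitory rate is at least the excitatory one
  expect_true(all(fi >= fe - 1e-6))
  # zero input, zero drive: output below 0.1 Hz
  expect_lt(evaluate_tf(tfe, 0, 0, 0), 0.1)
  # monotone in excitation at fixed inhibition over the fitted grid
  for (ni in c(0, 10, 30)) {
    out <- evaluate_tf(tfe, seq(0, 40, by = 2), ni, 0)
    expect_true(all(diff(out) > -1e-9))
  }
  expect_error(evaluate_tf(adexbrain:::new_tf("RS", adex_params(), 400,
                                              100, numeric(10)), 1, 1),
               "not been fitted")
})

test_that("fit_tf calibrates against single-neuron simulations", {
  tf <- fit_tf(population = "FS", nu_e_grid = c(0, 2, 5, 10),
               nu_i_grid = c(0, 5, 12, 25), sim_time = 10000,
               transient = 1000, n_rep = 10, seed = 31, rms_tol = 2)
  expect_s3_class(tf, "adex_tf")
  expect_true(all(is.finite(tf$P)))
  expect_lt(tf$fit$rms_hz, 2)

  # refitting with a different seed moves grid outputs by < 0.5 Hz
  tf2 <- fit_tf(population = "FS", nu_e_grid = c(0, 2, 5, 10),
                nu_i_grid = c(0, 5, 12, 25), sim_time = 10000,
                transient = 1000, n_rep = 10, seed = 77, rms_tol = 2)
  g <- tf$fit$grid
  d <- evaluate_tf(tf, g$nu_e, g$nu_i, g$W) -
    evaluate_tf(tf2, g$nu_e, g$nu_i, g$W)
  expect_lt(max(abs(d)), 0.5)
})

test_that("a grid with no firing is rejected as degenerate", {
  expect_error(
    fit_tf(population = "RS", nu_e_grid = 0, nu_i_grid = c(20, 40),
           W_grid = 0, sim_time = 300, transient = 100, n_rep = 1,
           seed = 1),
    "degenerate")
})

test_that("oracle equivalence: evaluator matches held-out simulations", {
  # held-out grid inside the fluctuation-driven operating region,
  # not on the calibration lattice
  tfe <- default_tf("RS")
  # balanced pairs along the operating band (measured outputs < 30 Hz)
  held <- data.frame(nu_e = c(1.5, 3, 4.5, 6, 7.5, 9, 2, 5, 8, 10,
                              3.5, 6.5, 9.5, 1, 7),
                     nu_i = c(4, 8, 11, 15, 19, 22, 7, 14, 21, 27,
                              10, 17, 25, 5, 18))
  set.seed(99)
  meas <- adexbrain:::sim_single_neuron_rates_cpp(
    unclass(adex_params()), FALSE, held$nu_e / 1000, held$nu_i / 1000,
    rep(0, nrow(held)), 400, 100, 8000, 1000, 0.1, 10L) * 1000
  pred <- evaluate_tf(tfe, held$nu_e, held$nu_i, 0)
  expect_lt(sqrt(mean((pred - meas)^2)), 1)
})

test_that("transfer functions survive a JSON round trip", {
  tf <- default_tf("RS")
  path <- tempfile(fileext = ".json")
  write_tf_json(tf, path)
  back <- read_tf_json(path)
  expect_equal(back$P, tf$P)
  expect_equal(back$population, tf$population)
  expect_equal(evaluate_tf(back, 5, 10, 20), evaluate_tf(tf, 5, 10, 20))
})
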