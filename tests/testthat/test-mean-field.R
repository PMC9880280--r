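test_that("fixed-point finder handles the degenerate zero transfer map", {
  # a polynomial with a huge constant threshold never fires
  p <- adex_params()
  zero_tf <- adexbrain:::new_tf("RS", p, 400, 100,
                                c(1000, rep(0, 9)))
  zero_tf_i <- adexbrain:::new_tf("FS", p, 400, 100,
                                  c(1000, rep(0, 9)))
  fp <- find_fixed_points(zero_tf, zero_tf_i, W = 0, bracket = c(0, 50))
  expect_equal(nrow(fp), 1)
  expect_equal(fp$nu_e, 0)
  expect_equal(fp$nu_i, 0)
  expect_equal(fp$type, "boundary")
})

test_that("default transfer functions give a low and a high fixed point", {
  fp <- find_fixed_points(default_tf("RS"), default_tf("FS"), W = 0)
  cross <- fp[fp$type == "crossing", ]
  expect_equal(nrow(cross), 2)
  expect_lt(cross$nu_e[1], 2)      # near-zero crossing
  expect_gt(cross$nu_e[2], 4)      # high-rate crossing
  expect_true(cross$stable[2])
  # self-consistent adaptation at b = 60 removes the high-rate crossing
  # or moves it down (adaptation destabilizes the active state)
  fp60 <- find_fixed_points(default_tf("RS"), default_tf("FS"),
                            W_mode = "self-consistent", b = 60)
  hi60 <- fp60[fp60$type == "crossing" & fp60$stable, "nu_e"]
  expect_true(length(hi60) == 0 || max(hi60) < cross$nu_e[2])
})

test_that("first-order integration is deterministic and stays in bounds", {
  p <- mf_params()
  a <- simulate_first_order(p, duration = 2000, seed = 4)
  b <- simulate_first_order(p, duration = 2000, seed = 4)
  expect_identical(a$nu_e, b$nu_e)
  c <- simulate_first_order(p, duration = 2000, seed = 5)
  expect_false(identical(a$nu_e, c$nu_e))
  expect_true(all(a$nu_e >= 0 & a$nu_e <= 200))
  expect_true(all(a$nu_i >= 0 & a$nu_i <= 200))
  expect_true(all(a$W >= 0))
})

test_that("a noise-free run initialized at a fixed point stays there", {
  tfe <- default_tf("RS"); tfi <- default_tf("FS")
  # equilibrium of the driven system (constant drive = mean)
  dr <- 0.3
  ni_star <- function(ne) uniroot(function(x)
    evaluate_tf(tfi, ne + dr, x, 0) - x, c(0, 201), tol = 1e-10)$root
  fe0 <- uniroot(function(ne)
    evaluate_tf(tfe, ne + dr, ni_star(ne), 0) - ne, c(2, 50),
    tol = 1e-10)$root
  p <- mf_params(drive_sd = 0)
  ts <- simulate_first_order(p, duration = 1000, seed = 1,
                             init = list(nu_e = fe0, nu_i = ni_star(fe0),
                                         W = 0))
  expect_lt(max(abs(ts$nu_e - fe0)), 0.05)
})

test_that("slow-wave frequency decreases when u_w is doubled", {
  peak_at <- function(u_w) {
    p <- mf_params(b = 60, u_w = u_w)
    ts <- simulate_first_order(p, duration = 12000, seed = 2)
    post <- ts[ts$time > 2000, ]
    power_spectrum(post$nu_e, fs = 1000, window_s = 4,
                   peak_range = c(0.2, 20))$peak_frequency
  }
  expect_lt(peak_at(1000), peak_at(500))
})

test_that("second order: finite-size covariance scales away as 1/N", {
  p0 <- mf_params(drive_sd = 0)
  eq <- list(nu_e = 7.33, nu_i = 17.1, W = 0, c = c(0, 0, 0))
  small <- simulate_second_order(p0, duration = 4000, seed = 1, init = eq)
  big_p <- mf_params(drive_sd = 0, N_e = 8e7, N_i = 2e7)
  big <- simulate_second_order(big_p, duration = 4000, seed = 1, init = eq)
  cee_small <- tail(small$c_ee, 1)
  cee_big <- tail(big$c_ee, 1)
  expect_gt(cee_small, 0)
  # 1e4-fold larger populations: covariance ~1e4-fold smaller
  expect_lt(cee_big, cee_small / 1000)
  # and the rate trajectory converges to first order
  first <- simulate_first_order(p0, duration = 4000, seed = 1, init = eq)
  expect_lt(max(abs(big$nu_e - first$nu_e)), 0.05)
})

test_that("asymmetric initial covariance is rejected", {
  p <- mf_params()
  expect_error(simulate_second_order(p, duration = 100, seed = 1,
                                     init = list(c = c(1, 2, 3, 4))),
               "symmetric")
})

test_that("first and second order agree in the finite-size regime", {
  p <- mf_params(drive_sd = 0)
  eq <- list(nu_e = 7.33, nu_i = 17.1, W = 0)
  m1 <- mean(tail(simulate_first_order(p, duration = 5000, seed = 1,
                                       init = eq)$nu_e, 2000))
  m2 <- mean(tail(simulate_second_order(p, duration = 5000, seed = 1,
                                        init = eq)$nu_e, 2000))
  expect_lt(abs(m1 - m2) / m1, 0.2)
})

test_that("mean-field dt-halving changes the mean rate by < 5%", {
  p <- mf_params(drive_sd = 0)
  m1 <- mean(tail(simulate_first_order(p, duration = 3000, dt = 0.1,
                                       seed = 1)$nu_e, 1000))
  m2 <- mean(tail(simulate_first_order(p, duration = 3000, dt = 0.05,
                                       seed = 1)$nu_e, 1000))
  expect_lt(abs(m1 - m2) / m1, 0.05)
})
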