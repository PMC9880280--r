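test_that("connectome construction validates its invariants", {
  c2 <- connectome(diag(2), matrix(0, 2, 2))
  expect_equal(c2$n_regions, 2)
  expect_error(connectome(matrix(-1, 2, 2), matrix(0, 2, 2)), "negative")
  expect_error(connectome(diag(2), matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(connectome(diag(2), matrix(0, 3, 3)), "shape")
})

test_that("CSV round trip and ragged-file error contract", {
  conn <- small_conn()
  dir <- tempfile("conncsv")
  write_connectome_csv(conn, dir)
  back <- load_connectome(dir, dialect = "csv")
  expect_equal(back$weights, conn$weights, tolerance = 1e-12)
  expect_equal(back$tract_lengths, conn$tract_lengths, tolerance = 1e-12)
  expect_equal(back$labels, conn$labels)

  bad <- tempfile("badcsv"); dir.create(bad)
  writeLines(c("1,0,0", "0,1", "0,0,1"), file.path(bad, "weights.csv"))
  writeLines(c("0,0,0", "0,0,0", "0,0,0"),
             file.path(bad, "tract_lengths.csv"))
  expect_error(load_connectome(bad, dialect = "csv"), "row 2")
})

test_that("TVB text dialect loads matrices and centres", {
  conn <- small_conn()
  dir <- tempfile("tvb"); dir.create(dir)
  write.table(conn$weights, file.path(dir, "weights.txt"),
              row.names = FALSE, col.names = FALSE)
  write.table(conn$tract_lengths, file.path(dir, "tract_lengths.txt"),
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(conn$labels, conn$centres),
              file.path(dir, "centres.txt"), row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  back <- load_connectome(dir)
  expect_equal(back$n_regions, 8)
  expect_equal(back$weights, conn$weights, tolerance = 1e-12)
  expect_equal(unname(back$centres), unname(conn$centres),
               tolerance = 1e-12)
})

test_that("weight normalization follows the volume-sum rule", {
  expect_equal(normalize_weights(matrix(100, 1, 1), 10, rescale = FALSE),
               matrix(5, 1, 1))
  w <- normalize_weights(matrix(3, 4, 4), rep(2, 4))
  expect_true(all(w == 1))  # uniform counts and volumes -> all 1
  z <- normalize_weights(matrix(0, 3, 3), rep(1, 3))
  expect_true(all(z == 0))
  expect_error(normalize_weights(matrix(1, 2, 2), c(1, 0)), "positive")
})

test_that("delays derive from tract lengths and propagation speed", {
  conn <- connectome(matrix(1, 2, 2),
                     matrix(c(0, 130, 130, 0), 2))
  d <- compute_delays(conn, v_c = 3)
  expect_equal(d[1, 2], 130 / 3, tolerance = 1e-12)
  expect_equal(diag(d), c(0, 0))
  expect_equal(compute_delays(conn, 6), d / 2)
  expect_error(compute_delays(conn, 0), "v_c")
})

test_that("row shuffling preserves multisets and tract lengths", {
  conn <- small_conn()
  sh <- shuffle_weights(conn, seed = 4)
  expect_identical(sh$tract_lengths, conn$tract_lengths)
  expect_equal(sum(sh$weights), sum(conn$weights))
  for (j in seq_len(conn$n_regions)) {
    off <- setdiff(seq_len(conn$n_regions), j)
    expect_equal(sort(sh$weights[j, off]), sort(conn$weights[j, off]))
  }
  expect_identical(shuffle_weights(conn, seed = 4)$weights, sh$weights)
  expect_false(identical(shuffle_weights(conn, seed = 5)$weights,
                         sh$weights))
})

test_that("seeded 3x3 shuffle matches its frozen golden permutation", {
  conn <- connectome(matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3,
                            byrow = TRUE), matrix(0, 3, 3))
  sh <- shuffle_weights(conn, seed = 1)
  # frozen from one seeded run of the permuter
  expect_equal(sh$weights,
               matrix(c(0, 1, 2, 3, 0, 4, 6, 5, 0), 3, byrow = TRUE))
})

test_that("the synthetic connectome has the advertised structure", {
  conn <- syn_conn()
  expect_equal(conn$n_regions, 68)
  w <- conn$weights[upper.tri(conn$weights)]
  skew <- mean((w - mean(w))^3) / sd(w)^3
  expect_gt(skew, 1)  # heavy-tailed weights
  expect_equal(max(conn$weights), 1)
  # mirrored hemispheres: centroids symmetric about the midplane x = 0
  cl <- colMeans(conn$centres[conn$hemisphere == "L", ])
  cr <- colMeans(conn$centres[conn$hemisphere == "R", ])
  expect_equal(cl[1], -cr[1], tolerance = 1e-9)
  expect_equal(cl[2:3], cr[2:3], tolerance = 1e-9)
  # tract lengths = Euclidean distance x tortuosity
  d <- as.matrix(dist(conn$centres))
  expect_equal(conn$tract_lengths, unname(d * 1.3), tolerance = 1e-9)
  expect_identical(generate_synthetic_connectome(68, seed = 42)$weights,
                   conn$weights)
  expect_error(generate_synthetic_connectome(2), ">= 4")
  expect_error(generate_synthetic_connectome(9), "even")
})
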