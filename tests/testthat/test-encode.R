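test_that("spike latency is ln(R)/gamma with proper domain checks", {
  expect_equal(spike_latency(1, 0.37), 0)
  expect_equal(spike_latency(exp(1), 1), 1)
  set.seed(11)
  r <- exp(runif(200, -3, 6))
  g <- runif(200, 0.1, 5)
  expect_equal(spike_latency(r, g), log(r) / g, tolerance = 1e-12)
  expect_error(spike_latency(c(2, -1, 3)), "sensor index 1")
  expect_error(spike_latency(0), "sensor")
  expect_error(spike_latency(2, gamma = 0), "gamma")
})

test_that("encode_exposure maps one full exposure to latencies", {
  feats <- data.frame(sensor_index = 0:15, resistance = rep(1, 16),
                      analyte = "h2", concentration = 20)
  p <- encode_exposure(feats)
  expect_s3_class(p, "spike_pattern")
  expect_equal(p$latencies, rep(0, 16))
  expect_equal(as.character(p$analyte), "h2")

  feats$resistance <- exp(seq(0.1, 1.6, by = 0.1))
  expect_true(all(diff(encode_exposure(feats)$latencies) > 0))

  # shuffled row order must not matter: latencies keyed by sensor_index
  sh <- feats[sample(16), ]
  expect_equal(encode_exposure(sh)$latencies, encode_exposure(feats)$latencies)

  expect_error(encode_exposure(feats[-3, ]), "exactly one feature")
  dup <- feats; dup$sensor_index[2] <- 0L
  expect_error(encode_exposure(dup), "exactly one feature")
})

test_that("generator latencies round-trip through the encoder closed form", {
  cfg <- enose_config(noise_sd = 0, shuffle_sd = 0, seed = 5)
  ex <- sample_exposure(cfg, "acetone", 200, seed = 9)
  p <- encode_exposure(ex)
  k <- match("acetone", cfg$classes)
  expected <- cfg$beta_base + cfg$spacing * cfg$templates[[k]] -
    cfg$alpha[[k]] * log(200 / cfg$c0)
  expect_equal(p$latencies, expected, tolerance = 1e-12)
})

test_that("rank extraction matches an argsort oracle and breaks ties by sensor", {
  expect_equal(to_rank_order(0:15), 0:15)
  expect_equal(to_rank_order(rep(3.5, 16)), 0:15)  # tie rule
  set.seed(21)
  for (i in 1:200) {
    lat <- rnorm(16)
    expect_equal(to_rank_order(lat), rank(lat, ties.method = "first") - 1L)
  }
  # ranks are always a permutation, incl. with heavy ties
  for (i in 1:50) {
    lat <- sample(c(0, 1, 2), 16, replace = TRUE)
    expect_setequal(to_rank_order(lat), 0:15)
  }
  expect_error(to_rank_order(c(rep(0, 15), NA)), "finite")
})

test_that("latency is strictly increasing in resistance for fixed gamma", {
  r <- sort(exp(runif(50, -2, 4)))
  expect_true(all(diff(spike_latency(r, 2.3)) > 0))
})

test_that("byte encoding of rank orders is exact and invertible", {
  v <- rank_order_to_vector(0:15, scale = 16)
  expect_equal(v$components, seq(0L, 240L, by = 16L))
  expect_true(all(v$mask))

  empty <- rank_order_to_vector(0:15, received = integer(0))
  expect_false(any(empty$mask))
  expect_equal(manhattan_distance(empty, rank_vector(rep(255L, 16))), 0)

  set.seed(3)
  for (i in 1:25) {
    p <- rand_perm()
    for (scale in c(1L, 7L, 16L, 17L)) {
      v <- rank_order_to_vector(p, scale = scale)
      expect_equal(vector_to_rank_order(v, scale = scale), p)
    }
  }
  expect_error(rank_order_to_vector(0:15, scale = 18), "byte range")
  expect_error(rank_order_to_vector(c(0:14, 14L)), "permutation")
  expect_error(rank_order_to_vector(0:15, received = c(1, 1)), "distinct")
})

test_that("full-mask Manhattan distance equals scale x Spearman footrule", {
  set.seed(8)
  for (i in 1:100) {
    a <- rand_perm(); b <- rand_perm()
    scale <- sample(1:16, 1)
    d <- manhattan_distance(rank_order_to_vector(a, scale = scale),
                            rank_order_to_vector(b, scale = scale))
    expect_identical(d, scale * footrule_oracle(a, b))
    expect_identical(footrule(a, b), footrule_oracle(a, b))
  }
})

test_that("windowed vectors only compare received sensors", {
  a <- rand_perm(); b <- rand_perm()
  rec <- c(0L, 4L, 9L)
  v <- rank_order_to_vector(a, received = rec)
  p <- rank_order_to_vector(b)
  expect_equal(manhattan_distance(v, p),
               16 * sum(abs(a[rec + 1] - b[rec + 1])))
})

test_that("encode_table vectorises the pipeline and rejects bad features", {
  cfg <- enose_config(samples_per_class = 4, seed = 2)
  ds <- sample_dataset(cfg)
  enc <- encode_table(ds$features)
  expect_equal(dim(enc$ranks), c(24L, 16L))
  expect_equal(as.character(enc$labels), as.character(ds$labels))
  # row-wise agreement with the scalar path
  for (i in c(1, 10, 24)) {
    feats <- data.frame(sensor_index = 0:15,
                        resistance = as.numeric(ds$features[i, paste0("S", 0:15)]))
    expect_equal(unname(enc$ranks[i, ]),
                 to_rank_order(encode_exposure(feats)))
  }
  bad <- ds$features
  bad$S3[2] <- -1
  expect_error(encode_table(bad), "clamp")
})

test_that("gamma calibration back-solves the latency equation", {
  r <- c(10, 100, 1000)
  t_ref <- c(1, 2, 3)
  g <- estimate_gamma(r, t_ref)
  expect_equal(log(r) / g, t_ref)
  expect_error(estimate_gamma(c(2, 0.5), c(1, 1)), "positive gamma")
})
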