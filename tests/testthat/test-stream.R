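# a small trained network shared across streaming tests
stream_fixture <- function() {
  tpls <- default_templates(4)
  refs <- do.call(rbind, tpls)
  rownames(refs) <- c("w", "x", "y", "z")
  rosnn(references = refs, labels = rownames(refs))
}

test_that("the first spike is classified on a one-component window", {
  fit <- stream_fixture()
  st <- new_stream(fit$network)
  res <- push_spike(st, 5L)
  expect_s3_class(res, "rce_result")
  expect_equal(st$n_received, 1L)
  # one-component window: distance to each prototype is scale * its rank
  d0 <- 16 * fit$references[, 6]
  expect_equal(min(res$hits$distance), min(d0))
})

test_that("streaming a stored reference ends identified at distance zero", {
  fit <- stream_fixture()
  for (cl in rownames(fit$references)) {
    tr <- stream_pattern(fit$network, fit$references[cl, ])
    expect_true(tr$complete)
    final <- tr$results[[16]]
    expect_equal(final$hits$distance[1], 0)
    expect_equal(final$hits$category[1], cl)
    d <- latch_decision(tr)
    expect_equal(d$category, cl)
  }
})

test_that("duplicate or excess spikes are frame errors", {
  fit <- stream_fixture()
  st <- new_stream(fit$network)
  push_spike(st, 3L)
  expect_error(push_spike(st, 3L), "already spiked")
  expect_error(push_spike(st, 16L), "sensor_index")
  for (s in c(0:2, 4:15)) push_spike(st, s)
  expect_error(push_spike(st, 3L), "already spiked")
})

test_that("per-spike results equal batch classification of masked vectors", {
  fit <- stream_fixture()
  set.seed(47)
  for (i in 1:25) {
    frame <- rand_perm()
    tr <- stream_pattern(fit$network, frame)
    arrival <- order(frame) - 1L          # sensor indices in firing order
    for (m in 1:16) {
      batch <- rce_classify(fit$network,
                            rank_order_to_vector(frame,
                                                 received = arrival[1:m]))
      expect_equal(tr$results[[m]]$hits, batch$hits)
      expect_equal(tr$results[[m]]$status, batch$status)
    }
  }
})

test_that("masked distance grows monotonically with the window", {
  fit <- stream_fixture()
  set.seed(53)
  for (i in 1:20) {
    frame <- rand_perm()
    arrival <- order(frame) - 1L
    for (j in 1:4) {
      d <- vapply(1:16, function(m)
        manhattan_distance(rank_order_to_vector(frame,
                                                received = arrival[1:m]),
                           fit$network$proto[j, ]), 0)
      expect_true(all(diff(d) >= 0))
    }
  }
})

test_that("stable latch matches a brute-force suffix scan", {
  # hand cases
  tr1 <- fake_trace(rep("a", 16))
  expect_equal(latch_decision(tr1)$spikes_to_decision, 1L)
  expect_equal(latch_decision(tr1)$frame_fraction, 6.25)
  tr2 <- fake_trace(c(rep("b", 4), rep("a", 12)))
  expect_equal(latch_decision(tr2)$spikes_to_decision, 5L)
  tr3 <- fake_trace(c(rep("a", 15), NA))
  expect_null(latch_decision(tr3))
  # randomized traces vs oracle
  set.seed(59)
  for (i in 1:100) {
    top <- sample(c("a", "b", NA), 16, replace = TRUE,
                  prob = c(0.45, 0.45, 0.1))
    tr <- fake_trace(top)
    d <- latch_decision(tr)
    m <- stable_latch_oracle(top)
    if (is.na(m)) expect_null(d)
    else {
      expect_equal(d$spikes_to_decision, m)
      expect_equal(d$category, top[16])
      expect_equal(d$frame_fraction, 100 * m / 16)
    }
  }
})

test_that("first-identified latch picks the first unanimous window", {
  top <- c("b", "a", "a", rep("a", 13))
  status <- c("uncertain", "uncertain", "identified", rep("identified", 13))
  tr <- fake_trace(top, status)
  d <- latch_decision(tr, policy = "first-identified")
  expect_equal(d$spikes_to_decision, 3L)
  expect_equal(d$category, "a")
  # never identified -> no decision
  tr2 <- fake_trace(rep("a", 16), rep("uncertain", 16))
  expect_null(latch_decision(tr2, policy = "first-identified"))
})

test_that("anomaly log captures only unknown full frames", {
  fit <- stream_fixture()
  log <- new_anomaly_log()
  # a stored reference is never logged
  tr <- stream_pattern(fit$network, fit$references[1, ])
  expect_null(log_anomaly(log, tr))
  expect_length(anomaly_records(log), 0)
  # a frame beyond every influence field is logged with category unknown;
  # tight influence fields (max_if = 64, footrule 4 at scale 16) make any
  # pattern further than two adjacent swaps from every reference unknown
  tight <- rosnn(references = fit$references,
                 labels = rownames(fit$references), max_if = 64)
  set.seed(61)
  repeat {
    far <- rand_perm()
    if (min(apply(fit$references, 1, footrule, far)) > 4) break
  }
  tr2 <- stream_pattern(tight$network, far, frame_id = "f42")
  rec <- log_anomaly(log, tr2)
  expect_equal(rec$category, "unknown")
  expect_equal(rec$frame_id, "f42")
  expect_length(anomaly_records(log), 1)
  # incomplete frames are flagged and never logged
  partial <- fit$references[2, ]
  partial[partial > 11] <- NA
  tr3 <- stream_pattern(fit$network, partial)
  expect_false(tr3$complete)
  expect_equal(tr3$n_received, 12L)
  expect_null(log_anomaly(log, tr3))
})
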