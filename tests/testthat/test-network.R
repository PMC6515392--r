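test_that("Manhattan distance matches hand sums and the loop oracle", {
  expect_equal(manhattan_distance(c(0, 3), c(3, 0)), 6)
  v <- rank_vector(c(7L, 7L)); expect_equal(manhattan_distance(v, v), 0)
  set.seed(4)
  for (i in 1:200) {
    v <- sample(0:255, 16, replace = TRUE)
    p <- sample(0:255, 16, replace = TRUE)
    mask <- runif(16) < runif(1)
    expect_equal(manhattan_distance(rank_vector(v, mask), rank_vector(p)),
                 manhattan_oracle(v, p, mask))
  }
  expect_error(manhattan_distance(1:4, 1:5), "lengths differ")
})

test_that("first commit takes the maximum influence field", {
  net <- rce_network(rce_config(max_if = 1000, min_if = 10))
  rep1 <- rce_learn(net, rank_order_to_vector(rand_perm()), "A")
  expect_true(rep1$committed)
  expect_equal(net$aif, 1000L)
  expect_equal(net$category, "A")
})

test_that("learning a second category shrinks and commits at the mutual distance", {
  v1 <- rank_order_to_vector(0:15)
  p2 <- c(1L, 0L, 2:15)                      # one adjacent swap
  v2 <- rank_order_to_vector(p2)
  d <- manhattan_distance(v1, v2)            # 32
  net <- rce_network()
  rce_learn(net, v1, "A")
  rep2 <- rce_learn(net, v2, "B")
  expect_true(rep2$committed)
  expect_equal(net$aif, c(d, d))
  expect_equal(rep2$shrunk$neuron_id, 1L)
  expect_equal(rep2$shrunk$new_aif, d)
})

test_that("a firing correct-category neuron absorbs the pattern (no duplicate)", {
  net <- rce_network()
  v <- rank_order_to_vector(rand_perm())
  rce_learn(net, v, "A")
  rep2 <- rce_learn(net, v, "A")
  expect_false(rep2$committed)
  expect_equal(rce_size(net), 1L)
  res <- rce_classify(net, v)
  expect_equal(res$hits$distance, 0)
  expect_equal(res$status, "identified")
})

test_that("shrinkage clamps at min_if and flags the neuron degenerate", {
  net <- rce_network(rce_config(min_if = 100, max_if = 3840))
  p1 <- 0:15
  p2 <- c(1L, 0L, 2:15)                      # distance 32 < min_if
  rce_learn(net, rank_order_to_vector(p1), "A")
  rce_learn(net, rank_order_to_vector(p2), "B")
  expect_equal(net$aif[1], 100L)             # clamped, not 32
  expect_true(net$degenerate[1])
  expect_equal(net$aif[2], 100L)             # new neuron clamped too
})

test_that("capacity exhaustion raises when a commit is required", {
  net <- rce_network(rce_config(capacity = 2, max_if = 5, min_if = 1),
                     n_features = 16L)
  rce_learn(net, rank_order_to_vector(0:15), "A")
  rce_learn(net, rank_order_to_vector(15:0), "B")
  expect_error(rce_learn(net, rank_order_to_vector(rand_perm()), "C"),
               "capacity")
})

test_that("classification equals an exhaustive nearest-neighbour scan", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    protos <- matrix(sample(0:255, n * 16, replace = TRUE), n, 16)
    cats <- sample(LETTERS[1:4], n, replace = TRUE)
    k <- sample(1:4, 1)
    for (mode in c("RBF", "KNN")) {
      net <- toy_net(protos, cats,
                     rce_config(mode = mode, k = k, max_if = 2000,
                                min_if = 1))
      v <- sample(0:255, 16, replace = TRUE)
      res <- rce_classify(net, v)
      # oracle: brute-force scan of the *actual* stored neurons
      d <- apply(net$proto, 1, function(p) manhattan_oracle(v, p))
      firing <- if (mode == "RBF") which(d < net$aif) else seq_along(d)
      expect_equal(res$n_firing, length(firing))
      if (length(firing) == 0) {
        expect_equal(res$status, "unknown")
        expect_equal(nrow(res$hits), 0L)
      } else {
        ord <- firing[order(d[firing], firing)]
        top <- head(ord, k)
        expect_equal(res$hits$neuron_id, top)
        expect_equal(res$hits$distance, d[top])
        expect_equal(res$hits$category, net$category[top])
        expect_equal(res$status,
                     if (length(unique(net$category[firing])) == 1)
                       "identified" else "uncertain")
      }
    }
  }
})

test_that("KNN mode never returns unknown; RBF firing is a subset of KNN's", {
  set.seed(13)
  protos <- matrix(sample(0:255, 5 * 16, replace = TRUE), 5, 16)
  cats <- c("A", "B", "C", "A", "B")
  rbf <- toy_net(protos, cats, rce_config(mode = "RBF", min_if = 1,
                                          max_if = 50))
  knn <- toy_net(protos, cats, rce_config(mode = "KNN", min_if = 1,
                                          max_if = 50))
  for (i in 1:50) {
    v <- sample(0:255, 16, replace = TRUE)
    rk <- rce_classify(knn, v)
    rr <- rce_classify(rbf, v)
    expect_false(rk$status == "unknown")
    expect_true(rr$n_firing <= rk$n_firing)
    expect_true(all(rr$hits$neuron_id %in% seq_len(5)))
  }
})

test_that("classification is invariant to neuron commit order", {
  set.seed(17)
  protos <- matrix(sample(0:255, 6 * 16, replace = TRUE), 6, 16)
  cats <- c("A", "B", "C", "D", "E", "F")
  # max_if below every pairwise distance: commits never interact, so both
  # nets hold identical (prototype, category, aif) sets in different slots
  cfgs <- rce_config(max_if = 5, min_if = 1)
  net1 <- toy_net(protos, cats, cfgs)
  ord <- sample(6)
  net2 <- toy_net(protos[ord, ], cats[ord], cfgs)
  for (i in 1:40) {
    v <- sample(0:255, 16, replace = TRUE)
    r1 <- rce_classify(net1, v)
    r2 <- rce_classify(net2, v)
    expect_equal(r1$status, r2$status)
    expect_equal(r1$hits$distance, r2$hits$distance)
    expect_equal(sort(paste(r1$hits$category, r1$hits$distance)),
                 sort(paste(r2$hits$category, r2$hits$distance)))
  }
})

test_that("equal distances are won by the lower neuron id", {
  protos <- rbind(0:15, 0:15) * 16L
  net <- toy_net(protos, c("A", "B"), rce_config(max_if = 5, min_if = 1))
  # both neurons hold the same prototype (committed under tiny max_if)
  expect_equal(rce_size(net), 2L)
  res <- rce_classify(net, rank_order_to_vector(0:15))
  expect_equal(res$hits$neuron_id, c(1L, 2L))
  expect_equal(res$hits$category[1], "A")
})

test_that("AIF trajectories are non-increasing within [min_if, max_if]", {
  set.seed(23)
  cfg <- rce_config(max_if = 2000, min_if = 8)
  net <- rce_network(cfg)
  prev <- integer(0)
  for (i in 1:120) {
    v <- sample(0:240, 16, replace = TRUE)
    rce_learn(net, rank_vector(v), sample(c("A", "B", "C"), 1))
    cur <- net$aif
    expect_true(all(cur >= cfg$min_if & cur <= cfg$max_if))
    if (length(prev)) expect_true(all(cur[seq_along(prev)] <= prev))
    prev <- cur
  }
})

test_that("network state survives a JSON round trip bit-exactly", {
  set.seed(29)
  net <- rce_network(rce_config(mode = "RBF", k = 3, max_if = 999,
                                min_if = 7))
  for (i in 1:10)
    rce_learn(net, rank_order_to_vector(rand_perm()), sample(c("x", "y"), 1))
  js <- rce_serialize(net)
  back <- rce_deserialize(js)
  expect_identical(back$proto, net$proto)
  expect_identical(back$category, net$category)
  expect_identical(back$aif, net$aif)
  expect_identical(back$degenerate, net$degenerate)
  expect_identical(unclass(back$config), unclass(net$config))
  # and via a file
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(js, f)
  expect_identical(rce_deserialize(f)$proto, net$proto)
  # empty network round trip
  e <- rce_network()
  expect_equal(rce_size(rce_deserialize(rce_serialize(e))), 0L)
})

test_that("classifying on an empty network is a state error", {
  expect_error(rce_classify(rce_network(), rank_order_to_vector(0:15)),
               "no committed neurons")
})
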