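# shared helpers: independent brute-force oracles and small generators

rand_perm <- function(n = 16L) sample(0:(n - 1L))

# elementwise loop oracle for the masked Manhattan distance
manhattan_oracle <- function(v, p, mask = rep(TRUE, length(v))) {
  s <- 0
  for (i in which(mask)) s <- s + abs(v[i] - p[i])
  s
}

# footrule by explicit loop (independent of footrule())
footrule_oracle <- function(a, b) {
  s <- 0L
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s
}

# all permutations of 1..n (for exhaustive assignment oracles)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# exhaustive maximum-probability assignment score on a small matrix
best_assignment_score <- function(p) {
  n <- nrow(p)
  best <- -Inf
  for (perm in all_perms(n)) {
    s <- sum(p[cbind(seq_len(n), perm)])
    if (s > best) best <- s
  }
  best
}

# build a trained toy network from explicit prototypes
toy_net <- function(protos, cats, config = rce_config()) {
  net <- rce_network(config, n_features = ncol(protos))
  for (i in seq_len(nrow(protos)))
    rce_learn(net, as.integer(protos[i, ]), cats[i])
  net
}

# hand-made trace with given per-spike top-1 categories and statuses
fake_trace <- function(top, status = NULL, frame_size = 16L) {
  m <- length(top)
  if (is.null(status))
    status <- ifelse(is.na(top), "unknown", "identified")
  results <- lapply(seq_len(m), function(i) {
    hits <- if (is.na(top[i]))
      data.frame(category = character(0), distance = numeric(0),
                 neuron_id = integer(0))
    else data.frame(category = top[i], distance = i, neuron_id = 1L)
    structure(list(hits = hits, status = status[i],
                   n_firing = nrow(hits)), class = "rce_result")
  })
  structure(list(results = results, ranks = rep(NA_integer_, frame_size),
                 n_received = m, complete = m == frame_size,
                 frame_id = NULL, frame_size = frame_size),
            class = "rosnn_trace")
}

# suffix-scan oracle for the stable latch policy
stable_latch_oracle <- function(top) {
  M <- length(top)
  for (m in seq_len(M)) {
    w <- top[m:M]
    if (!anyNA(w) && all(w == w[1])) return(m)
  }
  NA_integer_
}
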