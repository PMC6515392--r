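#' Open a streaming classification frame
#'
#' Starts an increasing pattern-matching window against a trained
#' network. Spikes are pushed one at a time with [push_spike()]; each
#' spike enlarges the window (the mask of received sensors) and triggers
#' a classification of the partial rank-order signature, so a recognition
#' result is available from the very first spike.
#'
#' @param net a trained `"rce_network"`.
#' @param scale byte step per rank level (must match the encoding used at
#'   training; default 16).
#' @param frame_size sensors per frame (default: the network's feature
#'   length).
#' @param frame_id optional identifier carried into anomaly records.
#' @return a mutable object of class `"rosnn_stream"`.
#' @export
new_stream <- function(net, scale = 16L, frame_size = net$n_features,
                       frame_id = NULL) {
  stopifnot(inherits(net, "rce_network"))
  st <- new.env(parent = emptyenv())
  st$net <- net
  st$scale <- as.integer(scale)
  st$frame_size <- as.integer(frame_size)
  st$ranks <- rep(NA_integer_, frame_size)
  st$n_received <- 0L
  st$results <- vector("list", frame_size)
  st$frame_id <- frame_id
  class(st) <- "rosnn_stream"
  st
}

#' Push one spike into the pattern-matching window
#'
#' The `n`-th spike received in a frame carries rank `n - 1` (spikes
#' arrive in firing order). The partial signature over all received
#' sensors is encoded with the received set as mask and broadcast to the
#' network; the per-spike result is appended to the frame trace and
#' returned.
#'
#' @param stream a `"rosnn_stream"`.
#' @param sensor_index 0-based index of the sensor that just spiked; a
#'   sensor may appear at most once per frame.
#' @return the `"rce_result"` for the current window.
#' @export
push_spike <- function(stream, sensor_index) {
  stopifnot(inherits(stream, "rosnn_stream"))
  s <- as.integer(sensor_index)
  if (length(s) != 1L || is.na(s) || s < 0L || s >= stream$frame_size)
    stop("sensor_index must be a single value in 0..",
         stream$frame_size - 1L, call. = FALSE)
  if (!is.na(stream$ranks[s + 1L]))
    stop("sensor ", s, " already spiked in this frame", call. = FALSE)
  if (stream$n_received >= stream$frame_size)
    stop("frame already complete (", stream$frame_size, " spikes)",
         call. = FALSE)
  stream$ranks[s + 1L] <- stream$n_received
  stream$n_received <- stream$n_received + 1L
  received <- which(!is.na(stream$ranks)) - 1L
  comp <- ifelse(is.na(stream$ranks), 0L, stream$ranks) * stream$scale
  v <- rank_vector(comp, mask = !is.na(stream$ranks))
  res <- rce_classify(stream$net, v)
  stream$results[[stream$n_received]] <- res
  res
}

#' Finalize a streamed frame into a trace
#'
#' @param stream a `"rosnn_stream"` after pushing its spikes.
#' @return object of class `"rosnn_trace"`: list with `results` (one
#'   `"rce_result"` per spike received), `ranks` (rank of each sensor, NA
#'   for sensors that never spiked), `n_received`, `complete` (all sensors
#'   seen), `frame_id`, `frame_size`.
#' @export
stream_trace <- function(stream) {
  stopifnot(inherits(stream, "rosnn_stream"))
  structure(list(results = stream$results[seq_len(stream$n_received)],
                 ranks = stream$ranks,
                 n_received = stream$n_received,
                 complete = stream$n_received == stream$frame_size,
                 frame_id = stream$frame_id,
                 frame_size = stream$frame_size),
            class = "rosnn_trace")
}

#' Stream a complete rank-order signature through the network
#'
#' Convenience wrapper: replays the frame spike by spike in firing order
#' (sensor with rank 0 first) and returns the finished trace.
#'
#' @param net a trained `"rce_network"`.
#' @param ranks integer rank-of-sensor signature (may contain NA for
#'   sensors that never fired; the frame is then flagged incomplete).
#' @param scale,frame_id see [new_stream()].
#' @return a `"rosnn_trace"`.
#' @export
stream_pattern <- function(net, ranks, scale = 16L, frame_id = NULL) {
  ranks <- as.integer(ranks)
  st <- new_stream(net, scale = scale, frame_size = length(ranks),
                   frame_id = frame_id)
  fired <- which(!is.na(ranks))
  for (s in fired[order(ranks[fired])]) push_spike(st, s - 1L)
  stream_trace(st)
}

#' @export
print.rosnn_trace <- function(x, ...) {
  cat("Stream trace", if (!is.null(x$frame_id)) paste0(" [", x$frame_id, "]"),
      ": ", x$n_received, "/", x$frame_size, " spikes",
      if (!x$complete) " (incomplete)", "\n", sep = "")
  top <- vapply(x$results, function(r)
    if (nrow(r$hits)) r$hits$category[1] else "-", "")
  cat("  per-spike top-1:", paste(top, collapse = " "), "\n")
  d <- latch_decision(x)
  if (is.null(d)) cat("  no latched decision\n")
  else cat(sprintf("  decision: %s after %d spikes (%.2f%% of frame)\n",
                   d$category, d$spikes_to_decision, d$frame_fraction))
  invisible(x)
}

#' Latch a continuous-classification decision from a trace
#'
#' Two policies for turning the per-spike results into a single decision
#' with its spikes-to-decision count:
#' \itemize{
#'   \item `"stable"` (default, used for reported metrics): the smallest
#'     window `m` such that a top-1 category exists at every window
#'     `m..M` and never changes again;
#'   \item `"first-identified"`: the smallest window whose status is
#'     `"identified"` (every firing neuron agrees).
#' }
#'
#' @param trace a `"rosnn_trace"`.
#' @param policy `"stable"` or `"first-identified"`.
#' @return list with `category`, `spikes_to_decision`, `frame_fraction`
#'   (percent of the frame), or `NULL` if no decision latches.
#' @export
latch_decision <- function(trace, policy = c("stable", "first-identified")) {
  stopifnot(inherits(trace, "rosnn_trace"))
  policy <- match.arg(policy)
  M <- trace$n_received
  if (M == 0L) return(NULL)
  top <- vapply(trace$results, function(r)
    if (nrow(r$hits)) r$hits$category[1] else NA_character_, "")
  m <- NA_integer_
  if (policy == "stable") {
    if (!is.na(top[M])) {
      m <- M
      while (m > 1L && !is.na(top[m - 1L]) && top[m - 1L] == top[M])
        m <- m - 1L
    }
  } else {
    idf <- which(vapply(trace$results, function(r)
      r$status == "identified", TRUE))
    if (length(idf)) m <- idf[1L]
  }
  if (is.na(m)) return(NULL)
  list(category = top[if (policy == "stable") M else m],
       spikes_to_decision = m,
       frame_fraction = frame_fraction(m, trace$frame_size))
}

#' Create an anomaly log
#'
#' Open-set bookkeeping: frames whose complete signature matches no
#' stored reference (full-frame RBF status `"unknown"`) are stored with
#' the category `"unknown"` for later retrieval and labelling — e.g. to
#' detect consistent signature changes caused by sensor drift.
#'
#' @return a mutable object of class `"rosnn_anomaly_log"`.
#' @export
new_anomaly_log <- function() {
  lg <- new.env(parent = emptyenv())
  lg$records <- list()
  class(lg) <- "rosnn_anomaly_log"
  lg
}

#' Log a frame as an anomaly if its full signature is unknown
#'
#' @param log a `"rosnn_anomaly_log"`.
#' @param trace a complete `"rosnn_trace"`.
#' @return the anomaly record (list with `ranks`, `frame_id`, `category =
#'   "unknown"`, `timestamp`), or `NULL` when the frame was recognised.
#'   Incomplete frames are never logged.
#' @export
log_anomaly <- function(log, trace) {
  stopifnot(inherits(log, "rosnn_anomaly_log"),
            inherits(trace, "rosnn_trace"))
  if (!trace$complete) return(invisible(NULL))
  final <- trace$results[[trace$n_received]]
  if (final$status != "unknown") return(invisible(NULL))
  rec <- list(ranks = trace$ranks, frame_id = trace$frame_id,
              category = "unknown", timestamp = Sys.time())
  log$records[[length(log$records) + 1L]] <- rec
  invisible(rec)
}

#' Retrieve logged anomaly records
#' @param log a `"rosnn_anomaly_log"`.
#' @return list of anomaly records (possibly empty).
#' @export
anomaly_records <- function(log) {
  stopifnot(inherits(log, "rosnn_anomaly_log"))
  log$records
}
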