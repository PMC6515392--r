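#' Percentage of the pattern frame consumed by a decision
#'
#' @param spikes number of spikes received before the decision (may be a
#'   fractional average), in `(0, frame_size]`.
#' @param frame_size sensors per frame (default 16).
#' @return percentage, `100 * spikes / frame_size`.
#' @examples
#' frame_fraction(3)      # 18.75
#' frame_fraction(3.25)   # 20.3125
#' @export
frame_fraction <- function(spikes, frame_size = 16L) {
  if (any(!is.finite(spikes)) || any(spikes <= 0) ||
      any(spikes > frame_size))
    stop("spikes must lie in (0, frame_size]", call. = FALSE)
  100 * spikes / frame_size
}

#' Evaluate streamed classification against ground truth
#'
#' Summarises a set of frame traces: confusion matrix, accuracy, and the
#' continuous-classification cost (spikes to decision / fraction of the
#' pattern frame), overall and per analyte. Frames that never latch a
#' decision, or whose full-frame status is unknown and unlatched, count
#' as errors (conservative) and appear in the trailing `"unknown"` column
#' of the confusion matrix; they are excluded from the spike-count
#' averages.
#'
#' @param traces list of `"rosnn_trace"` objects.
#' @param truth true analyte labels, same length (factor or character;
#'   factor levels fix the class order).
#' @param policy decision policy passed to [latch_decision()].
#' @return object of class `"rosnn_eval"`: list with `confusion`
#'   (classes x (classes + unknown) integer matrix), `accuracy` (percent),
#'   `n`, `mean_spikes_to_decision`, `mean_frame_fraction` (percent),
#'   `per_analyte` (data.frame with n, n_latched, mean_spikes,
#'   mean_frame_fraction, var_frame_fraction), `anomalies` (full-frame
#'   unknown count), `policy`.
#' @export
evaluate_traces <- function(traces, truth,
                            policy = c("stable", "first-identified")) {
  policy <- match.arg(policy)
  if (length(traces) != length(truth))
    stop("traces and truth lengths differ", call. = FALSE)
  truth <- if (is.factor(truth)) truth else factor(truth)
  classes <- levels(truth)
  n <- length(traces)
  decisions <- lapply(traces, latch_decision, policy = policy)
  pred <- vapply(decisions, function(d)
    if (is.null(d)) "unknown" else d$category, "")
  pred[!pred %in% classes] <- "unknown"
  spikes <- vapply(decisions, function(d)
    if (is.null(d)) NA_real_ else as.numeric(d$spikes_to_decision), 0)
  confusion <- table(truth = truth,
                     predicted = factor(pred,
                                        levels = c(classes, "unknown")))
  confusion <- unclass(confusion)
  storage.mode(confusion) <- "integer"
  correct <- sum(diag(confusion[, classes, drop = FALSE]))
  frac <- vapply(seq_len(n), function(i)
    if (is.na(spikes[i])) NA_real_
    else frame_fraction(spikes[i], traces[[i]]$frame_size), 0)
  anomalies <- sum(vapply(traces, function(tr)
    tr$complete && tr$results[[tr$n_received]]$status == "unknown", TRUE))
  per <- do.call(rbind, lapply(classes, function(cl) {
    sel <- truth == cl
    sp <- spikes[sel]; fr <- frac[sel]
    data.frame(analyte = cl, n = sum(sel), n_latched = sum(!is.na(sp)),
               mean_spikes = mean(sp, na.rm = TRUE),
               mean_frame_fraction = mean(fr, na.rm = TRUE),
               var_frame_fraction = stats::var(fr[!is.na(fr)]))
  }))
  rownames(per) <- NULL
  structure(list(confusion = confusion,
                 accuracy = 100 * correct / n,
                 n = n,
                 mean_spikes_to_decision = mean(spikes, na.rm = TRUE),
                 mean_frame_fraction = mean(frac, na.rm = TRUE),
                 per_analyte = per,
                 anomalies = anomalies,
                 policy = policy),
            class = "rosnn_eval")
}

#' @export
print.rosnn_eval <- function(x, ...) {
  cat("Streamed classification report (", x$policy, " policy, n = ",
      x$n, ")\n", sep = "")
  cat(sprintf("  accuracy: %.2f%%\n", x$accuracy))
  cat(sprintf("  mean spikes to decision: %.2f (%.2f%% of frame)\n",
              x$mean_spikes_to_decision, x$mean_frame_fraction))
  cat("  full-frame anomalies (unknown):", x$anomalies, "\n")
  cat("  confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat("  per analyte:\n")
  p <- x$per_analyte
  p[-1] <- lapply(p[-1], function(v) round(v, 2))
  print(p, row.names = FALSE)
  invisible(x)
}
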