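#' Fit a rank-order spiking network classifier
#'
#' The standard training pipeline for rank-order olfaction data: the
#' rank-order signatures of each analyte are summarised by probabilistic
#' rank-score coding (see [rank_score_matrix()]), collapsed into one
#' reference signature per analyte (see [reference_signature()]), and the
#' references — a learning set completely distinct from, and far smaller
#' than, the classified data — are taught to an RCE nearest-neighbour
#' network with influence-field learning. Set `learn = "exemplars"` to
#' instead teach every training signature (ablation mode).
#'
#' @param x n x 16 integer matrix of rank-of-sensor signatures (rows are
#'   exposures), e.g. `encode_table(...)$ranks`. Ignored when
#'   `references` is supplied together with `labels` as the class names.
#' @param labels analyte label per row of `x` (factor levels fix the
#'   class / neuron commit order), or — with `references` — one label per
#'   reference.
#' @param references optional K x 16 matrix of ready-made reference
#'   signatures, bypassing rank-score derivation.
#' @param k winner-takes-all neighbours (default 2).
#' @param mode `"RBF"` (open-set, default) or `"KNN"`.
#' @param scale byte step per rank level (default 16).
#' @param max_if,min_if influence-field registers, see [rce_config()].
#' @param assignment method for [reference_signature()].
#' @param learn `"reference"` (default: one signature per class) or
#'   `"exemplars"` (every training pattern).
#' @return an object of class `"rosnn"`: list with `network` (the trained
#'   `"rce_network"`), `references` (K x 16 matrix), `score_matrices`
#'   (per-class `"rank_score"` objects, when derived), `classes`,
#'   `scale`, `learn`, `call`.
#' @seealso [predict.rosnn()], [stream_pattern()], [evaluate_traces()]
#' @examples
#' cfg <- enose_config(samples_per_class = 8, seed = 1)
#' ds <- sample_dataset(cfg)
#' enc <- encode_table(ds$features)
#' fit <- rosnn(enc$ranks, enc$labels)
#' fit
#' @export
rosnn <- function(x, labels, references = NULL, k = 2L,
                  mode = c("RBF", "KNN"), scale = 16L,
                  max_if = 3840L, min_if = 16L,
                  assignment = c("greedy", "optimal"),
                  learn = c("reference", "exemplars")) {
  mode <- match.arg(mode)
  assignment <- match.arg(assignment)
  learn <- match.arg(learn)
  score_matrices <- NULL
  if (is.null(references)) {
    x <- as.matrix(x)
    labels <- if (is.factor(labels)) labels else factor(labels)
    if (nrow(x) != length(labels))
      stop("x and labels lengths differ", call. = FALSE)
    classes <- levels(labels)
    score_matrices <- lapply(classes, function(cl)
      rank_score_matrix(x[labels == cl, , drop = FALSE], analyte = cl))
    names(score_matrices) <- classes
    references <- t(vapply(score_matrices, reference_signature,
                           integer(ncol(x)), method = assignment))
  } else {
    references <- as.matrix(references)
    classes <- as.character(labels)
    if (nrow(references) != length(classes))
      stop("one label per reference required", call. = FALSE)
  }
  rownames(references) <- classes
  cfg <- rce_config(max_if = max_if, min_if = min_if, mode = mode, k = k)
  net <- rce_network(cfg, n_features = ncol(references))
  if (learn == "reference") {
    for (i in seq_len(nrow(references)))
      rce_learn(net, rank_order_to_vector(references[i, ], scale = scale),
                classes[i])
  } else {
    for (i in seq_len(nrow(x)))
      rce_learn(net, rank_order_to_vector(x[i, ], scale = scale),
                as.character(labels[i]))
  }
  structure(list(network = net, references = references,
                 score_matrices = score_matrices, classes = classes,
                 scale = as.integer(scale), learn = learn,
                 call = match.call()),
            class = "rosnn")
}

#' @export
print.rosnn <- function(x, ...) {
  cat("Rank-order spiking network classifier\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  learning set:",
      if (x$learn == "reference") "one rank-score reference per class"
      else "all training exemplars", "\n")
  print(x$network)
  invisible(x)
}

#' @export
summary.rosnn <- function(object, ...) {
  net <- object$network
  structure(list(classes = object$classes,
                 references = object$references,
                 neurons = data.frame(neuron_id = seq_len(rce_size(net)),
                                      category = net$category,
                                      aif = net$aif,
                                      degenerate = net$degenerate),
                 mode = net$config$mode, k = net$config$k,
                 scale = object$scale),
            class = "summary.rosnn")
}

#' @export
print.summary.rosnn <- function(x, ...) {
  cat("Rank-order spiking network classifier (", x$mode, ", k = ", x$k,
      ", scale = ", x$scale, ")\n", sep = "")
  cat("Reference signatures (rank of each sensor):\n")
  print(x$references)
  cat("Committed neurons:\n")
  print(x$neurons, row.names = FALSE)
  invisible(x)
}

#' Stored prototypes of a fitted classifier
#'
#' @param object a `"rosnn"` fit.
#' @param ... unused.
#' @return integer matrix of committed byte prototypes, one row per
#'   neuron, row names = categories.
#' @export
coef.rosnn <- function(object, ...) {
  p <- object$network$proto
  rownames(p) <- object$network$category
  p
}

#' Classify new rank-order signatures
#'
#' @param object a `"rosnn"` fit.
#' @param newdata n x 16 integer matrix of rank-of-sensor signatures (or a
#'   single signature vector).
#' @param type `"class"` (factor of full-frame top-1 categories, NA when
#'   unknown), `"result"` (list of full-frame `"rce_result"` objects), or
#'   `"stream"` (per-spike streaming: list with `traces`, `decisions`
#'   data.frame and an `anomaly_log`).
#' @param policy decision-latch policy for `type = "stream"`.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.rosnn <- function(object, newdata,
                          type = c("class", "result", "stream"),
                          policy = c("stable", "first-identified"), ...) {
  type <- match.arg(type)
  policy <- match.arg(policy)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  if (type == "stream") {
    log <- new_anomaly_log()
    traces <- vector("list", n)
    for (i in seq_len(n)) {
      traces[[i]] <- stream_pattern(object$network, newdata[i, ],
                                    scale = object$scale, frame_id = i)
      log_anomaly(log, traces[[i]])
    }
    dec <- lapply(traces, latch_decision, policy = policy)
    decisions <- data.frame(
      frame = seq_len(n),
      category = vapply(dec, function(d)
        if (is.null(d)) NA_character_ else d$category, ""),
      spikes_to_decision = vapply(dec, function(d)
        if (is.null(d)) NA_integer_ else d$spikes_to_decision, 0L),
      frame_fraction = vapply(dec, function(d)
        if (is.null(d)) NA_real_ else d$frame_fraction, 0),
      final_status = vapply(traces, function(tr)
        tr$results[[tr$n_received]]$status, ""))
    return(list(traces = traces, decisions = decisions, anomaly_log = log))
  }
  results <- lapply(seq_len(n), function(i)
    rce_classify(object$network,
                 rank_order_to_vector(newdata[i, ], scale = object$scale)))
  if (type == "result") return(results)
  top <- vapply(results, function(r)
    if (nrow(r$hits)) r$hits$category[1] else NA_character_, "")
  factor(top, levels = object$classes)
}

#' Plot a fitted rank-order classifier
#'
#' `which = "references"` draws the per-class reference signatures (rank
#' at which each sensor fires); `which = "scores"` draws the rank-score
#' probability matrix of one analyte as an image.
#'
#' @param x a `"rosnn"` fit.
#' @param which `"references"` or `"scores"`.
#' @param analyte analyte name for `which = "scores"` (default: first).
#' @param ... passed to the underlying base graphics call.
#' @export
plot.rosnn <- function(x, which = c("references", "scores"),
                       analyte = NULL, ...) {
  which <- match.arg(which)
  if (which == "references") {
    r <- x$references
    graphics::matplot(t(r), type = "b", pch = seq_len(nrow(r)),
                      lty = 1, xlab = "sensor index + 1",
                      ylab = "firing rank (0 = earliest)",
                      main = "Reference rank-order signatures", ...)
    graphics::legend("topleft", legend = rownames(r),
                     pch = seq_len(nrow(r)), col = seq_len(nrow(r)),
                     cex = 0.8, bty = "n")
  } else {
    if (is.null(x$score_matrices))
      stop("no rank-score matrices stored (fit used ready-made references)",
           call. = FALSE)
    if (is.null(analyte)) analyte <- x$classes[1]
    p <- x$score_matrices[[analyte]]$probs
    graphics::image(0:15, 0:15, t(p)[, rev(seq_len(nrow(p)))],
                    xlab = "rank", ylab = "sensor (top = S0)",
                    main = paste("Rank-score probabilities:", analyte),
                    axes = FALSE, ...)
    graphics::axis(1, at = 0:15)
    graphics::axis(2, at = 0:15, labels = 15:0)
    graphics::box()
  }
  invisible(x)
}

#' Stream many frames and evaluate in one call
#'
#' @param object a `"rosnn"` fit.
#' @param newdata n x 16 matrix of rank-order signatures.
#' @param truth true labels (length n).
#' @param policy decision-latch policy.
#' @return a `"rosnn_eval"` report (see [evaluate_traces()]).
#' @export
stream_evaluate <- function(object, newdata, truth,
                            policy = c("stable", "first-identified")) {
  policy <- match.arg(policy)
  pr <- predict(object, newdata, type = "stream", policy = policy)
  evaluate_traces(pr$traces, truth, policy = policy)
}
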