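#' Spike latency of a sensor from its steady-state resistance
#'
#' Resistance-to-time conversion at the heart of rank-order encoding: the
#' firing latency of a sensor is `ln(R) / gamma`, where `R` is the
#' steady-state resistance-derived feature of the sensor during an exposure
#' and `gamma` a positive constant describing the sensor's characteristics
#' for the analyte. With `gamma = 1` the rank order of latencies is simply
#' the rank order of the resistances.
#'
#' @param resistance positive numeric vector of steady-state features.
#' @param gamma positive numeric, recycled against `resistance`.
#' @return numeric vector of latencies (arbitrary time units; may be
#'   negative when `R < 1`).
#' @examples
#' spike_latency(exp(1), 1)     # 1
#' spike_latency(c(1, 10), 2)   # 0, log(10)/2
#' @export
spike_latency <- function(resistance, gamma = 1) {
  bad <- !is.finite(resistance) | resistance <= 0
  if (any(bad))
    stop("non-positive or non-finite resistance for sensor index ",
         paste(which(bad) - 1L, collapse = ", "),
         " (log-latency undefined)", call. = FALSE)
  badg <- !is.finite(gamma) | gamma <= 0
  if (any(badg))
    stop("gamma must be positive and finite (offending position ",
         paste(which(badg) - 1L, collapse = ", "), ")", call. = FALSE)
  log(resistance) / gamma
}

#' Calibrate gamma from a reference exposure
#'
#' Convenience helper that back-solves `gamma = ln(R) / t_ref` so that a
#' designated reference exposure maps onto user-supplied target latencies.
#' This is a calibration aid only; the default encoding uses `gamma = 1`
#' for every sensor.
#'
#' @param resistance positive numeric vector (reference steady-state values).
#' @param target_latency numeric vector of desired latencies, same length;
#'   must be non-zero and share the sign of `ln(R)` so the result is positive.
#' @return numeric vector of gamma values.
#' @export
estimate_gamma <- function(resistance, target_latency) {
  if (length(resistance) != length(target_latency))
    stop("resistance and target_latency lengths differ", call. = FALSE)
  if (any(!is.finite(resistance) | resistance <= 0))
    stop("resistance must be positive and finite", call. = FALSE)
  g <- log(resistance) / target_latency
  if (any(!is.finite(g) | g <= 0))
    stop("target latencies incompatible with positive gamma", call. = FALSE)
  g
}

#' Encode one exposure of the sensor array as a spike-latency pattern
#'
#' Takes the 16 steady-state features of a single exposure (one per sensor)
#' and returns the latency vector `t_i = ln(R_i) / gamma_i` together with
#' the exposure metadata.
#'
#' @param features data.frame with columns `sensor_index` (0..15, each
#'   exactly once), `resistance` (> 0), and optionally `analyte` and
#'   `concentration`.
#' @param gamma positive numeric scalar or length-16 vector (per sensor,
#'   ordered by `sensor_index`).
#' @param n_sensors number of sensors in the array (16 for the 4x4 array).
#' @return an object of class `"spike_pattern"`: a list with `latencies`
#'   (length `n_sensors`, ordered by sensor index), `analyte`,
#'   `concentration`.
#' @export
encode_exposure <- function(features, gamma = 1, n_sensors = 16L) {
  if (!is.data.frame(features) ||
      !all(c("sensor_index", "resistance") %in% names(features)))
    stop("features must be a data.frame with sensor_index and resistance",
         call. = FALSE)
  idx <- as.integer(features$sensor_index)
  if (nrow(features) != n_sensors || anyDuplicated(idx) ||
      !setequal(idx, 0:(n_sensors - 1L)))
    stop("an exposure needs exactly one feature per sensor_index 0..",
         n_sensors - 1L, call. = FALSE)
  ord <- order(idx)
  r <- features$resistance[ord]
  g <- if (length(gamma) == 1L) rep(gamma, n_sensors) else gamma
  if (length(g) != n_sensors)
    stop("gamma must have length 1 or ", n_sensors, call. = FALSE)
  lat <- spike_latency(r, g)
  structure(list(latencies = lat,
                 analyte = if ("analyte" %in% names(features))
                   features$analyte[ord][1] else NA,
                 concentration = if ("concentration" %in% names(features))
                   features$concentration[ord][1] else NA_real_),
            class = "spike_pattern")
}

#' @export
print.spike_pattern <- function(x, ...) {
  cat("Spike-latency pattern (", length(x$latencies), " sensors)\n", sep = "")
  if (!is.na(x$analyte)) cat("  analyte:", as.character(x$analyte), "\n")
  if (!is.na(x$concentration))
    cat("  concentration:", x$concentration, "ppmv\n")
  cat("  latencies:", paste(signif(x$latencies, 4), collapse = " "), "\n")
  invisible(x)
}

#' Rank-order signature of a latency pattern
#'
#' Discards absolute timing and keeps only the firing order: component `i`
#' of the result is the rank (0 = earliest spike) at which sensor `i`
#' fired. Ties in latency are broken deterministically in favour of the
#' lower sensor index.
#'
#' @param x a `"spike_pattern"` or a finite numeric latency vector.
#' @return integer vector, a permutation of `0:(n-1)` (rank of each sensor).
#' @examples
#' to_rank_order(c(0.3, 0.1, 0.2, 0.4))  # 2 0 1 3
#' @export
to_rank_order <- function(x) {
  lat <- if (inherits(x, "spike_pattern")) x$latencies else as.numeric(x)
  if (length(lat) < 1L || any(!is.finite(lat)))
    stop("latencies must be finite", call. = FALSE)
  ord <- order(lat, seq_along(lat), method = "radix")
  ranks <- integer(length(lat))
  ranks[ord] <- seq_along(lat) - 1L
  ranks
}

.check_rank_order <- function(ranks, n = length(ranks)) {
  ranks <- as.integer(ranks)
  if (length(ranks) != n || !setequal(ranks, 0:(n - 1L)))
    stop("rank-order pattern must be a permutation of 0..", n - 1L,
         call. = FALSE)
  ranks
}

#' Spearman footrule distance between two rank-order signatures
#'
#' Sum over sensors of the absolute rank difference. Under the
#' rank-by-sensor byte encoding (see [rank_order_to_vector()]) the
#' full-frame Manhattan distance equals `scale` times this quantity.
#'
#' @param a,b integer permutations of `0:(n-1)`.
#' @return non-negative integer.
#' @export
footrule <- function(a, b) {
  a <- .check_rank_order(a)
  b <- .check_rank_order(b, n = length(a))
  sum(abs(a - b))
}

#' Byte-valued feature vector from a rank-order signature
#'
#' Maps a rank-order signature onto the byte vector broadcast to the
#' network: component `i` is `scale * rank_of_sensor[i]`, and the mask
#' marks which sensors have spiked so far (all of them for a complete
#' frame). With the default `scale = 16` the sixteen rank levels span
#' 0..240 of the byte range.
#'
#' @param ranks integer permutation of `0:(n-1)` (rank of each sensor).
#' @param received optional integer vector of 0-based sensor indices that
#'   have spiked (the pattern-matching window); default all sensors.
#' @param scale positive integer step between rank levels; `scale * (n-1)`
#'   must not exceed 255.
#' @return object of class `"rank_vector"`: list with integer `components`
#'   and logical `mask`.
#' @export
rank_order_to_vector <- function(ranks, received = NULL, scale = 16L) {
  ranks <- .check_rank_order(ranks)
  n <- length(ranks)
  scale <- as.integer(scale)
  if (length(scale) != 1L || is.na(scale) || scale < 1L)
    stop("scale must be a positive integer", call. = FALSE)
  if (scale * (n - 1L) > 255L)
    stop("scale ", scale, " pushes components beyond the byte range ",
         "(max allowed here: ", 255L %/% (n - 1L), ")", call. = FALSE)
  mask <- rep(TRUE, n)
  if (!is.null(received)) {
    received <- as.integer(received)
    if (length(received) && (anyDuplicated(received) ||
        any(received < 0L | received >= n)))
      stop("received must be distinct sensor indices in 0..", n - 1L,
           call. = FALSE)
    mask <- rep(FALSE, n)
    mask[received + 1L] <- TRUE
  }
  structure(list(components = scale * ranks, mask = mask),
            class = "rank_vector")
}

#' Construct a raw byte feature vector
#'
#' Low-level constructor for arbitrary byte vectors (components in 0..255)
#' with an optional validity mask, as stored and broadcast by the network.
#'
#' @param components integer vector, each element in 0..255, length <= 256.
#' @param mask logical vector of the same length (default: all valid).
#' @return object of class `"rank_vector"`.
#' @export
rank_vector <- function(components, mask = NULL) {
  components <- as.integer(components)
  if (length(components) < 1L || length(components) > 256L)
    stop("components must have length 1..256", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, length(components))
  mask <- as.logical(mask)
  if (length(mask) != length(components) || anyNA(mask))
    stop("mask must be a logical vector matching components", call. = FALSE)
  if (any(components[mask] < 0L | components[mask] > 255L))
    stop("unmasked components must lie in 0..255", call. = FALSE)
  structure(list(components = components, mask = mask),
            class = "rank_vector")
}

#' @export
print.rank_vector <- function(x, ...) {
  cat("Byte feature vector (", sum(x$mask), "/", length(x$components),
      " components in window)\n", sep = "")
  shown <- ifelse(x$mask, x$components, NA_integer_)
  cat(" ", paste(ifelse(is.na(shown), ".", shown), collapse = " "), "\n")
  invisible(x)
}

#' Recover a rank-order signature from a byte feature vector
#'
#' Inverse of [rank_order_to_vector()] for fully masked vectors.
#'
#' @param v a `"rank_vector"` produced with a known `scale`.
#' @param scale the scale used to encode it.
#' @return integer permutation (rank of each sensor).
#' @export
vector_to_rank_order <- function(v, scale = 16L) {
  if (!inherits(v, "rank_vector")) stop("v must be a rank_vector",
                                        call. = FALSE)
  if (!all(v$mask)) stop("vector is windowed; full frame required",
                         call. = FALSE)
  .check_rank_order(v$components %/% as.integer(scale))
}

#' Encode a feature table to rank-order signatures
#'
#' Applies the latency encoding and rank extraction row-wise to a standard
#' feature table (one exposure per row, columns `sample_id`, `analyte`,
#' `concentration_ppmv`, `S0..S15`).
#'
#' @param features data.frame in the standard layout (see
#'   [read_feature_table()]).
#' @param gamma positive scalar or length-16 vector passed to the encoder.
#' @return list with `ranks` (n x 16 integer matrix of rank-of-sensor
#'   signatures), `labels` (analyte factor) and `info` (sample_id, analyte,
#'   concentration_ppmv).
#' @export
encode_table <- function(features, gamma = 1) {
  scols <- paste0("S", 0:15)
  need <- c("sample_id", "analyte", "concentration_ppmv", scols)
  if (!all(need %in% names(features)))
    stop("feature table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  r <- as.matrix(features[, scols])
  if (any(!is.finite(r) | r <= 0)) {
    bad <- which(apply(!is.finite(r) | r <= 0, 1, any))
    stop("non-positive steady-state feature in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; rejected rather than clamped (clamping would corrupt rank order)",
         call. = FALSE)
  }
  g <- if (length(gamma) == 1L) rep(gamma, 16L) else gamma
  if (length(g) != 16L) stop("gamma must have length 1 or 16", call. = FALSE)
  lat <- sweep(log(r), 2L, g, "/")
  ranks <- t(apply(lat, 1L, to_rank_order))
  colnames(ranks) <- scols
  list(ranks = ranks,
       labels = factor(features$analyte),
       info = features[, c("sample_id", "analyte", "concentration_ppmv")])
}
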