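#' Latency jitter giving a target expected number of adjacent rank swaps
#'
#' Independent Gaussian jitter with standard deviation `sd` on each of two
#' latencies separated by `spacing` swaps them with probability
#' `pnorm(-spacing / (sd * sqrt(2)))`. Solving for the per-frame
#' expectation over the `n - 1` adjacent pairs of a frame gives the jitter
#' level used as a "shuffle severity" dial.
#'
#' @param swaps_per_frame expected number of adjacent-rank swaps per frame.
#' @param spacing latency gap between consecutive ranks (log-response
#'   units).
#' @param n_sensors sensors per frame.
#' @return standard deviation of the latency jitter.
#' @export
noise_for_swaps <- function(swaps_per_frame, spacing = 1, n_sensors = 16L) {
  if (swaps_per_frame <= 0) return(0)
  p <- swaps_per_frame / (n_sensors - 1L)
  if (p >= 0.5) stop("swaps_per_frame too large for this frame size",
                     call. = FALSE)
  spacing / (sqrt(2) * stats::qnorm(1 - p))
}

#' Configuration of the synthetic electronic-nose generator
#'
#' Emulates a 4x4 metal-oxide array exposed to six analytes. Each class
#' `k` has a 16-permutation template; the log steady-state response of
#' sensor `i` at concentration `C` in batch `b` is
#' `beta_i(k) - alpha_i(k) * log(C / c0) + b * drift_rate + eps`, with
#' `beta_i(k) = beta_base + spacing * template_rank_k(i)` (a power law in
#' concentration on the natural scale) and `eps` Gaussian with total sd
#' `sqrt(noise_sd^2 + shuffle_sd^2)`. With sensor-constant `alpha` within
#' a class, the concentration term is a common latency shift, so the
#' noise-free rank order equals the class template at every concentration.
#'
#' Defaults reproduce the structure of a six-gas benchmark: the analyte
#' names, concentration grids (50-500 ppmv, toluene 20-75) and per-class
#' sample counts (55, 23, 40, 64, 46, 57; 285 exposures in all) of the
#' batch-1 drift-dataset subset, templates with pairwise footrule
#' separation >= 40 plus one deliberately confusable pair
#' (ethylene/ethanol, footrule 8), and latency jitter giving an expected
#' ~1 adjacent rank swap per frame.
#'
#' @param n_classes number of analytes (default 6).
#' @param classes analyte names (length `n_classes`).
#' @param templates list of 16-permutations (rank of each sensor), one per
#'   class; default [default_templates()].
#' @param samples_per_class integer vector of exposures per class.
#' @param concentrations list of ppmv grids, one per class (cycled to
#'   reach the sample count).
#' @param alpha power-law sensitivity exponent: scalar, per-class vector,
#'   or list of per-sensor length-16 vectors.
#' @param beta_base,spacing baseline log-response and log-response gap
#'   between consecutive template ranks.
#' @param c0 reference concentration (ppmv) for the power law.
#' @param noise_sd additional sensor noise sd on the log response.
#' @param shuffle_sd latency jitter sd controlling rank-shuffle severity;
#'   default `noise_for_swaps(1)`.
#' @param drift_rate additive log-response shift per batch (monotone
#'   drift), default 0.
#' @param n_batches batches the samples are spread over (round robin).
#' @param seed integer; fully determines the generated dataset.
#' @return a list of class `"enose_config"`.
#' @export
enose_config <- function(n_classes = 6L,
                         classes = c("ammonia", "acetaldehyde", "acetone",
                                     "ethylene", "ethanol", "toluene"),
                         templates = NULL,
                         samples_per_class = c(55L, 23L, 40L, 64L, 46L, 57L),
                         concentrations = list(
                           seq(50, 275, by = 25),
                           seq(50, 300, by = 25),
                           seq(150, 500, by = 50),
                           seq(50, 275, by = 25),
                           seq(50, 300, by = 25),
                           seq(20, 75, by = 5)),
                         alpha = 0.5, beta_base = 4, spacing = 1,
                         c0 = 100, noise_sd = 0,
                         shuffle_sd = noise_for_swaps(1),
                         drift_rate = 0, n_batches = 1L, seed = 0L) {
  n_classes <- as.integer(n_classes)
  if (length(classes) != n_classes)
    stop("classes must have length n_classes", call. = FALSE)
  if (is.null(templates)) templates <- default_templates(n_classes)
  if (length(templates) != n_classes)
    stop("one template per class required", call. = FALSE)
  templates <- lapply(templates, .check_rank_order)
  if (length(samples_per_class) == 1L)
    samples_per_class <- rep(samples_per_class, n_classes)
  if (length(concentrations) != n_classes)
    stop("one concentration grid per class required", call. = FALSE)
  if (any(unlist(concentrations) <= 0))
    stop("concentrations must be positive (ppmv)", call. = FALSE)
  if (noise_sd < 0 || shuffle_sd < 0 || drift_rate < 0)
    stop("noise_sd, shuffle_sd and drift_rate must be >= 0", call. = FALSE)
  if (is.list(alpha)) {
    stopifnot(length(alpha) == n_classes)
    alpha <- lapply(alpha, function(a) if (length(a) == 1L) rep(a, 16L) else a)
  } else {
    if (length(alpha) == 1L) alpha <- rep(alpha, n_classes)
    alpha <- lapply(alpha, rep, 16L)
  }
  if (any(vapply(alpha, length, 1L) != 16L) || any(unlist(alpha) < 0))
    stop("alpha must be non-negative, per class scalar or length 16",
         call. = FALSE)
  structure(list(n_classes = n_classes, classes = classes,
                 templates = templates,
                 samples_per_class = as.integer(samples_per_class),
                 concentrations = concentrations, alpha = alpha,
                 beta_base = beta_base, spacing = spacing, c0 = c0,
                 noise_sd = noise_sd, shuffle_sd = shuffle_sd,
                 drift_rate = drift_rate, n_batches = as.integer(n_batches),
                 seed = as.integer(seed)),
            class = "enose_config")
}

# run expr with a private RNG stream seeded by `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Default class templates
#'
#' Six fixed rank-order templates: five drawn (internal seed 0) as random
#' permutations with pairwise Spearman footrule distance >= `min_sep`,
#' plus ethanol constructed from ethylene by swapping the sensors at rank
#' pairs (2,3), (6,7), (10,11) and (14,15) — footrule distance exactly 8
#' — to mimic a pair of closely related odours whose signatures share
#' their first two elements.
#'
#' @param n_classes 2..6 templates are returned (the first `n_classes`).
#' @param min_sep minimum pairwise footrule separation of the random
#'   templates.
#' @param seed internal seed of the template draw.
#' @return list of integer 16-permutations (rank of each sensor).
#' @export
default_templates <- function(n_classes = 6L, min_sep = 40L, seed = 0L) {
  if (n_classes < 1L || n_classes > 6L)
    stop("default templates cover 1..6 classes", call. = FALSE)
  tpl <- .with_seed(seed, {
    acc <- list()
    while (length(acc) < 5L) {
      cand <- to_rank_order(stats::runif(16))
      ok <- all(vapply(acc, function(t) footrule(t, cand) >= min_sep, TRUE))
      if (ok) acc[[length(acc) + 1L]] <- cand
    }
    acc
  })
  # order: ammonia, acetaldehyde, acetone, ethylene, ethanol, toluene
  ethylene <- tpl[[4L]]
  swap <- c(0L, 1L, 3L, 2L, 4L, 5L, 7L, 6L, 8L, 9L, 11L, 10L,
            12L, 13L, 15L, 14L)
  ethanol <- swap[ethylene + 1L]
  out <- list(tpl[[1L]], tpl[[2L]], tpl[[3L]], ethylene, ethanol, tpl[[5L]])
  out[seq_len(n_classes)]
}

#' Draw a template distant from an existing set
#'
#' Rejection-samples a random permutation whose footrule distance to every
#' template in `templates` is at least `min_sep`; used to build an
#' untrained "seventh gas" for open-set (anomaly) experiments.
#'
#' @param templates list of existing 16-permutations.
#' @param min_sep minimum footrule distance to each of them.
#' @param seed seed of the private draw.
#' @param max_tries rejection-sampling budget before giving up.
#' @return an integer 16-permutation.
#' @export
distant_template <- function(templates, min_sep = 60L, seed = 0L,
                             max_tries = 100000L) {
  .with_seed(seed, {
    for (i in seq_len(max_tries)) {
      cand <- to_rank_order(stats::runif(16))
      if (all(vapply(templates, function(t) footrule(t, cand) >= min_sep,
                     TRUE)))
        return(cand)
    }
    stop("no permutation at footrule >= ", min_sep,
         " from every template found in ", max_tries, " draws",
         call. = FALSE)
  })
}

# log steady-state responses for one exposure (internal; consumes RNG)
.sample_log_response <- function(config, class_idx, concentration, batch) {
  tpl <- config$templates[[class_idx]]
  beta <- config$beta_base + config$spacing * tpl
  sd_tot <- sqrt(config$noise_sd^2 + config$shuffle_sd^2)
  beta - config$alpha[[class_idx]] * log(concentration / config$c0) +
    batch * config$drift_rate + stats::rnorm(16L, 0, sd_tot)
}

#' Generate one synthetic exposure
#'
#' @param config an [enose_config()].
#' @param class analyte name or class index.
#' @param concentration exposure concentration, ppmv (> 0).
#' @param batch 0-based batch index (drift multiplies it).
#' @param seed optional seed for this single draw; default draws from the
#'   current RNG stream.
#' @return data.frame of 16 rows: `sensor_index`, `analyte`,
#'   `concentration`, `resistance`.
#' @export
sample_exposure <- function(config, class, concentration, batch = 0L,
                            seed = NULL) {
  stopifnot(inherits(config, "enose_config"))
  k <- if (is.character(class)) match(class, config$classes)
       else as.integer(class)
  if (is.na(k) || k < 1L || k > config$n_classes)
    stop("unknown class", call. = FALSE)
  if (!is.finite(concentration) || concentration <= 0)
    stop("concentration must be positive (ppmv)", call. = FALSE)
  draw <- function() .sample_log_response(config, k, concentration, batch)
  lnr <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  data.frame(sensor_index = 0:15, analyte = config$classes[k],
             concentration = concentration, resistance = exp(lnr))
}

#' Generate a full synthetic dataset
#'
#' Draws `samples_per_class[k]` exposures for every class, cycling through
#' the class's concentration grid and assigning batches round-robin, and
#' returns the standard feature table together with the ground truth.
#' The output is fully determined by `config$seed`.
#'
#' @param config an [enose_config()].
#' @return list with `features` (data.frame: `sample_id`, `analyte`,
#'   `concentration_ppmv`, `batch`, `S0..S15`), `labels` (analyte factor,
#'   levels in class order) and `templates` (the true per-class
#'   signatures, for recovery checks).
#' @export
sample_dataset <- function(config) {
  stopifnot(inherits(config, "enose_config"))
  .with_seed(config$seed, {
    rows <- vector("list", config$n_classes)
    for (k in seq_len(config$n_classes)) {
      nk <- config$samples_per_class[k]
      if (nk == 0L) next
      conc <- rep_len(config$concentrations[[k]], nk)
      batch <- rep_len(seq_len(config$n_batches) - 1L, nk)
      lnr <- t(vapply(seq_len(nk), function(s)
        .sample_log_response(config, k, conc[s], batch[s]),
        numeric(16L)))
      df <- data.frame(sample_id = paste0(config$classes[k], "_",
                                          seq_len(nk)),
                       analyte = config$classes[k],
                       concentration_ppmv = conc, batch = batch)
      resp <- as.data.frame(exp(lnr))
      names(resp) <- paste0("S", 0:15)
      rows[[k]] <- cbind(df, resp)
    }
    features <- do.call(rbind, rows)
    if (is.null(features)) {
      features <- data.frame(sample_id = character(0),
                             analyte = character(0),
                             concentration_ppmv = numeric(0),
                             batch = integer(0))
      for (s in paste0("S", 0:15)) features[[s]] <- numeric(0)
    }
    rownames(features) <- NULL
    list(features = features,
         labels = factor(features$analyte, levels = config$classes),
         templates = config$templates)
  })
}
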