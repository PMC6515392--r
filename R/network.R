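#' Network configuration
#'
#' Parameters of the simulated daisy-chain nearest-neighbour network.
#' `max_if` is the maximum influence field register: the AIF given to a
#' neuron committed while no other neuron fires. The default 3840 is a
#' conservative upper bound on any Manhattan distance between encoded
#' frames at `scale = 16` (16 components x 240). `min_if = 16` is one rank
#' step at that scale; shrinkage is clamped there and the neuron flagged
#' degenerate.
#'
#' @param capacity maximum number of committed neurons (hardware: 1024).
#' @param max_if,min_if influence-field registers, `0 < min_if <= max_if`.
#' @param mode `"RBF"` (a neuron fires only when the broadcast pattern is
#'   within its AIF; open-set capable) or `"KNN"` (every committed neuron
#'   answers regardless of AIF).
#' @param k number of nearest neighbours reported by the winner-takes-all
#'   readout (default 2, the configuration used for gas identification).
#' @return a list of class `"rce_config"`.
#' @export
rce_config <- function(capacity = 1024L, max_if = 3840L, min_if = 16L,
                       mode = c("RBF", "KNN"), k = 2L) {
  mode <- match.arg(mode)
  capacity <- as.integer(capacity); max_if <- as.integer(max_if)
  min_if <- as.integer(min_if); k <- as.integer(k)
  if (capacity < 1L) stop("capacity must be >= 1", call. = FALSE)
  if (min_if < 1L || min_if > max_if)
    stop("need 0 < min_if <= max_if", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  structure(list(capacity = capacity, max_if = max_if, min_if = min_if,
                 mode = mode, k = k), class = "rce_config")
}

#' Create an empty RCE network
#'
#' The network is a mutable simulator object (an environment):
#' [rce_learn()] commits and shrinks neurons in place, [rce_classify()]
#' reads it. Each committed neuron stores a byte prototype, a category,
#' and an active influence field (AIF) that only ever shrinks after
#' commit.
#'
#' @param config an [rce_config()].
#' @param n_features prototype length in bytes (16 for rank-order frames;
#'   up to 256, the neuron's associative memory).
#' @return an environment of class `"rce_network"`.
#' @export
rce_network <- function(config = rce_config(), n_features = 16L) {
  n_features <- as.integer(n_features)
  if (n_features < 1L || n_features > 256L)
    stop("n_features must be in 1..256", call. = FALSE)
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$n_features <- n_features
  net$proto <- matrix(integer(0), nrow = 0L, ncol = n_features)
  net$category <- character(0)
  net$aif <- integer(0)
  net$degenerate <- logical(0)
  class(net) <- "rce_network"
  net
}

#' Number of committed neurons
#' @param net an `"rce_network"`.
#' @return integer.
#' @export
rce_size <- function(net) nrow(net$proto)

#' Manhattan (city-block) distance over the broadcast window
#'
#' Distance used by every neuron: the sum of absolute component
#' differences, restricted to the components currently inside the
#' broadcast vector's pattern-matching window (its mask). A partial window
#' naturally yields smaller distances; this is the mechanism behind
#' continuous classification and is deliberately not rescaled.
#'
#' @param v broadcast vector: a `"rank_vector"` (its mask defines the
#'   window) or plain numeric vector (full window).
#' @param p stored prototype: a `"rank_vector"` or numeric vector of the
#'   same length.
#' @return non-negative integer.
#' @examples
#' manhattan_distance(c(0, 3), c(3, 0))  # 6
#' @export
manhattan_distance <- function(v, p) {
  vm <- if (inherits(v, "rank_vector")) v$mask else rep(TRUE, length(v))
  vc <- if (inherits(v, "rank_vector")) v$components else as.numeric(v)
  pc <- if (inherits(p, "rank_vector")) p$components else as.numeric(p)
  if (length(vc) != length(pc))
    stop("vector and prototype lengths differ", call. = FALSE)
  sum(abs(vc[vm] - pc[vm]))
}

# distances from a broadcast (components, mask) to every committed neuron
.rce_distances <- function(net, components, mask) {
  if (length(components) != net$n_features)
    stop("broadcast vector length ", length(components),
         " does not match network feature length ", net$n_features,
         call. = FALSE)
  n <- nrow(net$proto)
  if (n == 0L) return(numeric(0))
  m <- sum(mask)
  if (m == 0L) return(numeric(n))
  sub <- net$proto[, mask, drop = FALSE]
  rowSums(abs(sub - matrix(components[mask], n, m, byrow = TRUE)))
}

.as_broadcast <- function(vector, net) {
  if (inherits(vector, "rank_vector"))
    list(components = vector$components, mask = vector$mask)
  else
    list(components = as.integer(vector),
         mask = rep(TRUE, length(vector)))
}

#' Supervised learning of one pattern
#'
#' Broadcasts `vector` with a target `category` and applies the
#' influence-field learning rule:
#' \itemize{
#'   \item no committed neuron fires: a new neuron is committed with the
#'     pattern as prototype and AIF set to the maximum influence field
#'     register;
#'   \item neurons fire but none carries the target category: a new neuron
#'     is committed with AIF equal to the distance of the closest firing
#'     neuron; in addition every firing neuron of a different category
#'     shrinks its AIF to its distance from the broadcast pattern (clamped
#'     at `min_if`, setting the degenerate flag on clamp);
#'   \item a firing neuron already carries the target category: no commit;
#'     wrong-category firing neurons still shrink.
#' }
#' A neuron fires when its distance is strictly less than its AIF.
#'
#' @param net an `"rce_network"` (modified in place).
#' @param vector the pattern (a `"rank_vector"` or integer vector).
#' @param category category label (coerced to character).
#' @return invisibly, a commit report: list with `committed`, `neuron_id`
#'   (NA when nothing was committed), `new_aif`, and `shrunk`
#'   (data.frame of neuron_id, old_aif, new_aif, degenerate).
#' @export
rce_learn <- function(net, vector, category) {
  stopifnot(inherits(net, "rce_network"))
  category <- as.character(category)
  if (length(category) != 1L || is.na(category) || !nzchar(category))
    stop("category must be a single non-empty label", call. = FALSE)
  b <- .as_broadcast(vector, net)
  cfg <- net$config
  d <- .rce_distances(net, b$components, b$mask)
  firing <- which(d < net$aif)
  have_cat <- any(net$category[firing] == category)
  shrunk <- data.frame(neuron_id = integer(0), old_aif = integer(0),
                       new_aif = integer(0), degenerate = logical(0))

  # corrective action: wrong-category firing neurons shrink to their distance
  wrong <- firing[net$category[firing] != category]
  if (length(wrong)) {
    old <- net$aif[wrong]
    newv <- pmax(as.integer(d[wrong]), cfg$min_if)
    clamp <- as.integer(d[wrong]) < cfg$min_if
    net$aif[wrong] <- newv
    net$degenerate[wrong] <- net$degenerate[wrong] | clamp
    shrunk <- data.frame(neuron_id = wrong, old_aif = old, new_aif = newv,
                         degenerate = net$degenerate[wrong])
  }

  committed <- FALSE; neuron_id <- NA_integer_; new_aif <- NA_integer_
  if (!have_cat) {
    if (nrow(net$proto) >= cfg$capacity)
      stop("network capacity (", cfg$capacity,
           " neurons) exhausted; cannot commit", call. = FALSE)
    new_aif <- if (length(firing) == 0L) cfg$max_if else {
      a <- as.integer(min(d[firing]))
      min(max(a, cfg$min_if), cfg$max_if)
    }
    degen <- length(firing) > 0L && min(d[firing]) < cfg$min_if
    net$proto <- rbind(net$proto, as.integer(b$components))
    net$category <- c(net$category, category)
    net$aif <- c(net$aif, new_aif)
    net$degenerate <- c(net$degenerate, degen)
    committed <- TRUE
    neuron_id <- nrow(net$proto)
  }
  invisible(list(committed = committed, neuron_id = neuron_id,
                 new_aif = new_aif, shrunk = shrunk))
}

#' Classify a broadcast pattern
#'
#' In RBF mode the firing set is every committed neuron whose distance to
#' the broadcast (over its window) is strictly below its AIF; the status
#' is `"unknown"` when no neuron fires, `"identified"` when all firing
#' neurons agree on one category, and `"uncertain"` otherwise. In KNN mode
#' every committed neuron answers (the AIF is ignored) and the status is
#' never `"unknown"`. The winner-takes-all readout returns the `k` best
#' firing neurons ordered by increasing distance, ties broken by lower
#' neuron id (commit order, matching daisy-chain search).
#'
#' @param net an `"rce_network"` with at least one committed neuron.
#' @param vector broadcast pattern (`"rank_vector"` or integer vector).
#' @return object of class `"rce_result"`: list with `hits` (data.frame
#'   `category`, `distance`, `neuron_id`, at most `k` rows), `status`, and
#'   `n_firing`.
#' @export
rce_classify <- function(net, vector) {
  stopifnot(inherits(net, "rce_network"))
  if (nrow(net$proto) == 0L)
    stop("network has no committed neurons", call. = FALSE)
  b <- .as_broadcast(vector, net)
  cfg <- net$config
  d <- .rce_distances(net, b$components, b$mask)
  firing <- if (cfg$mode == "RBF") which(d < net$aif)
            else seq_along(d)
  if (length(firing) == 0L) {
    status <- "unknown"
    hits <- data.frame(category = character(0), distance = numeric(0),
                       neuron_id = integer(0))
  } else {
    cats <- unique(net$category[firing])
    status <- if (length(cats) == 1L) "identified" else "uncertain"
    ord <- firing[order(d[firing], firing)]
    top <- utils::head(ord, cfg$k)
    hits <- data.frame(category = net$category[top], distance = d[top],
                       neuron_id = top)
  }
  structure(list(hits = hits, status = status, n_firing = length(firing)),
            class = "rce_result")
}

#' @export
print.rce_result <- function(x, ...) {
  cat("RCE classification:", x$status,
      sprintf("(%d firing)\n", x$n_firing))
  if (nrow(x$hits)) print(x$hits, row.names = FALSE)
  invisible(x)
}

#' @export
print.rce_network <- function(x, ...) {
  cfg <- x$config
  cat("RCE nearest-neighbour network (", cfg$mode, " mode, k = ", cfg$k,
      ")\n", sep = "")
  cat("  neurons committed: ", rce_size(x), " / ", cfg$capacity, "\n",
      sep = "")
  cat("  influence field: [", cfg$min_if, ", ", cfg$max_if, "]",
      if (any(x$degenerate)) paste0("; ", sum(x$degenerate), " degenerate"),
      "\n", sep = "")
  if (rce_size(x)) {
    tab <- table(x$category)
    cat("  categories:",
        paste(names(tab), "(", as.integer(tab), ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a network to JSON
#'
#' Writes the complete network state (config, prototypes, categories,
#' AIFs, degenerate flags) as a JSON string; [rce_deserialize()] restores
#' it bit-exactly.
#'
#' @param net an `"rce_network"`.
#' @return a JSON character scalar.
#' @export
rce_serialize <- function(net) {
  stopifnot(inherits(net, "rce_network"))
  obj <- list(
    config = unclass(net$config),
    n_features = net$n_features,
    neurons = list(
      prototype = unname(net$proto),
      category = net$category,
      aif = net$aif,
      degenerate = net$degenerate
    )
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' Restore a network from JSON
#' @param json a string produced by [rce_serialize()] (or a file path to
#'   one).
#' @return an `"rce_network"`.
#' @export
rce_deserialize <- function(json) {
  if (length(json) == 1L && !grepl("^\\s*\\{", json) && file.exists(json))
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  cfg <- rce_config(capacity = obj$config$capacity,
                    max_if = obj$config$max_if,
                    min_if = obj$config$min_if,
                    mode = obj$config$mode, k = obj$config$k)
  net <- rce_network(cfg, n_features = obj$n_features)
  pr <- obj$neurons$prototype
  if (length(pr)) {
    pr <- matrix(as.integer(pr), ncol = net$n_features)
    net$proto <- pr
    net$category <- as.character(obj$neurons$category)
    net$aif <- as.integer(obj$neurons$aif)
    net$degenerate <- as.logical(obj$neurons$degenerate)
  }
  net
}
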