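#' Read a delimited steady-state feature table
#'
#' Standard layout: one exposure per row with columns `sample_id`,
#' `analyte`, `concentration_ppmv` and `S0..S15` (steady-state
#' resistance-derived features of the 16 sensors). Extra columns (e.g.
#' `batch`) are carried through.
#'
#' @param path file path (CSV, or TSV with `sep = "\t"`).
#' @param sep field separator.
#' @return a data.frame.
#' @export
read_feature_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "analyte", "concentration_ppmv", paste0("S", 0:15))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("feature table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Write a feature table
#' @param features data.frame in the standard layout.
#' @param path output CSV path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sparse "index:value" feature file
#'
#' Reader for the libsvm-style dialect used by public gas-sensor-array
#' archives: each line is `label feat:value feat:value ...`, with 8
#' transient/steady-state features per sensor (128 features for a 16
#' sensor array) and a label of the form `class` or `class;concentration`.
#' One designated feature per sensor (by default the first, the
#' steady-state response) is mapped onto the standard `S0..S15` columns.
#'
#' @param path file path.
#' @param feature_index 1-based feature picked within each sensor's block.
#' @param features_per_sensor features recorded per sensor (default 8).
#' @param n_sensors sensors in the array (default 16).
#' @param classes optional character vector mapping numeric class labels
#'   to analyte names.
#' @return data.frame in the standard feature-table layout.
#' @export
read_sparse_features <- function(path, feature_index = 1L,
                                 features_per_sensor = 8L,
                                 n_sensors = 16L, classes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  want <- (seq_len(n_sensors) - 1L) * features_per_sensor + feature_index
  parse_line <- function(ln) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    lab <- strsplit(parts[1], ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts[-1], ":", fixed = TRUE)
    idx <- vapply(kv, function(x) as.integer(x[1]), 0L)
    val <- vapply(kv, function(x) as.numeric(x[2]), 0)
    pos <- match(want, idx)
    if (anyNA(pos))
      stop("line lacks feature index ", want[which(is.na(pos))[1]],
           call. = FALSE)
    list(class = lab[1],
         conc = if (length(lab) > 1L) as.numeric(lab[2]) else NA_real_,
         s = val[pos])
  }
  rec <- lapply(lines, parse_line)
  cls <- vapply(rec, `[[`, "", "class")
  if (!is.null(classes)) {
    ci <- suppressWarnings(as.integer(cls))
    cls <- ifelse(is.na(ci), cls, classes[ci])
  }
  out <- data.frame(sample_id = paste0("x", seq_along(rec)),
                    analyte = cls,
                    concentration_ppmv = vapply(rec, `[[`, 0, "conc"))
  s <- t(vapply(rec, `[[`, numeric(n_sensors), "s"))
  colnames(s) <- paste0("S", seq_len(n_sensors) - 1L)
  cbind(out, as.data.frame(s))
}

#' Write rank-order signatures
#'
#' CSV layout: `sample_id`, `analyte`, then 16 rank columns `R0..R15`
#' (rank of each sensor). JSON layout: an array of records with the same
#' fields, `ranks` as an array.
#'
#' @param ranks n x 16 integer matrix of rank-of-sensor signatures.
#' @param path output path.
#' @param info optional data.frame with `sample_id` and `analyte` columns
#'   (defaults generated when omitted).
#' @param format `"csv"` or `"json"`.
#' @export
write_rank_orders <- function(ranks, path, info = NULL,
                              format = c("csv", "json")) {
  format <- match.arg(format)
  ranks <- as.matrix(ranks)
  n <- nrow(ranks)
  if (is.null(info))
    info <- data.frame(sample_id = paste0("x", seq_len(n)),
                       analyte = NA_character_)
  if (nrow(info) != n) stop("info and ranks lengths differ", call. = FALSE)
  if (format == "csv") {
    out <- cbind(info[, c("sample_id", "analyte")], as.data.frame(ranks))
    names(out) <- c("sample_id", "analyte",
                    paste0("R", seq_len(ncol(ranks)) - 1L))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    recs <- lapply(seq_len(n), function(i)
      list(sample_id = info$sample_id[i],
           analyte = info$analyte[i],
           ranks = unname(ranks[i, ])))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read rank-order signatures written by [write_rank_orders()]
#' @param path CSV path.
#' @return list with `ranks` (integer matrix) and `info` (sample_id,
#'   analyte).
#' @export
read_rank_orders <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rcols <- grep("^R[0-9]+$", names(df), value = TRUE)
  rcols <- rcols[order(as.integer(sub("R", "", rcols)))]
  ranks <- as.matrix(df[, rcols])
  storage.mode(ranks) <- "integer"
  list(ranks = ranks, info = df[, c("sample_id", "analyte")])
}

#' Read a spike stream
#'
#' CSV with columns `frame_id`, `arrival_order`, `sensor_index` (or
#' line-per-spike `frame_id,sensor_index` with arrival implied by line
#' order, e.g. when piped on standard input). Returns the per-frame
#' arrival sequences.
#'
#' @param con file path or connection (use `file("stdin")` for piping).
#' @return named list: for each frame id, the integer vector of 0-based
#'   sensor indices in arrival order.
#' @export
read_spike_stream <- function(con) {
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  has_header <- grepl("frame_id", lines[1], fixed = TRUE)
  body <- if (has_header) lines[-1] else lines
  fields <- strsplit(body, ",", fixed = TRUE)
  ncol <- length(fields[[1]])
  if (!all(lengths(fields) == ncol) || !ncol %in% c(2L, 3L))
    stop("spike stream lines must be frame_id,sensor_index or ",
         "frame_id,arrival_order,sensor_index", call. = FALSE)
  frame <- vapply(fields, `[[`, "", 1L)
  sensor <- as.integer(vapply(fields, `[[`, "", ncol))
  ord <- if (ncol == 3L) as.integer(vapply(fields, `[[`, "", 2L))
         else stats::ave(seq_along(frame), frame, FUN = seq_along)
  out <- lapply(split(data.frame(ord, sensor), frame),
                function(d) d$sensor[order(d$ord)])
  out[unique(frame)]
}
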