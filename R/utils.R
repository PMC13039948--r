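# Internal helpers: condition classes, seeded sub-streams, metadata-headed TSVs.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_validation <- function(msg, ...) {
  stop(structure(class = c("m6aland_validation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' @noRd
stop_data <- function(msg, ...) {
  stop(structure(class = c("m6aland_data_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Deterministic 31-bit sub-seed per (master seed, stage label, index).
# Keeps every derived seed well below 2^31.
derive_seed <- function(seed, stage, index = 0L) {
  h <- fnv1a32(paste(stage, index, sep = ":"))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587 + 1)
}

# FNV-1a 32-bit hash, kept in double arithmetic (exact below 2^53).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h %/% 2^31) * 2^31
    h <- (h * 16777619) %% 4294967296
  }
  h %% 2147483587
}

hash_object <- function(x) {
  sprintf("%08x", fnv1a32(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)))
}

read_lines_any <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Write a data table as TSV with a commented metadata header
#'
#' Each element of `meta` becomes a `#key=value` line before the column header.
#' @param x data.frame/data.table to write.
#' @param path output path.
#' @param meta named list of scalar metadata values.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = list()) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    v <- if (is.numeric(v)) sprintf("%.15g", v) else format(v)
    writeLines(sprintf("#%s=%s", k, v), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path file path.
#' @return list with `data` (data.table) and `meta` (named character).
#' @export
read_tsv_meta <- function(path) {
  lines <- read_lines_any(path)
  is_meta <- grepl("^#", lines)
  n_meta <- if (any(!is_meta)) which(!is_meta)[1] - 1L else length(lines)
  meta <- character(0)
  if (n_meta > 0) {
    kv <- sub("^#", "", lines[seq_len(n_meta)])
    meta <- sub("^[^=]*=", "", kv)
    names(meta) <- sub("=.*$", "", kv)
  }
  body <- lines[-seq_len(n_meta)]
  data <- if (length(body) > 1) {
    data.table::fread(text = body, sep = "\t", header = TRUE)
  } else {
    data.table::data.table()
  }
  list(data = data, meta = as.list(meta))
}

clamp01 <- function(x) pmin(1, pmax(0, x))
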