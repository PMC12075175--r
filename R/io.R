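#' Session file format
#'
#' Sessions are stored as a self-describing CSV: a block of `#`-prefixed
#' metadata header lines (schema version, sampling rate, channel map, free
#' metadata), then an RFC-4180 body with header `t,ch01,...,chNN,label`.
#' Signal values are printed with 17 significant digits so a write/read
#' round trip reproduces the doubles bit-exactly. A plain CSV without the
#' metadata block is also readable: `t` is then interpreted as time in
#' seconds and the sampling rate is inferred from its spacing.
#'
#' @name session-format
NULL

.SCHEMA_VERSION <- "emgband-session-1"

#' Write a session to disk
#'
#' @param rec an \code{\link{emg_recording}}.
#' @param path output file path (CSV, see \link{session-format}).
#' @return \code{path}, invisibly.
#' @export
write_session <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  C <- ncol(rec$data)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# schema=", .SCHEMA_VERSION),
    paste0("# fs=", sprintf("%.17g", rec$fs)),
    paste0("# channel_map=", paste(sprintf("%d:%d", rec$channel_map$node,
                                           rec$channel_map$pos),
                                   collapse = ",")),
    paste0("# meta=", jsonlite::toJSON(rec$meta, auto_unbox = TRUE))
  ), con)
  writeLines(paste(c("t", sprintf("ch%02d", seq_len(C)), "label"),
                   collapse = ","), con)
  t <- sprintf("%.10g", (seq_len(nrow(rec$data)) - 1) / rec$fs)
  body <- do.call(paste, c(list(t), lapply(seq_len(C), function(j)
    sprintf("%.17g", rec$data[, j])), list(rec$labels), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a session from disk
#'
#' Accepts files written by \code{\link{write_session}} and the plain CSV
#' dialect (`t,ch01..chNN,label` with `t` in seconds). Malformed files --
#' unknown schema version, missing label column, ragged rows -- raise errors
#' rather than returning a truncated recording.
#'
#' @param path file path.
#' @return an \code{\link{emg_recording}}.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  fs <- NA_real_; channel_map <- NULL; meta <- list()
  if (length(meta_lines)) {
    kv <- sub("^#\\s*", "", meta_lines)
    get <- function(key) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (!length(hit)) return(NULL)
      sub(paste0("^", key, "="), "", hit[1])
    }
    schema <- get("schema")
    if (!is.null(schema) && schema != .SCHEMA_VERSION)
      stop("unknown session schema version: ", schema)
    if (!is.null(get("fs"))) fs <- as.numeric(get("fs"))
    cmr <- get("channel_map")
    if (!is.null(cmr)) {
      parts <- strsplit(strsplit(cmr, ",")[[1]], ":")
      channel_map <- data.frame(
        channel = seq_along(parts),
        node = as.integer(vapply(parts, `[`, "", 1)),
        pos = as.integer(vapply(parts, `[`, "", 2)))
    }
    mj <- get("meta")
    if (!is.null(mj)) meta <- jsonlite::fromJSON(mj, simplifyVector = TRUE)
  }
  df <- utils::read.csv(path, comment.char = "#", header = TRUE,
                        check.names = FALSE, colClasses = "numeric")
  if (!"label" %in% names(df))
    stop("session file lacks the required 'label' column")
  if (!"t" %in% names(df) || names(df)[1] != "t")
    stop("session file must start with a 't' column")
  ch_cols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  if (!length(ch_cols)) stop("session file has no channel columns")
  if (anyNA(df)) stop("malformed session file: missing values / ragged rows")
  if (is.na(fs)) {
    dt <- diff(df$t)
    if (length(dt) < 1L || any(dt <= 0))
      stop("cannot infer sampling rate from the t column")
    fs <- 1 / stats::median(dt)
    fs <- round(fs)
  }
  emg_recording(as.matrix(df[ch_cols]), fs = fs,
                labels = as.integer(df$label),
                channel_map = channel_map, meta = as.list(meta))
}
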