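#' Beat-to-beat interval series
#'
#' Container for one subject's ambulatory inter-beat-interval (IBI) record.
#' Beat times are seconds since the recording start; intervals are in
#' milliseconds; every beat carries a quality flag (`"valid"`, `"corrected"`,
#' or `"rejected"`). For consecutive non-rejected beats with no intervening
#' gap, successive times differ by the interval itself (within 1 ms), the
#' usual RR-export convention.
#'
#' @param subject_id character scalar identifying the subject.
#' @param start_time `POSIXct` timestamp of the recording start.
#' @param ibi numeric vector of inter-beat intervals in milliseconds, all > 0.
#' @param t optional numeric vector of beat times in seconds since
#'   `start_time`; defaults to the cumulative sum of `ibi` (gap-free record).
#' @param flag optional character vector of per-beat flags; defaults to
#'   `"valid"` for every beat.
#' @return An object of class `ibi_series`: a list with elements
#'   `subject_id`, `start_time`, and a data frame `beats` with columns
#'   `t` (s), `ibi` (ms) and `flag`.
#' @examples
#' s <- ibi_series("demo", as.POSIXct("2019-06-01 10:00:00", tz = "UTC"),
#'                 ibi = rep(1000, 10))
#' s$beats$t
#' @export
ibi_series <- function(subject_id, start_time, ibi, t = NULL, flag = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L) {
    stop("'subject_id' must be a character scalar")
  }
  if (!inherits(start_time, "POSIXct") || length(start_time) != 1L) {
    stop("'start_time' must be a single POSIXct timestamp")
  }
  ibi <- as.numeric(ibi)
  if (any(!is.finite(ibi)) || any(ibi <= 0)) {
    stop("all inter-beat intervals must be finite and > 0 ms")
  }
  if (is.null(t)) t <- cumsum(ibi) / 1000
  t <- as.numeric(t)
  if (length(t) != length(ibi)) stop("'t' and 'ibi' lengths differ")
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("beat times must be strictly increasing")
  }
  if (is.null(flag)) flag <- rep("valid", length(ibi))
  flag <- as.character(flag)
  if (!all(flag %in% c("valid", "corrected", "rejected"))) {
    stop("beat flags must be one of 'valid', 'corrected', 'rejected'")
  }
  structure(
    list(subject_id = subject_id,
         start_time = start_time,
         beats = data.frame(t = t, ibi = ibi, flag = flag,
                            stringsAsFactors = FALSE)),
    class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  n <- nrow(x$beats)
  dur <- if (n) x$beats$t[n] / 3600 else 0
  cat("IBI series for subject '", x$subject_id, "'\n", sep = "")
  cat("  start:   ", format(x$start_time, "%Y-%m-%d %H:%M:%S %Z"), "\n", sep = "")
  cat(sprintf("  beats:   %d over %.2f h\n", n, dur))
  if (n) {
    tab <- table(factor(x$beats$flag, c("valid", "corrected", "rejected")))
    cat(sprintf("  flags:   %d valid, %d corrected, %d rejected\n",
                tab[["valid"]], tab[["corrected"]], tab[["rejected"]]))
  }
  invisible(x)
}

# clock hour (0-24) of the recording start, in its own timezone
start_clock_hours <- function(series) {
  lt <- as.POSIXlt(series$start_time)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Read an IBI file
#'
#' Parses the package's plain-text IBI dialect: optional header lines
#' prefixed with `#` carrying `subject_id` and an ISO-8601 `start_time`,
#' followed by one inter-beat interval in milliseconds per line. Beat times
#' are reconstructed as the cumulative sum of the intervals from the start
#' time, and all flags are initialized to `"valid"`. A permissive mode reads
#' bare single-column RR lists (Kubios-TXT-like) when `subject_id` and
#' `start_time` are supplied by the caller.
#'
#' @param path path to the file.
#' @param subject_id,start_time overrides used when the file has no header
#'   (permissive mode) or to replace header values.
#' @return An [ibi_series] object.
#' @export
read_ibi <- function(path, subject_id = NULL, start_time = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]

  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), header, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", m[1]))
  }
  if (is.null(subject_id)) subject_id <- get_field("subject_id")
  if (is.null(start_time)) {
    st <- get_field("start_time")
    if (!is.null(st)) {
      start_time <- as.POSIXct(st, tz = "UTC", tryFormats = c(
        "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
    }
  }
  if (is.null(subject_id)) stop("no subject_id in header and none supplied")
  if (is.null(start_time) || is.na(start_time)) {
    stop("no parseable start_time in header and none supplied")
  }

  suppressWarnings(ibi <- as.numeric(body))
  if (anyNA(ibi)) {
    bad <- which(!grepl("^#", lines) & nzchar(trimws(lines)))[which(is.na(ibi))[1]]
    stop("non-numeric IBI value at line ", bad, " of ", path)
  }
  if (!length(ibi)) {
    warning("IBI file ", path, " has an empty body")
    return(ibi_series(subject_id, start_time, numeric(0)))
  }
  if (any(ibi <= 0)) stop("non-positive IBI value in ", path)
  ibi_series(subject_id, start_time, ibi)
}

#' Write an IBI file
#'
#' Writes the dialect that [read_ibi] expects. Rejected beats are omitted;
#' the interval written for each retained beat is the time elapsed since the
#' previous retained beat, so absolute beat times survive a write/read
#' round trip even across rejected stretches (a gap shows up as one long
#' interval, which the plausibility filter rejects again downstream).
#'
#' @param series an [ibi_series].
#' @param path output path.
#' @param digits decimal digits used for the interval values.
#' @return Invisibly, the number of beats written.
#' @export
write_ibi <- function(series, path, digits = 6) {
  stopifnot(inherits(series, "ibi_series"))
  keep <- series$beats$flag != "rejected"
  n_drop <- sum(!keep)
  if (n_drop) {
    message("write_ibi: omitting ", n_drop, " rejected beat(s) for subject ",
            series$subject_id)
  }
  t <- series$beats$t[keep]
  out_ibi <- diff(c(0, t)) * 1000
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# subject_id: ", series$subject_id),
    paste0("# start_time: ", format(series$start_time, "%Y-%m-%dT%H:%M:%S",
                                    tz = "UTC")),
    formatC(out_ibi, format = "f", digits = digits, drop0trailing = TRUE)
  ), con = con)
  invisible(length(out_ibi))
}
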