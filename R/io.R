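#' Read and write TRC marker-trajectory files
#'
#' The TRC dialect used by biomechanics tools: a 3-line header
#' (`PathFileType`, a metadata key row, a metadata value row with
#' `DataRate`/`NumFrames`/`NumMarkers`/`Units`), a label row, an axis row,
#' then `Frame# Time X1 Y1 Z1 ...` tab-separated data. Missing samples are
#' empty fields. Units `mm` are converted to m on read.
#'
#' @param ts a `trajectory_set`.
#' @param path file path.
#' @param units `"m"` or `"mm"` written in the header.
#' @return `read_trc()` returns a `trajectory_set`; `write_trc()` returns
#'   `path` invisibly.
#' @export
write_trc <- function(ts, path, units = "m") {
  stopifnot(inherits(ts, "trajectory_set"))
  w <- traj_wide(ts)
  f <- if (units == "mm") 1000 else 1
  con <- file(path, "w")
  on.exit(close(con))
  rate <- traj_rate(ts)
  n <- length(w$times); m <- length(w$labels)
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(paste(rate, rate, n, m, units, rate, 1, n, sep = "\t"), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(w$labels, "", ""))), collapse = "\t"), con)
  writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), m),
                                    rep(seq_len(m), each = 3))),
                   collapse = "\t"), con)
  num <- function(v) ifelse(is.na(v), "", format(v * f, digits = 10,
                                                 scientific = FALSE, trim = TRUE))
  body <- vapply(seq_len(n), function(i) {
    xyz <- as.vector(rbind(num(w$x[i, ]), num(w$y[i, ]), num(w$z[i, ])))
    paste(c(i, format(w$times[i], digits = 10, trim = TRUE), xyz),
          collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_trc
#' @param stream_kind stream kind recorded on the returned set.
#' @param meta metadata list for the returned set.
#' @export
read_trc <- function(path, stream_kind = "marker", meta = list()) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("truncated TRC file: fewer than 6 lines")
  if (!startsWith(lines[1], "PathFileType")) {
    stop("malformed TRC header at line 1: expected PathFileType")
  }
  keys <- strsplit(lines[2], "\t")[[1]]
  vals <- strsplit(lines[3], "\t")[[1]]
  hd <- stats::setNames(as.list(vals), keys)
  for (k in c("DataRate", "NumFrames", "NumMarkers", "Units")) {
    if (is.null(hd[[k]])) stop("malformed TRC header at line 2: missing ", k)
  }
  rate <- as.numeric(hd$DataRate)
  m <- as.integer(hd$NumMarkers)
  units <- hd$Units
  if (!units %in% c("m", "mm")) stop("unsupported TRC units at line 3: ", units)
  f <- if (units == "mm") 1 / 1000 else 1
  labrow <- strsplit(lines[4], "\t")[[1]]
  labels <- labrow[seq(3, by = 3, length.out = m)]
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  n <- length(data_lines)
  x <- matrix(NA_real_, n, m, dimnames = list(NULL, labels))
  y <- x; z <- x
  times <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(data_lines[i], "\t")[[1]]
    if (length(fields) < 2 + 3 * m) {
      fields <- c(fields, rep("", 2 + 3 * m - length(fields)))
    }
    vv <- suppressWarnings(as.numeric(fields))
    if (is.na(vv[2])) stop("bad TRC data at line ", i + 5, ": unreadable time")
    times[i] <- vv[2]
    x[i, ] <- vv[seq(3, by = 3, length.out = m)] * f
    y[i, ] <- vv[seq(4, by = 3, length.out = m)] * f
    z[i, ] <- vv[seq(5, by = 3, length.out = m)] * f
  }
  traj_from_wide(list(times = times, labels = labels, x = x, y = y, z = z),
                 rate = rate, stream_kind = stream_kind, meta = meta)
}

#' Read and write STO/MOT time-series files
#'
#' Generic tab-separated time series with a small `key=value` header closed
#' by `endheader`; first column is time. Used for coordinates (degrees),
#' moments (N m) and muscle forces (N).
#'
#' @param data tibble whose first column is `time`.
#' @param path file path.
#' @param name series name written in the header.
#' @param in_degrees logical flag written in the header.
#' @return `read_sto()` returns a tibble; `write_sto()` returns `path`
#'   invisibly.
#' @export
write_sto <- function(data, path, name = "series", in_degrees = TRUE) {
  stopifnot(names(data)[1] == "time")
  if (is.unsorted(data$time)) stop("non-monotone time column")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               "version=1",
               paste0("nRows=", nrow(data)),
               paste0("nColumns=", ncol(data)),
               paste0("inDegrees=", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(names(data), collapse = "\t")), con)
  body <- apply(as.matrix(data), 1, function(row)
    paste(format(row, digits = 10, scientific = FALSE, trim = TRUE),
          collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_sto
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "endheader")
  if (!length(end)) stop("malformed STO file: missing endheader")
  end <- end[1]
  cols <- strsplit(lines[end + 1], "\t")[[1]]
  data_lines <- lines[-(1:(end + 1))]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  vals <- lapply(data_lines, function(l) as.numeric(strsplit(l, "\t")[[1]]))
  m <- do.call(rbind, vals)
  out <- tibble::as_tibble(stats::setNames(as.data.frame(m), cols))
  if (nrow(out) > 1 && is.unsorted(out$time)) {
    stop("non-monotone time column in ", path)
  }
  out
}
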