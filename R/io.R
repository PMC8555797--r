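#' Read a recording in the canonical CSV dialect
#'
#' The canonical interchange format is a UTF-8 CSV with a header row
#' \code{timestamp,count[,light,marker]} and ISO-8601 timestamps labelling the
#' start of each epoch. Rows must be strictly increasing in time. Gaps in the
#' source (missing epochs) are filled with count 0 and mask \code{FALSE}, so
#' the returned series is always on a uniform grid.
#'
#' @param path path to the CSV file.
#' @param epoch_length epoch duration in seconds; when \code{NULL} it is
#'   inferred as the modal difference between consecutive timestamps.
#' @param subject_id recording identifier; defaults to the file name without
#'   extension.
#' @return an \code{\link{epoch_series}}.
#' @export
read_canonical_csv <- function(path, epoch_length = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("timestamp", "count") %in% names(df)))
    stop("canonical CSV must have columns 'timestamp' and 'count': ", path)
  ts <- parse_time(df$timestamp)
  if (anyNA(ts)) stop("unparseable timestamp in ", path)
  if (is.unsorted(as.numeric(ts), strictly = TRUE))
    stop("timestamps must be strictly increasing: ", path)
  counts <- as.numeric(df$count)
  if (anyNA(counts)) stop("non-numeric count in ", path)
  if (any(counts < 0)) stop("negative activity count in ", path)
  if (is.null(epoch_length)) {
    if (length(ts) < 2L)
      stop("cannot infer epoch length from a single row; pass epoch_length")
    d <- diff(as.numeric(ts))
    tab <- table(d)
    epoch_length <- as.numeric(names(tab)[which.max(tab)])
  }
  offs <- as.numeric(ts) - as.numeric(ts[1])
  idx <- offs / epoch_length
  if (any(abs(idx - round(idx)) > 1e-6))
    stop("timestamps in ", path, " are not reconcilable with an epoch length of ",
         epoch_length, " s")
  idx <- as.integer(round(idx)) + 1L
  n <- idx[length(idx)]
  full <- numeric(n)
  mask <- logical(n)
  full[idx] <- counts
  mask[idx] <- TRUE
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  meta <- list(format = "canonical_csv", source = basename(path))
  if ("light" %in% names(df)) meta$has_light <- "yes"
  epoch_series(full, ts[1], epoch_length, subject_id = subject_id,
               mask = mask, meta = meta)
}

#' Write a recording in the canonical CSV dialect
#'
#' Only valid (unmasked) epochs are written as rows, mirroring how gaps are
#' represented on disk; \code{read_canonical_csv} reconstructs the mask from
#' the missing rows, so write-then-read round trips counts, mask and
#' timestamps exactly.
#'
#' @param series an \code{\link{epoch_series}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_canonical_csv <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  ts <- series_times(series)
  keep <- series$mask
  df <- data.frame(timestamp = format_time(ts[keep]),
                   count = series$counts[keep])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- AWD-style plaintext --------------------------------------------------

# Epoch codes of the AWD dialect (CamNtech convention).
.awd_epoch_codes <- c(`1` = 15, `2` = 30, `4` = 60, `8` = 120)

#' Read an AWD-style plaintext recording
#'
#' AWD files carry a 7-line header (subject name, start date, start time,
#' epoch code, age, serial number, sex) followed by one activity count per
#' line. Epoch codes map to epoch lengths via the commonly documented table
#' 1 = 15 s, 2 = 30 s, 4 = 60 s, 8 = 120 s; any other code is rejected.
#' Count lines may carry a trailing non-numeric event marker (e.g.
#' \code{"123M"}); the numeric part is used and the markers are recorded in
#' the series metadata.
#'
#' @param path path to the AWD file.
#' @return an \code{\link{epoch_series}} with all epochs valid.
#' @export
read_awd_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (length(lines) < 8L)
    stop("truncated AWD file (need 7 header lines plus data): ", path)
  hdr <- lines[1:7]
  code <- hdr[4]
  if (!code %in% names(.awd_epoch_codes))
    stop("unknown AWD epoch code '", code, "' in ", path,
         " (known codes: ", paste(names(.awd_epoch_codes), collapse = ", "), ")")
  epoch_length <- .awd_epoch_codes[[code]]
  start <- parse_awd_datetime(hdr[2], hdr[3])
  data <- lines[-(1:7)]
  data <- data[nzchar(data)]
  num <- suppressWarnings(as.numeric(data))
  marked <- which(is.na(num))
  markers <- character(0)
  if (length(marked)) {
    m <- regmatches(data[marked], regexec("^([0-9.]+)([^0-9.].*)$", data[marked]))
    bad <- marked[vapply(m, length, integer(1)) == 0L]
    if (length(bad))
      stop("unparseable count line ", 7L + bad[1], " in ", path, ": '",
           data[bad[1]], "'")
    num[marked] <- as.numeric(vapply(m, `[`, character(1), 2L))
    markers <- paste0(marked, ":", vapply(m, `[`, character(1), 3L))
  }
  meta <- list(format = "awd", source = basename(path), name = hdr[1],
               age = hdr[5], serial = hdr[6], sex = hdr[7])
  if (length(markers)) meta$markers <- paste(markers, collapse = ",")
  epoch_series(num, start, epoch_length, subject_id = hdr[1], meta = meta)
}

.awd_months <- c(jan = 1, feb = 2, mar = 3, apr = 4, may = 5, jun = 6,
                 jul = 7, aug = 8, sep = 9, oct = 10, nov = 11, dec = 12)

# dates "dd-mon-yyyy" or "yyyy-mm-dd" or "dd/mm/yyyy"; times "HH:MM[:SS]"
parse_awd_datetime <- function(date, time) {
  date <- trimws(date)
  m <- regexec("^([0-9]{1,2})-([A-Za-z]{3})-([0-9]{4})$", date)[[1]]
  if (m[1] != -1) {
    g <- regmatches(date, regexec("^([0-9]{1,2})-([A-Za-z]{3})-([0-9]{4})$", date))[[1]]
    mon <- .awd_months[[tolower(g[3])]]
    if (is.null(mon)) stop("unknown month in AWD date: ", date)
    iso <- sprintf("%s-%02d-%02d", g[4], mon, as.integer(g[2]))
  } else if (grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", date)) {
    iso <- date
  } else if (grepl("^[0-9]{1,2}/[0-9]{1,2}/[0-9]{4}$", date)) {
    g <- as.integer(strsplit(date, "/", fixed = TRUE)[[1]])
    iso <- sprintf("%04d-%02d-%02d", g[3], g[2], g[1])
  } else stop("unparseable AWD start date: ", date)
  if (grepl("^[0-9]{1,2}:[0-9]{2}$", trimws(time))) time <- paste0(time, ":00")
  t <- parse_time(paste(iso, trimws(time)))
  if (anyNA(t)) stop("unparseable AWD start date/time: ", date, " ", time)
  t
}

## ---- start/stop-time logs --------------------------------------------------

#' Read a start/stop-time (SST) log
#'
#' The log is a CSV with columns \code{SUBJECT_ID,START,STOP} (case
#' insensitive), one row per participant, delimiting the portion of each
#' recording that was actually worn.
#'
#' @param path path to the log file.
#' @return data.frame with columns \code{subject_id}, \code{start},
#'   \code{stop} (POSIXct).
#' @export
read_sst_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("subject_id", "start", "stop") %in% names(df)))
    stop("SST log must have columns SUBJECT_ID, START, STOP: ", path)
  out <- data.frame(subject_id = as.character(df$subject_id),
                    start = parse_time(df$start), stop = parse_time(df$stop),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$stop))
    stop("unparseable timestamp in SST log ", path)
  if (any(as.numeric(out$stop) <= as.numeric(out$start)))
    stop("SST log entries must have start < stop: ", path)
  out
}

#' Restrict a recording to its worn time range
#'
#' Epochs outside the half-open interval \code{[start, stop)} are dropped;
#' only the retained range is analysed downstream. Applying the same entry
#' twice is a no-op.
#'
#' @param series an \code{\link{epoch_series}}.
#' @param start,stop timestamps (POSIXct or ISO-8601 strings) with
#'   \code{start < stop}.
#' @return the truncated \code{\link{epoch_series}}.
#' @export
apply_sst <- function(series, start, stop) {
  stopifnot(inherits(series, "epoch_series"))
  start <- as_time(start); stop <- as_time(stop)
  if (as.numeric(stop) <= as.numeric(start)) stop("SST entry must have start < stop")
  t <- as.numeric(series_times(series))
  keep <- t >= as.numeric(start) & t < as.numeric(stop)
  if (!any(keep))
    stop("SST range [", format_time(start), ", ", format_time(stop),
         ") does not overlap the recording")
  i <- range(which(keep))
  out <- series
  out$counts <- series$counts[i[1]:i[2]]
  out$mask <- series$mask[i[1]:i[2]]
  out$start_time <- series$start_time + (i[1] - 1) * series$epoch_length
  out
}

#' Read several recordings at once
#'
#' Reads each file with the reader selected by \code{format} and, when an SST
#' log is supplied, truncates each series whose \code{subject_id} appears in
#' the log. Log entries without a matching recording produce a warning, not an
#' error. Reading is order-preserving and independent per file.
#'
#' @param paths character vector of file paths.
#' @param format \code{"canonical_csv"} or \code{"awd"}.
#' @param sst_log optional path to an SST log CSV.
#' @return a list of \code{\link{epoch_series}}, one per input path.
#' @export
read_batch <- function(paths, format = c("canonical_csv", "awd"), sst_log = NULL) {
  format <- match.arg(format)
  reader <- switch(format, canonical_csv = read_canonical_csv, awd = read_awd_text)
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    out[[i]] <- tryCatch(reader(paths[[i]]),
                         error = function(e) stop("failed to read '", paths[[i]],
                                                  "': ", conditionMessage(e)))
  }
  if (!is.null(sst_log)) {
    log <- read_sst_log(sst_log)
    ids <- vapply(out, function(s) s$subject_id, character(1))
    for (j in seq_len(nrow(log))) {
      hit <- which(ids == log$subject_id[j])
      if (!length(hit)) {
        warning("SST log subject '", log$subject_id[j],
                "' has no matching recording")
        next
      }
      for (k in hit)
        out[[k]] <- apply_sst(out[[k]], log$start[j], log$stop[j])
    }
  }
  out
}
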