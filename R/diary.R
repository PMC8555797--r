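#' Read a sleep diary
#'
#' Sleep diaries are event tables with columns \code{TYPE}, \code{START},
#' \code{END} (case insensitive), one row per reported event, encoded either
#' as CSV or as an OpenDocument spreadsheet (.ods). The default event
#' vocabulary of the field (active, nap, night, no-wear) is not enforced:
#' any non-empty type is accepted, so users can extend or rename event types
#' freely.
#'
#' @param path path to a \code{.csv} or \code{.ods} diary file.
#' @return data.frame of class \code{sleep_diary} with columns \code{type}
#'   (character), \code{start}, \code{end} (POSIXct), in file order.
#' @export
read_diary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub("^.*\\.", "", path))
  df <- if (ext == "ods") read_ods_table(path) else
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  names(df) <- tolower(names(df))
  if (!all(c("type", "start", "end") %in% names(df)))
    stop("diary must have columns TYPE, START, END: ", path)
  type <- trimws(as.character(df$type))
  start <- parse_time(df$start)
  end <- parse_time(df$end)
  if (anyNA(start) || anyNA(end))
    stop("unparseable diary timestamp in ", path)
  if (any(!nzchar(type))) stop("empty event type in ", path)
  bad <- which(as.numeric(end) <= as.numeric(start))
  if (length(bad))
    stop("diary row ", bad[1], " has END <= START (", type[bad[1]], ")")
  structure(data.frame(type = type, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("sleep_diary", "data.frame"))
}

# Minimal ODS table reader: extracts the first sheet of content.xml.
# Handles the attributes LibreOffice-style writers actually emit for plain
# tables (number-columns-repeated on cells); values are taken from the cell
# text content.
read_ods_table <- function(path) {
  tmp <- tempfile("ods_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  utils::unzip(path, files = "content.xml", exdir = tmp, unzip = "internal")
  doc <- xml2::read_xml(file.path(tmp, "content.xml"))
  rows <- xml2::xml_find_all(doc, "//table:table[1]//table:table-row")
  cells <- lapply(rows, function(r) {
    cs <- xml2::xml_find_all(r, "table:table-cell")
    out <- character(0)
    for (c in cs) {
      rep <- xml2::xml_attr(c, "number-columns-repeated")
      rep <- if (is.na(rep)) 1L else as.integer(rep)
      val <- paste(xml2::xml_text(xml2::xml_find_all(c, "text:p")), collapse = "\n")
      out <- c(out, rep(val, rep))
    }
    out
  })
  cells <- Filter(function(x) any(nzchar(x)), cells)
  if (length(cells) < 2L) stop("ODS sheet has no data rows: ", path)
  header <- cells[[1]]
  ncol <- length(header)
  body <- lapply(cells[-1], function(x) { length(x) <- ncol; x })
  df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Descriptive statistics of diary events by type
#'
#' Computes, per event type, the number of events and the mean, standard
#' deviation and quantiles of event duration. The population standard
#' deviation (denominator n) is used so that a type with a single event
#' reports 0 rather than NA.
#'
#' @param events a \code{sleep_diary} data.frame from \code{\link{read_diary}}.
#' @param probs quantile fractions to report (monotone, in \code{[0, 1]}).
#' @return data.frame of class \code{diary_summary}, one row per type, with
#'   durations in minutes.
#' @export
summarize_diary <- function(events, probs = c(0.25, 0.5, 0.75)) {
  if (!nrow(events)) stop("no diary events to summarize")
  if (is.unsorted(probs)) stop("quantile fractions must be monotone")
  dur <- as.numeric(events$end) - as.numeric(events$start)
  types <- sort(unique(events$type))
  rows <- lapply(types, function(tp) {
    d <- dur[events$type == tp] / 60
    q <- stats::quantile(d, probs = probs, names = FALSE)
    out <- data.frame(type = tp, n = length(d), mean_min = mean(d),
                      sd_min = sqrt(mean((d - mean(d))^2)))
    for (i in seq_along(probs))
      out[[sprintf("q%02.0f_min", 100 * probs[i])]] <- q[i]
    out
  })
  structure(do.call(rbind, rows), class = c("diary_summary", "data.frame"))
}
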