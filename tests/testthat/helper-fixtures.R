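# Fixture builders shared across the suite. Everything is generated in code
# at test time; no binary files ship with the package.

make_series <- function(counts, epoch = 60, start = "2020-01-06 00:00:00",
                        mask = NULL, subject = "test") {
  epoch_series(counts, start, epoch, subject_id = subject, mask = mask)
}

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

diary_csv_lines <- function() c(
  "TYPE,START,END",
  "nap,2020-01-06 13:00:00,2020-01-06 13:30:00",
  "night,2020-01-06 23:00:00,2020-01-07 07:00:00",
  "no-wear,2020-01-07 10:00:00,2020-01-07 11:00:00",
  "nap,2020-01-07 14:00:00,2020-01-07 15:30:00")

awd_lines <- function(counts, name = "subj01", date = "25-jan-1918",
                      time = "00:00", code = "4") {
  c(name, date, time, code, "33", "V123456", "M", as.character(counts))
}

## ---- minimal stored-entry ZIP writer (for the .ods fixture) ---------------

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), -306674912L) else
        bitwShiftR(c, 1L)
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

int_le <- function(x, n) {
  out <- raw(n)
  x <- as.numeric(x) %% 2^(8 * n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# uncompressed ZIP with the given named character entries
write_stored_zip <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  centrals <- list()
  pos <- 0
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- charToRaw(entries[[i]])
    crc <- crc32(data)
    local_hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), int_le(20, 2),
                   int_le(0, 2), int_le(0, 2), int_le(0, 2), int_le(0, 2),
                   int_le(crc, 4), int_le(length(data), 4),
                   int_le(length(data), 4), int_le(length(name), 2),
                   int_le(0, 2))
    offsets[i] <- pos
    writeBin(c(local_hdr, name, data), con)
    pos <- pos + length(local_hdr) + length(name) + length(data)
    centrals[[i]] <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), int_le(20, 2),
                       int_le(20, 2), int_le(0, 2), int_le(0, 2), int_le(0, 2),
                       int_le(0, 2), int_le(crc, 4), int_le(length(data), 4),
                       int_le(length(data), 4), int_le(length(name), 2),
                       int_le(0, 2), int_le(0, 2), int_le(0, 2), int_le(0, 2),
                       int_le(0, 4), int_le(offsets[i], 4), name)
  }
  cd_start <- pos
  for (c in centrals) { writeBin(c, con); pos <- pos + length(c) }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), int_le(0, 2), int_le(0, 2),
            int_le(length(entries), 2), int_le(length(entries), 2),
            int_le(pos - cd_start, 4), int_le(cd_start, 4), int_le(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

# .ods encoding of a character table (rows of equal length)
write_ods_fixture <- function(path, rows) {
  cell <- function(v) paste0(
    '<table:table-cell office:value-type="string"><text:p>', v,
    "</text:p></table:table-cell>")
  row_xml <- vapply(rows, function(r)
    paste0("<table:table-row>", paste(vapply(r, cell, character(1)),
                                      collapse = ""), "</table:table-row>"),
    character(1))
  content <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<office:document-content ',
    'xmlns:office="urn:oasis:names:tc:opendocument:xmlns:office:1.0" ',
    'xmlns:table="urn:oasis:names:tc:opendocument:xmlns:table:1.0" ',
    'xmlns:text="urn:oasis:names:tc:opendocument:xmlns:text:1.0" ',
    'office:version="1.2"><office:body><office:spreadsheet>',
    '<table:table table:name="Sheet1">',
    paste(row_xml, collapse = ""),
    "</table:table></office:spreadsheet></office:body></office:document-content>")
  write_stored_zip(path, c(
    mimetype = "application/vnd.oasis.opendocument.spreadsheet",
    "content.xml" = content))
  invisible(path)
}
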