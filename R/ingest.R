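#' Anonymize a MAC address
#'
#' One-way salted hash of a hardware address: SHA-256 over
#' \code{"<salt>:<mac>"} (MAC lower-cased, separators stripped),
#' truncated to 16 hex characters. Deterministic for a given
#' \code{(mac, salt)} pair; different salts yield unrelated digests, and
#' no byte of the MAC survives into the digest.
#'
#' @param mac character vector of 12-hex-digit MAC addresses; \code{":"}
#'   and \code{"-"} separators are accepted.
#' @param salt nonempty salt string.
#' @return character vector of 16-hex-character device identifiers.
#' @export
#' @examples
#' anonymize_identifier("A4:C1:38:01:23:45", "pepper")
anonymize_identifier <- function(mac, salt) {
  if (!is.character(salt) || length(salt) != 1 || !nzchar(salt))
    stop("`salt` must be a nonempty string", call. = FALSE)
  norm <- tolower(gsub("[:-]", "", mac))
  bad <- !grepl("^[0-9a-f]{12}$", norm)
  if (any(bad))
    stop("malformed MAC address: ", paste(mac[bad], collapse = ", "),
         call. = FALSE)
  substr(as.character(openssl::sha256(paste0(salt, ":", norm))), 1, 16)
}

format_probe_time <- function(t) {
  s <- format(t, "%Y-%m-%dT%H:%M:%S%z")
  sub("([+-][0-9]{2})([0-9]{2})$", "\\1:\\2", s)
}

parse_probe_time <- function(x, tz) {
  suppressWarnings(
    lubridate::with_tz(lubridate::ymd_hms(x, quiet = TRUE), tz)
  )
}

#' Read a probe-request log
#'
#' Reads the canonical detection stream (\code{timestamp, device_id,
#' oui, rssi}) from CSV or JSON-lines, validates every row, and returns
#' the surviving records time-sorted together with an ingest report.
#' Malformed rows (unparseable timestamp, RSSI outside [-100, 0], OUI
#' not 6 hex digits, device id not a 16-hex digest) are counted and
#' dropped, never fatal. OUIs are normalized to upper case and device
#' ids to lower case.
#'
#' @param source path to the log file.
#' @param format \code{"csv"} or \code{"jsonl"}.
#' @param tz timezone the timestamps are converted to for analysis.
#' @return list with \code{records} (tibble) and \code{report} (list:
#'   \code{read}, \code{kept}, \code{dropped}, and a named integer
#'   vector \code{reasons}).
#' @export
read_probe_log <- function(source, format = c("csv", "jsonl"),
                           tz = "Asia/Tokyo") {
  format <- match.arg(format)
  if (!file.exists(source))
    stop("cannot read probe log: ", source, call. = FALSE)

  empty_df <- data.frame(timestamp = character(), device_id = character(),
                         oui = character(), rssi = character())
  if (format == "csv") {
    df <- tryCatch(utils::read.csv(source, colClasses = "character"),
                   error = function(e) empty_df)
    if (nrow(df) == 0) df <- empty_df
  } else {
    lines <- readLines(source, warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(l) {
      x <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
      if (is.null(x)) {
        list(timestamp = NA_character_, device_id = NA_character_,
             oui = NA_character_, rssi = NA_character_)
      } else {
        list(timestamp = as.character(x$timestamp %||% NA),
             device_id = as.character(x$device_id %||% NA),
             oui = as.character(x$oui %||% NA),
             rssi = as.character(x$rssi %||% NA))
      }
    })
    df <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  }
  n_read <- nrow(df)
  if (n_read == 0) {
    return(list(records = empty_probe_log(tz),
                report = list(read = 0L, kept = 0L, dropped = 0L,
                              reasons = integer(0))))
  }

  ts <- parse_probe_time(df$timestamp, tz)
  rssi <- suppressWarnings(as.numeric(df$rssi))
  oui <- toupper(trimws(df$oui))
  dev <- tolower(trimws(df$device_id))

  bad_ts <- is.na(ts)
  bad_rssi <- !bad_ts & (is.na(rssi) | rssi < -100 | rssi > 0 |
                           rssi != trunc(rssi))
  bad_oui <- !bad_ts & !bad_rssi & !grepl("^[0-9A-F]{6}$", oui)
  bad_dev <- !bad_ts & !bad_rssi & !bad_oui & !grepl("^[0-9a-f]{16}$", dev)
  ok <- !(bad_ts | bad_rssi | bad_oui | bad_dev)

  reasons <- c(bad_timestamp = sum(bad_ts),
               rssi_out_of_range = sum(bad_rssi),
               bad_oui = sum(bad_oui),
               bad_device_id = sum(bad_dev))
  reasons <- reasons[reasons > 0]

  rec <- tibble::tibble(
    timestamp = ts[ok], device_id = dev[ok], oui = oui[ok],
    rssi = as.integer(rssi[ok])
  )
  rec <- rec[order(rec$timestamp, rec$device_id, rec$rssi), , drop = FALSE]
  list(records = rec,
       report = list(read = n_read, kept = sum(ok),
                     dropped = n_read - sum(ok),
                     reasons = as.integer(reasons) |>
                       stats::setNames(names(reasons))))
}

#' Write a probe-request log
#'
#' Serializes canonical probe records to CSV or JSON-lines with
#' ISO-8601 timestamps carrying the local UTC offset (e.g.
#' \code{2023-10-28T15:00:00+09:00}). A write/read round trip through
#' [read_probe_log()] preserves every field value exactly.
#'
#' @param records canonical probe-record tibble.
#' @param path output file.
#' @param format \code{"csv"} or \code{"jsonl"}.
#' @return \code{path}, invisibly.
#' @export
write_probe_log <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  out <- data.frame(
    timestamp = format_probe_time(records$timestamp),
    device_id = records$device_id,
    oui = records$oui,
    rssi = records$rssi
  )
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}
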