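# On-disk session format: a directory holding
#   channels.csv  time_s, ach_465, ach_405, da_465, da_405  (wide table)
#   events.csv    label, time_s
#   meta.json     session metadata
# plus optionally ground_truth.csv for synthetic sessions.

CSV_CHANNEL_COLS <- c(ACh_465 = "ach_465", ACh_405 = "ach_405",
                      DA_465 = "da_465", DA_405 = "da_405")

#' Write a session to a directory
#'
#' Serializes the four raw traces as a wide CSV, the event stream as a
#' second CSV and the metadata as JSON. `writeSession` followed by
#' [readSession()] reproduces the session up to numeric round-trip.
#'
#' @param session a [PhotometrySession-class].
#' @param path directory to create/write into.
#' @param truth optional ground-truth data.frame written as
#'   `ground_truth.csv` (synthetic sessions).
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path, truth = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ch <- data.table::data.table(time_s = sessionTime(session))
  for (k in names(CSV_CHANNEL_COLS))
    ch[[CSV_CHANNEL_COLS[[k]]]] <- session@channels[[k]]
  data.table::fwrite(ch, file.path(path, "channels.csv"))
  data.table::fwrite(sessionEvents(session), file.path(path, "events.csv"))
  jsonlite::write_json(sessionMeta(session), file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth))
    data.table::fwrite(truth, file.path(path, "ground_truth.csv"))
  invisible(path)
}

#' Read a session from a directory
#'
#' Validates the on-disk layout before any analysis can run: all four
#' channels must be present and equal in length to the time base, the time
#' base strictly increasing with near-uniform spacing, and every event
#' inside the recorded span (each violation raises a format error naming
#' the offending field). Unknown event labels are kept verbatim with a
#' warning.
#'
#' @param path session directory as written by [writeSession()].
#' @return A [PhotometrySession-class].
#' @export
readSession <- function(path) {
  chFile <- file.path(path, "channels.csv")
  if (!file.exists(chFile)) stop("no channels.csv under ", path)
  ch <- data.table::fread(chFile, data.table = FALSE)
  if (!"time_s" %in% names(ch)) stop("channels.csv lacks time_s column")
  miss <- CSV_CHANNEL_COLS[!CSV_CHANNEL_COLS %in% names(ch)]
  if (length(miss)) {
    pretty <- vapply(names(miss), function(k) {
      p <- strsplit(k, "_")[[1]]
      paste0("(", p[1], ", ", p[2], ")")
    }, character(1))
    stop("missing ", paste(pretty, collapse = ", "))
  }
  evFile <- file.path(path, "events.csv")
  events <- if (file.exists(evFile))
    data.table::fread(evFile, data.table = FALSE)
  else data.frame(label = character(0), time_s = numeric(0))
  if (nrow(events)) {
    unknown <- setdiff(unique(events$label), KNOWN_EVENT_LABELS)
    if (length(unknown))
      warning("unknown event label(s) preserved verbatim: ",
              paste(unknown, collapse = ", "))
  }
  metaFile <- file.path(path, "meta.json")
  meta <- if (file.exists(metaFile))
    jsonlite::read_json(metaFile, simplifyVector = TRUE)
  else list()
  channels <- lapply(CSV_CHANNEL_COLS, function(col) ch[[col]])
  names(channels) <- names(CSV_CHANNEL_COLS)
  photometrySession(time = ch$time_s, channels = channels,
                    events = events, meta = meta)
}

#' Read the ground-truth sidecar of a synthetic session
#'
#' @param path session directory.
#' @return data.frame, or NULL when the session has no sidecar.
#' @export
readGroundTruth <- function(path) {
  f <- file.path(path, "ground_truth.csv")
  if (!file.exists(f)) return(NULL)
  data.table::fread(f, data.table = FALSE)
}
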