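# Reading GPS and metadata tables, collar-to-animal assignment, regular
# 30-minute segmentation, and season/diel labelling.

GPS_COLUMNS <- c("collar_id", "timestamp_utc", "lat", "lon")
META_COLUMNS <- c("collar_id", "animal_id", "herd_id", "herd_type",
                  "start_utc", "end_utc")

parse_utc <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%d %H:%M", "%Y-%m-%d"))
}

#' Read a GPS fix table
#'
#' Expected CSV columns: `collar_id,timestamp_utc,lat,lon` plus optional
#' `dop` and `temperature_c`; ISO-8601 UTC timestamps. Malformed rows
#' (unparseable timestamp, latitude/longitude out of range) are reported
#' with their line numbers and excluded, never silently dropped; duplicate
#' (collar, timestamp) rows are deduplicated with a warning.
#'
#' @param path CSV file path (leading `#` comment lines allowed).
#' @return data.frame of fixes sorted by collar and time, with attributes
#'   `bad_rows` (data.frame: line, reason) and `n_duplicates`.
#' @export
read_gps_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(GPS_COLUMNS, names(df))
  if (length(missing_cols))
    stop("GPS table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  ts <- suppressWarnings(parse_utc(df$timestamp_utc))
  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$lon))
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(ts)] <- "unparseable timestamp"
  reason[is.na(reason) & (is.na(lat) | lat < -90 | lat > 90)] <-
    "latitude out of [-90, 90]"
  reason[is.na(reason) & (is.na(lon) | lon < -180 | lon > 180)] <-
    "longitude out of [-180, 180]"
  bad <- which(!is.na(reason))
  bad_rows <- data.frame(line = bad + 1L, reason = reason[bad])
  if (length(bad))
    warning(length(bad), " malformed row(s) excluded (see attr 'bad_rows')")
  keep <- setdiff(seq_len(nrow(df)), bad)
  out <- data.frame(collar_id = as.character(df$collar_id[keep]),
                    timestamp = ts[keep], lat = lat[keep], lon = lon[keep])
  out$dop <- if ("dop" %in% names(df))
    suppressWarnings(as.numeric(df$dop[keep])) else NA_real_
  out$temperature_c <- if ("temperature_c" %in% names(df))
    suppressWarnings(as.numeric(df$temperature_c[keep])) else NA_real_
  out <- out[order(out$collar_id, out$timestamp), ]
  dup <- duplicated(out[c("collar_id", "timestamp")])
  if (any(dup))
    warning(sum(dup), " duplicate (collar, timestamp) row(s) removed")
  out <- out[!dup, ]
  rownames(out) <- NULL
  attr(out, "bad_rows") <- bad_rows
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Read a collar-assignment metadata table
#'
#' Columns: `collar_id,animal_id,herd_id,herd_type,start_utc,end_utc`.
#' Periods of one collar must not overlap; `herd_type` must be `resident`
#' or `transhumant`.
#'
#' @param path CSV file path.
#' @return validated data.frame of assignment periods.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(META_COLUMNS, names(df))
  if (length(missing_cols))
    stop("metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(collar_id = as.character(df$collar_id),
                    animal_id = as.character(df$animal_id),
                    herd_id = as.character(df$herd_id),
                    herd_type = as.character(df$herd_type),
                    start = parse_utc(df$start_utc),
                    end = parse_utc(df$end_utc))
  if (any(is.na(out$start) | is.na(out$end)))
    stop("metadata has unparseable start/end timestamps")
  if (any(out$start >= out$end))
    stop("metadata periods must satisfy start < end")
  if (!all(out$herd_type %in% c("resident", "transhumant")))
    stop("herd_type must be 'resident' or 'transhumant'")
  for (cid in unique(out$collar_id)) {
    per <- out[out$collar_id == cid, ]
    per <- per[order(per$start), ]
    if (nrow(per) > 1 && any(per$start[-1] < per$end[-nrow(per)]))
      stop("overlapping assignment periods for collar ", cid)
  }
  out
}

#' Build a filter report
#'
#' Accounting of the cleaning rules: `n_collected = n_usable + sum(rules)`
#' holds by construction and `pct_removed = 100 (n_collected - n_usable) /
#' n_collected`.
#'
#' @param n_collected number of raw fixes.
#' @param rules named integer vector of per-rule removal counts.
#' @return list of class `filter_report`.
#' @export
filter_report <- function(n_collected, rules = integer(0)) {
  n_usable <- n_collected - sum(rules)
  stopifnot(n_usable >= 0)
  structure(list(n_collected = as.integer(n_collected),
                 n_usable = as.integer(n_usable),
                 pct_removed = 100 * (n_collected - n_usable) / n_collected,
                 rules = as.list(rules)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("collected %d, usable %d (%.2f%% removed)\n",
              x$n_collected, x$n_usable, x$pct_removed))
  for (r in names(x$rules)) cat(sprintf("  %-18s %d\n", r, x$rules[[r]]))
  invisible(x)
}

#' Assign fixes to animals and cut into regular segments
#'
#' Each fix is mapped to an animal via the assignment period covering its
#' timestamp (fixes outside any period are removed under rule
#' `unassigned`); rows with missing coordinates fall under `incomplete`.
#' Within an animal the fix stream is cut wherever the inter-fix gap
#' deviates from the nominal interval by more than `tolerance`; runs
#' shorter than `min_len` are removed (`short_segment`). Running the
#' segmentation again on its own output changes nothing.
#'
#' @param gps fix table from [read_gps_table()].
#' @param metadata assignment table from [read_metadata()].
#' @param interval_s nominal fix interval, seconds (default 1800).
#' @param tolerance_s allowed deviation around the nominal interval
#'   (default 300 s, i.e. plus/minus 5 min).
#' @param min_len minimum usable run length in fixes (default 10).
#' @return list with `segments` (fix data.frame with `animal_id`,
#'   `herd_id`, `herd_type`, `segment_id` columns) and `report`
#'   (a [filter_report()]).
#' @export
assign_and_segment <- function(gps, metadata, interval_s = 1800,
                               tolerance_s = 300, min_len = 10) {
  n_collected <- nrow(gps)
  incomplete <- is.na(gps$lat) | is.na(gps$lon) | is.na(gps$timestamp)
  gps2 <- gps[!incomplete, , drop = FALSE]
  # period lookup per collar
  animal <- rep(NA_character_, nrow(gps2))
  herd <- rep(NA_character_, nrow(gps2))
  htype <- rep(NA_character_, nrow(gps2))
  for (k in seq_len(nrow(metadata))) {
    m <- metadata[k, ]
    hit <- gps2$collar_id == m$collar_id &
      gps2$timestamp >= m$start & gps2$timestamp < m$end
    animal[hit] <- m$animal_id
    herd[hit] <- m$herd_id
    htype[hit] <- m$herd_type
  }
  unassigned <- is.na(animal)
  df <- gps2[!unassigned, , drop = FALSE]
  df$animal_id <- animal[!unassigned]
  df$herd_id <- herd[!unassigned]
  df$herd_type <- htype[!unassigned]
  df <- df[order(df$animal_id, df$timestamp), ]
  short <- 0L
  if (nrow(df)) {
    dt <- c(Inf, as.numeric(diff(df$timestamp), units = "secs"))
    newanimal <- c(TRUE, df$animal_id[-1] != df$animal_id[-nrow(df)])
    cut <- newanimal | abs(dt - interval_s) > tolerance_s
    run <- cumsum(cut)
    len <- stats::ave(run, run, FUN = length)
    keep <- len >= min_len
    short <- sum(!keep)
    df <- df[keep, , drop = FALSE]
    run <- run[keep]
    df$segment_id <- paste0(df$animal_id, "_s",
                            as.integer(factor(run, levels = unique(run))))
  } else {
    df$segment_id <- character(0)
  }
  rownames(df) <- NULL
  rules <- c(incomplete = sum(incomplete), unassigned = sum(unassigned),
             short_segment = short)
  list(segments = df, report = filter_report(n_collected, rules))
}

#' Season and diel labels for fixes
#'
#' Season from the calendar month (November-February cold dry, March-May
#' warm dry, June-October rainy); diel phase from sunrise/sunset computed
#' at the dataset centre in local apparent solar time: `day` iff
#' sunrise <= local apparent time < sunset.
#'
#' @param timestamps POSIXct, UTC.
#' @param centre numeric `c(lon, lat)` of the dataset's geographic centre.
#' @return data.frame with factors `season` (`cold_dry`, `warm_dry`,
#'   `rainy`) and `diel` (`day`, `night`).
#' @export
label_time <- function(timestamps, centre) {
  if (any(!is.finite(centre))) stop("centre must be finite")
  mon <- as.POSIXlt(timestamps, tz = "UTC")$mon + 1L
  season <- factor(ifelse(mon %in% c(11, 12, 1, 2), "cold_dry",
                   ifelse(mon %in% 3:5, "warm_dry", "rainy")),
                   levels = c("cold_dry", "warm_dry", "rainy"))
  ast <- apparent_solar_time(timestamps, centre[1])
  st <- sun_times_apparent(timestamps, centre[2])
  diel <- factor(ifelse(ast >= st$sunrise & ast < st$sunset,
                        "day", "night"),
                 levels = c("day", "night"))
  data.frame(season = season, diel = diel)
}
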