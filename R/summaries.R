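# Thematic summaries of decoded, annotated fixes: activity budgets, daily
# movement metrics and transhumance phase detection.

#' Activity budget: per-state proportions within key combinations
#'
#' Counts and within-cell proportions of fixes per state, for every
#' combination of the requested keys (subset of `hour`, `season`,
#' `herd_type`, `diel`, `unit`). Cells with no fixes are reported with
#' count 0 and proportion `NA` (never NaN arithmetic downstream); total
#' fix count equals the sum of counts over all cells.
#'
#' @param fixes data.frame of decoded fixes with a `state` column (factor
#'   or label) plus the key columns; an `hour` key is derived from
#'   `timestamp` if absent.
#' @param keys character vector of key column names (may be empty for a
#'   global budget).
#' @return data.frame: keys, `state`, `n`, `prop`.
#' @export
activity_budget <- function(fixes, keys = character(0)) {
  if (!"state" %in% names(fixes)) stop("fixes must carry a state column")
  if ("hour" %in% keys && !"hour" %in% names(fixes))
    fixes$hour <- as.POSIXlt(fixes$timestamp, tz = "UTC")$hour
  missing_keys <- setdiff(keys, names(fixes))
  if (length(missing_keys))
    stop("missing key column(s): ", paste(missing_keys, collapse = ", "))
  fct <- lapply(fixes[c(keys, "state")], factor)
  counts <- as.data.frame(table(fct, dnn = c(keys, "state")),
                          responseName = "n")
  cell <- if (length(keys)) interaction(counts[keys], drop = FALSE)
          else factor(rep(1, nrow(counts)))
  tot <- stats::ave(counts$n, cell, FUN = sum)
  counts$prop <- ifelse(tot > 0, counts$n / tot, NA_real_)
  counts
}

#' Daily distance and time per state
#'
#' For each animal-day (UTC date): time per state = 0.5 h times the fix
#' count in that state; distance per state = sum of the lengths of steps
#' whose originating fix is in that state. With `daytime_only` only fixes
#' labelled `day` contribute. Days interrupted by data gaps keep their
#' available fixes and are flagged `partial` (fewer fixes than the nominal
#' day span). Per-herd-type means over animal-days are returned alongside.
#'
#' @param fixes decoded fixes with `animal_id`, `herd_type`, `timestamp`,
#'   `state`, `diel` and `step_m` (length of the step leaving each fix;
#'   last fix of a segment NA).
#' @param daytime_only restrict to daytime fixes (default TRUE).
#' @param interval_s nominal fix interval, seconds.
#' @return list: `daily` (animal, date, state, time_h, distance_m, n_fixes,
#'   partial) and `means` (herd_type, state, mean time and distance per
#'   day).
#' @export
daily_metrics <- function(fixes, daytime_only = TRUE, interval_s = 1800) {
  need <- c("animal_id", "herd_type", "timestamp", "state", "step_m")
  miss <- setdiff(need, names(fixes))
  if (length(miss)) stop("fixes lack column(s): ", paste(miss, collapse = ", "))
  if (daytime_only) {
    if (!"diel" %in% names(fixes)) stop("daytime_only needs a diel column")
    fixes <- fixes[fixes$diel == "day", , drop = FALSE]
  }
  if (!nrow(fixes))
    return(list(daily = data.frame(), means = data.frame()))
  fixes$date <- as.Date(fixes$timestamp, tz = "UTC")
  fixes$state <- factor(fixes$state)
  step0 <- ifelse(is.na(fixes$step_m), 0, fixes$step_m)
  key <- list(animal_id = fixes$animal_id, herd_type = fixes$herd_type,
              date = fixes$date, state = fixes$state)
  cnt <- aggregate(list(n_fixes = rep(1L, nrow(fixes))), key, sum, drop = FALSE)
  dst <- aggregate(list(distance_m = step0), key, sum, drop = FALSE)
  daily <- merge(cnt, dst)
  daily <- daily[!is.na(daily$animal_id), ]
  daily$n_fixes[is.na(daily$n_fixes)] <- 0L
  daily$distance_m[is.na(daily$distance_m)] <- 0
  daily$time_h <- daily$n_fixes * interval_s / 3600
  # a full day of fixes at the nominal interval; daytime days are shorter
  perday <- aggregate(list(day_total = daily$n_fixes),
                      daily[c("animal_id", "date")], sum)
  daily <- merge(daily, perday)
  expected <- max(perday$day_total)
  daily$partial <- daily$day_total < 0.75 * expected
  daily$day_total <- NULL
  daily <- daily[order(daily$animal_id, daily$date, daily$state), ]
  rownames(daily) <- NULL
  means <- aggregate(daily[c("time_h", "distance_m")],
                     daily[c("herd_type", "state")], mean)
  list(daily = daily, means = means)
}

daily_centroids <- function(track) {
  track$date <- as.Date(track$timestamp, tz = "UTC")
  centre <- c(mean(track$lon), mean(track$lat))
  xy <- local_xy(track[, c("lon", "lat")], centre)
  agg <- aggregate(list(x = xy[, 1], y = xy[, 2]),
                   list(date = track$date), mean)
  agg[order(agg$date), ]
}

#' Detect transhumance departure, stops and phases
#'
#' Works on daily centroids of one herd's track. Departure is the first day
#' of a run of at least `persistence_days` days whose centroid lies outside
#' `home_area`. Stops are maximal runs of at least `min_stop_days` days
#' whose centroids stay within `stop_radius_km` of the running stop
#' centroid. Stop durations are grouped by seeded 1-D k-means (best of 50
#' starts) into `n_clusters` duration classes. Return is the first day back
#' inside `home_area` after the day of maximum displacement. A track that
#' never leaves the home area yields a record with no departure (resident).
#'
#' @param track chronological data.frame with `lon`, `lat`, `timestamp`
#'   (one herd).
#' @param home_area two-column lon/lat matrix: the home-area polygon.
#' @param stop_radius_km radius within which daily centroids count as one
#'   stop (default 2 km).
#' @param min_stop_days minimum stop duration in days (default 3).
#' @param persistence_days days outside home required to call a departure
#'   (default 2).
#' @param n_clusters duration classes for the k-means step (default 3).
#' @param seed seed for the k-means initialisation.
#' @param herd_id identifier stored in the record.
#' @return list of class `phase_record`: `herd_id`, `departure`, `return`
#'   (Dates or NA), `stops` (data.frame: start, end, duration_days,
#'   centroid lon/lat, duration_class), `phases` (data.frame: label,
#'   start, end).
#' @export
detect_stops_and_phases <- function(track, home_area, stop_radius_km = 2,
                                    min_stop_days = 3, persistence_days = 2,
                                    n_clusters = 3, seed = 1,
                                    herd_id = "herd") {
  cen <- daily_centroids(track)
  centre <- c(mean(track$lon), mean(track$lat))
  ll <- local_lonlat(as.matrix(cen[, c("x", "y")]), centre)
  outside <- !vapply(seq_len(nrow(cen)), function(i)
    point_in_polygon(ll[i, 1], ll[i, 2], home_area), logical(1))
  rec <- list(herd_id = herd_id, departure = as.Date(NA),
              return_date = as.Date(NA),
              stops = data.frame(), phases = data.frame())
  class(rec) <- "phase_record"
  runs <- true_runs(outside)
  runs <- runs[runs$end - runs$start + 1 >= persistence_days, , drop = FALSE]
  if (!nrow(runs)) {
    rec$phases <- data.frame(label = "home", start = cen$date[1],
                             end = cen$date[nrow(cen)])
    return(rec)
  }
  dep_i <- runs$start[1]
  rec$departure <- cen$date[dep_i]
  # furthest day, then first day back inside home after it
  d_home <- sqrt(cen$x^2 + cen$y^2) # centred near home for a home-start track
  far_i <- which.max(d_home)
  back <- which(!outside & seq_len(nrow(cen)) > far_i)
  if (length(back)) rec$return_date <- cen$date[back[1]]
  # stops: greedy runs of days within stop_radius of the running centroid
  jmax <- if (length(back)) back[1] - 1 else nrow(cen)
  away <- cen[dep_i:jmax, , drop = FALSE]
  stops <- list()
  i <- 1
  while (i <= nrow(away)) {
    cx <- away$x[i]; cy <- away$y[i]; j <- i
    while (j < nrow(away)) {
      nx <- away$x[j + 1]; ny <- away$y[j + 1]
      if (sqrt((nx - cx)^2 + (ny - cy)^2) > stop_radius_km * 1000) break
      j <- j + 1
      k <- j - i + 1
      cx <- cx + (nx - cx) / k; cy <- cy + (ny - cy) / k
    }
    if (j - i + 1 >= min_stop_days) {
      ctr <- local_lonlat(matrix(c(cx, cy), 1, 2), centre)
      stops[[length(stops) + 1]] <- data.frame(
        start = away$date[i], end = away$date[j],
        duration_days = as.numeric(away$date[j] - away$date[i]) + 1,
        lon = ctr[1, 1], lat = ctr[1, 2])
    }
    i <- j + 1
  }
  if (length(stops)) {
    st <- do.call(rbind, stops)
    st$duration_class <- cluster_durations(st$duration_days, n_clusters, seed)
    rec$stops <- st
  }
  rec$phases <- build_phases(cen$date, rec)
  rec
}

#' Group stop durations into duration classes by 1-D k-means
#'
#' Seeded `stats::kmeans` with 50 random starts; classes are relabelled in
#' ascending order of their mean duration, so class 1 is the shortest-stop
#' cluster.
#'
#' @param durations numeric vector of stop durations (days).
#' @param n_clusters number of classes.
#' @param seed RNG seed.
#' @return integer class per duration (all 1 when there are fewer distinct
#'   durations than classes).
#' @export
cluster_durations <- function(durations, n_clusters = 3, seed = 1) {
  if (length(unique(durations)) < n_clusters)
    return(rep(1L, length(durations)))
  set.seed(seed)
  km <- kmeans(durations, centers = n_clusters, nstart = 50)
  ord <- order(km$centers)
  match(km$cluster, ord)
}

build_phases <- function(dates, rec) {
  ph <- list()
  first <- dates[1]; last <- dates[length(dates)]
  if (is.na(rec$departure))
    return(data.frame(label = "home", start = first, end = last))
  ph[[1]] <- data.frame(label = "home", start = first,
                        end = rec$departure - 1)
  if (nrow(rec$stops)) {
    for (k in seq_len(nrow(rec$stops)))
      ph[[length(ph) + 1]] <- data.frame(
        label = paste0("stop-", k),
        start = rec$stops$start[k], end = rec$stops$end[k])
  }
  if (!is.na(rec$return_date))
    ph[[length(ph) + 1]] <- data.frame(label = "home-return",
                                       start = rec$return_date, end = last)
  out <- do.call(rbind, ph)
  out[order(out$start), ]
}

#' @export
print.phase_record <- function(x, ...) {
  cat("herd", x$herd_id, "\n")
  if (is.na(x$departure)) {
    cat("  no departure detected (resident)\n")
  } else {
    cat("  departure:", format(x$departure),
        " return:", format(x$return_date), "\n")
    cat("  stops:", nrow(x$stops), "\n")
  }
  invisible(x)
}
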