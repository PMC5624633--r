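#' Great-circle distance between two points (haversine, km)
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees; vectors recycle.
#' @return distance in km on a 6371-km sphere.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Split hourly track points into vessel-day tracks
#'
#' Partitions points by vessel and local calendar date (the fishery's
#' single time zone, UTC+8 by default). Days with fewer than
#' `min_points` positions are kept but marked unclassifiable.
#'
#' @param points data frame `vessel_id, timestamp, lat, lon, speed_kn`,
#'   timestamps sorted (POSIXct) within vessel.
#' @param tz_offset_h local-time offset from UTC in hours.
#' @param min_points minimum positions for a day to be classifiable.
#' @return list of `day_track` objects (each a list with `vessel_id`,
#'   `date`, `points`, `classifiable`).
#' @export
split_days <- function(points, tz_offset_h = 8, min_points = 3L) {
  stopifnot(is.data.frame(points))
  ord <- order(points$vessel_id, points$timestamp)
  if (any(ord != seq_len(nrow(points)))) {
    byv <- split(points$timestamp, points$vessel_id)
    if (any(vapply(byv, is.unsorted, logical(1)))) {
      stop("track points must be time-sorted within vessel", call. = FALSE)
    }
    points <- points[ord, ]
  }
  local_date <- as.Date(points$timestamp + tz_offset_h * 3600, tz = "UTC")
  key <- paste(points$vessel_id, local_date)
  idx <- split(seq_len(nrow(points)), key)
  lapply(idx, function(ii) {
    pts <- points[ii, , drop = FALSE]
    structure(list(
      vessel_id = pts$vessel_id[1],
      date = as.Date(pts$timestamp[1] + tz_offset_h * 3600, tz = "UTC"),
      points = pts,
      classifiable = nrow(pts) >= min_points
    ), class = "day_track")
  })
}

#' @export
print.day_track <- function(x, ...) {
  cat(sprintf("<day_track> %s %s: %d points%s\n", x$vessel_id,
              format(x$date), nrow(x$points),
              if (x$classifiable) "" else " (unclassifiable)"))
  invisible(x)
}

#' Thin a day track to one position every `interval_h` hours
#'
#' Keeps the earliest point of the day and, for each successive
#' `interval_h` offset from it, the point nearest in time; no point is
#' selected twice and order is preserved. `interval_h = 1` on hourly data
#' is the identity.
#'
#' @param day a `day_track`.
#' @param interval_h resampling interval, 1--6 h.
#' @return the resampled `day_track`.
#' @export
resample_day <- function(day, interval_h) {
  stopifnot(inherits(day, "day_track"))
  if (!(interval_h %in% 1:6)) stop("interval_h must be in 1..6", call. = FALSE)
  pts <- day$points
  t0 <- pts$timestamp[1]
  off_h <- as.numeric(difftime(pts$timestamp, t0, units = "hours"))
  targets <- seq(0, max(off_h), by = interval_h)
  sel <- unique(vapply(targets, function(tt) which.min(abs(off_h - tt)),
                       integer(1)))
  out <- day
  out$points <- pts[sort(sel), , drop = FALSE]
  out
}

# Forward azimuths of consecutive segments, skipping segments whose
# displacement is below `min_disp_km` (bearings of sub-km displacements
# are GPS jitter, not vessel heading).
segment_azimuths <- function(pts, min_disp_km = 1) {
  n <- nrow(pts)
  if (n < 2L) return(numeric(0))
  p1 <- cbind(pts$lon[-n], pts$lat[-n])
  p2 <- cbind(pts$lon[-1], pts$lat[-1])
  disp <- geosphere::distHaversine(p1, p2, r = 6371000) / 1000
  az <- geosphere::bearing(p1, p2) %% 360
  az[disp >= min_disp_km]
}

#' Speed criterion: any slow instance marks a fishing day
#'
#' A day is a fishing day if at least one recorded speed is at (i.e. at
#' or below) the threshold --- slow speeds signal hook retrieval. Set
#' `comparison = "at_least"` to flip the inequality.
#'
#' @param day a classifiable `day_track`.
#' @param threshold_kn speed threshold in knots.
#' @param comparison `"at_most"` (default) or `"at_least"`.
#' @return `TRUE` for fishing, `FALSE` for non-fishing, `NA` if
#'   unclassifiable (no speeds recorded).
#' @export
classify_speed <- function(day, threshold_kn, comparison = c("at_most", "at_least")) {
  comparison <- match.arg(comparison)
  sp <- day$points$speed_kn
  sp <- sp[!is.na(sp)]
  if (!isTRUE(day$classifiable) || length(sp) == 0L) return(NA)
  if (comparison == "at_most") any(sp <= threshold_kn) else any(sp >= threshold_kn)
}

#' Within-day-distance criterion
#'
#' A day is a fishing day if the cumulative path length (sum of
#' consecutive great-circle segment lengths) is less than the threshold:
#' an operating longliner covers far less ground than one in transit.
#'
#' @param day a `day_track` with at least two points.
#' @param threshold_km path-length threshold in km.
#' @return `TRUE`/`FALSE`, or `NA` if unclassifiable.
#' @export
classify_distance <- function(day, threshold_km) {
  pts <- day$points
  if (!isTRUE(day$classifiable) || nrow(pts) < 2L) return(NA)
  total <- sum(haversine_km(pts$lat[-nrow(pts)], pts$lon[-nrow(pts)],
                            pts$lat[-1], pts$lon[-1]))
  total < threshold_km
}

#' Direction-change criterion
#'
#' Resamples the day at `interval_h`, computes forward azimuths of
#' consecutive segments (ignoring sub-km displacements), folds successive
#' heading changes to \[0, 180\] degrees, and flags a fishing day when the
#' maximum change is at least `angle_deg`: hook retrieval requires a
#' turn-around, whereas a transit is near-straight. `comparison =
#' "at_most"` flips the rule (the literal "change within x degrees"
#' reading) for fidelity experiments.
#'
#' @param day a `day_track`.
#' @param angle_deg heading-change threshold in degrees.
#' @param interval_h resampling interval (1--6 h).
#' @param comparison `"at_least"` (default) or `"at_most"`.
#' @param min_disp_km displacement below which a segment bearing is
#'   treated as noise.
#' @return `TRUE`/`FALSE`, or `NA` if fewer than three resampled points
#'   or fewer than two usable segment bearings.
#' @export
classify_direction <- function(day, angle_deg, interval_h = 1L,
                               comparison = c("at_least", "at_most"),
                               min_disp_km = 1) {
  comparison <- match.arg(comparison)
  if (!isTRUE(day$classifiable)) return(NA)
  rs <- resample_day(day, interval_h)
  if (nrow(rs$points) < 3L) return(NA)
  az <- segment_azimuths(rs$points, min_disp_km)
  if (length(az) < 2L) return(NA)
  changes <- fold_angle(diff(az))
  if (comparison == "at_least") max(changes) >= angle_deg
  else max(changes) <= angle_deg
}

#' Confusion-matrix statistics for a binary fishing-day classifier
#'
#' @param predicted,truth equal-length logical vectors; `NA` predictions
#'   are dropped pairwise.
#' @return object of class `confusion_stats`: TP/FN/FP/TN counts plus
#'   TPR (sensitivity), TNR (specificity), SSS = TPR + TNR and
#'   DSS = |TPR - TNR|.
#' @export
confusion_stats <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  keep <- !is.na(predicted) & !is.na(truth)
  predicted <- predicted[keep]; truth <- truth[keep]
  if (!any(truth) || all(truth)) {
    stop("truth must contain at least one positive and one negative",
         call. = FALSE)
  }
  confusion_from_counts(
    tp = sum(predicted & truth), fn = sum(!predicted & truth),
    fp = sum(predicted & !truth), tn = sum(!predicted & !truth)
  )
}

#' Confusion statistics from the four counts
#'
#' @param tp,fn,fp,tn nonnegative integer counts.
#' @return a `confusion_stats` object (see [confusion_stats()]).
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("undefined rate: no positives or no negatives in truth", call. = FALSE)
  }
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  structure(list(TP = tp, FN = fn, FP = fp, TN = tn,
                 TPR = tpr, TNR = tnr,
                 SSS = tpr + tnr, DSS = abs(tpr - tnr)),
            class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("<confusion_stats> TP %d FN %d FP %d TN %d\n",
              x$TP, x$FN, x$FP, x$TN))
  cat(sprintf("  TPR %.3f TNR %.3f SSS %.3f DSS %.3f\n",
              x$TPR, x$TNR, x$SSS, x$DSS))
  invisible(x)
}

# Per-day summaries that make every grid cell a cheap comparison:
# minimum speed, path length, and max folded heading change per
# resampling interval.
day_summaries <- function(days, intervals = 1:6, min_disp_km = 1) {
  rows <- lapply(days, function(day) {
    pts <- day$points
    sp <- pts$speed_kn[!is.na(pts$speed_kn)]
    path <- if (nrow(pts) >= 2L) {
      sum(haversine_km(pts$lat[-nrow(pts)], pts$lon[-nrow(pts)],
                       pts$lat[-1], pts$lon[-1]))
    } else NA_real_
    turns <- vapply(intervals, function(h) {
      if (!isTRUE(day$classifiable)) return(NA_real_)
      rs <- resample_day(day, h)
      if (nrow(rs$points) < 3L) return(NA_real_)
      az <- segment_azimuths(rs$points, min_disp_km)
      if (length(az) < 2L) return(NA_real_)
      max(fold_angle(diff(az)))
    }, numeric(1))
    c(min_speed = if (length(sp)) min(sp) else NA_real_,
      path_km = path, setNames(turns, paste0("turn_", intervals, "h")))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$vessel_id <- vapply(days, `[[`, character(1), "vessel_id")
  out$date <- as.Date(vapply(days, function(d) as.character(d$date),
                             character(1)))
  out$classifiable <- vapply(days, `[[`, logical(1), "classifiable")
  out
}

#' Grid-search the optimal fishing-day criterion
#'
#' Evaluates every cell of a criterion grid against labelled vessel-days
#' and returns the cell maximizing SSS; cells whose SSS is within
#' `sss_tol` of the maximum are treated as ties and broken by minimum
#' DSS. The full score table is returned for score-surface plots.
#'
#' @param days list of `day_track`s.
#' @param labels data frame `vessel_id, date, is_fishing`.
#' @param approach `"speed"`, `"distance"` or `"direction"`.
#' @param thresholds numeric grid of thresholds (knots, km or degrees);
#'   defaults to the approach's standard grid (speed 1--7 kn by 1,
#'   distance 70--190 km by 10, direction 5--180 degrees by 5).
#' @param intervals_h resampling intervals for the direction approach.
#' @param sss_tol SSS tie tolerance.
#' @return list with `best` (a criterion spec: `approach, threshold,
#'   interval_h, sss, dss`) and `table` (one row per grid cell with
#'   counts and scores).
#' @export
grid_search <- function(days, labels,
                        approach = c("speed", "distance", "direction"),
                        thresholds = NULL, intervals_h = 1:6,
                        sss_tol = 0.01) {
  approach <- match.arg(approach)
  if (is.null(thresholds)) {
    thresholds <- switch(approach,
      speed = 1:7, distance = seq(70, 190, 10), direction = seq(5, 180, 5))
  }
  if (length(thresholds) == 0L) stop("empty grid", call. = FALSE)
  summ <- day_summaries(days, intervals = if (approach == "direction") intervals_h else 1L)
  summ <- merge(summ, labels[, c("vessel_id", "date", "is_fishing")],
                by = c("vessel_id", "date"))
  cells <- if (approach == "direction") {
    expand.grid(threshold = thresholds, interval_h = intervals_h)
  } else {
    data.frame(threshold = thresholds, interval_h = NA_integer_)
  }
  score_one <- function(threshold, interval_h) {
    pred <- switch(approach,
      speed = ifelse(summ$classifiable, summ$min_speed <= threshold, NA),
      distance = ifelse(summ$classifiable, summ$path_km < threshold, NA),
      direction = summ[[paste0("turn_", interval_h, "h")]] >= threshold)
    cs <- try(confusion_stats(pred, summ$is_fishing), silent = TRUE)
    if (inherits(cs, "try-error")) {
      setNames(rep(NA_real_, 8),
               c("TP", "FN", "FP", "TN", "TPR", "TNR", "SSS", "DSS"))
    } else unlist(cs)
  }
  scores <- t(mapply(score_one, cells$threshold, cells$interval_h))
  tab <- cbind(cells, as.data.frame(scores))
  ok <- !is.na(tab$SSS)
  if (!any(ok)) stop("all grid cells degenerate", call. = FALSE)
  best_sss <- max(tab$SSS[ok])
  tied <- ok & tab$SSS >= best_sss - sss_tol
  pick <- which(tied)[order(tab$DSS[tied], -tab$SSS[tied])][1]
  list(
    best = list(approach = approach,
                threshold = tab$threshold[pick],
                interval_h = tab$interval_h[pick],
                sss = tab$SSS[pick], dss = tab$DSS[pick]),
    table = tab
  )
}

#' Apply a fishing-day criterion to vessel-day tracks
#'
#' Dispatches to the matching classifier and returns one flag per
#' vessel-day; unclassifiable days carry `NA` and their count is
#' reported via the `n_unclassifiable` attribute so they can be excluded
#' from effort sums explicitly.
#'
#' @param days list of `day_track`s.
#' @param spec list with `approach`, `threshold`, and (direction only)
#'   `interval_h`, as returned in `grid_search()$best`.
#' @return data frame `vessel_id, date, fishing` with attribute
#'   `n_unclassifiable`.
#' @export
apply_criterion <- function(days, spec) {
  stopifnot(is.list(spec), spec$approach %in% c("speed", "distance", "direction"))
  flags <- vapply(days, function(day) {
    switch(spec$approach,
      speed = classify_speed(day, spec$threshold),
      distance = classify_distance(day, spec$threshold),
      direction = classify_direction(day, spec$threshold,
                                     spec$interval_h %||% 1L))
  }, logical(1))
  out <- data.frame(
    vessel_id = vapply(days, `[[`, character(1), "vessel_id"),
    date = as.Date(vapply(days, function(d) as.character(d$date),
                          character(1))),
    fishing = unname(flags),
    stringsAsFactors = FALSE
  )
  attr(out, "n_unclassifiable") <- sum(is.na(flags))
  out
}
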