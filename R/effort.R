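#' Screen trip records and derive at-sea days
#'
#' At-sea days are the number of distinct local calendar dates
#' intersected by `[depart, return]` (a trip leaving at 09:00 on day 1
#' and returning at 17:00 on day 3 spends 3 days at sea). Screening
#' drops trips with `return <= depart`, durations above `max_days`, and
#' trips overlapping a previous trip of the same vessel; unparseable
#' rows are collected, not fatal.
#'
#' @param trips data frame `vessel_id, port, vessel_class, depart,
#'   return` (POSIXct or parseable character timestamps).
#' @param tz_offset_h local-time offset from UTC in hours.
#' @param max_days screening cap on trip duration in days.
#' @return list with `trips` (screened records plus `at_sea_days`),
#'   `rejects` (dropped rows with a `reject_reason`), and `n_dropped`.
#' @export
trips_to_at_sea_days <- function(trips, tz_offset_h = 8, max_days = 60) {
  parse_ts <- function(x) {
    if (inherits(x, "POSIXct")) return(x)
    as.POSIXct(as.character(x), tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%d"))
  }
  dep <- suppressWarnings(parse_ts(trips$depart))
  ret <- suppressWarnings(parse_ts(trips$return))
  reason <- rep(NA_character_, nrow(trips))
  reason[is.na(dep) | is.na(ret)] <- "unparseable timestamp"
  ok <- is.na(reason)
  bad_order <- ok & ret <= dep
  reason[bad_order] <- "return at or before depart"
  dur_days <- as.numeric(difftime(ret, dep, units = "days"))
  too_long <- is.na(reason) & dur_days > max_days
  reason[too_long] <- sprintf("duration over %g days", max_days)
  # overlapping trips per vessel: keep the earlier-departing one
  keep <- is.na(reason)
  for (v in unique(trips$vessel_id[keep])) {
    ii <- which(keep & trips$vessel_id == v)
    ii <- ii[order(dep[ii])]
    if (length(ii) < 2L) next
    last_ret <- ret[ii[1]]
    for (j in ii[-1]) {
      if (dep[j] < last_ret) {
        reason[j] <- "overlaps previous trip"
        keep[j] <- FALSE
      } else last_ret <- ret[j]
    }
  }
  keep <- is.na(reason)
  d0 <- as.Date(dep + tz_offset_h * 3600, tz = "UTC")
  d1 <- as.Date(ret + tz_offset_h * 3600, tz = "UTC")
  out <- trips[keep, , drop = FALSE]
  out$depart <- dep[keep]
  out$return <- ret[keep]
  out$at_sea_days <- as.integer(d1[keep] - d0[keep]) + 1L
  rejects <- trips[!keep, , drop = FALSE]
  if (nrow(rejects)) rejects$reject_reason <- reason[!keep]
  list(trips = out, rejects = rejects, n_dropped = sum(!keep))
}

#' Zero-intercept fishing-days ~ at-sea-days regressions by fleet segment
#'
#' Fits `fishing_days = slope * at_sea_days` per port x vessel-class
#' group (no at-sea days imply no fishing days, hence zero intercept);
#' the closed form is `slope = sum(xy) / sum(x^2)`. Both R-squared
#' conventions are reported: the uncentered one implied by the
#' zero-intercept model (`1 - SSE / sum(y^2)`, which overstates fit) and
#' the centered one (`1 - SSE / sum((y - mean(y))^2)`).
#'
#' @param pairs data frame `port, vessel_class, at_sea_days,
#'   fishing_days`.
#' @return object of class `effort_model`: data frame with one row per
#'   group (`port, vessel_class, slope, r2_zero_intercept, r2_centered,
#'   n`) plus port-level pooled slopes in attribute `port_slopes`.
#' @export
fit_effort_model <- function(pairs) {
  need <- c("port", "vessel_class", "at_sea_days", "fishing_days")
  stopifnot(all(need %in% names(pairs)))
  grp <- interaction(pairs$port, pairs$vessel_class, drop = TRUE)
  rows <- lapply(levels(grp), function(g) {
    d <- pairs[grp == g, ]
    x <- d$at_sea_days; y <- d$fishing_days
    if (length(x) < 2L || all(x == 0)) {
      warning(sprintf("group %s skipped (n < 2 or all-zero at-sea days)", g))
      return(NULL)
    }
    slope <- sum(x * y) / sum(x^2)
    sse <- sum((y - slope * x)^2)
    data.frame(port = d$port[1], vessel_class = d$vessel_class[1],
               slope = slope,
               r2_zero_intercept = 1 - sse / sum(y^2),
               r2_centered = 1 - sse / sum((y - mean(y))^2),
               n = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no fittable groups", call. = FALSE)
  ports <- unique(pairs$port)
  port_slopes <- vapply(ports, function(p) {
    d <- pairs[pairs$port == p, ]
    sum(d$at_sea_days * d$fishing_days) / sum(d$at_sea_days^2)
  }, numeric(1))
  attr(out, "port_slopes") <- setNames(port_slopes, ports)
  class(out) <- c("effort_model", "data.frame")
  out
}

#' Sequential ANOVA for the fishing-days linear relationship
#'
#' Type-I (sequential) sums of squares for
#' `fishing_days ~ at_sea_days + port + vessel_class`, in that order,
#' testing whether the linear relation and the port and class effects
#' are significant.
#'
#' @param pairs as in [fit_effort_model()].
#' @return the `anova` table of the sequential fit.
#' @export
effort_anova <- function(pairs) {
  for (f in c("port", "vessel_class")) {
    if (length(unique(pairs[[f]])) < 2L) {
      warning(sprintf("factor %s has a single level and is dropped", f))
    }
  }
  terms <- c("at_sea_days",
             if (length(unique(pairs$port)) > 1L) "port",
             if (length(unique(pairs$vessel_class)) > 1L) "vessel_class")
  fml <- stats::reformulate(terms, response = "fishing_days")
  stats::anova(stats::lm(fml, data = pairs))
}

#' Predict fishing days from at-sea days
#'
#' `slope(port, class) * at_sea_days`, kept fractional and clipped to at
#' most the at-sea days. Trips whose (port, class) group is missing from
#' the model fall back to the port-level pooled slope, with a message.
#'
#' @param trips data frame with `port, vessel_class, at_sea_days`.
#' @param model an [fit_effort_model()] result.
#' @return `trips` with a `fishing_days_est` column.
#' @export
predict_fishing_days <- function(trips, model) {
  stopifnot(inherits(model, "effort_model"))
  key <- paste(trips$port, trips$vessel_class)
  mkey <- paste(model$port, model$vessel_class)
  slope <- model$slope[match(key, mkey)]
  missing_grp <- is.na(slope)
  if (any(missing_grp)) {
    ps <- attr(model, "port_slopes")
    slope[missing_grp] <- ps[trips$port[missing_grp]]
    message(sprintf("%d trip(s) used port-level pooled slopes (missing port x class group)",
                    sum(missing_grp)))
    if (any(is.na(slope))) {
      stop("no slope available for some trips' ports", call. = FALSE)
    }
  }
  est <- slope * trips$at_sea_days
  trips$fishing_days_est <- pmin(est, trips$at_sea_days)
  trips
}
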