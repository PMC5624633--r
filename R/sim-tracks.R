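#' Generate synthetic hourly vessel tracks with fishing-day labels
#'
#' Produces 24 hourly positions per vessel-day, one of three day types:
#'
#' * *fishing*: a morning hook-deployment leg at operation speed on a
#'   base heading, a mid-day turn, and a long hook-retrieval leg near the
#'   reciprocal heading at retrieval speed (<= ~3 kn), book-ended by the
#'   tail of the previous night's retrieval;
#' * *transit*: a near-constant-heading leg at cruise speed, optionally
#'   containing a few slow drift hours;
#' * *port* (non-fishing): a short moving leg plus hours moored with only
#'   GPS jitter, emulating arrival/departure days.
#'
#' Timestamps are hourly in UTC; local days run on UTC+8. Ground-truth
#' labels (`is_fishing`) are returned alongside the points.
#'
#' @param cfg a [sim_config()].
#' @return list with `points` (data frame `vessel_id, timestamp, lat,
#'   lon, speed_kn`) and `labels` (data frame `vessel_id, date,
#'   is_fishing, day_type`).
#' @export
gen_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 202L, {
    dates <- seq(as.Date("2010-05-01"), by = "day", length.out = cfg$n_days)
    out_pts <- vector("list", cfg$n_vessels * cfg$n_days)
    out_lab <- vector("list", cfg$n_vessels * cfg$n_days)
    i <- 0L
    for (v in seq_len(cfg$n_vessels)) {
      vid <- sprintf("V%03d", v)
      for (d in seq_len(cfg$n_days)) {
        i <- i + 1L
        fishing <- runif(1) < cfg$fishing_day_prob
        type <- if (fishing) "fishing" else {
          if (runif(1) < cfg$port_day_frac) "port" else "transit"
        }
        start <- c(runif(1, 120.5, 123.5), runif(1, 21.5, 25.5)) # lon, lat
        trk <- sim_day_track(type, cfg, start)
        ts_utc <- as.POSIXct(dates[d], tz = "UTC") +
          (0:23) * 3600 - 8 * 3600
        out_pts[[i]] <- data.frame(
          vessel_id = vid, timestamp = ts_utc,
          lat = trk$lat, lon = trk$lon, speed_kn = trk$speed,
          stringsAsFactors = FALSE
        )
        out_lab[[i]] <- data.frame(
          vessel_id = vid, date = dates[d], is_fishing = fishing,
          day_type = type, stringsAsFactors = FALSE
        )
      }
    }
    list(points = do.call(rbind, out_pts),
         labels = do.call(rbind, out_lab))
  })
}

# One 24-h day of hourly headings/speeds for a given day type, walked
# into positions on a 6371-km sphere. `start` is c(lon, lat).
sim_day_track <- function(type, cfg, start) {
  KN2M <- 1852 # metres per nautical mile, so knots x h -> metres
  hd <- runif(1, 0, 360)
  if (type == "fishing") {
    retr <- function(n) pmax(1.6, pmin(3.2, rnorm(n, cfg$retrieval_speed_kn, 0.3)))
    heading <- c(rep(hd + 180, 3) + rnorm(3, 0, 6),     # previous retrieval tail
                 rep(hd, 5) + rnorm(5, 0, 3),           # deployment
                 rep(hd, 4) + rnorm(4, 0, 5),           # soak drift along line
                 rep(hd + 180, 12) + rnorm(12, 0, 6))   # retrieval
    speed <- c(retr(3),
               rnorm(5, cfg$operation_speed_kn, 0.3),
               runif(4, 1.8, 3.0),
               retr(12))
  } else if (type == "transit") {
    heading <- hd + cumsum(rnorm(24, 0, 1.5))
    if (runif(1) < cfg$course_change_prob) { # mid-route waypoint: a moderate course change
      wp <- sample(6:18, 1)
      heading[wp:24] <- heading[wp:24] + sample(c(-1, 1), 1) * runif(1, 25, 70)
    }
    speed <- rnorm(24, cfg$transit_speed_kn, 0.4)
    if (runif(1) < cfg$slow_hour_prob) {
      n_drift <- sample(1:3, 1)
      at <- sample(24, n_drift)
      speed[at] <- runif(n_drift, 0.2, 3.5)
    }
  } else { # port arrival/departure day
    n_move <- sample(5:8, 1)
    mv_head <- rep(hd, n_move) + rnorm(n_move, 0, 1.5)
    mv_speed <- rnorm(n_move, cfg$transit_speed_kn - 0.5, 0.4)
    n_moor <- 24 - n_move
    moor_speed <- runif(n_moor, 0, 0.4)
    if (runif(1) < 0.5) { # arrival: steam in, then moor
      heading <- c(mv_head, rep(hd, n_moor))
      speed <- c(mv_speed, moor_speed)
      moored <- c(rep(FALSE, n_move), rep(TRUE, n_moor))
    } else {              # departure: moored, then steam out
      heading <- c(rep(hd, n_moor), mv_head)
      speed <- c(moor_speed, mv_speed)
      moored <- c(rep(TRUE, n_moor), rep(FALSE, n_move))
    }
  }
  speed <- pmax(speed, 0)
  lon <- lat <- numeric(24)
  lon[1] <- start[1]; lat[1] <- start[2]
  pos <- start
  for (h in 1:23) {
    step_m <- speed[h] * KN2M
    if (type == "port" && moored[h]) {
      # moored: position held, ~30 m GPS jitter
      pos_h <- pos + rnorm(2, 0, 30 / 111320)
      step_m <- 0
    } else {
      pos_h <- as.numeric(
        geosphere::destPoint(pos, heading[h] %% 360, step_m, r = 6371000)
      )
      pos <- pos_h
    }
    lon[h + 1] <- pos_h[1]; lat[h + 1] <- pos_h[2]
  }
  list(lon = lon, lat = lat, speed = round(speed, 2))
}
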