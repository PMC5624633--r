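# Independent oracles used across tests; deliberately brute-force and
# separate from the package's own code paths.

# Two-sample KS D by a double loop over every observed jump point.
brute_force_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  d <- 0
  for (x in pts) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# Truncated-lognormal mean by numerical quadrature.
quadrature_trunc_lnorm_mean <- function(meanlog, sdlog, lo, hi) {
  num <- stats::integrate(function(x) x * stats::dlnorm(x, meanlog, sdlog),
                          lo, hi, rel.tol = 1e-10)$value
  den <- stats::plnorm(hi, meanlog, sdlog) - stats::plnorm(lo, meanlog, sdlog)
  num / den
}

# Path length by summed haversine, written out from the formula rather
# than through the package helper.
raw_haversine_path_km <- function(lat, lon) {
  R <- 6371
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(lat)
  a <- sin((phi[-1] - phi[-n]) / 2)^2 +
    cos(phi[-n]) * cos(phi[-1]) * sin((lam[-1] - lam[-n]) / 2)^2
  sum(2 * R * asin(pmin(1, sqrt(a))))
}

# Small labelled track fixture: a hand-built day_track at given hourly
# lat/lon/speeds (UTC+8 local day).
make_day <- function(lat, lon, speed, vessel = "V1", date = "2010-05-01") {
  n <- length(lat)
  ts <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
    (seq_len(n) - 1) * 3600 - 8 * 3600
  pts <- data.frame(vessel_id = vessel, timestamp = ts,
                    lat = lat, lon = lon, speed_kn = speed,
                    stringsAsFactors = FALSE)
  structure(list(vessel_id = vessel, date = as.Date(date), points = pts,
                 classifiable = n >= 3),
            class = "day_track")
}

# Straight-line track northwards at a given speed (knots), hourly steps.
straight_day <- function(hours = 24, speed_kn = 9, lat0 = 22, lon0 = 121) {
  step_deg <- speed_kn * 1.852 / 111.19 # km per hour / km per degree
  make_day(lat = lat0 + (0:(hours - 1)) * step_deg,
           lon = rep(lon0, hours),
           speed = rep(speed_kn, hours))
}
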