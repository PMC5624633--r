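#' Generate synthetic port entry/exit trip records
#'
#' Each trip gets a port, a vessel class drawn from the classes present
#' at that port, an at-sea duration of 3--20 calendar days, and a true
#' fishing-day total `slope(port, class) * at_sea_days` plus
#' truncated-normal noise, clipped to `[0, at_sea_days]`. Departure and
#' return timestamps are laid out so that the number of local calendar
#' dates intersected equals the at-sea days.
#'
#' @param cfg a [sim_config()].
#' @return list with `trips` (data frame `trip_id, vessel_id, port,
#'   vessel_class, depart, return`) and `truth` (adds `at_sea_days`,
#'   `fishing_days`).
#' @export
gen_trips <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  es <- cfg$effort_slopes
  with_seed(cfg$seed + 303L, {
    n <- cfg$n_trips
    seg <- sample(nrow(es), n, replace = TRUE)
    port <- es$port[seg]
    vclass <- es$vessel_class[seg]
    slope <- es$slope[seg]
    vessel <- sprintf("V%03d", sample(cfg$n_vessels, n, replace = TRUE))
    at_sea <- sample(3:20, n, replace = TRUE)
    start <- as.Date("2007-05-01") + sample(0:1600, n, replace = TRUE)
    depart <- as.POSIXct(start, tz = "UTC") + 9 * 3600 - 8 * 3600
    ret <- as.POSIXct(start + at_sea - 1, tz = "UTC") + 17 * 3600 - 8 * 3600
    fishing <- slope * at_sea + rnorm(n, 0, cfg$trip_noise_sd)
    fishing <- pmin(pmax(fishing, 0), at_sea)
    trips <- data.frame(
      trip_id = sprintf("T%05d", seq_len(n)),
      vessel_id = vessel, port = port, vessel_class = vclass,
      depart = depart, return = ret, stringsAsFactors = FALSE
    )
    truth <- cbind(trips, at_sea_days = at_sea, fishing_days = fishing)
    list(trips = trips, truth = truth)
  })
}

#' Generate synthetic trip-level CPUE records with known effects
#'
#' A delta-lognormal generative process: each trip is a zero-catch trip
#' with probability `p_zero(covariates)`; positive trips have catch rate
#' `year x month x area x class effect x lognormal(0, pcm_logsd)` error.
#' Catch is carried as `cpue * fishing_days` and may be fractional --- a
#' continuous catch-rate process does not produce integers, and keeping
#' it exact preserves the known-effect structure for recovery tests.
#'
#' @param cfg a [sim_config()]; every level of `year_effects`,
#'   `month_effects`, `area_effects`, `class_effects` must be defined.
#'   `year_effects` may be a data frame `year, area, effect` for
#'   area-specific year trends, and `pcm_logsd` a named vector by area
#'   for area-specific error variances.
#' @return data frame of CPUE records: `trip_id, year, month, area,
#'   vessel_class, fishing_days, catch_n, cpue, true_mean` where
#'   `true_mean` is the noise-free effect product.
#' @export
gen_cpue <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 404L, {
    n <- cfg$n_trips
    pick <- function(levels) { # robust to single-level vectors
      levels[sample.int(length(levels), n, replace = TRUE)]
    }
    covars <- data.frame(
      year = pick(year_levels(cfg$year_effects)),
      month = as.integer(pick(names(cfg$month_effects))),
      area = pick(names(cfg$area_effects)),
      vessel_class = pick(names(cfg$class_effects)),
      stringsAsFactors = FALSE
    )
    ye <- year_area_effect(cfg$year_effects, covars)
    mu <- ye *
      cfg$month_effects[as.character(covars$month)] *
      cfg$area_effects[covars$area] *
      cfg$class_effects[covars$vessel_class]
    if (any(is.na(mu))) stop_config("effect undefined for some covariate level")
    pz <- resolve_p_zero(cfg$p_zero, covars)
    zero <- runif(n) < pz
    sdlog <- if (!is.null(names(cfg$pcm_logsd))) {
      unname(cfg$pcm_logsd[covars$area]) # area-specific error SD
    } else rep(cfg$pcm_logsd, n)
    if (any(is.na(sdlog))) stop_config("pcm_logsd undefined for some area")
    err <- ifelse(sdlog > 0, rlnorm(n, 0, sdlog), 1)
    cpue <- ifelse(zero, 0, as.numeric(mu) * err)
    fishing_days <- pmin(pmax(rlnorm(n, log(8), 0.35), 2), 25)
    data.frame(
      trip_id = sprintf("T%05d", seq_len(n)),
      year = as.integer(covars$year), month = covars$month,
      area = covars$area, vessel_class = covars$vessel_class,
      fishing_days = fishing_days,
      catch_n = cpue * fishing_days,
      cpue = cpue,
      true_mean = as.numeric(mu),
      stringsAsFactors = FALSE
    )
  })
}
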