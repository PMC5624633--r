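#' Configuration for the synthetic longline-fishery generator
#'
#' Bundles every parameter of the synthetic data generators
#' ([gen_landings()], [gen_tracks()], [gen_trips()], [gen_cpue()]) into a
#' validated list. The defaults describe a small offshore bluefin longline
#' fleet: per-fish weights are lognormal within the 80--350 kg market
#' range, fishing days show the deployment--turn--retrieval track
#' geometry, trip fishing days are a near-proportional fraction of at-sea
#' days by port and vessel class, and trip-level CPUE follows a
#' delta-lognormal process with multiplicative year/month/area effects.
#'
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param wpf_logmean,wpf_logsd log-scale mean and SD of the
#'   weight-per-fish (WPF) distribution, in log-kg.
#' @param wpf_min,wpf_max truncation bounds of the WPF distribution (kg).
#' @param count_p success probability of the truncated-geometric fish
#'   count per landing record (mass decreasing from k = 1).
#' @param max_count largest fish count per landing record.
#' @param mask_frac fraction of landing records whose fish count is
#'   masked to missing.
#' @param n_vessels number of vessels.
#' @param n_days tracked days per vessel.
#' @param n_trips number of trips (for [gen_trips()] and [gen_cpue()]).
#' @param fishing_day_prob probability that a tracked vessel-day is a
#'   fishing day.
#' @param port_day_frac among non-fishing days, the fraction that are
#'   port-arrival/departure days (short moving leg, rest moored) rather
#'   than full transit days.
#' @param slow_hour_prob probability that a transit day contains 1--3
#'   slow drift hours.
#' @param course_change_prob probability that a transit day contains one
#'   mid-route waypoint course change of 25--70 degrees.
#' @param transit_speed_kn,operation_speed_kn,retrieval_speed_kn cruise,
#'   hook-deployment and hook-retrieval speeds (knots).
#' @param effort_slopes data frame `port, vessel_class, slope` giving the
#'   true fishing/at-sea ratio per fleet segment, each slope in (0, 1].
#' @param trip_noise_sd SD (days) of the truncated-normal noise on trip
#'   fishing days.
#' @param year_effects,month_effects,area_effects,class_effects named
#'   numeric vectors of multiplicative effects on expected CPUE. Months
#'   are restricted to the May--July season, areas to north/south of the
#'   fishing-ground split, classes to CT1--CT4.
#' @param p_zero probability of a zero-catch trip: a single number, a
#'   named vector indexed by year, or a data frame with covariate
#'   columns (any of `year, month, area, vessel_class`) plus `p_zero`.
#' @param pcm_logsd log-scale SD of the positive catch-rate error.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       wpf_logmean = log(190), wpf_logsd = 0.25,
                       wpf_min = 80, wpf_max = 350,
                       count_p = 0.45, max_count = 50L,
                       mask_frac = 0.3,
                       n_vessels = 20L, n_days = 25L, n_trips = 2000L,
                       fishing_day_prob = 0.6,
                       port_day_frac = 0.5,
                       slow_hour_prob = 0.5,
                       course_change_prob = 0.3,
                       transit_speed_kn = 9, operation_speed_kn = 5.5,
                       retrieval_speed_kn = 2.2,
                       effort_slopes = default_effort_slopes(),
                       trip_noise_sd = 0.5,
                       year_effects = default_year_effects(),
                       month_effects = c(`5` = 1, `6` = 1.3, `7` = 0.7),
                       area_effects = c(north = 0.8, south = 1),
                       class_effects = c(CT1 = 1, CT2 = 1, CT3 = 1, CT4 = 1),
                       p_zero = 0.35,
                       pcm_logsd = 0.6) {
  cfg <- list(
    seed = as.integer(seed),
    wpf_logmean = wpf_logmean, wpf_logsd = wpf_logsd,
    wpf_min = wpf_min, wpf_max = wpf_max,
    count_p = count_p, max_count = as.integer(max_count),
    mask_frac = mask_frac,
    n_vessels = as.integer(n_vessels), n_days = as.integer(n_days),
    n_trips = as.integer(n_trips),
    fishing_day_prob = fishing_day_prob,
    port_day_frac = port_day_frac,
    slow_hour_prob = slow_hour_prob,
    course_change_prob = course_change_prob,
    transit_speed_kn = transit_speed_kn,
    operation_speed_kn = operation_speed_kn,
    retrieval_speed_kn = retrieval_speed_kn,
    effort_slopes = effort_slopes,
    trip_noise_sd = trip_noise_sd,
    year_effects = year_effects,
    month_effects = month_effects,
    area_effects = area_effects,
    class_effects = class_effects,
    p_zero = p_zero,
    pcm_logsd = pcm_logsd
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d vessels x %d days | %d trips\n",
              x$seed, x$n_vessels, x$n_days, x$n_trips))
  cat(sprintf("  WPF lognormal(%.3f, %.3f) on [%g, %g] kg\n",
              x$wpf_logmean, x$wpf_logsd, x$wpf_min, x$wpf_max))
  cat(sprintf("  %d years x months {%s} x areas {%s}\n",
              length(x$year_effects),
              paste(names(x$month_effects), collapse = ","),
              paste(names(x$area_effects), collapse = ",")))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  if (cfg$wpf_min >= cfg$wpf_max) {
    stop_config("wpf_min (%g) must be below wpf_max (%g)",
                cfg$wpf_min, cfg$wpf_max)
  }
  probs <- c(mask_frac = cfg$mask_frac,
             fishing_day_prob = cfg$fishing_day_prob,
             port_day_frac = cfg$port_day_frac,
             slow_hour_prob = cfg$slow_hour_prob,
             course_change_prob = cfg$course_change_prob,
             count_p = cfg$count_p)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop_config("probabilities outside [0,1]: %s",
                paste(names(probs)[bad], collapse = ", "))
  }
  es <- cfg$effort_slopes
  if (!is.data.frame(es) ||
      !all(c("port", "vessel_class", "slope") %in% names(es))) {
    stop_config("effort_slopes must be a data frame with columns port, vessel_class, slope")
  }
  if (any(es$slope <= 0 | es$slope > 1)) {
    stop_config("effort slopes must lie in (0, 1]")
  }
  for (nm in c("month_effects", "area_effects", "class_effects")) {
    v <- cfg[[nm]]
    if (is.null(names(v)) || any(!is.finite(v)) || any(v < 0)) {
      stop_config("%s must be a named, nonnegative numeric vector", nm)
    }
  }
  ye <- cfg$year_effects
  if (is.data.frame(ye)) {
    if (!all(c("year", "area", "effect") %in% names(ye)) ||
        any(!is.finite(ye$effect)) || any(ye$effect < 0)) {
      stop_config("year_effects data frame needs year, area and nonnegative effect columns")
    }
  } else if (is.null(names(ye)) || any(!is.finite(ye)) || any(ye < 0)) {
    stop_config("year_effects must be a named, nonnegative numeric vector")
  }
  if (any(cfg$pcm_logsd < 0)) stop_config("pcm_logsd must be nonnegative")
  pz <- cfg$p_zero
  pz_vals <- if (is.data.frame(pz)) pz$p_zero else pz
  if (any(pz_vals < 0 | pz_vals > 1)) {
    stop_config("p_zero values must lie in [0,1]")
  }
  cfg
}

#' Default fishing/at-sea effort ratios by port and vessel class
#'
#' One slope per fleet segment of a three-port, four-class offshore
#' longline fleet (the northern port hosts no CT1 vessels). Values are in
#' the 0.69--0.83 range typical of offshore longliners that spend roughly
#' two of every ten at-sea days in transit.
#'
#' @return data frame with columns `port`, `vessel_class`, `slope`.
#' @export
default_effort_slopes <- function() {
  data.frame(
    port = rep(c("Suao", "Singang", "Tungkang"), times = c(3, 4, 4)),
    vessel_class = c("CT2", "CT3", "CT4",
                     "CT1", "CT2", "CT3", "CT4",
                     "CT1", "CT2", "CT3", "CT4"),
    slope = c(0.828, 0.824, 0.797,
              0.818, 0.816, 0.831, 0.791,
              0.750, 0.810, 0.752, 0.693),
    stringsAsFactors = FALSE
  )
}

#' Default multiplicative year effects (a declining series)
#'
#' Eight years of a roughly halving relative-abundance trend, mirroring a
#' stock in decline over the simulated period.
#'
#' @return named numeric vector of year effects.
#' @export
default_year_effects <- function() {
  setNames(c(1.00, 0.92, 0.80, 0.74, 0.65, 0.58, 0.50, 0.45),
           as.character(2001:2008))
}

# Resolve p_zero for a covariate frame: scalar, year-named vector, or a
# data frame keyed on any subset of the covariates.
resolve_p_zero <- function(p_zero, covars) {
  n <- nrow(covars)
  if (is.data.frame(p_zero)) {
    keys <- intersect(c("year", "month", "area", "vessel_class"),
                      names(p_zero))
    if (length(keys) == 0L) {
      stop_config("p_zero data frame needs at least one covariate column")
    }
    merged <- merge(cbind(covars, .row = seq_len(n)), p_zero,
                    by = keys, all.x = TRUE, sort = FALSE)
    merged <- merged[order(merged$.row), ]
    if (any(is.na(merged$p_zero))) {
      stop_config("p_zero undefined for some covariate combinations")
    }
    return(merged$p_zero)
  }
  if (length(p_zero) == 1L && is.null(names(p_zero))) {
    return(rep(p_zero, n))
  }
  out <- unname(p_zero[as.character(covars$year)])
  if (any(is.na(out))) {
    stop_config("p_zero missing for years: %s",
                paste(setdiff(unique(covars$year), names(p_zero)),
                      collapse = ", "))
  }
  out
}

# Year-effect levels and per-record lookup, supporting either a named
# vector (shared trend) or a (year, area, effect) frame (area-specific
# trends).
year_levels <- function(year_effects) {
  if (is.data.frame(year_effects)) unique(as.character(year_effects$year))
  else names(year_effects)
}

year_area_effect <- function(year_effects, covars) {
  if (!is.data.frame(year_effects)) {
    return(unname(year_effects[covars$year]))
  }
  key <- paste(covars$year, covars$area)
  m <- match(key, paste(year_effects$year, year_effects$area))
  if (anyNA(m)) stop_config("year_effects undefined for some year x area")
  year_effects$effect[m]
}
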