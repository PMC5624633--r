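#' Assign records to the northern or southern fishing ground
#'
#' The two grounds are split at 24.3 deg N. Records with a latitude are
#' assigned directly (>= cutoff is north); records without one (early
#' years with no geolocation) are assigned by departure port: the
#' northern ground is fished by vessels leaving Suao, the southern by
#' vessels leaving Singang and Tungkang.
#'
#' @param lat numeric latitudes (may contain `NA`).
#' @param port character ports, used where `lat` is missing.
#' @param cutoff_deg latitude split, default 24.3.
#' @return character vector `"north"`/`"south"`.
#' @export
assign_area <- function(lat = NULL, port = NULL, cutoff_deg = 24.3) {
  n <- max(length(lat), length(port))
  if (n == 0L) stop("need latitude or port", call. = FALSE)
  if (is.null(lat)) lat <- rep(NA_real_, n)
  if (is.null(port)) port <- rep(NA_character_, n)
  out <- ifelse(!is.na(lat), ifelse(lat >= cutoff_deg, "north", "south"),
                NA_character_)
  need_port <- is.na(out)
  if (any(need_port)) {
    p <- port[need_port]
    if (any(is.na(p))) {
      stop("records with neither latitude nor port cannot be assigned",
           call. = FALSE)
    }
    out[need_port] <- ifelse(p == "Suao", "north", "south")
  }
  out
}

#' Aggregate catch events to trip-level CPUE records
#'
#' Sums catch over events per trip, joins trip effort, restricts to the
#' fishing season months, and drops trips of unregistered vessels;
#' exclusion counts are attached as attributes and orphan events (no
#' matching trip) are returned in a rejects table.
#'
#' @param events data frame `trip_id` plus optional `n_fish` (defaults
#'   to one fish per event).
#' @param effort data frame with `trip_id, year, month, area,
#'   vessel_class, fishing_days` and optional logical `registered`.
#' @param months months retained (default May--July).
#' @return data frame of CPUE records (`trip_id, year, month, area,
#'   vessel_class, fishing_days, catch_n, cpue`), with attributes
#'   `rejects` (orphan events) and `n_excluded` (named counts).
#' @export
aggregate_trips <- function(events, effort, months = c(5, 6, 7)) {
  stopifnot(all(c("trip_id", "fishing_days") %in% names(effort)))
  if (any(effort$fishing_days <= 0)) {
    stop("trip fishing_days must be positive", call. = FALSE)
  }
  if (!"n_fish" %in% names(events)) events$n_fish <- 1L
  orphan <- !(events$trip_id %in% effort$trip_id)
  catch <- stats::aggregate(n_fish ~ trip_id, data = events[!orphan, ], sum)
  out <- merge(effort, catch, by = "trip_id", all.x = TRUE)
  out$catch_n <- ifelse(is.na(out$n_fish), 0, out$n_fish)
  out$n_fish <- NULL
  out_of_season <- !(out$month %in% months)
  unregistered <- if ("registered" %in% names(out)) !out$registered else rep(FALSE, nrow(out))
  keep <- !out_of_season & !unregistered
  res <- out[keep, , drop = FALSE]
  res$cpue <- res$catch_n / res$fishing_days
  attr(res, "rejects") <- events[orphan, , drop = FALSE]
  attr(res, "n_excluded") <- c(out_of_season = sum(out_of_season),
                               unregistered = sum(unregistered),
                               orphan_events = sum(orphan))
  res
}

# Factor-coded modelling frame with the delta-model response columns.
prep_records <- function(records) {
  d <- records
  d$year <- factor(d$year)
  d$month <- factor(d$month)
  d$vessel_class <- factor(d$vessel_class)
  if ("area" %in% names(d)) d$area <- factor(d$area)
  d$positive <- d$catch_n > 0
  d$log_cpue <- ifelse(d$positive, log(d$catch_n / d$fishing_days), NA_real_)
  d
}

delta_formula <- function(response, fixed, random) {
  rhs <- c(fixed, if (length(random)) sprintf("(1 | %s)", random))
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit one component of the delta-lognormal model
#'
#' The zero-proportion model (`"ZPM"`) is a logit-link binomial model on
#' the positive-catch indicator over all records; the positive-catch
#' model (`"PCM"`) is a linear model on log CPUE over positive records.
#' Random terms (year-by-categorical interactions, independent normal
#' deviates with a common variance) switch the fit to a mixed model via
#' lme4; fixed-only specifications use glm/lm. Fits are by maximum
#' likelihood so AIC/BIC are comparable; `reml = TRUE` refits a final
#' PCM by restricted likelihood.
#'
#' @param records CPUE records (see [aggregate_trips()] / [gen_cpue()]).
#' @param component `"ZPM"` or `"PCM"`.
#' @param fixed character vector of fixed terms; must include `"year"`.
#' @param random character vector of random interaction terms, e.g.
#'   `"year:month"`.
#' @param reml use REML for a mixed PCM (final fits only).
#' @return object of class `delta_fit`: list with `component`, `fixed`,
#'   `random`, `fit`, `aic`, `bic`, `converged`, `sigma2` (PCM residual
#'   variance), `n`, and the modelling frame `data`.
#' @export
fit_delta_component <- function(records, component = c("ZPM", "PCM"),
                                fixed = "year", random = character(0),
                                reml = FALSE) {
  component <- match.arg(component)
  if (!"year" %in% fixed) stop("year must be a fixed term", call. = FALSE)
  d <- prep_records(records)
  if (nlevels(d$year) < 2L) {
    stop("need at least two year levels to estimate a year effect",
         call. = FALSE)
  }
  if (component == "PCM") {
    pos_years <- unique(as.character(d$year[d$positive]))
    missing_years <- setdiff(levels(d$year), pos_years)
    if (length(missing_years)) {
      stop(sprintf("PCM year effect undefined: no positive catches in year(s) %s",
                   paste(missing_years, collapse = ", ")), call. = FALSE)
    }
    d <- d[d$positive, , drop = FALSE]
    response <- "log_cpue"
  } else {
    response <- "positive"
  }
  fml <- delta_formula(response, fixed, random)
  msgs <- character(0)
  fit <- withCallingHandlers(
    {
      if (length(random)) {
        if (component == "ZPM") {
          lme4::glmer(fml, data = d, family = stats::binomial())
        } else {
          lme4::lmer(fml, data = d, REML = reml)
        }
      } else {
        if (component == "ZPM") {
          stats::glm(fml, data = d, family = stats::binomial())
        } else {
          stats::lm(fml, data = d)
        }
      }
    },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  converged <- TRUE
  if (inherits(fit, "merMod")) {
    cc <- fit@optinfo$conv$lme4
    converged <- is.null(cc$code) || cc$code == 0
    if (any(grepl("failed to converge", msgs))) converged <- FALSE
  } else if (inherits(fit, "glm")) {
    converged <- fit$converged
  }
  sigma2 <- if (component == "PCM") stats::sigma(fit)^2 else NA_real_
  structure(list(component = component, fixed = fixed, random = random,
                 formula = fml, fit = fit,
                 aic = stats::AIC(fit), bic = stats::BIC(fit),
                 converged = converged, warnings = msgs,
                 sigma2 = sigma2, n = nrow(d), data = d),
            class = "delta_fit")
}

#' @export
print.delta_fit <- function(x, ...) {
  cat(sprintf("<delta_fit %s> %s | n %d | AIC %.1f BIC %.1f%s\n",
              x$component, deparse(x$formula), x$n, x$aic, x$bic,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Fit both delta-lognormal components
#'
#' @param records CPUE records.
#' @param spec_zpm,spec_pcm lists with `fixed` and `random` term sets
#'   (see [fit_delta_component()]).
#' @param reml_pcm refit the PCM by REML.
#' @return list with `zpm` and `pcm` delta fits.
#' @export
fit_delta_models <- function(records,
                             spec_zpm = list(fixed = c("year", "month"),
                                             random = character(0)),
                             spec_pcm = spec_zpm,
                             reml_pcm = FALSE) {
  list(
    zpm = fit_delta_component(records, "ZPM", spec_zpm$fixed,
                              spec_zpm$random %||% character(0)),
    pcm = fit_delta_component(records, "PCM", spec_pcm$fixed,
                              spec_pcm$random %||% character(0),
                              reml = reml_pcm)
  )
}

#' Stepwise AIC/BIC selection for one delta component
#'
#' Backward elimination over the fixed main effects starting from the
#' full main-effects model (year is never removed), then forward
#' addition over the candidate random year-interactions; at each step
#' the move is kept only if it lowers the criterion. Candidates that
#' error out or fail to converge are skipped with a message.
#'
#' @param records CPUE records.
#' @param component `"ZPM"` or `"PCM"`.
#' @param criterion `"AIC"` or `"BIC"`.
#' @param candidates_fixed removable fixed mains (year is always kept).
#' @param candidates_random addable random interaction terms.
#' @return the selected `delta_fit` (its `fixed`/`random`/`aic`/`bic`
#'   describe the chosen specification).
#' @export
stepwise_select <- function(records, component = c("ZPM", "PCM"),
                            criterion = c("AIC", "BIC"),
                            candidates_fixed = c("month", "vessel_class"),
                            candidates_random = c("year:month",
                                                  "year:vessel_class")) {
  component <- match.arg(component)
  criterion <- match.arg(criterion)
  crit <- function(f) if (criterion == "AIC") f$aic else f$bic
  try_fit <- function(fixed, random) {
    f <- try(fit_delta_component(records, component, fixed, random),
             silent = TRUE)
    if (inherits(f, "try-error")) {
      message(sprintf("candidate {%s | %s} failed: %s",
                      paste(fixed, collapse = "+"),
                      paste(random, collapse = "+"),
                      attr(f, "condition")$message))
      return(NULL)
    }
    if (!f$converged) {
      message(sprintf("candidate {%s | %s} did not converge; skipped",
                      paste(fixed, collapse = "+"),
                      paste(random, collapse = "+")))
      return(NULL)
    }
    f
  }
  current <- try_fit(c("year", candidates_fixed), character(0))
  if (is.null(current)) {
    # fall back to year-only before giving up
    current <- try_fit("year", character(0))
    if (is.null(current)) stop("no convergent candidate model", call. = FALSE)
  }
  repeat { # backward over fixed mains
    removable <- setdiff(current$fixed, "year")
    if (!length(removable)) break
    trials <- lapply(removable, function(tm) {
      try_fit(setdiff(current$fixed, tm), current$random)
    })
    scores <- vapply(trials, function(f) if (is.null(f)) Inf else crit(f),
                     numeric(1))
    if (min(scores) < crit(current)) {
      current <- trials[[which.min(scores)]]
    } else break
  }
  repeat { # forward over random interactions
    addable <- setdiff(candidates_random, current$random)
    # a random interaction only makes sense if its categorical main
    # effect is still in the model frame's candidate set
    addable <- addable[vapply(addable, function(tm) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      all(parts %in% c("year", current$fixed))
    }, logical(1))]
    if (!length(addable)) break
    trials <- lapply(addable, function(tm) {
      try_fit(current$fixed, c(current$random, tm))
    })
    scores <- vapply(trials, function(f) if (is.null(f)) Inf else crit(f),
                     numeric(1))
    if (min(scores) < crit(current)) {
      current <- trials[[which.min(scores)]]
    } else break
  }
  current
}

#' Observation-weighted least-squares means of the year effect
#'
#' Per-year marginal predictions averaged over the other model factors
#' with weights proportional to the observation counts of those factor
#' levels (the same margins for every year, so the index is comparable
#' across years). Estimates are on the link scale: log CPUE for the
#' PCM, logit probability for the ZPM.
#'
#' @param fit a `delta_fit`.
#' @param weights emmeans weighting scheme; `"proportional"` implements
#'   the observation-count weighting, `"equal"` gives unweighted means.
#' @return data frame `year, estimate, se` (link scale).
#' @export
lsmeans_year <- function(fit, weights = "proportional") {
  stopifnot(inherits(fit, "delta_fit"))
  if (!fit$converged) stop("model did not converge", call. = FALSE)
  em <- emmeans::emmeans(fit$fit, "year", weights = weights,
                         data = fit$data, lmer.df = "asymptotic")
  s <- summary(em)
  data.frame(year = as.character(s$year),
             estimate = s$emmean, se = s$SE,
             stringsAsFactors = FALSE)
}

#' Bias-corrected standardized index from the two delta components
#'
#' The annual index is the product of the ZPM probability of a positive
#' catch and the lognormal bias-corrected back-transform of the PCM
#' year LSmean: `index_y = p_pos_y * exp(mu_y + sigma2_y / 2)`. The
#' relative index is scaled to its series mean. Confidence limits use a
#' normal approximation on the log scale, combining the LSmean variance
#' with the binomial component by the delta method.
#'
#' @param p_pos per-year probability of a positive catch.
#' @param mu per-year PCM LSmean (log scale).
#' @param sigma2 per-year lognormal variance used in the back-transform
#'   correction (typically the PCM residual variance).
#' @param se_mu,se_p optional standard errors of `mu` and `p_pos`.
#' @param years optional year labels.
#' @param level confidence level.
#' @return object of class `standardized_index`: data frame `year,
#'   p_pos, mu, sigma2, index, relative_index, lo, hi`.
#' @export
bias_corrected_index <- function(p_pos, mu, sigma2, se_mu = NULL,
                                 se_p = NULL, years = NULL, level = 0.95) {
  n <- length(mu)
  stopifnot(length(p_pos) == n)
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, n)
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative", call. = FALSE)
  se_mu <- se_mu %||% rep(0, n)
  se_p <- se_p %||% rep(0, n)
  index <- p_pos * exp(mu + sigma2 / 2)
  rel <- index / mean(index)
  var_log <- se_mu^2 + ifelse(p_pos > 0, (se_p / p_pos)^2, 0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(
    year = years %||% as.character(seq_len(n)),
    p_pos = p_pos, mu = mu, sigma2 = sigma2,
    index = index, relative_index = rel,
    lo = index * exp(-z * sqrt(var_log)),
    hi = index * exp(z * sqrt(var_log)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("standardized_index", "data.frame")
  out
}

#' Full delta-lognormal standardization of a CPUE table
#'
#' Runs stepwise selection for both components (or uses the supplied
#' specifications), refits the final PCM by REML when it has random
#' terms, extracts observation-weighted year LSmeans, and builds the
#' bias-corrected standardized index.
#'
#' @param records CPUE records for one design (one area, or all areas
#'   with `combined_area = TRUE`).
#' @param combined_area add `area` to the candidate fixed terms.
#' @param criterion stepwise criterion, `"AIC"` or `"BIC"`.
#' @param specs optional list with `zpm`/`pcm` specification lists
#'   (`fixed`, `random`) to skip the stepwise stage.
#' @return list with `zpm`, `pcm` (final `delta_fit`s) and `index` (a
#'   [bias_corrected_index()] table).
#' @export
standardize_cpue <- function(records, combined_area = FALSE,
                             criterion = "AIC", specs = NULL) {
  cand_fixed <- c("month", "vessel_class", if (combined_area) "area")
  if (is.null(specs)) {
    zpm <- stepwise_select(records, "ZPM", criterion,
                           candidates_fixed = cand_fixed)
    pcm <- stepwise_select(records, "PCM", criterion,
                           candidates_fixed = cand_fixed)
  } else {
    zpm <- fit_delta_component(records, "ZPM", specs$zpm$fixed,
                               specs$zpm$random %||% character(0))
    pcm <- fit_delta_component(records, "PCM", specs$pcm$fixed,
                               specs$pcm$random %||% character(0))
  }
  if (length(pcm$random)) { # final PCM reported under REML
    pcm <- fit_delta_component(records, "PCM", pcm$fixed, pcm$random,
                               reml = TRUE)
  }
  ls_z <- lsmeans_year(zpm)
  ls_p <- lsmeans_year(pcm)
  stopifnot(identical(ls_z$year, ls_p$year))
  p_pos <- stats::plogis(ls_z$estimate)
  # delta method: se(p) = p (1 - p) se(logit p)
  se_p <- p_pos * (1 - p_pos) * ls_z$se
  index <- bias_corrected_index(
    p_pos = p_pos, mu = ls_p$estimate, sigma2 = pcm$sigma2,
    se_mu = ls_p$se, se_p = se_p, years = ls_z$year
  )
  list(zpm = zpm, pcm = pcm, index = index)
}

#' Residual diagnostics for a fitted positive-catch model
#'
#' Standardized residuals, their quantile summary against the standard
#' normal, and a two-sample KS comparison with a matched-moments normal
#' sample (the PCM assumes lognormal positive catches, i.e. normal log
#' residuals).
#'
#' @param pcm a fitted PCM `delta_fit`.
#' @param n_ref size of the reference normal sample.
#' @param seed integer seed for the reference draw.
#' @return list with `residuals` (standardized), `qq` (observed vs
#'   theoretical quartiles), `ks` (a [ks_two_sample()] result), and
#'   `degenerate` (all-zero residual flag).
#' @export
residual_diagnostics <- function(pcm, n_ref = 10000L, seed = 1L) {
  stopifnot(inherits(pcm, "delta_fit"), pcm$component == "PCM")
  r <- stats::residuals(pcm$fit)
  s <- stats::sd(r)
  if (!is.finite(s) || s < 1e-10) { # all-zero residuals up to rounding
    return(list(residuals = r, qq = NULL, ks = NULL, degenerate = TRUE))
  }
  rs <- (r - mean(r)) / s
  probs <- c(0.25, 0.5, 0.75)
  qq <- data.frame(prob = probs,
                   observed = unname(stats::quantile(rs, probs)),
                   theoretical = stats::qnorm(probs))
  ks <- with_seed(seed, ks_two_sample(rs, rnorm(n_ref)))
  list(residuals = rs, qq = qq, ks = ks, degenerate = FALSE)
}
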