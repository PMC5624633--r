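#' Stratified random split of CPUE records
#'
#' Within each year x month x area x vessel-class stratum, each record
#' is sent to the build set when an independent U(0,1) draw falls below
#' `p_build`; the rest form the validation set. Union equals the input
#' and the two sets are disjoint. A stratum so small that one side ends
#' up empty raises a warning, not an error.
#'
#' @param records CPUE records.
#' @param seed integer seed.
#' @param p_build build-set probability.
#' @return list with `build` and `validation` data frames.
#' @export
stratified_split <- function(records, seed, p_build = 0.5) {
  if (nrow(records) == 0L) stop("records must be non-empty", call. = FALSE)
  strat_cols <- intersect(c("year", "month", "area", "vessel_class"),
                          names(records))
  strata <- interaction(records[strat_cols], drop = TRUE)
  build <- logical(nrow(records))
  with_seed(seed, {
    for (s in levels(strata)) {
      ii <- which(strata == s)
      build[ii] <- runif(length(ii)) < p_build
    }
  })
  small <- tapply(build, strata, function(b) all(b) || !any(b))
  if (any(small & table(strata) > 1)) {
    warning(sprintf("%d stratum/strata fell entirely on one side of the split",
                    sum(small & table(strata) > 1)))
  }
  list(build = records[build, , drop = FALSE],
       validation = records[!build, , drop = FALSE])
}

#' Stochastic delta-model CPUE prediction
#'
#' For each record, a positive/zero indicator is drawn by comparing a
#' U(0,1) deviate with the ZPM's fitted probability of a positive
#' catch; the prediction is that indicator times the bias-corrected
#' back-transformed PCM prediction. Records at factor levels unseen by
#' the fitted models are skipped with a message.
#'
#' @param zpm,pcm fitted `delta_fit`s.
#' @param newdata records to predict.
#' @param seed integer seed for the indicator draws.
#' @return data frame `newdata` rows (predictable ones) with columns
#'   `p_pos_hat`, `indicator`, `cpue_pred`; skipped rows are reported
#'   via attribute `n_skipped`.
#' @export
predict_delta <- function(zpm, pcm, newdata, seed = 1L) {
  stopifnot(inherits(zpm, "delta_fit"), inherits(pcm, "delta_fit"))
  d <- prep_records(newdata)
  usable <- rep(TRUE, nrow(d))
  for (v in c("year", "month", "vessel_class", "area")) {
    if (v %in% all.vars(zpm$formula) || v %in% all.vars(pcm$formula)) {
      seen <- levels(zpm$data[[v]])
      usable <- usable & (as.character(d[[v]]) %in% seen)
    }
  }
  if (any(!usable)) {
    message(sprintf("%d record(s) at unseen factor levels skipped", sum(!usable)))
  }
  d <- d[usable, , drop = FALSE]
  # align factor levels with the training frames
  for (v in c("year", "month", "vessel_class", "area")) {
    if (v %in% names(d) && v %in% names(zpm$data)) {
      d[[v]] <- factor(as.character(d[[v]]), levels = levels(zpm$data[[v]]))
    }
  }
  pred_fit <- function(fit_obj, response_scale) {
    f <- fit_obj$fit
    if (inherits(f, "merMod")) {
      stats::predict(f, newdata = d, re.form = NA,
                     type = if (response_scale) "response" else "link",
                     allow.new.levels = TRUE)
    } else if (inherits(f, "glm")) {
      stats::predict(f, newdata = d,
                     type = if (response_scale) "response" else "link")
    } else {
      stats::predict(f, newdata = d) # lm: linear predictor (log scale)
    }
  }
  p_pos <- pred_fit(zpm, response_scale = TRUE)
  mu <- pred_fit(pcm, response_scale = FALSE)
  out <- newdata[usable, , drop = FALSE]
  out$p_pos_hat <- as.numeric(p_pos)
  ind <- with_seed(seed, runif(nrow(d)) < out$p_pos_hat)
  out$indicator <- as.integer(ind)
  out$cpue_pred <- out$indicator * exp(as.numeric(mu) + pcm$sigma2 / 2)
  attr(out, "n_skipped") <- sum(!usable)
  out
}

#' Overall R-squared between observed and predicted CPUE
#'
#' The squared Pearson correlation of observed and predicted values. By
#' definition it is scale-free: predictions proportional to the
#' observations score 1.
#'
#' @param observed,predicted equal-length numeric vectors (n >= 3).
#' @return squared correlation in \[0, 1\].
#' @export
overall_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3L) {
    stop("need equal-length vectors with at least 3 pairs", call. = FALSE)
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("zero variance: R-squared undefined", call. = FALSE)
  }
  stats::cor(observed, predicted)^2
}

#' Cross-validated comparison of area-separated vs area-combined designs
#'
#' Repeats `n_rep` times: stratified-split the records, refit the three
#' final model formulations (south, north, combined) on the build set,
#' stochastically predict the validation set, then compute one overall
#' R-squared from the pooled south+north pairs (area-separated design)
#' and one from the combined model's pairs. Reports the per-replicate
#' values with means and percentile confidence intervals. The final
#' specifications are fixed before the loop; no re-selection happens
#' inside it. Replicates with a failed fit are dropped and counted; more
#' than `max_fail_frac` dropped is an error.
#'
#' @param records CPUE records with an `area` column.
#' @param specs list with `south`, `north`, `combined` entries, each a
#'   list with `zpm`/`pcm` specification lists (`fixed`, `random`).
#' @param n_rep number of replicates.
#' @param seed integer seed; replicate r uses `seed + r` for its split
#'   and prediction draws.
#' @param level confidence level for the percentile interval.
#' @param max_fail_frac tolerated fraction of failed replicates.
#' @return object of class `cv_result`: list of per-design summaries
#'   (`r2_mean`, `ci_lo`, `ci_hi`, `per_rep_r2`), plus `n_rep`,
#'   `n_failed`.
#' @export
cv_compare <- function(records, specs, n_rep = 200L, seed = 1L,
                       level = 0.95, max_fail_frac = 0.1) {
  stopifnot(all(c("south", "north", "combined") %in% names(specs)),
            "area" %in% names(records))
  r2_sep <- r2_comb <- rep(NA_real_, n_rep)
  n_failed <- 0L
  for (r in seq_len(n_rep)) {
    rep_seed <- seed + r
    res <- try({
      sp <- stratified_split(records, seed = rep_seed)
      build <- sp$build; valid <- sp$validation
      fit_design <- function(dat, spec) {
        list(zpm = fit_delta_component(dat, "ZPM", spec$zpm$fixed,
                                       spec$zpm$random %||% character(0)),
             pcm = fit_delta_component(dat, "PCM", spec$pcm$fixed,
                                       spec$pcm$random %||% character(0)))
      }
      pairs_for <- function(models, dat, pseed) {
        pr <- suppressMessages(
          predict_delta(models$zpm, models$pcm, dat, seed = pseed))
        data.frame(obs = pr$catch_n / pr$fishing_days, pred = pr$cpue_pred)
      }
      south_m <- fit_design(build[build$area == "south", ], specs$south)
      north_m <- fit_design(build[build$area == "north", ], specs$north)
      comb_m <- fit_design(build, specs$combined)
      sep_pairs <- rbind(
        pairs_for(south_m, valid[valid$area == "south", ], rep_seed * 2L),
        pairs_for(north_m, valid[valid$area == "north", ], rep_seed * 2L + 1L)
      )
      comb_pairs <- pairs_for(comb_m, valid, rep_seed * 2L + 2L)
      c(sep = overall_r2(sep_pairs$obs, sep_pairs$pred),
        comb = overall_r2(comb_pairs$obs, comb_pairs$pred))
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      n_failed <- n_failed + 1L
    } else {
      r2_sep[r] <- res["sep"]
      r2_comb[r] <- res["comb"]
    }
  }
  if (n_failed > max_fail_frac * n_rep) {
    stop(sprintf("%d of %d replicates failed", n_failed, n_rep),
         call. = FALSE)
  }
  alpha <- (1 - level) / 2
  summarize <- function(x) {
    x <- x[!is.na(x)]
    list(r2_mean = mean(x),
         ci_lo = unname(stats::quantile(x, alpha)),
         ci_hi = unname(stats::quantile(x, 1 - alpha)),
         per_rep_r2 = x)
  }
  structure(list(area_separated = summarize(r2_sep),
                 area_combined = summarize(r2_comb),
                 n_rep = n_rep, n_failed = n_failed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d replicates (%d failed)\n", x$n_rep, x$n_failed))
  for (d in c("area_separated", "area_combined")) {
    s <- x[[d]]
    cat(sprintf("  %-15s mean R2 %.3f (%.3f-%.3f)\n", d, s$r2_mean,
                s$ci_lo, s$ci_hi))
  }
  invisible(x)
}
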