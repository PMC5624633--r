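#' Build a weight-per-fish (WPF) sample from landing records
#'
#' Selects the landing records whose total weight lies inside the
#' single-fish market range (80--350 kg by default) and treats each such
#' record as one fish, yielding an empirical per-fish weight sample.
#'
#' @param landings data frame with a `weight_kg` column.
#' @param min_kg,max_kg inclusive selection bounds (kg).
#' @return object of class `wpf_sample`: numeric vector of per-fish
#'   weights with attributes `min_kg`, `max_kg`, `n_input`.
#' @export
build_wpf <- function(landings, min_kg = 80, max_kg = 350) {
  if (!is.data.frame(landings) || nrow(landings) == 0L) {
    stop("landings must be a non-empty data frame", call. = FALSE)
  }
  w <- landings$weight_kg
  keep <- !is.na(w) & w >= min_kg & w <= max_kg
  if (!any(keep)) {
    stop(sprintf("no landing records inside [%g, %g] kg", min_kg, max_kg),
         call. = FALSE)
  }
  out <- w[keep]
  attr(out, "min_kg") <- min_kg
  attr(out, "max_kg") <- max_kg
  attr(out, "n_input") <- nrow(landings)
  class(out) <- "wpf_sample"
  out
}

#' @export
print.wpf_sample <- function(x, ...) {
  cat(sprintf("<wpf_sample> %d fish in [%g, %g] kg; mean %.1f, sd %.1f\n",
              length(x), attr(x, "min_kg"), attr(x, "max_kg"),
              mean(unclass(x)), stats::sd(unclass(x))))
  invisible(x)
}

#' Two-sample Kolmogorov--Smirnov test
#'
#' D is the supremum of the absolute difference between the two empirical
#' CDFs; the p-value comes from the asymptotic two-sample KS
#' distribution.
#'
#' @param a,b non-empty numeric samples.
#' @return list with `d_stat` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(d_stat = unname(res$statistic), p_value = unname(res$p.value))
}

#' Choose between normal and lognormal WPF distributions
#'
#' Fits both families by moment matching (the lognormal on log weights),
#' draws a large matched sample from each fit, and compares each to the
#' observed WPF sample by the two-sample KS D statistic. The family with
#' the smaller D is returned.
#'
#' @param wpf a [build_wpf()] sample (n >= 30).
#' @param n_ref size of the fitted reference samples.
#' @param seed integer seed for the reference draws.
#' @return list with `label` (`"normal"` or `"lognormal"`), `ks_normal`,
#'   `ks_lognormal`, and the fitted moments.
#' @export
choose_wpf_model <- function(wpf, n_ref = 10000L, seed = 1L) {
  w <- as.numeric(wpf)
  if (length(w) < 30L) stop("need at least 30 weights", call. = FALSE)
  if (any(w <= 0)) stop("nonpositive weights are incompatible with a lognormal fit",
                        call. = FALSE)
  m <- mean(w); s <- stats::sd(w)
  ml <- mean(log(w)); sl <- stats::sd(log(w))
  with_seed(seed, {
    ref_norm <- rnorm(n_ref, m, s)
    ref_lnorm <- rlnorm(n_ref, ml, sl)
    ks_n <- ks_two_sample(w, ref_norm)
    ks_l <- ks_two_sample(w, ref_lnorm)
    list(
      label = if (ks_l$d_stat < ks_n$d_stat) "lognormal" else "normal",
      ks_normal = ks_n, ks_lognormal = ks_l,
      normal = c(mean = m, sd = s),
      lognormal = c(meanlog = ml, sdlog = sl)
    )
  })
}

#' Monte Carlo weight distribution by fish count
#'
#' For each count k = 1..`max_count`, draws k fish (with replacement)
#' from the empirical WPF distribution and sums their weights; repeated
#' `n_rep` times, giving the simulated total-weight distribution of a
#' k-fish landing. These per-count weight bands are the lookup table for
#' imputing missing fish counts.
#'
#' @param wpf a [build_wpf()] sample (or any positive numeric vector).
#' @param max_count largest count simulated.
#' @param n_rep replicates per count.
#' @param seed integer seed.
#' @return object of class `weight_by_count`: list with `totals` (an
#'   `n_rep` x `max_count` matrix of simulated total weights), `counts`,
#'   `n_rep`.
#' @export
simulate_weight_by_count <- function(wpf, max_count = 50L, n_rep = 10000L,
                                     seed = 1L) {
  w <- as.numeric(wpf)
  if (length(w) == 0L) stop("empty WPF sample", call. = FALSE)
  if (max_count < 1L || n_rep < 1L) {
    stop("max_count and n_rep must be at least 1", call. = FALSE)
  }
  totals <- with_seed(seed, {
    vapply(seq_len(max_count), function(k) {
      draws <- sample(w, n_rep * k, replace = TRUE)
      # n_rep sums of k draws each
      colSums(matrix(draws, nrow = k))
    }, numeric(n_rep))
  })
  structure(list(totals = totals, counts = seq_len(max_count),
                 n_rep = as.integer(n_rep)),
            class = "weight_by_count")
}

#' @export
print.weight_by_count <- function(x, ...) {
  cat(sprintf("<weight_by_count> counts 1..%d, %d replicates each\n",
              max(x$counts), x$n_rep))
  cat(sprintf("  one-fish band [%.0f, %.0f] kg; %d-fish band [%.0f, %.0f] kg\n",
              min(x$totals[, 1]), max(x$totals[, 1]), max(x$counts),
              min(x$totals[, ncol(x$totals)]),
              max(x$totals[, ncol(x$totals)])))
  invisible(x)
}

#' Impute missing fish counts from landed weight
#'
#' For each record with a missing count and total weight w, the count k
#' is drawn with probability proportional to the number of simulated
#' k-fish totals falling in the weight bin `[w - bin_kg/2, w + bin_kg/2)`.
#' Records whose bin contains no simulated total for any k are flagged
#' `unassignable` (never silently dropped); a count is never drawn for a
#' k with zero support in the bin.
#'
#' @param landings data frame with `weight_kg` and `fish_count` (missing
#'   counts are `NA`).
#' @param table a [simulate_weight_by_count()] result.
#' @param bin_kg weight bin width (kg).
#' @param seed integer seed.
#' @return `landings` with `fish_count` filled where assignable, plus
#'   logical columns `imputed` and `unassignable`.
#' @export
assign_fish_counts <- function(landings, table, bin_kg = 10, seed = 1L) {
  stopifnot(inherits(table, "weight_by_count"))
  if (any(landings$weight_kg <= 0, na.rm = TRUE)) {
    stop("weights must be positive", call. = FALSE)
  }
  out <- landings
  out$imputed <- FALSE
  out$unassignable <- FALSE
  todo <- which(is.na(out$fish_count))
  if (length(todo) == 0L) return(out)
  totals <- table$totals
  with_seed(seed, {
    for (i in todo) {
      w <- out$weight_kg[i]
      support <- colSums(totals >= w - bin_kg / 2 & totals < w + bin_kg / 2)
      if (sum(support) == 0) {
        out$unassignable[i] <- TRUE
      } else {
        k <- sample(table$counts, 1, prob = support)
        out$fish_count[i] <- k
        out$imputed[i] <- TRUE
      }
    }
  })
  out
}
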