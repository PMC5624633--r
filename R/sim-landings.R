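#' Generate synthetic market landing records
#'
#' Each landing record is one offload event (vessel x day): its fish
#' count k is drawn from a truncated geometric on 1..`max_count`
#' (single-fish landings are the most common outcome), its weight is the
#' sum of k independent truncated-lognormal per-fish weights, and a
#' `mask_frac` fraction of records has the fish count masked to missing,
#' emulating years for which only landed weight was recorded. The full
#' counts are retained in a truth table for recovery checks.
#'
#' @param cfg a [sim_config()].
#' @return list with `landings` (data frame `vessel_id, date, port,
#'   weight_kg, fish_count` where `fish_count` is `NA` for masked
#'   records) and `truth` (same rows with the unmasked `fish_count`).
#' @export
gen_landings <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 101L, {
    n <- cfg$n_vessels * cfg$n_days
    vessel <- sprintf("V%03d", rep(seq_len(cfg$n_vessels), each = cfg$n_days))
    date <- rep(seq(as.Date("2001-05-01"), by = "day",
                    length.out = cfg$n_days), times = cfg$n_vessels)
    port <- sample(c("Tungkang", "Suao", "Singang"), n, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
    k <- rgeom_trunc(n, cfg$count_p, cfg$max_count)
    fish_w <- rlnorm_trunc(sum(k), cfg$wpf_logmean, cfg$wpf_logsd,
                           cfg$wpf_min, cfg$wpf_max)
    weight <- as.numeric(tapply(fish_w, rep(seq_len(n), times = k), sum))
    masked <- runif(n) < cfg$mask_frac
    truth <- data.frame(vessel_id = vessel, date = date, port = port,
                        weight_kg = weight, fish_count = k,
                        stringsAsFactors = FALSE)
    landings <- truth
    landings$fish_count[masked] <- NA_integer_
    list(landings = landings, truth = truth)
  })
}
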