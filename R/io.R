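#' Table schemas used by the pipeline CSV readers
#'
#' Column names and types for the four interchange tables: `landings`
#' (`vessel_id,date,port,weight_kg,fish_count`), `tracks`
#' (`vessel_id,timestamp,lat,lon,speed_kn`), `trips`
#' (`vessel_id,port,vessel_class,depart,return`), and `cpue`
#' (`trip_id,year,month,area,vessel_class,fishing_days,catch_n`).
#' @keywords internal
table_schemas <- function() {
  list(
    landings = list(
      cols = c(vessel_id = "character", date = "Date", port = "character",
               weight_kg = "numeric", fish_count = "integer"),
      check = function(d) {
        bad <- rep(FALSE, nrow(d))
        bad[!is.na(d$weight_kg) & d$weight_kg <= 0] <- TRUE
        bad[!is.na(d$fish_count) & d$fish_count < 1] <- TRUE
        bad[is.na(d$weight_kg) | is.na(d$date)] <- TRUE
        bad
      }
    ),
    tracks = list(
      cols = c(vessel_id = "character", timestamp = "POSIXct",
               lat = "numeric", lon = "numeric", speed_kn = "numeric"),
      check = function(d) {
        is.na(d$timestamp) | is.na(d$lat) | is.na(d$lon) |
          abs(d$lat) > 90 | abs(d$lon) > 180 |
          (!is.na(d$speed_kn) & d$speed_kn < 0)
      }
    ),
    trips = list(
      cols = c(vessel_id = "character", port = "character",
               vessel_class = "character", depart = "POSIXct",
               return = "POSIXct"),
      check = function(d) is.na(d$depart) | is.na(d$return)
    ),
    cpue = list(
      cols = c(trip_id = "character", year = "integer", month = "integer",
               area = "character", vessel_class = "character",
               fishing_days = "numeric", catch_n = "numeric"),
      check = function(d) {
        is.na(d$fishing_days) | d$fishing_days <= 0 |
          is.na(d$catch_n) | d$catch_n < 0
      }
    )
  )
}

#' Read and validate a pipeline CSV table
#'
#' Reads a UTF-8 CSV with header, coerces columns to the schema types
#' (ISO-8601 timestamps), and collects rows violating the schema's row
#' checks into a rejects table with their line numbers instead of
#' failing. Missing required columns are fatal.
#'
#' @param path CSV file path.
#' @param schema one of `"landings"`, `"tracks"`, `"trips"`, `"cpue"`.
#' @return the validated data frame, with attributes `rejects` (the
#'   offending rows with `line`) and `n_rejected`.
#' @export
read_table <- function(path, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) {
    stop(sprintf("unknown schema '%s'", schema), call. = FALSE)
  }
  sc <- schemas[[schema]]
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(names(sc$cols), names(d))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(sc$cols)) {
    d[[nm]] <- switch(sc$cols[[nm]],
      character = as.character(d[[nm]]),
      numeric = suppressWarnings(as.numeric(d[[nm]])),
      integer = suppressWarnings(as.integer(d[[nm]])),
      Date = as.Date(as.character(d[[nm]])),
      POSIXct = as.POSIXct(as.character(d[[nm]]), tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                          "%Y-%m-%d %H:%M:%S",
                                          "%Y-%m-%d"))
    )
  }
  bad <- sc$check(d)
  rejects <- d[bad, , drop = FALSE]
  if (nrow(rejects)) rejects$line <- which(bad) + 1L # header is line 1
  out <- d[!bad, , drop = FALSE]
  attr(out, "rejects") <- rejects
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write a pipeline table as CSV
#'
#' UTF-8 CSV with header; `Date` columns as `YYYY-MM-DD`, timestamps as
#' ISO-8601 UTC.
#'
#' @param d data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(d, path) {
  d2 <- d
  for (nm in names(d2)) {
    if (inherits(d2[[nm]], "POSIXct")) {
      d2[[nm]] <- format(d2[[nm]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    } else if (inherits(d2[[nm]], "Date")) {
      d2[[nm]] <- format(d2[[nm]], "%Y-%m-%d")
    }
  }
  utils::write.csv(d2, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full synthetic reconstruction-and-standardization pipeline
#'
#' Chains the stages on generated data: simulate (landings, tracks,
#' trips, CPUE) -> impute fish counts -> tune and apply the fishing-day
#' criterion -> fit the effort model -> standardize CPUE -> optionally
#' cross-validate the area designs. Every stage writes its CSV outputs
#' under `out_dir` and is recorded in a manifest with parameter values,
#' seeds, and file MD5 hashes; rerunning with the same configuration
#' reproduces identical outputs.
#'
#' @param cfg a [sim_config()]; its seed drives every stage.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("simulate", "impute", "classify", "effort", "standardize",
#'   "evaluate")`; dependencies must be included.
#' @param n_rep_cv cross-validation replicates for the evaluate stage.
#' @return the manifest: a list with per-stage parameters, outputs and
#'   MD5 hashes.
#' @export
run_pipeline <- function(cfg, out_dir,
                         stages = c("simulate", "impute", "classify",
                                    "effort", "standardize"),
                         n_rep_cv = 50L) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list())
  paths <- list()
  record <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      params = params,
      outputs = setNames(as.character(tools::md5sum(unlist(files))),
                         basename(unlist(files)))
    )
  }
  need <- function(stage, dep) {
    if (!dep %in% names(manifest$stages)) {
      stop(sprintf("stage '%s' requires stage '%s' to run first",
                   stage, dep), call. = FALSE)
    }
  }
  sim <- NULL
  if ("simulate" %in% stages) {
    sim <- list(landings = gen_landings(cfg), tracks = gen_tracks(cfg),
                trips = gen_trips(cfg), cpue = gen_cpue(cfg))
    paths$landings <- file.path(out_dir, "landings.csv")
    paths$tracks <- file.path(out_dir, "tracks.csv")
    paths$trips <- file.path(out_dir, "trips.csv")
    paths$cpue <- file.path(out_dir, "cpue.csv")
    write_table(sim$landings$landings, paths$landings)
    write_table(sim$tracks$points, paths$tracks)
    write_table(sim$trips$trips, paths$trips)
    write_table(sim$cpue, paths$cpue)
    record("simulate", list(n_vessels = cfg$n_vessels, n_days = cfg$n_days,
                            n_trips = cfg$n_trips), paths)
  }
  if ("impute" %in% stages) {
    need("impute", "simulate")
    wpf <- build_wpf(sim$landings$landings, cfg$wpf_min, cfg$wpf_max)
    wbc <- simulate_weight_by_count(wpf, max_count = cfg$max_count,
                                    seed = cfg$seed + 11L)
    imputed <- assign_fish_counts(sim$landings$landings, wbc,
                                  seed = cfg$seed + 12L)
    p <- file.path(out_dir, "landings_imputed.csv")
    write_table(imputed, p)
    record("impute", list(bin_kg = 10, n_rep = wbc$n_rep,
                          seed = cfg$seed + 11L), list(p))
  }
  if ("classify" %in% stages) {
    need("classify", "simulate")
    days <- split_days(sim$tracks$points)
    gs <- grid_search(days, sim$tracks$labels, "direction",
                      intervals_h = 5L)
    flags <- apply_criterion(days, gs$best)
    p1 <- file.path(out_dir, "criterion_scores.csv")
    p2 <- file.path(out_dir, "fishing_days.csv")
    write_table(gs$table, p1)
    write_table(flags, p2)
    record("classify", gs$best, list(p1, p2))
  }
  if ("effort" %in% stages) {
    need("effort", "simulate")
    screened <- trips_to_at_sea_days(sim$trips$trips)
    pairs <- cbind(screened$trips,
                   fishing_days = sim$trips$truth$fishing_days[
                     match(screened$trips$trip_id, sim$trips$truth$trip_id)])
    model <- fit_effort_model(pairs)
    pred <- predict_fishing_days(screened$trips, model)
    p1 <- file.path(out_dir, "effort_model.json")
    p2 <- file.path(out_dir, "trips_predicted.csv")
    jsonlite::write_json(as.data.frame(model), p1, digits = NA)
    write_table(pred, p2)
    record("effort", list(n_dropped = screened$n_dropped), list(p1, p2))
  }
  if ("standardize" %in% stages) {
    need("standardize", "simulate")
    std <- standardize_cpue(sim$cpue, combined_area = TRUE)
    p <- file.path(out_dir, "standardized_index.csv")
    write_table(as.data.frame(std$index), p)
    record("standardize",
           list(zpm = paste(std$zpm$fixed, collapse = "+"),
                pcm = paste(std$pcm$fixed, collapse = "+")),
           list(p))
  }
  if ("evaluate" %in% stages) {
    need("evaluate", "simulate")
    spec_fix <- list(zpm = list(fixed = c("year", "month")),
                     pcm = list(fixed = c("year", "month")))
    spec_comb <- list(zpm = list(fixed = c("year", "month", "area")),
                      pcm = list(fixed = c("year", "month", "area")))
    cv <- cv_compare(sim$cpue,
                     specs = list(south = spec_fix, north = spec_fix,
                                  combined = spec_comb),
                     n_rep = n_rep_cv, seed = cfg$seed + 21L)
    p <- file.path(out_dir, "cv_summary.json")
    jsonlite::write_json(
      list(area_separated = cv$area_separated[c("r2_mean", "ci_lo", "ci_hi")],
           area_combined = cv$area_combined[c("r2_mean", "ci_lo", "ci_hi")]),
      p, auto_unbox = TRUE, digits = NA)
    record("evaluate", list(n_rep = n_rep_cv), list(p))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  manifest
}
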