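# --- provenance ------------------------------------------------------------

# Comment header stamped on every output file: package version, md5 of the
# payload, and the seed when one was involved. Deliberately no timestamp,
# so repeated runs are byte-identical.
prov_header <- function(payload_lines, seed = NULL) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(payload_lines, tmp)
  h <- unname(tools::md5sum(tmp))
  c(paste0("# airhia ", as.character(utils::packageVersion("airhia"))),
    paste0("# config_hash=", h),
    if (!is.null(seed)) paste0("# seed=", seed))
}

# --- daily series CSV ------------------------------------------------------

#' Read a daily concentration series from CSV
#'
#' Expects a header `date,value`, ISO-8601 dates and decimal points
#' (decimal commas are rejected with an explicit message rather than
#' guessed at). Comment lines starting with `#` are ignored. Rows with a
#' blank value are skipped and the skip count reported; malformed dates or
#' numbers are an error naming the offending line; duplicate dates are an
#' error naming the date.
#'
#' @param path CSV path.
#' @param pollutant pollutant the file records (default `"PM10"`).
#' @param quiet suppress the skipped-row message.
#' @return a [daily_series()].
#' @export
read_daily_csv <- function(path, pollutant = "PM10", quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("no data: ", path, " is empty")
  if (trimws(lines[1]) != "date,value")
    stop("expected header 'date,value' in ", path)
  body <- lines[-1]; body_no <- lineno[-1]
  if (length(body) == 0) stop("no data rows in ", path)
  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf > 2))
    stop("line ", body_no[which(nf > 2)[1]],
         ": too many fields - decimal commas are not supported, ",
         "use decimal points")
  date_s <- vapply(fields, function(f) trimws(f[1]), character(1))
  val_s <- vapply(fields, function(f)
    if (length(f) >= 2) trimws(f[2]) else "", character(1))
  blank <- !nzchar(val_s)
  if (any(blank) && !quiet)
    message("skipped ", sum(blank), " row(s) with blank value")
  date_s <- date_s[!blank]; val_s <- val_s[!blank]
  body_no <- body_no[!blank]
  d <- as.Date(date_s, format = "%Y-%m-%d")
  if (anyNA(d))
    stop("line ", body_no[which(is.na(d))[1]], ": malformed date '",
         date_s[which(is.na(d))[1]], "' (expected YYYY-MM-DD)")
  v <- suppressWarnings(as.numeric(val_s))
  if (anyNA(v))
    stop("line ", body_no[which(is.na(v))[1]], ": malformed number '",
         val_s[which(is.na(v))[1]], "'")
  daily_series(d, v, pollutant)
}

#' Write a daily series to CSV
#'
#' @param series a [daily_series()].
#' @param path output path.
#' @param seed seed recorded in the provenance header, if any.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(series, path, seed = NULL) {
  stopifnot(inherits(series, "daily_series"))
  payload <- c("date,value",
               paste(format(series$date), series$value, sep = ","))
  writeLines(c(prov_header(payload, seed), payload), path)
  invisible(path)
}

# --- exposure summary JSON -------------------------------------------------

#' Serialize / deserialize an exposure summary
#'
#' JSON with keys `pollutant`, `annual_mean`, `n_days`, `derivation`,
#' `conversion_factor`; a write-read round trip is the identity.
#'
#' @param summary an [exposure_summary()].
#' @param path JSON path.
#' @return `write_exposure_json()` returns `path` invisibly;
#'   `read_exposure_json()` returns an [exposure_summary()].
#' @export
write_exposure_json <- function(summary, path) {
  stopifnot(inherits(summary, "exposure_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_exposure_json
#' @export
read_exposure_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  exposure_summary(x$annual_mean, x$pollutant,
                   n_days = if (is.null(x$n_days)) NA_integer_ else x$n_days,
                   derivation = x$derivation,
                   conversion_factor = if (is.null(x$conversion_factor))
                     NA_real_ else x$conversion_factor)
}

# --- scenario bundle -------------------------------------------------------

#' Write a scenario bundle to a directory
#'
#' The file interface to a full assessment: `population.csv` (one row per
#' scenario: label, age_band, population, cases, incidence, denominator),
#' `scenario.json` (exposure, per-scenario counterfactual / CRF reference
#' / horizon / optional stated AP) and `crf_registry.json`.
#'
#' @param fixture a list shaped like [agadir_fixture()]: elements
#'   `scenarios`, `registry`, and the exposure summaries.
#' @param dir output directory (created if needed).
#' @param seed seed recorded in provenance headers, if any.
#' @return `dir`, invisibly.
#' @export
write_scenario_bundle <- function(fixture, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scns <- fixture$scenarios
  ids <- vapply(scns, function(s)
    paste0(s$baseline$endpoint, "_", s$horizon), character(1))
  ids <- make.unique(ids, sep = "_")
  pop_lines <- c(
    "label,age_band,population,cases,incidence,denominator",
    vapply(seq_along(scns), function(i) {
      s <- scns[[i]]
      paste(ids[i], s$group$age_band, s$group$population,
            ifelse(is.na(s$baseline$observed_cases), "",
                   s$baseline$observed_cases),
            ifelse(is.na(s$baseline$incidence_value), "",
                   s$baseline$incidence_value),
            s$baseline$denominator, sep = ",")
    }, character(1)))
  writeLines(c(prov_header(pop_lines, seed), pop_lines),
             file.path(dir, "population.csv"))
  write_crf_registry(fixture$registry, file.path(dir, "crf_registry.json"))
  crf_keys <- vapply(scns, function(s) {
    for (k in names(fixture$registry)) {
      c2 <- crf_from_registry(fixture$registry, k)
      if (identical(class(c2), class(s$crf)) &&
          isTRUE(all.equal(unclass(c2), unclass(s$crf),
                           check.attributes = FALSE)))
        return(k)
    }
    NA_character_
  }, character(1))
  scn_json <- list(
    exposure = unclass(fixture$pm25),
    registry = "crf_registry.json",
    population = "population.csv",
    scenarios = lapply(seq_along(scns), function(i) {
      s <- scns[[i]]
      list(id = ids[i], label = s$label, endpoint = s$baseline$endpoint,
           horizon = s$horizon, outcome = s$outcome,
           counterfactual = s$counterfactual,
           concentration = s$concentration, crf = crf_keys[i],
           ap_override = if (is.null(s$ap_override)) NULL
                         else as.numeric(s$ap_override))
    }))
  jsonlite::write_json(scn_json, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read a scenario bundle
#'
#' @param config path to a `scenario.json` written by
#'   [write_scenario_bundle()] (sibling files are resolved relative to
#'   it).
#' @return a list with `scenarios` (list of [endpoint_scenario()]),
#'   `registry`, and the exposure summary `pm25`.
#' @export
read_scenario_bundle <- function(config) {
  if (!file.exists(config)) stop("config not found: ", config)
  dir <- dirname(config)
  cfg <- jsonlite::read_json(config, simplifyVector = FALSE)
  ex <- cfg$exposure
  pm25 <- exposure_summary(ex$annual_mean, ex$pollutant,
    n_days = if (is.null(ex$n_days)) NA_integer_ else ex$n_days,
    derivation = ex$derivation,
    conversion_factor = if (is.null(ex$conversion_factor)) NA_real_
                        else ex$conversion_factor)
  registry <- read_crf_registry(file.path(dir, cfg$registry))
  pop <- utils::read.csv(file.path(dir, cfg$population),
                         comment.char = "#", stringsAsFactors = FALSE)
  scenarios <- lapply(cfg$scenarios, function(s) {
    row <- pop[pop$label == s$id, , drop = FALSE]
    if (nrow(row) != 1)
      stop("population.csv has no unique row labelled '", s$id, "'")
    endpoint_scenario(
      s$label, pm25, counterfactual = s$counterfactual,
      crf = crf_from_registry(registry, s$crf),
      group = population_group(s$id, row$age_band, row$population),
      baseline = baseline_health(
        s$endpoint,
        observed_cases = if (is.na(row$cases)) NA_real_ else row$cases,
        incidence_value = if (is.na(row$incidence)) NA_real_
                          else row$incidence,
        denominator = row$denominator),
      horizon = s$horizon, outcome = s$outcome,
      ap_override = if (length(s$ap_override) == 0) NULL
                    else as_triple(unlist(s$ap_override)),
      concentration = s$concentration)
  })
  list(scenarios = scenarios, registry = registry, pm25 = pm25)
}

# --- report ----------------------------------------------------------------

#' Write a report as TSV and aligned text
#'
#' @param report an `"hia_report"` from [build_report()].
#' @param tsv_path TSV output path (`NULL` to skip).
#' @param txt_path aligned-text output path (`NULL` to skip).
#' @param seed seed recorded in provenance headers, if any.
#' @return the report, invisibly.
#' @export
write_report <- function(report, tsv_path = NULL, txt_path = NULL,
                         seed = NULL) {
  stopifnot(inherits(report, "hia_report"))
  if (!is.null(tsv_path)) {
    payload <- c(paste(names(report), collapse = "\t"),
                 apply(report, 1, paste, collapse = "\t"))
    writeLines(c(prov_header(payload, seed), payload), tsv_path)
  }
  if (!is.null(txt_path)) {
    payload <- utils::capture.output(print(report))
    writeLines(c(prov_header(payload, seed), payload), txt_path)
  }
  invisible(report)
}
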