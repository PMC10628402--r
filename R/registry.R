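#' Default concentration-response registry
#'
#' The endpoint-to-CRF bindings used by the packaged assessment: all-cause
#' mortality through the log-linear model (long-term against the annual
#' PM2.5 guideline 10 µg/m³, short-term against the 24-h guideline
#' 25 µg/m³) and the cause-specific endpoints through IER curves with
#' counterfactuals 2.4 µg/m³ (lung cancer; the lower edge of the GBD 2015
#' counterfactual range) and 15 µg/m³ (ALRI, COPD; WHO interim target 3).
#'
#' The IER shape parameters in circulation are not published alongside the
#' study RRs, so the registry ships curves with gamma = 0.05, delta = 1
#' and alpha calibrated via [fit_ier_scale()] so each curve passes through
#' the RR implied by the published attributable proportion at the study
#' exposure of 35.45 µg/m³. The registry is an editable plain list and can
#' be round-tripped through JSON with [write_crf_registry()] /
#' [read_crf_registry()].
#'
#' @return a named list; each entry has `form = "loglinear"` (with `rr`,
#'   `increment`, `counterfactual`) or `form = "ier"` (with `cause`,
#'   `alpha`, `gamma`, `delta`, `zcf`).
#' @export
default_crf_registry <- function() {
  cal <- function(cause, zcf, ap)
    fit_ier_scale(ier_crf(cause, alpha = 1, gamma = 0.05, delta = 1,
                          zcf = zcf),
                  z_obs = 35.45, rr_obs = rr_from_ap(ap))
  ier_entry <- function(crf)
    list(form = "ier", cause = crf$cause, alpha = crf$alpha,
         gamma = crf$gamma, delta = crf$delta, zcf = crf$zcf)
  list(
    total_mortality_long_term = list(
      form = "loglinear", rr = c(1.062, 1.040, 1.083), increment = 10,
      counterfactual = 10),
    total_mortality_short_term = list(
      form = "loglinear", rr = c(1.0123, 1.0045, 1.0201), increment = 10,
      counterfactual = 25),
    LC = ier_entry(cal("LC", 2.4, 0.1842)),
    ALRI = ier_entry(cal("ALRI", 15, 0.1436)),
    COPD = ier_entry(cal("COPD", 15, 0.1568))
  )
}

#' Materialize a CRF from a registry entry
#'
#' @param registry a registry list, as from [default_crf_registry()] or
#'   [read_crf_registry()].
#' @param endpoint entry name.
#' @return a [loglinear_crf()] or [ier_crf()].
#' @export
crf_from_registry <- function(registry, endpoint) {
  e <- registry[[endpoint]]
  if (is.null(e)) stop("no CRF registered for endpoint '", endpoint, "'")
  switch(e$form,
    loglinear = loglinear_crf(unlist(e$rr), increment = e$increment,
                              counterfactual = e$counterfactual),
    ier = ier_crf(e$cause, alpha = e$alpha, gamma = e$gamma,
                  delta = e$delta, zcf = e$zcf),
    stop("unknown CRF form '", e$form, "'"))
}

#' Write a CRF registry to JSON
#'
#' @param registry a registry list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crf_registry <- function(registry, path) {
  jsonlite::write_json(registry, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a CRF registry from JSON
#'
#' @param path path to a JSON registry, as written by
#'   [write_crf_registry()].
#' @return a registry list.
#' @export
read_crf_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(reg, function(e) {
    if (!is.null(e$rr)) e$rr <- as.numeric(e$rr)
    e
  })
}
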