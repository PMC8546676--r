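#' Estimate methylation rate constants from single-time-point tracer data
#'
#' Inverts the simplified tracer forward model for each incubation replicate:
#' \deqn{k_m = -\ln(1 - [MM^{200}Hg]_t / [^{200}Hg^{II}]_0)\,/\,t.}
#' A replicate whose product tracer concentration does not exceed the MMHg
#' detection limit is censored (`detected = FALSE`, `value = NA`): a rate is
#' only reported where methylation was actually observed.
#'
#' @param data A tracer incubation tibble with columns `site_id`,
#'   `replicate_id`, `ihg200_0`, `mmhg200_t`, `t_days`, `lod_mmhg` (see
#'   [read_tracer_tsv()] / [sim_tracer_experiment()]).
#' @return A tibble with one row per replicate: `site_id`, `replicate_id`,
#'   `kind` (`"methylation"`), `value` (day^-1, `NA` when non-detect),
#'   `detected`.
#' @export
#' @examples
#' inc <- simulate_simplified_tracers(km = 5.9e-3, kd = 1.78, t = 2)
#' estimate_km(tibble::tibble(
#'   site_id = "wetland", replicate_id = "r1", ihg200_0 = 4,
#'   mmhg200_t = inc$mmhg200_t, t_days = 2, lod_mmhg = 0.01
#' ))
estimate_km <- function(data) {
  check_cols(data, c("ihg200_0", "mmhg200_t", "t_days", "lod_mmhg"), "tracer table")
  if (any(data$t_days <= 0)) abort("Incubation time `t_days` must be positive.")
  if (any(data$ihg200_0 <= 0)) abort("`ihg200_0` spike must be positive.")
  if (any(data$lod_mmhg <= 0)) abort("`lod_mmhg` must be positive.")
  bad <- !is.na(data$mmhg200_t) & data$mmhg200_t >= data$ihg200_0
  if (any(bad)) {
    abort(paste0(
      "Measured MM200Hg >= initial Hg(II) spike in replicate(s): ",
      paste(replicate_label(data)[bad], collapse = ", "),
      " (logarithm undefined; impossible measurement)."
    ))
  }
  # values reported below the detection limit (possibly as NA) are censored
  detected <- !is.na(data$mmhg200_t) & data$mmhg200_t > data$lod_mmhg
  value <- ifelse(detected, -log(1 - data$mmhg200_t / data$ihg200_0) / data$t_days, NA_real_)
  rate_tbl(data, kind = "methylation", value = value, detected = detected)
}

#' Estimate demethylation rate constants from single-time-point tracer data
#'
#' Inverts the exponential loss of the enriched MMHg tracer:
#' \deqn{k_d = -\ln([MM^{198}Hg]_t / [MM^{198}Hg]_0)\,/\,t.}
#' An apparent gain of the tracer (negative rate) is clamped to zero with a
#' warning, since the decay model presumes net loss.
#'
#' @param data A tracer incubation tibble with columns `site_id`,
#'   `replicate_id`, `mmhg198_0`, `mmhg198_t`, `t_days`.
#' @return A tibble as in [estimate_km()], with `kind = "demethylation"`.
#'   Demethylation tracer levels sit near the spike, so no detection-limit
#'   censoring applies; `detected` is `TRUE` throughout.
#' @export
estimate_kd <- function(data) {
  check_cols(data, c("mmhg198_0", "mmhg198_t", "t_days"), "tracer table")
  if (any(data$t_days <= 0)) abort("Incubation time `t_days` must be positive.")
  if (any(data$mmhg198_0 <= 0)) abort("`mmhg198_0` spike must be positive.")
  if (any(data$mmhg198_t <= 0)) {
    abort(paste0(
      "Non-positive MM198Hg at time t in replicate(s): ",
      paste(replicate_label(data)[data$mmhg198_t <= 0], collapse = ", "),
      " (logarithm undefined)."
    ))
  }
  value <- -log(data$mmhg198_t / data$mmhg198_0) / data$t_days
  if (any(value < 0)) {
    warn(paste0(
      "Apparent MM198Hg gain (negative kd) clamped to 0 in replicate(s): ",
      paste(replicate_label(data)[value < 0], collapse = ", ")
    ))
    value <- pmax(value, 0)
  }
  rate_tbl(data, kind = "demethylation", value = value, detected = TRUE)
}

#' Estimate both rate constants for every replicate
#'
#' @inheritParams estimate_km
#' @return Row-bound output of [estimate_km()] and [estimate_kd()].
#' @export
estimate_rates <- function(data) {
  bind_rows(estimate_km(data), estimate_kd(data))
}

rate_tbl <- function(data, kind, value, detected) {
  tibble(
    site_id = as.character(data$site_id %||% NA_character_),
    replicate_id = as.character(data$replicate_id %||% seq_len(nrow(data))),
    kind = kind,
    value = value,
    detected = rep_len(detected, nrow(data))
  )
}

replicate_label <- function(data) {
  paste0(data$site_id %||% "?", "/", data$replicate_id %||% seq_len(nrow(data)))
}

#' Summarise replicate rate estimates per site
#'
#' Mean and standard error (sd/sqrt(n)) of the rate constant over detected
#' replicates of each site. Non-detects are excluded from the mean by default
#' but always counted in `n_total`; set `nondetect_as_zero = TRUE` to instead
#' include censored replicates as zeros.
#'
#' @param estimates Output of [estimate_rates()] (or either estimator).
#' @param nondetect_as_zero Include non-detects as 0 in the mean? Default
#'   `FALSE` (detected-only averaging).
#' @return A tibble with `site_id`, `kind`, `mean`, `se`, `n_detected`,
#'   `n_total`. `mean`/`se` are `NA` where nothing was detected.
#' @export
summarize_site_rates <- function(estimates, nondetect_as_zero = FALSE) {
  check_cols(estimates, c("site_id", "kind", "value", "detected"), "rate estimates")
  if (nrow(estimates) == 0) abort("No rate estimates supplied.")
  estimates |>
    group_by(.data$site_id, .data$kind) |>
    summarise(
      mean = site_mean(.data$value, .data$detected, nondetect_as_zero),
      se = site_se(.data$value, .data$detected, nondetect_as_zero),
      n_detected = sum(.data$detected),
      n_total = n(),
      .groups = "drop"
    )
}

site_mean <- function(value, detected, zero) {
  v <- if (zero) ifelse(detected, value, 0) else value[detected]
  if (length(v) == 0 || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

site_se <- function(value, detected, zero) {
  v <- if (zero) ifelse(detected, value, 0) else value[detected]
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_real_ else if (length(v) == 1) 0 else sd(v) / sqrt(length(v))
}

check_cols <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("The ", what, " is missing column(s): ", paste(missing, collapse = ", "), "."))
  }
  invisible(NULL)
}
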