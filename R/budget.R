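#' Fill inorganic mercury by subtraction
#'
#' IHg is not measured directly; it is estimated as total mercury minus
#' monomethylmercury, per matrix and site. An existing `ihg` column is kept
#' where consistent and overwritten with a warning where it disagrees with
#' `thg - mmhg` beyond 1e-9.
#'
#' @param data Speciation tibble with columns `mmhg` and `thg` (any units,
#'   consistent within a row), typically also `site_id` and `matrix`.
#' @return `data` with `ihg` filled in.
#' @export
#' @examples
#' ihg_by_subtraction(tibble::tibble(site_id = "natural", thg = 1.72, mmhg = 0.10))
ihg_by_subtraction <- function(data) {
  check_cols(data, c("mmhg", "thg"), "speciation table")
  if (any(data$mmhg < 0 | data$thg < 0, na.rm = TRUE)) {
    abort("Concentrations must be non-negative.")
  }
  if (any(data$mmhg > data$thg, na.rm = TRUE)) {
    abort("MMHg exceeds THg; negative IHg is impossible.")
  }
  ihg_new <- data$thg - data$mmhg
  if ("ihg" %in% names(data)) {
    clash <- !is.na(data$ihg) & abs(data$ihg - ihg_new) > 1e-9
    if (any(clash)) {
      warn(paste0(
        "Overwriting inconsistent `ihg` in ", sum(clash), " row(s) with thg - mmhg."
      ))
    }
  }
  mutate(data, ihg = ihg_new)
}

#' Percent monomethylmercury of total mercury
#'
#' Computes 100 * MMHg / THg at full precision, reconstructing THg as
#' MMHg + IHg where `thg` is absent. Rounding to one decimal is presentation
#' only and left to the caller.
#'
#' @param data Speciation tibble with `mmhg` and at least one of `thg`, `ihg`.
#' @return `data` with a `pct_mmhg` column appended.
#' @export
#' @examples
#' percent_mmhg(tibble::tibble(mmhg = 0.23, ihg = 0.76))$pct_mmhg # 23.23...
percent_mmhg <- function(data) {
  check_cols(data, "mmhg", "speciation table")
  if (!"thg" %in% names(data) && !"ihg" %in% names(data)) {
    abort("Need `thg` or `ihg` alongside `mmhg` to compute percent MMHg.")
  }
  thg <- if ("thg" %in% names(data)) data$thg else rep(NA_real_, nrow(data))
  if ("ihg" %in% names(data)) {
    thg <- ifelse(is.na(thg), data$mmhg + data$ihg, thg)
  }
  if (any(is.na(thg))) abort("THg unresolvable (both `thg` and `ihg` missing) in some rows.")
  if (any(thg == 0)) abort("THg is zero; percent MMHg undefined.")
  mutate(data, pct_mmhg = 100 * .data$mmhg / thg)
}

#' Ash-free dry weight fraction
#'
#' Organic-matter content of periphyton biomass as a percentage,
#' 100 * AFDW / DW.
#'
#' @param data Tibble with columns `afdw` and `dw` (same mass units).
#' @return `data` with an `afdw_pct` column appended.
#' @export
afdw_fraction <- function(data) {
  check_cols(data, c("afdw", "dw"), "biomass table")
  if (any(data$dw <= 0)) abort("Dry weight `dw` must be positive.")
  if (any(data$afdw < 0 | data$afdw > data$dw)) {
    abort("`afdw` must lie in [0, dw].")
  }
  mutate(data, afdw_pct = 100 * .data$afdw / .data$dw)
}

#' Spike-to-ambient fold ratio
#'
#' How many times the isotope spike concentration exceeds the mean ambient
#' water concentration of a mercury species across sites. THg is
#' reconstructed as MMHg + IHg where absent.
#'
#' @param data Ambient water speciation tibble (one row per site).
#' @param spike_conc Spike concentration, ng L^-1.
#' @param species `"thg"` or `"mmhg"`.
#' @return One-row tibble: `species`, `spike_conc`, `ambient_mean`, `fold`.
#' @export
#' @examples
#' amb <- tibble::tibble(mmhg = c(0.10, 0.12, 0.23), ihg = c(1.62, 1.25, 0.76))
#' spike_fold_ratio(amb, spike_conc = 4, species = "thg")
spike_fold_ratio <- function(data, spike_conc, species = c("thg", "mmhg")) {
  species <- match.arg(species)
  if (spike_conc <= 0) abort("`spike_conc` must be positive.")
  conc <- if (species == "mmhg") {
    check_cols(data, "mmhg", "ambient table")
    data$mmhg
  } else if ("thg" %in% names(data)) {
    data$thg
  } else {
    check_cols(data, c("mmhg", "ihg"), "ambient table")
    data$mmhg + data$ihg
  }
  conc <- conc[!is.na(conc)]
  if (length(conc) == 0) abort("No ambient measurements for the requested species.")
  m <- mean(conc)
  if (m == 0) abort("Mean ambient concentration is zero; fold ratio undefined.")
  tibble(species = species, spike_conc = spike_conc, ambient_mean = m, fold = spike_conc / m)
}
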