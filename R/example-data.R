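#' Example ambient mercury speciation survey
#'
#' A small three-site boreal-river speciation table (water in ng L^-1,
#' periphyton in ng g^-1 dry weight) of the kind produced by a field survey
#' accompanying tracer incubations: monomethylmercury and inorganic mercury
#' per site and matrix. Used by the worked examples and the default
#' pipeline's budget stage.
#'
#' @return Tibble: `site_id`, `matrix`, `mmhg`, `ihg`.
#' @export
example_speciation <- function() {
  tibble(
    site_id = rep(c("natural", "flooded", "wetland"), 2),
    matrix = rep(c("water", "periphyton"), each = 3),
    mmhg = c(0.10, 0.12, 0.23, 3.4, 6.7, 2.7),
    ihg = c(1.62, 1.25, 0.76, 23.3, 30.5, 21.7)
  )
}

#' Example periphyton biomass measurements
#'
#' Dry weight and ash-free dry weight per site (mg), matching the organic
#' matter fractions of the example survey.
#'
#' @return Tibble: `site_id`, `dw`, `afdw`.
#' @export
example_biomass <- function() {
  tibble(
    site_id = c("natural", "flooded", "wetland"),
    dw = c(100, 100, 100),
    afdw = c(24.0, 35.7, 26.3)
  )
}
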