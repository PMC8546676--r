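#' Forward-simulate coupled isotope tracer pools
#'
#' Solves the two-compartment first-order net methylation model
#' \deqn{d[MMHg]/dt = k_m [Hg^{II}] - k_d [MMHg]}
#' analytically for both enriched tracer pools of a spiked incubation: the
#' methylation tracer starts as pure inorganic \eqn{^{200}}Hg(II)
#' (\code{ihg200_0}, no MM\eqn{^{200}}Hg at t = 0) and the demethylation
#' tracer as pure MM\eqn{^{198}}Hg (\code{mmhg198_0}, no \eqn{^{198}}Hg(II)
#' at t = 0). Each pool evolves independently and its total is conserved
#' exactly: for a pool of total \eqn{T}, the methylated fraction relaxes to
#' the equilibrium \eqn{T k_m/(k_m+k_d)} at rate \eqn{k_m+k_d}.
#'
#' @param km Methylation rate constant, day^-1 (>= 0).
#' @param kd Demethylation rate constant, day^-1 (>= 0).
#' @param ihg200_0 Initial enriched Hg(II) spike, ng L^-1 (> 0).
#' @param mmhg198_0 Initial enriched MMHg spike, ng L^-1 (> 0).
#' @param t Incubation time in days (>= 0). Vectorised; other arguments are
#'   recycled against it.
#'
#' @return A tibble with columns `t`, `mmhg200_t`, `ihg200_t`, `mmhg198_t`,
#'   `ihg198_t` (ng L^-1).
#' @seealso [simulate_simplified_tracers()] for the no-back-reaction forward
#'   maps whose exact inverses are [estimate_km()] and [estimate_kd()].
#' @export
#' @examples
#' simulate_coupled_tracers(km = 5.9e-3, kd = 1.78, t = 2)
simulate_coupled_tracers <- function(km, kd, ihg200_0 = 4, mmhg198_0 = 4, t) {
  check_rates(km, kd)
  if (any(t < 0)) abort("`t` must be non-negative.")
  if (any(ihg200_0 <= 0) || any(mmhg198_0 <= 0)) {
    abort("Spike concentrations must be positive.")
  }
  n <- max(length(km), length(kd), length(ihg200_0), length(mmhg198_0), length(t))
  km <- rep_len(km, n); kd <- rep_len(kd, n); t <- rep_len(t, n)
  ihg200_0 <- rep_len(ihg200_0, n); mmhg198_0 <- rep_len(mmhg198_0, n)

  b200 <- pool_mmhg(total = ihg200_0, b0 = 0, km = km, kd = kd, t = t)
  b198 <- pool_mmhg(total = mmhg198_0, b0 = mmhg198_0, km = km, kd = kd, t = t)
  tibble(
    t = t,
    mmhg200_t = b200, ihg200_t = ihg200_0 - b200,
    mmhg198_t = b198, ihg198_t = mmhg198_0 - b198
  )
}

# MMHg compartment of a closed two-pool linear system with total `total` and
# initial MMHg `b0`; km + kd == 0 degenerates to no reaction.
pool_mmhg <- function(total, b0, km, kd, t) {
  s <- km + kd
  eq <- ifelse(s > 0, total * km / s, b0)
  ifelse(s > 0, eq + (b0 - eq) * exp(-s * t), b0)
}

#' Forward-simulate tracers under the simplified (no back-reaction) model
#'
#' With tracer spikes the initial MM\eqn{^{200}}Hg and \eqn{^{198}}Hg(II)
#' pools are zero, so over a short incubation the back-reactions on each
#' product are dropped, giving the integrable forms
#' \deqn{[MM^{200}Hg]_t = [^{200}Hg^{II}]_0 (1 - e^{-k_m t}),\qquad
#'       [MM^{198}Hg]_t = [MM^{198}Hg]_0\, e^{-k_d t}.}
#' These are the exact inverses of the single-time-point estimators.
#'
#' @inheritParams simulate_coupled_tracers
#' @return A tibble with columns `t`, `mmhg200_t`, `mmhg198_t`.
#' @export
simulate_simplified_tracers <- function(km, kd, ihg200_0 = 4, mmhg198_0 = 4, t) {
  check_rates(km, kd)
  if (any(t < 0)) abort("`t` must be non-negative.")
  tibble(
    t = t,
    mmhg200_t = ihg200_0 * (1 - exp(-km * t)),
    mmhg198_t = mmhg198_0 * exp(-kd * t)
  )
}

check_rates <- function(km, kd) {
  if (any(!is.finite(km)) || any(!is.finite(kd)) || any(km < 0) || any(kd < 0)) {
    abort("Rate constants `km` and `kd` must be finite and non-negative.")
  }
  invisible(NULL)
}
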