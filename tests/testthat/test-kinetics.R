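test_that("coupled tracer model conserves mass and matches an ODE integrator", {
  skip_if_not_installed("deSolve")
  # closed form vs numerical integration of dB/dt = km*A - kd*B, A = total - B
  cases <- expand.grid(km = c(0, 5.9e-3, 0.2, 1.5), kd = c(0, 0.3, 1.78))
  for (i in seq_len(nrow(cases))) {
    km <- cases$km[i]
    kd <- cases$kd[i]
    out <- simulate_coupled_tracers(km, kd, ihg200_0 = 4, mmhg198_0 = 4, t = 2)
    # mass conservation, both pools
    expect_equal(out$mmhg200_t + out$ihg200_t, 4, tolerance = 1e-12)
    expect_equal(out$mmhg198_t + out$ihg198_t, 4, tolerance = 1e-12)
    ode <- deSolve::ode(
      y = c(b200 = 0, b198 = 4),
      times = c(0, 2),
      func = function(t, y, p) {
        list(c(
          p["km"] * (4 - y["b200"]) - p["kd"] * y["b200"],
          p["km"] * (4 - y["b198"]) - p["kd"] * y["b198"]
        ))
      },
      parms = c(km = km, kd = kd),
      rtol = 1e-12, atol = 1e-14
    )
    expect_equal(out$mmhg200_t, unname(ode[2, "b200"]), tolerance = 1e-8)
    expect_equal(out$mmhg198_t, unname(ode[2, "b198"]), tolerance = 1e-8)
  }
})

test_that("coupled model degenerate and limiting behaviour", {
  # no reaction: pools unchanged
  out <- simulate_coupled_tracers(0, 0, ihg200_0 = 4, mmhg198_0 = 4, t = 2)
  expect_equal(out$mmhg200_t, 0)
  expect_equal(out$ihg200_t, 4)
  expect_equal(out$mmhg198_t, 4)
  # equal rates equilibrate each pool to half its total
  out <- simulate_coupled_tracers(0.7, 0.7, ihg200_0 = 4, mmhg198_0 = 4, t = 1e4)
  expect_equal(out$mmhg200_t, 2, tolerance = 1e-9)
  expect_equal(out$mmhg198_t, 2, tolerance = 1e-9)
  expect_error(simulate_coupled_tracers(0.1, 0.1, t = -1), "non-negative")
  expect_error(simulate_coupled_tracers(-0.1, 0.1, t = 1), "non-negative")
})

test_that("simplified forward maps match independent series evaluation", {
  # product growth: 4 * (1 - exp(-km t)) via truncated exponential series
  series_exp <- function(x, n = 30) sum((-x)^(0:n) / factorial(0:n))
  out <- simulate_simplified_tracers(km = 5.9e-3, kd = 1.78, t = 2)
  expect_equal(out$mmhg200_t, 4 * (1 - series_exp(0.0118)), tolerance = 1e-10)
  expect_equal(out$mmhg198_t, 4 * series_exp(3.56), tolerance = 1e-10)
  expect_equal(out$mmhg200_t, 0.0469226, tolerance = 1e-5)
  expect_equal(out$mmhg198_t, 0.113755, tolerance = 1e-5)
  expect_equal(simulate_simplified_tracers(0, 1, t = 2)$mmhg200_t, 0)
})

test_that("rate estimators invert the simplified model exactly (round trip)", {
  t <- 2
  for (km_t in c(1e-4, 0.0118, 0.5, 2, 4.9)) {
    km <- km_t / t
    fwd <- simulate_simplified_tracers(km, 0, t = t)
    est <- estimate_km(make_incubation(fwd$mmhg200_t, 4, t = t, lod = 1e-15))
    expect_true(est$detected)
    expect_equal(est$value, km, tolerance = 1e-12)
  }
  for (kd_t in c(1e-4, 0.5, 3.56, 9.9)) {
    kd <- kd_t / t
    fwd <- simulate_simplified_tracers(0, kd, t = t)
    est <- estimate_kd(make_incubation(0.001, fwd$mmhg198_t, t = t))
    expect_equal(est$value, kd, tolerance = 1e-12)
  }
})

test_that("detection-limit censoring and error handling in estimate_km", {
  # at the detection limit: censored, no rate
  est <- estimate_km(make_incubation(0.01, 4, lod = 0.01))
  expect_false(est$detected)
  expect_true(is.na(est$value))
  # NA measurement (censored upstream) also treated as non-detect
  est <- estimate_km(make_incubation(NA_real_, 4))
  expect_false(est$detected)
  # impossible measurement: product exceeds the spike
  expect_error(estimate_km(make_incubation(4.1, 4)), "impossible")
  expect_error(estimate_km(make_incubation(4, 4)), "impossible")
  # small-signal limit: first-order agreement with mmhg200_t / (spike * t)
  m <- 4 * 1e-5
  est <- estimate_km(make_incubation(m, 4, t = 2, lod = 1e-9))
  expect_equal(est$value, m / (4 * 2), tolerance = 1e-4)
})

test_that("estimate_kd handles no-decay, gain clamping, and zero input", {
  expect_equal(estimate_kd(make_incubation(0.1, 4))$value, 0)
  expect_warning(
    est <- estimate_kd(make_incubation(0.1, 4.5)),
    "clamped"
  )
  expect_equal(est$value, 0)
  expect_error(estimate_kd(make_incubation(0.1, 0)), "logarithm undefined")
})

test_that("estimator bias under the coupled model: km underestimated when kd > 0", {
  true_km <- 5.9e-3
  coupled <- simulate_coupled_tracers(true_km, 1.78, t = 2)
  est <- estimate_km(make_incubation(coupled$mmhg200_t, 4))
  expect_lt(est$value, true_km)
  expect_equal(est$value, 1.608e-3, tolerance = 1e-3)
  # no demethylation: no bias
  coupled0 <- simulate_coupled_tracers(true_km, 0, t = 2)
  est0 <- estimate_km(make_incubation(coupled0$mmhg200_t, 4))
  expect_equal(est0$value, true_km, tolerance = 1e-12)
})

test_that("site summaries average detected replicates and report censoring", {
  est <- tibble::tibble(
    site_id = "w", replicate_id = paste0("r", 1:3), kind = "methylation",
    value = c(2.5e-3, 5.9e-3, 9.3e-3), detected = TRUE
  )
  s <- summarize_site_rates(est)
  expect_equal(s$mean, 5.9e-3)
  expect_equal(s$se, sd(c(2.5e-3, 5.9e-3, 9.3e-3)) / sqrt(3))
  expect_equal(s$se, 1.963e-3, tolerance = 1e-3)

  # identical detected values: zero spread
  est$value <- 5e-3
  expect_equal(summarize_site_rates(est)$se, 0)

  # two non-detects and one detect: mean is the lone detect
  est2 <- est
  est2$detected <- c(FALSE, TRUE, FALSE)
  est2$value <- c(NA, 4e-3, NA)
  s2 <- summarize_site_rates(est2)
  expect_equal(s2$mean, 4e-3)
  expect_equal(s2$n_detected, 1L)
  expect_equal(s2$n_total, 3L)
  # all censored: undefined mean, counts still reported
  est3 <- est2
  est3$detected <- FALSE
  est3$value <- NA_real_
  s3 <- summarize_site_rates(est3)
  expect_true(is.na(s3$mean))
  expect_equal(s3$n_detected, 0L)
  # selectable policy: non-detects as zeros
  s4 <- summarize_site_rates(est2, nondetect_as_zero = TRUE)
  expect_equal(s4$mean, 4e-3 / 3)
  expect_error(summarize_site_rates(est[0, ]), "No rate estimates")
})

test_that("site ANOVA matches hand-computed sums of squares and F density", {
  est <- tibble::tibble(
    site_id = rep(c("a", "b"), each = 3),
    value = c(1, 2, 3, 4, 5, 6),
    detected = TRUE
  )
  fit <- compare_sites_anova(est)
  # SSB = 13.5, SSW = 4 on (1, 4) df -> F = 13.5
  expect_equal(fit$f, 13.5)
  # p by numerical integration of the F(1, 4) density
  f_density <- function(x) df(x, 1, 4)
  p_num <- integrate(f_density, 13.5, Inf)$value
  expect_equal(fit$p, p_num, tolerance = 1e-6)
  expect_equal(fit$p, 0.0213, tolerance = 1e-2)
  expect_equal(nrow(tidy(fit)), 1L)
  expect_equal(glance(fit)$df, 1)

  # identical groups: no between-group variance
  est2 <- est
  est2$value <- rep(c(1, 2, 3), 2)
  fit2 <- compare_sites_anova(est2)
  expect_equal(fit2$f, 0)
  expect_equal(fit2$p, 1)

  # under-replicated group dropped with warning; < 2 usable groups errors
  est3 <- dplyr::bind_rows(est, tibble::tibble(
    site_id = "c", value = 9, detected = TRUE
  ))
  expect_warning(fit3 <- compare_sites_anova(est3), "Excluding")
  expect_equal(fit3$df[["between"]], 1)
  expect_error(
    suppressWarnings(compare_sites_anova(est[c(1, 4), ])),
    "at least two sites"
  )
})

test_that("ANOVA type-I error is near nominal under the null", {
  set.seed(42)
  n_sim <- 600
  rejections <- 0
  for (i in seq_len(n_sim)) {
    est <- tibble::tibble(
      site_id = rep(c("a", "b", "c"), each = 3),
      value = rnorm(9),
      detected = TRUE
    )
    if (compare_sites_anova(est)$p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / n_sim, 0.02)
  expect_lt(rejections / n_sim, 0.09)
})

test_that("km is recovered from noisy replicates (median over simulations)", {
  true_km <- 5.9e-3
  sites <- tibble::tibble(site_id = "w", km = true_km, kd = 1.78)
  medians <- vapply(1:300, function(i) {
    sim <- sim_tracer_experiment(
      sites, noise_cv = 0.1, model = "simplified", seed = i
    )
    est <- estimate_km(sim$samples)
    mean(est$value[est$detected])
  }, numeric(1))
  expect_equal(median(medians), true_km, tolerance = 0.05)
})
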