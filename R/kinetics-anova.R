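#' Compare rate constants between sites by one-way ANOVA
#'
#' One-way analysis of variance (via [stats::aov()]) of detected rate
#' estimates across sites, followed by Tukey HSD pairwise comparisons.
#' Sites contributing fewer than two detected values cannot inform the
#' within-group variance and are dropped with a warning.
#'
#' @param estimates A tibble with columns `site_id` and `value` (and
#'   optionally `detected`, used to drop censored replicates first), e.g. one
#'   `kind` of [estimate_rates()] output.
#' @param alpha Significance level used when flagging pairwise differences.
#' @return An object of class `hg_site_anova`: a list with `f`, `p`, `df`,
#'   `pairwise` (tibble: `contrast`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`), `alpha` and the fitted `aov`. `tidy()` returns the
#'   pairwise table, `glance()` the omnibus test.
#' @export
compare_sites_anova <- function(estimates, alpha = 0.05) {
  check_cols(estimates, c("site_id", "value"), "rate estimates")
  dat <- estimates
  if ("detected" %in% names(dat)) dat <- filter(dat, .data$detected)
  dat <- filter(dat, !is.na(.data$value))
  counts <- table(dat$site_id)
  thin <- names(counts)[counts < 2]
  if (length(thin) > 0) {
    warn(paste0(
      "Excluding site(s) with < 2 detected values from ANOVA: ",
      paste(thin, collapse = ", ")
    ))
    dat <- filter(dat, !.data$site_id %in% thin)
  }
  if (length(unique(dat$site_id)) < 2) {
    abort("ANOVA needs at least two sites with >= 2 detected values each.")
  }
  dat$site_id <- factor(dat$site_id)
  fit <- aov(value ~ site_id, data = dat)
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$site_id
  pairwise <- tibble(
    contrast = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  structure(
    list(
      f = tab[1, "F value"], p = tab[1, "Pr(>F)"],
      df = c(between = tab[1, "Df"], within = tab[2, "Df"]),
      pairwise = pairwise, alpha = alpha, fit = fit
    ),
    class = "hg_site_anova"
  )
}

#' @export
print.hg_site_anova <- function(x, ...) {
  cat(sprintf(
    "One-way site ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
    x$df[["between"]], x$df[["within"]], x$f, x$p
  ))
  cat(sprintf("Tukey HSD pairwise comparisons (alpha = %.2g):\n", x$alpha))
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_sites_anova
#' @param x An `hg_site_anova` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hg_site_anova <- function(x, ...) x$pairwise

#' @rdname compare_sites_anova
#' @exportS3Method generics::glance
glance.hg_site_anova <- function(x, ...) {
  tibble(
    statistic = x$f, p.value = x$p,
    df = x$df[["between"]], df.residual = x$df[["within"]]
  )
}
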