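#' Relative abundance of taxa at a rank
#'
#' Aggregates ASV counts by lineage at the requested rank and divides by the
#' sample total, so each sample's fractions sum to one. ASVs unassigned at
#' the rank are pooled into an `"unclassified"` taxon.
#'
#' @param counts Samples-by-ASV count tibble: first column `sample_id`, one
#'   integer column per ASV.
#' @param lineages Tibble mapping `asv_id` to lineage columns
#'   ([lineage_ranks()]).
#' @param rank Aggregation rank, e.g. `"phylum"` or `"family"`.
#' @return Tibble: `sample_id` plus one fraction column per taxon.
#' @export
relative_abundance <- function(counts, lineages, rank = "phylum") {
  rank <- match.arg(rank, lineage_ranks())
  check_cols(counts, "sample_id", "count table")
  check_cols(lineages, c("asv_id", rank), "lineage table")
  asvs <- setdiff(names(counts), "sample_id")
  missing <- setdiff(asvs, lineages$asv_id)
  if (length(missing) > 0) {
    abort(paste0("ASV(s) without a lineage entry: ", paste(missing, collapse = ", ")))
  }
  mat <- as.matrix(counts[asvs])
  if (any(mat < 0)) abort("Counts must be non-negative.")
  totals <- rowSums(mat)
  if (any(totals == 0)) {
    abort(paste0(
      "Zero-total sample(s): ",
      paste(counts$sample_id[totals == 0], collapse = ", ")
    ))
  }
  taxon <- lineages[[rank]][match(asvs, lineages$asv_id)]
  taxon <- ifelse(is.na(taxon) | taxon == "", "unclassified", taxon)
  agg <- t(rowsum(t(mat), group = taxon))
  frac <- sweep(agg, 1, totals, "/")
  dplyr::bind_cols(tibble(sample_id = counts$sample_id), as_tibble(frac))
}

#' Lump rare taxa into an "others" column
#'
#' Taxa whose mean fraction across the displayed samples falls strictly below
#' the threshold are merged into a single `"others"` column; row sums are
#' preserved. A taxon at exactly the threshold is kept.
#'
#' @param fractions Output of [relative_abundance()].
#' @param threshold Mean-fraction cutoff (default 0.02, i.e. 2%).
#' @return Same shape as `fractions`, rare columns replaced by `others`.
#' @export
lump_rare <- function(fractions, threshold = 0.02) {
  check_cols(fractions, "sample_id", "fraction table")
  taxa <- setdiff(names(fractions), "sample_id")
  mat <- as.matrix(fractions[taxa])
  rare <- colMeans(mat) < threshold
  if (!any(rare)) return(fractions)
  kept <- mat[, !rare, drop = FALSE]
  out <- dplyr::bind_cols(
    tibble(sample_id = fractions$sample_id),
    as_tibble(kept)
  )
  out$others <- rowSums(mat[, rare, drop = FALSE])
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC_{ij} = 1 - 2\sum_k \min(x_{ik}, x_{jk}) / \sum_k (x_{ik}+x_{jk})},
#' computed on relative abundances (the recommended input). Delegates to
#' [vegan::vegdist()].
#'
#' @param fractions Abundance tibble (`sample_id` + numeric columns) or a
#'   plain numeric matrix with row names.
#' @return A symmetric `dist` object labelled by sample id.
#' @export
bray_curtis <- function(fractions) {
  mat <- abundance_matrix(fractions)
  if (any(mat < 0)) abort("Abundances must be non-negative.")
  zero <- rowSums(mat) == 0
  if (sum(zero) >= 2) {
    abort(paste0(
      "Bray-Curtis undefined between all-zero samples: ",
      paste(rownames(mat)[zero], collapse = ", ")
    ))
  }
  vegan::vegdist(mat, method = "bray")
}

abundance_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  check_cols(x, "sample_id", "abundance table")
  mat <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(mat) <- x$sample_id
  mat
}

#' Principal-coordinate analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of \eqn{-D^2/2} and
#' eigendecomposition (via [stats::cmdscale()]). Coordinates are eigenvectors
#' scaled by the square root of their eigenvalues; axes with non-positive
#' eigenvalues are dropped, and explained fractions are taken over the
#' positive eigenvalues only.
#'
#' @param d A `dist` or symmetric distance matrix with labels.
#' @param k Maximum number of axes to keep (default all positive ones).
#' @return An `hg_pcoa` object: list with `coordinates` (tibble `sample_id`,
#'   `axis1`, `axis2`, ...), `eigenvalues`, `explained_fraction`. Supports
#'   `tidy()` and `autoplot()`.
#' @export
pcoa_ordination <- function(d, k = NULL) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) abort("Distance matrix must be symmetric.")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  # cmdscale warns when non-Euclidean distances yield negative eigenvalues;
  # those axes are handled explicitly below
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  pos <- fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig))
  n_axes <- sum(pos)
  if (!is.null(k)) n_axes <- min(n_axes, k)
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(n_axes))
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))
  structure(
    list(
      coordinates = dplyr::bind_cols(tibble(sample_id = labels), as_tibble(coords)),
      eigenvalues = fit$eig[pos][seq_len(n_axes)],
      explained_fraction = (fit$eig[pos] / sum(fit$eig[pos]))[seq_len(n_axes)]
    ),
    class = "hg_pcoa"
  )
}

#' @export
print.hg_pcoa <- function(x, ...) {
  cat(sprintf(
    "PCoA: %d axes; first axes explain %s\n",
    length(x$eigenvalues),
    paste(sprintf("%.1f%%", 100 * head(x$explained_fraction, 3)), collapse = ", ")
  ))
  print(x$coordinates)
  invisible(x)
}

#' @rdname pcoa_ordination
#' @param x An `hg_pcoa` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hg_pcoa <- function(x, ...) x$coordinates

#' Permutational multivariate analysis of variance on a distance matrix
#'
#' One-way PERMANOVA: partitions the total sum of squared distances into
#' among- and within-group components,
#' \eqn{F = (SS_A/(a-1)) / (SS_W/(n-a))}, and obtains the p-value by
#' permuting group labels. The observed statistic is included in the
#' reference set, \eqn{p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})}, so the
#' smallest attainable p with 999 permutations is 1/1000. With a fixed seed
#' the result is reproducible bit for bit.
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param groups Group label per sample, or a metadata tibble with
#'   `sample_id` plus the column named by `factor_name`.
#' @param factor_name Column of `groups` to test when a tibble is given.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return An `hg_permanova` object with `pseudo_f`, `r2`, `p`, `n_perm`,
#'   `df`; supports `tidy()` and `glance()`.
#' @export
permanova <- function(d, groups, factor_name = NULL, n_perm = 999, seed = 1L) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) abort("Distance matrix must be symmetric.")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  if (is.data.frame(groups)) {
    check_cols(groups, c("sample_id", factor_name %||% "group"), "metadata")
    labels <- attr(d, "Labels")
    groups <- groups[[factor_name %||% "group"]][match(labels, groups$sample_id)]
  }
  if (length(groups) != n) abort("One group label per sample is required.")
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) < 2) abort("PERMANOVA needs at least two groups.")
  if (any(table(g) < 2)) abort("Each group needs at least two samples.")

  d2 <- as.matrix(d)^2
  f_obs <- permanova_f(d2, g)
  set.seed(seed)
  f_perm <- vapply(
    seq_len(n_perm),
    function(i) permanova_f(d2, sample(g)),
    numeric(1)
  )
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- within_ss(d2, g)
  structure(
    list(
      pseudo_f = f_obs,
      r2 = (ss_t - ss_w) / ss_t,
      p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
      n_perm = n_perm,
      df = c(among = nlevels(droplevels(g)) - 1L, within = n - nlevels(droplevels(g))),
      seed = seed
    ),
    class = "hg_permanova"
  )
}

within_ss <- function(d2, g) {
  sum(vapply(levels(g), function(lv) {
    idx <- which(g == lv)
    if (length(idx) < 2) return(0)
    sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }, numeric(1)))
}

permanova_f <- function(d2, g) {
  n <- nrow(d2)
  a <- nlevels(droplevels(g))
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- within_ss(d2, g)
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

#' @export
print.hg_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F(%d, %d) = %.4g, R2 = %.3f, p = %.4g (%d permutations)\n",
    x$df[["among"]], x$df[["within"]], x$pseudo_f, x$r2, x$p, x$n_perm
  ))
  invisible(x)
}

#' @rdname permanova
#' @param x An `hg_permanova` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hg_permanova <- function(x, ...) {
  tibble(
    term = "group", df = x$df[["among"]], pseudo_f = x$pseudo_f,
    r2 = x$r2, p.value = x$p
  )
}

#' @rdname permanova
#' @exportS3Method generics::glance
glance.hg_permanova <- function(x, ...) {
  tibble(pseudo_f = x$pseudo_f, r2 = x$r2, p.value = x$p, n_perm = x$n_perm)
}
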