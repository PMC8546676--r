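toy_counts <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2"),
    a1 = c(30L, 10L), a2 = c(70L, 40L), a3 = c(0L, 50L)
  )
}

toy_lineages <- function() {
  tibble::tibble(
    asv_id = c("a1", "a2", "a3"),
    domain = "Bacteria",
    phylum = c("Proteobacteria", "Proteobacteria", NA),
    class = NA_character_, order = NA_character_, family = NA_character_
  )
}

test_that("relative abundance aggregates by rank and pools unassigned ASVs", {
  frac <- relative_abundance(toy_counts(), toy_lineages(), "phylum")
  expect_equal(frac$Proteobacteria, c(1.0, 0.5))
  expect_equal(frac$unclassified, c(0, 0.5))
  expect_equal(rowSums(as.matrix(frac[-1])), c(1, 1), ignore_attr = TRUE)

  # single sample, two taxa at 30/70
  one <- tibble::tibble(sample_id = "s", x = 30L, y = 70L)
  lin <- tibble::tibble(
    asv_id = c("x", "y"), domain = "Bacteria", phylum = c("A", "B"),
    class = NA, order = NA, family = NA
  )
  f1 <- relative_abundance(one, lin, "phylum")
  expect_equal(f1$A, 0.3)
  expect_equal(f1$B, 0.7)

  zero <- toy_counts()
  zero[2, -1] <- 0L
  expect_error(relative_abundance(zero, toy_lineages()), "s2")
  expect_error(
    relative_abundance(dplyr::rename(toy_counts(), zz = a3), toy_lineages()),
    "zz"
  )
})

test_that("generated community recovers its planted phylum fractions", {
  # low-dispersion, high-depth regime so the site means converge on the
  # planted compositions
  asv <- sim_asv_table(depth = 50000, concentration = 2500,
                       n_per_treatment = 6, seed = 3)
  frac <- relative_abundance(asv$counts, asv$lineages, "phylum")
  obs <- dplyr::left_join(asv$metadata, frac, by = "sample_id") |>
    dplyr::group_by(site) |>
    dplyr::summarise(obs = mean(Proteobacteria))
  truth <- dplyr::filter(asv$truth, phylum == "Proteobacteria")
  merged <- dplyr::left_join(obs, truth, by = "site")
  expect_lt(max(abs(merged$obs - merged$fraction)), 0.01)
})

test_that("rare-taxon lumping is strict at the threshold and preserves sums", {
  frac <- tibble::tibble(
    sample_id = c("s1", "s2"),
    big = c(0.95, 0.97),
    borderline = c(0.02, 0.02), # mean exactly 2%: kept
    rare = c(0.03, 0.008)       # mean 1.9%: merged
  )
  out <- lump_rare(frac, threshold = 0.02)
  expect_true("borderline" %in% names(out))
  expect_false("rare" %in% names(out))
  expect_equal(out$others, frac$rare)
  expect_equal(rowSums(as.matrix(out[-1])), rowSums(as.matrix(frac[-1])))

  # nothing rare: unchanged
  expect_identical(lump_rare(frac, threshold = 0.001), frac)
  # everything rare: single others column summing to 1
  tiny <- tibble::tibble(sample_id = "s", a = 0.4, b = 0.6)
  all_lumped <- lump_rare(tiny, threshold = 0.7)
  expect_equal(names(all_lumped), c("sample_id", "others"))
  expect_equal(all_lumped$others, 1)
})

test_that("Bray-Curtis matches the double-loop oracle and its bounds", {
  u <- c(10, 0, 5)
  v <- c(5, 5, 5)
  m <- rbind(s1 = u, s2 = v)
  d <- bray_curtis(m)
  expect_equal(as.numeric(d), 1 - 20 / 30)
  expect_equal(as.numeric(d), bc_oracle(u, v))

  expect_equal(as.numeric(bray_curtis(rbind(a = u, b = u))), 0)
  expect_equal(as.numeric(bray_curtis(rbind(a = c(1, 0), b = c(0, 2)))), 1)

  set.seed(11)
  mat <- matrix(rpois(8 * 12, 20), nrow = 8,
                dimnames = list(paste0("s", 1:8), NULL))
  got <- as.matrix(bray_curtis(mat))
  expect_equal(unname(got), unname(bc_matrix_oracle(mat)), tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
  expect_equal(got, t(got))
  expect_equal(diag(got), setNames(rep(0, 8), rownames(mat)))

  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(0, 0))), "all-zero")
})

test_that("PCoA reproduces geometry", {
  # two points at distance d: +/- d/2 on one axis
  d <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa_ordination(d)
  expect_equal(sort(ord$coordinates$axis1), c(-0.4, 0.4))
  expect_equal(ord$explained_fraction, 1)

  # Euclidean distances of known planar points are reproduced exactly
  set.seed(4)
  pts <- matrix(rnorm(12 * 2), ncol = 2)
  rownames(pts) <- paste0("p", 1:12)
  d_eu <- dist(pts)
  ord2 <- pcoa_ordination(d_eu)
  coords <- as.matrix(ord2$coordinates[-1])
  expect_equal(as.numeric(dist(coords)), as.numeric(d_eu), tolerance = 1e-9)
  expect_true(all(diff(ord2$explained_fraction) <= 1e-12))
  expect_lte(sum(ord2$explained_fraction), 1 + 1e-12)

  # coincident samples land on the same spot
  d3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d3["a", "c"] <- d3["c", "a"] <- 1
  d3["b", "c"] <- d3["c", "b"] <- 1
  ord3 <- pcoa_ordination(d3)
  cc <- as.matrix(ord3$coordinates[-1])
  rownames(cc) <- ord3$coordinates$sample_id
  expect_equal(cc["a", ], cc["b", ], tolerance = 1e-9)

  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA statistic agrees with adonis2 and the oracle", {
  asv <- sim_asv_table(n_per_treatment = 1, depth = 2000, seed = 8) # 9 samples
  mat <- as.matrix(asv$counts[-1])
  rownames(mat) <- asv$counts$sample_id
  d <- bray_curtis(sweep(mat, 1, rowSums(mat), "/"))
  pm <- permanova(d, asv$metadata, factor_name = "site", n_perm = 199, seed = 3)

  expect_equal(pm$pseudo_f, permanova_f_oracle(d, asv$metadata$site))
  ad <- vegan::adonis2(d ~ site, data = as.data.frame(asv$metadata),
                       permutations = 199)
  expect_equal(pm$pseudo_f, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$r2, ad$R2[1], tolerance = 1e-10)

  # bit-reproducible under a fixed seed; invariant to group renaming
  pm2 <- permanova(d, asv$metadata, factor_name = "site", n_perm = 199, seed = 3)
  expect_identical(pm$p, pm2$p)
  relabeled <- chartr("nfw", "xyz", asv$metadata$site)
  pm3 <- permanova(d, relabeled, n_perm = 199, seed = 3)
  expect_identical(pm$p, pm3$p)
})

test_that("PERMANOVA p-value conventions and degenerate inputs", {
  # perfectly separated groups (between-distances 1, within 0): the observed
  # split is extreme among permutations, so p hits the permutation floor
  n <- 16
  d <- matrix(1, n, n) - diag(n)
  d[1:8, 1:8] <- 0
  d[9:16, 9:16] <- 0
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  g <- rep(c("a", "b"), each = 8)
  pm <- permanova(d, g, n_perm = 999, seed = 1)
  expect_equal(pm$p, 1 / 1000)
  expect_equal(pm$r2, 1, tolerance = 1e-12)

  expect_error(permanova(d, rep("a", n)), "two groups")
  expect_error(permanova(d, c(rep("a", n - 1), "b")), "two samples")
})

test_that("site signal is detected and shuffled treatment labels are not", {
  asv <- sim_asv_table(seed = 21)
  mat <- as.matrix(asv$counts[-1])
  rownames(mat) <- asv$counts$sample_id
  d <- bray_curtis(sweep(mat, 1, rowSums(mat), "/"))
  pm_site <- permanova(d, asv$metadata, factor_name = "site",
                       n_perm = 999, seed = 21)
  expect_lte(pm_site$p, 0.001)
  pm_trt <- permanova(d, asv$metadata, factor_name = "treatment",
                      n_perm = 999, seed = 21)
  expect_gt(pm_trt$p, 0.05)
})
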