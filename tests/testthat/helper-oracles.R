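# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Bray-Curtis by explicit double loop over taxa.
bc_oracle <- function(u, v) {
  num <- 0
  den <- 0
  for (k in seq_along(u)) {
    num <- num + 2 * min(u[k], v[k])
    den <- den + u[k] + v[k]
  }
  1 - num / den
}

bc_matrix_oracle <- function(mat) {
  n <- nrow(mat)
  out <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) out[i, j] <- bc_oracle(mat[i, ], mat[j, ])
    }
  }
  out
}

# PERMANOVA pseudo-F from first principles (per-pair squared distances).
permanova_f_oracle <- function(d, groups) {
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  g <- as.factor(groups)
  ss_t <- sum(dm[upper.tri(dm)]) / n
  ss_w <- 0
  for (lv in levels(g)) {
    idx <- which(g == lv)
    sub <- dm[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  a <- nlevels(g)
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# Clade assignment by exhaustive clade enumeration: list every clade (tip set
# of every internal node), keep those containing the query plus >= 1
# reference tip, pick the smallest, and check rank-name unanimity.
clade_oracle <- function(tree, leaf_taxa, query, query_leaves, rank) {
  n_tip <- length(tree$tip.label)
  nodes <- (n_tip + 1):(n_tip + tree$Nnode)
  tipsets <- lapply(nodes, function(nd) {
    tree$tip.label[unlist(phangorn::Descendants(tree, nd, type = "tips"))]
  })
  keep <- vapply(tipsets, function(ts) {
    query %in% ts && length(setdiff(ts, query_leaves)) > 0
  }, logical(1))
  if (!any(keep)) return(NA_character_)
  sizes <- vapply(tipsets, length, integer(1))
  best <- tipsets[keep][[which.min(sizes[keep])]]
  refs <- setdiff(best, query_leaves)
  names_at_rank <- leaf_taxa[[rank]][match(refs, leaf_taxa$leaf)]
  u <- unique(names_at_rank)
  if (length(u) == 1 && !is.na(u)) u else NA_character_
}

# Exact substring motif scan by sliding window.
motif_scan_oracle <- function(sequence, motifs) {
  n <- nchar(sequence)
  best_pos <- Inf
  best_motif <- NA_character_
  for (m in motifs) {
    w <- nchar(m)
    if (n < w) next
    for (i in seq_len(n - w + 1)) {
      if (substr(sequence, i, i + w - 1) == m) {
        if (i < best_pos) {
          best_pos <- i
          best_motif <- m
        }
        break
      }
    }
  }
  list(found = is.finite(best_pos), motif = best_motif)
}

# Small tracer incubation tibble builder used by the kinetics tests.
make_incubation <- function(mmhg200_t, mmhg198_t, t = 2, spike = 4,
                            lod = 0.01, site = "site", rep_id = NULL) {
  n <- max(length(mmhg200_t), length(mmhg198_t))
  tibble::tibble(
    site_id = site,
    replicate_id = rep_id %||% paste0("r", seq_len(n)),
    ihg200_0 = spike,
    mmhg198_0 = spike,
    mmhg200_t = rep_len(mmhg200_t, n),
    mmhg198_t = rep_len(mmhg198_t, n),
    t_days = t,
    lod_mmhg = lod
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
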