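#' Taxonomic ranks used throughout the package
#'
#' Lineages are tibble columns named after these ranks, filled top-down;
#' `NA` means unassigned at that rank.
#'
#' @return `c("domain", "phylum", "class", "order", "family")`
#' @export
lineage_ranks <- function() c("domain", "phylum", "class", "order", "family")

#' Filter similarity hits on E-value, identity and query coverage
#'
#' Retains hits passing all three thresholds (inclusive bounds), preserving
#' input order. Defaults are E <= 1e-20, identity >= 40%, query coverage
#' >= 80%.
#'
#' @param hits Tibble with columns `evalue`, `percent_identity`,
#'   `query_coverage` (see [read_similarity_hits()]).
#' @param max_evalue,min_identity,min_qcov Thresholds.
#' @return The retained subset of `hits`.
#' @export
filter_hits <- function(hits, max_evalue = 1e-20, min_identity = 40, min_qcov = 80) {
  check_cols(hits, c("evalue", "percent_identity", "query_coverage"), "similarity hits")
  filter(
    hits,
    .data$evalue <= max_evalue,
    .data$percent_identity >= min_identity,
    .data$query_coverage >= min_qcov
  )
}

#' Assign taxonomy from filtered similarity hits
#'
#' For each query, the best remaining hit by bit score wins. When several
#' hits tie for the top bit score but disagree taxonomically, the lowest
#' common ancestor of the tied hits is taken rank by rank, so the assignment
#' may stop above the requested rank. Queries without passing hits are
#' reported unassigned at every rank.
#'
#' @param hits Filtered hits carrying `query_id`, `bit_score` and lineage
#'   columns ([lineage_ranks()]) of each subject.
#' @param queries Optional character vector of query ids to report (ensures
#'   hitless queries appear as unassigned rows).
#' @param rank Rank whose label is copied into the `taxon` column.
#' @return Tibble: `query_id`, lineage columns, `taxon`.
#' @export
similarity_assign <- function(hits, queries = NULL, rank = "family") {
  rank <- match.arg(rank, lineage_ranks())
  check_cols(hits, c("query_id", "bit_score", lineage_ranks()), "similarity hits")
  assigned <- hits |>
    group_by(.data$query_id) |>
    dplyr::group_modify(function(g, key) {
      top <- g[g$bit_score == max(g$bit_score), , drop = FALSE]
      lineage_lca(top)
    }) |>
    ungroup()
  if (!is.null(queries)) {
    missing <- setdiff(queries, assigned$query_id)
    if (length(missing) > 0) {
      blank <- tibble(query_id = missing)
      for (r in lineage_ranks()) blank[[r]] <- NA_character_
      assigned <- bind_rows(assigned, blank)
    }
    assigned <- assigned[match(queries, assigned$query_id), , drop = FALSE]
  }
  assigned$taxon <- assigned[[rank]]
  assigned
}

# Rank-wise lowest common ancestor of a set of lineages: keep a rank's name
# while all rows agree on one non-NA value; blank that rank and below at the
# first disagreement (top-down fill invariant).
lineage_lca <- function(lineages) {
  out <- tibble(.rows = 1)
  broken <- FALSE
  for (r in lineage_ranks()) {
    vals <- unique(lineages[[r]])
    keep <- !broken && length(vals) == 1 && !is.na(vals[1])
    out[[r]] <- if (keep) vals[1] else NA_character_
    if (!keep) broken <- TRUE
  }
  out
}

#' Assign taxonomy by phylogenetic clade placement
#'
#' Each query leaf is assigned from the smallest ancestral clade that
#' contains at least one reference leaf (other query leaves are ignored
#' during clade inspection). If every reference leaf in that clade carries
#' the same name at a rank, the query inherits it; a mixed clade leaves the
#' rank unassigned. The tree is used rooted exactly as written.
#'
#' @param tree An [ape::read.tree()] `phylo` object (or Newick file path).
#' @param leaf_taxa Tibble mapping reference leaves to lineages: columns
#'   `leaf` plus [lineage_ranks()].
#' @param query_leaves Character vector of query leaf labels present in the
#'   tree.
#' @param rank Rank whose label is copied into the `taxon` column.
#' @return Tibble: `query_id`, lineage columns (clade consensus per rank),
#'   `taxon`.
#' @export
clade_assign <- function(tree, leaf_taxa, query_leaves, rank = "family") {
  rank <- match.arg(rank, lineage_ranks())
  if (is.character(tree)) tree <- ape::read.tree(tree)
  check_cols(leaf_taxa, c("leaf", lineage_ranks()), "leaf taxonomy")
  absent <- setdiff(query_leaves, tree$tip.label)
  if (length(absent) > 0) {
    abort(paste0("Query leaves absent from the tree: ", paste(absent, collapse = ", ")))
  }
  ref_tips <- setdiff(tree$tip.label, query_leaves)
  no_lineage <- setdiff(ref_tips, leaf_taxa$leaf)
  if (length(no_lineage) > 0) {
    abort(paste0(
      "Reference leaves without a lineage: ", paste(no_lineage, collapse = ", ")
    ))
  }
  rows <- purrr::map(query_leaves, function(q) {
    tips <- clade_reference_tips(tree, q, query_leaves)
    lin <- clade_consensus_lineage(leaf_taxa, tips)
    dplyr::bind_cols(tibble(query_id = q), lin)
  })
  out <- bind_rows(rows)
  out$taxon <- out[[rank]]
  out
}

# Reference tips of the smallest ancestral clade of `q` holding >= 1
# reference leaf; character(0) when no such clade exists (query-only tree).
clade_reference_tips <- function(tree, q, query_leaves) {
  tip <- match(q, tree$tip.label)
  node <- tip
  repeat {
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(parent) == 0) return(character(0)) # reached above the root
    tips <- tree$tip.label[tip_descendants(tree, parent)]
    refs <- setdiff(tips, query_leaves)
    if (length(refs) > 0) return(refs)
    node <- parent
  }
}

tip_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    cur <- stack[[1]]
    stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}

clade_consensus_lineage <- function(leaf_taxa, tips) {
  if (length(tips) == 0) {
    lin <- tibble(.rows = 1)
    for (r in lineage_ranks()) lin[[r]] <- NA_character_
    return(lin)
  }
  lineage_lca(leaf_taxa[match(tips, leaf_taxa$leaf), , drop = FALSE])
}

#' Consensus between similarity and clade taxonomy assignments
#'
#' Joins the two assignments per query and compares labels at one rank.
#' Agreement means equal labels, with both-unassigned counting as agreement.
#' The consensus label is the shared one; where the two routes disagree the
#' similarity label is retained but flagged hypothetical (the tree could not
#' corroborate it).
#'
#' @param similarity Output of [similarity_assign()] (`query_id`, `taxon`).
#' @param tree Output of [clade_assign()] (`query_id`, `taxon`).
#' @param rank Comparison rank (the `taxon` columns must have been produced
#'   at this rank); recorded in the result.
#' @return An `hg_consensus` object: list with `records` (tibble `query_id`,
#'   `tax_similarity`, `tax_tree`, `agree`, `tax_consensus`, `hypothetical`),
#'   `agreement_pct`, `rank`. `tidy()` returns the records, `glance()` the
#'   agreement summary.
#' @export
consensus_compare <- function(similarity, tree, rank = "family") {
  check_cols(similarity, c("query_id", "taxon"), "similarity assignments")
  check_cols(tree, c("query_id", "taxon"), "tree assignments")
  rec <- dplyr::full_join(
    select(similarity, "query_id", tax_similarity = "taxon"),
    select(tree, "query_id", tax_tree = "taxon"),
    by = "query_id"
  )
  if (nrow(rec) == 0) abort("No records to compare.")
  both_na <- is.na(rec$tax_similarity) & is.na(rec$tax_tree)
  same <- !is.na(rec$tax_similarity) & !is.na(rec$tax_tree) &
    rec$tax_similarity == rec$tax_tree
  rec$agree <- both_na | same
  rec$tax_consensus <- ifelse(rec$agree, rec$tax_similarity, rec$tax_similarity)
  rec$hypothetical <- !rec$agree & !is.na(rec$tax_similarity)
  structure(
    list(
      records = rec,
      agreement_pct = 100 * sum(rec$agree) / nrow(rec),
      rank = rank
    ),
    class = "hg_consensus"
  )
}

#' @export
print.hg_consensus <- function(x, ...) {
  cat(sprintf(
    "Taxonomy consensus at rank '%s': %d/%d agree (%.1f%%)\n",
    x$rank, sum(x$records$agree), nrow(x$records), x$agreement_pct
  ))
  print(x$records)
  invisible(x)
}

#' @rdname consensus_compare
#' @param x An `hg_consensus` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hg_consensus <- function(x, ...) x$records

#' @rdname consensus_compare
#' @exportS3Method generics::glance
glance.hg_consensus <- function(x, ...) {
  tibble(
    n = nrow(x$records), n_agree = sum(x$records$agree),
    agreement_pct = x$agreement_pct, rank = x$rank
  )
}
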