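#' Read a tracer-incubation TSV
#'
#' Expected columns: `site_id`, `replicate_id`, `ihg200_0`, `mmhg198_0`,
#' `mmhg200_t`, `mmhg198_t`, `t_days`, `lod_mmhg`. Empty `mmhg200_t` cells
#' are censored measurements.
#'
#' @param path TSV path.
#' @return Tracer tibble for [estimate_rates()].
#' @export
read_tracer_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  check_cols(
    out,
    c("site_id", "replicate_id", "ihg200_0", "mmhg198_0", "mmhg200_t",
      "mmhg198_t", "t_days", "lod_mmhg"),
    "tracer TSV"
  )
  out
}

#' Read similarity hits in 12/13-column tabular alignment format
#'
#' Columns follow BLAST tabular output (query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' E-value, bit score), optionally followed by a 13th query-coverage column.
#' Without the 13th column, `query_lengths` must be supplied so coverage can
#' be computed as `100 * (qend - qstart + 1) / qlen`.
#'
#' @param path Tabular hits path (no header).
#' @param subject_lineages Optional tibble (or TSV path) with `subject_id`
#'   plus [lineage_ranks()] columns, joined onto the hits.
#' @param query_lengths Optional named vector of query lengths (aa).
#' @return Tibble with `query_id`, `subject_id`, `percent_identity`,
#'   `evalue`, `bit_score`, `query_coverage` and any joined lineage columns.
#' @export
read_similarity_hits <- function(path, subject_lineages = NULL, query_lengths = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 12) abort("Similarity hits must have at least 12 columns.")
  hits <- tibble(
    query_id = as.character(raw[[1]]),
    subject_id = as.character(raw[[2]]),
    percent_identity = as.numeric(raw[[3]]),
    qstart = as.integer(raw[[7]]),
    qend = as.integer(raw[[8]]),
    evalue = as.numeric(raw[[11]]),
    bit_score = as.numeric(raw[[12]])
  )
  if (ncol(raw) >= 13) {
    hits$query_coverage <- as.numeric(raw[[13]])
  } else if (!is.null(query_lengths)) {
    qlen <- query_lengths[hits$query_id]
    if (any(is.na(qlen))) abort("Query lengths missing for some hits.")
    hits$query_coverage <- 100 * (hits$qend - hits$qstart + 1) / qlen
  } else {
    abort("Need a 13th query-coverage column or `query_lengths`.")
  }
  if (!is.null(subject_lineages)) {
    if (is.character(subject_lineages)) {
      subject_lineages <- readr::read_tsv(subject_lineages, show_col_types = FALSE)
    }
    check_cols(subject_lineages, c("subject_id", lineage_ranks()), "subject lineages")
    hits <- left_join(hits, subject_lineages, by = "subject_id")
  }
  select(hits, -"qstart", -"qend")
}

#' Read an ASV table triplet (counts, lineages, metadata)
#'
#' @param counts_path Counts TSV: `sample_id` column plus one column per ASV.
#' @param lineage_path Lineage TSV: `asv_id` plus [lineage_ranks()].
#' @param metadata_path Metadata TSV: `sample_id`, `site`, `treatment`,
#'   optionally `molecule`.
#' @return List with `counts`, `lineages`, `metadata` tibbles.
#' @export
read_asv_table <- function(counts_path, lineage_path, metadata_path) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE)
  lineages <- readr::read_tsv(lineage_path, show_col_types = FALSE)
  metadata <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  check_cols(counts, "sample_id", "counts TSV")
  check_cols(lineages, c("asv_id", lineage_ranks()), "lineage TSV")
  check_cols(metadata, c("sample_id", "site", "treatment"), "metadata TSV")
  no_meta <- setdiff(counts$sample_id, metadata$sample_id)
  if (length(no_meta) > 0) {
    abort(paste0("Samples without metadata: ", paste(no_meta, collapse = ", ")))
  }
  list(counts = counts, lineages = lineages, metadata = metadata)
}

#' Write the synthetic fixture files an analysis run consumes
#'
#' Materialises generator output ([sim_tracer_experiment()],
#' [sim_hgca_fixture()], [sim_reference_tree()], [sim_asv_table()]) as the
#' plain-text inputs of the corresponding readers.
#'
#' @param fixtures Named list with any of `tracer`, `hgca`, `tree`,
#'   `community` generator outputs.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixtures <- function(fixtures, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(obj, name) {
    p <- file.path(dir, name)
    readr::write_tsv(obj, p)
    paths[[name]] <<- p
  }
  if (!is.null(fixtures$tracer)) {
    emit(fixtures$tracer$samples, "tracer.tsv")
    emit(fixtures$tracer$truth, "tracer_truth.tsv")
  }
  if (!is.null(fixtures$hgca)) {
    h <- fixtures$hgca
    fa <- file.path(dir, "proteins.faa")
    Biostrings::writeXStringSet(h$fasta, fa)
    paths[["proteins.faa"]] <- fa
    emit(h$hmm_hits, "hmm_hits.tsv")
    emit(h$coverage, "coverage.tsv")
    emit(h$subject_lineages, "subject_lineages.tsv")
    readr::write_tsv(h$similarity_hits, file.path(dir, "similarity_hits.tsv"),
                     col_names = FALSE)
    paths[["similarity_hits.tsv"]] <- file.path(dir, "similarity_hits.tsv")
  }
  if (!is.null(fixtures$tree)) {
    tr <- file.path(dir, "reference_tree.nwk")
    ape::write.tree(fixtures$tree$tree, tr)
    paths[["reference_tree.nwk"]] <- tr
    emit(fixtures$tree$leaf_taxa, "leaf_taxa.tsv")
    emit(tibble(query_id = fixtures$tree$query_leaves), "query_leaves.tsv")
  }
  if (!is.null(fixtures$community)) {
    emit(fixtures$community$counts, "asv_counts.tsv")
    emit(fixtures$community$lineages, "asv_lineages.tsv")
    emit(fixtures$community$metadata, "sample_metadata.tsv")
  }
  invisible(paths)
}
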