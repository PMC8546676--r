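#' Conserved HgcA cap-helix motifs
#'
#' The discrete 8-residue cap-helix motif variants whose exact presence marks
#' a complete HgcA corrinoid-binding region.
#'
#' @return Character vector of six 8-mers.
#' @export
hgca_motifs <- function() {
  c("NVWCAAGK", "NVWCASGK", "NVWCAGGK", "NIWCAAGK", "NIWCAGGK", "NVWCSAGK")
}

#' Screening configuration for HgcA candidates
#'
#' Bit-score thresholds and motif set for classifying profile-search hits.
#' Scores >= `min_score_complete` together with a motif mark complete HgcA;
#' scores >= `min_score_candidate` mark partial sequences that align well but
#' miss the motif region (typically because the contig is too short); lower
#' scores are rejected.
#'
#' @param min_score_candidate Candidate bit-score threshold (default 100).
#' @param min_score_complete Complete-sequence bit-score threshold (default 164).
#' @param motifs Character vector of exact 8-mer motifs.
#' @return A list of class `hgca_screen_config`.
#' @export
screen_config <- function(min_score_candidate = 100, min_score_complete = 164,
                          motifs = hgca_motifs()) {
  if (min_score_complete < min_score_candidate) {
    abort("`min_score_complete` must be >= `min_score_candidate`.")
  }
  if (any(nchar(motifs) != 8)) abort("All motifs must be 8 residues long.")
  structure(
    list(
      min_score_candidate = min_score_candidate,
      min_score_complete = min_score_complete,
      motifs = toupper(motifs)
    ),
    class = "hgca_screen_config"
  )
}

#' Join profile-search hits to their protein records
#'
#' Reads a protein FASTA and a profile-search hits table and joins them on
#' protein id. The hits table is either a two-plus-column TSV with a header
#' containing `protein_id` and `score` (full-sequence bit score), or raw
#' HMMER `--tblout` output (`format = "tblout"`; whitespace-delimited, `#`
#' comments, target in column 1, full-sequence score in column 6). Contig ids
#' are recovered from protein ids by stripping the trailing `_<gene index>`
#' unless the hits table already carries a `contig_id` column, and contig
#' coverage (mean read depth) is joined from `coverage` when given.
#'
#' @param hits_path Path to the hits table.
#' @param fasta_path Path to the predicted-protein FASTA.
#' @param coverage Optional coverage table (or TSV path) with columns
#'   `contig_id`, `mean_depth`.
#' @param format `"tsv"` (default) or `"tblout"`.
#' @return Tibble: `protein_id`, `contig_id`, `sequence`, `hmm_score`,
#'   `coverage` (NA when no coverage table given).
#' @export
parse_hmm_hits <- function(hits_path, fasta_path, coverage = NULL,
                           format = c("tsv", "tblout")) {
  format <- match.arg(format)
  hits <- if (format == "tblout") read_tblout(hits_path) else read_hits_tsv(hits_path)
  seqs <- Biostrings::readAAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(hits$protein_id, names(seqs))
  if (length(missing) > 0) {
    abort(paste0(
      "Hit id(s) absent from the protein FASTA: ",
      paste(missing, collapse = ", ")
    ))
  }
  out <- hits
  out$sequence <- unname(as.character(seqs[out$protein_id]))
  if (!"contig_id" %in% names(out)) {
    out$contig_id <- sub("_[0-9]+$", "", out$protein_id)
  }
  out$coverage <- NA_real_
  if (!is.null(coverage)) {
    cov <- if (is.character(coverage)) {
      readr::read_tsv(coverage, show_col_types = FALSE)
    } else {
      as_tibble(coverage)
    }
    check_cols(cov, c("contig_id", "mean_depth"), "coverage table")
    out$coverage <- cov$mean_depth[match(out$contig_id, cov$contig_id)]
  }
  select(out, "protein_id", "contig_id", "sequence", "hmm_score", "coverage")
}

read_hits_tsv <- function(path) {
  hits <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(hits) == 0 && !all(c("protein_id", "score") %in% names(hits))) {
    return(tibble(protein_id = character(), hmm_score = numeric()))
  }
  check_cols(hits, c("protein_id", "score"), "hmm hits table")
  if (any(is.na(hits$protein_id)) || any(is.na(suppressWarnings(as.numeric(hits$score))))) {
    bad <- which(is.na(hits$protein_id) | is.na(suppressWarnings(as.numeric(hits$score))))
    abort(paste0("Malformed hmm hits row(s) at line(s): ", paste(bad + 1, collapse = ", ")))
  }
  tibble(protein_id = as.character(hits$protein_id), hmm_score = as.numeric(hits$score))
}

read_tblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) return(tibble(protein_id = character(), hmm_score = numeric()))
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, 1L) < 6)
  if (length(bad) > 0) {
    abort(paste0("Malformed tblout row(s) at line(s): ", paste(bad, collapse = ", ")))
  }
  tibble(
    protein_id = vapply(fields, `[[`, "", 1L),
    hmm_score = as.numeric(vapply(fields, `[[`, "", 6L))
  )
}

#' Scan sequences for conserved HgcA motifs
#'
#' Exact substring search of each amino-acid sequence against the configured
#' motif set. When several motifs occur, the leftmost match wins; ties at the
#' same position are broken by motif list order.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param cfg A [screen_config()].
#' @return Tibble: `motif_found` (logical), `motif_hit` (the motif, or NA).
#' @export
scan_conserved_motifs <- function(sequence, cfg = screen_config()) {
  sequence <- toupper(sequence)
  pos <- vapply(cfg$motifs, function(m) {
    p <- stringr::str_locate(sequence, stringr::fixed(m))[, "start"]
    ifelse(is.na(p), Inf, p)
  }, numeric(length(sequence)))
  pos <- matrix(pos, nrow = length(sequence))
  best <- apply(pos, 1, which.min)
  found <- apply(pos, 1, min) < Inf
  tibble(
    motif_found = found,
    motif_hit = ifelse(found, cfg$motifs[best], NA_character_)
  )
}

#' Assign HgcA confidence tiers from score and motif presence
#'
#' @param score Numeric full-sequence bit scores.
#' @param motif_found Logical, conserved motif present.
#' @param cfg A [screen_config()].
#' @return Character vector: `"complete"`, `"partial"` or `"rejected"`.
#'   A score at or above the complete threshold without a motif is demoted to
#'   `"partial"` with a warning (contig too short, or an anomaly).
#' @export
assign_confidence_tier <- function(score, motif_found, cfg = screen_config()) {
  if (any(!is.finite(score))) abort("Scores must be finite.")
  anomalous <- score >= cfg$min_score_complete & !motif_found
  if (any(anomalous)) {
    warn(paste0(
      sum(anomalous), " sequence(s) scored >= ", cfg$min_score_complete,
      " without the conserved motif; classed as partial."
    ))
  }
  dplyr::case_when(
    score >= cfg$min_score_complete & motif_found ~ "complete",
    score >= cfg$min_score_candidate ~ "partial",
    TRUE ~ "rejected"
  )
}

#' Screen joined protein records into HgcA candidates
#'
#' Applies the motif scan and tier assignment to the output of
#' [parse_hmm_hits()].
#'
#' @param records Tibble from [parse_hmm_hits()] (columns `protein_id`,
#'   `sequence`, `hmm_score`, optionally `contig_id`, `coverage`).
#' @param cfg A [screen_config()].
#' @param keep_rejected Keep rejected rows (default drops them).
#' @return `records` with `motif_found`, `motif_hit`, `tier` appended.
#' @export
screen_hgca <- function(records, cfg = screen_config(), keep_rejected = FALSE) {
  check_cols(records, c("protein_id", "sequence", "hmm_score"), "protein records")
  scan <- scan_conserved_motifs(records$sequence, cfg)
  out <- mutate(records,
    motif_found = scan$motif_found,
    motif_hit = scan$motif_hit,
    tier = assign_confidence_tier(.data$hmm_score, scan$motif_found, cfg)
  )
  if (!keep_rejected) out <- filter(out, .data$tier != "rejected")
  out
}

#' Coverage-weighted abundance of HgcA candidates by taxon
#'
#' Each surviving candidate contributes its contig's mean read depth (one
#' gene copy times coverage) to the abundance of its assigned taxon; sums and
#' relative fractions are returned per taxon.
#'
#' @param candidates Screened candidates with a `coverage` column and a
#'   taxonomy column.
#' @param taxon_col Name of the column holding the taxon label (default
#'   `"taxonomy_consensus"`; unassigned/NA labels are pooled as
#'   `"unassigned"`).
#' @return Tibble: `taxon`, `n_candidates`, `abundance`, `fraction`, sorted
#'   by decreasing abundance.
#' @export
coverage_weighted_abundance <- function(candidates, taxon_col = "taxonomy_consensus") {
  check_cols(candidates, c("protein_id", "coverage"), "candidates")
  live <- if ("tier" %in% names(candidates)) {
    filter(candidates, .data$tier != "rejected")
  } else {
    candidates
  }
  if (any(is.na(live$coverage))) {
    abort(paste0(
      "Missing coverage for candidate(s): ",
      paste(live$protein_id[is.na(live$coverage)], collapse = ", ")
    ))
  }
  taxon <- if (taxon_col %in% names(live)) live[[taxon_col]] else rep(NA_character_, nrow(live))
  taxon <- ifelse(is.na(taxon) | taxon == "", "unassigned", taxon)
  out <- tibble(taxon = taxon, coverage = live$coverage) |>
    group_by(.data$taxon) |>
    summarise(n_candidates = n(), abundance = sum(.data$coverage), .groups = "drop") |>
    arrange(dplyr::desc(.data$abundance))
  mutate(out, fraction = .data$abundance / sum(.data$abundance))
}

#' Count mer detoxification genes from an EC annotation table
#'
#' Tallies genes annotated as mercuric reductase (merA, EC 1.16.1.1) and
#' organomercury lyase (merB, EC 4.99.1.2). Both counts are always reported,
#' zeros included. Rows with malformed EC strings are skipped with a warning.
#'
#' @param annotations Tibble (or TSV path) with columns `gene_id`, `ec_number`.
#' @param sample_id Label attached to the output rows.
#' @return Tibble: `sample_id`, `gene`, `ec_number`, `count`.
#' @export
screen_mer_genes <- function(annotations, sample_id = "sample") {
  if (is.character(annotations) && length(annotations) == 1) {
    annotations <- readr::read_tsv(annotations, show_col_types = FALSE)
  }
  check_cols(annotations, c("gene_id", "ec_number"), "annotation table")
  ec <- as.character(annotations$ec_number)
  ok <- grepl("^EC:?\\s*[0-9]+(\\.[0-9n-]+){3}$", ec) | grepl("^[0-9]+(\\.[0-9n-]+){3}$", ec)
  ok[is.na(ec)] <- FALSE
  if (any(!ok)) {
    warn(paste0("Skipping ", sum(!ok), " row(s) with malformed EC numbers."))
  }
  ec <- sub("^EC:?\\s*", "", ec[ok])
  tibble(
    sample_id = sample_id,
    gene = c("merA", "merB"),
    ec_number = c("1.16.1.1", "4.99.1.2"),
    count = c(sum(ec == "1.16.1.1"), sum(ec == "4.99.1.2"))
  )
}
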