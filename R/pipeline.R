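#' Run the full periphyton mercury analysis pipeline
#'
#' Orchestrates the stages end to end: (optional) synthetic-data generation,
#' tracer rate estimation and site comparison, speciation budget, HgcA
#' screening with coverage-weighted abundance, dual-route taxonomy with
#' consensus, and 16S community profiling (relative abundance, Bray-Curtis,
#' PCoA, PERMANOVA). Each stage's table is written to `outdir` as TSV; a run
#' log records the seed and every threshold applied. A stage failure aborts
#' with the stage name and cause; tables already written are kept.
#'
#' @param outdir Output directory.
#' @param config Named list (or YAML file path) of options. Recognised
#'   entries: `tracer`, `hgca`, `tree`, `community` input-path lists (each
#'   stage is simulated when its paths are absent), `speciation` (TSV path;
#'   defaults to [example_speciation()]), `spike_conc` (default 4),
#'   `min_score_candidate`/`min_score_complete`, `max_evalue`,
#'   `min_identity`, `min_qcov`, `lump_threshold` (default 0.02), `n_perm`
#'   (default 999), `rank` (consensus rank, default `"family"`),
#'   `community_rank` (default `"phylum"`).
#' @param seed Integer seed used for simulation and permutation tests.
#' @return Invisibly, a report list: `site_rates`, `rate_anova`, `budget`,
#'   `spike_folds`, `candidates`, `abundance`, `consensus`, `fractions`,
#'   `ordination`, `permanova_site`, `permanova_treatment`, `mer_genes`.
#' @export
run_pipeline <- function(outdir, config = list(), seed = 1L) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- utils::modifyList(
    list(
      spike_conc = 4, min_score_candidate = 100, min_score_complete = 164,
      max_evalue = 1e-20, min_identity = 40, min_qcov = 80,
      lump_threshold = 0.02, n_perm = 999, rank = "family",
      community_rank = "phylum"
    ),
    config
  )
  report <- list()
  log_lines <- c(
    "perihg pipeline run",
    paste0("seed: ", seed),
    paste0("thresholds: score>=", cfg$min_score_candidate,
           " complete>=", cfg$min_score_complete,
           " E<=", cfg$max_evalue, " id>=", cfg$min_identity,
           " qcov>=", cfg$min_qcov, " lump<", cfg$lump_threshold,
           " n_perm=", cfg$n_perm)
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  save <- function(obj, name) {
    readr::write_tsv(obj, file.path(outdir, paste0(name, ".tsv")))
  }

  # --- tracer rates ---------------------------------------------------------
  tracer <- stage("rates", {
    if (!is.null(cfg[["tracer"]]$path)) {
      read_tracer_tsv(cfg[["tracer"]]$path)
    } else {
      sim <- sim_tracer_experiment(seed = seed)
      save(sim$truth, "tracer_truth")
      save(sim$samples, "tracer_samples")
      sim$samples
    }
  })
  estimates <- stage("rates", estimate_rates(tracer))
  report$site_rates <- stage("rates", summarize_site_rates(estimates))
  save(estimates, "rate_estimates")
  save(report$site_rates, "site_rates")
  kd_est <- filter(estimates, .data$kind == "demethylation")
  report$rate_anova <- stage("rates", tryCatch(
    compare_sites_anova(kd_est),
    error = function(e) NULL
  ))

  # --- speciation budget ----------------------------------------------------
  spec_tbl <- stage("budget", {
    if (!is.null(cfg[["speciation"]])) {
      readr::read_tsv(cfg[["speciation"]], show_col_types = FALSE)
    } else {
      example_speciation()
    }
  })
  report$budget <- stage("budget", percent_mmhg(spec_tbl))
  water <- filter(report$budget, .data$matrix == "water")
  report$spike_folds <- stage("budget", bind_rows(
    spike_fold_ratio(water, cfg$spike_conc, "thg"),
    spike_fold_ratio(water, cfg$spike_conc, "mmhg")
  ))
  save(report$budget, "speciation_budget")
  save(report$spike_folds, "spike_folds")

  # --- HgcA screening -------------------------------------------------------
  screen_cfg <- screen_config(cfg$min_score_candidate, cfg$min_score_complete)
  hg <- stage("screen-hgca", {
    if (!is.null(cfg[["hgca"]]$hits)) {
      records <- parse_hmm_hits(cfg[["hgca"]]$hits, cfg[["hgca"]]$fasta, cfg[["hgca"]]$coverage)
      list(records = records,
           similarity = read_similarity_hits(cfg[["hgca"]]$similarity, cfg[["hgca"]]$lineages))
    } else {
      fix <- sim_hgca_fixture(cfg = screen_cfg, seed = seed)
      sim_hits <- fix$similarity_hits |>
        left_join(fix$subject_lineages, by = "subject_id")
      list(records = select(
        fix$proteins, "protein_id", "contig_id", "sequence", "hmm_score", "coverage"
      ), similarity = sim_hits, fixture = fix)
    }
  })
  candidates <- stage("screen-hgca", screen_hgca(hg$records, screen_cfg))

  # --- taxonomy -------------------------------------------------------------
  tax <- stage("taxonomy", {
    passing <- filter_hits(hg$similarity, cfg$max_evalue, cfg$min_identity, cfg$min_qcov)
    sim_assign <- similarity_assign(passing, queries = candidates$protein_id,
                                    rank = cfg$rank)
    tree_fix <- if (!is.null(cfg[["tree"]]$newick)) {
      list(
        tree = ape::read.tree(cfg[["tree"]]$newick),
        leaf_taxa = readr::read_tsv(cfg[["tree"]]$leaf_taxa, show_col_types = FALSE),
        query_leaves = candidates$protein_id
      )
    } else {
      # plant most queries inside their similarity family, a few at a mixed clade
      fams <- sim_assign$taxon
      placement <- ifelse(
        seq_along(fams) %% 6 == 0 | is.na(fams), "mixed", "inside"
      )
      sim_reference_tree(
        tibble(query_id = sim_assign$query_id, family = fams, placement = placement),
        seed = seed
      )
    }
    tree_assign <- clade_assign(tree_fix$tree, tree_fix$leaf_taxa,
                                tree_fix$query_leaves, rank = cfg$rank)
    consensus_compare(sim_assign, tree_assign, rank = cfg$rank)
  })
  report$consensus <- tax
  cand_tax <- left_join(
    candidates,
    select(tax$records, "query_id", taxonomy_consensus = "tax_consensus"),
    by = c(protein_id = "query_id")
  )
  report$candidates <- cand_tax
  report$abundance <- stage("screen-hgca", coverage_weighted_abundance(cand_tax))
  save(cand_tax, "hgca_candidates")
  save(report$abundance, "hgca_abundance")
  save(tax$records, "taxonomy_consensus")

  # --- mer genes ------------------------------------------------------------
  report$mer_genes <- stage("screen-hgca", {
    if (!is.null(cfg[["hgca"]]$annotations)) {
      screen_mer_genes(cfg[["hgca"]]$annotations, sample_id = "pooled")
    } else {
      screen_mer_genes(
        tibble(gene_id = character(), ec_number = character()),
        sample_id = "pooled"
      )
    }
  })
  save(report$mer_genes, "mer_genes")

  # --- community ------------------------------------------------------------
  comm <- stage("community", {
    if (!is.null(cfg[["community"]]$counts)) {
      read_asv_table(cfg[["community"]]$counts, cfg[["community"]]$lineages,
                     cfg[["community"]]$metadata)
    } else {
      sim_asv_table(seed = seed)
    }
  })
  report$fractions <- stage("community", {
    relative_abundance(comm$counts, comm$lineages, rank = cfg$community_rank) |>
      lump_rare(threshold = cfg$lump_threshold)
  })
  asv_frac <- stage("community", {
    mat <- as.matrix(comm$counts[setdiff(names(comm$counts), "sample_id")])
    rownames(mat) <- comm$counts$sample_id
    sweep(mat, 1, rowSums(mat), "/")
  })
  d <- stage("community", bray_curtis(asv_frac))
  report$ordination <- stage("community", pcoa_ordination(d))
  report$permanova_site <- stage("community", {
    permanova(d, comm$metadata, factor_name = "site",
              n_perm = cfg$n_perm, seed = seed)
  })
  report$permanova_treatment <- stage("community", {
    permanova(d, comm$metadata, factor_name = "treatment",
              n_perm = cfg$n_perm, seed = seed)
  })
  save(report$fractions, "community_fractions")
  save(report$ordination$coordinates, "pcoa_coordinates")
  save(bind_rows(
    mutate(tidy(report$permanova_site), term = "site"),
    mutate(tidy(report$permanova_treatment), term = "treatment")
  ), "permanova")

  # --- summary --------------------------------------------------------------
  log_lines <- c(
    log_lines,
    sprintf("hgca candidates: %d", nrow(report$candidates)),
    sprintf("consensus agreement: %.1f%%", report$consensus$agreement_pct),
    sprintf("permanova site p: %.4g", report$permanova_site$p),
    sprintf("permanova treatment p: %.4g", report$permanova_treatment$p)
  )
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(report)
}
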