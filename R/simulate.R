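#' Default site kinetic parameters for simulated tracer assays
#'
#' Per-site methylation/demethylation rate constants used by
#' [sim_tracer_experiment()]. These are coupled-model (true) parameters
#' chosen so that the single-time-point assay reproduces the field regimes:
#' the wetland's product tracer reaches ~4.7e-2 ng/L at 48 h, i.e. a
#' simplified-estimator yield of ~5.9e-3 day^-1, and stays detectable in
#' every replicate; the natural and flooded sites produce near the 0.01
#' ng/L detection limit, so with realistic noise methylation is detected in
#' only some replicates. Demethylation is of order 1.8 day^-1 everywhere,
#' with the natural and flooded sites apart.
#'
#' @return Tibble: `site_id`, `km`, `kd` (day^-1).
#' @export
default_tracer_sites <- function() {
  tibble(
    site_id = c("natural", "flooded", "wetland"),
    km = c(3.3e-3, 4.3e-3, 2.2e-2),
    kd = c(1.55, 2.0, 1.8)
  )
}

#' Simulate an isotope-tracer incubation experiment
#'
#' Generates per-replicate tracer measurements from the kinetic forward
#' model with multiplicative lognormal measurement noise and left-censoring
#' of the product tracer at the MMHg detection limit. Censored values are
#' reported as `NA` with `censored = TRUE`, not as zeros. The lognormal is
#' mean-unbiased (meanlog = log(x) - sigma^2/2 with
#' sigma^2 = log(1 + CV^2)).
#'
#' @param sites Tibble of true parameters (`site_id`, `km`, `kd`), default
#'   [default_tracer_sites()].
#' @param spike Spike concentration of each enriched isotope, ng L^-1.
#' @param t_days Incubation time, days.
#' @param n_replicates Replicates per site.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param lod_mmhg MMHg detection limit, ng L^-1.
#' @param model `"coupled"` (full two-compartment forward model, default) or
#'   `"simplified"` (no back-reaction; the estimators' exact inverse).
#' @param seed Integer seed.
#' @return List: `samples` (tracer tibble ready for [estimate_rates()], with
#'   a `censored` column) and `truth` (the `sites` tibble).
#' @export
sim_tracer_experiment <- function(sites = default_tracer_sites(), spike = 4,
                                  t_days = 2, n_replicates = 3,
                                  noise_cv = 0.5, lod_mmhg = 0.01,
                                  model = c("coupled", "simplified"),
                                  seed = 1L) {
  model <- match.arg(model)
  check_cols(sites, c("site_id", "km", "kd"), "site parameters")
  check_rates(sites$km, sites$kd)
  if (noise_cv < 0) abort("`noise_cv` must be non-negative.")
  set.seed(seed)
  grid <- tidyr::expand_grid(
    site_id = sites$site_id,
    replicate_id = paste0("r", seq_len(n_replicates))
  ) |>
    left_join(sites, by = "site_id")
  sim <- if (model == "coupled") {
    simulate_coupled_tracers(grid$km, grid$kd, spike, spike, t_days)
  } else {
    simulate_simplified_tracers(grid$km, grid$kd, spike, spike, t_days)
  }
  m200 <- noisy(sim$mmhg200_t, noise_cv)
  m198 <- noisy(sim$mmhg198_t, noise_cv)
  censored <- m200 <= lod_mmhg
  samples <- tibble(
    site_id = grid$site_id,
    replicate_id = grid$replicate_id,
    ihg200_0 = spike,
    mmhg198_0 = spike,
    mmhg200_t = ifelse(censored, NA_real_, m200),
    mmhg198_t = m198,
    t_days = t_days,
    lod_mmhg = lod_mmhg,
    censored = censored
  )
  list(samples = samples, truth = sites)
}

noisy <- function(x, cv) {
  if (cv == 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# ---------------------------------------------------------------------------

#' Reference families used by the metagenome and tree fixtures
#'
#' Family-level lineages of known mercury methylators (plus lineage context)
#' used when planting synthetic HgcA candidates.
#'
#' @return Tibble with [lineage_ranks()] columns, one row per family.
#' @export
default_hgca_families <- function() {
  tibble(
    domain = c(rep("Bacteria", 7), "Archaea"),
    phylum = c(
      "Proteobacteria", "Proteobacteria", "Proteobacteria", "Proteobacteria",
      "Nitrospirae", "Actinobacteria", "Bacteroidetes", "Euryarchaeota"
    ),
    class = c(
      "Deltaproteobacteria", "Deltaproteobacteria", "Deltaproteobacteria",
      "Deltaproteobacteria", "Nitrospira", "Acidimicrobiia", "Bacteroidia",
      "Methanomicrobia"
    ),
    order = c(
      "Desulfuromonadales", "Syntrophobacterales", "Desulfobacterales",
      "Desulfuromonadales", "Nitrospirales", "Acidimicrobiales",
      "Bacteroidales", "Methanomicrobiales"
    ),
    family = c(
      "Geobacteraceae", "Syntrophaceae", "Desulfobacteraceae",
      "Desulfuromonadaceae", "Nitrospiraceae", "Acidimicrobiaceae",
      "Bacteroidaceae", "Methanoregulaceae"
    )
  )
}

aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")

plant_motif <- function(sequence, motif) {
  n <- nchar(sequence)
  pos <- sample.int(n - 8L + 1L, 1)
  paste0(substr(sequence, 1, pos - 1), motif, substr(sequence, pos + 8L, n))
}

shuffle_protein <- function(sequence) {
  paste(sample(strsplit(sequence, "")[[1]]), collapse = "")
}

#' Simulate a screened-metagenome fixture with planted HgcA proteins
#'
#' Plants `n_complete` proteins carrying a conserved motif with bit scores at
#' or above the complete threshold, `n_partial` motif-less truncations
#' scoring in the candidate band, and `n_decoys` decoys scoring below it.
#' Decoys are composition-preserving shuffles of true sequences, so chance
#' motif matches remain possible (they still fail on score). Similarity hits
#' matching each true protein's planted family are emitted alongside, with a
#' subject lineage table.
#'
#' @param n_complete,n_partial,n_decoys Fixture sizes (default 16/8/50; the
#'   24 true proteins mirror a wetland screen).
#' @param families Family lineages to plant, recycled over the true
#'   proteins; default [default_hgca_families()].
#' @param cfg A [screen_config()] providing the score bands.
#' @param seed Integer seed.
#' @return List: `proteins` (tibble incl. `sequence`, `hmm_score`,
#'   `coverage`, truth columns `tier_truth`, `family_truth`), `fasta`
#'   (`Biostrings::AAStringSet`), `hmm_hits`, `coverage`, `similarity_hits`
#'   (13-column BLAST-style tibble), `subject_lineages`.
#' @export
sim_hgca_fixture <- function(n_complete = 16, n_partial = 8, n_decoys = 50,
                             families = default_hgca_families(),
                             cfg = screen_config(), seed = 1L) {
  set.seed(seed)
  n_true <- n_complete + n_partial
  fam <- families[rep_len(seq_len(nrow(families)), max(n_true, 1)), , drop = FALSE]
  lens <- sample(102:292, n_true, replace = TRUE) # partial proteins, 306-876 bp
  seqs <- vapply(lens, random_protein, "")
  motifs <- sample(cfg$motifs, n_true, replace = TRUE)
  complete_idx <- seq_len(n_complete)
  seqs[complete_idx] <- mapply(plant_motif, seqs[complete_idx], motifs[complete_idx])
  # partial truncations keep scoring in the candidate band but lack the motif
  scores <- c(
    runif(n_complete, cfg$min_score_complete, cfg$min_score_complete + 120),
    runif(n_partial, cfg$min_score_candidate, cfg$min_score_complete - 1),
    runif(n_decoys, 20, cfg$min_score_candidate - 1)
  )
  decoys <- if (n_true > 0) {
    vapply(sample(seqs, n_decoys, replace = TRUE), shuffle_protein, "")
  } else {
    vapply(sample(102:292, n_decoys, replace = TRUE), random_protein, "")
  }
  all_seqs <- c(seqs, decoys)
  ids <- sprintf("contig%04d_1", seq_along(all_seqs))
  contigs <- sub("_1$", "", ids)
  coverage <- round(rlnorm(length(ids), meanlog = log(8), sdlog = 0.6), 2)
  proteins <- tibble(
    protein_id = ids,
    contig_id = contigs,
    sequence = all_seqs,
    hmm_score = round(scores, 1),
    coverage = coverage,
    tier_truth = c(
      rep("complete", n_complete), rep("partial", n_partial),
      rep("rejected", n_decoys)
    ),
    family_truth = c(fam$family[seq_len(n_true)], rep(NA_character_, n_decoys))
  )
  true_idx <- seq_len(n_true)
  sim_hits <- tibble(
    query_id = ids[true_idx],
    subject_id = paste0("ref_", fam$family[true_idx], "_1"),
    percent_identity = round(runif(n_true, 55, 90), 1),
    length = lens,
    mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = lens, sstart = 1L, send = lens,
    evalue = 10^runif(n_true, -80, -30),
    bit_score = round(runif(n_true, 180, 400), 1),
    query_coverage = round(runif(n_true, 85, 100), 1)
  )
  subject_lineages <- dplyr::bind_cols(
    tibble(subject_id = paste0("ref_", families$family, "_1")), families
  )
  fasta <- Biostrings::AAStringSet(setNames(all_seqs, ids))
  list(
    proteins = proteins,
    fasta = fasta,
    hmm_hits = tibble(protein_id = ids, score = proteins$hmm_score),
    coverage = tibble(contig_id = contigs, mean_depth = coverage),
    similarity_hits = sim_hits,
    subject_lineages = subject_lineages
  )
}

# ---------------------------------------------------------------------------

#' Simulate a reference placement tree with planted query leaves
#'
#' Builds a rooted Newick tree in which each family's reference leaves form a
#' monophyletic clade, then attaches query leaves either inside their
#' family's clade (`placement = "inside"`, clade assignment succeeds) or
#' inside a deliberately mixed clade holding references from two families
#' (`placement = "mixed"`, clade assignment returns unassigned at family).
#'
#' @param queries Tibble with `query_id`, `family`, `placement`
#'   (`"inside"`/`"mixed"`).
#' @param families Family lineages, default [default_hgca_families()].
#' @param leaves_per_family Reference leaves per family clade.
#' @param seed Integer seed (branch lengths only; topology is deterministic).
#' @return List: `tree` (`phylo`), `leaf_taxa` (tibble `leaf` + lineage
#'   columns), `query_leaves` (character).
#' @export
sim_reference_tree <- function(queries, families = default_hgca_families(),
                               leaves_per_family = 3, seed = 1L) {
  check_cols(queries, c("query_id", "family", "placement"), "query table")
  if (nrow(families) < 2) abort("Need at least two reference families.")
  bad <- setdiff(queries$family[queries$placement == "inside"], families$family)
  if (length(bad) > 0) {
    abort(paste0("Unknown families in query table: ", paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  leaf_of <- function(fami, i) paste0(gsub("[^A-Za-z]", "", fami), "_ref", i)
  clades <- vapply(seq_len(nrow(families)), function(i) {
    fami <- families$family[i]
    tips <- leaf_of(fami, seq_len(leaves_per_family))
    q <- queries$query_id[queries$placement == "inside" & queries$family == fami]
    paste0("(", paste(c(tips, q), collapse = ","), ")")
  }, "")
  # mixed clade: one extra reference from each of the first two families
  mixed_tips <- c(leaf_of(families$family[1], "X"), leaf_of(families$family[2], "X"))
  mixed_q <- queries$query_id[queries$placement == "mixed"]
  mixed <- paste0("(", paste(c(mixed_tips, mixed_q), collapse = ","), ")")
  newick <- paste0("(", paste(c(clades, mixed), collapse = ","), ");")
  tree <- ape::read.tree(text = newick)
  tree$edge.length <- runif(nrow(tree$edge), 0.02, 0.4)
  ref_rows <- purrr::map(seq_len(nrow(families)), function(i) {
    fami <- families$family[i]
    tibble(leaf = leaf_of(fami, c(seq_len(leaves_per_family), "X"))) |>
      dplyr::bind_cols(families[rep(i, leaves_per_family + 1), , drop = FALSE])
  })
  leaf_taxa <- bind_rows(ref_rows) |>
    filter(.data$leaf %in% tree$tip.label)
  list(tree = tree, leaf_taxa = leaf_taxa, query_leaves = queries$query_id)
}

# ---------------------------------------------------------------------------

#' Default phylum-level base composition for community simulation
#'
#' A periphyton-like phylum profile: Proteobacteria 36.3%, Cyanobacteria
#' 26.8%, with the remainder spread over typical freshwater-biofilm phyla.
#'
#' @return Named numeric vector of fractions summing to 1.
#' @export
default_community_profile <- function() {
  c(
    Proteobacteria = 0.363, Cyanobacteria = 0.268, Verrucomicrobia = 0.09,
    Acidobacteria = 0.07, Chloroflexi = 0.05, Bacteroidetes = 0.045,
    Planctomycetes = 0.04, Actinobacteria = 0.03, Nitrospirae = 0.012,
    Euryarchaeota = 0.008, Firmicutes = 0.008, Gemmatimonadetes = 0.016
  )
}

#' Simulate a site-structured ASV count table
#'
#' Dirichlet-multinomial sampling around site-specific base compositions.
#' Each phylum is split over a few ASVs with fixed within-phylum weights;
#' per-sample compositions are drawn from a Dirichlet distribution centred on
#' the site's base ASV profile with the given concentration, then counts are
#' multinomial at the given depth. Treatment labels carry no effect, so a
#' treatment-level PERMANOVA should be null; site tilts create a recoverable
#' site signal.
#'
#' @param base Named phylum fractions, default [default_community_profile()].
#' @param site_tilt Named list of per-site multiplicative tilts on selected
#'   phyla (renormalised); defaults give each site a distinct signature while
#'   leaving Proteobacteria near its base value.
#' @param n_per_treatment Samples per site x treatment cell (default 3;
#'   3 sites x 3 treatments x 3 = 27 samples).
#' @param depth Reads per sample.
#' @param concentration Dirichlet concentration (larger = less overdispersed).
#' @param asv_per_phylum ASVs per phylum.
#' @param seed Integer seed.
#' @return List: `counts` (tibble `sample_id` x ASVs), `lineages`
#'   (`asv_id` + lineage columns), `metadata` (`sample_id`, `site`,
#'   `treatment`, `molecule`), `truth` (per-site phylum fractions).
#' @export
sim_asv_table <- function(base = default_community_profile(),
                          site_tilt = list(
                            natural = c(Cyanobacteria = 1.25, Chloroflexi = 0.7),
                            flooded = c(Verrucomicrobia = 1.5, Acidobacteria = 0.6),
                            wetland = c(
                              Euryarchaeota = 2.5, Nitrospirae = 2.0,
                              Cyanobacteria = 0.85
                            )
                          ),
                          n_per_treatment = 3, depth = 10000,
                          concentration = 500, asv_per_phylum = 3,
                          seed = 1L) {
  if (abs(sum(base) - 1) > 1e-8) abort("`base` fractions must sum to 1.")
  if (depth <= 0) abort("`depth` must be positive.")
  set.seed(seed)
  sites <- names(site_tilt)
  treatments <- c("t0", "incubated_control", "incubated_spiked")
  phyla <- names(base)
  asv_ids <- paste0("ASV", sprintf("%03d", seq_len(length(phyla) * asv_per_phylum)))
  asv_phylum <- rep(phyla, each = asv_per_phylum)
  # fixed ASV weights, normalised within each phylum so phylum totals are
  # exactly the site profile
  w <- stats::rgamma(length(asv_ids), shape = 2)
  w <- w / stats::ave(w, asv_phylum, FUN = sum)
  site_profiles <- purrr::map(sites, function(s) {
    p <- base
    tilt <- site_tilt[[s]]
    p[names(tilt)] <- p[names(tilt)] * tilt
    p / sum(p)
  })
  names(site_profiles) <- sites
  meta <- tidyr::expand_grid(
    site = sites, treatment = treatments, rep = seq_len(n_per_treatment)
  ) |>
    mutate(
      sample_id = paste(.data$site, .data$treatment, .data$rep, sep = "_"),
      molecule = "rDNA"
    ) |>
    select("sample_id", "site", "treatment", "molecule")
  count_rows <- purrr::map(seq_len(nrow(meta)), function(i) {
    p_phy <- site_profiles[[meta$site[i]]]
    base_asv <- w * p_phy[asv_phylum]
    base_asv <- base_asv / sum(base_asv)
    p <- rdirichlet_one(concentration * base_asv)
    as.integer(rmultinom(1, depth, p))
  })
  counts <- do.call(rbind, count_rows)
  colnames(counts) <- asv_ids
  lineages <- tibble(
    asv_id = asv_ids,
    domain = ifelse(asv_phylum == "Euryarchaeota", "Archaea", "Bacteria"),
    phylum = asv_phylum,
    class = paste0(asv_phylum, "_c1"),
    order = paste0(asv_phylum, "_o1"),
    family = paste0(asv_phylum, "_f", rep(seq_len(asv_per_phylum), length(phyla)))
  )
  truth <- purrr::imap(site_profiles, function(p, s) {
    tibble(site = s, phylum = names(p), fraction = unname(p))
  }) |> bind_rows()
  list(
    counts = dplyr::bind_cols(tibble(sample_id = meta$sample_id), as_tibble(counts)),
    lineages = lineages,
    metadata = meta,
    truth = truth
  )
}

rdirichlet_one <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}
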