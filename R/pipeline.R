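#' Run the full analysis pipeline from one configuration
#'
#' Chains simulation (or VCF input), site filtering, relatedness pruning,
#' LD pruning, diversity and ROH summaries, the pairwise FST / Q tables,
#' population-specific FST outliers with their LoF intersection, f3/f4
#' statistics, and the genotype-distance matrix with its neighbor-joining
#' tree. Writes one tab-separated table per stage plus a JSON run manifest
#' recording seeds, stage counts and output hashes; re-running with the
#' same config and seed reproduces byte-identical tables.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   `seed` (root seed; per-stage seeds are derived from it),
#'   `simulate` (arguments passed to [demography()]), or `vcf` +
#'   `populations` for file input; optional `accessible_site_total`,
#'   `kinship_threshold`, `block_size`, `top_fraction`, `outgroup`
#'   (population label used for f3 and LoF polarization), `f4_quartets`
#'   (list of 4-vectors), `lof_fraction`, `gene_intervals`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of result tibbles plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  root_seed <- config$seed %||% 1L
  set.seed(root_seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 8L)
  results <- list()

  # --- panel -----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    dem <- do.call(demography, config$simulate)
    sim <- simulate_panel(dem, stage_seeds[1])
    panel <- sim$panel
    truth <- sim$truth
  } else if (!is.null(config$vcf)) {
    pops <- config$populations
    if (is.character(pops) && length(pops) == 1) {
      pops <- readr::read_tsv(pops, show_col_types = FALSE)
    }
    panel <- read_vcf(config$vcf, pops, config$ploidy_rules)
  } else {
    rlang::abort("config must name a panel source: `simulate` or `vcf`",
                 class = "popgenpanel_config_error")
  }

  # --- site filters ----------------------------------------------------
  mask <- hard_filter(panel)
  panel <- panel_subset(panel, variants = mask$retained)
  accessible <- config$accessible_site_total %||%
    (max(panel$variants$pos) - min(panel$variants$pos) + 1)

  # --- relatedness -----------------------------------------------------
  kin <- king_kinship(panel)
  retained_samples <- prune_related(panel,
                                    config$kinship_threshold %||% 0.0884,
                                    kinship = kin)
  unrelated <- panel_subset(panel, samples = as.character(retained_samples))
  results$kinship <- kin

  block_size <- config$block_size %||% 25000

  # --- diversity -------------------------------------------------------
  results$heterozygosity <- individual_heterozygosity(panel, accessible)
  results$pi <- tibble::tibble(
    pi = panel_pi(panel, accessible, samples = as.character(retained_samples)))
  roh <- dplyr::bind_rows(lapply(panel$samples, function(s) {
    roh_call(panel, s)
  }))
  results$roh <- roh_filter(roh)

  # --- LD pruning ------------------------------------------------------
  ld_keep <- ld_prune(unrelated)
  results$ld <- tibble::tibble(n_before = n_variants(unrelated),
                               n_after = length(ld_keep))

  # --- differentiation -------------------------------------------------
  pops_all <- unique(unname(unrelated$populations))
  main_pops <- setdiff(pops_all, config$outgroup)
  main_panel <- panel_subset(
    unrelated,
    samples = unrelated$samples[unrelated$populations %in% main_pops])
  if (length(main_pops) >= 2) {
    ft <- fst_table(main_panel, block_size)
    results$fst <- tibble::as_tibble(ft)
    if (any(ft$chrom_set == "X")) {
      qs <- lapply(seq_len(sum(ft$chrom_set == "autosomes")), function(i) {
        a <- ft[ft$chrom_set == "autosomes", ][i, ]
        x <- ft[ft$chrom_set == "X" & ft$pop_a == a$pop_a &
                  ft$pop_b == a$pop_b, ]
        dplyr::bind_cols(a[, c("pop_a", "pop_b")],
                         q_statistic(a$fst, x$fst))
      })
      results$q <- dplyr::bind_rows(qs)
    }
  }

  # --- population-specific FST + LoF intersection ----------------------
  if (!is.null(config$gene_intervals)) {
    cons <- assign_consequences(panel, tibble::as_tibble(config$gene_intervals),
                                config$lof_fraction %||% 0.1, stage_seeds[2])
    lof <- classify_lof(cons)
    if (!is.null(config$outgroup)) {
      spec_mask <- polarize_species_specific(
        panel, panel$samples[panel$populations %in% config$outgroup])
      lof_specific <- lof[lof$variant %in% which(spec_mask), , drop = FALSE]
      focal <- panel$samples[!panel$populations %in% config$outgroup]
      burden <- lof_burden(panel, lof_specific, focal)
      results$lof_burden <- burden$per_sample
    }
    outl <- lapply(main_pops, function(pp) {
      ps <- population_specific_fst(main_panel, pp,
                                    config$top_fraction %||% 0.01)
      idx <- which(ps$outlier)
      tibble::tibble(population = pp, variant = idx,
                     chrom = ps$chrom[idx], pos = ps$pos[idx],
                     fst = ps$fst[idx],
                     lof = idx %in% lof$variant)
    })
    results$pop_specific <- dplyr::bind_rows(outl)
  }

  # --- f3 / f4 ---------------------------------------------------------
  if (!is.null(config$outgroup) && length(main_pops) >= 2) {
    pr <- utils::combn(main_pops, 2)
    results$f3 <- dplyr::bind_rows(lapply(seq_len(ncol(pr)), function(j) {
      tidy(f3_outgroup(unrelated, config$outgroup[1], pr[1, j], pr[2, j],
                       block_size))
    }))
  }
  if (!is.null(config$f4_quartets)) {
    results$f4 <- dplyr::bind_rows(lapply(config$f4_quartets, function(q) {
      tidy(f4(unrelated, q[1], q[2], q[3], q[4], block_size))
    }))
  }

  # --- distances / tree ------------------------------------------------
  dm <- genotype_distance(unrelated)
  results$distance <- tidy(dm)
  export_result(dm, file.path(out_dir, "distances.phy"), "phylip")
  export_result(dm, file.path(out_dir, "distances.nex"), "nexus")
  if (length(unrelated$samples) >= 3) {
    tree <- neighbor_joining(dm)
    export_result(tree, file.path(out_dir, "nj_tree.nwk"), "newick")
  }

  # --- write tables + manifest -----------------------------------------
  counts <- list(n_variants = n_variants(panel),
                 n_samples = length(panel$samples),
                 n_unrelated = length(retained_samples),
                 n_removed_hard_filter = sum(mask$n_removed))
  for (nm in names(results)) {
    readr::write_tsv(results[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    root_seed = root_seed,
    stage_seeds = as.integer(stage_seeds),
    config = config[setdiff(names(config), "gene_intervals")],
    counts = counts,
    hashes = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  if (!is.null(truth)) results$truth <- truth
  invisible(results)
}
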