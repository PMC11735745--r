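#' Outgroup-polarized species-specific variant mask
#'
#' A site is species-specific (its alternate allele a derived allele private
#' to the focal species) iff every outgroup sample is homozygous reference
#' with no missingness — "unambiguously" carries the ancestral state. A
#' missing or heterozygous outgroup genotype excludes the site.
#'
#' @param panel A `gt_panel`.
#' @param outgroup_samples Outgroup sample identifiers (default: all samples
#'   whose population label is `"outgroup"`).
#' @return Logical vector, one element per variant.
#' @export
polarize_species_specific <- function(panel, outgroup_samples = NULL) {
  if (is.null(outgroup_samples)) {
    outgroup_samples <- panel$samples[panel$populations == "outgroup"]
  }
  if (length(outgroup_samples) == 0) {
    rlang::abort("outgroup sample list is empty",
                 class = "popgenpanel_config_error")
  }
  stopifnot(all(outgroup_samples %in% panel$samples))
  g <- panel$genotypes[, outgroup_samples, drop = FALSE]
  rowSums(g == 0L) == length(outgroup_samples)
}

#' Classify loss-of-function variants
#'
#' Returns the variants whose consequence class belongs to the LoF
#' vocabulary: frameshifts, premature stop codons, and splice-site
#' disruptions (acceptor/donor, not `splice_region`). Unknown class labels
#' are warned about and treated as non-LoF.
#'
#' @param consequences Consequence table (tibble with `variant`, `gene`,
#'   `consequence`), e.g. from [assign_consequences()].
#' @param lof_classes Controlled vocabulary of LoF classes.
#' @param known_classes Classes that do not trigger the unknown-label
#'   warning.
#' @return Tibble of LoF variants (`variant`, `gene`, `consequence`).
#' @export
classify_lof <- function(consequences,
                         lof_classes = c("frameshift", "stop_gained",
                                         "splice_acceptor", "splice_donor"),
                         known_classes = c("missense", "synonymous",
                                           "intergenic", "splice_region",
                                           "intron", "utr")) {
  unknown <- setdiff(unique(consequences$consequence),
                     c(lof_classes, known_classes))
  if (length(unknown) > 0) {
    rlang::warn(paste0("unknown consequence class(es) treated as non-LoF: ",
                       paste(unknown, collapse = ", ")))
  }
  out <- consequences[consequences$consequence %in% lof_classes, , drop = FALSE]
  if (any(is.na(out$gene))) {
    rlang::warn("LoF variants without a gene identifier present")
  }
  out
}

#' Partition variants into fixed and segregating sets
#'
#' A variant is fixed in the focal sample set iff every focal sample is
#' homozygous alternate with no missingness; all other variants of the set
#' are segregating.
#'
#' @param panel A `gt_panel`.
#' @param focal_samples Non-empty focal sample list.
#' @param variant_set Integer variant indices to partition (default: all).
#' @return List with integer vectors `fixed` and `segregating`.
#' @export
partition_fixed <- function(panel, focal_samples,
                            variant_set = seq_len(n_variants(panel))) {
  stopifnot(length(focal_samples) > 0)
  g <- panel$genotypes[variant_set, focal_samples, drop = FALSE]
  # hom-alt is code 2 for both diploid and haploid entries
  all_alt <- rowSums(g == 2L) == length(focal_samples)
  list(fixed = variant_set[all_alt], segregating = variant_set[!all_alt])
}

#' Per-individual loss-of-function burden
#'
#' Counts, per focal sample: homozygous genotypes at segregating
#' species-specific LoF variants split by variant class (SNV / indel), and
#' the number of distinct genes carrying at least one LoF allele
#' (heterozygous or homozygous) in that sample, over fixed plus segregating
#' species-specific LoF variants.
#'
#' @param panel A `gt_panel`.
#' @param lof_set Tibble from [classify_lof()] already restricted to the
#'   species-specific mask (`variant`, `gene`, `consequence`).
#' @param focal_samples Focal sample identifiers.
#' @return List with `per_sample` (tibble: `sample`, `n_hom_lof_snv`,
#'   `n_hom_lof_indel`, `n_genes_lof`), `panel_means` (one-row tibble),
#'   `fixed` / `segregating` variant index vectors, and `genes_fixed`
#'   (genes hit by fixed LoF variants).
#' @export
lof_burden <- function(panel, lof_set, focal_samples) {
  part <- partition_fixed(panel, focal_samples, lof_set$variant)
  seg <- lof_set[lof_set$variant %in% part$segregating, , drop = FALSE]
  cls <- panel$variants$class
  per_sample <- lapply(focal_samples, function(s) {
    g_seg <- panel$genotypes[seg$variant, s]
    g_all <- panel$genotypes[lof_set$variant, s]
    tibble::tibble(
      sample = s,
      n_hom_lof_snv = sum(g_seg == 2L & cls[seg$variant] == "snv"),
      n_hom_lof_indel = sum(g_seg == 2L & cls[seg$variant] == "indel"),
      n_genes_lof = dplyr::n_distinct(
        lof_set$gene[g_all %in% c(1L, 2L) & !is.na(lof_set$gene)])
    )
  })
  per_sample <- dplyr::bind_rows(per_sample)
  list(
    per_sample = per_sample,
    panel_means = tibble::tibble(
      mean_hom_lof_snv = mean(per_sample$n_hom_lof_snv),
      mean_hom_lof_indel = mean(per_sample$n_hom_lof_indel),
      mean_genes_lof = mean(per_sample$n_genes_lof)),
    fixed = part$fixed, segregating = part$segregating,
    genes_fixed = unique(lof_set$gene[lof_set$variant %in% part$fixed]))
}
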