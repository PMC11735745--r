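#' KING-robust pairwise kinship
#'
#' The between-family KING estimator:
#' `phi = (N_het_het - 2 * N_opp_hom) / (N_het_i + N_het_j)` over autosomal
#' sites where both samples are genotyped, with `N_het_het` the number of
#' sites at which both are heterozygous, `N_opp_hom` the number with
#' opposite homozygotes, and `N_het_s` the heterozygote count of sample `s`
#' over the shared sites. Expected values: 0.5 for identical genomes, 0.25
#' for parent-offspring, ~0 for unrelated samples; 0.0884 (= 2^-3.5) is the
#' conventional third-degree cut-off.
#'
#' @param panel A `gt_panel`.
#' @param samples Samples to compare (default: all); all unordered pairs are
#'   returned.
#' @param chrom_set Chromosome set used, normally `"autosomes"`.
#' @return Tibble with `id1`, `id2`, `n_sites`, `n_het_het`, `n_opp_hom`,
#'   `phi` (`NA` when the denominator is 0, i.e. monomorphic input).
#' @export
king_kinship <- function(panel, samples = NULL,
                         chrom_set = c("autosomes", "X")) {
  chrom_set <- match.arg(chrom_set)
  panel <- panel_chrom_set(panel, chrom_set)
  if (is.null(samples)) samples <- panel$samples
  g <- panel$genotypes[, samples, drop = FALSE]
  pairs <- utils::combn(samples, 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    gi <- g[, pairs[1, k]]; gj <- g[, pairs[2, k]]
    ok <- gi >= 0L & gj >= 0L
    gi <- gi[ok]; gj <- gj[ok]
    n_hh <- sum(gi == 1L & gj == 1L)
    n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
    den <- sum(gi == 1L) + sum(gj == 1L)
    out[[k]] <- tibble::tibble(
      id1 = pairs[1, k], id2 = pairs[2, k], n_sites = length(gi),
      n_het_het = n_hh, n_opp_hom = n_opp,
      phi = if (den > 0) (n_hh - 2 * n_opp) / den else NA_real_)
  }
  dplyr::bind_rows(out)
}

#' Exclude close relatives by greedy kinship pruning
#'
#' While any pair has kinship at or above the threshold, removes the sample
#' participating in the most such pairs (ties broken toward the later sample
#' in panel order). The default threshold 0.0884 excludes pairs related at
#' the third degree or closer.
#'
#' @param panel A `gt_panel`, or a kinship tibble from [king_kinship()].
#' @param threshold Kinship cut-off (default `2^-3.5`, printed 0.0884).
#' @param kinship Optional precomputed [king_kinship()] result when `panel`
#'   is a `gt_panel`.
#' @return Character vector of retained sample identifiers, with attribute
#'   `excluded`.
#' @export
prune_related <- function(panel, threshold = 0.0884, kinship = NULL) {
  if (inherits(panel, "gt_panel")) {
    samples <- panel$samples
    if (is.null(kinship)) kinship <- king_kinship(panel)
  } else {
    kinship <- panel
    samples <- unique(c(kinship$id1, kinship$id2))
  }
  kin <- kinship[!is.na(kinship$phi) & kinship$phi >= threshold, , drop = FALSE]
  retained <- samples
  excluded <- character(0)
  while (nrow(kin) > 0) {
    deg <- table(factor(c(kin$id1, kin$id2), levels = retained))
    worst <- names(deg)[deg == max(deg)]
    victim <- worst[which.max(match(worst, samples))]
    excluded <- c(excluded, victim)
    retained <- setdiff(retained, victim)
    kin <- kin[kin$id1 != victim & kin$id2 != victim, , drop = FALSE]
  }
  structure(retained, excluded = excluded, threshold = threshold)
}

#' Sliding-window LD pruning
#'
#' Within each window of `window` variants, repeatedly removes one variant
#' of any pair whose squared Pearson correlation of genotype codes exceeds
#' `r2_max` (the later variant in genomic order is dropped), then slides the
#' window by `step` variants. Windows never span chromosomes. Correlations
#' use samples non-missing in both variants; zero-variance variants are
#' retained.
#'
#' @param panel A `gt_panel`.
#' @param window Window size in variant count (default 50).
#' @param step Slide in variant count (default 5).
#' @param r2_max Maximum tolerated r-squared (default 0.5).
#' @return Integer vector of retained variant indices.
#' @export
ld_prune <- function(panel, window = 50, step = 5, r2_max = 0.5) {
  stopifnot(ncol(panel$genotypes) >= 2)
  g <- panel$genotypes
  g[g < 0L] <- NA_integer_
  chroms <- panel$variants$chrom
  removed <- rep(FALSE, nrow(g))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    start <- 1L
    repeat {
      win_all <- idx[start:min(start + window - 1L, length(idx))]
      win <- win_all[!removed[win_all]]
      if (length(win) >= 2) {
        r2 <- suppressWarnings(
          stats::cor(g[win, , drop = FALSE] |> t(),
                     use = "pairwise.complete.obs"))^2
        repeat {
          r2[!upper.tri(r2)] <- NA
          bad <- which(!is.na(r2) & r2 > r2_max, arr.ind = TRUE)
          if (nrow(bad) == 0) break
          # later variant (largest column index) of the first offending pair
          drop_local <- max(bad[1, ])
          removed[win[drop_local]] <- TRUE
          r2 <- r2[-drop_local, -drop_local, drop = FALSE]
          win <- win[-drop_local]
          if (length(win) < 2) break
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  which(!removed)
}
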