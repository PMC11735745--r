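#' Per-site Hudson FST components
#'
#' Numerator and denominator of Hudson's estimator with sampling correction:
#' `N = (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)`,
#' `D = p1 (1 - p2) + p2 (1 - p1)`, with `p` the alternate-allele frequency
#' and `n` the observed allele count in each population. Per-site values can
#' be negative; the genome-wide estimate is the ratio of averages, never the
#' average of per-site ratios.
#'
#' @param p1,p2 Alternate-allele frequencies in the two populations.
#' @param n1,n2 Observed allele counts (must be >= 2; sites failing this are
#'   returned as `NA` and should be counted as skipped by the caller).
#' @return Tibble with `num`, `den`, and `fst` (`num/den` where `den > 0`).
#' @export
hudson_components <- function(p1, n1, p2, n2) {
  ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  num <- den <- rep(NA_real_, length(p1))
  num[ok] <- (p1[ok] - p2[ok])^2 -
    p1[ok] * (1 - p1[ok]) / (n1[ok] - 1) -
    p2[ok] * (1 - p2[ok]) / (n2[ok] - 1)
  den[ok] <- p1[ok] * (1 - p2[ok]) + p2[ok] * (1 - p1[ok])
  tibble::tibble(num = num, den = den,
                 fst = ifelse(!is.na(den) & den > 0, num / den, NA_real_))
}

#' Genome-wide Hudson FST with block-jackknife standard error
#'
#' Averages the per-site numerators and denominators, takes the ratio, and
#' attaches a delete-one-block weighted jackknife standard error
#' ([block_ratio_estimate()]); the conventional block size is 25,000 SNVs.
#'
#' @param panel A `gt_panel`.
#' @param pop_a,pop_b Population labels.
#' @param chrom_set `"autosomes"` or `"X"`.
#' @param block_size Variants per jackknife block.
#' @param samples Optional sample subset (e.g. after relatedness pruning).
#' @return A `block_estimate` with extra fields `pop_a`, `pop_b`,
#'   `chrom_set`, `n_skipped` (sites with < 2 observed alleles in either
#'   population).
#' @export
hudson_fst <- function(panel, pop_a, pop_b,
                       chrom_set = c("autosomes", "X"),
                       block_size = 25000, samples = NULL) {
  chrom_set <- match.arg(chrom_set)
  if (!is.null(samples)) panel <- panel_subset(panel, samples = samples)
  panel <- panel_chrom_set(panel, chrom_set)
  pf <- pop_freqs(panel, c(pop_a, pop_b))
  comp <- hudson_components(pf$p[, pop_a], pf$n[, pop_a],
                            pf$p[, pop_b], pf$n[, pop_b])
  block <- partition_blocks(panel, block_size)
  est <- block_ratio_estimate(comp$num, comp$den, block, block_size)
  est$pop_a <- pop_a; est$pop_b <- pop_b; est$chrom_set <- chrom_set
  est$n_skipped <- sum(is.na(comp$num))
  est
}

#' Population-specific FST per variant with top-tail outlier designation
#'
#' Per-variant Hudson `N/D` between the target population and the pooled
#' background (all other panel samples, or an explicit background after
#' relatedness exclusion). Both SNVs and indels are eligible. The upper
#' `top_fraction` tail of defined per-variant values is designated as the
#' population-specific set; ties at the cut-off value are all included.
#'
#' @param panel A `gt_panel`.
#' @param target_pop Target population label.
#' @param top_fraction Upper-tail fraction designated (default 0.01).
#' @param background_samples Background sample set (default: every panel
#'   sample not in `target_pop`).
#' @return Tibble with one row per variant: `chrom`, `pos`, `class`, `fst`,
#'   `outlier` (logical; `NA` fst is never an outlier). Attribute `cutoff`
#'   holds the designation threshold.
#' @export
population_specific_fst <- function(panel, target_pop, top_fraction = 0.01,
                                    background_samples = NULL) {
  target_samples <- panel$samples[panel$populations == target_pop]
  if (is.null(background_samples)) {
    background_samples <- setdiff(panel$samples, target_samples)
  }
  if (length(background_samples) == 0) {
    rlang::abort("background sample set is empty",
                 class = "popgenpanel_config_error")
  }
  t_ac <- allele_counts(panel, target_samples)
  b_ac <- allele_counts(panel, background_samples)
  comp <- hudson_components(t_ac$p, t_ac$an, b_ac$p, b_ac$an)
  vals <- comp$fst
  defined <- which(!is.na(vals))
  n_top <- max(1L, ceiling(top_fraction * length(defined)))
  cutoff <- sort(vals[defined], decreasing = TRUE)[min(n_top, length(defined))]
  outlier <- !is.na(vals) & vals >= cutoff
  out <- tibble::tibble(chrom = panel$variants$chrom, pos = panel$variants$pos,
                        class = panel$variants$class, fst = vals,
                        outlier = outlier)
  attr(out, "cutoff") <- cutoff
  out
}

#' X-to-autosome drift ratio (Q statistic)
#'
#' With per-chromosome-set drift `d = -ln(1 - FST)`, the statistic is
#' `Q = d_auto / d_X = ln(1 - FST_auto) / ln(1 - FST_X)`. Under equal
#' effective sizes and migration for both sexes the X drifts 4/3 as fast as
#' the autosomes and Q is expected to be 0.75; smaller values indicate
#' relatively stronger X drift (e.g. male-biased migration). The result is
#' undefined when either FST estimate lies outside (0, 1), mirroring cases
#' where the computation is impractical for highly differentiated pairs.
#'
#' @param fst_auto,fst_x Genome-wide FST estimates (numbers or
#'   `block_estimate` objects).
#' @return One-row tibble with `fst_auto`, `fst_x`, `q`, `defined`.
#' @export
q_statistic <- function(fst_auto, fst_x) {
  val <- function(x) if (inherits(x, "block_estimate")) x$estimate else x
  fa <- val(fst_auto); fx <- val(fst_x)
  defined <- is.finite(fa) && is.finite(fx) &&
    fa > 0 && fa < 1 && fx > 0 && fx < 1
  tibble::tibble(
    fst_auto = fa, fst_x = fx,
    q = if (defined) log(1 - fa) / log(1 - fx) else NA_real_,
    defined = defined)
}

#' Pairwise FST table across populations and chromosome sets
#'
#' Computes [hudson_fst()] for every population pair on autosomes and
#' (when X sites exist) on the X, in the conventional square layout: the
#' upper-right triangle holds autosomal values, the lower-left triangle the
#' X values, standard errors in parentheses.
#'
#' @param panel A `gt_panel`.
#' @param block_size Jackknife block size.
#' @param samples Optional sample subset.
#' @return Tibble with `pop_a`, `pop_b`, `chrom_set`, `fst`, `se`, `z`,
#'   `n_blocks`, of class `fst_table`.
#' @export
fst_table <- function(panel, block_size = 25000, samples = NULL) {
  pops <- unique(unname(panel$populations))
  sets <- "autosomes"
  if (any(panel$variants$chrom %in% c("chrX", "X"))) sets <- c(sets, "X")
  pairs <- utils::combn(pops, 2)
  out <- list()
  for (set in sets) {
    for (j in seq_len(ncol(pairs))) {
      est <- hudson_fst(panel, pairs[1, j], pairs[2, j], set, block_size,
                        samples)
      out[[length(out) + 1]] <- tibble::tibble(
        pop_a = pairs[1, j], pop_b = pairs[2, j], chrom_set = set,
        fst = est$estimate, se = est$se, z = est$z, n_blocks = est$n_blocks)
    }
  }
  structure(dplyr::bind_rows(out), class = c("fst_table", "tbl_df", "tbl",
                                             "data.frame"))
}

#' Format an FST table as a square matrix
#'
#' @param x An `fst_table`.
#' @param digits Digits for the `"value (se)"` formatting.
#' @return Character matrix with autosomal values in the upper-right and X
#'   values in the lower-left triangle (empty when no X values exist).
#' @export
fst_matrix <- function(x, digits = 3) {
  pops <- unique(c(x$pop_a, x$pop_b))
  m <- matrix("", length(pops), length(pops), dimnames = list(pops, pops))
  fmt <- function(f, s) sprintf("%.*f (%.*f)", digits, f, digits, s)
  for (i in seq_len(nrow(x))) {
    a <- x$pop_a[i]; b <- x$pop_b[i]
    ia <- match(a, pops); ib <- match(b, pops)
    up <- sort(c(ia, ib))
    if (x$chrom_set[i] == "autosomes") {
      m[up[1], up[2]] <- fmt(x$fst[i], x$se[i])
    } else {
      m[up[2], up[1]] <- fmt(x$fst[i], x$se[i])
    }
  }
  m
}
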