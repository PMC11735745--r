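#' Construct a genotype panel
#'
#' A `gt_panel` is the universal substrate of the package: a site-by-sample
#' matrix of diploid/haploid genotype codes together with variant metadata,
#' sample identifiers, a sample-to-population mapping and a ploidy table.
#'
#' Genotype codes are `0` (homozygous reference), `1` (heterozygous),
#' `2` (homozygous alternate) and `-1` (missing). Haploid entries (e.g. male
#' samples on the non-pseudoautosomal X) are restricted to `{0, 2, -1}`: a
#' single reference allele is coded `0`, a single alternate allele `2`.
#' Phase is deliberately dropped (`0|1` and `0/1` are the same code); no
#' statistic in the package is haplotype-aware.
#'
#' @param variants Tibble with at least `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`, `class` (`"snv"` or `"indel"`). Additional numeric columns
#'   (`qual`, `QD`, `FS`, ...) are kept and used by [hard_filter()].
#' @param genotypes Integer matrix `n_variants x n_samples` of genotype codes.
#' @param samples Character vector of sample identifiers (column order of
#'   `genotypes`).
#' @param populations Named character vector mapping every sample to a
#'   population label.
#' @param ploidy Tibble with columns `sample`, `chrom`, `ploidy`; pairs not
#'   listed default to ploidy 2. `NULL` means everything is diploid.
#'
#' @return An object of class `gt_panel`.
#' @seealso [read_vcf()], [simulate_panel()]
#' @export
gt_panel <- function(variants, genotypes, samples, populations, ploidy = NULL) {
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "class") %in% names(variants)))
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(variants) != nrow(genotypes)) {
    rlang::abort("`variants` and `genotypes` disagree on the number of sites")
  }
  samples <- as.character(samples)
  if (ncol(genotypes) != length(samples)) {
    rlang::abort("`genotypes` must have one column per sample")
  }
  colnames(genotypes) <- samples
  if (!all(samples %in% names(populations))) {
    missing <- setdiff(samples, names(populations))
    rlang::abort(paste0("samples missing from the population map: ",
                        paste(missing, collapse = ", ")))
  }
  populations <- populations[samples]
  if (is.null(ploidy)) {
    ploidy <- tibble::tibble(sample = character(), chrom = character(),
                             ploidy = integer())
  }
  ploidy <- tibble::as_tibble(ploidy)
  x <- structure(
    list(variants = variants, genotypes = genotypes, samples = samples,
         populations = populations, ploidy = ploidy),
    class = "gt_panel"
  )
  validate_gt_panel(x)
}

validate_gt_panel <- function(x) {
  v <- x$variants
  if (nrow(v) > 1L) {
    o <- order(v$chrom, v$pos)
    if (!identical(o, seq_len(nrow(v)))) {
      rlang::abort("variants must be sorted by (chrom, pos)")
    }
  }
  if (any(!x$genotypes %in% c(-1L, 0L, 1L, 2L))) {
    rlang::abort("genotype codes must be in {-1, 0, 1, 2}")
  }
  pm <- ploidy_matrix(x)
  if (any(pm == 1L & x$genotypes == 1L)) {
    rlang::abort("haploid entries cannot be heterozygous (code 1)")
  }
  x
}

#' @export
print.gt_panel <- function(x, ...) {
  cat(sprintf("<gt_panel> %d variants x %d samples\n",
              n_variants(x), length(x$samples)))
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  pops <- table(x$populations)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  invisible(x)
}

#' Number of variants in a panel
#' @param panel A `gt_panel`.
#' @return Integer count of variant sites.
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' Ploidy of every (variant, sample) cell
#'
#' Expands the panel's ploidy table to a matrix aligned with the genotype
#' matrix. Unlisted (sample, chromosome) pairs are diploid.
#'
#' @param panel A `gt_panel`.
#' @return Integer matrix `n_variants x n_samples` of 1s and 2s.
#' @export
ploidy_matrix <- function(panel) {
  n_v <- nrow(panel$genotypes)
  n_s <- ncol(panel$genotypes)
  pm <- matrix(2L, n_v, n_s, dimnames = list(NULL, panel$samples))
  if (nrow(panel$ploidy) > 0L) {
    chroms <- panel$variants$chrom
    for (i in seq_len(nrow(panel$ploidy))) {
      s <- panel$ploidy$sample[i]
      if (!s %in% panel$samples) next
      rows <- chroms == panel$ploidy$chrom[i]
      pm[rows, s] <- as.integer(panel$ploidy$ploidy[i])
    }
  }
  pm
}

#' Subset a panel by variant index or sample
#'
#' @param panel A `gt_panel`.
#' @param variants Integer or logical index over variant rows (`NULL` keeps all).
#' @param samples Character vector of sample names to keep (`NULL` keeps all).
#' @return A `gt_panel` restricted to the requested sites and samples.
#' @export
panel_subset <- function(panel, variants = NULL, samples = NULL) {
  if (is.null(variants)) variants <- seq_len(n_variants(panel))
  if (is.logical(variants)) variants <- which(variants)
  if (is.null(samples)) samples <- panel$samples
  stopifnot(all(samples %in% panel$samples))
  gt_panel(
    variants = panel$variants[variants, , drop = FALSE],
    genotypes = panel$genotypes[variants, samples, drop = FALSE],
    samples = samples,
    populations = panel$populations[samples],
    ploidy = panel$ploidy[panel$ploidy$sample %in% samples, , drop = FALSE]
  )
}

#' Restrict a panel to a chromosome set
#'
#' @param panel A `gt_panel`.
#' @param chrom_set `"autosomes"` (everything but the X) or `"X"`.
#' @param x_chroms Chromosome labels treated as the X.
#' @return A `gt_panel` containing only the requested chromosomes.
#' @export
panel_chrom_set <- function(panel, chrom_set = c("autosomes", "X"),
                            x_chroms = c("chrX", "X")) {
  chrom_set <- match.arg(chrom_set)
  on_x <- panel$variants$chrom %in% x_chroms
  panel_subset(panel, variants = if (chrom_set == "X") on_x else !on_x)
}

#' Per-site allele counts for a set of samples
#'
#' Counts observed alternate alleles and observed allele totals per site,
#' honouring ploidy: a diploid genotype contributes `code` alternate alleles
#' out of 2, a haploid genotype contributes `code/2` out of 1. Missing
#' genotypes contribute nothing.
#'
#' @param panel A `gt_panel`.
#' @param samples Samples to pool (default: all).
#' @return Tibble with `ac` (alt allele count), `an` (total observed alleles)
#'   and `p` (`ac/an`, `NA` where `an == 0`), one row per variant.
#' @export
allele_counts <- function(panel, samples = NULL) {
  if (is.null(samples)) samples <- panel$samples
  g <- panel$genotypes[, samples, drop = FALSE]
  pm <- ploidy_matrix(panel)[, samples, drop = FALSE]
  obs <- g >= 0L
  alt <- ifelse(obs, ifelse(pm == 1L, g / 2, g), 0)
  an <- rowSums(ifelse(obs, pm, 0L))
  ac <- rowSums(alt)
  tibble::tibble(ac = ac, an = an, p = ifelse(an > 0, ac / an, NA_real_))
}

#' Per-population allele frequencies
#'
#' @param panel A `gt_panel`.
#' @param pops Population labels (default: all populations in the panel).
#' @return List with matrices `p` (alt frequency) and `n` (observed allele
#'   count), each `n_variants x n_pops`.
#' @export
pop_freqs <- function(panel, pops = NULL) {
  if (is.null(pops)) pops <- unique(unname(panel$populations))
  p <- n <- matrix(NA_real_, n_variants(panel), length(pops),
                   dimnames = list(NULL, pops))
  for (pp in pops) {
    members <- panel$samples[panel$populations == pp]
    ac <- allele_counts(panel, members)
    p[, pp] <- ac$p
    n[, pp] <- ac$an
  }
  list(p = p, n = n)
}

#' Variant metadata and genotypes as a long tibble
#'
#' @param x A `gt_panel`.
#' @param ... Unused.
#' @return Tibble with one row per (variant, sample) holding the genotype code.
#' @method as_tibble gt_panel
#' @export
as_tibble.gt_panel <- function(x, ...) {
  g <- x$genotypes
  tibble::tibble(
    chrom = rep(x$variants$chrom, times = ncol(g)),
    pos = rep(x$variants$pos, times = ncol(g)),
    sample = rep(colnames(g), each = nrow(g)),
    population = rep(unname(x$populations[colnames(g)]), each = nrow(g)),
    genotype = as.integer(g)
  )
}
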