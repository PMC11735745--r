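#' Per-individual heterozygosity
#'
#' Heterozygosity per base pair: the number of heterozygous autosomal calls
#' divided by the number of accessible genomic sites (the filter-passing
#' denominator, not just variant sites). Missing genotypes are excluded from
#' the numerator only.
#'
#' @param panel A `gt_panel`.
#' @param accessible_site_total Number of genomic positions passing the site
#'   filters (> 0).
#' @param chrom_set Chromosome set, normally `"autosomes"`.
#' @return Tibble with `sample`, `population`, `n_het`, `heterozygosity`.
#' @export
individual_heterozygosity <- function(panel, accessible_site_total,
                                      chrom_set = c("autosomes", "X")) {
  if (accessible_site_total <= 0) {
    rlang::abort("accessible_site_total must be > 0")
  }
  chrom_set <- match.arg(chrom_set)
  panel <- panel_chrom_set(panel, chrom_set)
  n_het <- colSums(panel$genotypes == 1L)
  tibble::tibble(
    sample = panel$samples,
    population = unname(panel$populations[panel$samples]),
    n_het = unname(n_het),
    heterozygosity = unname(n_het) / accessible_site_total
  )
}

#' Panel nucleotide diversity
#'
#' `pi = sum_sites 2 * p * (1 - p) * n / (n - 1) / accessible_site_total`,
#' with `p` the sample alternate-allele frequency and `n` the observed
#' allele count at the site (missing genotypes excluded; sites with fewer
#' than 2 observed alleles skipped).
#'
#' @param panel A `gt_panel`.
#' @param accessible_site_total Accessible-site denominator (> 0).
#' @param samples Samples to pool (default: all).
#' @return Nucleotide diversity per accessible base pair.
#' @export
panel_pi <- function(panel, accessible_site_total, samples = NULL) {
  if (accessible_site_total <= 0) {
    rlang::abort("accessible_site_total must be > 0")
  }
  ac <- allele_counts(panel, samples)
  ok <- ac$an >= 2
  terms <- 2 * ac$p[ok] * (1 - ac$p[ok]) * ac$an[ok] / (ac$an[ok] - 1)
  sum(terms) / accessible_site_total
}

roh_default_params <- function() {
  list(trans_hw_az = 6.6e-9,  # per-bp rate of entering autozygosity
       trans_az_hw = 5.0e-9,  # per-bp rate of leaving autozygosity
       err = 1e-3,            # genotyping-error shrink on P(het | outbred)
       err_het = 1e-3,        # floor on P(het | outbred)
       err_az = 1e-3,         # P(het | autozygous)
       max_quality = 99)
}

# emission probabilities of the observed het/hom symbol per site
roh_emissions <- function(het, p, params) {
  e_het_hw <- 2 * p * (1 - p) * (1 - params$err) + params$err_het
  e_het_az <- rep(params$err_az, length(p))
  cbind(hw = ifelse(het, e_het_hw, 1 - e_het_hw),
        az = ifelse(het, e_het_az, 1 - e_het_az))
}

roh_transitions <- function(dist_bp, params) {
  p_in <- 1 - exp(-params$trans_hw_az * dist_bp)
  p_out <- 1 - exp(-params$trans_az_hw * dist_bp)
  list(p_in = p_in, p_out = p_out)
}

# Viterbi decode of the two-state HW/AZ chain; returns integer vector
# (1 = HW, 2 = AZ)
roh_viterbi <- function(em, tr, start = c(0.5, 0.5)) {
  n <- nrow(em)
  lv <- matrix(-Inf, n, 2)
  back <- matrix(1L, n, 2)
  lv[1, ] <- log(start) + log(em[1, ])
  for (i in seq_len(n - 1)) {
    lt <- log(matrix(c(1 - tr$p_in[i], tr$p_in[i],
                       tr$p_out[i], 1 - tr$p_out[i]), 2, 2, byrow = TRUE))
    for (s in 1:2) {
      cand <- lv[i, ] + lt[, s]
      back[i + 1, s] <- which.max(cand)
      lv[i + 1, s] <- max(cand) + log(em[i + 1, s])
    }
  }
  path <- integer(n)
  path[n] <- which.max(lv[n, ])
  for (i in rev(seq_len(n - 1))) path[i] <- back[i + 1, path[i + 1]]
  path
}

# scaled forward-backward; returns posterior P(AZ) per site
roh_posterior <- function(em, tr, start = c(0.5, 0.5)) {
  n <- nrow(em)
  fwd <- matrix(0, n, 2)
  scale <- numeric(n)
  fwd[1, ] <- start * em[1, ]
  scale[1] <- sum(fwd[1, ])
  fwd[1, ] <- fwd[1, ] / scale[1]
  for (i in seq_len(n - 1)) {
    tm <- matrix(c(1 - tr$p_in[i], tr$p_in[i],
                   tr$p_out[i], 1 - tr$p_out[i]), 2, 2, byrow = TRUE)
    f <- (fwd[i, ] %*% tm) * em[i + 1, ]
    scale[i + 1] <- sum(f)
    fwd[i + 1, ] <- f / scale[i + 1]
  }
  bwd <- matrix(0, n, 2)
  bwd[n, ] <- 1
  for (i in rev(seq_len(n - 1))) {
    tm <- matrix(c(1 - tr$p_in[i], tr$p_in[i],
                   tr$p_out[i], 1 - tr$p_out[i]), 2, 2, byrow = TRUE)
    bwd[i, ] <- tm %*% (em[i + 1, ] * bwd[i + 1, ]) / scale[i + 1]
  }
  post <- fwd * bwd
  post[, 2] / rowSums(post)
}

#' Call runs of homozygosity with a two-state HMM
#'
#' A hidden Markov model over the sample's genotyped variant sites with
#' states HW (outbred, Hardy-Weinberg emissions given the site's population
#' alternate frequency) and AZ (autozygous, heterozygotes only through
#' error). Transition probabilities scale with the physical distance
#' between adjacent sites. The Viterbi path defines segments (first to last
#' AZ site); segment quality is the Phred-scaled mean forward-backward
#' posterior of AZ over the segment's sites,
#' `-10 * log10(1 - mean posterior)`, capped at `params$max_quality`.
#'
#' @param panel A `gt_panel`.
#' @param sample Sample identifier.
#' @param allele_freqs Optional per-variant alternate-allele frequencies;
#'   default: panel-wide empirical frequencies.
#' @param params HMM parameters, see `roh_default_params()`: per-bp
#'   transition rates `trans_hw_az` (6.6e-9) and `trans_az_hw` (5e-9),
#'   emission error terms, quality cap.
#' @return Tibble of segments: `sample`, `chrom`, `start`, `end`, `n_sites`,
#'   `quality`, `length`.
#' @export
roh_call <- function(panel, sample, allele_freqs = NULL,
                     params = roh_default_params()) {
  stopifnot(sample %in% panel$samples)
  params <- utils::modifyList(roh_default_params(), params)
  if (is.null(allele_freqs)) allele_freqs <- allele_counts(panel)$p
  if (any(allele_freqs < 0 | allele_freqs > 1, na.rm = TRUE)) {
    rlang::abort("allele frequencies must lie in [0, 1]")
  }
  v <- panel$variants
  g <- panel$genotypes[, sample]
  segs <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch & g >= 0L & !is.na(allele_freqs))
    if (length(idx) < 2) next
    pos <- v$pos[idx]
    if (is.unsorted(pos)) rlang::abort("sites are not position-sorted")
    het <- g[idx] == 1L
    em <- roh_emissions(het, allele_freqs[idx], params)
    tr <- roh_transitions(diff(pos), params)
    path <- roh_viterbi(em, tr)
    post <- roh_posterior(em, tr)
    runs <- rle(path == 2L)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      span <- starts[r]:ends[r]
      q <- -10 * log10(pmax(1 - mean(post[span]), 1e-300))
      segs[[length(segs) + 1]] <- tibble::tibble(
        sample = sample, chrom = ch,
        start = pos[starts[r]], end = pos[ends[r]],
        n_sites = length(span),
        quality = min(q, params$max_quality))
    }
  }
  out <- if (length(segs) > 0) dplyr::bind_rows(segs) else {
    tibble::tibble(sample = character(), chrom = character(),
                   start = integer(), end = integer(),
                   n_sites = integer(), quality = numeric())
  }
  out$length <- out$end - out$start + 1L
  out
}

#' Filter ROH segments by quality and length
#'
#' Keeps segments with Phred quality at or above `min_quality` and length at
#' or above `min_length` (boundary values kept; segments below 30 or shorter
#' than 100 kb are filtered out under the defaults).
#'
#' @param segments Tibble from [roh_call()].
#' @param min_quality Minimum Phred quality (default 30).
#' @param min_length Minimum length in bp (default 100,000).
#' @return Filtered tibble.
#' @export
roh_filter <- function(segments, min_quality = 30, min_length = 100000) {
  len <- segments$end - segments$start + 1L
  segments[segments$quality >= min_quality & len >= min_length, , drop = FALSE]
}
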