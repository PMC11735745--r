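# Build a small panel from a genotype matrix (rows = sites, cols = samples).
# Populations default to one per sample prefix before "_", else "P".
toy_panel <- function(g, chrom = "chr1", pos = NULL, samples = NULL,
                      populations = NULL, ploidy = NULL, class = "snv",
                      ref = "A", alt = "T") {
  g <- as.matrix(g)
  n <- nrow(g)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(samples)) {
    samples <- colnames(g) %||% paste0("S", seq_len(ncol(g)))
  }
  if (is.null(populations)) {
    pref <- sub("_.*$", "", samples)
    populations <- stats::setNames(
      if (all(grepl("_", samples))) pref else rep("P", length(samples)),
      samples)
  }
  variants <- tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    class = rep_len(class, n))
  gt_panel(variants, g, samples, populations, ploidy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force genome-wide Hudson FST from genotype codes,
# written directly from the within/between heterozygosity definition
oracle_hudson_fst <- function(g1, g2) {
  num <- den <- 0
  for (i in seq_len(nrow(g1))) {
    a1 <- sum(g1[i, g1[i, ] >= 0]); n1 <- 2 * sum(g1[i, ] >= 0)
    a2 <- sum(g2[i, g2[i, ] >= 0]); n2 <- 2 * sum(g2[i, ] >= 0)
    if (n1 < 2 || n2 < 2) next
    p1 <- a1 / n1; p2 <- a2 / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num / den
}
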