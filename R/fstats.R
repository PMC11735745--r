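#' f4 statistic with block-jackknife Z-score
#'
#' Per-site term `(pA - pB)(pC - pD)` of population alternate-allele
#' frequencies, averaged over sites with all four populations observed
#' (unweighted mean; each retained site has weight 1). The standard error
#' and Z-score come from the delete-one-block weighted jackknife. Under a
#' simple tree in which (A, B) and (C, D) are symmetric pairs, f4 is 0;
#' gene flow pushes it away from 0 with a sign given by the tree
#' orientation. A single individual may stand as a population, in which
#' case its frequencies take values 0, 0.5, 1.
#'
#' @param panel A `gt_panel`.
#' @param A,B,C,D Distinct population labels.
#' @param block_size Jackknife block size in variants (default 25,000).
#' @param chrom_set Chromosome set (default autosomes).
#' @return An `fstat_result`: list with `kind = "f4"`, `pops`, and the
#'   `block_estimate` fields (`estimate`, `se`, `z`, ...).
#' @export
f4 <- function(panel, A, B, C, D, block_size = 25000,
               chrom_set = c("autosomes", "X")) {
  pops <- c(A, B, C, D)
  if (anyDuplicated(pops)) rlang::abort("populations must be distinct")
  chrom_set <- match.arg(chrom_set)
  panel <- panel_chrom_set(panel, chrom_set)
  pf <- pop_freqs(panel, pops)
  term <- (pf$p[, A] - pf$p[, B]) * (pf$p[, C] - pf$p[, D])
  ok <- rowSums(pf$n > 0) == 4 & !is.na(term)
  block <- partition_blocks(panel, block_size)
  est <- block_ratio_estimate(ifelse(ok, term, NA_real_),
                              ifelse(ok, 1, NA_real_), block, block_size)
  structure(c(list(kind = "f4", pops = pops), unclass(est)),
            class = c("fstat_result", "block_estimate"))
}

#' Outgroup f3 statistic
#'
#' Per-site term `(pO - pA)(pO - pB)`, measuring the drift shared by A and
#' B relative to the outgroup O: larger values mean A and B share more of
#' their history. Aggregation and jackknife as in [f4()].
#'
#' @param panel A `gt_panel`.
#' @param O,A,B Distinct population labels; `O` is the outgroup.
#' @param block_size Jackknife block size in variants.
#' @param chrom_set Chromosome set (default autosomes).
#' @return An `fstat_result` with `kind = "f3"`.
#' @export
f3_outgroup <- function(panel, O, A, B, block_size = 25000,
                        chrom_set = c("autosomes", "X")) {
  pops <- c(O, A, B)
  if (anyDuplicated(pops)) rlang::abort("populations must be distinct")
  chrom_set <- match.arg(chrom_set)
  panel <- panel_chrom_set(panel, chrom_set)
  pf <- pop_freqs(panel, pops)
  term <- (pf$p[, O] - pf$p[, A]) * (pf$p[, O] - pf$p[, B])
  ok <- rowSums(pf$n > 0) == 3 & !is.na(term)
  block <- partition_blocks(panel, block_size)
  est <- block_ratio_estimate(ifelse(ok, term, NA_real_),
                              ifelse(ok, 1, NA_real_), block, block_size)
  structure(c(list(kind = "f3", pops = pops), unclass(est)),
            class = c("fstat_result", "block_estimate"))
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("<%s(%s)> %.6g (SE %.3g, Z %.3g), %d sites in %d blocks\n",
              x$kind, paste(x$pops, collapse = ", "), x$estimate, x$se, x$z,
              x$n_sites, x$n_blocks))
  invisible(x)
}

#' @rdname tidy.block_estimate
#' @method tidy fstat_result
#' @export
tidy.fstat_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(statistic_kind = x$kind,
                   pops = paste(x$pops, collapse = ",")),
    tidy.block_estimate(x))
}
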