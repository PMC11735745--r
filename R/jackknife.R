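#' Genome-wide ratio statistic with weighted block-jackknife error
#'
#' All genome-wide statistics in the package (Hudson FST, f3, f4) are ratios
#' of sums of per-site terms. The point estimate is the ratio of averages
#' (sum of numerators over sum of denominators) and the standard error comes
#' from a delete-one-block weighted jackknife in which blocks are weighted by
#' their variant count, so a short final block on a chromosome contributes
#' proportionally (Busing's weighted delete-one formula).
#'
#' @param num,den Per-site numerator and denominator terms (equal length).
#'   Sites with `NA` in either are dropped.
#' @param block Integer block id per site, e.g. from [partition_blocks()].
#' @param block_size Nominal block size, recorded in the result.
#' @return A `block_estimate`: list with `estimate`, `se`, `z`, `n_blocks`,
#'   `n_sites`, `block_size` and per-block components `block_num`,
#'   `block_den`, `block_m`. `se` and `z` are `NA` with fewer than 2 blocks.
#' @export
block_ratio_estimate <- function(num, den, block, block_size = NA_integer_) {
  keep <- !(is.na(num) | is.na(den))
  num <- num[keep]; den <- den[keep]; block <- block[keep]
  tot_n <- sum(num); tot_d <- sum(den)
  if (tot_d <= 0) {
    rlang::abort("total denominator is not positive; statistic undefined")
  }
  est <- tot_n / tot_d
  bn <- tapply(num, block, sum)
  bd <- tapply(den, block, sum)
  bm <- tapply(num, block, length)
  g <- length(bn)
  if (g < 2) {
    se <- NA_real_
  } else {
    theta_j <- (tot_n - bn) / (tot_d - bd)
    n <- sum(bm)
    h <- n / bm
    tau <- h * est - (h - 1) * theta_j
    theta_dot <- g * est - sum((1 - 1 / h) * theta_j)
    se <- sqrt(sum((tau - theta_dot)^2 / (h - 1)) / g)
  }
  structure(
    list(estimate = est, se = se,
         z = if (!is.na(se) && se > 0) est / se else NA_real_,
         n_blocks = g, n_sites = length(num),
         block_size = block_size,
         block_num = as.numeric(bn), block_den = as.numeric(bd),
         block_m = as.integer(bm)),
    class = "block_estimate"
  )
}

#' @export
print.block_estimate <- function(x, ...) {
  cat(sprintf("<block_estimate> %.6g (SE %.3g, Z %.3g) from %d blocks / %d sites\n",
              x$estimate, x$se, x$z, x$n_blocks, x$n_sites))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a block-jackknife estimate
#'
#' @param x A `block_estimate`.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `std.error`, `statistic` (the
#'   Z-score), `n.blocks`, `n.sites`.
#' @method tidy block_estimate
#' @export
tidy.block_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, std.error = x$se, statistic = x$z,
                 n.blocks = x$n_blocks, n.sites = x$n_sites)
}

#' @rdname tidy.block_estimate
#' @method glance block_estimate
#' @export
glance.block_estimate <- function(x, ...) tidy.block_estimate(x)
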