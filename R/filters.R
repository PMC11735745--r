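#' Brute-force (k, e)-mappability scores
#'
#' The score at position `i` is `1 / m` where `m` is the number of start
#' positions in `sequence` whose k-mer lies within Hamming distance `e` of
#' the k-mer starting at `i` (forward strand only; a caller emulating
#' strand-aware tools can concatenate the reverse complement). A score of 1
#' means the 30-mer (for the conventional `k = 30, e = 2`) is unique in the
#' genome even allowing two mismatches; the site filter retains exactly
#' those positions. Brute force by design — intended for the small synthetic
#' genomes used in testing, not for genome-scale masking.
#'
#' @param sequence A single character string over `A/C/G/T`.
#' @param k K-mer length (default 30).
#' @param e Maximum Hamming distance (default 2).
#' @return Numeric vector of scores, one per position at which a full k-mer
#'   starts (length `nchar(sequence) - k + 1`; empty if the sequence is
#'   shorter than `k`).
#' @export
mappability_scores <- function(sequence, k = 30, e = 2) {
  stopifnot(k >= 1, e >= 0)
  s <- utf8ToInt(toupper(sequence))
  n <- length(s) - k + 1
  if (n < 1) return(numeric(0))
  # k x n matrix of k-mer letters
  km <- vapply(seq_len(n), function(i) s[i:(i + k - 1)], integer(k))
  if (k == 1) km <- matrix(km, nrow = 1)
  counts <- vapply(seq_len(n), function(i) {
    sum(colSums(km != km[, i]) <= e)
  }, numeric(1))
  1 / counts
}

#' Coverage-mode accessibility mask
#'
#' Sums depth across samples at each site, finds the mode of the total-depth
#' distribution (ties broken toward the smaller value) and retains sites
#' whose total depth lies within `[mode / 2, 2 * mode]`, both bounds
#' inclusive.
#'
#' @param depth_matrix Non-negative integer matrix `n_sites x n_samples`.
#' @return List with `mode`, `low`, `high` and `retained` (logical per site).
#' @export
accessibility_mask <- function(depth_matrix) {
  stopifnot(nrow(depth_matrix) > 0, all(depth_matrix >= 0))
  total <- rowSums(depth_matrix)
  tab <- table(total)
  mode <- min(as.numeric(names(tab)[tab == max(tab)]))
  if (mode == 0) {
    rlang::warn("modal total depth is 0; accessibility band is degenerate")
  }
  low <- mode / 2
  high <- 2 * mode
  list(mode = mode, low = low, high = high,
       retained = total >= low & total <= high)
}

#' Default hard-filter rule set
#'
#' GATK-style expression thresholds: SNVs fail on `QD < 2`, `QUAL < 30`,
#' `SOR > 3`, `FS > 60`, `MQ < 40`, `MQRankSum < -12.5`,
#' `ReadPosRankSum < -8`, `ExcessHet > 30`; indels fail on `QD < 2`,
#' `QUAL < 30`, `FS > 200`, `ReadPosRankSum < -20`, `ExcessHet > 30`.
#'
#' @return Tibble with `class`, `key`, `op`, `threshold`.
#' @export
default_hard_filter_rules <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      class = "snv",
      key = c("QD", "qual", "SOR", "FS", "MQ", "MQRankSum",
              "ReadPosRankSum", "ExcessHet"),
      op = c("<", "<", ">", ">", "<", "<", "<", ">"),
      threshold = c(2, 30, 3, 60, 40, -12.5, -8, 30)),
    tibble::tibble(
      class = "indel",
      key = c("QD", "qual", "FS", "ReadPosRankSum", "ExcessHet"),
      op = c("<", "<", ">", "<", ">"),
      threshold = c(2, 30, 200, -20, 30))
  )
}

#' Apply hard-filter threshold rules to a panel
#'
#' A variant is removed if any rule for its class fires on a present
#' annotation; absent (`NA`) annotations never fire, matching the observable
#' behaviour of expression-based filtering on missing fields.
#'
#' @param panel A `gt_panel` whose variant table carries annotation columns.
#' @param rules Tibble with `class` (`"snv"`/`"indel"`), `key` (a variant
#'   column), `op` (one of `<`, `<=`, `>`, `>=`), `threshold`.
#' @return A `site_mask`: list with `retained` (logical per variant),
#'   `n_removed` (named count per filter label `class:key`) and
#'   `n_missing_annotation`.
#' @export
hard_filter <- function(panel, rules = default_hard_filter_rules()) {
  v <- panel$variants
  ops <- list(`<` = `<`, `<=` = `<=`, `>` = `>`, `>=` = `>=`)
  bad_op <- setdiff(unique(rules$op), names(ops))
  if (length(bad_op) > 0) {
    rlang::abort(paste0("unknown comparator: ", paste(bad_op, collapse = ", ")),
                 class = "popgenpanel_config_error")
  }
  fails <- matrix(FALSE, nrow(v), nrow(rules))
  n_missing <- 0L
  for (i in seq_len(nrow(rules))) {
    in_class <- v$class == rules$class[i]
    key <- rules$key[i]
    if (!key %in% names(v)) {
      n_missing <- n_missing + sum(in_class)
      next
    }
    val <- v[[key]]
    n_missing <- n_missing + sum(in_class & is.na(val))
    fires <- in_class & !is.na(val) & ops[[rules$op[i]]](val, rules$threshold[i])
    fails[, i] <- fires
  }
  removed <- rowSums(fails) > 0
  labels <- paste(rules$class, rules$key, sep = ":")
  n_removed <- stats::setNames(colSums(fails), labels)
  structure(
    list(retained = !removed, n_removed = n_removed,
         n_missing_annotation = n_missing),
    class = "site_mask"
  )
}

#' @export
print.site_mask <- function(x, ...) {
  cat(sprintf("<site_mask> %d / %d sites retained\n",
              sum(x$retained), length(x$retained)))
  invisible(x)
}

#' Combine site masks by intersection
#'
#' Filters are order-independent: a site is retained iff every mask retains
#' it.
#'
#' @param ... Logical vectors or `site_mask` objects of equal length.
#' @return Logical vector of jointly retained sites.
#' @export
combine_masks <- function(...) {
  masks <- lapply(list(...), function(m) {
    if (inherits(m, "site_mask")) m$retained else as.logical(m)
  })
  Reduce(`&`, masks)
}
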