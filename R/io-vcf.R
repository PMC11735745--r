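#' Read a VCF into a genotype panel
#'
#' Parses a (plain or gzipped) VCF 4.x with vcfR, keeps biallelic records
#' only, and converts GT fields to genotype codes. Phased and unphased calls
#' are collapsed (`0|1` is `0/1`). Multiallelic records are skipped and
#' counted in the `n_skipped_multiallelic` attribute.
#'
#' @param path Path to a VCF file (`.vcf` or `.vcf.gz`).
#' @param sample_population_map Named character vector or two-column data
#'   frame (`sample`, `population`). Every VCF sample must be present.
#' @param ploidy_rules Optional list describing haploid calls, with elements
#'   `x_chroms` (labels of the X chromosome), `male_samples`, and `nonpar`
#'   (length-2 numeric, 1-based inclusive bounds of the non-PAR interval).
#'   Male samples are haploid at X positions inside `nonpar`. The default
#'   non-PAR interval is chrX:2,364,962-151,635,290 (rheMac10 coordinates),
#'   overridable here.
#' @param info_keys INFO annotations parsed into numeric variant columns.
#' @return A [gt_panel()] with attribute `n_skipped_multiallelic`.
#' @export
read_vcf <- function(path, sample_population_map, ploidy_rules = NULL,
                     info_keys = c("QD", "FS", "MQ", "MQRankSum",
                                   "ReadPosRankSum", "SOR", "ExcessHet")) {
  map <- as_pop_map(sample_population_map)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) > 0 && !"GT" %in% strsplit(vcf@gt[1, "FORMAT"], ":")[[1]]) {
    rlang::abort("VCF has no GT field", class = "popgenpanel_format_error")
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vcf_samples <- colnames(vcf@gt)[-1]
  absent <- setdiff(vcf_samples, names(map))
  if (length(absent) > 0) {
    rlang::abort(paste0("VCF samples absent from the population map: ",
                        paste(absent, collapse = ", ")),
                 class = "popgenpanel_config_error")
  }

  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0) {
    message(sprintf("read_vcf: skipped %d multiallelic record(s)", n_skipped))
  }

  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_chr))) {
    gt_chr <- matrix(gt_chr, nrow = nrow(fix),
                     dimnames = list(NULL, vcf_samples))
  }
  g <- apply(gt_chr, 2, gt_string_to_code)
  if (is.null(dim(g))) g <- matrix(g, nrow = nrow(gt_chr))

  variants <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"]))
  )
  variants$class <- ifelse(nchar(variants$ref) == 1 &
                             nchar(variants$alt) == 1, "snv", "indel")
  for (k in info_keys) {
    val <- suppressWarnings(vcfR::extract.info(vcf, element = k, as.numeric = TRUE))
    if (!all(is.na(val))) variants[[k]] <- val
  }

  variants <- variants[biallelic, , drop = FALSE]
  g <- g[biallelic, , drop = FALSE]
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  g <- g[o, , drop = FALSE]

  ploidy <- ploidy_table_from_rules(ploidy_rules, vcf_samples,
                                    unique(variants$chrom))
  panel <- gt_panel(variants, g, vcf_samples, map, ploidy)
  attr(panel, "n_skipped_multiallelic") <- n_skipped
  panel
}

as_pop_map <- function(x) {
  if (is.data.frame(x)) {
    stats::setNames(as.character(x$population), x$sample)
  } else {
    x
  }
}

gt_string_to_code <- function(gt) {
  gt <- sub(":.*", "", gt)
  out <- rep(-1L, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  out[gt %in% "0"] <- 0L
  out[gt %in% "1"] <- 2L
  out
}

ploidy_table_from_rules <- function(rules, samples, chroms) {
  if (is.null(rules) || length(rules$male_samples) == 0) return(NULL)
  x_chroms <- rules$x_chroms %||% c("chrX", "X")
  males <- intersect(rules$male_samples, samples)
  x_present <- intersect(x_chroms, chroms)
  if (length(males) == 0 || length(x_present) == 0) return(NULL)
  tidyr::expand_grid(sample = males, chrom = x_present) |>
    dplyr::mutate(ploidy = 1L)
}

#' Write a genotype panel as a minimal VCF 4.2
#'
#' Haploid calls (ploidy-1 cells) are written as single-allele GT fields.
#' Output is gzip-compressed when `path` ends in `.gz`.
#'
#' @param panel A `gt_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  code_dip <- c(`-1` = "./.", `0` = "0/0", `1` = "0/1", `2` = "1/1")
  code_hap <- c(`-1` = ".", `0` = "0", `1` = "0/1", `2` = "1")
  g <- panel$genotypes
  pm <- ploidy_matrix(panel)
  gt <- matrix("", nrow(g), ncol(g))
  key <- as.character(g)
  gt[] <- code_dip[key]
  hap <- pm == 1L
  gt[hap] <- code_hap[as.character(g[hap])]

  v <- panel$variants
  qual <- if ("qual" %in% names(v)) ifelse(is.na(v$qual), ".", v$qual) else "."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popgenpanel",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  )
  body <- character(0)
  if (nrow(v) > 0) {
    left <- paste(v$chrom, v$pos, ".", v$ref, v$alt, qual, ".", ".", "GT",
                  sep = "\t")
    body <- paste(left, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    if (ncol(gt) == 0) body <- left
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open on disk; the returned tibble is 1-based inclusive
#' to match the package's internal convention.
#'
#' @param path Path to a BED(3+) file.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive) and any
#'   further columns as `name`, `score`, ...
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  if (ncol(x) > 3) names(x)[4:min(6, ncol(x))] <- extra[seq_len(min(3, ncol(x) - 3))]
  x$start <- x$start + 1L
  tibble::as_tibble(x)
}

#' Write intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive)
#'   and optional further columns, written after the first three.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  out <- intervals
  out$start <- out$start - 1L
  core <- c("chrom", "start", "end")
  out <- out[, c(core, setdiff(names(out), core)), drop = FALSE]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Partition panel variants into contiguous genomic blocks
#'
#' Blocks are contiguous runs of `block_size` variants in panel order, never
#' spanning a chromosome boundary; the last block on each chromosome may be
#' smaller. Used as the resampling unit of the block jackknife (the
#' genome-wide convention is 25,000 SNVs per block).
#'
#' @param panel A `gt_panel`, or a character vector of per-variant chromosome
#'   labels in sorted order.
#' @param block_size Variants per block (>= 1).
#' @return Integer vector of block ids, one per variant.
#' @export
partition_blocks <- function(panel, block_size = 25000) {
  stopifnot(block_size >= 1)
  chroms <- if (inherits(panel, "gt_panel")) panel$variants$chrom else panel
  if (length(chroms) == 0) return(integer(0))
  block <- integer(length(chroms))
  next_id <- 0L
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    within <- (seq_along(idx) - 1L) %/% block_size
    block[idx] <- next_id + within + 1L
    next_id <- next_id + max(within) + 1L
  }
  block
}
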