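#' Pairwise genotype distance matrix
#'
#' Per-site distance between two individuals by allele sharing: identical
#' homozygotes 0; opposite homozygotes 1; a heterozygote against anything
#' (including another heterozygote) 0.5. The pair distance is the mean over
#' sites genotyped in both samples (pairwise deletion); `n_sites_used` is
#' recorded so imbalance is visible.
#'
#' @param panel A `gt_panel` with >= 2 samples.
#' @param polymorphic_only Drop sites monomorphic across the whole panel
#'   before averaging (default `FALSE`: shared monomorphic sites contribute
#'   0 and dilute distances proportionally).
#' @return A `genotype_dist`: list with `d` (symmetric matrix, zero
#'   diagonal), `n_sites_used`, `samples`.
#' @export
genotype_distance <- function(panel, polymorphic_only = FALSE) {
  stopifnot(length(panel$samples) >= 2)
  g <- panel$genotypes
  if (polymorphic_only) {
    ac <- allele_counts(panel)
    g <- g[!is.na(ac$p) & ac$p > 0 & ac$p < 1, , drop = FALSE]
  }
  n <- ncol(g)
  d <- matrix(0, n, n, dimnames = list(panel$samples, panel$samples))
  ns <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      gi <- g[, i]; gj <- g[, j]
      ok <- gi >= 0L & gj >= 0L
      gi <- gi[ok]; gj <- gj[ok]
      # |gi - gj| / 2 handles every cell except het-het, which is 0.5 not 0
      per_site <- abs(gi - gj) / 2
      per_site[gi == 1L & gj == 1L] <- 0.5
      ns[i, j] <- ns[j, i] <- length(per_site)
      d[i, j] <- d[j, i] <-
        if (length(per_site) > 0) mean(per_site) else NA_real_
    }
  }
  if (any(is.na(d))) rlang::warn("some pairs share no genotyped sites")
  structure(list(d = d, n_sites_used = ns, samples = panel$samples),
            class = "genotype_dist")
}

#' @export
print.genotype_dist <- function(x, ...) {
  cat(sprintf("<genotype_dist> %d samples, mean distance %.4g\n",
              length(x$samples), mean(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' @export
as.dist.genotype_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Tidy a genotype distance matrix
#'
#' @param x A `genotype_dist`.
#' @param ... Unused.
#' @return Tibble with `id1`, `id2`, `distance`, `n_sites_used` per
#'   unordered pair.
#' @method tidy genotype_dist
#' @export
tidy.genotype_dist <- function(x, ...) {
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble::tibble(id1 = x$samples[idx[, 1]], id2 = x$samples[idx[, 2]],
                 distance = x$d[idx], n_sites_used = x$n_sites_used[idx])
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) with deterministic
#' post-processing: negative branch lengths are clamped to 0 and the excess
#' is transferred to the sibling branch, preserving pairwise path lengths.
#'
#' @param x A `genotype_dist` or a symmetric numeric matrix (n >= 3, no
#'   undefined entries).
#' @return An [ape::phylo] tree with branch lengths.
#' @export
neighbor_joining <- function(x) {
  d <- if (inherits(x, "genotype_dist")) x$d else as.matrix(x)
  if (any(is.na(d))) rlang::abort("distance matrix has undefined entries")
  stopifnot(nrow(d) >= 3)
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tree)
}

clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    i <- neg[1]
    parent <- tree$edge[i, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), i)
    if (length(sibs) > 0) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] +
        tree$edge.length[i]
    }
    tree$edge.length[i] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Export a distance matrix or tree to standard formats
#'
#' @param x A `genotype_dist` (formats `"phylip"`, `"nexus"`) or an
#'   [ape::phylo] tree (format `"newick"`).
#' @param path Output path.
#' @param format `"phylip"` (square distance matrix with a count header
#'   line), `"nexus"` (a DISTANCES block consumable by split-network
#'   software), or `"newick"`.
#' @return `path`, invisibly.
#' @export
export_result <- function(x, path, format = c("phylip", "nexus", "newick")) {
  format <- match.arg(format)
  if (format == "newick") {
    if (!inherits(x, "phylo")) rlang::abort("newick export needs a phylo tree",
                                            class = "popgenpanel_config_error")
    ape::write.tree(x, file = path)
    return(invisible(path))
  }
  if (!inherits(x, "genotype_dist")) {
    rlang::abort("distance export needs a genotype_dist",
                 class = "popgenpanel_config_error")
  }
  if (format == "phylip") {
    write_dist_phylip(x$d, path)
  } else {
    write_dist_nexus(x$d, path)
  }
  invisible(path)
}

write_dist_phylip <- function(d, path) {
  labs <- formatC(substr(rownames(d), 1, 10), width = 10, flag = "-")
  lines <- c(format(nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(labs[i], paste(sprintf("%.6f", d[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path Path to a PHYLIP distance file written by [export_result()].
#' @return Symmetric numeric matrix with sample names.
#' @export
read_dist_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "[[:space:]]+")[[1]]
    labs[i] <- parts[1]
    d[i, ] <- as.numeric(parts[-1])
  }
  dimnames(d) <- list(labs, labs)
  d
}

write_dist_nexus <- function(d, path) {
  n <- nrow(d)
  lines <- c(
    "#NEXUS", "",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", n),
    "  TAXLABELS",
    paste0("    ", rownames(d)),
    "  ;",
    "END;",
    "",
    "BEGIN DISTANCES;",
    sprintf("  DIMENSIONS NTAX=%d;", n),
    "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
    "  MATRIX",
    vapply(seq_len(n), function(i) {
      paste0("    ", rownames(d)[i], " ",
             paste(sprintf("%.6f", d[i, ]), collapse = " "))
    }, character(1)),
    "  ;",
    "END;")
  writeLines(lines, path)
  invisible(path)
}
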