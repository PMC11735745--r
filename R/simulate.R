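#' Describe a structured-population demography
#'
#' The demography is a population tree with branch lengths in generations.
#' Allele frequencies drift along each branch under the Balding-Nichols
#' model with branch drift `F = 1 - exp(-t / (2N))`; X-linked sites use an
#' effective size of `N * x_factor` (3/4 under sex-symmetric demography,
#' hence the neutral X-to-autosome drift ratio Q of 0.75). Sites are
#' unlinked; linkage for LD-pruning tests is emulated by duplicated
#' "tag pair" sites.
#'
#' @param tree Newick string; tip labels are population names, edge lengths
#'   are branch durations in generations (e.g. `"((A:2000,B:2000):0);"`).
#' @param N Effective population size per branch (scalar default), optionally
#'   overridden per branch via `N_branch`, a named vector keyed by the label
#'   of the node the branch leads to (tips by name).
#' @param x_factor Ratio of X to autosomal effective size, in (0, 1].
#' @param n_sites_autosome,n_sites_x Number of simulated biallelic sites on
#'   the single autosome (`chr1`) and on the X (`chrX`).
#' @param n_per_pop Diploid individuals per population (scalar or named).
#' @param admixture Optional tibble with `source`, `target`, `alpha` (and
#'   optionally `time`, recorded only): after drift, the target tip frequency
#'   becomes `(1 - alpha) * p_target + alpha * p_source`.
#' @param ancestral_shape,ancestral_trunc Shape parameters and truncation
#'   bounds of the ancestral allele-frequency density (Beta(0.2, 0.2)
#'   truncated to \[0.05, 0.95\] by default, so variants are common and the
#'   estimators are well conditioned).
#' @param indel_fraction Fraction of sites written as short indels.
#' @param site_spacing Mean spacing between adjacent sites in bp.
#' @param n_tag_pairs Number of sites duplicated at the adjacent position
#'   with identical genotypes (r^2 = 1), for LD-pruning tests.
#' @param mutation_rate,generation_time Recorded for reporting only
#'   (defaults: 6.5e-9 per site per generation, 11 years).
#' @return A `demography` object (list).
#' @export
demography <- function(tree, N = 10000, x_factor = 0.75,
                       n_sites_autosome = 10000, n_sites_x = 0,
                       n_per_pop = 10, admixture = NULL,
                       N_branch = NULL,
                       ancestral_shape = c(0.2, 0.2),
                       ancestral_trunc = c(0.05, 0.95),
                       indel_fraction = 0, site_spacing = 1000,
                       n_tag_pairs = 0,
                       mutation_rate = 6.5e-9, generation_time = 11) {
  phy <- ape::read.tree(text = tree)
  if (is.null(phy)) rlang::abort("could not parse `tree` as newick",
                                 class = "popgenpanel_config_error")
  if (x_factor <= 0 || x_factor > 1) {
    rlang::abort("x_factor must be in (0, 1]", class = "popgenpanel_config_error")
  }
  if (!is.null(admixture)) {
    admixture <- tibble::as_tibble(admixture)
    stopifnot(all(c("source", "target", "alpha") %in% names(admixture)))
    if (any(admixture$alpha < 0 | admixture$alpha > 1)) {
      rlang::abort("admixture alpha must be in [0, 1]",
                   class = "popgenpanel_config_error")
    }
  }
  if (any(phy$edge.length < 0)) {
    rlang::abort("branch lengths (generations) must be >= 0",
                 class = "popgenpanel_config_error")
  }
  pops <- phy$tip.label
  n_ind <- if (length(n_per_pop) == 1 && is.null(names(n_per_pop))) {
    stats::setNames(rep(n_per_pop, length(pops)), pops)
  } else {
    stopifnot(all(pops %in% names(n_per_pop)))
    n_per_pop[pops]
  }
  structure(
    list(tree = phy, N = N, N_branch = N_branch, x_factor = x_factor,
         n_sites_autosome = n_sites_autosome, n_sites_x = n_sites_x,
         n_per_pop = n_ind, admixture = admixture,
         ancestral_shape = ancestral_shape, ancestral_trunc = ancestral_trunc,
         indel_fraction = indel_fraction, site_spacing = site_spacing,
         n_tag_pairs = n_tag_pairs,
         mutation_rate = mutation_rate, generation_time = generation_time),
    class = "demography"
  )
}

# branch table with drift F per chromosome set; node labels: tips by name,
# internal nodes as "node<i>"
branch_table <- function(dem) {
  phy <- dem$tree
  lab <- function(i) {
    if (i <= length(phy$tip.label)) phy$tip.label[i] else paste0("node", i)
  }
  child_lab <- vapply(phy$edge[, 2], lab, character(1))
  n_e <- if (is.null(dem$N_branch)) rep(dem$N, nrow(phy$edge)) else {
    ifelse(child_lab %in% names(dem$N_branch),
           dem$N_branch[child_lab], dem$N)
  }
  t <- phy$edge.length
  tibble::tibble(
    parent = phy$edge[, 1], child = phy$edge[, 2], child_label = child_lab,
    t = t, N = as.numeric(n_e),
    f_auto = 1 - exp(-t / (2 * n_e)),
    f_x = 1 - exp(-t / (2 * n_e * dem$x_factor))
  )
}

# expected Hudson FST per pair: mean of the two path drifts from the MRCA,
# each path compounded as 1 - prod(1 - F_branch)
expected_fst_table <- function(dem, bt) {
  phy <- dem$tree
  pops <- phy$tip.label
  if (length(pops) < 2) {
    return(tibble::tibble(pop_a = character(), pop_b = character(),
                          chrom_set = character(), fst = numeric()))
  }
  pairs <- utils::combn(pops, 2)
  mrca <- ape::mrca(phy)
  out <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    anc <- mrca[a, b]
    for (set in c("autosomes", "X")) {
      fcol <- if (set == "X") "f_x" else "f_auto"
      fa <- path_drift(phy, bt, anc, which(phy$tip.label == a), fcol)
      fb <- path_drift(phy, bt, anc, which(phy$tip.label == b), fcol)
      out[[length(out) + 1]] <- tibble::tibble(
        pop_a = a, pop_b = b, chrom_set = set, fst = (fa + fb) / 2)
    }
  }
  dplyr::bind_rows(out)
}

path_drift <- function(phy, bt, from_node, to_tip, fcol) {
  path <- ape::nodepath(phy, from_node, to_tip)
  if (length(path) < 2) return(0)
  f <- 1
  for (i in seq_len(length(path) - 1)) {
    row <- bt$parent == path[i] & bt$child == path[i + 1]
    f <- f * (1 - bt[[fcol]][row])
  }
  1 - f
}

rbeta_bn <- function(p, f) {
  out <- p
  drift <- f > 0 & p > 0 & p < 1
  if (any(drift)) {
    a <- p[drift] * (1 - f) / f
    b <- (1 - p[drift]) * (1 - f) / f
    out[drift] <- stats::rbeta(sum(drift), a, b)
  }
  out
}

#' Simulate a genotype panel with known demographic truth
#'
#' Ancestral frequencies are drawn from a truncated Beta density; population
#' frequencies evolve along the demography tree by hierarchical
#' Balding-Nichols draws with branch-specific drift; optional admixture
#' mixes tip frequencies; genotypes are sampled under Hardy-Weinberg within
#' each population. On the X, male samples are haploid (a single allele
#' draw, coded 0/2) and the panel's ploidy table marks them. The reference
#' allele is the ancestral allele, so an outgroup population that is
#' homozygous reference carries the ancestral state — matching the
#' outgroup-polarization logic of [polarize_species_specific()].
#'
#' @param dem A [demography()].
#' @param seed Integer seed; every stochastic step flows from it.
#' @return List with `panel` (a [gt_panel()]; samples named `<pop>_<i>`,
#'   odd-numbered individuals male) and `truth` (a `sim_truth` list with
#'   `branch_f`, `expected_fst`, `pedigree`, `planted_roh`, `planted_lof`,
#'   `admixture`, `sexes`).
#' @export
simulate_panel <- function(dem, seed) {
  stopifnot(inherits(dem, "demography"))
  set.seed(seed)
  phy <- ape::reorder.phylo(dem$tree, "cladewise")
  bt <- branch_table(dem)
  pops <- phy$tip.label

  sexes <- unlist(lapply(pops, function(pp) {
    n <- dem$n_per_pop[[pp]]
    stats::setNames(rep_len(c("M", "F"), n),
                    paste0(pp, "_", seq_len(n)))
  }))
  samples <- names(sexes)
  populations <- stats::setNames(
    rep(pops, times = unname(dem$n_per_pop[pops])), samples)

  sim_chrom <- function(n_sites, chrom, x_linked) {
    if (n_sites == 0) return(NULL)
    p0 <- rtrunc_beta(n_sites, dem$ancestral_shape, dem$ancestral_trunc)
    root <- length(phy$tip.label) + 1L
    freqs <- list()
    freqs[[as.character(root)]] <- p0
    ord <- ape::reorder.phylo(phy, "cladewise")$edge
    fcol <- if (x_linked) "f_x" else "f_auto"
    for (i in seq_len(nrow(ord))) {
      par <- ord[i, 1]; chl <- ord[i, 2]
      row <- which(bt$parent == par & bt$child == chl)
      freqs[[as.character(chl)]] <-
        rbeta_bn(freqs[[as.character(par)]], bt[[fcol]][row])
    }
    tipfreq <- do.call(cbind, lapply(seq_along(pops), function(i) {
      freqs[[as.character(i)]]
    }))
    colnames(tipfreq) <- pops
    if (!is.null(dem$admixture)) {
      for (i in seq_len(nrow(dem$admixture))) {
        src <- dem$admixture$source[i]; tgt <- dem$admixture$target[i]
        al <- dem$admixture$alpha[i]
        tipfreq[, tgt] <- (1 - al) * tipfreq[, tgt] + al * tipfreq[, src]
      }
    }
    g <- matrix(-1L, n_sites, length(samples),
                dimnames = list(NULL, samples))
    for (pp in pops) {
      members <- samples[populations == pp]
      p <- tipfreq[, pp]
      for (s in members) {
        if (x_linked && sexes[[s]] == "M") {
          g[, s] <- 2L * stats::rbinom(n_sites, 1L, p)
        } else {
          g[, s] <- stats::rbinom(n_sites, 2L, p)
        }
      }
    }
    pos <- sort(sample.int(n_sites * dem$site_spacing, n_sites))
    list(chrom = chrom, pos = pos, g = g, freq = tipfreq)
  }

  auto <- sim_chrom(dem$n_sites_autosome, "chr1", FALSE)
  xchr <- sim_chrom(dem$n_sites_x, "chrX", TRUE)
  parts <- Filter(Negate(is.null), list(auto, xchr))
  if (length(parts) == 0) rlang::abort("no sites requested",
                                       class = "popgenpanel_config_error")
  g <- do.call(rbind, lapply(parts, `[[`, "g"))
  variants <- dplyr::bind_rows(lapply(parts, function(pt) {
    tibble::tibble(chrom = pt$chrom, pos = pt$pos)
  }))
  n_sites <- nrow(variants)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  is_indel <- stats::runif(n_sites) < dem$indel_fraction
  alt[is_indel] <- paste0(ref[is_indel], "C")
  variants$ref <- unname(ref)
  variants$alt <- unname(alt)
  variants$class <- ifelse(is_indel, "indel", "snv")

  if (dem$n_tag_pairs > 0) {
    dup <- sort(sample.int(n_sites, min(dem$n_tag_pairs, n_sites)))
    ins <- variants[dup, , drop = FALSE]
    ins$pos <- ins$pos + 1L
    variants <- dplyr::bind_rows(variants, ins)
    g <- rbind(g, g[dup, , drop = FALSE])
    o <- order(variants$chrom, variants$pos)
    variants <- variants[o, , drop = FALSE]
    g <- g[o, , drop = FALSE]
  }

  ploidy <- NULL
  if (!is.null(xchr)) {
    males <- names(sexes)[sexes == "M"]
    if (length(males) > 0) {
      ploidy <- tibble::tibble(sample = males, chrom = "chrX", ploidy = 1L)
    }
  }
  panel <- gt_panel(variants, g, samples, populations, ploidy)
  truth <- structure(
    list(branch_f = bt,
         expected_fst = expected_fst_table(dem, bt),
         pedigree = tibble::tibble(child = character(), parent1 = character(),
                                   parent2 = character()),
         planted_roh = tibble::tibble(sample = character(), chrom = character(),
                                      start = integer(), end = integer()),
         planted_lof = tibble::tibble(variant = integer(), gene = character(),
                                      consequence = character()),
         admixture = dem$admixture,
         sexes = sexes,
         tip_freqs = lapply(parts, function(pt) {
           list(chrom = pt$chrom, freq = pt$freq)
         })),
    class = "sim_truth"
  )
  list(panel = panel, truth = truth)
}

rtrunc_beta <- function(n, shape, trunc) {
  lo <- stats::pbeta(trunc[1], shape[1], shape[2])
  hi <- stats::pbeta(trunc[2], shape[1], shape[2])
  stats::qbeta(stats::runif(n, lo, hi), shape[1], shape[2])
}

#' Add offspring of existing samples by Mendelian transmission
#'
#' Each child genotype is formed by transmitting one allele from each parent
#' independently per site (sites are unlinked). Children are diploid
#' everywhere and join their first parent's population.
#'
#' @param panel A `gt_panel`.
#' @param pedigree Tibble with `child`, `parent1`, `parent2`.
#' @param seed Integer seed.
#' @return List with `panel` (parents plus children) and `pedigree`.
#' @export
spawn_relatives <- function(panel, pedigree, seed) {
  pedigree <- tibble::as_tibble(pedigree)
  set.seed(seed)
  miss <- setdiff(c(pedigree$parent1, pedigree$parent2), panel$samples)
  if (length(miss) > 0) {
    rlang::abort(paste0("parents not in panel: ", paste(miss, collapse = ", ")),
                 class = "popgenpanel_config_error")
  }
  pm <- ploidy_matrix(panel)
  draw_allele <- function(parent) {
    g <- panel$genotypes[, parent]
    hap <- pm[, parent] == 1L
    a <- integer(length(g))
    a[g == 2L] <- 1L
    het <- g == 1L & !hap
    a[het] <- stats::rbinom(sum(het), 1L, 0.5)
    a[g == -1L] <- NA_integer_
    if (any(hap)) a[hap] <- ifelse(g[hap] == -1L, NA_integer_, g[hap] %/% 2L)
    a
  }
  g <- panel$genotypes
  pops <- panel$populations
  for (i in seq_len(nrow(pedigree))) {
    a1 <- draw_allele(pedigree$parent1[i])
    a2 <- draw_allele(pedigree$parent2[i])
    child <- a1 + a2
    child[is.na(child)] <- -1L
    g <- cbind(g, child)
    colnames(g)[ncol(g)] <- pedigree$child[i]
    pops[pedigree$child[i]] <- pops[[pedigree$parent1[i]]]
  }
  new_panel <- gt_panel(panel$variants, g, colnames(g), pops, panel$ploidy)
  list(panel = new_panel, pedigree = pedigree)
}

#' Plant an autozygous tract into one sample
#'
#' Within the interval the sample's genotype becomes homozygous by drawing a
#' single allele from its population's empirical allele frequency, i.e. the
#' two haplotypes are forced identical by descent. Planted tracts are
#' recorded in the `planted_roh` attribute; overlapping plants for the same
#' sample are an error.
#'
#' @param panel A `gt_panel`.
#' @param sample Sample identifier.
#' @param chrom,start,end Interval (1-based inclusive bp).
#' @param seed Integer seed.
#' @return The modified `gt_panel`, with attribute `planted_roh` updated.
#' @export
plant_roh <- function(panel, sample, chrom, start, end, seed) {
  stopifnot(sample %in% panel$samples)
  planted <- attr(panel, "planted_roh") %||%
    tibble::tibble(sample = character(), chrom = character(),
                   start = integer(), end = integer())
  clash <- planted$sample == sample & planted$chrom == chrom &
    planted$start <= end & planted$end >= start
  if (any(clash)) {
    rlang::abort("interval overlaps an existing planted tract",
                 class = "popgenpanel_config_error")
  }
  set.seed(seed)
  idx <- which(panel$variants$chrom == chrom &
                 panel$variants$pos >= start & panel$variants$pos <= end)
  if (length(idx) > 0) {
    members <- panel$samples[panel$populations ==
                               panel$populations[[sample]]]
    p <- allele_counts(panel, members)$p[idx]
    p[is.na(p)] <- 0
    panel$genotypes[idx, sample] <- 2L * stats::rbinom(length(idx), 1L, p)
  }
  attr(panel, "planted_roh") <- dplyr::bind_rows(
    planted, tibble::tibble(sample = sample, chrom = chrom,
                            start = as.integer(start), end = as.integer(end)))
  panel
}

#' Assign consequence annotations to panel variants
#'
#' Emulates a SNPEff-style annotation: variants inside gene intervals get a
#' coding consequence, a fraction of which are loss-of-function (indels get
#' `frameshift`; SNVs get `stop_gained` or a splice-site class); the rest
#' are `missense`/`synonymous`. Variants outside genes are `intergenic`.
#'
#' @param panel A `gt_panel`.
#' @param gene_intervals Tibble with `chrom`, `start`, `end`, `gene`
#'   (non-overlapping within a chromosome).
#' @param lof_fraction Fraction of in-gene variants made loss-of-function.
#' @param seed Integer seed.
#' @return A consequence table: tibble with `variant` (row index in the
#'   panel), `chrom`, `pos`, `gene`, `consequence`.
#' @export
assign_consequences <- function(panel, gene_intervals, lof_fraction, seed) {
  if (lof_fraction < 0 || lof_fraction > 1) {
    rlang::abort("lof_fraction must be in [0, 1]",
                 class = "popgenpanel_config_error")
  }
  set.seed(seed)
  v <- panel$variants
  gene <- rep(NA_character_, nrow(v))
  for (i in seq_len(nrow(gene_intervals))) {
    hit <- v$chrom == gene_intervals$chrom[i] &
      v$pos >= gene_intervals$start[i] & v$pos <= gene_intervals$end[i]
    gene[hit] <- gene_intervals$gene[i]
  }
  cons <- rep("intergenic", nrow(v))
  in_gene <- which(!is.na(gene))
  if (length(in_gene) > 0) {
    lof <- in_gene[stats::runif(length(in_gene)) < lof_fraction]
    non_lof <- setdiff(in_gene, lof)
    cons[non_lof] <- sample(c("missense", "synonymous"),
                            length(non_lof), replace = TRUE)
    snv_lof <- lof[v$class[lof] == "snv"]
    ind_lof <- setdiff(lof, snv_lof)
    cons[snv_lof] <- sample(c("stop_gained", "splice_acceptor", "splice_donor"),
                            length(snv_lof), replace = TRUE)
    cons[ind_lof] <- "frameshift"
  }
  tibble::tibble(variant = seq_len(nrow(v)), chrom = v$chrom, pos = v$pos,
                 gene = gene, consequence = cons)
}

#' Simulate per-site per-sample sequencing depth
#'
#' Depths are negative-binomial around `mean_depth`; a fraction of sites is
#' drawn with doubled or halved mean to create the inaccessible tails that
#' the coverage-mode accessibility filter should remove.
#'
#' @param panel A `gt_panel` (or an integer number of sites).
#' @param mean_depth Mean depth per sample (> 0).
#' @param dispersion Negative-binomial size parameter; `Inf` gives Poisson.
#' @param prop_outlier Fraction of sites with doubled/halved mean
#'   (half each).
#' @param seed Integer seed.
#' @param n_samples Number of samples when `panel` is a count.
#' @return Integer matrix `n_sites x n_samples` of depths.
#' @export
simulate_depth <- function(panel, mean_depth = 35, dispersion = 20,
                           prop_outlier = 0, seed = 1, n_samples = NULL) {
  stopifnot(mean_depth > 0)
  set.seed(seed)
  if (inherits(panel, "gt_panel")) {
    n_sites <- n_variants(panel)
    n_samples <- length(panel$samples)
  } else {
    n_sites <- as.integer(panel)
  }
  if (n_sites == 0) return(matrix(0L, 0, n_samples))
  mult <- rep(1, n_sites)
  n_out <- round(prop_outlier * n_sites)
  if (n_out > 0) {
    out_idx <- sample.int(n_sites, n_out)
    mult[out_idx] <- rep_len(c(2, 0.5), n_out)
  }
  mu <- rep(mean_depth * mult, n_samples)
  d <- if (is.infinite(dispersion)) {
    stats::rpois(n_sites * n_samples, mu)
  } else {
    stats::rnbinom(n_sites * n_samples, size = dispersion, mu = mu)
  }
  matrix(as.integer(d), n_sites, n_samples)
}
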