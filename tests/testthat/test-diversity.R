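test_that("heterozygosity is het calls over accessible sites", {
  g <- matrix(c(0L, 0L, 2L,   # S1: no hets
                1L, -1L, 1L), ncol = 2)
  panel <- toy_panel(g)
  het <- individual_heterozygosity(panel, 1000)
  expect_equal(het$heterozygosity, c(0, 2 / 1000))
  expect_error(individual_heterozygosity(panel, 0), "accessible")
})

test_that("simulated heterozygosity matches the Hardy-Weinberg expectation", {
  dem <- demography("(A:0);", n_sites_autosome = 20000, n_per_pop = 4)
  sim <- simulate_panel(dem, 301)
  p <- sim$truth$tip_freqs[[1]]$freq[, "A"]
  L <- 20000 * 1000  # accessible denominator for the simulated chromosome
  expected <- sum(2 * p * (1 - p)) / L
  het <- individual_heterozygosity(sim$panel, L)
  se <- sqrt(sum(2 * p * (1 - p))) / L  # binomial site-sum error
  for (h in het$heterozygosity) expect_lt(abs(h - expected), 4 * se)
})

test_that("nucleotide diversity has its closed forms", {
  # monomorphic panel
  expect_equal(panel_pi(toy_panel(matrix(0L, 50, 3)), 50), 0)
  # two haploid samples differing at 1 site of 100: pi = 0.01
  ploidy <- tibble::tibble(sample = c("S1", "S2"), chrom = "chr1",
                           ploidy = c(1L, 1L))
  g <- matrix(0L, 100, 2)
  g[10, 2] <- 2L
  expect_equal(panel_pi(toy_panel(g, ploidy = ploidy), 100), 0.01)
})

test_that("pi equals the mean pairwise allele mismatch rate", {
  set.seed(302)
  g <- matrix(sample(c(0:2, -1L), 80, TRUE, prob = c(.3, .3, .3, .1)),
              20, 4)
  panel <- toy_panel(g)
  # brute force: at each site, fraction of differing ordered allele pairs
  brute <- 0
  for (i in seq_len(nrow(g))) {
    alleles <- unlist(lapply(g[i, ], function(x) {
      if (x < 0) NULL else c(rep(1, x), rep(0, 2 - x))
    }))
    n <- length(alleles)
    if (n < 2) next
    k <- sum(alleles)
    brute <- brute + k * (n - k) / choose(n, 2)
  }
  expect_equal(panel_pi(panel, 20), brute / 20)
})

test_that("Viterbi segmentation equals exhaustive path enumeration", {
  params <- list(trans_hw_az = 6.6e-9, trans_az_hw = 5.0e-9, err = 1e-3,
                 err_het = 1e-3, err_az = 1e-3, max_quality = 99)
  # independent oracle: enumerate all 2^n state paths
  enumerate_az <- function(g, pos, freqs) {
    n <- length(g)
    het <- g == 1L
    e_het_hw <- 2 * freqs * (1 - freqs) * (1 - params$err) + params$err_het
    em <- cbind(ifelse(het, e_het_hw, 1 - e_het_hw),
                ifelse(het, params$err_az, 1 - params$err_az))
    d <- diff(pos)
    p_in <- 1 - exp(-params$trans_hw_az * d)
    p_out <- 1 - exp(-params$trans_az_hw * d)
    best <- NULL; best_lp <- -Inf
    for (mask in 0:(2^n - 1)) {
      states <- as.integer(intToBits(mask))[1:n]  # 0 = HW, 1 = AZ
      lp <- log(0.5) + log(em[1, states[1] + 1])
      for (i in 2:n) {
        tp <- if (states[i - 1] == 0) {
          if (states[i] == 1) p_in[i - 1] else 1 - p_in[i - 1]
        } else {
          if (states[i] == 0) p_out[i - 1] else 1 - p_out[i - 1]
        }
        lp <- lp + log(tp) + log(em[i, states[i] + 1])
      }
      if (lp > best_lp) { best_lp <- lp; best <- states }
    }
    which(best == 1)
  }
  cases <- list(
    list(g = c(1L, 1L, 0L, 2L, 0L, 0L, 2L, 0L, 1L, 1L), spacing = 50000L),
    list(g = rep(c(0L, 2L), 6), spacing = 5000000L),  # sparse all-hom
    list(g = c(1L, rep(0L, 9), 1L, 0L), spacing = 2000000L))
  for (case in cases) {
    n <- length(case$g)
    pos <- cumsum(rep(case$spacing, n))
    panel <- toy_panel(matrix(case$g, ncol = 1), pos = pos,
                       samples = "S1", populations = c(S1 = "P"))
    freqs <- rep(0.5, n)
    segs <- roh_call(panel, "S1", allele_freqs = freqs, params = params)
    az_sites <- enumerate_az(case$g, pos, freqs)
    if (length(az_sites) == 0) {
      expect_equal(nrow(segs), 0L)
    } else {
      runs <- sum(diff(az_sites) > 1) + 1L
      expect_equal(nrow(segs), runs)
      expect_equal(segs$start[1], pos[min(az_sites)])
      expect_equal(segs$end[nrow(segs)], pos[max(az_sites)])
      called <- unlist(lapply(seq_len(nrow(segs)), function(i) {
        which(pos >= segs$start[i] & pos <= segs$end[i])
      }))
      expect_equal(sort(called), az_sites)
    }
  }
})

test_that("an all-heterozygous sample yields no ROH segments", {
  g <- matrix(1L, 50, 1)
  panel <- toy_panel(g, samples = "S1", populations = c(S1 = "P"))
  segs <- roh_call(panel, "S1", allele_freqs = rep(0.5, 50))
  expect_equal(nrow(segs), 0L)
})

test_that("a planted autozygous tract is recovered by the HMM", {
  dem <- demography("(A:0);", n_sites_autosome = 10000, n_per_pop = 6,
                    site_spacing = 1000)
  sim <- simulate_panel(dem, 303)
  planted <- plant_roh(sim$panel, "A_1", "chr1", 4e6, 4.5e6, 304)
  segs <- roh_call(planted, "A_1")
  hit <- segs[segs$start < 4.5e6 & segs$end > 4e6, ]
  expect_equal(nrow(hit), 1L)
  overlap <- min(hit$end, 4.5e6) - max(hit$start, 4e6) + 1
  expect_gt(overlap / 5e5, 0.9)
})

test_that("ROH filtering keeps boundary values and drops below-threshold", {
  segs <- tibble::tibble(
    sample = "S", chrom = "chr1",
    start = c(1L, 1L, 1L),
    end = c(99999L, 100000L, 150000L),   # lengths 99,999 / 100,000 / 150,000
    n_sites = 10L,
    quality = c(50, 30, 29))
  out <- roh_filter(segs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$end, 100000L)  # quality 30 & length 100 kb boundary kept
})

test_that("ROH burden anti-correlates with heterozygosity when autozygosity is planted", {
  dem <- demography("(A:0);", n_sites_autosome = 8000, n_per_pop = 6,
                    site_spacing = 1000)
  sim <- simulate_panel(dem, 305)
  panel <- sim$panel
  # plant increasing autozygosity into samples 1-3
  panel <- plant_roh(panel, "A_1", "chr1", 1e6, 3e6, 306)
  panel <- plant_roh(panel, "A_2", "chr1", 1e6, 2e6, 307)
  panel <- plant_roh(panel, "A_3", "chr1", 1e6, 1.5e6, 308)
  het <- individual_heterozygosity(panel, 8e6)
  roh <- dplyr::bind_rows(lapply(panel$samples, function(s) {
    roh_call(panel, s)
  }))
  burden <- vapply(panel$samples, function(s) {
    sum(roh$length[roh$sample == s])
  }, numeric(1))
  expect_lt(stats::cor(het$heterozygosity, burden), 0)
})
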