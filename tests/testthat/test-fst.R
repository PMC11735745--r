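test_that("Hudson components have their closed forms", {
  # fixed difference
  c1 <- hudson_components(1, 100, 0, 100)
  expect_equal(c1$num, 1)
  expect_equal(c1$den, 1)
  expect_equal(c1$fst, 1)
  # equal intermediate frequencies: negative numerator is legal
  c2 <- hudson_components(0.5, 100, 0.5, 100)
  expect_equal(c2$num, -2 * 0.25 / 99)
  expect_equal(c2$den, 0.5)
  # insufficient allele counts are flagged as NA
  expect_true(is.na(hudson_components(0.5, 1, 0.5, 100)$num))
})

test_that("genome-wide FST equals an independent textbook implementation", {
  dem <- demography("((A:800,B:1200):0);", n_sites_autosome = 2000,
                    n_per_pop = c(A = 8, B = 12))
  sim <- simulate_panel(dem, 401)
  panel <- sim$panel
  panel$genotypes[sample(length(panel$genotypes), 200)] <- -1L
  panel <- gt_panel(panel$variants, panel$genotypes, panel$samples,
                    panel$populations)
  est <- hudson_fst(panel, "A", "B", block_size = 500)
  gA <- panel$genotypes[, panel$populations == "A"]
  gB <- panel$genotypes[, panel$populations == "B"]
  expect_equal(est$estimate, oracle_hudson_fst(gA, gB), tolerance = 1e-12)
})

test_that("FST is symmetric and invariant to allele relabeling", {
  dem <- demography("((A:500,B:500):0);", n_sites_autosome = 1000,
                    n_per_pop = 6)
  sim <- simulate_panel(dem, 402)
  ab <- hudson_fst(sim$panel, "A", "B", block_size = 250)
  ba <- hudson_fst(sim$panel, "B", "A", block_size = 250)
  expect_equal(ab$estimate, ba$estimate)
  expect_equal(ab$se, ba$se)
  flipped <- sim$panel
  flipped$genotypes <- ifelse(flipped$genotypes >= 0L,
                              2L - flipped$genotypes, -1L)
  flipped <- gt_panel(flipped$variants, flipped$genotypes, flipped$samples,
                      flipped$populations)
  expect_equal(hudson_fst(flipped, "A", "B", block_size = 250)$estimate,
               ab$estimate)
})

test_that("identical blocks give zero jackknife SE", {
  # every block holds the same composition of sites
  block <- rep(1:10, each = 10)
  num <- rep(c(0.1, 0.2), 50)
  den <- rep(c(0.5, 0.6), 50)
  est <- block_ratio_estimate(num, den, block)
  expect_equal(est$se, 0)
  expect_equal(est$estimate, sum(num) / sum(den))
})

test_that("delete-one jackknife matches brute-force leave-one-out on 4 blocks", {
  set.seed(403)
  num <- rnorm(40, 0.1, 0.05)
  den <- runif(40, 0.3, 0.7)
  block <- rep(1:4, each = 10)
  est <- block_ratio_estimate(num, den, block)
  theta <- sum(num) / sum(den)
  loo <- vapply(1:4, function(b) {
    sum(num[block != b]) / sum(den[block != b])
  }, numeric(1))
  # equal block sizes: the weighted formula reduces to the classic one
  g <- 4
  se_classic <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  expect_equal(est$se, se_classic, tolerance = 1e-12)
  # leave-one-out components recomputed from the stored block sums
  expect_equal((sum(est$block_num) - est$block_num) /
                 (sum(est$block_den) - est$block_den), loo)
  expect_equal(est$estimate, theta)
})

test_that("unequal final blocks are handled by the weighted jackknife", {
  set.seed(404)
  num <- rnorm(105, 0.1, 0.05)
  den <- runif(105, 0.3, 0.7)
  block <- partition_blocks(rep("chr1", 105), 25)  # sizes 25,25,25,25,5
  est <- block_ratio_estimate(num, den, block)
  expect_equal(est$n_blocks, 5L)
  expect_equal(est$block_m, c(25L, 25L, 25L, 25L, 5L))
  expect_true(is.finite(est$se) && est$se > 0)
  # weighted formula recomputed directly (Busing delete-one pseudovalues)
  theta <- sum(num) / sum(den)
  m <- est$block_m; n <- sum(m); g <- 5
  loo <- (sum(num) - est$block_num) / (sum(den) - est$block_den)
  h <- n / m
  tau <- h * theta - (h - 1) * loo
  theta_dot <- g * theta - sum((1 - 1 / h) * loo)
  expect_equal(est$se, sqrt(sum((tau - theta_dot)^2 / (h - 1)) / g))
})

test_that("a random split of one population has FST near zero", {
  dem <- demography("(A:0);", n_sites_autosome = 10000, n_per_pop = 20)
  sim <- simulate_panel(dem, 405)
  panel <- sim$panel
  half <- panel$samples[1:10]
  pops <- stats::setNames(ifelse(panel$samples %in% half, "L", "R"),
                          panel$samples)
  split_panel <- gt_panel(panel$variants, panel$genotypes, panel$samples, pops)
  est <- hudson_fst(split_panel, "L", "R", block_size = 1000)
  expect_lt(abs(est$estimate), 3 * est$se)
})

test_that("population-specific FST designates the top tail with ties", {
  # variant fixed alt in target, absent in background, lands in the top set
  g <- cbind(matrix(0L, 200, 4), matrix(0L, 200, 6))
  g[1, 1:4] <- 2L
  set.seed(406)
  g[2:200, ] <- sample(0:2, 199 * 10, TRUE)
  samples <- c(paste0("T_", 1:4), paste0("B_", 1:6))
  colnames(g) <- samples
  panel <- toy_panel(g)
  ps <- population_specific_fst(panel, "T", top_fraction = 0.01)
  expect_equal(ps$fst[1], 1)
  expect_true(ps$outlier[1])
  # designation equals a brute-force sort-and-slice recount
  vals <- ps$fst[!is.na(ps$fst)]
  n_top <- max(1, ceiling(0.01 * length(vals)))
  cutoff <- sort(vals, decreasing = TRUE)[n_top]
  expect_equal(which(ps$outlier), which(!is.na(ps$fst) & ps$fst >= cutoff))
  expect_gte(sum(ps$outlier), floor(0.01 * length(vals)))
  expect_error(population_specific_fst(panel, "T", background_samples = character(0)),
               "background")
})

test_that("the Q statistic follows its drift-ratio definition", {
  expect_equal(q_statistic(0.2, 0.2)$q, 1)
  expect_equal(q_statistic(0.1, 0.125)$q, log(0.9) / log(0.875))
  expect_false(q_statistic(1, 0.5)$defined)   # FST at domain limit
  expect_false(q_statistic(0.5, 1)$defined)
  expect_false(q_statistic(-0.01, 0.5)$defined)
  expect_true(is.na(q_statistic(1.2, 0.5)$q))
  # fst_x -> 1 drives Q toward 0
  expect_lt(q_statistic(0.1, 0.999)$q, 0.02)
})

test_that("sex-symmetric demography with x_factor 1 gives Q near 1", {
  dem <- demography("((A:1500,B:1500):0);", N = 10000, x_factor = 1,
                    n_sites_autosome = 15000, n_sites_x = 15000,
                    n_per_pop = 15)
  sim <- simulate_panel(dem, 407)
  fa <- hudson_fst(sim$panel, "A", "B", "autosomes", 1500)
  fx <- hudson_fst(sim$panel, "A", "B", "X", 1500)
  expect_lt(abs(q_statistic(fa, fx)$q - 1), 0.1)
})

test_that("fst_table lays out autosomes upper-right and X lower-left", {
  dem <- demography("((A:400,B:400):200,C:600);", n_sites_autosome = 3000,
                    n_sites_x = 1000, n_per_pop = 6)
  sim <- simulate_panel(dem, 408)
  ft <- fst_table(sim$panel, block_size = 500)
  expect_setequal(unique(ft$chrom_set), c("autosomes", "X"))
  expect_equal(nrow(ft), 6L)  # 3 pairs x 2 chromosome sets
  m <- fst_matrix(ft)
  pops <- rownames(m)
  expect_equal(diag(m), stats::setNames(rep("", 3), pops))
  expect_true(all(m[upper.tri(m)] != ""))
  expect_true(all(m[lower.tri(m)] != ""))
  # upper-right entries reproduce the autosomal estimates
  a_ab <- ft$fst[ft$chrom_set == "autosomes" & ft$pop_a == "A" & ft$pop_b == "B"]
  expect_match(m[1, 2], sprintf("%.3f", a_ab), fixed = TRUE)
})
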