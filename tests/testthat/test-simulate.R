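test_that("zero drift yields identical population frequencies and FST near 0", {
  dem <- demography("((A:0,B:0):0);", n_sites_autosome = 10000, n_per_pop = 10)
  sim <- simulate_panel(dem, 31)
  expect_equal(sim$truth$expected_fst$fst, c(0, 0))
  est <- hudson_fst(sim$panel, "A", "B", block_size = 1000)
  expect_lt(abs(est$estimate), 3 * est$se)
})

test_that("a single population with one individual yields biallelic records", {
  dem <- demography("(A:0);", n_sites_autosome = 100, n_per_pop = 1)
  sim <- simulate_panel(dem, 5)
  expect_equal(n_variants(sim$panel), 100L)
  expect_true(all(nchar(sim$panel$variants$ref) >= 1))
  expect_true(all(sim$panel$variants$ref != sim$panel$variants$alt))
  expect_true(all(sim$panel$genotypes %in% 0:2))
})

test_that("Balding-Nichols drift preserves the mean allele frequency", {
  dem <- demography("((A:2000,B:2000):0);", N = 10000,
                    n_sites_autosome = 20000, n_per_pop = 15)
  sim <- simulate_panel(dem, 77)
  pf <- pop_freqs(sim$panel)
  # both tips are unbiased draws around the same ancestral frequencies,
  # so their mean frequencies agree within Monte-Carlo error
  diff_mean <- mean(pf$p[, "A"]) - mean(pf$p[, "B"])
  se <- stats::sd(pf$p[, "A"] - pf$p[, "B"]) / sqrt(nrow(pf$p))
  expect_lt(abs(diff_mean), 3 * se)
})

test_that("simulated FST matches its recorded truth within 3 SE", {
  dem <- demography("((A:2107,B:2107):0);", N = 10000,
                    n_sites_autosome = 20000, n_per_pop = 20)
  sim <- simulate_panel(dem, 13)
  truth <- sim$truth$expected_fst
  target <- truth$fst[truth$chrom_set == "autosomes"]
  expect_equal(target, 1 - exp(-2107 / 20000), tolerance = 1e-12)
  est <- hudson_fst(sim$panel, "A", "B", block_size = 2000)
  expect_lt(abs(est$estimate - target), 3 * est$se)
})

test_that("males are haploid on the X and never heterozygous there", {
  dem <- demography("(A:100);", n_sites_autosome = 50, n_sites_x = 500,
                    n_per_pop = 6)
  sim <- simulate_panel(dem, 3)
  males <- names(sim$truth$sexes)[sim$truth$sexes == "M"]
  xp <- panel_chrom_set(sim$panel, "X")
  expect_true(all(xp$genotypes[, males] %in% c(0L, 2L)))
  expect_true(all(ploidy_matrix(xp)[, males] == 1L))
  # females stay diploid and do show hets
  females <- setdiff(sim$panel$samples, males)
  expect_true(any(xp$genotypes[, females] == 1L))
})

test_that("Mendelian transmission is forced at fixed parental genotypes", {
  g <- matrix(c(2L, 0L,   # site 1: both hom-alt / parent2 hom-ref
                2L, 2L), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("P_1", "P_2")))
  panel <- toy_panel(g)
  fam <- spawn_relatives(panel,
                         tibble::tibble(child = "P_kid", parent1 = "P_1",
                                        parent2 = "P_2"), 1)
  kid <- fam$panel$genotypes[, "P_kid"]
  expect_equal(kid[2], 2L)  # both hom-alt -> hom-alt
  expect_equal(kid[1], 1L)  # hom-alt x hom-ref -> het
  expect_error(
    spawn_relatives(panel, tibble::tibble(child = "c", parent1 = "nope",
                                          parent2 = "P_1"), 1),
    "parents")
})

test_that("parent-offspring KING kinship is near 0.25 over many sites", {
  dem <- demography("(A:0);", n_sites_autosome = 12000, n_per_pop = 4)
  sim <- simulate_panel(dem, 17)
  fam <- spawn_relatives(sim$panel,
                         tibble::tibble(child = "A_kid", parent1 = "A_1",
                                        parent2 = "A_2"), 18)
  kk <- king_kinship(fam$panel, c("A_1", "A_kid"))
  expect_lt(abs(kk$phi - 0.25), 0.03)
})

test_that("planted autozygous tracts have no hets and leave the rest alone", {
  dem <- demography("(A:0);", n_sites_autosome = 5000, n_per_pop = 8,
                    site_spacing = 1000)
  sim <- simulate_panel(dem, 23)
  before <- sim$panel$genotypes[, "A_1"]
  planted <- plant_roh(sim$panel, "A_1", "chr1", 1e6, 2e6, 24)
  idx <- which(planted$variants$pos >= 1e6 & planted$variants$pos <= 2e6)
  expect_gt(length(idx), 100)
  expect_true(all(planted$genotypes[idx, "A_1"] != 1L))
  expect_identical(planted$genotypes[-idx, "A_1"], before[-idx])

  # het rate outside matches the Hardy-Weinberg expectation sum(2pq)/L
  p <- sim$truth$tip_freqs[[1]]$freq[, "A"]
  exp_het <- mean(2 * p[-idx] * (1 - p[-idx]))
  obs_het <- mean(planted$genotypes[-idx, "A_1"] == 1L)
  se <- sqrt(exp_het * (1 - exp_het) / length(p[-idx]))
  expect_lt(abs(obs_het - exp_het), 4 * se)

  # zero-length interval is a no-op; overlapping plants error
  same <- plant_roh(planted, "A_2", "chr1", 10, 9, 25)
  expect_identical(same$genotypes[, "A_2"], planted$genotypes[, "A_2"])
  expect_error(plant_roh(planted, "A_1", "chr1", 1.5e6, 3e6, 26), "overlap")
})

test_that("consequence assignment respects lof_fraction and planted truth", {
  dem <- demography("(A:0);", n_sites_autosome = 2000, n_per_pop = 2,
                    indel_fraction = 0.3)
  sim <- simulate_panel(dem, 41)
  genes <- tibble::tibble(chrom = "chr1", start = c(1, 1e6),
                          end = c(5e5, 1.5e6), gene = c("g1", "g2"))

  none <- assign_consequences(sim$panel, genes, 0, 1)
  expect_false(any(none$consequence %in%
                     c("frameshift", "stop_gained", "splice_acceptor",
                       "splice_donor")))

  all_lof <- assign_consequences(sim$panel, genes, 1, 2)
  in_gene <- !is.na(all_lof$gene)
  expect_true(all(all_lof$consequence[in_gene] %in%
                    c("frameshift", "stop_gained", "splice_acceptor",
                      "splice_donor")))
  expect_true(all(all_lof$consequence[!in_gene] == "intergenic"))
  # indels get frameshift, SNVs get SNV-compatible LoF classes
  cls <- sim$panel$variants$class
  expect_true(all(all_lof$consequence[in_gene & cls == "indel"] == "frameshift"))
  expect_false(any(all_lof$consequence[in_gene & cls == "snv"] == "frameshift"))

  # classify_lof recovers exactly the generator's LoF labels
  some <- assign_consequences(sim$panel, genes, 0.4, 3)
  lof <- classify_lof(some)
  truth_idx <- some$variant[some$consequence %in%
                              c("frameshift", "stop_gained",
                                "splice_acceptor", "splice_donor")]
  expect_setequal(lof$variant, truth_idx)

  expect_error(assign_consequences(sim$panel, genes, 1.2, 1), "lof_fraction")
})

test_that("simulated depth matches its distributional targets", {
  panel <- toy_panel(matrix(0L, 500, 4))
  d <- simulate_depth(panel, mean_depth = 35, dispersion = Inf, seed = 6)
  expect_equal(dim(d), c(500L, 4L))
  se <- sqrt(35 / length(d))
  expect_lt(abs(mean(d) - 35), 3 * se)

  # negative binomial keeps the mean but inflates the variance
  d2 <- simulate_depth(panel, mean_depth = 35, dispersion = 5, seed = 7)
  expect_lt(abs(mean(d2) - 35), 3 * sqrt((35 + 35^2 / 5) / length(d2)))
  expect_gt(stats::var(as.numeric(d2)), stats::var(as.numeric(d)))

  expect_equal(nrow(simulate_depth(toy_panel(matrix(0L, 0, 2)),
                                   n_samples = 2, seed = 1)), 0L)
})

test_that("tag pairs create perfectly correlated adjacent duplicates", {
  dem <- demography("(A:0);", n_sites_autosome = 300, n_per_pop = 5,
                    n_tag_pairs = 10)
  sim <- simulate_panel(dem, 55)
  expect_equal(n_variants(sim$panel), 310L)
  d <- diff(sim$panel$variants$pos)
  dup_next <- which(d == 1L)
  expect_gte(length(dup_next), 10L)
})
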