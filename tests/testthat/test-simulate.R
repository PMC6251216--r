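small_design <- function(n_f2 = 40, seed = 9, ...) {
  cross_design(n_f2 = n_f2, n_chromosomes = 2, chrom_length_bp = 5e6,
               variants_per_chrom = 30, causal_chrom = 1, causal_pos = 2.5e6,
               missing_rate = 0, seed = seed, ...)
}

test_that("identical designs give identical populations", {
  a <- simulate_f2(small_design())
  b <- simulate_f2(small_design())
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  c <- simulate_f2(small_design(seed = 10))
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("design validation rejects impossible crosses", {
  expect_error(cross_design(chrom_length_bp = 0), "positive")
  expect_error(cross_design(causal_pos = 4e7), "within")
  expect_error(cross_design(penetrance = 1.5), "0, 1")
  expect_error(cross_design(n_f2 = -1), ">= 0")
})

test_that("an empty population still carries a variant list", {
  pop <- simulate_f2(small_design(n_f2 = 0))
  expect_equal(nrow(pop$phenotypes), 0)
  expect_gt(nrow(pop$genotypes), 0)
  expect_length(setdiff(names(pop$genotypes),
                        c("variant_id", "chrom", "pos", "ref", "alt", "type")), 0)
})

test_that("single-locus genotype frequencies segregate 1:2:1", {
  pop <- simulate_f2(cross_design(n_f2 = 4000, n_chromosomes = 1,
                                  variants_per_chrom = 5, causal_pos = 1e6,
                                  chrom_length_bp = 27e6, missing_rate = 0,
                                  seed = 21))
  g <- unlist(pop$genotypes[1, sprintf("F2_%04d", 1:4000)])
  counts <- tabulate(g + 1L, nbins = 3)
  # goodness of fit against 1:2:1 should not reject wildly
  gof <- seg_test(counts, ratio = c(1, 2, 1))
  expect_gt(gof$p_value, 1e-4)
  expect_lt(abs(counts[2] / 4000 - 0.5), 0.04)
})

test_that("the recessive phenotype fraction is binomial around 1/4", {
  pop <- simulate_f2(cross_design(n_f2 = 10000, n_chromosomes = 1,
                                  variants_per_chrom = 10, causal_pos = 1e7,
                                  missing_rate = 0, seed = 33))
  frac <- mean(pop$phenotypes$phenotype == "cl")
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(frac - 0.25), 3 * se)
})

test_that("penetrance thins the recessive class", {
  pop <- simulate_f2(cross_design(n_f2 = 8000, n_chromosomes = 1,
                                  variants_per_chrom = 5, causal_pos = 1e6,
                                  penetrance = 0.5, missing_rate = 0, seed = 5))
  frac <- mean(pop$phenotypes$phenotype == "cl")
  se <- sqrt(0.125 * 0.875 / 8000)
  expect_lt(abs(frac - 0.125), 4 * se)
})

test_that("genotype correlation between linked markers decays per Haldane", {
  pop <- simulate_f2(cross_design(n_f2 = 4000, n_chromosomes = 1,
                                  chrom_length_bp = 1e7, chrom_length_cM = 100,
                                  variants_per_chrom = 12, causal_pos = 5e6,
                                  missing_rate = 0, seed = 13))
  g <- as.matrix(pop$genotypes[, sprintf("F2_%04d", 1:4000)])
  pos <- pop$genotypes$pos
  for (j in 2:nrow(g)) {
    d_cM <- (pos[j] - pos[1]) / 1e7 * 100
    expected_cor <- 1 - 2 * haldane_r(d_cM)
    expect_lt(abs(stats::cor(g[1, ], g[j, ]) - expected_cor), 0.08)
  }
})

test_that("a genetically inert map yields identical genotypes everywhere", {
  # with an (almost) zero-length genetic map, r is 0 between all markers:
  # every chromosome segregates as a single block with no recombinants
  pop <- simulate_f2(cross_design(n_f2 = 200, n_chromosomes = 1,
                                  chrom_length_cM = 1e-9,
                                  variants_per_chrom = 20, causal_pos = 1e6,
                                  missing_rate = 0, seed = 2))
  g <- as.matrix(pop$genotypes[, sprintf("F2_%04d", 1:200)])
  expect_true(all(apply(g, 2, function(col) length(unique(col)) == 1)))
  expect_identical(haldane_r(0), 0)
})

test_that("panel construction never carries the causal allele", {
  pop <- simulate_f2(small_design())
  for (s in 1:5) {
    panel <- simulate_panel(pop$genotypes,
                            panel_design(n_accessions = 50, seed = s),
                            causal_id = pop$truth$causal_id)
    row <- panel[panel$variant_id == pop$truth$causal_id, -1]
    expect_equal(sum(unlist(row), na.rm = TRUE), 0)
  }
})

test_that("panel sharing fraction follows the binomial oracle", {
  pop <- simulate_f2(cross_design(n_f2 = 2, n_chromosomes = 4,
                                  variants_per_chrom = 250, causal_pos = 1e6,
                                  missing_rate = 0, seed = 3))
  panel <- simulate_panel(
    pop$genotypes,
    panel_design(n_accessions = 822, fraction_sharing = 0.5,
                 missing_rate = 0, seed = 4),
    causal_id = pop$truth$causal_id
  )
  carriers <- rowSums(as.matrix(panel[, -1]) >= 1)
  carriers <- carriers[panel$variant_id != pop$truth$causal_id]
  # mean carrier count across ~1000 variants: SE = sqrt(822 * 0.25 / n)
  se_mean <- sqrt(822 * 0.25 / length(carriers))
  expect_lt(abs(mean(carriers) - 411), 3 * se_mean)
})

test_that("zero sharing gives a monomorphic-reference panel", {
  pop <- simulate_f2(small_design())
  panel <- simulate_panel(pop$genotypes,
                          panel_design(n_accessions = 20, fraction_sharing = 0,
                                       missing_rate = 0, seed = 1),
                          causal_id = pop$truth$causal_id)
  expect_true(all(as.matrix(panel[, -1]) == 0))
})

test_that("pool counts are fixed at the causal variant and balanced far from it", {
  pop <- simulate_f2(cross_design(n_f2 = 600, n_chromosomes = 2,
                                  variants_per_chrom = 40, causal_pos = 2.5e6,
                                  chrom_length_bp = 5e6, missing_rate = 0,
                                  seed = 17))
  pool <- simulate_pool(pop, pool_design(n_individuals = 50, mean_depth = 60,
                                         seed = 18))
  causal <- pool[pool$variant_id == pop$truth$causal_id, ]
  expect_equal(causal$ref_count, 0)
  expect_gt(causal$alt_count, 0)
  # unlinked chromosome: pooled alternate fraction hovers around 1/2
  off <- pool[pool$chrom == "C2", ]
  frac <- sum(off$alt_count) / sum(off$ref_count + off$alt_count)
  # pooled frequencies are correlated along the chromosome (linkage), so
  # the averaging gain over variants is limited
  expect_lt(abs(frac - 0.5), 0.08)
})

test_that("pool edge cases behave: zero depth and recessive shortfall", {
  pop <- simulate_f2(cross_design(n_f2 = 600, n_chromosomes = 1,
                                  variants_per_chrom = 10, causal_pos = 2.5e6,
                                  chrom_length_bp = 5e6, missing_rate = 0,
                                  seed = 17))
  pool0 <- simulate_pool(pop, pool_design(n_individuals = 20, mean_depth = 0,
                                          seed = 1))
  expect_true(all(pool0$ref_count + pool0$alt_count == 0))

  tiny <- simulate_f2(small_design(n_f2 = 8))
  expect_error(
    simulate_pool(tiny, pool_design(n_individuals = 50)),
    "short by"
  )
})

test_that("simulated gene models host the causal variant in an exon", {
  pop <- simulate_f2(small_design())
  ann <- simulate_gene_models(pop$genotypes, pop$truth$causal_id,
                              chrom_length_bp = 5e6, seed = 1)
  cv <- pop$genotypes[pop$genotypes$variant_id == pop$truth$causal_id, ]
  hit <- assign_to_genes(cv, ann)
  expect_equal(hit$region, "exon")
  expect_match(hit$gene_id, "\\.460$")
})
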