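make_panel <- function(ids, geno_rows) {
  g <- do.call(rbind, geno_rows)
  colnames(g) <- sprintf("M%02d", seq_len(ncol(g)))
  dplyr::bind_cols(tibble::tibble(variant_id = ids), tibble::as_tibble(g))
}

variants_tbl <- function(pos, chrom = "C29") {
  tibble::tibble(variant_id = marker_id(chrom, pos), chrom = chrom,
                 pos = as.integer(pos))
}

test_that("panel screen retains only carrier-free variants; missing calls are not carriers", {
  v <- variants_tbl(c(100, 200, 300, 400))
  panel <- make_panel(v$variant_id, list(
    c(0L, 0L, 0L, 0L),          # clean: retained
    c(0L, 1L, 0L, 0L),          # one het carrier: dropped
    c(NA, NA, NA, NA),          # all missing: retained (absence of evidence)
    c(0L, 2L, 2L, 0L)           # homozygous carriers: dropped
  ))
  kept <- panel_screen(v, panel)
  expect_equal(kept$variant_id, v$variant_id[c(1, 3)])
  expect_equal(kept$n_missing, c(0L, 4L))

  # under the homozygote-only rule heterozygous carriers are tolerated
  kept_hom <- panel_screen(v, panel, rule = "no-homozygote")
  expect_equal(kept_hom$variant_id, v$variant_id[1:3])
})

test_that("an empty panel is a vacuous filter and absent variants are governed by on_absent", {
  v <- variants_tbl(c(100, 200))
  empty <- tibble::tibble(variant_id = v$variant_id)
  expect_equal(panel_screen(v, empty)$variant_id, v$variant_id)

  partial <- make_panel(v$variant_id[1], list(c(0L, 0L)))
  expect_error(panel_screen(v, partial), "absent from the panel")
  expect_warning(kept <- panel_screen(v, partial, on_absent = "retain"),
                 "retained")
  expect_true(v$variant_id[2] %in% kept$variant_id)
})

test_that("panel screen agrees with the simulator's construction truth", {
  pop <- simulate_f2(cross_design(n_f2 = 10, n_chromosomes = 1,
                                  variants_per_chrom = 50, causal_pos = 1e7,
                                  seed = 44))
  panel <- simulate_panel(pop$genotypes,
                          panel_design(n_accessions = 300, seed = 45),
                          causal_id = pop$truth$causal_id)
  kept <- panel_screen(pop$genotypes[, c("variant_id", "chrom", "pos")], panel)
  expect_true(pop$truth$causal_id %in% kept$variant_id)
  # at sharing fraction 0.3 and 300 accessions every non-causal variant has
  # carriers with overwhelming probability
  expect_equal(kept$variant_id, pop$truth$causal_id)
})

test_that("pool screen thresholds, unevaluable flags and the membership oracle agree", {
  v <- variants_tbl(c(10, 20, 30, 40))
  pool <- tibble::tibble(
    variant_id = v$variant_id, chrom = "C29", pos = v$pos,
    ref_count = c(0L, 15L, 1L, 2L),
    alt_count = c(30L, 15L, 29L, 3L)
  )
  kept <- pool_screen(v, pool, min_depth = 10, min_alt_fraction = 0.95)
  expect_equal(kept$variant_id, v$variant_id[c(1, 3)])
  flags <- attr(kept, "flags")
  expect_equal(flags$status, c("retained", "dropped", "retained", "unevaluable"))

  # brute-force membership oracle on random counts
  set.seed(8)
  v2 <- variants_tbl(1:50 * 7)
  pool2 <- tibble::tibble(
    variant_id = v2$variant_id, chrom = "C29", pos = v2$pos,
    ref_count = rpois(50, 3), alt_count = rpois(50, 20)
  )
  kept2 <- pool_screen(v2, pool2, min_depth = 15, min_alt_fraction = 0.9)
  oracle <- v2$variant_id[
    (pool2$ref_count + pool2$alt_count) >= 15 &
      pool2$alt_count / (pool2$ref_count + pool2$alt_count) >= 0.9
  ]
  expect_equal(kept2$variant_id, oracle)

  expect_error(pool_screen(v, pool, min_alt_fraction = 0.5), "0.5, 1")
  expect_error(pool_screen(v, pool, min_depth = 0), ">= 1")
})

test_that("intersection equals a brute-force membership scan and ranks by p", {
  a <- variants_tbl(c(10, 30, 50, 70))
  b <- variants_tbl(c(30, 50, 90))
  scan <- tibble::tibble(variant_id = a$variant_id,
                         p_value = c(0.5, 1e-8, 1e-3, 0.2))
  inter <- screen_intersect(a, b, scan)
  expect_equal(inter$variant_id, c("C29_30", "C29_50"))
  expect_equal(inter$variant_id,
               sort(intersect(a$variant_id, b$variant_id)))

  disjoint <- screen_intersect(variants_tbl(1), variants_tbl(2))
  expect_equal(nrow(disjoint), 0)
})

test_that("panel and pool screens commute and tightening thresholds never grows the set", {
  fx <- screening_funnel_fixture(seed = 77)
  v <- fx$scan
  ab <- screen_intersect(panel_screen(v, fx$panel),
                         pool_screen(v, fx$pool))
  ba <- pool_screen(panel_screen(v, fx$panel), fx$pool)
  expect_setequal(ab$variant_id, ba$variant_id)

  loose <- pool_screen(v, fx$pool, min_alt_fraction = 0.9)
  tight <- pool_screen(v, fx$pool, min_alt_fraction = 0.99)
  expect_true(all(tight$variant_id %in% loose$variant_id))
})

test_that("gene assignment respects region priority, strand and the flank boundary", {
  genes <- tibble::tibble(
    gene_id = c("gplus", "gminus"),
    chrom = "C1", strand = c("+", "-"),
    start = c(50000L, 200000L), end = c(60000L, 210000L)
  )
  exons <- tibble::tibble(
    gene_id = c("gplus", "gplus", "gminus"),
    start = c(50000L, 55000L, 200000L),
    end = c(52000L, 60000L, 205000L)
  )
  ann <- gene_annotation(genes, exons)
  v <- variants_tbl(c(
    51000,   # exon of gplus
    53000,   # intron of gplus
    45000,   # 5 kb upstream of gplus (+): 5'-flanking
    65000,   # downstream of gplus (+): 3'-flanking
    215000,  # 5 kb beyond gminus end, minus strand: 5'-flanking
    195000,  # before gminus start, minus strand: 3'-flanking
    39999,   # 10,001 bp upstream of gplus: beyond the flank
    40000    # exactly 10,000 bp upstream: inside the flank
  ), chrom = "C1")
  got <- assign_to_genes(v, ann, flank_bp = 10000)
  expect_equal(
    got$region,
    c("exon", "intron", "5'-flanking", "3'-flanking", "5'-flanking",
      "3'-flanking", "intergenic", "5'-flanking")
  )
  expect_true(is.na(got$gene_id[7]))
})

test_that("overlapping genes produce one assignment row each", {
  genes <- tibble::tibble(
    gene_id = c("a", "b"), chrom = "C1", strand = "+",
    start = c(1000L, 1500L), end = c(3000L, 4000L)
  )
  exons <- tibble::tibble(gene_id = c("a", "b"),
                          start = c(1000L, 1500L), end = c(3000L, 4000L))
  ann <- gene_annotation(genes, exons)
  got <- assign_to_genes(variants_tbl(2000, chrom = "C1"), ann)
  expect_equal(nrow(got), 2)
  expect_setequal(got$gene_id, c("a", "b"))
})

test_that("gene nomination takes the plurality and breaks ties by best p", {
  assignments <- tibble::tibble(
    variant_id = sprintf("C1_%d", 1:5),
    gene_id = c("a", "a", "b", "b", NA),
    region = c("exon", "intron", "exon", "exon", "intergenic"),
    p_value = c(1e-4, 1e-6, 1e-9, 1e-2, 1e-12)
  )
  nom <- nominate_gene(assignments)
  expect_equal(nom$gene_id, "b") # tie on 2 supporters, b holds the lowest p
  expect_equal(nom$n_support, 2L)

  none <- nominate_gene(assignments[5, ])
  expect_equal(nrow(none), 0)
})

test_that("the canonical screening funnel is reproduced exactly", {
  fx <- screening_funnel_fixture()
  iv <- define_interval(fx$scan, flank_bp = 200000)
  expect_equal(iv$peak$variant_id, "C29_6721563")
  expect_equal(c(iv$start, iv$end), c(6522236, 6918901))
  expect_equal(nrow(iv$members), 90)

  report <- variant_screen(iv, fx$panel, fx$pool, fx$annotation)
  expect_equal(unname(report$funnel),
               c(90L, 6L, 42L, 6L))
  expect_setequal(report$intersection$variant_id, fx$candidate_ids)
  expect_true(all(fx$candidate_ids %in% report$pool_retained$variant_id))

  hosted <- report$assignments[!is.na(report$assignments$gene_id) &
                                 report$assignments$gene_id == fx$gene_id, ]
  expect_setequal(hosted$variant_id, fx$hosted_ids)
  expect_setequal(unique(hosted$region), c("5'-flanking", "exon", "intron"))
  expect_equal(report$nominated$gene_id, "C29.460")
  expect_equal(report$nominated$n_support, 5L)
  lone <- report$assignments[is.na(report$assignments$gene_id), ]
  expect_equal(lone$variant_id, "C29_6674693")
})
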