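test_that("gene model construction validates structure and splice motifs", {
  expect_error(
    gene_model("bad", "ATGAAACCCAAATAA",
               exons = tibble::tibble(start = c(1, 8), end = c(6, 15)),
               cds_start = 1),
    "Non-canonical"
  )
  m <- gene_model("ok", "ATGAAACCCAAATAA",
                  exons = tibble::tibble(start = c(1, 8), end = c(6, 15)),
                  cds_start = 1, check_splice = FALSE)
  expect_s3_class(m, "gene_model")
  expect_error(
    gene_model("x", "ATGAAA", exons = tibble::tibble(start = 1, end = 10),
               cds_start = 1),
    "within the gene"
  )
  expect_error(
    gene_model("x", "ATGAAACCC", exons = tibble::tibble(start = c(1, 3),
                                                        end = c(5, 9)),
               cds_start = 1),
    "non-overlapping"
  )
})

test_that("introns and the mature transcript follow the exon structure", {
  m <- toy_gene()
  intr <- gene_introns(m)
  expect_equal(nrow(intr), 2) # 3 exons imply 2 introns
  expect_equal(intr$start, c(10L, 27L))
  expect_equal(mature_transcript(m), "ATGGCCGCATCATCAGCAAAGGGATCCTAA")
})

test_that("a donor-destroying deletion retains its intron up to the intact acceptor", {
  m <- toy_gene()
  # delete gene positions 8-11: exon1 tail "CA" plus intron1 donor "GT"
  mut <- apply_gene_variant(m, 8, 11, "")
  expect_equal(attr(mut, "retained_introns"), 1L)
  expect_equal(nrow(mut$exons), 2) # exon1+intron1+exon2 merged; intron2 spliced
  # hand-built expectation: ATGGCCG | TTTTAG (intron1 remainder) | exon2 | exon3
  expect_equal(mature_transcript(mut),
               paste0("ATGGCCG", "TTTTAG", "TCATCAGCA", "AAGGGATCCTAA"))
})

test_that("identity events and exon-internal deletions behave plainly", {
  m <- toy_gene()
  same <- apply_gene_variant(m, 5, 7, substr(m$seq, 5, 7))
  expect_equal(mature_transcript(same), mature_transcript(m))

  # deletion wholly inside exon2 shrinks it; all introns spliced normally
  mut <- apply_gene_variant(m, 19, 21, "")
  expect_equal(nrow(mut$exons), 3)
  expect_equal(mature_transcript(mut),
               paste0("ATGGCCGCA", "TCAGCA", "AAGGGATCCTAA"))
})

test_that("unsupported rearrangements fail loudly", {
  m <- toy_gene()
  expect_error(apply_gene_variant(m, 9, 18, ""), "entire intron")
  expect_error(apply_gene_variant(m, 16, 18, ""), "acceptor")
  expect_error(apply_gene_variant(m, 0, 3, ""), "within the gene")
  expect_error(apply_gene_variant(m, 1, 2, ""), "CDS start")
  expect_error(apply_gene_variant(m, 5, 6, "NN"), "A/C/G/T")
})

test_that("the cryptic-GT policy re-splices at the next available donor", {
  m <- toy_gene()
  # destroying intron1's donor leaves "TTTAG" of intron sequence; no GT
  # exists before the acceptor, so the policy falls back to retention
  expect_warning(
    mut <- apply_gene_variant(m, 8, 11, "", splice_policy = "cryptic-gt"),
    "No cryptic GT"
  )
  expect_equal(attr(mut, "retained_introns"), 1L)

  # replacement that destroys the donor but provides a new downstream GT
  mut2 <- apply_gene_variant(m, 10, 11, "AGTT", splice_policy = "cryptic-gt")
  expect_equal(attr(mut2, "retained_introns"), integer(0))
  # intron1 re-splices from the introduced GT: exon1 gains the leading "A"
  expect_equal(mature_transcript(mut2),
               paste0("ATGGCCGCA", "A", "TCATCAGCA", "AAGGGATCCTAA"))
})

test_that("ORF translation reports protein, stop identity and ORF arithmetic", {
  tr <- translate_orf("ATGAAATAA", 1)
  expect_equal(tr$protein, "MK")
  expect_equal(tr$stop_codon, "TAA")
  expect_equal(tr$stop_residue, 3L)
  expect_equal(tr$orf_nt, 9L)

  no_stop <- translate_orf("ATGAAACCC", 1)
  expect_true(no_stop$non_stop)
  expect_equal(no_stop$protein, "MKP")

  expect_error(translate_orf("AAAATG", 1), "No ATG")

  set.seed(66)
  bases <- c("A", "C", "G", "T")
  for (i in 1:20) {
    body <- paste(sample(bases, 3 * sample(5:40, 1), replace = TRUE),
                  collapse = "")
    cds <- paste0("ATG", body, "TAA")
    got <- translate_orf(cds, 1)
    want <- oracle_translate(cds)
    expect_equal(got$protein, want$protein)
    if (!got$non_stop) {
      expect_equal(got$stop_codon, want$stop_codon)
      expect_equal(got$orf_nt, 3 * (got$n_aa + 1))
    }
  }
})

test_that("protein diffing finds the first change, the substituted run and the class", {
  same <- diff_proteins("MKLV", "MKLV")
  expect_true(same$identical)
  expect_equal(same$classification, "synonymous-length")

  d <- diff_proteins("MKLVRRK", "MKLVNNK")
  expect_equal(d$first_diff, 5L)
  expect_equal(d$run_length, 2L)
  expect_equal(d$from_run, "RR")
  expect_equal(d$to_run, "NN")

  trunc <- diff_proteins("MKLVRRK", "MKLV")
  expect_equal(trunc$classification, "truncating")
  expect_equal(trunc$first_diff, 5L)

  longer <- diff_proteins("MKLV", "MKLVAA")
  expect_equal(longer$classification, "elongating")

  expect_error(diff_proteins("", "MK"), "non-empty")
})

test_that("domain overlap distinguishes intact, disrupted and lost domains", {
  fx <- splice_loss_fixture()
  rep <- consequence_report(fx$model, fx$event$start, fx$event$end,
                            fx$event$replacement)
  domains <- tibble::tibble(
    domain = c("early", "myb", "tail"),
    start = c(1L, 271L, 350L),
    end = c(50L, 323L, 400L)
  )
  got <- domain_overlap(domains, rep)
  expect_equal(got$status, c("intact", "disrupted", "lost"))
})

test_that("the packaged splice-loss fixture reproduces the canonical report", {
  fx <- splice_loss_fixture()
  wild_tx <- mature_transcript(fx$model)
  wild <- translate_orf(wild_tx, 101)
  expect_equal(wild$n_aa, 440L)

  rep <- consequence_report(fx$model, fx$event$start, fx$event$end,
                            fx$event$replacement, domains = fx$domains)
  expect_equal(rep$mutant_protein_length, 299L)
  expect_equal(rep$mutant_orf_nt, 900L)
  expect_equal(rep$frameshift_cdna_pos, 883L)
  expect_equal(rep$diff$first_diff, 295L)
  expect_equal(rep$diff$run_length, 5L)
  expect_equal(rep$stop_codon, "TAA")
  expect_equal(rep$stop_residue, 300L)
  expect_equal(rep$classification, "truncating")
  expect_equal(rep$domains$status, "disrupted")
  expect_equal(rep$retained_introns, 2L)

  # donor destruction leaves the mature transcript longer than the wild
  # transcript minus the net deletion (the retained intron enters it)
  net_del <- (fx$event$end - fx$event$start + 1) - nchar(fx$event$replacement)
  expect_gt(nchar(mature_transcript(rep$model)), nchar(wild_tx) - net_del)
})

test_that("event plus inverse replacement restores sequence, transcript and protein", {
  m <- toy_gene()
  # exon-internal event: the full model round-trips
  mut2 <- apply_gene_variant(m, 19, 21, "G")
  back2 <- apply_gene_variant(mut2, 19, 19, substr(m$seq, 19, 21))
  expect_equal(back2$seq, m$seq)
  expect_equal(mature_transcript(back2), mature_transcript(m))
  expect_equal(translate_orf(mature_transcript(back2), 1)$protein,
               translate_orf(mature_transcript(m), 1)$protein)

  # donor-destroying event: the gene sequence round-trips exactly
  fx <- splice_loss_fixture()
  mu <- apply_gene_variant(fx$model, fx$event$start, fx$event$end,
                           fx$event$replacement)
  restored <- apply_gene_variant(
    mu, fx$event$start,
    fx$event$start + nchar(fx$event$replacement) - 1L,
    substr(fx$model$seq, fx$event$start, fx$event$end)
  )
  expect_equal(restored$seq, fx$model$seq)
})

test_that("alternative splice sites yield the expected isoform pair", {
  # exon2 of the toy gene begins with the codon TCA; a +3 acceptor shift
  # removes exactly that serine
  m <- toy_gene()
  iso <- alternative_splice_isoforms(m, intron_index = 1, shift = 3,
                                     site = "acceptor")
  expect_equal(nrow(iso), 2)
  expect_equal(iso$protein_length, c(9L, 8L))
  expect_false(any(iso$frameshift))
  d <- diff_proteins(iso$protein[1], iso$protein[2])
  expect_equal(d$classification, "truncating")
  expect_equal(d$wild_length - d$mutant_length, 1L)

  none <- alternative_splice_isoforms(m, 1, 0)
  expect_equal(nrow(none), 1)

  fs <- alternative_splice_isoforms(m, 1, shift = 1, site = "acceptor")
  expect_true(fs$frameshift[2])
})
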