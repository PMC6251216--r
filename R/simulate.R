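#' Simulate an F2 population from two inbred parents
#'
#' Generates every mapping-population input downstream stages consume: a
#' variant list, a samples-by-variants genotype table and a binary phenotype
#' table. The two parents are fully homozygous and opposite at every variant
#' (the mutant parent carries the alternate allele everywhere). Each F2
#' individual receives one recombinant gamete from each F1 parent; crossovers
#' between adjacent markers occur with the Haldane recombination fraction for
#' their map distance (see [haldane_r()]), with physical position mapped
#' linearly onto the genetic map. The phenotype is recessive (`"cl"`) iff the
#' individual is homozygous for the causal mutant allele, thinned by
#' `penetrance`; all other individuals are normal (`"CL"`).
#'
#' @param design A [cross_design()].
#' @return An object of class `f2_population`: a list with elements
#'   * `genotypes`: tibble, one row per variant; columns `variant_id`,
#'     `chrom`, `pos`, `ref`, `alt`, `type`, then one integer column per F2
#'     individual coded 0 (hom wild allele), 1 (het), 2 (hom mutant allele),
#'     `NA` (missing);
#'   * `phenotypes`: tibble `sample_id`, `phenotype` (`"CL"`/`"cl"`);
#'   * `parents`: tibble with the two parental genotype columns;
#'   * `truth`: list carrying `causal_id` and the design, for simulation
#'     provenance.
#' @examples
#' pop <- simulate_f2(cross_design(n_f2 = 12, n_chromosomes = 2,
#'                                 variants_per_chrom = 30, causal_pos = 5e6))
#' pop$phenotypes
#' @export
simulate_f2 <- function(design = cross_design()) {
  if (!inherits(design, "cross_design")) abort("`design` must be a cross_design.")
  withr::with_seed(design$seed, sim_f2_impl(design))
}

# `variants` lets a second population (e.g. the test F2 feeding the BSA
# pool) reuse an existing variant table instead of drawing a fresh one
sim_f2_impl <- function(design, variants = NULL) {
  if (is.null(variants)) variants <- sim_variant_table(design)
  n <- design$n_f2
  sample_ids <- if (n > 0) sprintf("F2_%04d", seq_len(n)) else character()

  geno <- matrix(integer(), nrow = nrow(variants), ncol = n)
  for (cc in seq_len(design$n_chromosomes)) {
    idx <- which(variants$chrom == chrom_name(cc))
    pos <- variants$pos[idx]
    d <- pos / design$chrom_length_bp * design$chrom_length_cM
    r <- haldane_r(diff(d))
    g <- sim_gametes(n, r) + sim_gametes(n, r)
    geno[idx, ] <- t(g)
  }

  causal_row <- which(variants$is_causal)
  true_causal <- if (n > 0) geno[causal_row, ] else integer()
  expressed <- true_causal == 2L & rbinom(n, 1L, design$penetrance) == 1L
  phenotypes <- tibble(
    sample_id = sample_ids,
    phenotype = ifelse(expressed, "cl", "CL")
  )

  if (design$missing_rate > 0 && length(geno) > 0) {
    geno[runif(length(geno)) < design$missing_rate] <- NA_integer_
  }

  gt <- as_tibble(matrix(geno, nrow = nrow(variants), dimnames = list(NULL, sample_ids)))
  genotypes <- bind_cols(variants[, GENO_META], gt)
  parents <- bind_cols(
    variants[, c("variant_id", "chrom", "pos")],
    tibble(
      P1_mutant = rep(2L, nrow(variants)),
      P2_wild = rep(0L, nrow(variants))
    )
  )

  structure(
    list(
      genotypes = genotypes,
      phenotypes = phenotypes,
      parents = parents,
      truth = list(
        causal_id = variants$variant_id[causal_row],
        design = design
      )
    ),
    class = "f2_population"
  )
}

# variant list with uniform random positions, deduplicated and sorted,
# causal variant planted at its exact position
sim_variant_table <- function(design) {
  per_chrom <- lapply(seq_len(design$n_chromosomes), function(cc) {
    m <- design$variants_per_chrom
    if (cc == design$causal_chrom) {
      pos <- sample.int(design$chrom_length_bp, m - 1L)
      pos <- sort(unique(c(setdiff(pos, design$causal_pos), design$causal_pos)))
      causal <- pos == design$causal_pos
    } else {
      pos <- sort(sample.int(design$chrom_length_bp, m))
      causal <- rep(FALSE, length(pos))
    }
    tibble(chrom = chrom_name(cc), pos = pos, is_causal = causal)
  })
  variants <- bind_rows(per_chrom)
  alleles <- sim_alleles(nrow(variants))
  # the planted causal lesion is an indel (a multi-bp replacement), the
  # hallmark event this pipeline is built to recover
  ci <- which(variants$is_causal)
  alleles$ref[ci] <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  alleles$alt[ci] <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
  variants <- bind_cols(variants, alleles)
  variants$type <- ifelse(nchar(variants$ref) == nchar(variants$alt), "SNP", "InDel")
  variants$variant_id <- marker_id(variants$chrom, variants$pos)
  variants[, c(GENO_META, "is_causal")]
}

sim_alleles <- function(n, indel_fraction = 0.1) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  is_indel <- runif(n) < indel_fraction
  ins <- runif(n) < 0.5
  ext <- vapply(sample.int(4L, n, replace = TRUE), function(k) {
    paste(sample(bases, k, replace = TRUE), collapse = "")
  }, character(1))
  alt[is_indel & ins] <- paste0(ref[is_indel & ins], ext[is_indel & ins])
  ref[is_indel & !ins] <- paste0(ref[is_indel & !ins], ext[is_indel & !ins])
  tibble(ref = unname(ref), alt = unname(alt))
}

# n recombinant gametes over length(r)+1 markers; 0 = wild allele, 1 = mutant
sim_gametes <- function(n, r) {
  m <- length(r) + 1L
  g <- matrix(0L, nrow = n, ncol = m)
  if (n == 0L) return(g)
  acc <- rbinom(n, 1L, 0.5)
  g[, 1L] <- acc
  if (m > 1L) {
    sw <- matrix(rbinom(n * (m - 1L), 1L, rep(r, each = n)), nrow = n)
    for (j in seq_len(m - 1L)) {
      acc <- (acc + sw[, j]) %% 2L
      g[, j + 1L] <- acc
    }
  }
  g
}

#' @export
print.f2_population <- function(x, ...) {
  cat(sprintf(
    "<f2_population> %d individuals x %d variants; causal %s; %d recessive\n",
    nrow(x$phenotypes), nrow(x$genotypes), x$truth$causal_id,
    sum(x$phenotypes$phenotype == "cl")
  ))
  invisible(x)
}

#' Simulate germplasm-panel genotypes
#'
#' Generates genotypes of a diversity panel of normal-phenotype accessions
#' over a supplied variant list. The causal mutant allele is absent from
#' every accession by construction; at each non-causal variant each accession
#' carries the mutant-parent allele with probability
#' `design$fraction_sharing` (heterozygous or homozygous with equal odds).
#' A small fraction of calls is set missing; missing calls are tracked as
#' `NA`, never counted as absence of the allele.
#'
#' @param variants Variant table with at least a `variant_id` column
#'   (typically `pop$genotypes` or its meta columns).
#' @param design A [panel_design()].
#' @param causal_id Marker identifier of the causal variant; must be present
#'   in `variants`.
#' @return A tibble: `variant_id`, then one integer genotype column per
#'   accession (0/1/2/`NA`, counting copies of the mutant-parent allele).
#' @examples
#' pop <- simulate_f2(cross_design(n_f2 = 5, n_chromosomes = 1,
#'                                 variants_per_chrom = 20, causal_pos = 1e6))
#' panel <- simulate_panel(pop$genotypes, panel_design(n_accessions = 10),
#'                         causal_id = pop$truth$causal_id)
#' @export
simulate_panel <- function(variants, design = panel_design(), causal_id) {
  if (!inherits(design, "panel_design")) abort("`design` must be a panel_design.")
  if (!"variant_id" %in% names(variants)) abort("`variants` must have a variant_id column.")
  if (missing(causal_id) || !causal_id %in% variants$variant_id) {
    abort("`causal_id` must name a variant present in `variants`.")
  }
  withr::with_seed(design$seed, {
    nv <- nrow(variants)
    na <- design$n_accessions
    carrier <- matrix(rbinom(nv * na, 1L, design$fraction_sharing), nrow = nv)
    g <- carrier * (1L + matrix(rbinom(nv * na, 1L, 0.5), nrow = nv))
    g[variants$variant_id == causal_id, ] <- 0L
    if (design$missing_rate > 0 && length(g) > 0) {
      g[runif(length(g)) < design$missing_rate] <- NA_integer_
    }
    acc_ids <- if (na > 0) sprintf("M%03d", seq_len(na)) else character()
    bind_cols(
      variants[, "variant_id", drop = FALSE],
      as_tibble(matrix(g, nrow = nv, dimnames = list(NULL, acc_ids)))
    )
  })
}

#' Simulate pooled BSA read counts
#'
#' Draws per-variant read counts for a sequencing pool of recessive-phenotype
#' F2 individuals. `n_individuals` recessives are sampled from the
#' population; per variant, depth is Poisson(`mean_depth`) and the
#' alternate-read count is binomial with success probability equal to the
#' pooled mutant-allele frequency among the pooled haplotypes (missing
#' genotypes are excluded from the frequency). Under full penetrance every
#' pooled individual is homozygous mutant at the causal variant, so its
#' pooled frequency is 1 and all its reads are alternate.
#'
#' @param pop An `f2_population` (see [simulate_f2()]); must contain at least
#'   `design$n_individuals` recessive-phenotype individuals.
#' @param design A [pool_design()].
#' @return A tibble `variant_id`, `chrom`, `pos`, `ref_count`, `alt_count`.
#' @export
simulate_pool <- function(pop, design = pool_design()) {
  if (!inherits(pop, "f2_population")) abort("`pop` must be an f2_population.")
  if (!inherits(design, "pool_design")) abort("`design` must be a pool_design.")
  rec <- pop$phenotypes$sample_id[pop$phenotypes$phenotype == "cl"]
  if (length(rec) < design$n_individuals) {
    abort(sprintf(
      "Pool needs %d recessive-phenotype individuals but only %d are available (short by %d).",
      design$n_individuals, length(rec), design$n_individuals - length(rec)
    ))
  }
  withr::with_seed(design$seed, {
    chosen <- sample(rec, design$n_individuals)
    g <- geno_matrix(pop$genotypes)[, chosen, drop = FALSE]
    n_obs <- rowSums(!is.na(g))
    freq <- ifelse(n_obs > 0, rowSums(g, na.rm = TRUE) / (2 * n_obs), NA_real_)
    depth <- rpois(nrow(g), design$mean_depth)
    alt <- ifelse(is.na(freq), NA_integer_, rbinom(nrow(g), depth, ifelse(is.na(freq), 0, freq)))
    tibble(
      variant_id = pop$genotypes$variant_id,
      chrom = pop$genotypes$chrom,
      pos = pop$genotypes$pos,
      ref_count = as.integer(unname(depth - alt)),
      alt_count = as.integer(unname(alt))
    )
  })
}

#' Simulate gene models along the simulated genome
#'
#' Builds a sparse gene annotation for a simulated variant set: one engineered
#' gene straddles the causal variant (three exons, the causal position inside
#' the middle exon), and background genes of two exons are scattered along
#' each chromosome. Used by [run_pipeline()] so candidate-gene assignment has
#' a substrate; spans are clamped to chromosome bounds.
#'
#' @param variants Variant table with `chrom` and `pos` columns.
#' @param causal_id Identifier of the causal variant (hosted by the planted
#'   gene).
#' @param genes_per_chrom Background genes per chromosome.
#' @param chrom_length_bp Chromosome length, for clamping.
#' @param seed Integer seed.
#' @return A `gene_annotation` (see [gene_annotation()]).
#' @export
simulate_gene_models <- function(variants, causal_id, genes_per_chrom = 20,
                                 chrom_length_bp = 27e6, seed = 1L) {
  cv <- variants[variants$variant_id == causal_id, ]
  if (nrow(cv) != 1) abort("`causal_id` must match exactly one variant.")
  withr::with_seed(seed, {
    chroms <- unique(variants$chrom)
    bg <- purrr::map_dfr(chroms, function(cc) {
      start <- sort(sample.int(max(chrom_length_bp - 6000, 1), genes_per_chrom))
      tibble(
        gene_id = paste0(cc, ".", seq_along(start) * 10),
        chrom = cc,
        strand = sample(c("+", "-"), genes_per_chrom, replace = TRUE),
        start = start,
        end = start + 4999L
      )
    })
    cp <- cv$pos
    causal_gene <- tibble(
      gene_id = paste0(cv$chrom, ".460"),
      chrom = cv$chrom,
      strand = "+",
      start = max(cp - 2000L, 1L),
      end = min(cp + 2999L, as.integer(chrom_length_bp))
    )
    # drop background genes colliding with the planted gene
    bg <- bg[!(bg$chrom == causal_gene$chrom &
                 bg$start <= causal_gene$end & bg$end >= causal_gene$start), ]
    genes <- arrange(bind_rows(bg, causal_gene), .data$chrom, .data$start)
    exons <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      gn <- genes[i, ]
      if (gn$gene_id == causal_gene$gene_id) {
        tibble(
          gene_id = gn$gene_id, chrom = gn$chrom,
          start = c(gn$start, cp - 200L, cp + 2100L),
          end = c(gn$start + 800L, cp + 300L, gn$end)
        )
      } else {
        tibble(
          gene_id = gn$gene_id, chrom = gn$chrom,
          start = c(gn$start, gn$start + 3000L),
          end = c(gn$start + 1500L, gn$end)
        )
      }
    })
    gene_annotation(genes, exons)
  })
}
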