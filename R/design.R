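#' Design of a biparental F2 mapping cross
#'
#' Bundles every parameter of the simulated cross between two fully inbred,
#' fully homozygous parents: the mutant line carrying the recessive causal
#' allele and a wild-type line. Defaults mirror the study design this package
#' models: 130 F2 individuals, 13 chromosomes of roughly 27 Mb each, and a
#' single fully penetrant recessive locus.
#'
#' Variant density is deliberately far below a real resequencing experiment
#' (hundreds of markers per chromosome rather than tens of thousands); the
#' genetic structure - Mendelian segregation, Haldane linkage decay, a causal
#' variant embedded among linked neighbours - is what downstream methods
#' consume, not the marker count.
#'
#' @param n_f2 Number of F2 individuals.
#' @param n_chromosomes Number of chromosomes (linkage groups).
#' @param chrom_length_bp Physical length of each chromosome, in bp.
#' @param chrom_length_cM Genetic map length of each chromosome, in
#'   centimorgans. Physical position maps linearly onto the genetic map.
#' @param variants_per_chrom Number of biallelic variants per chromosome.
#' @param causal_chrom Index of the chromosome carrying the causal variant.
#' @param causal_pos 1-based bp position of the causal variant.
#' @param penetrance Probability that a homozygous-mutant individual expresses
#'   the recessive phenotype.
#' @param missing_rate Per-call probability that an F2 genotype is missing in
#'   the emitted matrix (joint-calling dropout).
#' @param seed Integer seed; identical designs produce identical simulations.
#'
#' @return An object of class `cross_design` (a validated list).
#' @examples
#' cross_design(n_f2 = 20, variants_per_chrom = 50)
#' @export
cross_design <- function(n_f2 = 130,
                         n_chromosomes = 13,
                         chrom_length_bp = 27e6,
                         chrom_length_cM = 100,
                         variants_per_chrom = 200,
                         causal_chrom = 1,
                         causal_pos = 6721563,
                         penetrance = 1,
                         missing_rate = 0.02,
                         seed = 1L) {
  if (n_f2 < 0) abort("`n_f2` must be >= 0.")
  if (n_chromosomes < 1) abort("`n_chromosomes` must be >= 1.")
  if (chrom_length_bp <= 0) abort("`chrom_length_bp` must be positive.")
  if (chrom_length_cM <= 0) abort("`chrom_length_cM` must be positive.")
  if (variants_per_chrom < 1) abort("`variants_per_chrom` must be >= 1.")
  if (causal_chrom < 1 || causal_chrom > n_chromosomes) {
    abort("`causal_chrom` must index one of the chromosomes.")
  }
  if (causal_pos < 1 || causal_pos > chrom_length_bp) {
    abort(sprintf(
      "`causal_pos` (%d) must lie within [1, %d] (chromosome length).",
      as.integer(causal_pos), as.integer(chrom_length_bp)
    ))
  }
  if (penetrance < 0 || penetrance > 1) abort("`penetrance` must be in [0, 1].")
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  structure(
    list(
      n_f2 = as.integer(n_f2),
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length_bp = as.integer(chrom_length_bp),
      chrom_length_cM = as.numeric(chrom_length_cM),
      variants_per_chrom = as.integer(variants_per_chrom),
      causal_chrom = as.integer(causal_chrom),
      causal_pos = as.integer(causal_pos),
      penetrance = as.numeric(penetrance),
      missing_rate = as.numeric(missing_rate),
      seed = as.integer(seed)
    ),
    class = "cross_design"
  )
}

#' Design of a germplasm diversity panel
#'
#' Parameters for simulating genotypes of a panel of normal-phenotype
#' accessions. By construction the causal mutant allele is absent from every
#' accession; non-causal variants carry the mutant-parent allele in a random
#' subset of accessions, emulating shared standing variation between the
#' mutant parent's background and the wider germplasm.
#'
#' @param n_accessions Number of panel accessions (default 822).
#' @param fraction_sharing Per non-causal variant, probability that a given
#'   accession carries the mutant-parent allele.
#' @param missing_rate Per-call probability of a missing panel genotype.
#' @param seed Integer seed.
#' @return An object of class `panel_design`.
#' @examples
#' panel_design(n_accessions = 100)
#' @export
panel_design <- function(n_accessions = 822,
                         fraction_sharing = 0.3,
                         missing_rate = 0.01,
                         seed = 1L) {
  if (n_accessions < 0) abort("`n_accessions` must be >= 0.")
  if (fraction_sharing < 0 || fraction_sharing > 1) {
    abort("`fraction_sharing` must be in [0, 1].")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  structure(
    list(
      n_accessions = as.integer(n_accessions),
      fraction_sharing = as.numeric(fraction_sharing),
      missing_rate = as.numeric(missing_rate),
      seed = as.integer(seed)
    ),
    class = "panel_design"
  )
}

#' Design of a bulked-segregant (BSA) sequencing pool
#'
#' Parameters for simulating per-variant read counts of a pool of
#' recessive-phenotype individuals. Read depth is Poisson per site; the
#' alternate-read probability equals the pooled alternate-allele frequency
#' across the pooled haplotypes, so the causal variant is fixed (frequency 1)
#' in the pool by construction.
#'
#' @param n_individuals Number of pooled recessive individuals (default 50).
#' @param mean_depth Mean sequencing depth per variant site.
#' @param seed Integer seed.
#' @return An object of class `pool_design`.
#' @examples
#' pool_design(mean_depth = 50)
#' @export
pool_design <- function(n_individuals = 50, mean_depth = 30, seed = 1L) {
  if (n_individuals < 1) abort("`n_individuals` must be >= 1.")
  if (mean_depth < 0) abort("`mean_depth` must be >= 0.")
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      mean_depth = as.numeric(mean_depth),
      seed = as.integer(seed)
    ),
    class = "pool_design"
  )
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf(
    "<cross_design> %d F2, %d chromosomes x %d variants, causal %s:%d, penetrance %.2f, seed %d\n",
    x$n_f2, x$n_chromosomes, x$variants_per_chrom,
    chrom_name(x$causal_chrom), x$causal_pos, x$penetrance, x$seed
  ))
  invisible(x)
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf(
    "<panel_design> %d accessions, sharing fraction %.2f, seed %d\n",
    x$n_accessions, x$fraction_sharing, x$seed
  ))
  invisible(x)
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf(
    "<pool_design> %d pooled individuals, mean depth %.1f, seed %d\n",
    x$n_individuals, x$mean_depth, x$seed
  ))
  invisible(x)
}
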