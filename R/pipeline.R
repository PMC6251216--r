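#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with defaults mirroring
#' the study design this package models: a 130-individual mapping F2 on 13
#' chromosomes, a 1231-individual test F2 supplying the 50-individual BSA
#' pool, an 822-accession germplasm panel, joint-call QC at call count >= 100
#' and minor-allele frequency >= 0.1, a +/-200 kb target interval, pool
#' screening at depth >= 10 and alternate fraction >= 0.95, a strict
#' zero-carrier panel rule, and intron retention for splice-donor loss.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_f2 Mapping-population size.
#' @param n_f2_test Test-population size (source of the BSA pool).
#' @param n_chromosomes,variants_per_chrom,chrom_length_bp,chrom_length_cM,causal_chrom,causal_pos,penetrance,missing_rate
#'   Cross parameters, see [cross_design()].
#' @param n_accessions,panel_fraction_sharing,panel_missing_rate Panel
#'   parameters, see [panel_design()].
#' @param pool_individuals,pool_mean_depth Pool parameters, see
#'   [pool_design()].
#' @param qc_min_count,qc_min_freq QC thresholds, see [qc_filter()].
#' @param assoc_method `"chi2"` or `"glm"`, see [assoc_scan()].
#' @param flank_bp Interval flank, see [define_interval()].
#' @param pool_min_depth,pool_min_alt_fraction Pool-screen thresholds.
#' @param panel_rule `"no-allele"` or `"no-homozygote"`.
#' @param gene_flank_bp Gene-assignment flank.
#' @param splice_policy `"retain"` or `"cryptic-gt"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L,
                            n_f2 = 130L,
                            n_f2_test = 1231L,
                            n_chromosomes = 13L,
                            variants_per_chrom = 200L,
                            chrom_length_bp = 27e6,
                            chrom_length_cM = 100,
                            causal_chrom = 1L,
                            causal_pos = 6721563L,
                            penetrance = 1,
                            missing_rate = 0.02,
                            n_accessions = 822L,
                            panel_fraction_sharing = 0.3,
                            panel_missing_rate = 0.01,
                            pool_individuals = 50L,
                            pool_mean_depth = 30,
                            qc_min_count = 100L,
                            qc_min_freq = 0.1,
                            assoc_method = "chi2",
                            flank_bp = 200000L,
                            pool_min_depth = 10L,
                            pool_min_alt_fraction = 0.95,
                            panel_rule = "no-allele",
                            gene_flank_bp = 10000L,
                            splice_policy = "retain") {
  cfg <- as.list(environment())
  if (!assoc_method %in% c("chi2", "glm")) abort("`assoc_method` must be chi2 or glm.")
  if (!panel_rule %in% c("no-allele", "no-homozygote")) {
    abort("`panel_rule` must be no-allele or no-homozygote.")
  }
  if (!splice_policy %in% c("retain", "cryptic-gt")) {
    abort("`splice_policy` must be retain or cryptic-gt.")
  }
  cfg$seed <- as.integer(cfg$seed) %% 2147400000L
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param file YAML file of configuration overrides.
#' @export
read_pipeline_config <- function(file) {
  vals <- yaml::read_yaml(file)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration field(s): %s.", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> seed %d: %d F2 (%d test), %d x %d variants, %d-accession panel, pool of %d\n",
    x$seed, x$n_f2, x$n_f2_test, x$n_chromosomes, x$variants_per_chrom,
    x$n_accessions, x$pool_individuals
  ))
  invisible(x)
}

config_hash <- function(config) rlang::hash(unclass(config))

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)), parent = e)
  })
}

#' Run the whole gene-cloning workflow on simulated data
#'
#' Executes every stage in study order on data simulated from `config`:
#' inheritance-mode classification, joint-call QC and the per-variant
#' association scan, target-interval definition around the peak, the dual
#' germplasm-panel / BSA-pool screen with candidate-gene nomination, and the
#' molecular-consequence report for the packaged splice-donor-loss fixture.
#' Any stage failure halts the run with the stage name and cause. A fixed
#' seed yields a byte-identical summary.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, per-stage outputs (VCFs,
#'   TSVs, interval and summary JSON, config YAML) are written there.
#' @param verbose Narrate per-stage cardinalities via messages.
#' @return An object of class `pipeline_result`: list with `config`,
#'   `population`, `segregation`, `scan`, `interval`, `screen`,
#'   `consequence` and a plain-list `summary` (what `summary.json`
#'   contains).
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(seed = 42))
#' res$summary$screen$top_candidate
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config.")
  say <- function(...) if (verbose) inform(sprintf(...))
  s <- config$seed

  # --- simulate stage -------------------------------------------------
  pop <- run_stage("simulate", {
    simulate_f2(cross_design(
      n_f2 = config$n_f2, n_chromosomes = config$n_chromosomes,
      chrom_length_bp = config$chrom_length_bp,
      chrom_length_cM = config$chrom_length_cM,
      variants_per_chrom = config$variants_per_chrom,
      causal_chrom = config$causal_chrom, causal_pos = config$causal_pos,
      penetrance = config$penetrance, missing_rate = config$missing_rate,
      seed = s
    ))
  })
  variants <- pop$genotypes[, GENO_META]
  variants$is_causal <- variants$variant_id == pop$truth$causal_id
  say("simulated %d F2 individuals over %d variants", config$n_f2, nrow(variants))

  # --- inheritance stage ----------------------------------------------
  segregation <- run_stage("segregation", {
    f2_counts <- c(sum(pop$phenotypes$phenotype == "CL"),
                   sum(pop$phenotypes$phenotype == "cl"))
    if (sum(f2_counts) == 0) {
      # nothing to test; the empty population is reported by the scan stage
      structure(list(verdict = "not evaluated", reasons = "empty population",
                     bc1 = NULL, f2 = NULL),
                class = "inheritance_verdict")
    } else withr::with_seed(s + 5L, {
      # backcross to the mutant parent: offspring het or hom-mutant 1:1
      n_bc1 <- 434L
      hom <- rbinom(1L, n_bc1, 0.5)
      expressed <- rbinom(1L, hom, config$penetrance)
      bc1_counts <- c(n_bc1 - expressed, expressed)
      # F1s are heterozygous throughout, hence all normal-phenotype
      classify_inheritance(c(30L, 0L), bc1_counts, f2_counts)
    })
  })
  say("inheritance verdict: %s", segregation$verdict)

  # --- association stage ----------------------------------------------
  scan_res <- run_stage("scan", {
    validate_samples(pop$genotypes, pop$phenotypes)
    kept <- qc_filter(pop$genotypes, config$qc_min_count, config$qc_min_freq)
    assoc_scan(kept, pop$phenotypes, method = config$assoc_method)
  })
  interval <- run_stage("interval", define_interval(scan_res, config$flank_bp))
  say("scan: %d variants after QC; interval %s:%d-%d with %d members",
      nrow(scan_res), interval$chrom, interval$start, interval$end,
      nrow(interval$members))

  # --- screening stage ------------------------------------------------
  screen <- run_stage("screen", {
    panel <- simulate_panel(
      variants,
      panel_design(
        n_accessions = config$n_accessions,
        fraction_sharing = config$panel_fraction_sharing,
        missing_rate = config$panel_missing_rate, seed = s + 2L
      ),
      causal_id = pop$truth$causal_id
    )
    test_design <- cross_design(
      n_f2 = config$n_f2_test, n_chromosomes = config$n_chromosomes,
      chrom_length_bp = config$chrom_length_bp,
      chrom_length_cM = config$chrom_length_cM,
      variants_per_chrom = config$variants_per_chrom,
      causal_chrom = config$causal_chrom, causal_pos = config$causal_pos,
      penetrance = config$penetrance, missing_rate = config$missing_rate,
      seed = s + 1L
    )
    test_pop <- withr::with_seed(s + 1L, sim_f2_impl(test_design, variants))
    pool <- simulate_pool(test_pop, pool_design(
      n_individuals = config$pool_individuals,
      mean_depth = config$pool_mean_depth, seed = s + 3L
    ))
    annotation <- simulate_gene_models(
      variants, pop$truth$causal_id,
      chrom_length_bp = config$chrom_length_bp, seed = s + 4L
    )
    variant_screen(
      interval, panel, pool, annotation,
      min_depth = config$pool_min_depth,
      min_alt_fraction = config$pool_min_alt_fraction,
      panel_rule = config$panel_rule, flank_bp = config$gene_flank_bp
    )
  })
  say("screen: %d interval variants -> %d panel / %d pool -> %d intersected",
      screen$funnel[["input"]], screen$funnel[["panel_retained"]],
      screen$funnel[["pool_retained"]], screen$funnel[["intersection"]])

  # --- consequence stage ----------------------------------------------
  consequence <- run_stage("consequence", {
    fx <- splice_loss_fixture()
    consequence_report(fx$model, fx$event$start, fx$event$end,
                       fx$event$replacement, domains = fx$domains,
                       splice_policy = config$splice_policy)
  })

  top <- if (nrow(screen$intersection) > 0) screen$intersection$variant_id[1] else NA_character_
  summary <- list(
    config_hash = config_hash(config),
    seed = s,
    segregation = list(
      verdict = segregation$verdict,
      f2_chi_square = if (is.null(segregation$f2)) NA_real_ else round(segregation$f2$chi_square, 4),
      bc1_chi_square = if (is.null(segregation$bc1)) NA_real_ else round(segregation$bc1$chi_square, 4)
    ),
    scan = list(
      n_variants = nrow(variants),
      n_after_qc = nrow(scan_res),
      peak_id = interval$peak$variant_id,
      peak_p = signif(interval$peak$p_value, 6)
    ),
    interval = list(
      chrom = interval$chrom, start = interval$start, end = interval$end,
      span_bp = interval$end - interval$start,
      n_members = nrow(interval$members)
    ),
    screen = list(
      panel_retained = unname(screen$funnel[["panel_retained"]]),
      pool_retained = unname(screen$funnel[["pool_retained"]]),
      intersection = unname(screen$funnel[["intersection"]]),
      top_candidate = top,
      nominated_gene = if (nrow(screen$nominated) > 0) screen$nominated$gene_id else NA_character_,
      n_support = if (nrow(screen$nominated) > 0) screen$nominated$n_support else 0L
    ),
    truth = list(
      causal_id = pop$truth$causal_id,
      causal_in_intersection = pop$truth$causal_id %in% screen$intersection$variant_id,
      causal_top_ranked = identical(top, pop$truth$causal_id)
    ),
    consequence = list(
      classification = consequence$classification,
      mutant_protein_length = consequence$mutant_protein_length,
      frameshift_cdna_pos = consequence$frameshift_cdna_pos,
      stop_residue = consequence$stop_residue,
      domain_status = if (!is.null(consequence$domains)) consequence$domains$status[1] else NA_character_
    )
  )

  result <- structure(
    list(
      config = config, population = pop, segregation = segregation,
      scan = scan_res, interval = interval, screen = screen,
      consequence = consequence, summary = summary
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  pop <- result$population
  write_vcf(pop$genotypes, p("f2_genotypes.vcf"), parents = pop$parents)
  write_phenotypes(pop$phenotypes, p("phenotypes.tsv"))
  readr::write_tsv(as_tibble(result$scan), p("association_scan.tsv"))
  jsonlite::write_json(glance(result$interval), p("interval.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(result$screen$assignments, p("candidate_assignments.tsv"))
  jsonlite::write_json(result$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(result$config), p("config.yaml"))
  jsonlite::write_json(
    list(causal_id = pop$truth$causal_id, seed = result$config$seed),
    p("truth.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat(sprintf("  inheritance: %s\n", s$segregation$verdict))
  cat(sprintf("  peak %s (P = %g); interval %s:%d-%d (%d variants)\n",
              s$scan$peak_id, s$scan$peak_p, s$interval$chrom,
              s$interval$start, s$interval$end, s$interval$n_members))
  cat(sprintf("  screen funnel: %d -> panel %d / pool %d -> %d; top candidate %s\n",
              s$interval$n_members, s$screen$panel_retained,
              s$screen$pool_retained, s$screen$intersection,
              s$screen$top_candidate))
  cat(sprintf("  nominated gene: %s (%d variants); consequence: %s, %d aa\n",
              s$screen$nominated_gene, s$screen$n_support,
              s$consequence$classification, s$consequence$mutant_protein_length))
  invisible(x)
}
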