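#' Screen interval variants against a germplasm panel
#'
#' A causal mutant allele that is fully penetrant and recessive cannot be
#' homozygous in any normal-phenotype accession - and, if private to the
#' mutant line, cannot be present at all. `panel_screen()` retains the
#' interval variants whose mutant allele passes that test across the panel:
#' with `rule = "no-allele"` (default) a variant survives only if zero
#' accessions carry the allele at all; with `rule = "no-homozygote"` only
#' homozygous carriers disqualify it. Accessions with missing calls at a site
#' never count as carriers.
#'
#' @param variants Tibble of interval variants with a `variant_id` column
#'   (e.g. `tidy()` of a [define_interval()] result).
#' @param panel Panel genotype table as from [simulate_panel()]: `variant_id`
#'   plus one 0/1/2/`NA` column per accession (mutant-allele dosage).
#' @param rule Carrier rule, `"no-allele"` or `"no-homozygote"`.
#' @param on_absent What to do when an interval variant is missing from the
#'   panel index: `"error"` (default) or `"retain"` with a warning.
#' @return The retained rows of `variants` with appended columns
#'   `n_carriers`, `n_homozygous`, `n_missing`.
#' @export
panel_screen <- function(variants, panel,
                         rule = c("no-allele", "no-homozygote"),
                         on_absent = c("error", "retain")) {
  rule <- match.arg(rule)
  on_absent <- match.arg(on_absent)
  if (!"variant_id" %in% names(variants)) abort("`variants` must have a variant_id column.")
  if (!"variant_id" %in% names(panel)) abort("`panel` must have a variant_id column.")

  absent <- setdiff(variants$variant_id, panel$variant_id)
  if (length(absent) > 0) {
    msg <- sprintf(
      "%d interval variant(s) absent from the panel index: %s.",
      length(absent), paste(head(absent, 5), collapse = ", ")
    )
    if (on_absent == "error") abort(msg) else warn(paste(msg, "Treated as retained."))
  }

  acc_cols <- setdiff(names(panel), "variant_id")
  pm <- panel[match(variants$variant_id, panel$variant_id), acc_cols, drop = FALSE]
  pm <- as.matrix(pm)
  n_carriers <- rowSums(pm >= 1L, na.rm = TRUE)
  n_hom <- rowSums(pm == 2L, na.rm = TRUE)
  n_missing <- rowSums(is.na(pm))
  in_panel <- variants$variant_id %in% panel$variant_id
  n_missing[!in_panel] <- length(acc_cols)

  keep <- if (rule == "no-allele") n_carriers == 0 else n_hom == 0
  keep <- keep | !in_panel # only reachable with on_absent = "retain"
  out <- variants[keep, , drop = FALSE]
  out$n_carriers <- n_carriers[keep]
  out$n_homozygous <- n_hom[keep]
  out$n_missing <- n_missing[keep]
  out
}

#' Screen interval variants against a bulked-segregant pool
#'
#' In a pool of recessive-phenotype individuals the causal allele - and
#' anything tightly linked to it - is (near-)fixed, so its reads are almost
#' all alternate. `pool_screen()` retains variants with read depth at least
#' `min_depth` whose alternate-read fraction is at least `min_alt_fraction`.
#' Sites below `min_depth` are "unevaluable": excluded from the retained set
#' and flagged distinctly in the `flags` attribute rather than treated as
#' discordant.
#'
#' @param variants Tibble of interval variants with a `variant_id` column.
#' @param pool Pool counts with `variant_id`, `ref_count`, `alt_count` (see
#'   [simulate_pool()]).
#' @param min_depth Minimum evaluable depth (default 10).
#' @param min_alt_fraction Minimum alternate-read fraction in (0.5, 1]
#'   (default 0.95; below 1 to tolerate sequencing error).
#' @return The retained rows of `variants` with appended `depth`,
#'   `alt_fraction` and `status` columns; the attribute `flags` holds the
#'   full annotated table with `status` in `retained`, `dropped`,
#'   `unevaluable`.
#' @export
pool_screen <- function(variants, pool, min_depth = 10, min_alt_fraction = 0.95) {
  if (min_depth < 1) abort("`min_depth` must be >= 1.")
  if (min_alt_fraction <= 0.5 || min_alt_fraction > 1) {
    abort("`min_alt_fraction` must lie in (0.5, 1].")
  }
  if (!"variant_id" %in% names(variants)) abort("`variants` must have a variant_id column.")
  if (!all(c("variant_id", "ref_count", "alt_count") %in% names(pool))) {
    abort("`pool` must have variant_id, ref_count and alt_count columns.")
  }
  idx <- match(variants$variant_id, pool$variant_id)
  ref <- pool$ref_count[idx]
  alt <- pool$alt_count[idx]
  depth <- ref + alt
  frac <- ifelse(depth > 0, alt / depth, NA_real_)
  status <- dplyr::case_when(
    is.na(depth) | depth < min_depth ~ "unevaluable",
    frac >= min_alt_fraction ~ "retained",
    TRUE ~ "dropped"
  )
  flags <- variants
  flags$depth <- depth
  flags$alt_fraction <- frac
  flags$status <- status
  out <- flags[status == "retained", , drop = FALSE]
  attr(out, "flags") <- flags
  out
}

#' Intersect the two screens and rank candidates
#'
#' The candidate set is the intersection of the panel-retained and the
#' pool-retained variants, ordered by ascending association p-value (when a
#' scan is supplied) and then chromosome/position.
#'
#' @param panel_retained,pool_retained Variant tibbles from [panel_screen()]
#'   and [pool_screen()], over the same variant universe.
#' @param scan Optional association scan supplying `p_value` per variant.
#' @return A tibble of intersected variants, ranked; columns from
#'   `panel_retained` plus `depth`/`alt_fraction` from the pool screen and
#'   `p_value` when available.
#' @export
screen_intersect <- function(panel_retained, pool_retained, scan = NULL) {
  out <- panel_retained |>
    inner_join(
      select(pool_retained, "variant_id", dplyr::any_of(c("depth", "alt_fraction"))),
      by = "variant_id"
    )
  if (!is.null(scan) && !"p_value" %in% names(out)) {
    out <- left_join(out, select(scan, "variant_id", "p_value"), by = "variant_id")
  }
  if ("p_value" %in% names(out)) {
    out <- arrange(out, .data$p_value, .data$chrom, .data$pos)
  } else if (all(c("chrom", "pos") %in% names(out))) {
    out <- arrange(out, .data$chrom, .data$pos)
  }
  out
}

#' Gene annotation container
#'
#' Bundles gene spans and their exon intervals for candidate-gene
#' assignment. Exons must fall inside their gene's span.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `strand` (`"+"`/`"-"`),
#'   `start`, `end` (1-based inclusive).
#' @param exons Tibble with `gene_id`, `start`, `end`.
#' @return A list of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons) {
  need_g <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need_g %in% names(genes))) {
    abort(paste0("`genes` must have columns: ", paste(need_g, collapse = ", "), "."))
  }
  if (!all(c("gene_id", "start", "end") %in% names(exons))) {
    abort("`exons` must have gene_id, start and end columns.")
  }
  if (!all(genes$strand %in% c("+", "-"))) abort("`strand` must be \"+\" or \"-\".")
  if (!all(exons$gene_id %in% genes$gene_id)) {
    abort("Every exon must belong to a listed gene.")
  }
  structure(list(genes = as_tibble(genes), exons = as_tibble(exons)),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes, %d exons\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Assign variants to genes by genomic context
#'
#' Classifies each variant relative to every nearby gene with priority
#' exon > intron > 5'-flanking > 3'-flanking > intergenic. Flanking regions
#' extend `flank_bp` beyond the gene span and are strand-aware: for a `+`
#' strand gene the 5' flank lies upstream of `start`, for a `-` strand gene
#' upstream of `end`. A variant farther than `flank_bp` from every gene is
#' intergenic. Variants hit by several overlapping genes get one row per
#' gene.
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos` (and optionally
#'   `p_value`, carried through).
#' @param annotation A [gene_annotation()].
#' @param flank_bp Flank width in bp (default 10,000).
#' @return A tibble with one row per variant-gene assignment (or per variant
#'   for intergenic ones): input columns plus `gene_id` (`NA` when
#'   intergenic) and `region` in `"exon"`, `"intron"`, `"5'-flanking"`,
#'   `"3'-flanking"`, `"intergenic"`.
#' @export
assign_to_genes <- function(variants, annotation, flank_bp = 10000) {
  if (!inherits(annotation, "gene_annotation")) {
    abort("`annotation` must be a gene_annotation.")
  }
  if (!all(c("variant_id", "chrom", "pos") %in% names(variants))) {
    abort("`variants` must have variant_id, chrom and pos columns.")
  }
  genes <- annotation$genes
  exons <- annotation$exons
  if (nrow(variants) == 0) {
    return(bind_cols(variants, tibble(gene_id = character(), region = character())))
  }
  rows <- purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    near <- genes |>
      filter(.data$chrom == v$chrom,
             v$pos >= .data$start - flank_bp,
             v$pos <= .data$end + flank_bp)
    if (nrow(near) == 0) {
      return(bind_cols(v, tibble(gene_id = NA_character_, region = "intergenic")))
    }
    purrr::map_dfr(seq_len(nrow(near)), function(j) {
      gn <- near[j, ]
      ex <- exons[exons$gene_id == gn$gene_id, ]
      region <- if (v$pos >= gn$start && v$pos <= gn$end) {
        if (any(v$pos >= ex$start & v$pos <= ex$end)) "exon" else "intron"
      } else {
        before <- v$pos < gn$start
        if ((before && gn$strand == "+") || (!before && gn$strand == "-")) {
          "5'-flanking"
        } else {
          "3'-flanking"
        }
      }
      bind_cols(v, tibble(gene_id = gn$gene_id, region = region))
    })
  })
  rows
}

#' Nominate the candidate gene from variant assignments
#'
#' The nominated gene is the one hosting the plurality of assigned variants
#' (intergenic assignments do not vote); ties are broken by the member
#' variant with the lowest association p-value, then by gene id for
#' determinism.
#'
#' @param assignments Output of [assign_to_genes()].
#' @param scan Optional association scan supplying `p_value` for
#'   tie-breaking when `assignments` lacks it.
#' @return A one-row tibble `gene_id`, `n_support`, `best_p` (`NA` when no
#'   p-values are available), or a zero-row tibble when every variant is
#'   intergenic.
#' @export
nominate_gene <- function(assignments, scan = NULL) {
  a <- assignments[!is.na(assignments$gene_id), , drop = FALSE]
  if (!"p_value" %in% names(a) && !is.null(scan)) {
    a <- left_join(a, select(scan, "variant_id", "p_value"), by = "variant_id")
  }
  if (nrow(a) == 0) {
    return(tibble(gene_id = character(), n_support = integer(), best_p = numeric()))
  }
  if (!"p_value" %in% names(a)) a$p_value <- NA_real_
  a |>
    group_by(.data$gene_id) |>
    summarise(
      n_support = dplyr::n_distinct(.data$variant_id),
      best_p = suppressWarnings(min(.data$p_value, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    mutate(best_p = ifelse(is.finite(.data$best_p), .data$best_p, NA_real_)) |>
    arrange(dplyr::desc(.data$n_support), .data$best_p, .data$gene_id) |>
    slice(1)
}

#' Run the full dual screen over an interval
#'
#' Convenience orchestration of the screening stage: panel screen, pool
#' screen, intersection, gene assignment and nomination, with the funnel of
#' surviving set sizes recorded at each step.
#'
#' @param interval A [define_interval()] result (its members are screened).
#' @param panel Panel genotype table.
#' @param pool Pool read counts.
#' @param annotation A [gene_annotation()].
#' @param min_depth,min_alt_fraction Pool thresholds, see [pool_screen()].
#' @param panel_rule Carrier rule, see [panel_screen()].
#' @param flank_bp Gene-assignment flank, see [assign_to_genes()].
#' @return An object of class `screen_report`: list with `input`,
#'   `panel_retained`, `pool_retained`, `intersection`, `assignments`,
#'   `nominated`, `funnel` (named counts). `tidy()` returns the annotated
#'   intersection.
#' @export
variant_screen <- function(interval, panel, pool, annotation,
                           min_depth = 10, min_alt_fraction = 0.95,
                           panel_rule = "no-allele", flank_bp = 10000) {
  members <- if (inherits(interval, "target_interval")) interval$members else interval
  pan <- panel_screen(members, panel, rule = panel_rule)
  poo <- pool_screen(members, pool, min_depth = min_depth,
                     min_alt_fraction = min_alt_fraction)
  inter <- screen_intersect(pan, poo)
  assigned <- assign_to_genes(inter, annotation, flank_bp = flank_bp)
  nom <- nominate_gene(assigned)
  structure(
    list(
      input = members,
      panel_retained = pan,
      pool_retained = poo,
      intersection = inter,
      assignments = assigned,
      nominated = nom,
      funnel = c(
        input = nrow(members),
        panel_retained = nrow(pan),
        pool_retained = nrow(poo),
        intersection = nrow(inter)
      )
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  f <- x$funnel
  cat(sprintf(
    "<screen_report> %d interval variants -> %d panel-retained / %d pool-retained -> %d intersected\n",
    f[["input"]], f[["panel_retained"]], f[["pool_retained"]], f[["intersection"]]
  ))
  if (nrow(x$nominated) > 0) {
    cat(sprintf("  nominated gene: %s (%d supporting variants)\n",
                x$nominated$gene_id, x$nominated$n_support))
  } else {
    cat("  no candidate gene nominated\n")
  }
  invisible(x)
}

#' @export
tidy.screen_report <- function(x, ...) x$assignments

#' @export
glance.screen_report <- function(x, ...) {
  tibble(
    n_input = x$funnel[["input"]],
    n_panel_retained = x$funnel[["panel_retained"]],
    n_pool_retained = x$funnel[["pool_retained"]],
    n_intersection = x$funnel[["intersection"]],
    nominated_gene = if (nrow(x$nominated) > 0) x$nominated$gene_id else NA_character_,
    n_support = if (nrow(x$nominated) > 0) x$nominated$n_support else 0L
  )
}
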