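#' Default pipeline thresholds
#'
#' Every cutoff of the cascade, surfaced in one place so sensitivity
#' analyses are one-line edits: QUAL > 300 (SNV) / > 1000 (indel),
#' parental GQ >= 30, gnomAD AF <= 0.001, combined cohort frequency <=
#' 0.01, CADD >= 25, oe upper bound < 0.35, TPM >= 2, mosaic VAF within
#' [0.10, 0.40], parental alt reads <= 2, recurrence <= 2, allele gate
#' >= 5, FDR 0.05.
#'
#' @return named list of thresholds.
#' @export
pipeline_thresholds <- function() {
  list(qual_snv = 300, qual_indel = 1000, gq = 30, af_rare = 0.001,
       cohort_freq = 0.01, cadd_damaging = 25, oe_upper = 0.35, tpm = 2,
       vaf_window = c(0.10, 0.40), parental_alt_reads = 2, recurrence = 2,
       gate = 5, fdr = 0.05)
}

#' Cohort descriptive summary
#'
#' Tabulates heart-defect labels over probands as count and percentage
#' (rounded half-up to one decimal).
#'
#' @param cohort a \code{trio_cohort} with defect labels.
#' @return data.frame (defect, n, percent), decreasing by n.
#' @export
cohort_summary <- function(cohort) {
  n <- length(cohort$cases)
  if (is.null(cohort$defects))
    return(data.frame(defect = character(), n = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  tab <- sort(table(cohort$defects), decreasing = TRUE)
  data.frame(defect = names(tab), n = as.integer(tab),
             percent = defect_percentage(as.integer(tab), n),
             stringsAsFactors = FALSE)
}

.load_inputs <- function(inputs) {
  need <- c("vcf", "annotations", "constraint", "expression", "pedigree",
            "panels_dir")
  miss <- setdiff(need, names(inputs))
  if (length(miss))
    stop("missing pipeline inputs: ", paste(miss, collapse = ", "))
  for (f in c(need[need != "panels_dir"],
              intersect("mosaic", names(inputs))))
    if (!file.exists(inputs[[f]]))
      stop("input stage '", f, "': file not found: ", inputs[[f]])
  list(callset = read_callset(inputs$vcf),
       annotations = read_annotations(inputs$annotations),
       constraint = read_constraint(inputs$constraint),
       expression = read_expression(inputs$expression),
       cohort = read_pedigree(inputs$pedigree),
       panels = load_panels(inputs$panels_dir),
       mosaic_candidates = if (!is.null(inputs$mosaic))
         read_mosaic_candidates(inputs$mosaic) else NULL)
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: input loading (or simulation), embryonic
#' expression restriction, mosaic candidate post-filtering, HQ de novo /
#' inherited classification with MNV merging and relevance annotation, the
#' per-proband report, gene- and panel-level TDT, and the CADD-weighted
#' burden association test with relatedness exclusion and PC1 correction.
#' Per-stage attrition counts are logged via \code{message()}.
#'
#' @param config list with either \code{simulate} (arguments to
#'   \code{\link{sim_config}}) or \code{inputs} (named paths: vcf,
#'   annotations, constraint, expression, pedigree, panels_dir, optional
#'   mosaic), plus optional \code{thresholds} overrides,
#'   \code{tdt_method} ("binomial"/"chi2") and \code{seed}.
#' @param out_dir optional existing directory; when given, all result
#'   tables are written as tab-separated files.
#' @return list with elements inputs (data objects), mosaic, classified,
#'   report, tdt (gene/panel), at (gene/panel), summary, thresholds.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  th <- utils::modifyList(pipeline_thresholds(), config$thresholds %||% list())
  tdt_method <- config$tdt_method %||% "binomial"

  if (!is.null(config$simulate)) {
    sc <- do.call(sim_config, config$simulate)
    if (!is.null(config$seed)) sc$seed <- config$seed
    message("stage simulate: seed ", sc$seed)
    sim <- simulate_cohort(sc)
    dat <- sim[c("callset", "annotations", "constraint", "expression",
                 "cohort", "panels", "mosaic_candidates")]
    dat$truth <- sim$truth
  } else if (!is.null(config$inputs)) {
    dat <- .load_inputs(config$inputs)
  } else stop("config must contain either 'simulate' or 'inputs'")
  cs <- dat$callset
  message("stage load: ", nrow(cs$sites), " sites, ",
          length(cs$samples), " samples, ", nrow(dat$cohort$trios), " trios")

  expressed <- expressed_genes(dat$expression, tpm_threshold = th$tpm)
  panels_expr <- lapply(dat$panels, restrict_panel, expression = dat$expression,
                        tpm_threshold = th$tpm)
  message("stage expression: ", length(expressed), "/",
          nrow(dat$expression), " genes embryonically expressed")

  mosaic <- NULL
  if (!is.null(dat$mosaic_candidates) && nrow(dat$mosaic_candidates)) {
    filt <- filter_mosaic_candidates(
      dat$mosaic_candidates, cs, dat$cohort, dat$annotations,
      min_posterior = 0.90, vaf_window = th$vaf_window,
      max_parental_alt_reads = th$parental_alt_reads,
      max_recurrence = th$recurrence)
    surv <- filt[filt$pass, , drop = FALSE]
    message("stage mosaic: ", nrow(filt), " candidates -> ", nrow(surv),
            " survivors")
    relevance <- if (nrow(surv)) evaluate_mosaic_relevance(
      surv, dat$annotations, dat$constraint, dat$expression, panels_expr,
      oe_cutoff = th$oe_upper, cadd_cutoff = th$cadd_damaging,
      max_af = th$af_rare) else NULL
    mosaic <- list(filtered = filt, survivors = surv, relevance = relevance)
  }

  classified <- classify_trio_variants(
    cs, dat$cohort, dat$annotations, min_qual_snv = th$qual_snv,
    min_qual_indel = th$qual_indel, min_gq = th$gq,
    max_recurrence = th$recurrence)
  retained <- retain_rare_damaging(classified, max_af = th$af_rare)
  merged <- merge_mnv(retained)
  annotated <- evaluate_variant_relevance(
    merged, dat$constraint, dat$expression, panels_expr,
    oe_cutoff = th$oe_upper, cadd_cutoff = th$cadd_damaging,
    max_af = th$af_rare)
  message("stage classify: ", nrow(classified), " HQ calls -> ",
          nrow(retained), " rare LOF/missense -> ",
          sum(annotated$of_interest), " variants of interest")
  report <- per_proband_report(classified, annotated, dat$cohort,
                               max_af = th$af_rare)

  tdt_res <- list()
  for (lv in c("gene", "panel"))
    tdt_res[[lv]] <- suppressWarnings(tdt_analysis(
      cs, dat$cohort, dat$annotations, expressed,
      panels = panels_expr, level = lv, method = tdt_method,
      min_alleles = th$gate, min_qual_snv = th$qual_snv,
      min_qual_indel = th$qual_indel, max_af = th$af_rare))
  message("stage tdt: ", sum(tdt_res$gene$tested), " genes and ",
          sum(tdt_res$panel$tested), " panels tested")

  at_samples <- c(dat$cohort$cases, dat$cohort$controls)
  G <- genotype_matrix(cs, at_samples)
  grm <- compute_grm(G)
  excluded <- exclude_related(grm)
  kept <- setdiff(at_samples, excluded)
  message("stage relatedness: ", length(excluded), " samples excluded")
  pc1 <- compute_pc1(G[kept, , drop = FALSE])
  status <- setNames(as.integer(kept %in% dat$cohort$cases), kept)
  selected <- select_at_variants(cs, dat$annotations, expressed, kept,
                                 max_af = th$af_rare,
                                 max_cohort_af = th$cohort_freq)
  at_res <- list()
  for (lv in c("gene", "panel"))
    at_res[[lv]] <- suppressWarnings(run_at(
      cs, selected, status, pc1, level = lv, panels = panels_expr,
      min_alleles = th$gate))
  message("stage burden: ", sum(at_res$gene$tested), " genes and ",
          sum(at_res$panel$tested), " panels tested")

  n_sig <- sum(c(tdt_res$gene$q, tdt_res$panel$q, at_res$gene$q,
                 at_res$panel$q) < th$fdr, na.rm = TRUE)
  summary <- list(defects = cohort_summary(dat$cohort),
                  counts = report$summary,
                  n_significant = n_sig,
                  excluded_samples = excluded)
  message("stage report: ", n_sig, " unit(s) significant at FDR ", th$fdr)

  out <- list(inputs = dat, mosaic = mosaic, classified = classified,
              annotated = annotated, report = report, tdt = tdt_res,
              at = at_res, summary = summary, thresholds = th)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) stop("output directory not found: ", out_dir)
    .write_tsv(annotated, file.path(out_dir, "classified_variants.tsv"))
    .write_tsv(report$per_proband, file.path(out_dir, "per_proband.tsv"))
    .write_tsv(report$summary, file.path(out_dir, "count_summary.tsv"))
    if (!is.null(mosaic))
      .write_tsv(mosaic$filtered, file.path(out_dir, "mosaic_filtered.tsv"))
    .write_tsv(tdt_res$gene, file.path(out_dir, "tdt_gene.tsv"))
    .write_tsv(tdt_res$panel, file.path(out_dir, "tdt_panel.tsv"))
    .write_tsv(at_res$gene, file.path(out_dir, "at_gene.tsv"))
    .write_tsv(at_res$panel, file.path(out_dir, "at_panel.tsv"))
    .write_tsv(summary$defects, file.path(out_dir, "cohort_defects.tsv"))
  }
  invisible(out)
}
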