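#' Post-filter mosaic candidates
#'
#' Applies the five-way conjunction used to reduce a mosaic caller's
#' candidate list to credible de novo mosaic variants: posterior
#' probability >= 0.90, variant allele fraction within the closed window
#' [0.10, 0.40], at most 2 alternate-allele reads in each parent, cohort
#' recurrence <= 2 among case probands, and a predicted LOF or missense
#' consequence. Every candidate is returned with per-criterion pass/fail
#' flags; survivors are the rows with \code{pass == TRUE}. Candidates
#' without an annotation are excluded with reason "unannotated".
#'
#' @param candidates data.frame from \code{\link{read_mosaic_candidates}}
#'   (or the simulator).
#' @param callset a \code{callset} used to compute cohort recurrence.
#' @param cohort a \code{trio_cohort}.
#' @param annotations annotation table with a \code{key} column.
#' @param min_posterior,vaf_window,max_parental_alt_reads,max_recurrence
#'   filter thresholds; defaults are the published cutoffs.
#' @return the candidate table with columns pass_posterior, pass_vaf,
#'   pass_parental, pass_recurrence, pass_consequence, recurrence,
#'   consequence_class, pass and reason.
#' @export
filter_mosaic_candidates <- function(candidates, callset, cohort, annotations,
                                     min_posterior = 0.90,
                                     vaf_window = c(0.10, 0.40),
                                     max_parental_alt_reads = 2,
                                     max_recurrence = 2) {
  mc <- as.data.frame(candidates)
  if (!"key" %in% names(mc))
    mc$key <- variant_key(mc$chrom, mc$pos, mc$ref, mc$alt)
  idx <- match(mc$key, annotations$key)
  annotated <- !is.na(idx)
  cls <- rep(NA_character_, nrow(mc))
  cls[annotated] <-
    as.character(classify_consequence(annotations$consequence[idx[annotated]]))
  mc$consequence_class <- cls
  mc$recurrence <- cohort_recurrence(mc$key, callset, cohort)

  mc$pass_posterior <- mc$posterior >= min_posterior
  mc$pass_vaf <- mc$vaf >= vaf_window[1] & mc$vaf <= vaf_window[2]
  # per-parent reading: either parent above the background cap fails
  mc$pass_parental <- mc$father_alt_reads <= max_parental_alt_reads &
    mc$mother_alt_reads <= max_parental_alt_reads
  mc$pass_recurrence <- mc$recurrence <= max_recurrence
  mc$pass_consequence <- !is.na(cls) & cls %in% c("LOF", "missense")

  mc$pass <- annotated & mc$pass_posterior & mc$pass_vaf & mc$pass_parental &
    mc$pass_recurrence & mc$pass_consequence
  mc$reason <- ifelse(!annotated, "unannotated",
    ifelse(mc$pass, "",
      apply(cbind(posterior = !mc$pass_posterior, vaf = !mc$pass_vaf,
                  parental = !mc$pass_parental,
                  recurrence = !mc$pass_recurrence,
                  consequence = !mc$pass_consequence), 1L,
            function(f) paste(names(f)[f], collapse = ";"))))
  mc
}

#' Relevance annotation of a surviving mosaic candidate
#'
#' For each filtered candidate, evaluates the evidence used to judge
#' relevance to the heart phenotype: embryonic cardiac expression of the
#' gene, damaging in-silico prediction (LOF: LOF oe upper bound < 0.35;
#' missense: missense oe upper bound < 0.35 or CADD >= 25), rarity
#' (gnomAD AF <= 0.001, absent-from-gnomAD treated as 0), and gene panel
#' membership. A gene absent from the constraint table leaves the oe flag
#' NA while the CADD criterion is still evaluated.
#'
#' @param survivors filtered candidates (rows of
#'   \code{\link{filter_mosaic_candidates}} output with \code{pass} TRUE).
#' @param annotations,constraint,expression,panels reference tables.
#' @param oe_cutoff,cadd_cutoff,max_af damaging/rarity thresholds.
#' @return data.frame with columns expressed, damaging_oe, damaging_cadd,
#'   damaging, rare and panels (semicolon-joined panel names).
#' @export
evaluate_mosaic_relevance <- function(survivors, annotations, constraint,
                                      expression, panels,
                                      oe_cutoff = 0.35, cadd_cutoff = 25,
                                      max_af = 0.001) {
  mc <- as.data.frame(survivors)
  idx <- match(mc$key, annotations$key)
  gene <- annotations$gene[idx]
  cadd <- annotations$cadd[idx]
  af <- annotations$gnomad_af[idx]
  af[is.na(af)] <- 0
  cls <- as.character(classify_consequence(annotations$consequence[idx]))

  cidx <- match(gene, constraint$gene)
  oe <- ifelse(cls == "LOF", constraint$lof_oe_upper[cidx],
               constraint$mis_oe_upper[cidx])
  damaging_oe <- oe < oe_cutoff              # NA when gene unknown
  damaging_cadd <- cls == "missense" & !is.na(cadd) & cadd >= cadd_cutoff
  damaging <- ifelse(cls == "LOF", damaging_oe,
                     ifelse(is.na(damaging_oe), damaging_cadd,
                            damaging_oe | damaging_cadd))

  expressed <- is_embryonically_expressed(gene, expression)
  in_panels <- vapply(gene, function(g) {
    hit <- names(panels)[vapply(panels, function(p) g %in% p, logical(1))]
    paste(hit, collapse = ";")
  }, character(1))

  data.frame(mc, gene = gene, cadd = cadd, gnomad_af = af,
             expressed = unname(expressed), damaging_oe = damaging_oe,
             damaging_cadd = damaging_cadd, damaging = damaging,
             rare = af <= max_af, panels = unname(in_panels),
             stringsAsFactors = FALSE)
}
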