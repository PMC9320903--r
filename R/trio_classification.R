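#' High-quality de novo test for one site in one trio
#'
#' TRUE iff the proband is heterozygous, the site passes the quality
#' criterion (SNV QUAL > 300 or indel QUAL > 1000, strict), both parents
#' are homozygous reference with GQ >= 30, and the variant is seen in at
#' most \code{max_recurrence} case probands. A missing parental genotype
#' cannot certify a de novo event and yields FALSE.
#'
#' @param proband_gt,father_gt,mother_gt alt-allele counts (0/1/2/NA).
#' @param father_gq,mother_gq parental genotype qualities.
#' @param qual site QUAL; \code{indel} whether the record is an indel.
#' @param recurrence case-cohort carrier count of the variant.
#' @param min_qual_snv,min_qual_indel,min_gq,max_recurrence thresholds.
#' @return logical vector.
#' @export
is_hq_denovo <- function(proband_gt, father_gt, mother_gt,
                         father_gq, mother_gq, qual, indel, recurrence,
                         min_qual_snv = 300, min_qual_indel = 1000,
                         min_gq = 30, max_recurrence = 2) {
  qual_ok <- ifelse(indel, qual > min_qual_indel, qual > min_qual_snv)
  out <- !is.na(proband_gt) & proband_gt == 1L & qual_ok &
    !is.na(father_gt) & father_gt == 0L & !is.na(mother_gt) & mother_gt == 0L &
    !is.na(father_gq) & father_gq >= min_gq &
    !is.na(mother_gq) & mother_gq >= min_gq &
    recurrence <= max_recurrence
  out & !is.na(out)
}

#' High-quality inherited test for one site in one trio
#'
#' TRUE iff the proband carries at least one alt allele, the quality
#' criterion holds, at least one parent carries the allele, and recurrence
#' is at most \code{max_recurrence}. No GQ requirement is imposed on the
#' carrying parent. Mutually exclusive with \code{\link{is_hq_denovo}} at
#' any (variant, proband): de novo requires both parents hom-ref.
#'
#' @inheritParams is_hq_denovo
#' @return logical vector.
#' @export
is_hq_inherited <- function(proband_gt, father_gt, mother_gt, qual, indel,
                            recurrence, min_qual_snv = 300,
                            min_qual_indel = 1000, max_recurrence = 2) {
  qual_ok <- ifelse(indel, qual > min_qual_indel, qual > min_qual_snv)
  in_parent <- (!is.na(father_gt) & father_gt >= 1L) |
    (!is.na(mother_gt) & mother_gt >= 1L)
  out <- !is.na(proband_gt) & proband_gt >= 1L & qual_ok & in_parent &
    recurrence <= max_recurrence
  out & !is.na(out)
}

#' Classify HQ de novo and inherited variants across a cohort
#'
#' Runs the per-trio classifiers over every site of the call set. Variants
#' with an inframe-indel consequence are excluded up front (high
#' false-positive risk for this variant type); unannotated sites are kept
#' and classified, with NA consequence class.
#'
#' @param cs a \code{callset}.
#' @param cohort a \code{trio_cohort}.
#' @param annotations annotation table with a \code{key} column.
#' @param min_qual_snv,min_qual_indel,min_gq,max_recurrence thresholds.
#' @return data.frame with one row per (variant, proband, category):
#'   key, chrom, pos, ref, alt, proband, category (HQ_DNV | HQ_INHERITED),
#'   gene, consequence_class, gnomad_af, cadd.
#' @export
classify_trio_variants <- function(cs, cohort, annotations,
                                   min_qual_snv = 300, min_qual_indel = 1000,
                                   min_gq = 30, max_recurrence = 2) {
  aidx <- match(cs$sites$key, annotations$key)
  cls <- rep(NA_character_, nrow(cs$sites))
  ok <- !is.na(aidx)
  cls[ok] <- as.character(classify_consequence(annotations$consequence[aidx[ok]]))
  keep <- is.na(cls) | cls != "inframe_indel"

  rec <- site_recurrence(cs, cohort)
  indel <- is_indel_site(cs)
  qual <- cs$sites$qual
  tr <- cohort$trios
  res <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    pg <- cs$gt[, tr$proband[i]]
    fg <- cs$gt[, tr$father[i]]; mg <- cs$gt[, tr$mother[i]]
    fq <- cs$gq[, tr$father[i]]; mq <- cs$gq[, tr$mother[i]]
    dnv <- is_hq_denovo(pg, fg, mg, fq, mq, qual, indel, rec,
                        min_qual_snv, min_qual_indel, min_gq, max_recurrence)
    inh <- is_hq_inherited(pg, fg, mg, qual, indel, rec,
                           min_qual_snv, min_qual_indel, max_recurrence)
    hit <- keep & (dnv | inh)
    if (!any(hit)) next
    res[[i]] <- data.frame(
      key = cs$sites$key[hit], chrom = cs$sites$chrom[hit],
      pos = cs$sites$pos[hit], ref = cs$sites$ref[hit],
      alt = cs$sites$alt[hit], proband = tr$proband[i],
      category = ifelse(dnv[hit], "HQ_DNV", "HQ_INHERITED"),
      consequence_class = cls[hit],
      gnomad_af = annotations$gnomad_af[aidx[hit]],
      cadd = annotations$cadd[aidx[hit]],
      gene = annotations$gene[aidx[hit]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(key = character(), chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      proband = character(), category = character(),
                      consequence_class = character(), gnomad_af = numeric(),
                      cadd = numeric(), gene = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Retain rare LOF and missense variants
#'
#' Applies the post-classification retention rule shared by the de novo and
#' inherited branches: keep LOF and missense variants with
#' gnomAD AF <= \code{max_af}. A variant absent from gnomAD (NA AF) is
#' rarer than any listed variant and is treated as AF 0.
#'
#' @param classified output of \code{\link{classify_trio_variants}}.
#' @param max_af allele-frequency cutoff (default 0.001).
#' @return the retained subset.
#' @export
retain_rare_damaging <- function(classified, max_af = 0.001) {
  af <- classified$gnomad_af
  af[is.na(af)] <- 0
  classified[!is.na(classified$consequence_class) &
               classified$consequence_class %in% c("LOF", "missense") &
               af <= max_af, , drop = FALSE]
}

#' Group adjacent variants into multi-nucleotide variants
#'
#' Variants in the same proband and category at consecutive positions
#' (position difference exactly 1, same chromosome) represent a single
#' multi-nucleotide variant and share an \code{mnv_group} id; each group
#' counts once in all tallies. The group takes the maximum CADD and the
#' minimum gnomAD AF of its members.
#'
#' @param classified classified variant table (any stage).
#' @return input with added columns mnv_group, group_cadd, group_af.
#' @export
merge_mnv <- function(classified) {
  df <- classified
  if (!nrow(df)) {
    df$mnv_group <- character(0); df$group_cadd <- numeric(0)
    df$group_af <- numeric(0)
    return(df)
  }
  o <- order(df$proband, df$category, df$chrom, df$pos)
  df <- df[o, , drop = FALSE]
  same_run <- c(FALSE,
                df$proband[-1] == df$proband[-nrow(df)] &
                  df$category[-1] == df$category[-nrow(df)] &
                  df$chrom[-1] == df$chrom[-nrow(df)] &
                  df$pos[-1] == df$pos[-nrow(df)] + 1L)
  gid <- cumsum(!same_run)
  df$mnv_group <- sprintf("%s.mnv%04d", df$proband, gid)
  af <- df$gnomad_af; af[is.na(af)] <- 0
  df$group_cadd <- stats::ave(df$cadd, gid, FUN = function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  df$group_af <- stats::ave(af, gid, FUN = min)
  rownames(df) <- NULL
  df
}

#' Annotate retained variants with relevance evidence
#'
#' Adds the evidence columns used for the "variants of interest" tally:
#' embryonic expression of the gene, damaging prediction (LOF: LOF oe upper
#' bound < \code{oe_cutoff}; missense: missense oe upper bound <
#' \code{oe_cutoff} or CADD >= \code{cadd_cutoff}), rarity, and panel
#' membership. Variants in genes unknown to the expression or constraint
#' table get NA flags and never count as variants of interest.
#'
#' @param retained output of \code{\link{retain_rare_damaging}} (after
#'   \code{\link{merge_mnv}} if MNV grouping is wanted).
#' @param constraint,expression,panels reference tables.
#' @param oe_cutoff,cadd_cutoff,max_af thresholds.
#' @return input with added columns expressed, damaging, n_panels,
#'   panel_list, rare, of_interest.
#' @export
evaluate_variant_relevance <- function(retained, constraint, expression,
                                       panels, oe_cutoff = 0.35,
                                       cadd_cutoff = 25, max_af = 0.001) {
  df <- retained
  if (!nrow(df)) {
    for (cc in c("expressed", "damaging", "rare", "of_interest"))
      df[[cc]] <- logical(0)
    df$n_panels <- integer(0); df$panel_list <- character(0)
    return(df)
  }
  cadd <- if ("group_cadd" %in% names(df)) df$group_cadd else df$cadd
  af <- if ("group_af" %in% names(df)) df$group_af else df$gnomad_af
  af[is.na(af)] <- 0
  cidx <- match(df$gene, constraint$gene)
  oe <- ifelse(df$consequence_class == "LOF",
               constraint$lof_oe_upper[cidx], constraint$mis_oe_upper[cidx])
  damaging_oe <- oe < oe_cutoff
  damaging_cadd <- df$consequence_class == "missense" & !is.na(cadd) &
    cadd >= cadd_cutoff
  df$damaging <- ifelse(df$consequence_class == "LOF", damaging_oe,
                        ifelse(is.na(damaging_oe), damaging_cadd,
                               damaging_oe | damaging_cadd))
  df$expressed <- unname(is_embryonically_expressed(df$gene, expression))
  pn <- lapply(df$gene, function(g)
    names(panels)[vapply(panels, function(p) !is.na(g) && g %in% p,
                         logical(1))])
  df$n_panels <- lengths(pn)
  df$panel_list <- vapply(pn, paste, character(1), collapse = ";")
  df$rare <- af <= max_af
  df$of_interest <- !is.na(df$expressed) & df$expressed &
    !is.na(df$damaging) & df$damaging & df$rare & df$n_panels >= 1
  df
}

.count_stats <- function(x, sd_type) {
  n <- length(x)
  c(min = min(x), max = max(x), median = median(x),
    mean = sum(x) / n,
    sd = if (sd_type == "sample") sd(x) else
      sqrt(sum((x - mean(x))^2) / n))
}

#' Per-proband variant report
#'
#' Tallies, per proband, the stages of the classification cascade: HQ de
#' novo variants, rare HQ de novo variants, HQ rare inherited variants
#' (all consequence classes and the LOF+missense subset separately), and
#' variants of interest (rare, damaging, embryonically expressed, in at
#' least one panel). MNV groups count once where grouping has been applied.
#' Cohort statistics report min/max/median/mean/sd of each count; the mean
#' is total divided by the number of probands (empty probands included)
#' and the standard deviation is the sample sd (n - 1) by default.
#'
#' @param classified output of \code{\link{classify_trio_variants}}.
#' @param annotated relevance-annotated retained table from
#'   \code{\link{evaluate_variant_relevance}}.
#' @param cohort a \code{trio_cohort}.
#' @param max_af rarity cutoff for the "rare" tallies.
#' @param sd_type "sample" (n - 1, default) or "population".
#' @return list with \code{per_proband} (one row per proband) and
#'   \code{summary} (one row per count column).
#' @export
per_proband_report <- function(classified, annotated, cohort,
                               max_af = 0.001, sd_type = c("sample",
                                                           "population")) {
  sd_type <- match.arg(sd_type)
  probands <- cohort$trios$proband
  af <- classified$gnomad_af
  af[is.na(af)] <- 0

  tally <- function(df, who) {
    u <- if ("mnv_group" %in% names(df))
      df[!duplicated(df$mnv_group), , drop = FALSE] else df
    tab <- table(factor(u$proband, levels = probands))
    as.integer(tab[who])
  }
  dnv <- classified[classified$category == "HQ_DNV", , drop = FALSE]
  inh <- classified[classified$category == "HQ_INHERITED", , drop = FALSE]
  rare_dnv <- dnv[af[classified$category == "HQ_DNV"] <= max_af, ,
                  drop = FALSE]
  inh_lm <- inh[!is.na(inh$consequence_class) &
                  inh$consequence_class %in% c("LOF", "missense") &
                  af[classified$category == "HQ_INHERITED"] <= max_af, ,
                drop = FALSE]
  voi <- annotated[annotated$of_interest, , drop = FALSE]

  per <- data.frame(
    proband = probands,
    hq_dnv = tally(dnv, probands),
    rare_hq_dnv = tally(rare_dnv, probands),
    hq_inherited = tally(inh, probands),
    rare_inherited_lof_missense = tally(inh_lm, probands),
    variants_of_interest = tally(voi, probands),
    stringsAsFactors = FALSE)

  cols <- setdiff(names(per), "proband")
  summ <- t(vapply(cols, function(cc) .count_stats(per[[cc]], sd_type),
                   numeric(5)))
  summary_df <- data.frame(count = cols, summ, row.names = NULL,
                           stringsAsFactors = FALSE)
  list(per_proband = per, summary = summary_df)
}
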