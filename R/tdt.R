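#' Select informative parental variants for TDT
#'
#' The parental variant set consists of all HQ rare heterozygous LOF and
#' missense alleles in the case parents: parent genotype het, SNV QUAL >
#' 300 or indel QUAL > 1000, gnomAD AF <= 0.1% (NA treated as 0), LOF or
#' missense consequence (inframe indels excluded with the other classes),
#' and gene expressed in the embryonic heart.
#'
#' @param cs a \code{callset}.
#' @param cohort a \code{trio_cohort}.
#' @param annotations annotation table with a \code{key} column.
#' @param expressed character vector of embryonically expressed genes.
#' @param min_qual_snv,min_qual_indel,max_af thresholds.
#' @return data.frame with one row per informative parental allele:
#'   site (row index into the callset), key, gene, class, trio (row index
#'   into cohort$trios), parent ("father"/"mother"), parent_id.
#' @export
select_parental_variants <- function(cs, cohort, annotations, expressed,
                                     min_qual_snv = 300,
                                     min_qual_indel = 1000,
                                     max_af = 0.001) {
  aidx <- match(cs$sites$key, annotations$key)
  cls <- rep(NA_character_, nrow(cs$sites))
  ok <- !is.na(aidx)
  cls[ok] <- as.character(classify_consequence(annotations$consequence[aidx[ok]]))
  af <- annotations$gnomad_af[aidx]
  af[is.na(af)] <- 0
  gene <- annotations$gene[aidx]
  qual_ok <- ifelse(is_indel_site(cs), cs$sites$qual > min_qual_indel,
                    cs$sites$qual > min_qual_snv)
  site_ok <- ok & cls %in% c("LOF", "missense") & af <= max_af & qual_ok &
    !is.na(gene) & gene %in% expressed
  site_idx <- which(site_ok)
  if (!length(site_idx))
    return(data.frame(site = integer(), key = character(), gene = character(),
                      class = character(), trio = integer(),
                      parent = character(), parent_id = character(),
                      stringsAsFactors = FALSE))
  tr <- cohort$trios
  out <- list()
  for (i in seq_len(nrow(tr))) {
    for (role in c("father", "mother")) {
      pid <- tr[[role]][i]
      het <- which(!is.na(cs$gt[site_idx, pid]) & cs$gt[site_idx, pid] == 1L)
      if (!length(het)) next
      s <- site_idx[het]
      out[[length(out) + 1L]] <- data.frame(
        site = s, key = cs$sites$key[s], gene = gene[s], class = cls[s],
        trio = i, parent = role, parent_id = pid, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(site = integer(), key = character(), gene = character(),
                      class = character(), trio = integer(),
                      parent = character(), parent_id = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Tally transmitted and untransmitted alleles
#'
#' Resolves transmission at the allele level. For each (variant, trio)
#' group of informative parental heterozygous alleles, with h het parents
#' and child alt count a: b += min(a, h), c += h - min(a, h). This
#' reproduces the forced single-parent cases, counts a het child of two
#' het parents as one transmission and one non-transmission, and counts a
#' hom-alt child of two het parents as two transmissions. Groups with a
#' missing child genotype are uninformative and excluded.
#'
#' @param parental output of \code{\link{select_parental_variants}}.
#' @param cs a \code{callset}.
#' @param cohort a \code{trio_cohort}.
#' @return the parental table aggregated to one row per (variant, trio)
#'   with columns b and c, plus gene and class carried through.
#' @export
count_transmissions <- function(parental, cs, cohort) {
  if (!nrow(parental))
    return(data.frame(site = integer(), key = character(), gene = character(),
                      class = character(), trio = integer(), b = integer(),
                      c = integer(), stringsAsFactors = FALSE))
  grp <- paste(parental$site, parental$trio)
  first <- !duplicated(grp)
  g <- parental[first, c("site", "key", "gene", "class", "trio")]
  h <- as.integer(table(factor(grp, levels = grp[first])))
  child <- cohort$trios$proband[g$trio]
  a <- cs$gt[cbind(g$site, match(child, cs$samples))]
  informative <- !is.na(a)
  g <- g[informative, , drop = FALSE]
  h <- h[informative]; a <- a[informative]
  g$b <- pmin(as.integer(a), h)
  g$c <- h - g$b
  rownames(g) <- NULL
  g
}

#' Aggregate transmission counts per unit
#'
#' @param counts output of \code{\link{count_transmissions}}.
#' @param level "gene" (unit = gene symbol) or "panel".
#' @param panels named list of gene panels (required for level "panel"); a
#'   variant contributes to every panel containing its gene.
#' @return data.frame (unit, class, b, c), lexicographic unit order.
#' @export
aggregate_transmissions <- function(counts, level = c("gene", "panel"),
                                    panels = NULL) {
  level <- match.arg(level)
  if (level == "gene") {
    agg <- stats::aggregate(cbind(b, c) ~ gene + class, data = counts, FUN = sum)
    names(agg)[1] <- "unit"
  } else {
    stopifnot(!is.null(panels))
    rows <- list()
    for (nm in names(panels)) {
      sub <- counts[counts$gene %in% panels[[nm]], , drop = FALSE]
      if (!nrow(sub)) next
      a <- stats::aggregate(cbind(b, c) ~ class, data = sub, FUN = sum)
      rows[[nm]] <- data.frame(unit = nm, a, stringsAsFactors = FALSE)
    }
    agg <- if (length(rows)) do.call(rbind, rows) else
      data.frame(unit = character(), class = character(), b = integer(),
                 c = integer(), stringsAsFactors = FALSE)
  }
  agg <- agg[order(agg$unit, agg$class), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Transmission disequilibrium test for one count
#'
#' Tests b transmitted vs c untransmitted alleles against the Mendelian
#' null of equal transmission. Method "binomial" (default) is the exact
#' two-sided binomial test with success probability 0.5 — appropriate at
#' the small allele counts admitted by the >= 5 gate; method "chi2" is the
#' classical (b - c)^2 / (b + c) statistic against chi-square with 1 df.
#'
#' @param b,c transmitted / untransmitted allele counts.
#' @param method "binomial" or "chi2".
#' @return list(statistic, p).
#' @export
tdt_test <- function(b, c, method = c("binomial", "chi2")) {
  method <- match.arg(method)
  n <- b + c
  if (n == 0) stop("tdt_test undefined for b + c = 0; gate before testing")
  if (method == "chi2") {
    stat <- (b - c)^2 / n
    list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
  } else {
    # two-sided exact binomial, symmetric null: double the smaller tail
    p <- min(1, 2 * pbinom(min(b, c), n, 0.5))
    list(statistic = b - c, p = p)
  }
}

#' Run the TDT across units with gating and FDR correction
#'
#' @param agg aggregated counts from \code{\link{aggregate_transmissions}}
#'   (already at the wanted level), or any data.frame with unit, class, b, c.
#' @param method passed to \code{\link{tdt_test}}.
#' @param min_alleles gate: a unit x class is tested only when
#'   b + c >= \code{min_alleles}.
#' @param bh_family "per_class" (default: BH within each variant class
#'   family, mirroring separate LOF and missense testing) or "pooled".
#' @return data.frame (unit, class, b, c, tested, statistic, p, q);
#'   untested rows carry NA statistic/p/q.
#' @export
run_tdt <- function(agg, method = c("binomial", "chi2"), min_alleles = 5,
                    bh_family = c("per_class", "pooled")) {
  method <- match.arg(method)
  bh_family <- match.arg(bh_family)
  res <- agg[order(agg$unit, agg$class), , drop = FALSE]
  res$tested <- (res$b + res$c) >= min_alleles
  res$statistic <- NA_real_; res$p <- NA_real_
  for (i in which(res$tested)) {
    t <- tdt_test(res$b[i], res$c[i], method)
    res$statistic[i] <- t$statistic
    res$p[i] <- t$p
  }
  if (!any(res$tested)) warning("no testable units (all below allele gate)")
  res$q <- NA_real_
  if (bh_family == "pooled") {
    res$q <- bh_adjust(res$p)
  } else {
    for (cl in unique(res$class)) {
      sel <- res$class == cl
      res$q[sel] <- bh_adjust(res$p[sel])
    }
  }
  rownames(res) <- NULL
  res
}

#' Full TDT analysis from pipeline inputs
#'
#' Convenience wrapper: selects parental variants, tallies transmissions,
#' aggregates at the requested level and runs gated, BH-corrected tests.
#'
#' @inheritParams select_parental_variants
#' @inheritParams run_tdt
#' @param level "gene" or "panel".
#' @param panels named list of panels (level "panel"); panels should
#'   already be restricted to expressed genes.
#' @param classes variant classes to test (default both, separately).
#' @return data.frame of results over the requested classes.
#' @export
tdt_analysis <- function(cs, cohort, annotations, expressed, panels = NULL,
                         level = c("gene", "panel"),
                         classes = c("LOF", "missense"),
                         method = c("binomial", "chi2"), min_alleles = 5,
                         min_qual_snv = 300, min_qual_indel = 1000,
                         max_af = 0.001) {
  level <- match.arg(level)
  parental <- select_parental_variants(cs, cohort, annotations, expressed,
                                       min_qual_snv, min_qual_indel, max_af)
  counts <- count_transmissions(parental, cs, cohort)
  counts <- counts[counts$class %in% classes, , drop = FALSE]
  if (!nrow(counts)) {
    warning("no informative parental alleles for TDT")
    return(data.frame(unit = character(), class = character(), b = integer(),
                      c = integer(), tested = logical(), statistic = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE))
  }
  agg <- aggregate_transmissions(counts, level, panels)
  run_tdt(agg, method, min_alleles)
}
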