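#' Simulation configuration
#'
#' Parameters of the synthetic trio + control cohort generator. Defaults
#' describe a cohort with the published structure scaled to a synthetic
#' gene universe: 73 case trios, 1274 unrelated controls, two ancestry
#' blocks, about five HQ de novo variants per proband, and a rare-variant
#' spectrum drawn from a truncated power law on [1e-6, 1e-3].
#'
#' @param n_trios number of case parent-offspring trios.
#' @param n_controls number of unrelated control samples.
#' @param n_genes number of genes in the synthetic universe.
#' @param variants_per_gene mean number of rare inherited variants per gene.
#' @param rare_af_range truncation bounds of the rare allele-frequency
#'   power law (densities proportional to af^-rare_af_alpha).
#' @param rare_af_alpha power-law exponent (1 = log-uniform).
#' @param denovo_rate expected true de novo variants per proband.
#' @param n_bad_denovos number of deliberately sub-threshold de novo
#'   injections per cohort (cycling through low-QUAL SNV, low-QUAL indel,
#'   low parental GQ, and recurrence > 2 failure modes).
#' @param mosaic_rate expected true mosaic variants per proband.
#' @param mosaic_candidates_per_proband expected candidate-table rows per
#'   proband (decoys included), emulating a mosaic caller's output volume.
#' @param distortion_genes named numeric vector: transmission probability
#'   tau per distorted gene (0.5 = no distortion).
#' @param burden_genes named numeric vector: case-enrichment effect
#'   beta1_true per burden gene, on the variant-fraction scale.
#' @param n_subpops number of ancestry blocks.
#' @param fst Balding-Nichols allele-frequency divergence between blocks.
#' @param n_common_snps number of common SNPs emitted for GRM/PCA.
#' @param related_pairs number of duplicated control pairs injected to
#'   exercise relatedness exclusion.
#' @param quality_noise fraction of calls given sub-threshold QUAL/GQ.
#' @param prop_unexpressed fraction of genes below 2 TPM at every
#'   embryonic stage.
#' @param prop_constrained fraction of genes with oe upper bound < 0.35.
#' @param n_panels number of gene panels (a CHD panel, a transcription
#'   factor panel, and GO-style panels).
#' @param mean_depth mean sequencing depth for read-count simulation.
#' @param defect_labels,defect_probs heart-defect label distribution
#'   assigned to probands (defaults follow the cohort's published
#'   frequencies).
#' @param seed integer random seed; identical configs with identical seeds
#'   produce byte-identical fixture bundles.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_trios = 73,
                       n_controls = 1274,
                       n_genes = 100,
                       variants_per_gene = 8,
                       rare_af_range = c(1e-6, 1e-3),
                       rare_af_alpha = 1,
                       denovo_rate = 5,
                       n_bad_denovos = 0,
                       mosaic_rate = 0.08,
                       mosaic_candidates_per_proband = 21,
                       distortion_genes = numeric(),
                       burden_genes = numeric(),
                       n_subpops = 2,
                       fst = 0.05,
                       n_common_snps = 500,
                       related_pairs = 0,
                       quality_noise = 0,
                       prop_unexpressed = 0.2,
                       prop_constrained = 0.2,
                       n_panels = 5,
                       mean_depth = 60,
                       defect_labels = c("TGA", "ASD", "TOF", "VSD", "CoA",
                                         "UVH", "LVOTO", "AVSD", "DORV",
                                         "RVOTO"),
                       defect_probs = c(11, 11, 10, 10, 8, 6, 6, 6, 4, 1) / 73,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_trios", "n_controls", "n_genes", "n_subpops",
              "n_common_snps", "related_pairs", "n_bad_denovos", "n_panels")
  for (f in counts)
    if (cfg[[f]] < 0) stop("configuration error: ", f, " must be >= 0")
  if (any(cfg$distortion_genes <= 0) || any(cfg$distortion_genes >= 1))
    stop("configuration error: tau must lie in (0,1)")
  if (cfg$quality_noise < 0 || cfg$quality_noise > 1)
    stop("configuration error: quality_noise must lie in [0,1]")
  if (cfg$rare_af_range[2] > 0.001)
    stop("configuration error: rare AFs must not exceed 0.001")
  if (abs(sum(cfg$defect_probs) - 1) > 1e-8)
    stop("configuration error: defect_probs must sum to 1")
  class(cfg) <- "sim_config"
  cfg
}

# truncated power-law sampler for rare allele frequencies
.r_powerlaw <- function(n, range, alpha) {
  a <- range[1]; b <- range[2]
  u <- runif(n)
  if (abs(alpha - 1) < 1e-12) {
    exp(log(a) + u * (log(b) - log(a)))
  } else {
    k <- 1 - alpha
    (a^k + u * (b^k - a^k))^(1 / k)
  }
}

.CONSEQ_TERMS <- c(
  missense_variant = 0.45, synonymous_variant = 0.25,
  stop_gained = 0.03, frameshift_variant = 0.04,
  splice_donor_variant = 0.01, splice_acceptor_variant = 0.01,
  stop_lost = 0.005, start_lost = 0.005,
  inframe_deletion = 0.02, inframe_insertion = 0.02,
  intron_variant = 0.12, `3_prime_UTR_variant` = 0.04
)

.sample_consequences <- function(n) {
  sample(names(.CONSEQ_TERMS), n, replace = TRUE, prob = .CONSEQ_TERMS)
}

.variant_class_of <- function(consequence) {
  cls <- rep("SNV", length(consequence))
  cls[consequence == "frameshift_variant"] <- "indel"
  cls[consequence %in% c("inframe_deletion", "inframe_insertion")] <-
    "inframe_indel"
  cls
}

.alleles_for <- function(consequence) {
  # returns list(ref, alt) consistent with the variant class
  bases <- c("A", "C", "G", "T")
  n <- length(consequence)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  cls <- .variant_class_of(consequence)
  for (i in which(cls == "indel")) {
    if (runif(1) < 0.5) alt[i] <- paste0(ref[i], "TG")  # 2bp insertion
    else { ref[i] <- paste0(ref[i], "AG"); alt[i] <- substr(ref[i], 1, 1) }
  }
  for (i in which(cls == "inframe_indel")) {
    if (runif(1) < 0.5) alt[i] <- paste0(ref[i], "TGA")
    else { ref[i] <- paste0(ref[i], "CAT"); alt[i] <- substr(ref[i], 1, 1) }
  }
  list(ref = unname(ref), alt = unname(alt))
}

.draw_qual <- function(is_indel, noise) {
  n <- length(is_indel)
  q <- ifelse(is_indel, runif(n, 1200, 4000), runif(n, 500, 3000))
  bad <- runif(n) < noise
  q[bad] <- ifelse(is_indel[bad], runif(sum(bad), 50, 1000),
                   runif(sum(bad), 50, 300))
  round(q, 2)
}

.draw_ad <- function(gt, depth) {
  # read counts consistent with the genotype at mean coverage `depth`
  d <- matrix(rpois(length(gt), depth), nrow(gt), ncol(gt))
  d[d < 8] <- 8L
  alt <- matrix(0L, nrow(gt), ncol(gt))
  het <- !is.na(gt) & gt == 1L
  hom <- !is.na(gt) & gt == 2L
  alt[het] <- rbinom(sum(het), d[het], 0.5)
  alt[hom] <- d[hom] - rbinom(sum(hom), d[hom], 0.02)
  alt[is.na(gt)] <- NA_integer_
  d[is.na(gt)] <- NA_integer_
  list(ad_ref = d - alt, ad_alt = alt)
}

.mendel_child <- function(fg, mg, tau) {
  # one child alt count per trio given parental alt counts; a heterozygous
  # parent transmits the alt allele with probability tau
  n <- length(fg)
  f_alt <- ifelse(fg == 2L, 1L, ifelse(fg == 1L, rbinom(n, 1L, tau), 0L))
  m_alt <- ifelse(mg == 2L, 1L, ifelse(mg == 1L, rbinom(n, 1L, tau), 0L))
  as.integer(f_alt + m_alt)
}

#' Simulate a trio + control cohort with known truth
#'
#' Generates, under one seed, every input the pipeline consumes: a
#' decomposed call set, variant annotations, per-gene constraint, a
#' gene-by-stage expression table, gene panels, the pedigree, a
#' mosaic-candidate table, and a truth table recording each injected
#' de novo, mosaic, distorted-transmission, burden-effect and related-pair
#' event. Inherited genotypes obey Mendelian transmission with per-gene
#' probability tau (0.5 unless distorted); de novo variants appear in one
#' proband with hom-ref parents; mosaic candidates carry posteriors, VAFs
#' and read depths drawn so that the post-filter windows are exercised on
#' both sides.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{trio_sim} list with elements callset, annotations,
#'   constraint, expression, panels, cohort, mosaic_candidates, truth and
#'   config.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  if (!all(names(cfg$distortion_genes) %in% genes))
    stop("configuration error: distortion_genes outside the gene universe")
  if (!all(names(cfg$burden_genes) %in% genes))
    stop("configuration error: burden_genes outside the gene universe")
  set.seed(cfg$seed)

  n_tr <- cfg$n_trios
  probands <- sprintf("P%04d", seq_len(n_tr))
  fathers <- sprintf("F%04d", seq_len(n_tr))
  mothers <- sprintf("M%04d", seq_len(n_tr))
  controls <- sprintf("C%04d", seq_len(cfg$n_controls))
  samples <- c(probands, fathers, mothers, controls)
  n_smp <- length(samples)

  # ancestry blocks: whole families share a block
  fam_pop <- sample.int(cfg$n_subpops, n_tr, replace = TRUE)
  ctl_pop <- sample.int(cfg$n_subpops, cfg$n_controls, replace = TRUE)
  pop <- c(fam_pop, fam_pop, fam_pop, ctl_pop)

  gene_chrom <- as.character((seq_len(cfg$n_genes) - 1L) %% 22L + 1L)
  gene_base <- 1e6 * ((seq_len(cfg$n_genes) - 1L) %/% 22L) + 10000

  defects <- setNames(
    sample(cfg$defect_labels, n_tr, replace = TRUE, prob = cfg$defect_probs),
    probands)
  cohort <- trio_cohort(
    data.frame(proband = probands, father = fathers, mother = mothers,
               stringsAsFactors = FALSE),
    controls = controls, defects = defects)

  truth <- list()

  ## ---- expression, constraint, panels -----------------------------------
  stages <- c(EMBRYONIC_STAGES, "11wpc", "adult")
  n_unexpr <- round(cfg$prop_unexpressed * cfg$n_genes)
  unexpr <- sample(genes, n_unexpr)
  tpm <- matrix(runif(cfg$n_genes * length(stages), 0, 60),
                cfg$n_genes, length(stages),
                dimnames = list(genes, stages))
  emb <- seq_along(EMBRYONIC_STAGES)
  tpm[unexpr, emb] <- runif(length(unexpr) * length(emb), 0, 1.9)
  keep_expr <- setdiff(genes, unexpr)
  # guarantee expressed genes clear the threshold in >=1 embryonic stage
  hit_stage <- sample(emb, length(keep_expr), replace = TRUE)
  tpm[cbind(match(keep_expr, genes), hit_stage)] <-
    pmax(tpm[cbind(match(keep_expr, genes), hit_stage)], runif(length(keep_expr), 2, 60))
  expression <- data.frame(gene = genes, round(tpm, 3), check.names = FALSE,
                           stringsAsFactors = FALSE)

  n_constr <- round(cfg$prop_constrained * cfg$n_genes)
  lof_constr <- sample(genes, n_constr)
  mis_constr <- sample(genes, n_constr)
  constraint <- data.frame(
    gene = genes,
    lof_oe_upper = round(ifelse(genes %in% lof_constr, runif(cfg$n_genes, 0.03, 0.34),
                                runif(cfg$n_genes, 0.36, 2)), 3),
    mis_oe_upper = round(ifelse(genes %in% mis_constr, runif(cfg$n_genes, 0.03, 0.34),
                                runif(cfg$n_genes, 0.36, 2)), 3),
    stringsAsFactors = FALSE)

  panels <- list()
  if (cfg$n_panels >= 1)
    panels$CHD <- sort(sample(genes, max(1, round(0.3 * cfg$n_genes))))
  if (cfg$n_panels >= 2)
    panels$transcription_factors <-
      sort(sample(genes, max(1, round(0.2 * cfg$n_genes))))
  if (cfg$n_panels >= 3)
    for (k in seq_len(cfg$n_panels - 2))
      panels[[sprintf("GO_panel_%02d", k)]] <-
        sort(sample(genes, max(1, round(runif(1, 0.1, 0.25) * cfg$n_genes))))

  ## ---- rare inherited variants ------------------------------------------
  nv_gene <- rpois(cfg$n_genes, cfg$variants_per_gene)
  n_rare <- sum(nv_gene)
  rare_gene <- rep(genes, nv_gene)
  rare_conseq <- .sample_consequences(n_rare)
  rare_al <- .alleles_for(rare_conseq)
  off <- unlist(lapply(nv_gene, seq_len))
  rare <- data.frame(
    chrom = rep(gene_chrom, nv_gene),
    pos = rep(gene_base, nv_gene) + off * 7L,
    ref = rare_al$ref, alt = rare_al$alt,
    gene = rare_gene, consequence = rare_conseq,
    variant_class = .variant_class_of(rare_conseq),
    gnomad_af = signif(.r_powerlaw(n_rare, cfg$rare_af_range,
                                   cfg$rare_af_alpha), 4),
    cadd = round(pmin(rgamma(n_rare, shape = 2, scale = 6), 50), 1),
    stringsAsFactors = FALSE)

  tau_gene <- setNames(rep(0.5, cfg$n_genes), genes)
  tau_gene[names(cfg$distortion_genes)] <- cfg$distortion_genes

  gt_rare <- matrix(0L, n_rare, n_smp, dimnames = list(NULL, samples))
  if (n_rare > 0) {
    af <- rare$gnomad_af
    for (v in seq_len(n_rare)) {
      fg <- rbinom(n_tr, 2L, af[v])
      mg <- rbinom(n_tr, 2L, af[v])
      cg <- .mendel_child(fg, mg, tau_gene[rare$gene[v]])
      ctl <- rbinom(cfg$n_controls, 2L, af[v])
      gt_rare[v, ] <- c(cg, fg, mg, ctl)
    }
  }

  # burden-effect injection: extra transmitted father-het alleles in cases
  for (g in names(cfg$burden_genes)) {
    b1 <- cfg$burden_genes[[g]]
    vidx <- which(rare$gene == g)
    if (!length(vidx)) next
    q <- min(0.45, 0.05 * b1)
    for (v in vidx) {
      hit <- which(runif(n_tr) < q)
      if (length(hit)) {
        gt_rare[v, n_tr + hit] <- pmax(gt_rare[v, n_tr + hit], 1L)  # father
        gt_rare[v, hit] <- pmax(gt_rare[v, hit], 1L)                # child
      }
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "burden", chrom = rare$chrom[v], pos = rare$pos[v],
        ref = rare$ref[v], alt = rare$alt[v], carrier = g,
        vaf_true = NA_real_, tau = NA_real_, beta1_true = b1,
        hq_expected = NA, fail_mode = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  for (g in names(cfg$distortion_genes)) {
    vidx <- which(rare$gene == g)
    for (v in vidx)
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "distorted", chrom = rare$chrom[v], pos = rare$pos[v],
        ref = rare$ref[v], alt = rare$alt[v], carrier = g,
        vaf_true = NA_real_, tau = cfg$distortion_genes[[g]],
        beta1_true = NA_real_, hq_expected = NA, fail_mode = NA_character_,
        stringsAsFactors = FALSE)
  }

  rare$qual <- .draw_qual(rare$variant_class %in% c("indel", "inframe_indel"),
                          cfg$quality_noise)

  ## ---- de novo injections ------------------------------------------------
  dnv_rows <- list(); dnv_gt <- list(); dnv_meta <- list()
  gene_ctr <- setNames(rep(0L, cfg$n_genes), genes)
  new_dnv_site <- function(gene, conseq) {
    gene_ctr[gene] <<- gene_ctr[gene] + 1L
    gi <- match(gene, genes)
    al <- .alleles_for(conseq)
    data.frame(chrom = gene_chrom[gi],
               pos = gene_base[gi] + 5000L + gene_ctr[gene] * 7L,
               ref = al$ref, alt = al$alt, gene = gene, consequence = conseq,
               variant_class = .variant_class_of(conseq),
               gnomad_af = if (runif(1) < 0.85) 0 else
                 signif(runif(1, 0.002, 0.2), 3),
               cadd = round(pmin(rgamma(1, shape = 2, scale = 8), 50), 1),
               stringsAsFactors = FALSE)
  }
  dnv_conseq_pool <- c(missense_variant = 0.5, synonymous_variant = 0.2,
                       stop_gained = 0.06, frameshift_variant = 0.08,
                       splice_donor_variant = 0.02,
                       inframe_deletion = 0.04, intron_variant = 0.1)
  n_dnv_p <- rpois(n_tr, cfg$denovo_rate)
  for (i in seq_len(n_tr)) {
    for (k in seq_len(n_dnv_p[i])) {
      conseq <- sample(names(dnv_conseq_pool), 1, prob = dnv_conseq_pool)
      site <- new_dnv_site(sample(genes, 1), conseq)
      is_ind <- site$variant_class != "SNV"
      fail <- runif(1) < cfg$quality_noise
      mode <- NA_character_
      if (fail) {
        mode <- sample(c("low_qual", "low_gq"), 1)
        site$qual <- if (mode == "low_qual") {
          if (is_ind) round(runif(1, 50, 1000), 2) else round(runif(1, 50, 300), 2)
        } else if (is_ind) round(runif(1, 1200, 4000), 2) else
          round(runif(1, 500, 3000), 2)
      } else {
        site$qual <- if (is_ind) round(runif(1, 1200, 4000), 2) else
          round(runif(1, 500, 3000), 2)
      }
      g <- rep(0L, n_smp); g[i] <- 1L
      dnv_rows[[length(dnv_rows) + 1L]] <- site
      dnv_gt[[length(dnv_gt) + 1L]] <- g
      dnv_meta[[length(dnv_meta) + 1L]] <-
        list(proband = probands[i], fail_mode = mode,
             hq = !fail, trio = i)
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "denovo", chrom = site$chrom, pos = site$pos, ref = site$ref,
        alt = site$alt, carrier = probands[i], vaf_true = NA_real_,
        tau = NA_real_, beta1_true = NA_real_,
        hq_expected = !fail, fail_mode = mode, stringsAsFactors = FALSE)
    }
  }
  # deliberate sub-threshold injections (all must be rejected by HQ DNV)
  bad_modes <- c("low_qual_snv", "low_qual_indel", "low_gq", "recurrent")
  for (k in seq_len(cfg$n_bad_denovos)) {
    mode <- bad_modes[(k - 1L) %% length(bad_modes) + 1L]
    i <- sample.int(n_tr, 1)
    conseq <- if (mode == "low_qual_indel") "frameshift_variant" else
      "missense_variant"
    site <- new_dnv_site(sample(genes, 1), conseq)
    site$qual <- switch(mode,
      low_qual_snv = round(runif(1, 10, 300), 2),
      low_qual_indel = round(runif(1, 10, 1000), 2),
      round(runif(1, 500, 3000), 2))
    if (mode == "recurrent") {
      carriers <- sample.int(n_tr, min(3L, n_tr))
      g <- rep(0L, n_smp); g[carriers] <- 1L
      carrier_id <- paste(probands[carriers], collapse = ",")
    } else {
      carriers <- i
      g <- rep(0L, n_smp); g[i] <- 1L
      carrier_id <- probands[i]
    }
    dnv_rows[[length(dnv_rows) + 1L]] <- site
    dnv_gt[[length(dnv_gt) + 1L]] <- g
    dnv_meta[[length(dnv_meta) + 1L]] <-
      list(proband = carrier_id, fail_mode = mode, hq = FALSE, trio = carriers)
    truth[[length(truth) + 1L]] <- data.frame(
      kind = "denovo", chrom = site$chrom, pos = site$pos, ref = site$ref,
      alt = site$alt, carrier = carrier_id, vaf_true = NA_real_,
      tau = NA_real_, beta1_true = NA_real_, hq_expected = FALSE,
      fail_mode = mode, stringsAsFactors = FALSE)
  }
  # controls carry private variants at the same per-sample rate as proband
  # de novo injections (every individual has de novo/private variation, it
  # is just unidentifiable without parents); without this the case/control
  # burden comparison would be biased away from the null by construction
  n_cp <- rpois(cfg$n_controls, cfg$denovo_rate)
  for (j in which(n_cp > 0)) {
    for (k in seq_len(n_cp[j])) {
      conseq <- sample(names(dnv_conseq_pool), 1, prob = dnv_conseq_pool)
      site <- new_dnv_site(sample(genes, 1), conseq)
      is_ind <- site$variant_class != "SNV"
      site$qual <- if (is_ind) round(runif(1, 1200, 4000), 2) else
        round(runif(1, 500, 3000), 2)
      g <- rep(0L, n_smp); g[3L * n_tr + j] <- 1L
      dnv_rows[[length(dnv_rows) + 1L]] <- site
      dnv_gt[[length(dnv_gt) + 1L]] <- g
    }
  }
  dnv <- if (length(dnv_rows)) do.call(rbind, dnv_rows) else NULL
  gt_dnv <- if (length(dnv_gt)) do.call(rbind, dnv_gt) else NULL

  ## ---- common SNPs for GRM / PCA ----------------------------------------
  M <- cfg$n_common_snps
  common <- NULL; gt_common <- NULL
  if (M > 0) {
    p_anc <- runif(M, 0.05, 0.95)
    if (cfg$n_subpops > 1 && cfg$fst > 0) {
      a <- p_anc * (1 - cfg$fst) / cfg$fst
      b <- (1 - p_anc) * (1 - cfg$fst) / cfg$fst
      p_pop <- vapply(seq_len(cfg$n_subpops),
                      function(k) rbeta(M, a, b), numeric(M))
      p_pop <- matrix(p_pop, nrow = M)
    } else {
      p_pop <- matrix(p_anc, M, max(1L, cfg$n_subpops))
    }
    p_pop <- pmin(pmax(p_pop, 0.01), 0.99)
    gt_common <- matrix(0L, M, n_smp, dimnames = list(NULL, samples))
    for (v in seq_len(M)) {
      pf <- p_pop[v, fam_pop]
      fg <- rbinom(n_tr, 2L, pf)
      mg <- rbinom(n_tr, 2L, pf)
      cg <- .mendel_child(fg, mg, 0.5)
      ctl <- rbinom(cfg$n_controls, 2L, p_pop[v, ctl_pop])
      gt_common[v, ] <- c(cg, fg, mg, ctl)
    }
    bases <- c("A", "C", "G", "T")
    cref <- sample(bases, M, replace = TRUE)
    calt <- vapply(cref, function(r) sample(setdiff(bases, r), 1L), character(1))
    common <- data.frame(
      chrom = as.character(sample.int(22L, M, replace = TRUE)),
      pos = 5e7 + seq_len(M) * 100L,
      ref = unname(cref), alt = unname(calt), gene = NA_character_,
      consequence = "intergenic_variant", variant_class = "SNV",
      gnomad_af = round(p_anc, 4),
      cadd = round(runif(M, 0, 10), 1),
      qual = round(runif(M, 1500, 4000), 2),
      stringsAsFactors = FALSE)
  }

  ## ---- assemble callset --------------------------------------------------
  site_cols <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                 "variant_class", "gnomad_af", "cadd", "qual")
  all_sites <- rbind(rare[site_cols],
                     if (!is.null(dnv)) dnv[site_cols],
                     if (!is.null(common)) common[site_cols])
  gt <- rbind(gt_rare, gt_dnv, gt_common)
  ord <- order(as.integer(all_sites$chrom), all_sites$pos, all_sites$alt)
  all_sites <- all_sites[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  rownames(all_sites) <- NULL

  # related control pairs: exact genotype duplicates appended as controls
  if (cfg$related_pairs > 0) {
    if (cfg$related_pairs > cfg$n_controls)
      stop("configuration error: more related pairs than controls")
    dup_src <- controls[seq_len(cfg$related_pairs)]
    dup_ids <- sprintf("R%04d", seq_len(cfg$related_pairs))
    gt <- cbind(gt, gt[, dup_src, drop = FALSE])
    colnames(gt) <- c(samples, dup_ids)
    samples <- c(samples, dup_ids)
    cohort <- trio_cohort(cohort$trios, controls = c(controls, dup_ids),
                          defects = defects)
    for (k in seq_len(cfg$related_pairs))
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "related", chrom = NA_character_, pos = NA_integer_,
        ref = NA_character_, alt = NA_character_,
        carrier = paste(dup_src[k], dup_ids[k], sep = ","),
        vaf_true = NA_real_, tau = NA_real_, beta1_true = NA_real_,
        hq_expected = NA, fail_mode = NA_character_, stringsAsFactors = FALSE)
  }

  gq <- matrix(sample(30:99, length(gt), replace = TRUE),
               nrow(gt), ncol(gt), dimnames = dimnames(gt))
  if (cfg$quality_noise > 0) {
    bad <- runif(length(gq)) < cfg$quality_noise * 0.2
    gq[bad] <- sample(0:29, sum(bad), replace = TRUE)
  }
  # parental GQs of true de novo sites stay certifiable; the dedicated
  # low-GQ failure mode sets them below threshold explicitly
  if (length(dnv_meta)) {
    dnv_keys <- variant_key(vapply(dnv_rows, function(s) s$chrom, character(1)),
                            vapply(dnv_rows, function(s) s$pos, numeric(1)),
                            vapply(dnv_rows, function(s) s$ref, character(1)),
                            vapply(dnv_rows, function(s) s$alt, character(1)))
    site_keys <- variant_key(all_sites$chrom, all_sites$pos,
                             all_sites$ref, all_sites$alt)
    for (d in seq_along(dnv_meta)) {
      row <- match(dnv_keys[d], site_keys)
      tr <- dnv_meta[[d]]$trio
      gq[row, fathers[tr]] <- sample(30:99, length(tr), replace = TRUE)
      gq[row, mothers[tr]] <- sample(30:99, length(tr), replace = TRUE)
      if (identical(dnv_meta[[d]]$fail_mode, "low_gq")) {
        lowp <- sample(c("f", "m"), 1)
        if (lowp == "f") gq[row, fathers[tr[1]]] <- sample(0:29, 1)
        else gq[row, mothers[tr[1]]] <- sample(0:29, 1)
      }
    }
  }
  ad <- .draw_ad(gt, cfg$mean_depth)
  cs <- callset(
    data.frame(chrom = all_sites$chrom, pos = all_sites$pos,
               ref = all_sites$ref, alt = all_sites$alt,
               qual = all_sites$qual, stringsAsFactors = FALSE),
    gt, gq, ad$ad_ref, ad$ad_alt, samples = samples)

  annotations <- all_sites[c("chrom", "pos", "ref", "alt", "gene",
                             "consequence", "variant_class", "gnomad_af",
                             "cadd")]
  annotations$key <- variant_key(annotations$chrom, annotations$pos,
                                 annotations$ref, annotations$alt)

  ## ---- mosaic candidate table -------------------------------------------
  mosaic <- .simulate_mosaic_candidates(cfg, genes, gene_chrom, gene_base,
                                        gene_ctr, probands, cs, cohort)
  if (nrow(mosaic$candidates)) {
    annotations <- rbind(annotations, mosaic$annotations)
    truth <- c(truth, mosaic$truth)
  }

  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    kind = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), carrier = character(),
    vaf_true = numeric(), tau = numeric(), beta1_true = numeric(),
    hq_expected = logical(), fail_mode = character(),
    stringsAsFactors = FALSE)
  truth$key <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  truth$key[is.na(truth$chrom)] <- NA_character_
  rownames(truth) <- NULL

  subpops <- setNames(pop, c(probands, fathers, mothers, controls))
  if (cfg$related_pairs > 0) {
    dup_src <- controls[seq_len(cfg$related_pairs)]
    subpops <- c(subpops, setNames(subpops[dup_src],
                                   sprintf("R%04d", seq_len(cfg$related_pairs))))
  }
  structure(
    list(callset = cs, annotations = annotations, constraint = constraint,
         expression = expression, panels = panels, cohort = cohort,
         mosaic_candidates = mosaic$candidates, truth = truth,
         subpops = subpops, config = cfg),
    class = "trio_sim")
}

.simulate_mosaic_candidates <- function(cfg, genes, gene_chrom, gene_base,
                                        gene_ctr, probands, cs, cohort) {
  empty <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), proband = character(), posterior = numeric(),
    vaf = numeric(), father_alt_reads = integer(),
    mother_alt_reads = integer(), stringsAsFactors = FALSE)
  n_tr <- cfg$n_trios
  n_cand <- rpois(n_tr, cfg$mosaic_candidates_per_proband)
  n_true <- rpois(n_tr, min(cfg$mosaic_rate, cfg$mosaic_candidates_per_proband))
  total <- sum(n_cand) + sum(n_true)
  if (total == 0)
    return(list(candidates = empty, annotations = NULL, truth = list()))

  rec <- site_recurrence(cs, cohort)
  recurrent_keys <- cs$sites$key[rec > 2]

  rows <- list(); anns <- list(); truth <- list()
  conseq_pool <- c(missense_variant = 0.45, synonymous_variant = 0.25,
                   stop_gained = 0.05, intron_variant = 0.25)
  mk <- function(i, true_mosaic) {
    gene <- sample(genes, 1)
    gi <- match(gene, genes)
    gene_ctr[gene] <<- gene_ctr[gene] + 1L
    conseq <- if (true_mosaic) "missense_variant" else
      sample(names(conseq_pool), 1, prob = conseq_pool)
    al <- .alleles_for(conseq)
    chrom <- gene_chrom[gi]; pos <- gene_base[gi] + 8000L + gene_ctr[gene] * 7L
    ref <- al$ref; alt <- al$alt
    # a slice of decoys sits on cohort-recurrent germline sites
    if (!true_mosaic && length(recurrent_keys) && runif(1) < 0.05) {
      k <- strsplit(sample(recurrent_keys, 1), ":", fixed = TRUE)[[1]]
      chrom <- k[1]; pos <- as.integer(k[2]); ref <- k[3]; alt <- k[4]
      site_row <- match(variant_key(chrom, pos, ref, alt), cs$sites$key)
      ann_needed <- FALSE
    } else ann_needed <- TRUE
    vaf_true <- if (true_mosaic) runif(1, 0.12, 0.38) else runif(1, 0.01, 0.5)
    depth <- max(12L, rpois(1, cfg$mean_depth))
    alt_reads <- rbinom(1, depth, vaf_true)
    vaf_obs <- round(alt_reads / depth, 4)
    posterior <- if (true_mosaic) round(runif(1, 0.9, 1), 4) else
      round(ifelse(runif(1) < 0.75, runif(1, 0.9, 1), runif(1, 0.3, 0.9)), 4)
    pa <- if (!true_mosaic && runif(1) < 0.2) rpois(2, 4) else rpois(2, 0.3)
    # expected filter outcome, judged on the observed quantities the filter
    # will see (read noise can push a genuine mosaic outside the windows)
    recurrence <- if (ann_needed) 0L else
      sum(cs$gt[site_row, cohort$trios$proband] >= 1L, na.rm = TRUE)
    cls <- as.character(classify_consequence(conseq))
    pass_expected <- posterior >= 0.9 & vaf_obs >= 0.10 & vaf_obs <= 0.40 &
      pa[1] <= 2 & pa[2] <= 2 & cls %in% c("LOF", "missense") &
      recurrence <= 2
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, proband = probands[i],
      posterior = posterior, vaf = vaf_obs,
      father_alt_reads = pa[1], mother_alt_reads = pa[2],
      stringsAsFactors = FALSE)
    if (ann_needed)
      anns[[length(anns) + 1L]] <<- data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
        consequence = conseq, variant_class = .variant_class_of(conseq),
        gnomad_af = if (runif(1) < 0.8) signif(.r_powerlaw(1, cfg$rare_af_range,
                                                           cfg$rare_af_alpha), 4)
                    else round(runif(1, 0.01, 0.4), 3),
        cadd = round(pmin(rgamma(1, shape = 2, scale = 8), 50), 1),
        key = variant_key(chrom, pos, ref, alt), stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      kind = "mosaic", chrom = chrom, pos = pos, ref = ref, alt = alt,
      carrier = probands[i], vaf_true = round(vaf_true, 4), tau = NA_real_,
      beta1_true = NA_real_, hq_expected = pass_expected,
      fail_mode = if (true_mosaic) NA_character_ else "decoy",
      stringsAsFactors = FALSE)
    invisible(NULL)
  }
  for (i in seq_len(n_tr)) {
    for (k in seq_len(n_true[i])) mk(i, TRUE)
    for (k in seq_len(n_cand[i])) mk(i, FALSE)
  }
  cand <- do.call(rbind, rows)
  cand$key <- variant_key(cand$chrom, cand$pos, cand$ref, cand$alt)
  ann <- if (length(anns)) do.call(rbind, anns) else NULL
  if (!is.null(ann)) ann <- ann[!duplicated(ann$key), , drop = FALSE]
  list(candidates = cand, annotations = ann, truth = truth)
}

#' @export
print.trio_sim <- function(x, ...) {
  cat(sprintf(
    "<trio_sim> %d trios, %d controls, %d sites, %d mosaic candidates, %d truth rows\n",
    nrow(x$cohort$trios), length(x$cohort$controls), nrow(x$callset$sites),
    nrow(x$mosaic_candidates), nrow(x$truth)))
  invisible(x)
}

#' Check Mendelian consistency of proband genotypes
#'
#' For every (site, trio) pair with complete genotypes, checks whether the
#' proband's alt-allele count is attainable from the parental genotypes
#' under Mendelian transmission.
#'
#' @param cs a \code{callset}.
#' @param cohort a \code{trio_cohort}.
#' @return logical matrix (sites x trios); NA where any genotype missing.
#' @export
mendelian_consistent <- function(cs, cohort) {
  tr <- cohort$trios
  out <- matrix(NA, nrow(cs$sites), nrow(tr))
  for (i in seq_len(nrow(tr))) {
    fg <- cs$gt[, tr$father[i]]; mg <- cs$gt[, tr$mother[i]]
    pg <- cs$gt[, tr$proband[i]]
    lo <- (fg == 2L) + (mg == 2L)
    hi <- (fg >= 1L) + (mg >= 1L)
    out[, i] <- pg >= lo & pg <= hi
  }
  colnames(out) <- tr$proband
  out
}

#' Write a simulated cohort to disk as a fixture bundle
#'
#' Emits every file the pipeline readers consume: \code{callset.vcf},
#' \code{annotations.tsv}, \code{constraint.tsv}, \code{expression.tsv},
#' \code{pedigree.ped}, \code{mosaic_candidates.tsv}, \code{truth.tsv} and
#' one panel file per panel under \code{panels/}. Identical simulations
#' yield identical file bytes, hence identical checksums.
#'
#' @param sim a \code{trio_sim}.
#' @param directory existing output directory.
#' @return data.frame manifest (path, md5), invisibly returned and also
#'   written to \code{manifest.tsv}.
#' @export
write_fixture_bundle <- function(sim, directory) {
  stopifnot(inherits(sim, "trio_sim"))
  if (!dir.exists(directory))
    stop("output directory does not exist: ", directory)
  p <- function(f) file.path(directory, f)
  write_callset(sim$callset, p("callset.vcf"))
  .write_tsv(sim$annotations[setdiff(names(sim$annotations), "key")],
             p("annotations.tsv"))
  .write_tsv(sim$constraint, p("constraint.tsv"))
  .write_tsv(sim$expression, p("expression.tsv"))
  write_pedigree(sim$cohort, p("pedigree.ped"))
  .write_tsv(sim$mosaic_candidates[setdiff(names(sim$mosaic_candidates), "key")],
             p("mosaic_candidates.tsv"))
  .write_tsv(sim$truth[setdiff(names(sim$truth), "key")], p("truth.tsv"))
  panel_paths <- write_panels(sim$panels, p("panels"))
  files <- c(p(c("callset.vcf", "annotations.tsv", "constraint.tsv",
                 "expression.tsv", "pedigree.ped", "mosaic_candidates.tsv",
                 "truth.tsv")), panel_paths)
  manifest <- data.frame(path = unname(files),
                         md5 = unname(md5sum(unname(files))),
                         stringsAsFactors = FALSE)
  .write_tsv(manifest, p("manifest.tsv"))
  invisible(manifest)
}

#' Simulate unit-level transmission counts
#'
#' Draws transmitted/untransmitted allele tallies for independent test
#' units: each unit has a fixed number of informative parental heterozygous
#' alleles, each transmitted with probability tau. Used to study the
#' calibration and power of \code{\link{tdt_test}}.
#'
#' @param n_units number of units.
#' @param alleles_per_unit informative alleles b + c per unit.
#' @param tau transmission probability (0.5 under the null).
#' @return data.frame (unit, b, c).
#' @export
simulate_transmission_units <- function(n_units, alleles_per_unit, tau = 0.5) {
  b <- rbinom(n_units, alleles_per_unit, tau)
  data.frame(unit = sprintf("U%05d", seq_len(n_units)), b = b,
             c = alleles_per_unit - b, stringsAsFactors = FALSE)
}

#' Simulate case/control data from the burden logistic model
#'
#' Draws per-sample variant fractions and a structure covariate, then
#' assigns case status from the logistic model
#' logit(p) = beta0 + beta1 * VF + beta2 * PC1. With
#' \code{confounding > 0}, the variant fraction is shifted along PC1 so
#' that the structure axis confounds the VF-status relationship.
#'
#' @param n number of samples.
#' @param beta0,beta1,beta2 model coefficients.
#' @param confounding shift of mean VF per unit of PC1.
#' @return data.frame (status, vf, pc1).
#' @export
simulate_burden_dataset <- function(n, beta0 = -1, beta1 = 1, beta2 = 0.5,
                                    confounding = 0) {
  pc1 <- rnorm(n)
  vf <- rgamma(n, shape = 1.5, scale = 1) + confounding * (pc1 - min(pc1))
  eta <- beta0 + beta1 * vf + beta2 * pc1
  data.frame(status = rbinom(n, 1L, stats::plogis(eta)), vf = vf, pc1 = pc1)
}
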