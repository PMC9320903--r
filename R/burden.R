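#' Genotype matrix of a callset
#'
#' @param cs a \code{callset}.
#' @param samples sample subset (default all), order preserved.
#' @return samples x variants integer matrix of alt-allele counts.
#' @export
genotype_matrix <- function(cs, samples = cs$samples) {
  t(cs$gt[, samples, drop = FALSE])
}

#' Genetic relationship matrix from common variants
#'
#' Standardized (Yang-style) estimator: entry (j, k) is the mean over
#' variants of (g_j - 2p)(g_k - 2p) / (2p(1 - p)) with p the sample allele
#' frequency. Missing genotypes are mean-imputed per variant; monomorphic
#' variants are skipped. The self-relationship diagonal arises from the
#' same formula with j = k.
#'
#' @param G samples x variants genotype matrix (0/1/2, NA allowed).
#' @return symmetric samples x samples matrix with attribute
#'   \code{n_variants} (number of variants used).
#' @export
compute_grm <- function(G) {
  stopifnot(nrow(G) >= 2)
  G <- as.matrix(G)
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) stop("all variants monomorphic; cannot compute GRM")
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(G, 2L, 2 * p)
  X[is.na(X)] <- 0  # mean imputation after centering
  X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), "/")
  M <- ncol(X)
  grm <- tcrossprod(X) / M
  attr(grm, "n_variants") <- M
  grm
}

#' Exclude related samples by the minimum-diagonal rule
#'
#' The relatedness threshold is the smallest self-relationship value on the
#' GRM diagonal; every sample with at least one off-diagonal relationship
#' value above that threshold is excluded (both members of an offending
#' pair).
#'
#' @param grm matrix from \code{\link{compute_grm}} (row/col names = ids).
#' @return character vector of excluded sample ids (possibly empty).
#' @export
exclude_related <- function(grm) {
  d <- diag(grm)
  t <- min(d)
  off <- grm
  diag(off) <- -Inf
  hit <- apply(off, 1L, max) > t
  rownames(grm)[hit]
}

#' Leading principal component of the genotype matrix
#'
#' Variants are standardized to mean 0, variance 1 (missing values
#' mean-imputed); PC1 is the projection of samples on the leading principal
#' axis. The sign is fixed so that the largest-magnitude variant loading is
#' positive, making scores deterministic.
#'
#' @param G samples x variants genotype matrix of common variants.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param missing_max maximum per-variant missingness (default 0.1).
#' @return named numeric vector of PC1 scores, one per sample.
#' @export
compute_pc1 <- function(G, maf_min = 0.05, missing_max = 0.1) {
  G <- as.matrix(G)
  p <- colMeans(G, na.rm = TRUE) / 2
  miss <- colMeans(is.na(G))
  keep <- !is.na(p) & pmin(p, 1 - p) >= maf_min & miss <= missing_max
  if (!any(keep)) stop("no variants pass the MAF/missingness filters")
  X <- G[, keep, drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE)
  X <- sweep(X, 2L, mu)
  X[is.na(X)] <- 0
  s <- apply(X, 2L, stats::sd)
  ok <- s > 0
  X <- sweep(X[, ok, drop = FALSE], 2L, s[ok], "/")
  sv <- svd(X, nu = 1L, nv = 1L)
  scores <- sv$u[, 1L] * sv$d[1L]
  load <- sv$v[, 1L]
  if (load[which.max(abs(load))] < 0) scores <- -scores
  setNames(scores, rownames(G))
}

#' Select variants for the burden association test
#'
#' Retains LOF and missense variants with gnomAD AF <= \code{max_af} (NA
#' treated as 0), combined study-cohort alternate allele frequency <=
#' \code{max_cohort_af} (an in-house artifact guard), and a gene expressed
#' in the embryonic heart.
#'
#' @param cs a \code{callset}.
#' @param annotations annotation table with a \code{key} column.
#' @param expressed character vector of expressed genes.
#' @param samples analysis samples (cases and controls after relatedness
#'   exclusion); cohort frequency is computed over these.
#' @param max_af gnomAD AF cutoff (default 0.001).
#' @param max_cohort_af combined cohort allele-frequency cutoff (0.01).
#' @return data.frame (site, key, gene, class, cadd, cohort_af).
#' @export
select_at_variants <- function(cs, annotations, expressed, samples,
                               max_af = 0.001, max_cohort_af = 0.01) {
  aidx <- match(cs$sites$key, annotations$key)
  cls <- rep(NA_character_, nrow(cs$sites))
  ok <- !is.na(aidx)
  cls[ok] <- as.character(classify_consequence(annotations$consequence[aidx[ok]]))
  af <- annotations$gnomad_af[aidx]
  af[is.na(af)] <- 0
  gene <- annotations$gene[aidx]
  sub <- cs$gt[, samples, drop = FALSE]
  an <- rowSums(!is.na(sub)) * 2L
  cohort_af <- ifelse(an > 0, rowSums(sub, na.rm = TRUE) / an, 0)
  sel <- ok & cls %in% c("LOF", "missense") & af <= max_af &
    cohort_af <= max_cohort_af & !is.na(gene) & gene %in% expressed
  data.frame(site = which(sel), key = cs$sites$key[sel], gene = gene[sel],
             class = cls[sel], cadd = annotations$cadd[aidx][sel],
             cohort_af = cohort_af[sel], stringsAsFactors = FALSE)
}

#' CADD-weighted variant fraction
#'
#' Per-sample burden score over a set of selected variants:
#' VF = sum over variants of VAC * (CADD / 10), where VAC is the sample's
#' alternate allele count. Variants with missing CADD contribute with a
#' configurable default weight (0) and a warning.
#'
#' @param cs a \code{callset}.
#' @param selected rows of \code{\link{select_at_variants}} output
#'   belonging to one unit.
#' @param samples samples to score.
#' @param missing_cadd_weight weight substituted for a missing CADD score.
#' @return named numeric vector of VF values (0 for non-carriers).
#' @export
variant_fraction <- function(cs, selected, samples,
                             missing_cadd_weight = 0) {
  if (!nrow(selected)) return(setNames(numeric(length(samples)), samples))
  w <- selected$cadd / 10
  if (anyNA(w)) {
    warning(sum(is.na(w)), " selected variant(s) missing CADD; weight ",
            missing_cadd_weight, " used")
    w[is.na(w)] <- missing_cadd_weight
  }
  sub <- cs$gt[selected$site, samples, drop = FALSE]
  sub[is.na(sub)] <- 0L
  setNames(as.numeric(crossprod(sub, w)), samples)
}

#' Fit the burden logistic model
#'
#' Full model logit(p) = b0 + b1 VF + b2 PC1 against the reduced model
#' without VF, both fitted by maximum likelihood (IRLS, relative
#' log-likelihood tolerance 1e-8, at most 100 iterations). Complete
#' separation and non-convergence are detected and flagged; flagged fits
#' should be reported untested.
#'
#' @param status 0/1 case indicator.
#' @param vf variant-fraction vector.
#' @param pc1 structure covariate.
#' @return list(beta1, se_beta1, loglik_full, loglik_reduced, converged,
#'   separation, fit_full).
#' @export
fit_burden_model <- function(status, vf, pc1) {
  stopifnot(length(unique(stats::na.omit(status))) == 2)
  ctl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  sep <- FALSE
  full <- withCallingHandlers(
    glm(status ~ vf + pc1, family = binomial("logit"), control = ctl),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  red <- suppressWarnings(
    glm(status ~ pc1, family = binomial("logit"), control = ctl))
  co <- summary(full)$coefficients
  list(beta1 = unname(coef(full)["vf"]),
       se_beta1 = if ("vf" %in% rownames(co)) co["vf", "Std. Error"] else NA_real_,
       loglik_full = as.numeric(logLik(full)),
       loglik_reduced = as.numeric(logLik(red)),
       converged = full$converged && red$converged,
       separation = sep,
       fit_full = full)
}

#' Likelihood-ratio test p-value
#'
#' Statistic 2 * (loglik_full - loglik_reduced), clamped at 0, against
#' chi-square with 1 df. A full log-likelihood below the reduced one beyond
#' numerical tolerance indicates a fitting failure and raises an error.
#'
#' @param loglik_full,loglik_reduced log-likelihoods of nested fits.
#' @param tol numerical tolerance for the nesting violation check.
#' @return list(statistic, p).
#' @export
lrt_pvalue <- function(loglik_full, loglik_reduced, tol = 1e-6) {
  if (loglik_full < loglik_reduced - tol)
    stop("full model log-likelihood below reduced model: fitting failure")
  stat <- max(0, 2 * (loglik_full - loglik_reduced))
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Run the burden association test across units
#'
#' For each unit (gene or panel) and variant class, computes per-sample
#' CADD-weighted variant fractions over the selected variants, gates on a
#' minimum total alternate allele count across cases and controls, fits
#' the logistic model with PC1 correction, and applies the likelihood-ratio
#' test with BH correction within each class family.
#'
#' @param cs a \code{callset}.
#' @param selected output of \code{\link{select_at_variants}}.
#' @param status named 0/1 vector over analysis samples (1 = case).
#' @param pc1 named numeric vector over the same samples.
#' @param level "gene" or "panel".
#' @param panels named list of panels (level "panel").
#' @param classes variant classes tested separately.
#' @param min_alleles allele-count gate (default 5).
#' @param bh_family "per_class" or "pooled".
#' @return data.frame (unit, class, n_variants, allele_count, beta1, lrt,
#'   p, q, tested, note), lexicographic unit order.
#' @export
run_at <- function(cs, selected, status, pc1, level = c("gene", "panel"),
                   panels = NULL, classes = c("LOF", "missense"),
                   min_alleles = 5, bh_family = c("per_class", "pooled")) {
  level <- match.arg(level)
  bh_family <- match.arg(bh_family)
  samples <- names(status)
  stopifnot(!is.null(samples), identical(names(pc1), samples))
  units <- if (level == "gene") {
    u <- sort(unique(selected$gene))
    setNames(as.list(u), u)
  } else {
    stopifnot(!is.null(panels))
    panels
  }
  rows <- list()
  for (nm in sort(names(units))) {
    for (cl in classes) {
      sub <- selected[selected$class == cl &
                        selected$gene %in% units[[nm]], , drop = FALSE]
      if (!nrow(sub)) next
      gt <- cs$gt[sub$site, samples, drop = FALSE]
      ac <- sum(gt, na.rm = TRUE)
      row <- data.frame(unit = nm, class = cl, n_variants = nrow(sub),
                        allele_count = ac, beta1 = NA_real_,
                        lrt = NA_real_, p = NA_real_, q = NA_real_,
                        tested = FALSE, note = "", stringsAsFactors = FALSE)
      if (ac >= min_alleles) {
        vf <- variant_fraction(cs, sub, samples)
        if (stats::var(vf) == 0) {
          row$note <- "vf constant; beta1 unidentifiable"
        } else {
          fit <- fit_burden_model(status, vf, pc1)
          if (!fit$converged || fit$separation) {
            row$note <- if (fit$separation) "complete separation" else
              "non-convergence"
          } else {
            lrt <- lrt_pvalue(fit$loglik_full, fit$loglik_reduced)
            row$beta1 <- fit$beta1
            row$lrt <- lrt$statistic
            row$p <- lrt$p
            row$tested <- TRUE
          }
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit = character(), class = character(), n_variants = integer(),
               allele_count = integer(), beta1 = numeric(), lrt = numeric(),
               p = numeric(), q = numeric(), tested = logical(),
               note = character(), stringsAsFactors = FALSE)
  if (!any(res$tested)) warning("no testable units for burden AT")
  if (nrow(res)) {
    if (bh_family == "pooled") res$q <- bh_adjust(res$p)
    else for (cl in unique(res$class)) {
      sel <- res$class == cl
      res$q[sel] <- bh_adjust(res$p[sel])
    }
    res <- res[order(res$unit, res$class), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}
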