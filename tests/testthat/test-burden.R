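test_that("GRM has the expected structure on crafted genotypes", {
  set.seed(1)
  n <- 40; m <- 400
  p <- runif(m, 0.1, 0.9)
  G <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(G) <- sprintf("S%02d", seq_len(n))
  G <- rbind(G, DUP = G[1, ])  # duplicated sample
  grm <- compute_grm(G)
  expect_equal(grm, t(grm))
  # duplicate pair: off-diagonal equals both diagonal entries
  expect_equal(grm["S01", "DUP"], grm["S01", "S01"])
  expect_equal(grm["S01", "DUP"], grm["DUP", "DUP"])
  # independent samples: off-diagonals shrink to the centering bias
  # -1/(n-1) induced by sample allele frequencies (rows sum to ~0)
  off <- grm[2:(n - 1), 2:(n - 1)][upper.tri(matrix(0, n - 2, n - 2))]
  expect_lt(abs(mean(off) + 1 / (n + 1 - 1)), 0.02)
  expect_lt(max(abs(off)), 0.5)
  expect_error(compute_grm(matrix(2L, 5, 3)), "monomorphic")
})

test_that("relatedness exclusion applies the minimum-diagonal rule literally", {
  grm <- diag(c(1.0, 1.0, 0.98))
  grm[1, 2] <- grm[2, 1] <- 0.99  # larger than min self-relationship 0.98
  dimnames(grm) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_setequal(exclude_related(grm), c("A", "B"))
  grm[1, 2] <- grm[2, 1] <- 0.5
  expect_length(exclude_related(grm), 0)
})

test_that("injected related pairs are excluded exactly (truth comparison)", {
  sim <- simulate_cohort(sim_config(
    n_trios = 0, n_controls = 150, n_genes = 5, variants_per_gene = 2,
    denovo_rate = 0, mosaic_candidates_per_proband = 0,
    n_common_snps = 600, related_pairs = 3, seed = 42))
  G <- genotype_matrix(sim$callset, sim$cohort$controls)
  grm <- compute_grm(G)
  excluded <- exclude_related(grm)
  want <- unlist(strsplit(sim$truth$carrier[sim$truth$kind == "related"], ","))
  expect_setequal(excluded, want)
})

test_that("PC1 separates simulated ancestry blocks deterministically", {
  sim <- simulate_cohort(sim_config(
    n_trios = 0, n_controls = 120, n_genes = 5, variants_per_gene = 2,
    denovo_rate = 0, mosaic_candidates_per_proband = 0,
    n_common_snps = 500, n_subpops = 2, fst = 0.2, seed = 9))
  G <- genotype_matrix(sim$callset, sim$cohort$controls)
  pc1 <- compute_pc1(G)
  # point-biserial correlation with the true ancestry labels
  r <- abs(cor(pc1, sim$subpops[sim$cohort$controls]))
  expect_gt(r, 0.9)
  # determinism and equivariance under sample permutation
  expect_identical(pc1, compute_pc1(G))
  perm <- sample(nrow(G))
  expect_equal(compute_pc1(G[perm, ]), pc1[perm])
})

test_that("variant fraction follows VAC * CADD / 10", {
  cs <- make_callset(list(
    list(pos = 1, gt = c(1, 0, 2)),
    list(pos = 2, gt = c(0, 0, 1))))
  sel <- data.frame(site = c(1L, 2L), key = cs$sites$key, gene = "G",
                    class = "missense", cadd = c(30, 10),
                    stringsAsFactors = FALSE)
  vf <- variant_fraction(cs, sel, c("P1", "F1", "M1"))
  # het CADD 30 -> 3.0; hom CADD 30 + het CADD 10 -> 7.0
  expect_equal(unname(vf), c(3, 0, 2 * 3 + 1 * 1))
  # additivity over any partition of the variants
  vf1 <- variant_fraction(cs, sel[1, ], c("P1", "F1", "M1"))
  vf2 <- variant_fraction(cs, sel[2, ], c("P1", "F1", "M1"))
  expect_equal(vf, vf1 + vf2)
  # no variants -> 0; missing CADD -> warning, weight 0
  expect_equal(unname(variant_fraction(cs, sel[0, ], "P1")), 0)
  sel$cadd[2] <- NA
  expect_warning(vf3 <- variant_fraction(cs, sel, c("P1", "F1", "M1")),
                 "missing CADD")
  expect_equal(unname(vf3), c(3, 0, 6))
})

test_that("AT variant selection enforces the cohort-frequency guard", {
  # 3 samples -> 6 alleles; pos 2 carried by all -> cohort af 0.5
  cs <- make_callset(list(
    list(pos = 1, gt = c(1, 0, 0)),
    list(pos = 2, gt = c(1, 1, 1)),
    list(pos = 3, gt = c(0, 1, 0))))
  ann <- make_ann("1", 1:3, "A", "T", gene = c("GENE1", "GENE1", "SILENT"))
  out <- select_at_variants(cs, ann, expressed = "GENE1",
                            samples = c("P1", "F1", "M1"),
                            max_cohort_af = 0.2)
  expect_equal(cs$sites$pos[out$site], 1L)  # pos2 too common, pos3 silent
})

test_that("LRT p-values match chi-square reference values", {
  expect_equal(lrt_pvalue(-10, -10), list(statistic = 0, p = 1))
  r <- lrt_pvalue(-8.0795, -10)  # statistic 3.841
  expect_equal(r$p, 0.05, tolerance = 1e-3)
  r <- lrt_pvalue(-5, -10)       # statistic 10
  expect_equal(r$p, 0.001565402, tolerance = 1e-6)
  expect_error(lrt_pvalue(-11, -10), "fitting failure")
})

test_that("burden model recovers beta1 and is sign-symmetric", {
  set.seed(77)
  d <- simulate_burden_dataset(4000, beta0 = -1, beta1 = 1, beta2 = 0.5)
  fit <- fit_burden_model(d$status, d$vf, d$pc1)
  expect_true(abs(fit$beta1 - 1) < 3 * fit$se_beta1)
  lrt <- lrt_pvalue(fit$loglik_full, fit$loglik_reduced)
  # relabeling cases/controls flips beta1, keeps the statistic
  fit2 <- fit_burden_model(1 - d$status, d$vf, d$pc1)
  expect_equal(fit2$beta1, -fit$beta1, tolerance = 1e-4)
  lrt2 <- lrt_pvalue(fit2$loglik_full, fit2$loglik_reduced)
  expect_equal(lrt2$statistic, lrt$statistic, tolerance = 1e-6)
})

test_that("constant VF and separation are flagged, not tested", {
  cs <- make_callset(list(list(pos = 1, gt = c(1, 1, 1))),
                     samples = c("A", "B", "C"))
  sel <- data.frame(site = 1L, key = cs$sites$key, gene = "G",
                    class = "missense", cadd = 20, stringsAsFactors = FALSE)
  status <- setNames(c(1L, 0L, 0L), c("A", "B", "C"))
  pc1 <- setNames(c(0.1, -0.2, 0.3), c("A", "B", "C"))
  out <- suppressWarnings(
    run_at(cs, sel, status, pc1, level = "gene", min_alleles = 3))
  expect_false(out$tested)
  expect_match(out$note, "unidentifiable")
})

test_that("run_at gates on total allele count and reports effect direction", {
  set.seed(5)
  n <- 200
  samples <- sprintf("S%03d", 1:n)
  status <- setNames(rep(c(1L, 0L), each = n / 2), samples)
  # gene GA enriched in cases; gene GB too few alleles
  gt_a <- ifelse(status == 1, rbinom(n, 1, 0.4), rbinom(n, 1, 0.05))
  gt_b <- c(rep(1L, 4), rep(0L, n - 4))
  cs <- callset(
    data.frame(chrom = "1", pos = c(1L, 2L), ref = "A", alt = "T",
               qual = c(1000, 1000)),
    rbind(as.integer(gt_a), gt_b),
    matrix(60, 2, n), samples = samples)
  sel <- data.frame(site = c(1L, 2L), key = cs$sites$key,
                    gene = c("GA", "GB"), class = "missense",
                    cadd = c(30, 30), stringsAsFactors = FALSE)
  pc1 <- setNames(rnorm(n), samples)
  out <- run_at(cs, sel, status, pc1, level = "gene")
  expect_true(out$tested[out$unit == "GA"])
  expect_gt(out$beta1[out$unit == "GA"], 0)
  expect_lt(out$p[out$unit == "GA"], 0.01)
  expect_false(out$tested[out$unit == "GB"])  # 4 alleles < 5
})
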