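# Handcrafted candidate rows around every filter boundary.
boundary_candidates <- function() {
  base <- list(chrom = "1", ref = "A", alt = "T", proband = "P1",
               posterior = 0.95, vaf = 0.20, father_alt_reads = 0L,
               mother_alt_reads = 0L)
  specs <- list(
    list(pos = 101),                                    # clean pass
    list(pos = 102, vaf = 0.10), list(pos = 103, vaf = 0.40),  # window edges
    list(pos = 104, vaf = 0.05), list(pos = 105, vaf = 0.41),  # outside
    list(pos = 106, posterior = 0.90), list(pos = 107, posterior = 0.899),
    list(pos = 108, father_alt_reads = 2L), list(pos = 109, father_alt_reads = 3L),
    list(pos = 110, mother_alt_reads = 3L))
  do.call(rbind, lapply(specs, function(s) {
    r <- utils::modifyList(base, s)
    data.frame(r, stringsAsFactors = FALSE)
  }))
}

test_that("mosaic filter honours every boundary exactly as specified", {
  mc <- boundary_candidates()
  cs <- make_callset(list(list(pos = 999, gt = c(0, 0, 0))))
  cohort <- tiny_cohort()
  ann <- make_ann("1", mc$pos, "A", "T")  # all missense
  out <- filter_mosaic_candidates(mc, cs, cohort, ann)
  expected <- c(TRUE,        # clean
                TRUE, TRUE,  # VAF window closed at both ends
                FALSE, FALSE,
                TRUE, FALSE, # posterior >= 0.90
                TRUE, FALSE, # parental reads <= 2, per parent
                FALSE)
  expect_equal(out$pass, expected)
  expect_match(out$reason[4], "vaf")
  expect_match(out$reason[7], "posterior")
  expect_match(out$reason[10], "parental")
})

test_that("consequence, recurrence and annotation criteria are enforced", {
  # recurrent site: het in 3 probands
  cs <- make_callset(list(list(pos = 500, gt = c(1, 1, 1))),
                     samples = c("P1", "P2", "P3"))
  cohort <- trio_cohort(data.frame(proband = c("P1", "P2", "P3"),
                                   father = paste0("F", 1:3),
                                   mother = paste0("M", 1:3)))
  mc <- data.frame(
    chrom = "1", pos = c(500, 601, 602, 603), ref = "A", alt = "T",
    proband = "P1", posterior = 0.95, vaf = 0.2,
    father_alt_reads = 0L, mother_alt_reads = 0L, stringsAsFactors = FALSE)
  ann <- make_ann("1", c(500, 601, 602), "A", "T",
                  consequence = c("missense_variant", "synonymous_variant",
                                  "stop_gained"))
  out <- filter_mosaic_candidates(mc, cs, cohort, ann)
  expect_equal(out$recurrence, c(3L, 0L, 0L, 0L))
  expect_equal(out$pass, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$reason[1], "recurrence")
  expect_equal(out$reason[2], "consequence")
  expect_equal(out$reason[4], "unannotated")
})

test_that("filter equals the brute-force intersection of criterion sets", {
  sim <- simulate_cohort(sim_config(
    n_trios = 15, n_controls = 0, n_genes = 20, variants_per_gene = 5,
    denovo_rate = 0, mosaic_rate = 1, mosaic_candidates_per_proband = 15,
    n_common_snps = 0, seed = 17))
  mc <- sim$mosaic_candidates
  out <- filter_mosaic_candidates(mc, sim$callset, sim$cohort,
                                  sim$annotations)
  # independent brute force: per-criterion survivor sets, then intersect
  cls <- as.character(classify_consequence(
    sim$annotations$consequence[match(mc$key, sim$annotations$key)]))
  rec <- cohort_recurrence(mc$key, sim$callset, sim$cohort)
  sets <- list(which(mc$posterior >= 0.90),
               which(mc$vaf >= 0.10 & mc$vaf <= 0.40),
               which(mc$father_alt_reads <= 2 & mc$mother_alt_reads <= 2),
               which(rec <= 2),
               which(!is.na(cls) & cls %in% c("LOF", "missense")))
  brute <- Reduce(intersect, sets)
  expect_equal(which(out$pass), brute)
  expect_gt(length(brute), 0)

  # generator ground truth: candidates inside every window (as observed)
  # survive; everything outside any window is excluded
  tr <- sim$truth[sim$truth$kind == "mosaic", ]
  expect_equal(nrow(tr), nrow(mc))
  expect_equal(out$pass, tr$hq_expected)
})

test_that("relevance evaluation flags expression, damaging, rarity, panels", {
  mc <- data.frame(chrom = "1", pos = c(1, 2, 3), ref = "A", alt = "T",
                   proband = "P1", posterior = 0.95, vaf = 0.2,
                   father_alt_reads = 0L, mother_alt_reads = 0L,
                   key = variant_key("1", c(1, 2, 3), "A", "T"),
                   stringsAsFactors = FALSE)
  # candidate 1: high CADD missense in a missense-tolerant gene -> damaging
  #   via the CADD criterion despite the failing oe criterion
  # candidate 2: common SNP -> rare FALSE
  # candidate 3: silent gene -> expressed FALSE
  ann <- make_ann("1", c(1, 2, 3), "A", "T",
                  gene = c("GENE1", "GENE1", "SILENT"),
                  gnomad_af = c(0, 0.32, 0), cadd = c(28.7, 28.7, 10))
  constraint <- data.frame(gene = c("GENE1", "SILENT"),
                           lof_oe_upper = c(1.5, 0.2),
                           mis_oe_upper = c(1.16, 0.2),
                           stringsAsFactors = FALSE)
  expr <- make_expr()
  panels <- list(CHD = "OTHERGENE", TF = c("GENE1", "X"))
  out <- evaluate_mosaic_relevance(mc, ann, constraint, expr, panels)
  expect_false(out$damaging_oe[1])
  expect_true(out$damaging_cadd[1])
  expect_true(out$damaging[1])
  expect_false(out$rare[2])
  expect_false(out$expressed[3])
  expect_equal(out$panels, c("TF", "TF", ""))
})

test_that("gene absent from constraint leaves oe unknown, CADD still applies", {
  mc <- data.frame(chrom = "1", pos = 1, ref = "A", alt = "T", proband = "P1",
                   posterior = 0.95, vaf = 0.2, father_alt_reads = 0L,
                   mother_alt_reads = 0L,
                   key = variant_key("1", 1, "A", "T"), stringsAsFactors = FALSE)
  ann <- make_ann("1", 1, "A", "T", gene = "GENE1", cadd = 30)
  constraint <- data.frame(gene = "UNRELATED", lof_oe_upper = 0.1,
                           mis_oe_upper = 0.1, stringsAsFactors = FALSE)
  out <- evaluate_mosaic_relevance(mc, ann, constraint, make_expr(),
                                   list())
  expect_true(is.na(out$damaging_oe))
  expect_true(out$damaging_cadd)
  expect_true(out$damaging)
})
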