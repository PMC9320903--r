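test_that("HQ de novo criteria hold at every boundary", {
  base <- list(pg = 1L, fg = 0L, mg = 0L, fq = 30, mq = 45, qual = 301,
               indel = FALSE, rec = 1L)
  run <- function(...) {
    a <- utils::modifyList(base, list(...))
    is_hq_denovo(a$pg, a$fg, a$mg, a$fq, a$mq, a$qual, a$indel, a$rec)
  }
  expect_true(run())                         # all at/inside bounds
  expect_false(run(qual = 300))              # strict > on QUAL
  expect_false(run(indel = TRUE, qual = 999))
  expect_false(run(indel = TRUE, qual = 1000))
  expect_true(run(indel = TRUE, qual = 1001))
  expect_false(run(fq = 29))                 # GQ >= 30 inclusive
  expect_true(run(fq = 30))
  expect_false(run(rec = 3L))
  expect_true(run(rec = 2L))
  expect_false(run(pg = 2L))                 # criterion says heterozygous
  expect_false(run(fg = 1L))
  expect_false(run(fg = NA_integer_))        # cannot certify de novo
  expect_false(run(fq = NA_real_))
})

test_that("HQ inherited criteria mirror the de novo quality gates", {
  base <- list(pg = 1L, fg = 1L, mg = 0L, qual = 500, indel = FALSE, rec = 1L)
  run <- function(...) {
    a <- utils::modifyList(base, list(...))
    is_hq_inherited(a$pg, a$fg, a$mg, a$qual, a$indel, a$rec)
  }
  expect_true(run())
  expect_false(run(fg = 0L))                 # both parents hom-ref: DNV land
  expect_true(run(fg = 0L, mg = 2L))
  expect_false(run(rec = 3L))
  expect_false(run(qual = 300))
  expect_true(run(pg = 2L))                  # hom-alt proband counts
  expect_false(run(fg = NA_integer_, mg = NA_integer_))
  expect_true(run(fg = NA_integer_, mg = 1L))  # one parent missing, one carries
})

test_that("classification is disjoint and respects inframe-indel exclusion", {
  cs <- make_callset(list(
    list(pos = 100, gt = c(1, 0, 0), qual = 500),   # DNV
    list(pos = 200, gt = c(1, 1, 0), qual = 500),   # inherited
    list(pos = 300, gt = c(1, 0, 0), qual = 500),   # inframe indel: dropped
    list(pos = 400, gt = c(1, 0, 0), qual = 100)))  # low qual: neither
  ann <- make_ann("1", c(100, 200, 300, 400), "A", "T",
                  consequence = c("missense_variant", "stop_gained",
                                  "inframe_deletion", "missense_variant"))
  out <- classify_trio_variants(cs, tiny_cohort(), ann)
  expect_equal(nrow(out), 2L)
  expect_equal(out$category[out$pos == 100], "HQ_DNV")
  expect_equal(out$category[out$pos == 200], "HQ_INHERITED")
  # disjointness at any (variant, proband)
  expect_equal(anyDuplicated(paste(out$key, out$proband)), 0L)
})

test_that("retain_rare_damaging keeps rare LOF/missense, NA AF treated as 0", {
  df <- data.frame(
    key = letters[1:5], consequence_class = c("missense", "LOF", "missense",
                                              "other", "missense"),
    gnomad_af = c(0.0009, 0.002, NA, 0, 0.001),
    stringsAsFactors = FALSE)
  out <- retain_rare_damaging(df)
  expect_equal(out$key, c("a", "c", "e"))
  # NA AF equivalent to explicit 0
  df2 <- df; df2$gnomad_af[3] <- 0
  expect_equal(retain_rare_damaging(df2)$key, out$key)
})

test_that("merge_mnv groups adjacent same-proband variants only", {
  df <- data.frame(
    key = sprintf("k%d", 1:5),
    chrom = "1", pos = c(100L, 101L, 103L, 100L, 101L),
    proband = c("P1", "P1", "P1", "P2", "P3"),
    category = "HQ_DNV",
    consequence_class = "missense",
    gnomad_af = c(0.001, 0.0002, 0, 0, 0),
    cadd = c(20, 30, 10, 5, 5),
    stringsAsFactors = FALSE)
  out <- merge_mnv(df)
  p1 <- out[out$proband == "P1", ]
  expect_equal(length(unique(p1$mnv_group[p1$pos %in% c(100, 101)])), 1L)
  expect_false(p1$mnv_group[p1$pos == 103] %in%
                 p1$mnv_group[p1$pos %in% c(100, 101)])
  # adjacent but different probands -> different groups
  expect_false(out$mnv_group[out$proband == "P2"] ==
                 out$mnv_group[out$proband == "P3"])
  # group annotation: max CADD, min AF
  grp <- p1[p1$pos == 100, ]
  expect_equal(grp$group_cadd, 30)
  expect_equal(grp$group_af, 0.0002)
  # grouping never changes the union of sites
  expect_setequal(out$key, df$key)
  expect_equal(sum(table(out$mnv_group)), nrow(df))
})

test_that("relevance thresholds are applied as printed", {
  mk <- function(class, cadd, gene = "GENE1") data.frame(
    key = "k", chrom = "1", pos = 1L, proband = "P1", category = "HQ_DNV",
    consequence_class = class, gnomad_af = 0, cadd = cadd, gene = gene,
    stringsAsFactors = FALSE)
  constraint <- data.frame(gene = c("GENE1", "TIGHT"),
                           lof_oe_upper = c(0.30, 0.30),
                           mis_oe_upper = c(0.5, 0.2), stringsAsFactors = FALSE)
  expr <- make_expr()
  ev <- function(df) evaluate_variant_relevance(df, constraint, expr, list())
  expect_true(ev(mk("LOF", 10))$damaging)        # lof oe 0.30 < 0.35
  expect_true(ev(mk("missense", 25.0))$damaging) # CADD >= 25 inclusive
  expect_false(ev(mk("missense", 24.9))$damaging)
  expect_true(ev(mk("missense", 5, gene = "TIGHT"))$damaging)  # mis oe
})

test_that("per-proband report reproduces the descriptive statistics rules", {
  # three probands with counts {2, 8, 18}: median 8; empty proband P4
  cohort <- trio_cohort(data.frame(
    proband = paste0("P", 1:4), father = paste0("F", 1:4),
    mother = paste0("M", 1:4)))
  rows <- do.call(rbind, lapply(seq_len(28), function(i) data.frame(
    key = paste0("k", i), chrom = "1", pos = i * 10L, ref = "A", alt = "T",
    proband = rep(c("P1", "P2", "P3"), c(2, 8, 18))[i],
    category = "HQ_DNV", consequence_class = "missense", gnomad_af = 0,
    cadd = 20, gene = "GENE1", stringsAsFactors = FALSE)))
  empty_ann <- evaluate_variant_relevance(
    rows[0, ], data.frame(gene = character(), lof_oe_upper = numeric(),
                          mis_oe_upper = numeric()), make_expr(), list())
  rep <- per_proband_report(rows, empty_ann, cohort)
  per <- rep$per_proband
  expect_equal(per$hq_dnv, c(2L, 8L, 18L, 0L))
  s <- rep$summary[rep$summary$count == "hq_dnv", ]
  expect_equal(s$median, 5)  # median of {0, 2, 8, 18}
  expect_equal(s$mean, 28 / 4)
  expect_equal(s$sd, sd(c(2, 8, 18, 0)))
  # cohort mean rule: total / n_probands at printed precision
  expect_equal(cohort_mean(355, 73), 4.86)
  expect_equal(cohort_mean(28, 4), 7)
})

test_that("synthetic recovery: HQ DNV classification matches the truth table", {
  sim <- simulate_cohort(sim_config(
    n_trios = 25, n_controls = 0, n_genes = 30, variants_per_gene = 4,
    denovo_rate = 3, n_bad_denovos = 8, quality_noise = 0,
    mosaic_candidates_per_proband = 0, n_common_snps = 0, seed = 12))
  out <- classify_trio_variants(sim$callset, sim$cohort, sim$annotations)
  dnv <- out[out$category == "HQ_DNV", ]
  tr <- sim$truth[sim$truth$kind == "denovo", ]
  # inframe-indel de novo injections are excluded upstream by design
  cls <- classify_consequence(
    sim$annotations$consequence[match(tr$key, sim$annotations$key)])
  want <- tr[tr$hq_expected & cls != "inframe_indel", ]
  got <- paste(dnv$key, dnv$proband)
  expect_setequal(got, paste(want$key, want$carrier))
  # every deliberately sub-threshold injection rejected
  bad <- tr[!tr$hq_expected, ]
  expect_false(any(dnv$key %in% bad$key))
})
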