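test_that("transmission counting matches allele-level enumeration", {
  # enumerate every parental configuration with at least one het parent
  cases <- list(
    list(f = 1L, m = 0L, child = 1L, b = 1L, c = 0L),
    list(f = 1L, m = 0L, child = 0L, b = 0L, c = 1L),
    list(f = 0L, m = 1L, child = 1L, b = 1L, c = 0L),
    list(f = 1L, m = 1L, child = 1L, b = 1L, c = 1L),
    list(f = 1L, m = 1L, child = 2L, b = 2L, c = 0L),
    list(f = 1L, m = 1L, child = 0L, b = 0L, c = 2L),
    list(f = 1L, m = 2L, child = 2L, b = 1L, c = 0L),
    list(f = 1L, m = 2L, child = 1L, b = 1L, c = 0L))
  for (cc in cases) {
    cs <- make_callset(list(list(pos = 100, gt = c(cc$child, cc$f, cc$m))))
    ann <- make_ann("1", 100, "A", "T")
    parental <- select_parental_variants(cs, tiny_cohort(), ann,
                                         expressed = "GENE1")
    out <- count_transmissions(parental, cs, tiny_cohort())
    expect_equal(out$b, cc$b, info = paste(unlist(cc), collapse = "/"))
    expect_equal(out$c, cc$c, info = paste(unlist(cc), collapse = "/"))
  }
  # missing child genotype: allele uninformative
  cs <- make_callset(list(list(pos = 100, gt = c(NA, 1, 0))))
  parental <- select_parental_variants(cs, tiny_cohort(),
                                       make_ann("1", 100, "A", "T"),
                                       expressed = "GENE1")
  expect_equal(nrow(count_transmissions(parental, cs, tiny_cohort())), 0L)
})

test_that("parental variant selection applies every criterion", {
  rows <- list(
    list(pos = 1, gt = c(0, 1, 0), qual = 400),   # in: het father
    list(pos = 2, gt = c(0, 2, 0), qual = 400),   # out: hom-alt parent
    list(pos = 3, gt = c(0, 1, 0), qual = 250),   # out: QUAL
    list(pos = 4, gt = c(0, 1, 0), qual = 400),   # out: af
    list(pos = 5, gt = c(0, 1, 0), qual = 400),   # out: inframe indel
    list(pos = 6, gt = c(0, 1, 0), qual = 400),   # out: unexpressed gene
    list(pos = 7, gt = c(0, 0, 1), qual = 400))   # in: het mother, LOF
  cs <- make_callset(rows)
  ann <- make_ann("1", 1:7, "A", "T",
                  gene = c(rep("GENE1", 5), "SILENT", "GENE1"),
                  consequence = c("missense_variant", "missense_variant",
                                  "missense_variant", "missense_variant",
                                  "inframe_insertion", "missense_variant",
                                  "stop_gained"),
                  gnomad_af = c(0, 0, 0, 0.002, 0, 0, 0))
  out <- select_parental_variants(cs, tiny_cohort(), ann,
                                  expressed = "GENE1")
  expect_equal(sort(unique(cs$sites$pos[out$site])), c(1L, 7L))
  expect_equal(out$class[order(out$site)], c("missense", "LOF"))
})

test_that("tdt_test reproduces frozen reference values", {
  r <- tdt_test(5, 5, "chi2")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  r <- tdt_test(10, 0, "chi2")
  expect_equal(r$statistic, 10)
  expect_equal(r$p, 0.001565402, tolerance = 1e-6)
  r <- tdt_test(5, 0, "binomial")
  expect_equal(r$p, 0.0625)     # 2 * 0.5^5 by direct enumeration
  r <- tdt_test(0, 5, "binomial")
  expect_equal(r$p, 0.0625)
  expect_equal(tdt_test(4, 4, "binomial")$p, 1)
  expect_error(tdt_test(0, 0), "gate")
})

test_that("panel counts add over disjoint member genes", {
  cs <- make_callset(list(
    list(pos = 1, gt = c(1, 1, 0)),
    list(pos = 2, gt = c(0, 1, 0)),
    list(pos = 3, gt = c(1, 0, 1))))
  ann <- make_ann("1", 1:3, "A", "T", gene = c("GA", "GB", "GC"))
  parental <- select_parental_variants(cs, tiny_cohort(), ann,
                                       expressed = c("GA", "GB", "GC"))
  counts <- count_transmissions(parental, cs, tiny_cohort())
  genes <- aggregate_transmissions(counts, "gene")
  panels <- aggregate_transmissions(counts, "panel",
                                    panels = list(P_AB = c("GA", "GB"),
                                                  P_C = "GC",
                                                  P_ALL = c("GA", "GB", "GC")))
  get <- function(df, u) c(sum(df$b[df$unit == u]), sum(df$c[df$unit == u]))
  expect_equal(get(panels, "P_AB"), get(genes, "GA") + get(genes, "GB"))
  expect_equal(get(panels, "P_C"), get(genes, "GC"))
  expect_equal(get(panels, "P_ALL"),
               get(genes, "GA") + get(genes, "GB") + get(genes, "GC"))
})

test_that("run_tdt gates at 5 alleles and corrects within class families", {
  agg <- data.frame(
    unit = c("g1", "g2", "g3", "g4"),
    class = c("missense", "missense", "missense", "LOF"),
    b = c(9, 8, 4, 12), c = c(0, 1, 0, 0), stringsAsFactors = FALSE)
  out <- run_tdt(agg, method = "binomial")
  expect_false(out$tested[out$unit == "g3"])  # b + c = 4 < 5
  expect_true(is.na(out$p[out$unit == "g3"]))
  # single testable unit in the LOF family: q = p
  expect_equal(out$q[out$unit == "g4"], out$p[out$unit == "g4"])
  # missense family BH over the two tested units
  ms <- out[out$unit %in% c("g1", "g2"), ]
  expect_equal(ms$q, bh_adjust(ms$p))
})

test_that("type-I error and power behave as expected over simulated units", {
  set.seed(101)
  # null: exact binomial test is conservative at alpha = 0.05
  null_units <- simulate_transmission_units(800, 12, tau = 0.5)
  p_null <- mapply(function(b, c) tdt_test(b, c, "binomial")$p,
                   null_units$b, null_units$c)
  expect_lte(mean(p_null < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 800))
  # power increases with tau at fixed allele count
  power <- vapply(c(0.6, 0.7, 0.8), function(tau) {
    u <- simulate_transmission_units(400, 50, tau = tau)
    p <- mapply(function(b, c) tdt_test(b, c, "binomial")$p, u$b, u$c)
    mean(p < 0.05)
  }, numeric(1))
  expect_true(all(diff(power) > 0))
})
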