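# Shared fixture builders: everything is generated in code at test time.

# Write a small VCF from raw header/body lines and return its path.
write_test_vcf <- function(body, samples = c("P1", "F1", "M1"),
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

# One-trio cohort over samples P1/F1/M1 (+ optional controls).
tiny_cohort <- function(controls = character()) {
  trio_cohort(data.frame(proband = "P1", father = "F1", mother = "M1"),
              controls = controls)
}

# Minimal annotation table for handcrafted variants.
make_ann <- function(chrom, pos, ref, alt, gene = "GENE1",
                     consequence = "missense_variant",
                     variant_class = "SNV", gnomad_af = 0, cadd = 20) {
  ann <- data.frame(chrom = as.character(chrom), pos = pos, ref = ref,
                    alt = alt, gene = gene, consequence = consequence,
                    variant_class = variant_class, gnomad_af = gnomad_af,
                    cadd = cadd, stringsAsFactors = FALSE)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann
}

# Expression table: one embryonic-expressed and one silent gene by default.
make_expr <- function(genes = c("GENE1", "SILENT"),
                      embryonic_tpm = c(10, 0)) {
  stages <- c("4wpc", "5wpc", "6wpc", "7wpc", "8wpc", "adult")
  m <- matrix(0, length(genes), length(stages),
              dimnames = list(NULL, stages))
  m[, "6wpc"] <- embryonic_tpm
  m[, "adult"] <- 50
  data.frame(gene = genes, m, check.names = FALSE, stringsAsFactors = FALSE)
}

# In-memory callset for one trio: one row per variant spec list
# list(chrom, pos, ref, alt, qual, gt = c(P, F, M), gq = c(P, F, M))
make_callset <- function(rows, samples = c("P1", "F1", "M1")) {
  sites <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = as.character(r$chrom %||% "1"), pos = r$pos,
               ref = r$ref %||% "A", alt = r$alt %||% "T",
               qual = r$qual %||% 500, stringsAsFactors = FALSE)))
  gt <- do.call(rbind, lapply(rows, function(r) as.integer(r$gt)))
  gq <- do.call(rbind, lapply(rows, function(r)
    as.numeric(r$gq %||% rep(60, length(samples)))))
  colnames(gt) <- samples
  callset(sites, gt, gq, samples = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
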