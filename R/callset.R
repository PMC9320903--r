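#' Multi-sample variant call set
#'
#' In-memory representation of a jointly genotyped call set with one
#' alternate allele per record (multi-allelic sites are decomposed at
#' ingest). Genotypes are stored as alt-allele counts in \{0, 1, 2, NA\};
#' a missing (or half-missing) genotype is NA and forces the genotype
#' quality to NA as well.
#'
#' @param sites data.frame with columns chrom, pos, ref, alt, qual.
#' @param gt integer matrix (sites x samples) of alt-allele counts.
#' @param gq numeric matrix of genotype qualities, NA where gt is NA.
#' @param ad_ref,ad_alt numeric matrices of allele-supporting read counts.
#' @param samples character vector of sample ids (unique).
#' @return an object of class \code{callset}.
#' @export
callset <- function(sites, gt, gq, ad_ref = NULL, ad_alt = NULL,
                    samples = colnames(gt)) {
  sites <- as.data.frame(sites)
  stopifnot(
    all(c("chrom", "pos", "ref", "alt", "qual") %in% names(sites)),
    nrow(sites) == nrow(gt),
    is.null(samples) || !anyDuplicated(samples)
  )
  if (any(sites$pos < 1)) stop("site positions must be >= 1")
  if (any(sites$qual < 0, na.rm = TRUE)) stop("site QUAL must be >= 0")
  mode(gt) <- "integer"
  gq[is.na(gt)] <- NA_real_
  if (is.null(ad_ref)) ad_ref <- matrix(NA_real_, nrow(gt), ncol(gt))
  if (is.null(ad_alt)) ad_alt <- matrix(NA_real_, nrow(gt), ncol(gt))
  if (any(ad_ref < 0, na.rm = TRUE) || any(ad_alt < 0, na.rm = TRUE))
    stop("allele depths must be >= 0")
  dimnames(gt) <- dimnames(gq) <- dimnames(ad_ref) <- dimnames(ad_alt) <-
    list(NULL, samples)
  sites$key <- variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  rownames(sites) <- NULL
  structure(
    list(sites = sites, gt = gt, gq = gq, ad_ref = ad_ref, ad_alt = ad_alt,
         samples = samples),
    class = "callset"
  )
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset> %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' @export
dim.callset <- function(x) c(nrow(x$sites), length(x$samples))

#' Is a site a small indel?
#'
#' A record is an indel when REF and ALT differ in length; otherwise it is
#' treated as an SNV (or MNV substitution of equal length).
#'
#' @param cs a \code{callset}.
#' @return logical vector over sites.
#' @export
is_indel_site <- function(cs) {
  nchar(cs$sites$ref) != nchar(cs$sites$alt)
}

.parse_gt_string <- function(gt, alt_index) {
  # alt-allele count for one decomposed alt; any missing allele -> NA
  alleles <- strsplit(gt, "[/|]", perl = TRUE)
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(a == "." | a == "")) return(NA_integer_)
    sum(a == as.character(alt_index))
  }, integer(1))
}

#' Read a multi-sample VCF into a callset
#'
#' Parses a VCF v4.2+ file with FORMAT GT:GQ:AD via
#' \code{VariantAnnotation::readVcf} and decomposes multi-allelic records
#' into one record per alternate allele. Each decomposed record carries the
#' original site QUAL; a sample's alt count for allele k is the number of k
#' alleles in its genotype (other alt alleles count towards neither ref nor
#' this alt). Half-missing genotypes (e.g. "0/.") are treated as missing.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return a \code{callset}; sample order as in the VCF.
#' @export
read_callset <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  # check sample ids before handing over to the parser (duplicate columns
  # are a configuration error, not a parse error)
  head_lines <- readLines(path, n = 500L)
  chrom_line <- grep("^#CHROM\t", head_lines, value = TRUE)
  if (length(chrom_line)) {
    ids <- strsplit(chrom_line[1], "\t", fixed = TRUE)[[1]][-(1:9)]
    if (anyDuplicated(ids))
      stop("configuration error: duplicated sample ids in ", path)
  }
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  samples <- colnames(vcf)
  if (anyDuplicated(samples))
    stop("configuration error: duplicated sample ids in ", path)

  g <- VariantAnnotation::geno(vcf)
  gt_raw <- g$GT
  gq_raw <- if ("GQ" %in% names(g)) g$GQ else
    matrix(NA_real_, nrow(gt_raw), ncol(gt_raw))
  ad_raw <- if ("AD" %in% names(g)) g$AD else NULL

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  qual <- VariantAnnotation::qual(vcf)
  n_alt <- lengths(alt_list)
  alt_chr <- as.character(unlist(alt_list))

  # decomposition: one output row per (record, alt allele)
  rec_idx <- rep(seq_along(n_alt), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len))
  n_out <- length(rec_idx)
  n_smp <- length(samples)

  gt <- matrix(NA_integer_, n_out, n_smp)
  gq <- matrix(NA_real_, n_out, n_smp)
  ad_ref <- matrix(NA_real_, n_out, n_smp)
  ad_alt <- matrix(NA_real_, n_out, n_smp)
  # genotype strings come from a small vocabulary: parse each unique string
  # once per alt index and index into the lookup
  gt_vocab <- unique(as.vector(gt_raw))
  max_alt <- max(alt_idx)
  lut <- vapply(seq_len(max_alt),
                function(k) .parse_gt_string(gt_vocab, k),
                integer(length(gt_vocab)))
  lut <- matrix(lut, nrow = length(gt_vocab))
  gt_code <- matrix(match(gt_raw, gt_vocab), nrow(gt_raw), ncol(gt_raw))
  for (i in seq_len(n_out)) {
    r <- rec_idx[i]
    gt[i, ] <- lut[gt_code[r, ], alt_idx[i]]
    gq[i, ] <- ifelse(is.na(gt[i, ]), NA_real_, as.numeric(gq_raw[r, ]))
    if (!is.null(ad_raw)) {
      k <- alt_idx[i] + 1L
      ad_ref[i, ] <- vapply(ad_raw[r, ], function(a)
        if (length(a) >= k) as.numeric(a[1L]) else NA_real_, numeric(1))
      ad_alt[i, ] <- vapply(ad_raw[r, ], function(a)
        if (length(a) >= k) as.numeric(a[k]) else NA_real_, numeric(1))
    }
  }

  sites <- data.frame(
    chrom = chrom[rec_idx], pos = pos[rec_idx], ref = ref[rec_idx],
    alt = alt_chr, qual = as.numeric(qual)[rec_idx],
    stringsAsFactors = FALSE
  )
  callset(sites, gt, gq, ad_ref, ad_alt, samples = samples)
}

#' Write a callset to a VCF file
#'
#' Emits a minimal VCF v4.2 with FORMAT GT:GQ:AD, one alt per record
#' (the internal decomposed representation). Re-reading the file with
#' \code{\link{read_callset}} round-trips genotypes, QUALs and GQs.
#'
#' @param cs a \code{callset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_callset <- function(cs, path) {
  s <- cs$sites
  gt_str <- matrix("./.", nrow(cs$gt), ncol(cs$gt))
  gt_str[!is.na(cs$gt) & cs$gt == 0L] <- "0/0"
  gt_str[!is.na(cs$gt) & cs$gt == 1L] <- "0/1"
  gt_str[!is.na(cs$gt) & cs$gt == 2L] <- "1/1"
  gq_str <- ifelse(is.na(cs$gq), ".", format(cs$gq, trim = TRUE,
                                             scientific = FALSE))
  ad_str <- ifelse(is.na(cs$ad_ref) | is.na(cs$ad_alt), ".,.",
                   paste0(format(cs$ad_ref, trim = TRUE, scientific = FALSE),
                          ",",
                          format(cs$ad_alt, trim = TRUE, scientific = FALSE)))
  field <- matrix(paste(gt_str, gq_str, ad_str, sep = ":"),
                  nrow(cs$gt), ncol(cs$gt))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cs$samples), collapse = "\t")
  )
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt,
                ifelse(is.na(s$qual), ".",
                       format(s$qual, trim = TRUE, scientific = FALSE)),
                ".", ".", "GT:GQ:AD",
                apply(field, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Recurrence of a variant among case probands
#'
#' Number of probands in the case cohort carrying at least one alternate
#' allele at a variant, the quantity gated at "observed only once or twice"
#' by the HQ variant filters. A variant absent from the call set has
#' recurrence 0.
#'
#' @param key variant key(s) as produced by \code{\link{variant_key}}.
#' @param cs a \code{callset}.
#' @param cohort a \code{\link{trio_cohort}}.
#' @return integer vector of proband carrier counts, one per key.
#' @export
cohort_recurrence <- function(key, cs, cohort) {
  probands <- intersect(cohort$trios$proband, cs$samples)
  idx <- match(key, cs$sites$key)
  out <- integer(length(key))
  hit <- !is.na(idx)
  if (any(hit)) {
    sub <- cs$gt[idx[hit], probands, drop = FALSE]
    out[hit] <- as.integer(rowSums(sub >= 1L, na.rm = TRUE))
  }
  out
}

#' Recurrence for every site in a callset
#' @inheritParams cohort_recurrence
#' @return integer vector aligned with \code{cs$sites}.
#' @export
site_recurrence <- function(cs, cohort) {
  probands <- intersect(cohort$trios$proband, cs$samples)
  as.integer(rowSums(cs$gt[, probands, drop = FALSE] >= 1L, na.rm = TRUE))
}
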