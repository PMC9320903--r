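#' Read a variant annotation table
#'
#' Tab-separated, one header line, columns: chrom, pos, ref, alt, gene,
#' consequence, variant_class (SNV | indel | inframe_indel), gnomad_af,
#' cadd. One row per decomposed variant. Missing gnomAD AF (variant absent
#' from the database) may be encoded as NA or left empty and is treated as
#' 0 downstream; the parsed values are validated to lie in [0, 1] and CADD
#' to be non-negative.
#'
#' @param path path to the table.
#' @return data.frame with an added \code{key} column.
#' @export
read_annotations <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
            "variant_class", "gnomad_af", "cadd")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (any(ann$gnomad_af < 0 | ann$gnomad_af > 1, na.rm = TRUE))
    stop("gnomad_af outside [0,1]")
  if (any(ann$cadd < 0, na.rm = TRUE)) stop("cadd must be >= 0")
  ann$chrom <- as.character(ann$chrom)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann
}

#' Read a per-gene constraint table
#'
#' Tab-separated with columns gene, lof_oe_upper, mis_oe_upper: the upper
#' bounds of the observed/expected confidence intervals for LOF and
#' missense variation. One row per gene.
#'
#' @param path path to the table.
#' @return data.frame.
#' @export
read_constraint <- function(path) {
  con <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "lof_oe_upper", "mis_oe_upper")
  if (!all(need %in% names(con)))
    stop("constraint table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(con$gene)) stop("constraint table: one record per gene")
  if (any(con$lof_oe_upper < 0 | con$mis_oe_upper < 0, na.rm = TRUE))
    stop("oe upper bounds must be >= 0")
  con
}

#' Read a gene-by-stage expression table
#'
#' Tab-separated, first column \code{gene}, remaining columns developmental
#' stages (TPM values >= 0). Stage labels are free strings; the embryonic
#' window is selected by name downstream.
#'
#' @param path path to the table.
#' @return data.frame with rownames set to gene symbols.
#' @export
read_expression <- function(path) {
  ex <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(ex)[1] != "gene") stop("expression table: first column must be 'gene'")
  if (anyDuplicated(ex$gene)) stop("expression table: one row per gene")
  if (any(as.matrix(ex[-1]) < 0, na.rm = TRUE)) stop("TPM must be >= 0")
  ex
}

#' Read a mosaic-candidate table
#'
#' Tab-separated emulation of a mosaic caller's candidate output: columns
#' chrom, pos, ref, alt, proband, posterior, vaf, father_alt_reads,
#' mother_alt_reads.
#'
#' @param path path to the table.
#' @return data.frame with an added \code{key} column.
#' @export
read_mosaic_candidates <- function(path) {
  mc <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "proband", "posterior", "vaf",
            "father_alt_reads", "mother_alt_reads")
  if (!all(need %in% names(mc)))
    stop("mosaic candidate table must have columns: ",
         paste(need, collapse = ", "))
  if (any(mc$posterior < 0 | mc$posterior > 1, na.rm = TRUE))
    stop("posterior outside [0,1]")
  if (any(mc$vaf < 0 | mc$vaf > 1, na.rm = TRUE)) stop("vaf outside [0,1]")
  mc$chrom <- as.character(mc$chrom)
  mc$key <- variant_key(mc$chrom, mc$pos, mc$ref, mc$alt)
  mc
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
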