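#' Consequence classes
#'
#' The four mutually exclusive functional classes used throughout the
#' cascade. LOF groups the six Ensembl consequence terms: stop gained,
#' stop lost, start lost, frameshift variant, splice acceptor variant and
#' splice donor variant.
#'
#' @name consequence_classes
NULL

.LOF_TERMS <- c("stop_gained", "stop_lost", "start_lost",
                "frameshift_variant",
                "splice_acceptor_variant", "splice_donor_variant")
.MISSENSE_TERMS <- "missense_variant"
.INFRAME_TERMS <- c("inframe_insertion", "inframe_deletion")

#' Classify an Ensembl consequence term
#'
#' Maps a consequence term to one of LOF, missense, inframe_indel or other.
#' Matching is case-insensitive and tolerant to spaces vs underscores
#' (VEP emits underscores, printed tables often use spaces); every term
#' falls in exactly one class, unknown terms map to "other".
#'
#' @param consequence character vector of consequence terms.
#' @return factor with levels LOF, missense, inframe_indel, other.
#' @export
#' @examples
#' classify_consequence(c("stop_gained", "missense variant", "synonymous_variant"))
classify_consequence <- function(consequence) {
  stopifnot(is.character(consequence))
  term <- gsub(" ", "_", tolower(trimws(consequence)), fixed = TRUE)
  # splice acceptor/donor sometimes printed without the trailing "variant"
  term[term == "splice_acceptor"] <- "splice_acceptor_variant"
  term[term == "splice_donor"] <- "splice_donor_variant"
  out <- rep("other", length(term))
  out[term %in% .LOF_TERMS] <- "LOF"
  out[term %in% .MISSENSE_TERMS] <- "missense"
  out[term %in% .INFRAME_TERMS] <- "inframe_indel"
  factor(out, levels = c("LOF", "missense", "inframe_indel", "other"))
}
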