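#' Default embryonic window stage labels
#'
#' The developmental stages, four to eight weeks post-conception, within
#' which cardiac expression of at least 2 TPM qualifies a gene as expressed
#' in the embryonic heart.
#' @export
EMBRYONIC_STAGES <- c("4wpc", "5wpc", "6wpc", "7wpc", "8wpc")

#' Embryonic cardiac expression predicate
#'
#' A gene is embryonically expressed when its TPM reaches the threshold
#' (default 2, inclusive) in at least one stage of the embryonic window;
#' stages outside the window are ignored. Genes absent from the table get
#' NA (unknown), which downstream filters treat as an exclusion with
#' reason, distinct from FALSE.
#'
#' @param genes character vector of gene symbols to look up.
#' @param expression expression table from \code{\link{read_expression}}.
#' @param tpm_threshold inclusive TPM threshold (default 2).
#' @param stages stage labels forming the embryonic window.
#' @return named logical vector (NA for unknown genes).
#' @export
is_embryonically_expressed <- function(genes, expression,
                                       tpm_threshold = 2,
                                       stages = EMBRYONIC_STAGES) {
  miss <- setdiff(stages, names(expression))
  if (length(miss))
    stop("expression table lacks embryonic stages: ",
         paste(miss, collapse = ", "))
  m <- as.matrix(expression[, stages, drop = FALSE])
  flag <- apply(m >= tpm_threshold, 1L, any, na.rm = TRUE)
  setNames(flag[match(genes, expression$gene)], genes)
}

#' Genes expressed in the embryonic heart
#' @inheritParams is_embryonically_expressed
#' @return character vector of expressed gene symbols.
#' @export
expressed_genes <- function(expression, tpm_threshold = 2,
                            stages = EMBRYONIC_STAGES) {
  flag <- is_embryonically_expressed(expression$gene, expression,
                                     tpm_threshold, stages)
  names(flag)[!is.na(flag) & flag]
}

#' Restrict a gene panel to embryonically expressed genes
#'
#' Returns the intersection of the panel with the expressed gene set;
#' genes with unknown expression are dropped. Idempotent.
#'
#' @param panel character vector of gene symbols.
#' @inheritParams is_embryonically_expressed
#' @return character vector (subset of \code{panel}, original order).
#' @export
restrict_panel <- function(panel, expression, tpm_threshold = 2,
                           stages = EMBRYONIC_STAGES) {
  panel[panel %in% expressed_genes(expression, tpm_threshold, stages)]
}

#' Load gene panels from a directory
#'
#' One panel per file, one gene symbol per line; the panel name is the file
#' name without extension. Duplicate symbols within a file are deduplicated;
#' an empty file yields an empty panel with a warning.
#'
#' @param directory directory of plain-text gene lists.
#' @param pattern file name pattern (default all files).
#' @return named list of character vectors.
#' @export
load_panels <- function(directory, pattern = NULL) {
  if (!dir.exists(directory)) stop("panel directory not found: ", directory)
  files <- list.files(directory, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  panels <- lapply(files, function(f) {
    g <- readLines(f, warn = FALSE)
    g <- unique(trimws(g))
    g <- g[g != ""]
    if (!length(g)) warning("empty panel file: ", f)
    g
  })
  names(panels) <- sub("\\.[^.]*$", "", basename(files))
  panels
}

#' Write gene panels to a directory
#' @param panels named list of character vectors.
#' @param directory output directory (created if absent).
#' @return file paths, invisibly.
#' @export
write_panels <- function(panels, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(panels), function(nm) {
    p <- file.path(directory, paste0(nm, ".txt"))
    writeLines(panels[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
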