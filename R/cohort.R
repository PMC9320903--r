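#' Trio cohort with case/control labels
#'
#' Holds the pedigree structure of the study: proband/father/mother sample
#' triples, the case and control sample sets, and (optionally) a heart
#' defect label per proband. Every proband is a case; cases and controls
#' are disjoint; members of a trio are distinct samples.
#'
#' @param trios data.frame with columns proband, father, mother.
#' @param controls character vector of unrelated control sample ids.
#' @param defects optional named character vector of defect labels, one per
#'   proband.
#' @return an object of class \code{trio_cohort}.
#' @export
trio_cohort <- function(trios, controls = character(), defects = NULL) {
  trios <- as.data.frame(trios, stringsAsFactors = FALSE)
  stopifnot(all(c("proband", "father", "mother") %in% names(trios)))
  bad <- trios$proband == trios$father | trios$proband == trios$mother |
    trios$father == trios$mother
  if (any(bad)) stop("trio members must be distinct samples")
  cases <- trios$proband
  if (length(intersect(cases, controls)))
    stop("cases and controls overlap: ",
         paste(intersect(cases, controls), collapse = ", "))
  if (!is.null(defects)) {
    stopifnot(all(names(defects) %in% cases))
  }
  structure(
    list(trios = trios, cases = cases, controls = as.character(controls),
         defects = defects),
    class = "trio_cohort"
  )
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("<trio_cohort> %d trios, %d controls\n",
              nrow(x$trios), length(x$controls)))
  invisible(x)
}

#' All parental sample ids of a cohort
#' @param cohort a \code{trio_cohort}.
#' @return character vector (fathers then mothers, trio order).
#' @export
cohort_parents <- function(cohort) {
  c(cohort$trios$father, cohort$trios$mother)
}

#' Read a pedigree file
#'
#' Expects a tab-separated file with one header line and columns
#' \code{family, sample, father, mother, status} (status in
#' \{case, control, parent\}), plus an optional \code{defect} column giving
#' the heart defect label of each case. Parents are identified from the
#' father/mother columns of case rows.
#'
#' @param path path to the pedigree file.
#' @return a \code{\link{trio_cohort}}.
#' @export
read_pedigree <- function(path) {
  ped <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "sample", "father", "mother", "status")
  if (!all(need %in% names(ped)))
    stop("pedigree file must have columns: ", paste(need, collapse = ", "))
  caserows <- ped[ped$status == "case", , drop = FALSE]
  trios <- data.frame(proband = caserows$sample, father = caserows$father,
                      mother = caserows$mother, stringsAsFactors = FALSE)
  defects <- NULL
  if ("defect" %in% names(ped) && nrow(caserows) > 0) {
    defects <- setNames(caserows$defect, caserows$sample)
    defects <- defects[!is.na(defects) & defects != ""]
    if (!length(defects)) defects <- NULL
  }
  trio_cohort(trios,
              controls = ped$sample[ped$status == "control"],
              defects = defects)
}

#' Write a pedigree file
#' @param cohort a \code{trio_cohort}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pedigree <- function(cohort, path) {
  tr <- cohort$trios
  n <- nrow(tr)
  fam <- sprintf("FAM%03d", seq_len(n))
  def <- rep(NA_character_, n)
  if (!is.null(cohort$defects))
    def <- unname(cohort$defects[tr$proband])
  rows <- rbind(
    data.frame(family = fam, sample = tr$proband, father = tr$father,
               mother = tr$mother, status = "case", defect = def,
               stringsAsFactors = FALSE),
    data.frame(family = fam, sample = tr$father, father = ".", mother = ".",
               status = "parent", defect = NA, stringsAsFactors = FALSE),
    data.frame(family = fam, sample = tr$mother, father = ".", mother = ".",
               status = "parent", defect = NA, stringsAsFactors = FALSE),
    if (length(cohort$controls))
      data.frame(family = "CTRL", sample = cohort$controls, father = ".",
                 mother = ".", status = "control", defect = NA,
                 stringsAsFactors = FALSE)
  )
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
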