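#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats setNames
#' @useDynLib GSRegularity, .registration = TRUE
NULL

#' Gene set collection
#'
#' A named collection of gene sets, each a character vector of unique gene
#' symbols, as read from an MSigDB-style GMT file or built by
#' \code{\link{generateCohort}}.
#'
#' @slot sets Named list; each element a list with components \code{name},
#'   \code{description} and \code{genes} (character vector, unique, non-empty).
#' @slot sourceLabel Provenance string (file name or generator tag).
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", sourceLabel = "character"))

setValidity("GeneSetCollection", function(object) {
  msgs <- character()
  nm <- vapply(object@sets, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    msgs <- c(msgs, paste0("duplicate gene set name(s): ",
                           paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (!identical(names(object@sets), unname(nm)))
    msgs <- c(msgs, "list names must equal the sets' own names")
  for (s in object@sets) {
    if (!nzchar(s$name)) msgs <- c(msgs, "empty gene set name")
    if (length(s$genes) == 0L)
      msgs <- c(msgs, paste0("gene set '", s$name, "' is empty"))
    if (anyDuplicated(s$genes))
      msgs <- c(msgs, paste0("gene set '", s$name, "' has duplicate genes"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets A list; each element either a character vector of gene symbols
#'   (the list must then be named) or a list with \code{name},
#'   \code{description}, \code{genes}. Duplicate symbols within one set are
#'   removed, keeping first occurrence.
#' @param sourceLabel Provenance string.
#' @return A \code{GeneSetCollection}.
#' @examples
#' gsc <- GeneSetCollection(list(SET1 = c("TP53", "MYC"), SET2 = c("EGFR", "KRAS")))
#' names(gsc)
#' @export
GeneSetCollection <- function(sets, sourceLabel = NA_character_) {
  norm <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.character(s))
      s <- list(name = names(sets)[i], description = "", genes = s)
    s$genes <- s$genes[!duplicated(s$genes)]
    s
  })
  names(norm) <- vapply(norm, function(s) s$name, character(1))
  new("GeneSetCollection", sets = norm,
      sourceLabel = as.character(sourceLabel))
}

#' Baseline gene-pair ordering templates
#'
#' One template per scorable gene set: for each unordered gene pair (i, j),
#' i < j in the order of \code{genes}, the fraction of control samples with
#' strictly lower expression of gene i than gene j, and the majority
#' orientation ("A" if that fraction exceeds 0.5, otherwise "B").
#'
#' @slot templates Named list; each element a list with \code{set},
#'   \code{genes}, \code{pairI}, \code{pairJ}, \code{fraction},
#'   \code{orientation}.
#' @slot nControls Number of control samples the templates were built from.
#' @slot provenance Free-text identifier of the template batch.
#' @export
setClass("BaselineTemplates",
         representation(templates = "list", nControls = "integer",
                        provenance = "character"))

setValidity("BaselineTemplates", function(object) {
  msgs <- character()
  if (length(object@nControls) != 1L || object@nControls < 1L)
    msgs <- c(msgs, "nControls must be a single positive integer")
  for (tp in object@templates) {
    m <- length(tp$genes)
    np <- m * (m - 1L) / 2L
    if (m < 2L) msgs <- c(msgs, paste0("template '", tp$set, "': fewer than 2 genes"))
    if (length(tp$fraction) != np || length(tp$orientation) != np)
      msgs <- c(msgs, paste0("template '", tp$set, "': pair count mismatch"))
    if (any(tp$fraction < 0 | tp$fraction > 1))
      msgs <- c(msgs, paste0("template '", tp$set, "': fractions outside [0,1]"))
    if (!all((tp$fraction > 0.5) == (tp$orientation == "A")))
      msgs <- c(msgs, paste0("template '", tp$set,
                             "': orientation inconsistent with fraction"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Gene set regularity (GSR) matrix
#'
#' Gene sets x samples matrix of rank-conservation scores in [0, 1],
#' stored as a \code{SummarizedExperiment} (assay \code{"gsr"}; phenotype
#' labels in \code{colData()$group}). 1 means the sample's within-set
#' pairwise expression ordering matches the control-derived template at
#' every pair; 0 means it contradicts it at every pair.
#'
#' @slot skippedSets data.frame with columns \code{set}, \code{reason} for
#'   gene sets that could not be scored (e.g. fewer than 2 genes present).
#' @slot templateProvenance Identifier of the template batch used.
#' @export
setClass("GSRMatrix",
         contains = "SummarizedExperiment",
         representation(skippedSets = "data.frame",
                        templateProvenance = "character"))

setValidity("GSRMatrix", function(object) {
  v <- SummarizedExperiment::assay(object, "gsr")
  if (any(v < 0 | v > 1)) return("GSR values must lie in [0, 1]")
  if (!all(c("set", "reason") %in% colnames(object@skippedSets)))
    return("skippedSets must have columns 'set' and 'reason'")
  TRUE
})
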