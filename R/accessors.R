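#' @describeIn GeneSetCollection-class Number of gene sets.
#' @param x,object A \code{GeneSetCollection}.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class Gene set names.
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' Extract one gene set (a list with name, description, genes)
#' @param x A \code{GeneSetCollection}.
#' @param i Index or set name.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' Subset a collection
#' @param x A \code{GeneSetCollection}.
#' @param i Indices or set names.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
  new("GeneSetCollection", sets = x@sets[i], sourceLabel = x@sourceLabel)
})

#' Gene membership of each set
#'
#' @param x A \code{GeneSetCollection}.
#' @return Named list of character vectors.
#' @export
geneIds <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  lapply(x@sets, function(s) s$genes)
}

#' Sizes of the gene sets in a collection
#' @param x A \code{GeneSetCollection}.
#' @return Named integer vector of set sizes.
#' @export
setSizes <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  vapply(x@sets, function(s) length(s$genes), integer(1))
}

setMethod("show", "GeneSetCollection", function(object) {
  sz <- setSizes(object)
  cat("GeneSetCollection with", length(object), "gene sets",
      if (!is.na(object@sourceLabel)) paste0("[", object@sourceLabel, "]"), "\n")
  if (length(object))
    cat("  set sizes: ", min(sz), "-", max(sz),
        " (median ", stats::median(sz), ")\n", sep = "")
})

#' @describeIn BaselineTemplates-class Number of templates.
#' @param x,object A \code{BaselineTemplates}.
#' @export
setMethod("length", "BaselineTemplates", function(x) length(x@templates))

#' @describeIn BaselineTemplates-class Names of the templated gene sets.
#' @export
setMethod("names", "BaselineTemplates", function(x) names(x@templates))

#' Extract one baseline template
#' @param x A \code{BaselineTemplates}.
#' @param i Index or set name.
#' @export
setMethod("[[", "BaselineTemplates", function(x, i) x@templates[[i]])

#' Number of control samples behind a template batch
#' @param x A \code{BaselineTemplates}.
#' @export
nControls <- function(x) {
  stopifnot(is(x, "BaselineTemplates"))
  x@nControls
}

setMethod("show", "BaselineTemplates", function(object) {
  cat("BaselineTemplates for", length(object), "gene sets, built from",
      object@nControls, "control samples\n")
  if (!is.na(object@provenance) && nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

#' GSR values of a GSRMatrix
#'
#' @param x A \code{GSRMatrix}.
#' @return Numeric matrix (gene sets x samples) of scores in [0, 1].
#' @export
gsrValues <- function(x) {
  stopifnot(is(x, "GSRMatrix"))
  SummarizedExperiment::assay(x, "gsr")
}

#' Gene sets that could not be scored
#'
#' @param x A \code{GSRMatrix}.
#' @return data.frame with columns \code{set} and \code{reason}.
#' @export
skippedSets <- function(x) {
  stopifnot(is(x, "GSRMatrix"))
  x@skippedSets
}

#' Phenotype labels of the scored samples
#'
#' @param x A \code{GSRMatrix} (or any SummarizedExperiment with a
#'   \code{group} column in its colData).
#' @return Named character vector, one label per sample.
#' @export
sampleGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(as.character(cd$group), rownames(cd))
}

setMethod("show", "GSRMatrix", function(object) {
  cat("GSRMatrix:", nrow(object), "gene sets x", ncol(object), "samples\n")
  g <- sampleGroups(object)
  if (!all(is.na(g))) {
    tb <- table(g)
    cat("  groups:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  if (nrow(object@skippedSets))
    cat("  skipped sets:", nrow(object@skippedSets), "\n")
  cat("  mean GSR:", round(mean(SummarizedExperiment::assay(object, "gsr")), 4), "\n")
})
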