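#' Build the baseline gene-pair ordering template for one gene set
#'
#' For every unordered pair of set genes present in the expression matrix,
#' computes the fraction of control samples in which the first gene is
#' expressed strictly below the second, Pr(Ei < Ej | control), and assigns
#' the majority orientation: "A" when that fraction exceeds 0.5, "B"
#' otherwise (ties at exactly 0.5, and expression ties, count as "not
#' less", i.e. "B"). Pairs are enumerated in the canonical order
#' (1,2), (1,3), ..., (m-1, m) over the genes present.
#'
#' @param expr Expression input: \code{SummarizedExperiment} (assay 1) or a
#'   numeric genes-x-samples matrix with dimnames.
#' @param phenotypes Named character vector sample -> group (may be omitted
#'   when \code{expr} carries \code{colData()$group}).
#' @param set A gene set: character vector of symbols, or a list with a
#'   \code{genes} component (as stored in a \code{GeneSetCollection}).
#' @param controlLabel Group label of the baseline phenotype.
#' @param setName Name recorded in the template (defaults to the set's own
#'   name, if any).
#' @return A list template (\code{set}, \code{genes}, \code{pairI},
#'   \code{pairJ}, \code{fraction}, \code{orientation}), or \code{NULL}
#'   when fewer than 2 set genes are present (the set is skipped).
#' @export
buildBaselineTemplate <- function(expr, phenotypes = NULL, set,
                                  controlLabel = "control", setName = NULL) {
  m <- .exprMatrix(expr)
  ph <- .phenoVector(expr, phenotypes)
  if (is.list(set)) {
    if (is.null(setName)) setName <- set$name
    set <- set$genes
  }
  if (is.null(setName)) setName <- NA_character_
  ctrl <- names(ph)[ph == controlLabel]
  ctrl <- intersect(colnames(m), ctrl)
  if (length(ctrl) == 0L) stop("no control samples labelled '", controlLabel, "'")
  genes <- set[set %in% rownames(m)]
  if (length(genes) < 2L) return(NULL)   # skipped: insufficient genes
  X <- m[genes, ctrl, drop = FALSE]
  mu <- length(genes)
  pi <- rep(seq_len(mu - 1L), times = (mu - 1L):1L)
  pj <- unlist(lapply(seq_len(mu - 1L), function(i) (i + 1L):mu))
  fraction <- unname(rowMeans(X[pi, , drop = FALSE] < X[pj, , drop = FALSE]))
  list(set = setName, genes = genes, pairI = pi, pairJ = pj,
       fraction = fraction,
       orientation = ifelse(fraction > 0.5, "A", "B"))
}

#' GSR index of one sample against one template
#'
#' The fraction of the m(m-1)/2 gene pairs whose observed strict-order
#' relation in the sample (encoded "A" if Ei < Ej, else "B") equals the
#' template orientation. 1 = the sample reproduces the control-consensus
#' ordering at every pair; 0 = it contradicts it at every pair. Invariant
#' under any strictly increasing transform of the sample values.
#'
#' @param sampleValues Numeric vector aligned to \code{template$genes}
#'   (names, if present, are checked).
#' @param template A template from \code{\link{buildBaselineTemplate}}.
#' @return The GSR index, a number in [0, 1].
#' @export
gsrIndex <- function(sampleValues, template) {
  if (length(sampleValues) != length(template$genes))
    stop("sample vector length (", length(sampleValues),
         ") does not match template genes (", length(template$genes), ")")
  if (!is.null(names(sampleValues)) &&
      !identical(names(sampleValues), template$genes))
    sampleValues <- sampleValues[template$genes]
  if (anyNA(sampleValues)) stop("missing values in sample vector")
  obsA <- sampleValues[template$pairI] < sampleValues[template$pairJ]
  mean(obsA == (template$orientation == "A"))
}

#' Score a gene-set collection over all samples
#'
#' Builds one baseline template per scorable gene set from the control
#' samples, then scores every sample (controls included) against it.
#'
#' @inheritParams buildBaselineTemplate
#' @param collection A \code{GeneSetCollection}.
#' @param provenance Free-text template batch identifier.
#' @return A \code{\link{GSRMatrix}} (sets x samples); sets with fewer than
#'   2 genes present are recorded in \code{skippedSets()}.
#' @examples
#' sim <- generateCohort(syntheticConfig(nGenes = 60, nSets = 4,
#'   setSizes = c(5, 8), nControl = 6, nPerStage = c(3, 3, 3, 3), seed = 1))
#' gsr <- gsrMatrix(sim$expr, sim$phenotypes, sim$collection)
#' gsr
#' @export
gsrMatrix <- function(expr, phenotypes = NULL, collection,
                      controlLabel = "control", provenance = "in-memory") {
  m <- .exprMatrix(expr)
  ph <- .phenoVector(expr, phenotypes)
  stopifnot(is(collection, "GeneSetCollection"))
  ctrl <- intersect(colnames(m), names(ph)[ph == controlLabel])
  if (length(ctrl) == 0L) stop("no control samples labelled '", controlLabel, "'")
  scored <- list()
  skipped <- list()
  for (nm in names(collection)) {
    tp <- buildBaselineTemplate(m, ph, collection[[nm]],
                                controlLabel = controlLabel, setName = nm)
    if (is.null(tp)) {
      skipped[[nm]] <- "insufficient_genes"
      next
    }
    X <- m[tp$genes, , drop = FALSE]
    obsA <- X[tp$pairI, , drop = FALSE] < X[tp$pairJ, , drop = FALSE]
    scored[[nm]] <- colMeans(obsA == (tp$orientation == "A"))
  }
  if (length(scored) == 0L) stop("no scorable gene sets in the collection")
  values <- do.call(rbind, scored)
  colnames(values) <- colnames(m)
  skdf <- data.frame(set = names(skipped),
                     reason = unlist(skipped, use.names = FALSE),
                     stringsAsFactors = FALSE)
  if (length(skipped) == 0L)
    skdf <- data.frame(set = character(), reason = character())
  .newGSRMatrix(values, phenotypes = ph, provenance = provenance,
                skipped = skdf)
}

#' Build templates for a whole collection
#'
#' @inheritParams gsrMatrix
#' @return A \code{\link{BaselineTemplates}} object (unscorable sets are
#'   silently omitted; see \code{\link{gsrMatrix}} for the skipped-set
#'   record).
#' @export
buildTemplates <- function(expr, phenotypes = NULL, collection,
                           controlLabel = "control", provenance = "in-memory") {
  m <- .exprMatrix(expr)
  ph <- .phenoVector(expr, phenotypes)
  ctrl <- intersect(colnames(m), names(ph)[ph == controlLabel])
  tpl <- list()
  for (nm in names(collection)) {
    tp <- buildBaselineTemplate(m, ph, collection[[nm]],
                                controlLabel = controlLabel, setName = nm)
    if (!is.null(tp)) tpl[[nm]] <- tp
  }
  new("BaselineTemplates", templates = tpl,
      nControls = length(ctrl), provenance = as.character(provenance))
}

#' Score samples against pre-built templates
#'
#' @param expr Expression input (matrix or SummarizedExperiment) containing
#'   every templated gene.
#' @param templates A \code{\link{BaselineTemplates}}.
#' @param phenotypes Optional named group vector attached to the result.
#' @return A \code{\link{GSRMatrix}}.
#' @export
scoreSamples <- function(expr, templates, phenotypes = NULL) {
  m <- .exprMatrix(expr)
  stopifnot(is(templates, "BaselineTemplates"))
  values <- do.call(rbind, lapply(templates@templates, function(tp) {
    X <- m[tp$genes, , drop = FALSE]
    obsA <- X[tp$pairI, , drop = FALSE] < X[tp$pairJ, , drop = FALSE]
    colMeans(obsA == (tp$orientation == "A"))
  }))
  colnames(values) <- colnames(m)
  .newGSRMatrix(values, phenotypes = phenotypes,
                provenance = templates@provenance,
                skipped = data.frame(set = character(), reason = character()))
}

#' Write templates as a pair-level TSV
#'
#' One row per gene pair: set, gene_i, gene_j, fraction, orientation.
#' @param templates A \code{BaselineTemplates}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTemplates <- function(templates, path) {
  rows <- lapply(templates@templates, function(tp)
    data.frame(set = tp$set, gene_i = tp$genes[tp$pairI],
               gene_j = tp$genes[tp$pairJ],
               fraction = tp$fraction, orientation = tp$orientation,
               stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$fraction <- sprintf("%.17g", df$fraction)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read templates written by \code{writeTemplates}
#' @param path Path to the TSV.
#' @param nControls Control count to record (not stored in the TSV).
#' @return A \code{BaselineTemplates}.
#' @export
readTemplates <- function(path, nControls = 1L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  tpl <- lapply(split(df, df$set), function(d) {
    genes <- unique(c(d$gene_i, d$gene_j))
    # reconstruct canonical gene order: gene_i of the first m-1 rows, then
    # the final gene_j
    ord <- c(unique(d$gene_i), setdiff(genes, unique(d$gene_i)))
    idx <- stats::setNames(seq_along(ord), ord)
    list(set = d$set[1], genes = ord,
         pairI = unname(idx[d$gene_i]), pairJ = unname(idx[d$gene_j]),
         fraction = d$fraction,
         orientation = ifelse(d$fraction > 0.5, "A", "B"))
  })
  tpl <- tpl[unique(df$set)]
  new("BaselineTemplates", templates = tpl,
      nControls = as.integer(nControls), provenance = basename(path))
}
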