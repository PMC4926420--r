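#' Cumulative-proportion transform of an expression profile
#'
#' Per-sample monotone rescaling to [0, 1] by ranked cumulative share of the
#' total signal: a gene's value is the proportion of total expression
#' carried by all genes expressed strictly below it, i.e. 1 minus the
#' cumulative proportion of the genes ranked at or above it. The lowest gene
#' maps exactly to 0; 1 is a supremum, not attained. Tied genes share the
#' value of their block's last member. The transform is strictly
#' order-preserving within a sample, which makes GSR indices invariant to
#' it, and puts different platforms on a common scale before merging.
#' Vectors containing negative values (e.g. log-ratio arrays) are shifted by
#' the sample minimum first, since the transform needs non-negative mass.
#'
#' @param x Numeric vector (one sample), or a genes-x-samples matrix /
#'   SummarizedExperiment, transformed column by column.
#' @return Object of the same shape with values in [0, 1).
#' @examples
#' cumulativeProportionTransform(c(4, 3, 2, 1))  # 0.6 0.3 0.1 0.0
#' @export
cumulativeProportionTransform <- function(x) {
  if (is(x, "SummarizedExperiment") || is.matrix(x)) {
    m <- .exprMatrix(x)
    out <- apply(m, 2L, .cpTransform)
    dimnames(out) <- dimnames(m)
    return(out)
  }
  .cpTransform(x)
}

.cpTransform <- function(v) {
  if (anyNA(v)) stop("missing values in expression vector")
  if (min(v) < 0) v <- v - min(v)
  tot <- sum(v)
  if (tot <= 0) stop("zero total expression after shifting; cannot rescale")
  # value = (mass strictly below this gene) / total  == 1 - (mass at or above)
  sv <- sort(v)
  below <- c(0, cumsum(sv))[match(v, sv)]   # match() finds the FIRST tie,
  below / tot                               # so ties share the block minimum
}

#' Merge expression datasets on their common genes
#'
#' Intersects gene symbols across datasets. If the intersection falls below
#' \code{minCommon} (the integration filter: a dataset is discarded when it
#' would leave fewer than 4000 common genes), datasets are dropped greedily
#' - at each step the dataset whose removal maximises the intersection goes
#' first (ties broken by dataset order) - until the threshold is met or one
#' dataset remains.
#'
#' @param datasets Named list of SummarizedExperiments or numeric matrices
#'   (genes x samples).
#' @param minCommon Minimum acceptable number of common genes (default 4000).
#' @return List: \code{matrix} (merged common-gene matrix, columns
#'   concatenated in dataset order), \code{commonGenes}, \code{kept},
#'   \code{dropped} (data.frame id/reason), \code{sourceDataset} (named
#'   vector sample -> dataset id).
#' @export
mergeCommonGenes <- function(datasets, minCommon = 4000L) {
  stopifnot(length(datasets) >= 1L)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  mats <- lapply(datasets, .exprMatrix)
  ids <- names(mats)
  inter <- function(sel) Reduce(intersect, lapply(mats[sel], rownames))
  kept <- ids
  dropped <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  while (length(inter(kept)) < minCommon && length(kept) > 1L) {
    gains <- vapply(kept, function(d)
      length(inter(setdiff(kept, d))), integer(1))
    worst <- kept[which.max(gains)]      # first max wins: dataset order
    dropped <- rbind(dropped, data.frame(
      id = worst,
      reason = sprintf("dropping it raises common genes to %d", max(gains)),
      stringsAsFactors = FALSE))
    kept <- setdiff(kept, worst)
  }
  common <- sort(inter(kept))
  if (length(common) < minCommon)
    stop("common genes (", length(common), ") below minCommon (", minCommon,
         ") even after dropping datasets")
  merged <- do.call(cbind, lapply(mats[kept], function(m)
    m[common, , drop = FALSE]))
  src <- rep(kept, vapply(mats[kept], ncol, integer(1)))
  names(src) <- colnames(merged)
  list(matrix = merged, commonGenes = common, kept = kept,
       dropped = dropped, sourceDataset = src)
}

#' Moderated-t differential expression between two groups
#'
#' Per-gene two-group linear model with empirical-Bayes variance
#' moderation: gene-wise residual variances s_g^2 (df = n1 + n2 - 2) are
#' shrunk toward a prior s0^2 with prior df d0, both estimated by
#' moment-matching the log sample variances against a scaled-F model
#' (limma's fitFDist); the moderated t uses d0 + residual df degrees of
#' freedom. With \code{d0 = 0} forced, the statistic reduces to the
#' ordinary two-sample pooled t.
#'
#' @param x Numeric genes-x-samples matrix (e.g. cumulative-proportion
#'   scale) or SummarizedExperiment.
#' @param phenotypes Named group vector.
#' @param caseLabel,controlLabel Groups to compare (effect = case - control).
#' @param d0 Prior degrees of freedom; \code{NULL} (default) estimates
#'   (d0, s0^2) from the data, 0 disables shrinkage, \code{Inf} shrinks
#'   completely to the prior.
#' @return data.frame (one row per gene, input row order): \code{gene},
#'   \code{effect}, \code{s2}, \code{s2tilde}, \code{t}, \code{p}, \code{q},
#'   \code{rank}; attributes \code{d0} and \code{s02}.
#' @export
moderatedTTest <- function(x, phenotypes = NULL, caseLabel,
                           controlLabel = "control", d0 = NULL) {
  m <- .exprMatrix(x)
  ph <- .phenoVector(x, phenotypes)
  cs <- intersect(colnames(m), names(ph)[ph == caseLabel])
  ct <- intersect(colnames(m), names(ph)[ph == controlLabel])
  if (length(cs) < 2L || length(ct) < 2L)
    stop("both groups need at least 2 samples")
  n1 <- length(cs); n2 <- length(ct)
  m1 <- rowMeans(m[, cs, drop = FALSE])
  m2 <- rowMeans(m[, ct, drop = FALSE])
  ss <- rowSums((m[, cs, drop = FALSE] - m1)^2) +
    rowSums((m[, ct, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  s2 <- ss / df
  if (is.null(d0)) {
    fit <- limma::fitFDist(s2, df1 = df)
    d0 <- fit$df2
    s02 <- fit$scale
  } else {
    s02 <- stats::median(s2)
  }
  s2tilde <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df * s2) / (d0 + df)
  eff <- m1 - m2
  tstat <- eff / sqrt(s2tilde * (1 / n1 + 1 / n2))
  dfTotal <- if (is.infinite(d0)) Inf else d0 + df
  p <- 2 * stats::pt(-abs(tstat), df = dfTotal)
  q <- stats::p.adjust(p, method = "BH")
  ord <- order(p, rownames(m))
  rk <- integer(length(p)); rk[ord] <- seq_along(p)
  out <- data.frame(gene = rownames(m), effect = eff, s2 = s2,
                    s2tilde = s2tilde, t = tstat, p = p, q = q, rank = rk,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}
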