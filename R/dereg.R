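#' Rank gene sets by case-vs-control deregulation
#'
#' Per gene set, tests the difference in GSR indices between one case group
#' and the control group with a two-sided Mann-Whitney U test (exact
#' enumeration when both groups have at most 8 samples and the values are
#' tie-free, otherwise the tie-corrected normal approximation), adjusts the
#' p-values across all sets by the Benjamini-Hochberg step-up procedure, and
#' ranks sets by ascending p (ties broken lexicographically by set name).
#'
#' @param gsr A \code{\link{GSRMatrix}} or numeric sets-x-samples matrix.
#' @param phenotypes Named group vector (may come from the GSRMatrix).
#' @param caseLabel,controlLabel Group labels to compare.
#' @param exactMax Largest group size for which the exact null is enumerated.
#' @return data.frame with columns \code{set}, \code{stage}, \code{p},
#'   \code{q}, \code{rank}, ordered by rank.
#' @export
testDeregulation <- function(gsr, phenotypes = NULL, caseLabel,
                             controlLabel = "control", exactMax = 8L) {
  v <- if (is(gsr, "GSRMatrix")) gsrValues(gsr) else gsr
  ph <- if (is.null(phenotypes) && is(gsr, "GSRMatrix")) sampleGroups(gsr)
        else .phenoVector(gsr, phenotypes)
  cs <- intersect(colnames(v), names(ph)[ph == caseLabel])
  ct <- intersect(colnames(v), names(ph)[ph == controlLabel])
  if (length(cs) < 2L) stop("case group '", caseLabel, "' has fewer than 2 samples")
  if (length(ct) < 2L) stop("control group '", controlLabel, "' has fewer than 2 samples")
  p <- apply(v, 1L, function(row) .mwuP(row[cs], row[ct], exactMax = exactMax))
  q <- stats::p.adjust(p, method = "BH")
  ord <- order(p, rownames(v))
  rk <- integer(length(p))
  rk[ord] <- seq_along(p)
  out <- data.frame(set = rownames(v), stage = caseLabel, p = p, q = q,
                    rank = rk, stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$rank), , drop = FALSE]
}

# two-sided Mann-Whitney p-value; exact for small tie-free groups,
# tie-corrected normal approximation (with continuity correction) otherwise
.mwuP <- function(x, y, exactMax = 8L) {
  if (length(unique(c(x, y))) == 1L) return(1)
  exact <- length(x) <= exactMax && length(y) <= exactMax &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}

#' Top-k set analysis across stage groups
#'
#' Takes the k most deregulated gene sets of each group and counts, for
#' every non-empty subset of groups (every region of the Venn diagram), how
#' many sets fall in exactly that region. Also returns the sorted membership
#' of the all-groups intersection, the "commonly deregulated" list.
#'
#' @param recordsByStage Named list: per group, either a data.frame from
#'   \code{\link{testDeregulation}} or a ranked character vector of set
#'   names.
#' @param k Number of top sets per group.
#' @return List with \code{regionCounts} (named integer vector; region label
#'   = sorted group subset joined by "+"), \code{common} (character vector),
#'   and \code{k}.
#' @export
topKSetAnalysis <- function(recordsByStage, k = 200L) {
  stopifnot(length(recordsByStage) >= 2L, !is.null(names(recordsByStage)))
  tops <- lapply(recordsByStage, function(r) {
    sets <- if (is.data.frame(r)) r$set[order(r$rank)] else as.character(r)
    if (length(sets) < k)
      stop("k = ", k, " exceeds a group's list length (", length(sets), ")")
    sets[seq_len(k)]
  })
  groups <- names(tops)
  universe <- sort(unique(unlist(tops)))
  member <- vapply(tops, function(s) universe %in% s, logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(b) paste(sort(groups[b]), collapse = "+"))
  labels <- unlist(lapply(seq_along(groups), function(n)
    utils::combn(groups, n, function(g) paste(sort(g), collapse = "+"),
                 simplify = TRUE)))
  counts <- stats::setNames(integer(length(labels)), labels)
  tb <- table(sig)
  counts[names(tb)] <- as.integer(tb)
  common <- universe[rowSums(member) == length(groups)]
  list(regionCounts = counts, common = sort(common), k = as.integer(k))
}

#' Progressive-ranking criteria
#'
#' @param alpha Per-stage significance level on the raw Mann-Whitney p.
#' @param maxFinalRank The final-stage rank must be strictly below this.
#' @param minRankDrop Required rank improvement between consecutive stages.
#' @param mode \code{"every"}: the drop must exceed \code{minRankDrop} for
#'   every consecutive stage pair; \code{"some"}: for at least one pair.
#' @return A list of class-free criteria settings.
#' @export
progressiveCriteria <- function(alpha = 0.05, maxFinalRank = 200L,
                                minRankDrop = 15L,
                                mode = c("every", "some")) {
  stopifnot(alpha > 0, alpha < 1, maxFinalRank >= 1, minRankDrop >= 0)
  list(alpha = alpha, maxFinalRank = as.integer(maxFinalRank),
       minRankDrop = as.integer(minRankDrop), mode = match.arg(mode))
}

#' Select gene sets that climb the deregulation ranking across stages
#'
#' A set is selected when (1) its Mann-Whitney p is below \code{alpha} at
#' every stage, (2) its final-stage rank is below \code{maxFinalRank}, and
#' (3) its rank number decreases (moves toward 1) from each stage to the
#' next by more than \code{minRankDrop} (all consecutive pairs by default).
#'
#' @param recordsPerStage List of \code{\link{testDeregulation}} results in
#'   stage order (e.g. I, II, III, IV); all stages must cover the identical
#'   set universe.
#' @param criteria From \code{\link{progressiveCriteria}}.
#' @return data.frame: one row per selected set with its per-stage ranks,
#'   ordered by final-stage rank. Rank columns are named by stage.
#' @export
selectProgressive <- function(recordsPerStage,
                              criteria = progressiveCriteria()) {
  stopifnot(length(recordsPerStage) >= 2L)
  uni <- sort(recordsPerStage[[1]]$set)
  for (i in seq_along(recordsPerStage)) {
    ui <- sort(recordsPerStage[[i]]$set)
    if (!identical(ui, uni)) {
      asym <- c(setdiff(ui, uni), setdiff(uni, ui))
      stop("stage set universes differ; asymmetric sets: ",
           paste(asym, collapse = ", "))
    }
  }
  stages <- vapply(recordsPerStage, function(r) r$stage[1], character(1))
  ranks <- sapply(recordsPerStage, function(r)
    r$rank[match(uni, r$set)])
  ps <- sapply(recordsPerStage, function(r) r$p[match(uni, r$set)])
  drops <- -t(apply(ranks, 1L, diff))
  if (ncol(ranks) == 2L) drops <- matrix(drops, ncol = 1L)
  dropOK <- if (criteria$mode == "every")
    apply(drops > criteria$minRankDrop, 1L, all)
  else
    apply(drops > criteria$minRankDrop, 1L, any)
  keep <- apply(ps < criteria$alpha, 1L, all) &
    ranks[, ncol(ranks)] < criteria$maxFinalRank & dropOK
  out <- data.frame(set = uni, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rk <- as.data.frame(ranks[keep, , drop = FALSE])
  names(rk) <- paste0("rank_", stages)
  out <- cbind(out, rk)
  rownames(out) <- NULL
  out[order(out[[ncol(out)]]), , drop = FALSE]
}
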