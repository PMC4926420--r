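#' Linear soft-margin SVM (dual coordinate descent)
#'
#' Minimises 0.5 ||w||^2 + C * sum hinge(1 - y f(x)) with f(x) = w'x + b,
#' the bias handled as an augmented (regularised) feature. Deterministic:
#' coordinates are visited cyclically, so no RNG is consumed.
#'
#' @param x Numeric matrix, samples in rows.
#' @param y Labels in {-1, +1}.
#' @param C Soft-margin cost (default 1, the common default of linear SVM
#'   implementations).
#' @param maxEpochs,tol Stopping rule on the maximum projected gradient.
#' @return List with \code{w}, \code{b} and a \code{decision} function.
#' @export
linearSVM <- function(x, y, C = 1, maxEpochs = 400L, tol = 1e-6) {
  stopifnot(all(y %in% c(-1, 1)), nrow(x) == length(y))
  X <- cbind(x, bias = 1)
  n <- nrow(X)
  Qii <- rowSums(X^2)
  alpha <- numeric(n)
  w <- numeric(ncol(X))
  for (ep in seq_len(maxEpochs)) {
    maxPG <- 0
    for (i in seq_len(n)) {
      G <- y[i] * sum(w * X[i, ]) - 1
      PG <- G
      if (alpha[i] <= 0) PG <- min(G, 0)
      if (alpha[i] >= C) PG <- max(G, 0)
      maxPG <- max(maxPG, abs(PG))
      if (abs(PG) > 1e-12) {
        a_new <- min(max(alpha[i] - G / Qii[i], 0), C)
        if (a_new != alpha[i]) {
          w <- w + (a_new - alpha[i]) * y[i] * X[i, ]
          alpha[i] <- a_new
        }
      }
    }
    if (maxPG < tol) break
  }
  d <- length(w)
  list(w = unname(w[-d]), b = unname(w[d]),
       decision = function(newx) as.vector(newx %*% w[-d] + w[d]))
}

#' Area under the ROC curve from decision scores
#'
#' Exact rank (Mann-Whitney) formula with midrank tie handling.
#'
#' @param scores Numeric decision values.
#' @param positive Logical vector, TRUE for the positive class.
#' @return AUC in [0, 1].
#' @export
aucFromScores <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated SVM classification of functionome patterns
#'
#' Repeated stratified k-fold cross-validation of a linear soft-margin SVM
#' on GSR features (one feature per gene set; features are already
#' commensurate in [0,1], so no standardisation is applied). Binary mode
#' reports sensitivity, specificity, accuracy (from the cumulative confusion
#' counts over all repeats) and AUC (from the pooled out-of-fold decision
#' scores); multiclass mode uses one-vs-one voting and reports accuracy.
#'
#' @param gsr A \code{\link{GSRMatrix}} or numeric sets-x-samples matrix.
#' @param phenotypes Named group vector (defaults to the GSRMatrix colData).
#' @param labels Class labels to include. With exactly two, the first is the
#'   positive class.
#' @param nFolds Folds per repeat (default 5).
#' @param nRepeats Cross-validation repeats (default 10).
#' @param C Soft-margin cost.
#' @param seed RNG seed fixing the fold assignments.
#' @return List of class \code{"gsrClassificationReport"}: \code{mode},
#'   cumulative \code{confusion}, \code{accuracy}, and in binary mode
#'   \code{sensitivity}, \code{specificity}, \code{auc}; per-repeat values
#'   and their SDs in \code{perRepeat} / \code{sd}.
#' @export
svmCV <- function(gsr, phenotypes = NULL, labels, nFolds = 5L,
                  nRepeats = 10L, C = 1, seed = 1L) {
  v <- if (is(gsr, "GSRMatrix")) gsrValues(gsr) else gsr
  ph <- if (is.null(phenotypes) && is(gsr, "GSRMatrix")) sampleGroups(gsr)
        else .phenoVector(gsr, phenotypes)
  stopifnot(length(labels) >= 2L)
  keep <- sort(intersect(colnames(v), names(ph)[ph %in% labels]))
  y <- factor(ph[keep], levels = labels)   # canonical sample order: metrics
                                           # do not depend on input order
  X <- t(v[, keep, drop = FALSE])
  cnt <- table(y)
  if (any(cnt == 0)) stop("class with zero samples: ",
                          paste(names(cnt)[cnt == 0], collapse = ", "))
  if (any(cnt < nFolds))
    stop("every class needs at least nFolds samples; smallest has ", min(cnt))
  binary <- length(labels) == 2L
  set.seed(seed)
  perRepeat <- list()
  pooledScores <- numeric(0); pooledTruth <- logical(0)
  cum <- matrix(0L, length(labels), length(labels),
                dimnames = list(truth = labels, pred = labels))
  for (rep_ in seq_len(nRepeats)) {
    fold <- integer(length(y))
    for (cl in labels) {     # stratified assignment
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    conf <- matrix(0L, length(labels), length(labels),
                   dimnames = list(truth = labels, pred = labels))
    scores <- numeric(length(y))
    for (f in seq_len(nFolds)) {
      tr <- fold != f; te <- !tr
      if (binary) {
        yy <- ifelse(y[tr] == labels[1], 1, -1)
        fit <- linearSVM(X[tr, , drop = FALSE], yy, C = C)
        sc <- fit$decision(X[te, , drop = FALSE])
        pred <- ifelse(sc > 0, labels[1], labels[2])
        scores[te] <- sc
      } else {
        pred <- .ovoPredict(X[tr, , drop = FALSE], y[tr],
                            X[te, , drop = FALSE], labels, C)
      }
      tab <- table(factor(y[te], levels = labels),
                   factor(pred, levels = labels))
      conf <- conf + as.matrix(tab)
    }
    cum <- cum + conf
    rp <- list(accuracy = sum(diag(conf)) / sum(conf))
    if (binary) {
      tp <- conf[1, 1]; fn <- conf[1, 2]; fp <- conf[2, 1]; tn <- conf[2, 2]
      rp$sensitivity <- tp / (tp + fn)
      rp$specificity <- tn / (tn + fp)
      rp$auc <- aucFromScores(scores, y == labels[1])
      pooledScores <- c(pooledScores, scores)
      pooledTruth <- c(pooledTruth, y == labels[1])
    }
    perRepeat[[rep_]] <- rp
  }
  pr <- do.call(rbind, lapply(perRepeat, as.data.frame))
  out <- list(mode = if (binary) "binary" else "multiclass",
              labels = labels, nFolds = nFolds, nRepeats = nRepeats, C = C,
              confusion = cum,
              accuracy = sum(diag(cum)) / sum(cum),
              perRepeat = pr,
              sd = vapply(pr, stats::sd, numeric(1)))
  if (binary) {
    tp <- cum[1, 1]; fn <- cum[1, 2]; fp <- cum[2, 1]; tn <- cum[2, 2]
    out$sensitivity <- tp / (tp + fn)
    out$specificity <- tn / (tn + fp)
    out$auc <- aucFromScores(pooledScores, pooledTruth)
  }
  class(out) <- "gsrClassificationReport"
  out
}

# one-vs-one voting; ties broken by label order
.ovoPredict <- function(Xtr, ytr, Xte, labels, C) {
  votes <- matrix(0L, nrow(Xte), length(labels), dimnames = list(NULL, labels))
  for (a in seq_len(length(labels) - 1L)) for (b in (a + 1L):length(labels)) {
    sel <- ytr %in% labels[c(a, b)]
    yy <- ifelse(ytr[sel] == labels[a], 1, -1)
    fit <- linearSVM(Xtr[sel, , drop = FALSE], yy, C = C)
    sc <- fit$decision(Xte)
    votes[, a] <- votes[, a] + (sc > 0)
    votes[, b] <- votes[, b] + (sc <= 0)
  }
  labels[apply(votes, 1L, which.max)]
}

#' @export
print.gsrClassificationReport <- function(x, ...) {
  cat("SVM cross-validation (", x$mode, "): ", x$nFolds, "-fold x ",
      x$nRepeats, " repeats, C = ", x$C, "\n", sep = "")
  cat("  accuracy:", round(x$accuracy, 4))
  if (x$mode == "binary")
    cat("  sensitivity:", round(x$sensitivity, 4),
        "  specificity:", round(x$specificity, 4),
        "  AUC:", round(x$auc, 4))
  cat("\n")
  invisible(x)
}

#' Hierarchical clustering of group-mean GSR vectors
#'
#' Averages the GSR index of every gene set within each phenotype group and
#' clusters the group-mean vectors (Euclidean distance, complete linkage).
#'
#' @param gsr A \code{\link{GSRMatrix}} or numeric sets-x-samples matrix.
#' @param phenotypes Named group vector (defaults to the GSRMatrix colData).
#' @return List: \code{leafOrder} (group labels in dendrogram order),
#'   \code{merges} (data.frame of joins with heights, non-decreasing),
#'   \code{hclust} (the underlying stats::hclust object),
#'   \code{groupMeans} (groups x sets matrix).
#' @export
clusterGroupMeans <- function(gsr, phenotypes = NULL) {
  v <- if (is(gsr, "GSRMatrix")) gsrValues(gsr) else gsr
  ph <- if (is.null(phenotypes) && is(gsr, "GSRMatrix")) sampleGroups(gsr)
        else .phenoVector(gsr, phenotypes)
  ph <- ph[intersect(colnames(v), names(ph))]
  groups <- sort(unique(ph))
  if (length(groups) < 2L) stop("need at least 2 groups")
  gm <- do.call(rbind, lapply(groups, function(g)
    rowMeans(v[, names(ph)[ph == g], drop = FALSE])))
  rownames(gm) <- groups
  hc <- stats::hclust(stats::dist(gm), method = "complete")
  lab <- function(ks) vapply(ks, function(k)
    if (k < 0) groups[-k] else paste0("cluster", k), character(1))
  merges <- data.frame(a = lab(hc$merge[, 1]),
                       b = lab(hc$merge[, 2]),
                       height = hc$height, stringsAsFactors = FALSE)
  list(leafOrder = groups[hc$order], merges = merges, hclust = hc,
       groupMeans = gm)
}
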