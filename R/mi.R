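#' k-nearest-neighbour mutual information (Kraskov estimator)
#'
#' Kraskov-Stoegbauer-Grassberger variant 1 with the Chebyshev (max) metric:
#' MI = digamma(k) + digamma(N) - mean(digamma(nx+1) + digamma(ny+1)), in
#' nats, clamped at 0. kNN estimators are undefined under exact ties, so
#' tied values are perturbed by an infinitesimal deterministic, index-scaled
#' jitter before distance computation.
#'
#' @param x,y Numeric vectors of equal length (>= 2k + 2).
#' @param k Neighbour count (default 3).
#' @return MI estimate in nats, >= 0.
#' @examples
#' set.seed(1)
#' x <- rnorm(500); y <- x + rnorm(500, sd = 0.5)
#' knnMI(x, y) > knnMI(x, sample(y))
#' @export
knnMI <- function(x, y, k = 3L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L * k + 2L) stop("vectors too short: need length >= 2k + 2")
  max(0, .ksg1_mi(.breakTies(x), .breakTies(y), as.integer(k)))
}

# deterministic tie-break: add index-scaled epsilon relative to data spread
.breakTies <- function(v) {
  if (!anyDuplicated(v)) return(as.numeric(v))
  sc <- diff(range(v))
  if (sc == 0) sc <- 1
  v + seq_along(v) * sc * 1e-10
}

#' Pairwise mutual-information matrix over gene-set GSR profiles
#'
#' @param gsr A \code{\link{GSRMatrix}} or numeric sets-x-samples matrix;
#'   rows are the variables (gene sets), columns the samples.
#' @param sets Optional character vector restricting the rows used.
#' @param k kNN neighbour count.
#' @return Symmetric numeric matrix of MI estimates (nats, clamped at 0)
#'   with zero diagonal.
#' @export
miMatrix <- function(gsr, sets = NULL, k = 3L) {
  v <- if (is(gsr, "GSRMatrix")) gsrValues(gsr) else gsr
  if (!is.null(sets)) {
    missing <- setdiff(sets, rownames(v))
    if (length(missing))
      stop("set(s) not in the GSR matrix: ", paste(missing, collapse = ", "))
    v <- v[sets, , drop = FALSE]
  }
  p <- nrow(v)
  mi <- matrix(0, p, p, dimnames = list(rownames(v), rownames(v)))
  if (p >= 2L)
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p)
      mi[i, j] <- mi[j, i] <- knnMI(v[i, ], v[j, ], k = k)
  mi
}

#' ARACNE pruning by the data processing inequality
#'
#' Multiplicative model: an edge (i, j) is removed iff some third node z
#' satisfies mi(i,j) < tau * min(mi(i,z), mi(j,z)); all removals are
#' evaluated against the original matrix, not sequentially. Zero-weight
#' edges are dropped.
#'
#' @param mi Symmetric non-negative MI matrix with labelled dimnames.
#' @param tau DPI tolerance in (0, 1]; 1 is the strict multiplicative model,
#'   smaller values prune more aggressively.
#' @return Edge list data.frame with columns \code{from}, \code{to},
#'   \code{weight}, \code{from} < \code{to} lexicographically.
#' @export
aracnePrune <- function(mi, tau = 1.0) {
  if (!isTRUE(all.equal(mi, t(mi)))) stop("MI matrix must be symmetric")
  stopifnot(tau > 0, tau <= 1)
  p <- nrow(mi)
  labels <- rownames(mi)
  if (is.null(labels)) labels <- as.character(seq_len(p))
  keep <- list()
  for (i in seq_len(max(p - 1L, 0L))) for (j in (i + 1L):p) {
    w <- mi[i, j]
    if (w <= 0) next
    others <- setdiff(seq_len(p), c(i, j))
    removed <- length(others) > 0 &&
      any(w < tau * pmin(mi[i, others], mi[j, others]))
    if (!removed) {
      a <- labels[i]; b <- labels[j]
      if (a > b) { tmp <- a; a <- b; b <- tmp }
      keep[[length(keep) + 1L]] <- data.frame(from = a, to = b, weight = w,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(keep) == 0L)
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, keep)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Restrict an edge list to its largest connected component
#'
#' Ties in component size are broken toward the component containing the
#' lexicographically smallest node label.
#'
#' @param edges Edge list data.frame (\code{from}, \code{to}, \code{weight}).
#' @return The sub-edge-list of the winning component (empty input passes
#'   through unchanged).
#' @export
largestComponent <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest label wins
    firstLab <- vapply(best, function(b)
      min(names(comp$membership)[comp$membership == b]), character(1))
    best <- best[order(firstLab)[1L]]
  }
  nodes <- names(comp$membership)[comp$membership == best]
  edges[edges$from %in% nodes & edges$to %in% nodes, , drop = FALSE]
}

#' Build, prune and export an interaction network among gene sets
#'
#' Convenience wrapper: MI matrix over the selected gene sets' GSR profiles,
#' ARACNE/DPI pruning, optional restriction to the largest component, GML
#' export.
#'
#' @inheritParams miMatrix
#' @param tau DPI tolerance.
#' @param largestOnly Keep only the largest connected component.
#' @param gmlPath Optional output path for a GML file.
#' @return The pruned edge list (invisibly returns the same if written).
#' @export
buildNetwork <- function(gsr, sets = NULL, k = 3L, tau = 1.0,
                         largestOnly = FALSE, gmlPath = NULL) {
  mi <- miMatrix(gsr, sets = sets, k = k)
  edges <- aracnePrune(mi, tau = tau)
  if (largestOnly) edges <- largestComponent(edges)
  if (!is.null(gmlPath)) writeGML(edges, gmlPath)
  edges
}
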