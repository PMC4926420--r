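# Independent oracles and tiny fixture builders shared across tests.
# Oracles are deliberately naive (explicit loops, exhaustive enumeration)
# and never reuse the package's vectorised code paths.

# Brute-force GSR: template = per-pair majority over controls, score = pair-
# by-pair match count, all with explicit double loops.
bruteForceGSR <- function(exprMat, pheno, geneSets, controlLabel = "control") {
  ctrl <- names(pheno)[pheno == controlLabel]
  out <- list()
  for (sn in names(geneSets)) {
    genes <- geneSets[[sn]]
    genes <- genes[genes %in% rownames(exprMat)]
    if (length(genes) < 2) next
    m <- length(genes)
    scores <- numeric(ncol(exprMat))
    for (s in seq_len(ncol(exprMat))) {
      match_ <- 0L; total <- 0L
      for (i in 1:(m - 1)) for (j in (i + 1):m) {
        frac <- 0
        for (cc in ctrl)
          frac <- frac + (exprMat[genes[i], cc] < exprMat[genes[j], cc])
        orientA <- (frac / length(ctrl)) > 0.5
        obsA <- exprMat[genes[i], s] < exprMat[genes[j], s]
        match_ <- match_ + (obsA == orientA)
        total <- total + 1L
      }
      scores[s] <- match_ / total
    }
    out[[sn]] <- scores
  }
  res <- do.call(rbind, out)
  colnames(res) <- colnames(exprMat)
  res
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
enumMWU <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  U <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- U(x, y)
  n <- length(pooled)
  dev <- abs(obs - n1 * length(y) / 2)
  combs <- utils::combn(n, n1)
  stat <- apply(combs, 2, function(idx) U(pooled[idx], pooled[-idx]))
  mean(abs(stat - n1 * length(y) / 2) >= dev - 1e-12)
}

# Hand step-up BH: q_i = min over j >= i of p_(j) * m / j.
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# Exhaustive-triple DPI oracle (multiplicative model, original-matrix rule).
bruteForceDPI <- function(mi, tau = 1) {
  p <- nrow(mi)
  keep <- data.frame(from = character(), to = character(), weight = numeric())
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    w <- mi[i, j]
    if (w <= 0) next
    removed <- FALSE
    for (z in seq_len(p)) {
      if (z == i || z == j) next
      if (w < tau * min(mi[i, z], mi[j, z])) removed <- TRUE
    }
    if (!removed) {
      a <- rownames(mi)[i]; b <- rownames(mi)[j]
      keep <- rbind(keep, data.frame(from = min(a, b), to = max(a, b),
                                     weight = w))
    }
  }
  keep[order(keep$from, keep$to), , drop = FALSE]
}

# Brute-force complete-linkage agglomeration returning merge heights.
bruteForceCompleteLinkage <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  d <- as.matrix(stats::dist(x))
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestH <- Inf
    for (a in seq_len(length(clusters) - 1)) for (b in (a + 1):length(clusters)) {
      h <- max(d[clusters[[a]], clusters[[b]]])
      if (h < bestH) { bestH <- h; best <- c(a, b) }
    }
    heights <- c(heights, bestH)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# 1-D two-component Gaussian mixture EM; bimodality = BIC prefers two
# components AND Ashman's D > 2 (standard separation cutoff).
mixtureBimodality <- function(x, maxit = 300) {
  mu <- unname(stats::quantile(x, c(0.25, 0.75)))
  s2 <- rep(stats::var(x) / 2, 2)
  pi1 <- 0.5
  for (it in seq_len(maxit)) {
    d1 <- pi1 * stats::dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- (1 - pi1) * stats::dnorm(x, mu[2], sqrt(s2[2]))
    g <- d1 / (d1 + d2)
    pi1 <- mean(g)
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    s2 <- pmax(c(sum(g * (x - mu[1])^2) / sum(g),
                 sum((1 - g) * (x - mu[2])^2) / sum(1 - g)), 1e-8)
  }
  ll2 <- sum(log(pi1 * stats::dnorm(x, mu[1], sqrt(s2[1])) +
                 (1 - pi1) * stats::dnorm(x, mu[2], sqrt(s2[2]))))
  ll1 <- sum(stats::dnorm(x, mean(x), stats::sd(x), log = TRUE))
  bic2 <- -2 * ll2 + 5 * log(length(x))
  bic1 <- -2 * ll1 + 2 * log(length(x))
  ashmanD <- abs(diff(mu)) / sqrt((s2[1] + s2[2]) / 2)
  list(bimodal = (bic2 < bic1) && (ashmanD > 2), ashmanD = ashmanD,
       bic1 = bic1, bic2 = bic2, mu = mu)
}

# Deterministic toy cohort: genes with a fixed strict control ordering plus
# noise too small to flip any pair, one consensus case and one reversed case.
toyCohort <- function(m = 5, nControl = 10, noise = 0.01, seed = 42) {
  set.seed(seed)
  genes <- paste0("G", seq_len(m))
  base <- seq_len(m)                      # strict ordering G1 < G2 < ... < Gm
  ctrl <- sapply(seq_len(nControl), function(i)
    base + stats::runif(m, -noise, noise))
  consensus <- base + stats::runif(m, -noise, noise)
  reversed <- rev(base) + stats::runif(m, -noise, noise)
  x <- cbind(ctrl, consensus, reversed)
  dimnames(x) <- list(genes, c(sprintf("c%02d", seq_len(nControl)),
                               "consensus", "reversed"))
  pheno <- stats::setNames(c(rep("control", nControl), "case", "case"),
                           colnames(x))
  list(expr = x, pheno = pheno, genes = genes)
}

# Small-but-informative synthetic config used where the full preset would be
# wasteful (counts scaled down, world parameters unchanged).
smallConfig <- function(seed = 7)
  syntheticConfig(nGenes = 400, nSets = 20, setSizes = c(6, 12),
                  nControl = 12, nPerStage = c(6, 6, 6, 6), seed = seed)
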