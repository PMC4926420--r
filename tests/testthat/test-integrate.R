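test_that("cumulative-proportion transform matches hand arithmetic and tie rules", {
  expect_equal(cumulativeProportionTransform(c(4, 3, 2, 1)),
               c(0.6, 0.3, 0.1, 0))
  # complete tie: all outputs equal
  expect_equal(cumulativeProportionTransform(c(5, 5, 5)), c(0, 0, 0))
  # tie block shares its last member's value
  expect_equal(cumulativeProportionTransform(c(2, 2, 1)), c(0.2, 0.2, 0))
  # negative (log-ratio) input: shifted by the minimum first
  expect_equal(cumulativeProportionTransform(c(3, 2, 1, 0) - 1),
               cumulativeProportionTransform(c(3, 2, 1, 0)))
  expect_error(cumulativeProportionTransform(c(0, 0, 0)), "zero total")
})

test_that("the transform is order-preserving and bounded in [0, 1)", {
  set.seed(12)
  for (rep_ in 1:10) {
    v <- rgamma(50, shape = 2)
    tv <- cumulativeProportionTransform(v)
    expect_identical(order(tv), order(v))
    expect_true(all(tv >= 0 & tv < 1))
    expect_equal(min(tv), 0)
  }
})

test_that("the transform leaves GSR indices unchanged (cross-module rank invariance)", {
  sim <- generateCohort(smallConfig(seed = 44))
  raw <- SummarizedExperiment::assay(sim$expr)
  gsrRaw <- gsrValues(gsrMatrix(raw, sim$phenotypes, sim$collection))
  gsrCp <- gsrValues(gsrMatrix(cumulativeProportionTransform(raw),
                               sim$phenotypes, sim$collection))
  expect_identical(gsrRaw, gsrCp)
})

test_that("common-gene merging keeps shared symbols and drops greedily", {
  mk <- function(genes, id, n = 3) {
    m <- matrix(seq_len(length(genes) * n), length(genes), n,
                dimnames = list(genes, paste0(id, "_s", seq_len(n))))
    m
  }
  d1 <- mk(paste0("G", 1:12), "d1")
  d2 <- mk(paste0("G", 3:12), "d2")
  mc <- mergeCommonGenes(list(d1 = d1, d2 = d2), minCommon = 5)
  expect_equal(length(mc$commonGenes), 10L)
  expect_equal(mc$kept, c("d1", "d2"))
  expect_equal(nrow(mc$dropped), 0L)
  expect_equal(ncol(mc$matrix), 6L)

  # outlier sharing only 2 genes is dropped
  d3 <- mk(c("G1", "G2", "X1", "X2"), "d3")
  mc2 <- mergeCommonGenes(list(d1 = d1, d2 = d2, d3 = d3), minCommon = 5)
  expect_equal(mc2$kept, c("d1", "d2"))
  expect_equal(mc2$dropped$id, "d3")
  expect_equal(length(mc2$commonGenes), 10L)

  expect_error(mergeCommonGenes(list(d3 = d3), minCommon = 5),
               "below minCommon")
})

test_that("greedy dropping matches the exhaustive-subset oracle on <= 4 datasets", {
  set.seed(66)
  universe <- paste0("G", 1:40)
  for (rep_ in 1:5) {
    mats <- lapply(1:4, function(i) {
      genes <- sample(universe, sample(15:30, 1))
      matrix(rnorm(length(genes) * 2), length(genes), 2,
             dimnames = list(genes, paste0("d", i, "_s", 1:2)))
    })
    names(mats) <- paste0("d", 1:4)
    minCommon <- 8
    got <- tryCatch(mergeCommonGenes(mats, minCommon = minCommon),
                    error = function(e) NULL)
    # oracle: best subset = the largest subset (then most genes) meeting the
    # threshold; greedy must at least meet the threshold whenever some
    # subset of the same size does
    sizes <- lapply(4:1, function(k) utils::combn(names(mats), k,
                                                  simplify = FALSE))
    feasible <- NULL
    for (grp in unlist(sizes, recursive = FALSE)) {
      common <- Reduce(intersect, lapply(mats[grp], rownames))
      if (length(common) >= minCommon) { feasible <- grp; break }
    }
    if (is.null(feasible)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_gte(length(got$commonGenes), minCommon)
      expect_gte(length(got$kept), length(feasible))
    }
  }
})

test_that("moderated t reduces to the ordinary t at d0 = 0 and is a no-op at equal variances", {
  set.seed(7)
  m <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  ph <- stats::setNames(rep(c("case", "control"), each = 4), colnames(m))
  r0 <- moderatedTTest(m, ph, caseLabel = "case", d0 = 0)
  ordinary <- apply(m, 1, function(row)
    stats::t.test(row[1:4], row[5:8], var.equal = TRUE)$statistic)
  expect_equal(unname(r0$t), unname(ordinary), tolerance = 1e-10)

  # identical per-gene variances: shrinkage cannot change anything
  base <- rnorm(8)
  m2 <- t(sapply(1:20, function(i) base + i))    # shifted copies, same s2
  dimnames(m2) <- list(paste0("g", 1:20), names(ph))
  r1 <- moderatedTTest(m2, ph, caseLabel = "case", d0 = 0)
  r2 <- moderatedTTest(m2, ph, caseLabel = "case", d0 = 4)
  expect_equal(r1$t, r2$t, tolerance = 1e-10)
})

test_that("moderated t agrees with the limma cross-check route", {
  set.seed(15)
  m <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  m[1:10, 1:5] <- m[1:10, 1:5] + 2          # ten true positives
  ph <- stats::setNames(rep(c("case", "control"), each = 5), colnames(m))
  mine <- moderatedTTest(m, ph, caseLabel = "case")

  design <- cbind(1, as.integer(ph == "case"))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(unname(mine$t), unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(mine$p), unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(attr(mine, "d0"), fit$df.prior, tolerance = 1e-6)
})

test_that("moderated t holds its nominal type-I error on null data", {
  set.seed(27)
  m <- matrix(rnorm(2000 * 12), 2000, 12,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:12)))
  ph <- stats::setNames(rep(c("case", "control"), each = 6), colnames(m))
  r <- moderatedTTest(m, ph, caseLabel = "case")
  alphaHat <- mean(r$p < 0.05)
  expect_gt(alphaHat, 0.035)
  expect_lt(alphaHat, 0.065)
  expect_true(all(r$q >= r$p))
})

test_that("DEG output is stable under input row permutation", {
  set.seed(33)
  m <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:8)))
  ph <- stats::setNames(rep(c("case", "control"), each = 4), colnames(m))
  r1 <- moderatedTTest(m, ph, caseLabel = "case")
  perm <- sample(nrow(m))
  r2 <- moderatedTTest(m[perm, ], ph, caseLabel = "case")
  r2s <- r2[match(r1$gene, r2$gene), ]
  expect_equal(r2s$t, r1$t)
  expect_equal(r2s$q, r1$q)
  expect_equal(r2s$rank, r1$rank)
})
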