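test_that("baseline template encodes the control-majority pair orientations", {
  # 3 controls; g1 < g2 in all three -> fraction 1, orientation A
  x <- matrix(c(1, 2,
                1, 3,
                1, 4), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  ph <- c(c1 = "control", c2 = "control", c3 = "control")
  tp <- buildBaselineTemplate(x, ph, c("g1", "g2"))
  expect_equal(tp$fraction, 1)
  expect_equal(tp$orientation, "A")

  # g1 < g2 in exactly 1 of 3 -> fraction 1/3 <= 0.5 -> B
  x2 <- x; x2["g1", c("c2", "c3")] <- c(5, 6)
  tp2 <- buildBaselineTemplate(x2, ph, c("g1", "g2"))
  expect_equal(tp2$fraction, 1 / 3)
  expect_equal(tp2$orientation, "B")

  # 4 controls split 2-2 -> fraction exactly 0.5 -> B (ties go to B)
  x3 <- cbind(x2[, 1:2], c4 = c(1, 2), c5 = c(9, 2))
  rownames(x3) <- c("g1", "g2")
  ph3 <- stats::setNames(rep("control", 4), colnames(x3))
  tp3 <- buildBaselineTemplate(x3, ph3, c("g1", "g2"))
  expect_equal(tp3$fraction, 0.5)
  expect_equal(tp3$orientation, "B")
})

test_that("templates are stable under control duplication and sample order", {
  set.seed(5)
  x <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  ph <- stats::setNames(rep("control", 10), colnames(x))
  tp <- buildBaselineTemplate(x, ph, paste0("g", 1:4))

  dup <- cbind(x, x); colnames(dup) <- paste0("c", 1:20)
  phd <- stats::setNames(rep("control", 20), colnames(dup))
  tpd <- buildBaselineTemplate(dup, phd, paste0("g", 1:4))
  expect_equal(tpd$fraction, tp$fraction)
  expect_equal(tpd$orientation, tp$orientation)

  perm <- sample(ncol(x))
  tps <- buildBaselineTemplate(x[, perm], ph[perm], paste0("g", 1:4))
  expect_equal(tps$fraction, tp$fraction)
})

test_that("template building errors and skipping follow the m >= 2 / controls > 0 rules", {
  x <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  ph <- c(a = "control", b = "case")
  tp <- buildBaselineTemplate(x, ph, c("g1", "absent1", "absent2"))
  expect_null(tp)
  expect_error(buildBaselineTemplate(x, c(a = "case", b = "case"), c("g1", "g2")),
               "no control samples")
})

test_that("GSR index hits the boundary values and counts mismatches", {
  toy <- toyCohort(m = 5)
  tp <- buildBaselineTemplate(toy$expr, toy$pheno, toy$genes)
  expect_identical(gsrIndex(toy$expr[toy$genes, "consensus"], tp), 1)
  expect_identical(gsrIndex(toy$expr[toy$genes, "reversed"], tp), 0)

  # m = 3 (3 pairs), exactly one pair mismatched -> 2/3
  x <- matrix(rep(c(1, 2, 3), 3), 3, 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
  ph <- stats::setNames(rep("control", 3), colnames(x))
  tp3 <- buildBaselineTemplate(x, ph, rownames(x))
  expect_equal(gsrIndex(c(2, 1, 3), tp3), 2 / 3)   # only g1<g2 flipped

  expect_error(gsrIndex(c(1, 2), tp3), "does not match")
})

test_that("GSR is invariant under strictly increasing transforms", {
  set.seed(11)
  x <- matrix(rnorm(8 * 12), 8, 12,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:12)))
  ph <- stats::setNames(rep(c("control", "case"), each = 6), colnames(x))
  tp <- buildBaselineTemplate(x, ph, paste0("g", 1:8))
  for (f in list(function(v) exp(v), function(v) v^3 + 10 * v,
                 function(v) rank(v))) {
    for (s in colnames(x))
      expect_equal(gsrIndex(f(x[, s]), tp), gsrIndex(x[, s], tp))
  }
})

test_that("gsrMatrix equals the brute-force pair enumerator exactly", {
  set.seed(23)
  for (rep_ in 1:3) {
    genes <- paste0("g", 1:30)
    x <- matrix(rnorm(30 * 8), 30, 8,
                dimnames = list(genes, paste0("s", 1:8)))
    ph <- stats::setNames(c(rep("control", 4), rep("case", 4)), colnames(x))
    sets <- list(S1 = sample(genes, 6), S2 = sample(genes, 6),
                 S3 = sample(genes, 6))
    gsc <- GeneSetCollection(sets)
    got <- gsrValues(gsrMatrix(x, ph, gsc))
    want <- bruteForceGSR(x, ph, sets)
    expect_identical(got, want[rownames(got), ])
  }
})

test_that("gsrMatrix records skipped sets and keeps collection order", {
  toy <- toyCohort(m = 4)
  gsc <- GeneSetCollection(list(OK1 = toy$genes[1:3],
                                TOO_SMALL = c("G1", "nope"),
                                OK2 = toy$genes))
  gsr <- gsrMatrix(toy$expr, toy$pheno, gsc)
  expect_equal(rownames(gsr), c("OK1", "OK2"))
  expect_equal(skippedSets(gsr)$set, "TOO_SMALL")
  expect_equal(skippedSets(gsr)$reason, "insufficient_genes")
  expect_equal(unname(gsrValues(gsr)[, "consensus"]), c(1, 1))
  expect_true(all(gsrValues(gsr) >= 0 & gsrValues(gsr) <= 1))
})

test_that("null samples score symmetrically around 0.5", {
  toy <- toyCohort(m = 5)
  tpl <- buildTemplates(toy$expr, toy$pheno,
                        GeneSetCollection(list(S = toy$genes)))
  set.seed(99)
  n <- 5000
  rnd <- matrix(stats::runif(5 * n), 5, n,
                dimnames = list(toy$genes, paste0("r", seq_len(n))))
  r <- gsrValues(scoreSamples(rnd, tpl))
  expect_lt(abs(mean(r) - 0.5), 0.02)
  # symmetry: P(R > 0.5) ~= P(R < 0.5)
  expect_lt(abs(mean(r > 0.5) - mean(r < 0.5)), 0.05)
})

test_that("templates round-trip through the pair-level TSV", {
  toy <- toyCohort(m = 6)
  tpl <- buildTemplates(toy$expr, toy$pheno,
                        GeneSetCollection(list(A = toy$genes,
                                               B = toy$genes[1:4])))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTemplates(tpl, f)
  back <- readTemplates(f, nControls = nControls(tpl))
  expect_equal(names(back), names(tpl))
  for (nm in names(tpl)) {
    expect_equal(back[[nm]]$genes, tpl[[nm]]$genes)
    expect_equal(back[[nm]]$fraction, tpl[[nm]]$fraction)
    expect_equal(back[[nm]]$orientation, tpl[[nm]]$orientation)
  }
  # scoring through re-read templates is identical
  expect_identical(gsrValues(scoreSamples(toy$expr, back)),
                   gsrValues(scoreSamples(toy$expr, tpl)))
})
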