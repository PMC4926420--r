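test_that("Mann-Whitney p-values match exact enumeration on small groups", {
  # the 2-vs-2 worked case: {1,2} vs {3,4} -> exact two-sided p = 1/3
  v <- rbind(SETA = c(1, 2, 3, 4))
  colnames(v) <- c("a1", "a2", "b1", "b2")
  ph <- c(a1 = "I", a2 = "I", b1 = "control", b2 = "control")
  d <- testDeregulation(v, ph, caseLabel = "I")
  expect_equal(d$p, 1 / 3)
  expect_equal(d$p, enumMWU(c(1, 2), c(3, 4)))

  # more enumeration cross-checks at other shapes (tie-free)
  set.seed(4)
  for (rep_ in 1:5) {
    x <- sample(100, 4); y <- sample(200, 5) + 0.5
    v2 <- rbind(S = c(x, y))
    colnames(v2) <- paste0("s", 1:9)
    ph2 <- stats::setNames(rep(c("I", "control"), c(4, 5)), colnames(v2))
    expect_equal(testDeregulation(v2, ph2, caseLabel = "I")$p,
                 enumMWU(x, y))
  }
})

test_that("identical case and control distributions give p = 1 and constant rows p = 1", {
  v <- rbind(NULLSET = c(5, 7, 5, 7), FLAT = c(3, 3, 3, 3))
  colnames(v) <- c("a1", "a2", "b1", "b2")
  ph <- c(a1 = "I", a2 = "I", b1 = "control", b2 = "control")
  d <- testDeregulation(v, ph, caseLabel = "I")
  expect_equal(d$p[d$set == "NULLSET"], 1)
  expect_equal(d$p[d$set == "FLAT"], 1)
  expect_error(testDeregulation(v[, 1:3], ph[1:3], caseLabel = "I"),
               "fewer than 2")
})

test_that("BH adjustment matches the hand step-up and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stepUpBH(p), rep(0.04, 4))

  set.seed(9)
  v <- matrix(runif(20 * 12), 20, 12,
              dimnames = list(paste0("S", 1:20), paste0("s", 1:12)))
  ph <- stats::setNames(rep(c("I", "control"), each = 6), colnames(v))
  d <- testDeregulation(v, ph, caseLabel = "I")
  expect_equal(d$q, stepUpBH(d$p))
  expect_true(all(d$q >= d$p))
  expect_true(all(diff(d$q[order(d$p)]) >= -1e-12))

  # permuting set order changes nothing
  perm <- sample(nrow(v))
  d2 <- testDeregulation(v[perm, ], ph, caseLabel = "I")
  expect_equal(d2[order(d2$set), c("p", "q", "rank")],
               d[order(d$set), c("p", "q", "rank")], ignore_attr = TRUE)
})

test_that("p-values are invariant under common strictly increasing transforms", {
  set.seed(2)
  v <- matrix(runif(5 * 14), 5, 14,
              dimnames = list(paste0("S", 1:5), paste0("s", 1:14)))
  ph <- stats::setNames(rep(c("IV", "control"), each = 7), colnames(v))
  d1 <- testDeregulation(v, ph, caseLabel = "IV")
  d2 <- testDeregulation(exp(3 * v) - 1, ph, caseLabel = "IV")
  expect_equal(d1$p, d2$p)
})

test_that("ranks are a permutation 1..n with lexicographic tie-break", {
  v <- rbind(B_SET = c(1, 2, 3, 4), A_SET = c(1, 2, 3, 4),
             C_SET = c(3, 4, 1, 2))
  colnames(v) <- c("a1", "a2", "b1", "b2")
  ph <- c(a1 = "I", a2 = "I", b1 = "control", b2 = "control")
  d <- testDeregulation(v, ph, caseLabel = "I")
  expect_setequal(d$rank, 1:3)
  # A_SET and B_SET share p; A_SET must rank first of the two
  expect_lt(d$rank[d$set == "A_SET"], d$rank[d$set == "B_SET"])
})

test_that("top-k set analysis reproduces the degenerate and brute-force regions", {
  lists <- list(I = paste0("S", 1:20), II = paste0("S", 1:20),
                III = paste0("S", 1:20), IV = paste0("S", 1:20))
  va <- topKSetAnalysis(lists, k = 20)
  expect_equal(unname(va$regionCounts[["I+II+III+IV"]]), 20L)
  expect_equal(sum(va$regionCounts), 20L)
  expect_equal(va$common, sort(paste0("S", 1:20)))

  disj <- list(I = paste0("A", 1:5), II = paste0("B", 1:5),
               III = paste0("C", 1:5), IV = paste0("D", 1:5))
  vd <- topKSetAnalysis(disj, k = 5)
  expect_equal(unname(vd$regionCounts[c("I", "II", "III", "IV")]),
               rep(5L, 4))
  expect_equal(sum(vd$regionCounts), 20L)
  expect_equal(length(vd$common), 0L)

  expect_error(topKSetAnalysis(disj, k = 6), "exceeds")
})

test_that("random top-k lists match brute-force region enumeration and conservation", {
  set.seed(31)
  universe <- paste0("S", 1:100)
  lists <- lapply(stats::setNames(1:4, c("I", "II", "III", "IV")),
                  function(i) sample(universe, 20))
  va <- topKSetAnalysis(lists, k = 20)
  # brute force: classify every set of the union by its exact membership
  groups <- names(lists)
  union_ <- unique(unlist(lists))
  counts <- integer(0)
  for (s in union_) {
    inset <- groups[vapply(groups, function(g) s %in% lists[[g]], logical(1))]
    lab <- paste(sort(inset), collapse = "+")
    counts[lab] <- if (is.na(counts[lab])) 1L else counts[lab] + 1L
  }
  nz <- va$regionCounts[va$regionCounts > 0]
  expect_equal(as.list(nz), as.list(counts[names(nz)]))
  expect_equal(sum(va$regionCounts), length(union_))
  # each group's containing regions sum to k
  for (g in groups) {
    containing <- vapply(strsplit(names(va$regionCounts), "\\+"),
                         function(r) g %in% r, logical(1))
    expect_equal(sum(va$regionCounts[containing]), 20L)
  }
})

test_that("progressive selection applies the three criteria as stated", {
  mk <- function(stage, ranks, ps) {
    data.frame(set = paste0("S", seq_along(ranks)), stage = stage,
               p = ps, q = ps, rank = ranks, stringsAsFactors = FALSE)
  }
  # S1: ranks 100,80,60,20 all p<0.05 -> selected
  # S2: ranks 100,90,60,20 -> first drop 10 <= 15 -> rejected
  # S3: ranks 400,300,250,230 -> final rank 230 >= 200 -> rejected
  # S4: significant only at stage I -> rejected
  ranks <- cbind(c(100, 100, 400, 1), c(80, 90, 300, 2),
                 c(60, 60, 250, 3), c(20, 20, 230, 250))
  ps <- cbind(rep(0.01, 4), c(0.01, 0.01, 0.01, 0.2),
              c(0.01, 0.01, 0.01, 0.2), c(0.01, 0.01, 0.01, 0.2))
  recs <- lapply(1:4, function(g)
    mk(c("I", "II", "III", "IV")[g], ranks[, g], ps[, g]))
  sel <- selectProgressive(recs)
  expect_equal(sel$set, "S1")
  expect_equal(unname(unlist(sel[1, -1])), c(100, 80, 60, 20))

  # "some pair" mode admits S2 (drop II->III is 30 > 15)
  sel2 <- selectProgressive(recs, progressiveCriteria(mode = "some"))
  expect_setequal(sel2$set, c("S1", "S2"))

  # asymmetric universes are rejected by name
  recs2 <- recs
  recs2[[2]]$set[1] <- "OTHER"
  expect_error(selectProgressive(recs2), "OTHER")
})
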