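#' Configuration for the synthetic multi-stage cohort generator
#'
#' The generator's stated world: control samples share one latent gene
#' ordering (latent means drawn once, Uniform(0,1)) observed under Gaussian
#' noise; in each case stage a designated, nested fraction of gene sets is
#' perturbed by within-set pair-order scrambling of calibrated intensity,
#' emulating a disease whose functional deregulation broadens and deepens
#' with stage.
#'
#' @param nGenes Gene universe size.
#' @param nSets Number of generated gene sets (pairwise disjoint).
#' @param setSizes Length-2 range of set sizes, sampled uniformly.
#' @param nControl Control sample count.
#' @param nPerStage Case sample counts for stages I-IV (length 4).
#' @param piStage Fraction of sets perturbed per stage (non-decreasing).
#' @param lambdaStage Target discordant-pair fraction per perturbed set and
#'   stage (non-decreasing); the realized fraction is
#'   round(lambda * npairs) / npairs exactly.
#' @param sigma Observation noise SD. The default 0.25 solves
#'   E[Phi(|d|/(sigma*sqrt(2)))] = 0.78 for |d| the gap of two Uniform(0,1)
#'   latent means, so the expected control GSR is about 0.78.
#' @param seed RNG seed; the cohort is a pure function of (config, seed).
#' @return A list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(nGenes = 6000L, nSets = 200L,
                            setSizes = c(10L, 40L), nControl = 60L,
                            nPerStage = c(30L, 30L, 30L, 30L),
                            piStage = c(0.10, 0.20, 0.35, 0.50),
                            lambdaStage = c(0.30, 0.40, 0.50, 0.60),
                            sigma = 0.25, seed = 1L) {
  stopifnot(nGenes >= 2, nSets >= 1, length(setSizes) == 2,
            setSizes[1] >= 2, setSizes[2] >= setSizes[1],
            nControl >= 1, length(nPerStage) == length(piStage),
            length(piStage) == length(lambdaStage),
            all(nPerStage >= 1), all(piStage >= 0 & piStage <= 1),
            all(lambdaStage >= 0 & lambdaStage <= 1),
            sigma >= 0)
  if (is.unsorted(piStage) || is.unsorted(lambdaStage))
    warning("piStage / lambdaStage are usually non-decreasing across stages")
  structure(list(nGenes = as.integer(nGenes), nSets = as.integer(nSets),
                 setSizes = as.integer(setSizes),
                 nControl = as.integer(nControl),
                 nPerStage = as.integer(nPerStage),
                 piStage = piStage, lambdaStage = lambdaStage,
                 sigma = sigma, seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' The staging preset
#'
#' The default synthetic world used throughout validation: 6000 genes, 200
#' disjoint gene sets of 10-40 genes, 60 controls and 30 samples per stage
#' I-IV, perturbed-set fractions (0.10, 0.20, 0.35, 0.50), pair-flip
#' intensities (0.30, 0.40, 0.50, 0.60), noise sigma = 0.25 (expected
#' control GSR about 0.78). Calibrated so the stage-mean GSR declines
#' monotonically from stage I to IV and the late-stage score histograms are
#' bimodal (an intact mode plus a growing deregulated mode).
#'
#' @param seed RNG seed.
#' @return A \code{\link{syntheticConfig}}.
#' @export
stagingPreset <- function(seed = 1L) syntheticConfig(seed = seed)

#' Generate a synthetic multi-stage cohort with known ground truth
#'
#' Controls are latent means plus Gaussian noise. For each case sample of
#' stage g, every perturbed set has its within-set latent means reassigned
#' by a fresh random permutation at Kendall (inversion) distance exactly
#' round(lambda_g * npairs), drawn by discordance-increasing adjacent
#' transpositions; unperturbed sets are untouched. Perturbed-set lists are
#' nested across stages (stage I's sets are a subset of stage II's, and so
#' on), so deregulation broadens as disease progresses. Gene sets are
#' pairwise disjoint, so perturbation never leaks into unperturbed sets.
#'
#' @param config A \code{\link{syntheticConfig}}.
#' @return List: \code{expr} (SummarizedExperiment, assay \code{"exprs"},
#'   with \code{colData()$group}), \code{phenotypes} (named vector),
#'   \code{collection} (\code{GeneSetCollection}), \code{truth} (list:
#'   \code{latentMeans}; \code{latentProfiles}, the noise-free genes x
#'   samples matrix whose within-set discordance against the control
#'   ordering is exactly the realized lambda; \code{stages} - per stage the
#'   perturbed set names, target and realized lambda).
#' @export
generateCohort <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  nStages <- length(config$nPerStage)
  stageNames <- c("I", "II", "III", "IV", "V", "VI")[seq_len(nStages)]

  sizes <- sample(config$setSizes[1]:config$setSizes[2], config$nSets,
                  replace = TRUE)
  if (sum(sizes) > config$nGenes)
    stop("set sizes exceed the gene universe: need ", sum(sizes),
         " genes, have ", config$nGenes)
  geneIdsAll <- sprintf("g%05d", seq_len(config$nGenes))
  shuffled <- sample(geneIdsAll)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  setNames_ <- sprintf("SET%03d", seq_len(config$nSets))
  sets <- lapply(seq_len(config$nSets), function(i)
    list(name = setNames_[i], description = "synthetic",
         genes = shuffled[starts[i]:ends[i]]))
  names(sets) <- setNames_
  collection <- new("GeneSetCollection", sets = sets,
                    sourceLabel = "synthetic")

  mu <- stats::runif(config$nGenes)
  names(mu) <- geneIdsAll

  # nested perturbed-set lists: one shuffled order, stage g takes a prefix
  permOrder <- sample(setNames_)
  nPerturb <- round(config$piStage * config$nSets)
  perturbed <- lapply(nPerturb, function(np) sort(permOrder[seq_len(np)]))

  nCase <- sum(config$nPerStage)
  total <- config$nControl + nCase
  sampleIds <- c(sprintf("ctrl%03d", seq_len(config$nControl)),
                 unlist(lapply(seq_len(nStages), function(g)
                   sprintf("%s_s%03d", stageNames[g],
                           seq_len(config$nPerStage[g])))))
  phenotypes <- stats::setNames(
    c(rep("control", config$nControl),
      rep(stageNames, config$nPerStage)), sampleIds)

  # per-set sorted latent values and gene order, reused across samples
  setOrder <- lapply(sets, function(s) {
    g <- s$genes[order(mu[s$genes])]
    list(genes = g, values = unname(mu[g]))
  })

  X <- matrix(NA_real_, config$nGenes, total,
              dimnames = list(geneIdsAll, sampleIds))
  L <- matrix(NA_real_, config$nGenes, total,
              dimnames = list(geneIdsAll, sampleIds))
  realized <- vector("list", nStages)
  for (s in seq_len(total)) {
    lat <- mu
    g <- phenotypes[[s]]
    if (g != "control") {
      gi <- match(g, stageNames)
      lam <- config$lambdaStage[gi]
      for (nm in perturbed[[gi]]) {
        so <- setOrder[[nm]]
        m <- length(so$genes)
        npairs <- m * (m - 1L) / 2L
        d <- round(lam * npairs)
        p <- .perm_with_inversions(m, d)
        lat[so$genes] <- so$values[p]
      }
    }
    L[, s] <- lat
    X[, s] <- lat + stats::rnorm(config$nGenes, 0, config$sigma)
  }
  for (gi in seq_len(nStages)) {
    nm <- perturbed[[gi]]
    realized[[gi]] <- data.frame(
      set = nm,
      targetLambda = rep(config$lambdaStage[gi], length(nm)),
      realizedLambda = vapply(nm, function(x) {
        m <- length(sets[[x]]$genes)
        np <- m * (m - 1L) / 2L
        round(config$lambdaStage[gi] * np) / np
      }, numeric(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  names(realized) <- stageNames

  cd <- S4Vectors::DataFrame(group = unname(phenotypes),
                             row.names = sampleIds)
  expr <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = X), colData = cd,
    metadata = list(datasetId = "synthetic"))
  list(expr = expr, phenotypes = phenotypes, collection = collection,
       truth = list(latentMeans = mu, latentProfiles = L, stages = realized,
                    config = config))
}

#' Write a generated cohort to disk as plain text
#'
#' Expression TSV, phenotype TSV, GMT, and a truth TSV (stage, set, target
#' and realized lambda).
#'
#' @param cohort Result of \code{\link{generateCohort}}.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expression.tsv"),
             pheno = file.path(dir, "phenotypes.tsv"),
             gmt = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth.tsv"))
  writeExpression(cohort$expr, paths[["expr"]])
  writePhenotype(cohort$phenotypes, paths[["pheno"]])
  writeGMT(cohort$collection, paths[["gmt"]])
  tr <- do.call(rbind, lapply(names(cohort$truth$stages), function(g) {
    st <- cohort$truth$stages[[g]]
    cbind(stage = rep(g, nrow(st)), st)
  }))
  utils::write.table(tr, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
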