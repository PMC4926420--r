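#' Read a plain-text pipeline configuration
#'
#' \code{key = value} lines; '#' starts a comment. Keys mirror the
#' \code{\link{runPipeline}} arguments (\code{expr}, \code{pheno},
#' \code{gmt}, \code{out}, \code{alpha}, \code{k}, \code{folds},
#' \code{repeats}, \code{knnK}, \code{tau}, \code{seed}, \code{stages},
#' \code{caseLabels}, \code{controlLabel}); comma-separated lists allowed.
#'
#' @param path Path to the config file.
#' @return Named list of character values.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  stats::setNames(lapply(kv, function(x) {
    v <- paste(x[-1], collapse = "=")
    if (grepl(",", v)) trimws(strsplit(v, ",")[[1]]) else v
  }), vapply(kv, `[[`, character(1), 1L))
}

# md5 of a character scalar (via tempfile; base R has no string md5)
.hashString <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

.inputHash <- function(files, params) {
  fh <- vapply(files, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else "missing", character(1))
  .hashString(paste(c(fh, paste(names(params), unlist(params), sep = "=")),
                    collapse = ";"))
}

#' Run the functionome workflow end to end
#'
#' Orchestrates template building and scoring, per-stage deregulation
#' testing, top-k set analysis, progressive-ranking selection, SVM
#' classification, and mutual-information network reconstruction over the
#' commonly deregulated sets, writing each artifact once under
#' \code{outDir} with a manifest (stage, input hash, output). Re-running
#' with an unchanged config and inputs skips completed stages; a changed
#' input or parameter invalidates the stage and everything downstream.
#'
#' @param exprFile,phenoFile,gmtFile Input paths (expression TSV, phenotype
#'   TSV, GMT).
#' @param outDir Output directory.
#' @param stages Which stages to run, in dependency order; subset of
#'   \code{c("score", "test", "venn", "progressive", "classify", "network")}.
#' @param caseLabels Case group labels, in stage order.
#' @param controlLabel Control group label.
#' @param alpha,maxFinalRank,minRankDrop Progressive-ranking criteria.
#' @param k Top-k for the set analysis.
#' @param nFolds,nRepeats,C SVM cross-validation settings.
#' @param knnK,tau MI estimator neighbour count and DPI tolerance.
#' @param maxNetworkSets Cap on the number of commonly deregulated sets fed
#'   to the network stage.
#' @param seed Global seed (fixes the SVM fold assignments).
#' @return data.frame manifest (stage, output, inputHash, outputHash),
#'   invisibly; also written to \code{outDir/manifest.tsv}.
#' @export
runPipeline <- function(exprFile, phenoFile, gmtFile, outDir,
                        stages = c("score", "test", "venn", "progressive",
                                   "classify", "network"),
                        caseLabels = c("I", "II", "III", "IV"),
                        controlLabel = "control",
                        alpha = 0.05, maxFinalRank = 200L, minRankDrop = 15L,
                        k = 200L, nFolds = 5L, nRepeats = 10L, C = 1,
                        knnK = 3L, tau = 1.0, maxNetworkSets = 50L,
                        seed = 1L) {
  for (f in c(exprFile, phenoFile, gmtFile))
    if (!file.exists(f)) stop("input file not found: ", f)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(outDir, "manifest.tsv")
  manifest <- if (file.exists(manifestPath))
    utils::read.table(manifestPath, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  else data.frame(stage = character(), output = character(),
                  inputHash = character(), outputHash = character(),
                  stringsAsFactors = FALSE)
  params <- list(caseLabels = paste(caseLabels, collapse = ","),
                 controlLabel = controlLabel, alpha = alpha,
                 maxFinalRank = maxFinalRank, minRankDrop = minRankDrop,
                 k = k, nFolds = nFolds, nRepeats = nRepeats, C = C,
                 knnK = knnK, tau = tau, maxNetworkSets = maxNetworkSets,
                 seed = seed)
  upstreamInvalid <- FALSE
  state <- new.env(parent = emptyenv())

  fresh <- function(stage, outputs, hash) {
    if (upstreamInvalid) return(FALSE)
    rec <- manifest[manifest$stage == stage, , drop = FALSE]
    if (nrow(rec) == 0 || !all(rec$inputHash == hash) ||
        !setequal(rec$output, outputs) || !all(file.exists(outputs)))
      return(FALSE)
    # an artifact edited or corrupted on disk invalidates its stage
    current <- vapply(rec$output, function(f) unname(tools::md5sum(f)),
                      character(1))
    all(current == rec$outputHash)
  }
  record <- function(stage, outputs, hash) {
    manifest <<- manifest[manifest$stage != stage, , drop = FALSE]
    oh <- vapply(outputs, function(f) unname(tools::md5sum(f)), character(1))
    manifest <<- rbind(manifest, data.frame(stage = stage, output = outputs,
                                            inputHash = hash, outputHash = oh,
                                            stringsAsFactors = FALSE))
  }
  loadInputs <- function() {
    if (is.null(state$expr)) {
      state$expr <- readExpression(exprFile)
      state$pheno <- readPhenotype(phenoFile)
      state$collection <- readGMT(gmtFile)
    }
  }

  # -- score ---------------------------------------------------------------
  gsrPath <- file.path(outDir, "gsr.tsv")
  if ("score" %in% stages) {
    h <- .inputHash(c(exprFile, phenoFile, gmtFile), params["controlLabel"])
    if (!fresh("score", gsrPath, h)) {
      loadInputs()
      gsr <- gsrMatrix(state$expr, state$pheno, state$collection,
                       controlLabel = controlLabel)
      writeGSR(gsr, gsrPath)
      sk <- skippedSets(gsr)
      message("score: ", nrow(gsr), " sets scored, ", nrow(sk), " skipped")
      record("score", gsrPath, h)
      upstreamInvalid <- TRUE
      state$gsr <- gsr
    }
  }
  getGSR <- function() {
    if (is.null(state$gsr)) {
      state$pheno <- readPhenotype(phenoFile)
      state$gsr <- readGSR(gsrPath, phenotypes = state$pheno)
    }
    state$gsr
  }

  # -- per-stage deregulation tests ---------------------------------------
  deregPaths <- file.path(outDir, sprintf("dereg_%s.tsv", caseLabels))
  if ("test" %in% stages) {
    h <- .inputHash(gsrPath, params[c("caseLabels", "controlLabel")])
    if (!fresh("test", deregPaths, h)) {
      gsr <- getGSR()
      state$dereg <- lapply(caseLabels, function(cl)
        testDeregulation(gsr, caseLabel = cl, controlLabel = controlLabel))
      names(state$dereg) <- caseLabels
      for (i in seq_along(caseLabels))
        writeResultTable(state$dereg[[i]], deregPaths[i])
      record("test", deregPaths, h)
      upstreamInvalid <- TRUE
    }
  }
  getDereg <- function() {
    if (is.null(state$dereg)) {
      state$dereg <- lapply(deregPaths, function(p)
        utils::read.table(p, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE))
      names(state$dereg) <- caseLabels
    }
    state$dereg
  }

  # -- set analysis --------------------------------------------------------
  vennPath <- file.path(outDir, "venn.tsv")
  commonPath <- file.path(outDir, "common_sets.txt")
  if ("venn" %in% stages) {
    h <- .inputHash(deregPaths, params["k"])
    if (!fresh("venn", c(vennPath, commonPath), h)) {
      va <- topKSetAnalysis(getDereg(), k = min(k, nrow(getDereg()[[1]])))
      writeResultTable(data.frame(region = names(va$regionCounts),
                                  count = unname(va$regionCounts)), vennPath)
      writeLines(va$common, commonPath)
      record("venn", c(vennPath, commonPath), h)
      upstreamInvalid <- TRUE
    }
  }

  # -- progressive ranking -------------------------------------------------
  progPath <- file.path(outDir, "progressive.tsv")
  if ("progressive" %in% stages) {
    h <- .inputHash(deregPaths,
                    params[c("alpha", "maxFinalRank", "minRankDrop")])
    if (!fresh("progressive", progPath, h)) {
      sel <- selectProgressive(getDereg(),
                               progressiveCriteria(alpha, maxFinalRank,
                                                   minRankDrop))
      writeResultTable(sel, progPath)
      record("progressive", progPath, h)
      upstreamInvalid <- TRUE
    }
  }

  # -- classification ------------------------------------------------------
  reportPath <- file.path(outDir, "report.tsv")
  if ("classify" %in% stages) {
    h <- .inputHash(gsrPath, params[c("nFolds", "nRepeats", "C", "seed",
                                      "caseLabels", "controlLabel")])
    if (!fresh("classify", reportPath, h)) {
      gsr <- getGSR()
      rows <- lapply(caseLabels, function(cl) {
        r <- svmCV(gsr, labels = c(cl, controlLabel), nFolds = nFolds,
                   nRepeats = nRepeats, C = C, seed = seed)
        data.frame(comparison = paste(cl, "vs", controlLabel),
                   accuracy = r$accuracy, sensitivity = r$sensitivity,
                   specificity = r$specificity, auc = r$auc)
      })
      mc <- svmCV(gsr, labels = caseLabels, nFolds = nFolds,
                  nRepeats = nRepeats, C = C, seed = seed)
      rows <- c(rows, list(data.frame(comparison = "multiclass",
                                      accuracy = mc$accuracy,
                                      sensitivity = NA, specificity = NA,
                                      auc = NA)))
      writeResultTable(do.call(rbind, rows), reportPath)
      record("classify", reportPath, h)
      upstreamInvalid <- TRUE
    }
  }

  # -- network -------------------------------------------------------------
  netPath <- file.path(outDir, "net.gml")
  if ("network" %in% stages) {
    h <- .inputHash(c(gsrPath, commonPath), params[c("knnK", "tau")])
    if (!fresh("network", netPath, h)) {
      common <- readLines(commonPath, warn = FALSE)
      common <- utils::head(common[nzchar(common)], maxNetworkSets)
      if (length(common) >= 2L) {
        buildNetwork(getGSR(), sets = common, k = knnK, tau = tau,
                     gmlPath = netPath)
      } else {
        writeGML(data.frame(from = character(), to = character(),
                            weight = numeric()), netPath, nodes = common)
      }
      record("network", netPath, h)
    }
  }

  manifest <- manifest[order(match(manifest$stage, c("score", "test", "venn",
                                                     "progressive", "classify",
                                                     "network"))), ,
                       drop = FALSE]
  rownames(manifest) <- NULL
  utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
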