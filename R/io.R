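#' Read an MSigDB GMT gene-set file
#'
#' One gene set per line: name, description, then member gene symbols, all
#' tab-separated. Duplicate symbols within a line are dropped (first
#' occurrence kept); duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A \code{\link{GeneSetCollection}}.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("SETX\tdesc\tG1\tG2\tG3", f)
#' readGMT(f)
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(genes)]
    if (length(genes) == 0L) stop("malformed GMT line ", i, ": no genes")
    sets[[i]] <- list(name = f[1L], description = f[2L], genes = genes)
  }
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate gene set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  new("GeneSetCollection", sets = sets, sourceLabel = basename(path))
}

#' Write a GeneSetCollection to GMT
#'
#' @param collection A \code{GeneSetCollection}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(collection, path) {
  stopifnot(is(collection, "GeneSetCollection"))
  lines <- vapply(collection@sets, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-expression matrix
#'
#' Reads a genes-x-samples table: plain TSV (header row of sample ids, first
#' column gene or probe symbols) or a GEO series-matrix-style TSV where the
#' numeric table sits between \code{!series_matrix_table_begin} and
#' \code{!series_matrix_table_end} markers. Rows sharing a gene symbol are
#' collapsed by the arithmetic mean; rows containing any missing value are
#' dropped (count reported via \code{message}), matching the filter that
#' rejects profiles with missing data.
#'
#' @param path Path to the file.
#' @param dialect \code{"tsv"} or \code{"series_matrix"}.
#' @param datasetId Provenance string stored in the result's metadata
#'   (defaults to the file name).
#' @return A \code{SummarizedExperiment} with assay \code{"exprs"},
#'   row names = unique gene symbols, column names = sample ids.
#' @export
readExpression <- function(path, dialect = c("tsv", "series_matrix"),
                           datasetId = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "series_matrix") {
    b <- grep("^!series_matrix_table_begin", lines)
    e <- grep("^!series_matrix_table_end", lines)
    if (length(b) == 1L && length(e) == 1L && e > b + 1L)
      lines <- lines[(b + 1L):(e - 1L)]
    else
      lines <- lines[!startsWith(lines, "!")]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression table has no data rows")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1]]
  samples <- header[-1L]
  samples <- gsub('^"|"$', "", samples)
  if (length(samples) == 0L) stop("zero samples in expression table")
  if (anyDuplicated(samples)) stop("duplicate sample ids in header")
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  # strsplit drops trailing empty fields; pad them back as missing cells
  body <- lapply(body, function(f)
    if (length(f) < length(header))
      c(f, rep("", length(header) - length(f))) else f)
  ncols <- lengths(body)
  if (any(ncols != length(header)))
    stop("ragged expression table at data row ", which(ncols != length(header))[1])
  sym <- gsub('^"|"$', "", vapply(body, `[[`, character(1), 1L))
  cells <- vapply(body, function(f) f[-1L], character(length(samples)))
  cells <- if (is.null(dim(cells))) matrix(cells, nrow = 1L) else t(cells)
  cells[cells == "" | cells == "NA" | cells == "null"] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- !is.na(cells) & is.na(num)
  if (any(bad))
    stop("non-numeric cell at data row ", which(rowSums(bad) > 0)[1])
  missing <- rowSums(is.na(num)) > 0L
  if (any(missing)) {
    message("readExpression: dropped ", sum(missing),
            " row(s) containing missing values")
    num <- num[!missing, , drop = FALSE]
    sym <- sym[!missing]
  }
  if (nrow(num) == 0L) stop("zero genes after filtering")
  # mean-collapse probes sharing a symbol (order-independent)
  if (anyDuplicated(sym)) {
    num <- rowsum(num, group = sym, reorder = TRUE) /
      as.vector(table(sym)[sort(unique(sym))])
    sym <- rownames(num)
  }
  dimnames(num) <- list(sym, samples)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = num),
    metadata = list(datasetId = datasetId))
}

#' Write an expression matrix as TSV (full precision)
#'
#' @param expr A \code{SummarizedExperiment} (assay \code{"exprs"}) or a
#'   numeric matrix with gene symbols as row names and sample ids as column
#'   names.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(expr, path) {
  m <- .exprMatrix(expr)
  ch <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  out <- cbind(c("gene", rownames(m)),
               rbind(colnames(m), ch))
  writeLines(apply(out, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two tab-separated columns: sample id and group label (canonical labels:
#' \code{control}, \code{I}, \code{II}, \code{III}, \code{IV}). A header row
#' \code{sample<TAB>group} is tolerated and skipped.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping sample id to group label.
#' @export
readPhenotype <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("phenotype table needs two tab-separated columns")
  if (tolower(df[1, 1]) %in% c("sample", "sample_id") ) df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df[[1]]))
    stop("duplicate sample id(s) in phenotype table: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  stats::setNames(df[[2]], df[[1]])
}

#' Write a phenotype table
#' @param phenotypes Named character vector (sample id -> group).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePhenotype <- function(phenotypes, path) {
  writeLines(c("sample\tgroup",
               paste(names(phenotypes), phenotypes, sep = "\t")), path)
  invisible(path)
}

#' Export a weighted edge list as GML
#'
#' Writes plain-text graph modelling language with node \code{label}
#' attributes and edge \code{weight} attributes, readable by igraph and
#' Cytoscape.
#'
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{weight} (may have zero rows).
#' @param path Output path.
#' @param nodes Optional character vector of node labels (to include
#'   isolated nodes); defaults to the labels appearing in \code{edges}.
#' @return \code{path}, invisibly.
#' @export
writeGML <- function(edges, path, nodes = NULL) {
  if (is.null(nodes))
    nodes <- sort(unique(c(as.character(edges$from), as.character(edges$to))))
  if (anyDuplicated(nodes)) stop("duplicate node label(s)")
  id <- stats::setNames(seq_along(nodes) - 1L, nodes)
  out <- c("graph [", "  directed 0")
  for (nm in nodes)
    out <- c(out, "  node [", paste0("    id ", id[[nm]]),
             paste0('    label "', nm, '"'), "  ]")
  if (nrow(edges) > 0)
    for (r in seq_len(nrow(edges)))
      out <- c(out, "  edge [",
               paste0("    source ", id[[as.character(edges$from[r])]]),
               paste0("    target ", id[[as.character(edges$to[r])]]),
               paste0("    weight ", sprintf("%.17g", edges$weight[r])),
               "  ]")
  out <- c(out, "]")
  writeLines(out, path)
  invisible(path)
}

#' Write a deregulation / DEG result table as TSV
#' @param df A data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a GSR matrix as TSV (sets x samples, full precision)
#' @param gsr A \code{GSRMatrix} or numeric matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGSR <- function(gsr, path) {
  m <- if (is(gsr, "GSRMatrix")) gsrValues(gsr) else gsr
  ch <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  out <- cbind(c("set", rownames(m)), rbind(colnames(m), ch))
  writeLines(apply(out, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a GSR matrix written by \code{writeGSR}
#' @param path Path to the TSV.
#' @param phenotypes Optional named character vector of group labels to
#'   attach as colData.
#' @return A \code{GSRMatrix}.
#' @export
readGSR <- function(path, phenotypes = NULL) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  .newGSRMatrix(m, phenotypes = phenotypes, provenance = basename(path),
                skipped = data.frame(set = character(), reason = character()))
}

# ---- internal coercions ----

# accept a SummarizedExperiment (assay 1) or a plain numeric matrix
.exprMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, 1L)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix or SummarizedExperiment")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene row names and sample column names")
  x
}

# resolve phenotypes: explicit named vector, or colData(x)$group
.phenoVector <- function(x, phenotypes = NULL) {
  if (is.null(phenotypes)) {
    if (is(x, "SummarizedExperiment")) phenotypes <- sampleGroups(x)
    else stop("phenotypes required when expression is a plain matrix")
  }
  if (is.null(names(phenotypes))) stop("phenotypes must be a named vector")
  phenotypes
}

.newGSRMatrix <- function(values, phenotypes, provenance, skipped) {
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  cd$group <- if (!is.null(phenotypes))
    as.character(phenotypes[colnames(values)]) else NA_character_
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(gsr = values), colData = cd)
  new("GSRMatrix", se, skippedSets = skipped,
      templateProvenance = as.character(provenance))
}
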