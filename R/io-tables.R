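#' Read a tab-separated expression matrix
#'
#' Expects a TSV file whose first column holds gene symbols and whose header
#' row names the samples; every other cell must be numeric and finite. The
#' TSV dialect throughout the package is tab-delimited, "." decimal, no
#' quoting, UTF-8. Rows sharing a gene symbol (e.g. multiple probes per
#' symbol) are collapsed by the per-sample maximum by default, the common
#' microarray convention, or by the mean.
#'
#' @param path path to the expression TSV.
#' @param groups named character vector mapping every sample in the header
#'   to \code{"control"} or \code{"case"}; a header sample absent from this
#'   map is a hard error. Pass \code{NULL} for an ungrouped matrix.
#' @param scale scale of the stored values, \code{"log2"} or \code{"linear"}.
#' @param collapse rule for duplicate gene rows, \code{"max"} or
#'   \code{"mean"}.
#' @return An [ExpressionExperiment-class].
#' @seealso [writeExpressionTable()]
#' @export
readExpressionTable <- function(path, groups = NULL,
                                scale = c("log2", "linear"),
                                collapse = c("max", "mean")) {
  scale <- match.arg(scale)
  collapse <- match.arg(collapse)
  raw <- .readTsv(path, colClasses = "character")
  if (ncol(raw) < 2)
    stop("expression table needs a gene column plus >= 1 sample column")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (!is.null(groups)) {
    unknown <- setdiff(samples, names(groups))
    if (length(unknown))
      stop("sample(s) in header but not in group map: ",
           paste(unknown, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    cell <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(.normalizeMinus(cell)))
    bad <- which(!is.finite(num))
    if (length(bad))
      stop(sprintf(
        "non-numeric expression value '%s' at data row %d, sample '%s'",
        cell[bad[1]], bad[1], samples[j]))
    vals[, j] <- num
  }
  if (anyDuplicated(genes)) {
    fun <- if (collapse == "max") max else mean
    vals <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i)
      apply(vals[i, , drop = FALSE], 2, fun)))
    # split() sorts by gene; keep first-appearance order of the file
    vals <- vals[match(unique(genes), rownames(vals)), , drop = FALSE]
  } else {
    rownames(vals) <- genes
  }
  ExpressionExperiment(vals, groups = groups[samples], scale = scale)
}

#' Write an expression matrix as TSV (full precision)
#'
#' Values are written with enough digits that reading the file back
#' reproduces them bit-identically.
#'
#' @param expr an [ExpressionExperiment-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(expr, path) {
  v <- exprValues(expr)
  df <- data.frame(gene = rownames(v), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (s in colnames(v)) df[[s]] <- v[, s]
  .writeTsv(df, path)
  invisible(path)
}

#' Read a sample-to-group map
#'
#' Two-column TSV (sample, group) with header; groups must be
#' \code{control}/\code{case}.
#'
#' @param path path to the TSV.
#' @return named character vector sample -> group.
#' @export
readSampleGroups <- function(path) {
  df <- .readTsv(path, colClasses = "character")
  if (ncol(df) < 2) stop("group file needs columns (sample, group)")
  stats::setNames(df[[2]], df[[1]])
}

#' Read gene catalog and immune gene list
#'
#' The catalog is a two-column TSV (gene, biotype) with header, biotype
#' restricted to \code{mRNA}/\code{lncRNA}. The immune list is
#' ImmPort-style: one gene symbol per row, no header. A gene is flagged
#' immune iff its symbol appears in the immune list; immune-list symbols
#' absent from the catalog are ignored with a warning. Matching is exact
#' and case-sensitive unless \code{uppercase = TRUE}, which upper-cases
#' both sides (convenient for human symbols).
#'
#' @param catalogPath path to the (gene, biotype) TSV.
#' @param immunePath path to the immune gene list; \code{NULL} for none.
#' @param uppercase normalise symbols to upper case before matching.
#' @return A [GeneCatalog-class].
#' @export
readGeneCatalog <- function(catalogPath, immunePath = NULL,
                            uppercase = FALSE) {
  df <- .readTsv(catalogPath, colClasses = "character")
  if (ncol(df) < 2) stop("catalog needs columns (gene, biotype)")
  genes <- df[[1]]; biotype <- df[[2]]
  if (uppercase) genes <- toupper(genes)
  bad <- setdiff(unique(biotype), c("mRNA", "lncRNA"))
  if (length(bad))
    stop("unknown biotype value(s): ", paste(bad, collapse = ", "))
  immune <- character()
  if (!is.null(immunePath)) {
    lines <- readLines(immunePath, encoding = "UTF-8")
    immune <- trimws(lines[nzchar(trimws(lines))])
    if (uppercase) immune <- toupper(immune)
    orphan <- setdiff(immune, genes)
    if (length(orphan))
      warning(length(orphan), " immune-list symbol(s) absent from catalog, ",
              "ignored: ", paste(utils::head(orphan, 5), collapse = ", "))
  }
  GeneCatalog(genes, biotype, genes %in% immune)
}

#' Write a gene catalog (and optionally its immune list) as TSV
#' @param catalog a [GeneCatalog-class].
#' @param catalogPath output path for the (gene, biotype) table.
#' @param immunePath optional output path for the one-symbol-per-row
#'   immune list.
#' @return \code{catalogPath}, invisibly.
#' @export
writeGeneCatalog <- function(catalog, catalogPath, immunePath = NULL) {
  .writeTsv(data.frame(gene = geneIds(catalog),
                       biotype = unname(geneBiotype(catalog)),
                       stringsAsFactors = FALSE), catalogPath)
  if (!is.null(immunePath))
    writeLines(geneIds(catalog)[isImmune(catalog)], immunePath)
  invisible(catalogPath)
}

#' Read a miRNA-gene interaction table
#'
#' Two-column TSV (miRNA, gene) without header, miRcode-style. Duplicate
#' rows are deduplicated; an empty file yields an empty table. A row with
#' a field count other than 2 is an error naming the line.
#'
#' @param path path to the edge file.
#' @return An [InteractionTable-class].
#' @export
readInteractionTable <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(InteractionTable())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2))
    stop(sprintf("malformed interaction row at line %d (expected 2 fields, got %d)",
                 which(nf != 2)[1], nf[nf != 2][1]))
  tab <- InteractionTable(vapply(parts, `[`, "", 1),
                          vapply(parts, `[`, "", 2))
  message(nrow(interactionEdges(tab)), " unique miRNA-gene edges read from ",
          length(lines), " rows")
  tab
}

#' Write a miRNA-gene interaction table as headerless two-column TSV
#' @param interactions an [InteractionTable-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeInteractionTable <- function(interactions, path) {
  e <- interactionEdges(interactions)
  writeLines(paste(e$mirna, e$gene, sep = "\t"), path)
  invisible(path)
}

#' Read a published lncRNA-mRNA correlation table
#'
#' Three-column TSV with header (lncRNA, mRNA, correlation). Unicode minus
#' signs (U+2212), as printed in journal tables, are normalised to the
#' ASCII hyphen before numeric parsing.
#'
#' @param path path to the table.
#' @return data.frame with columns \code{lncrna}, \code{mrna}, \code{r}.
#' @export
readPairCorrelationTable <- function(path) {
  df <- .readTsv(path, colClasses = "character")
  if (ncol(df) < 3)
    stop("pair table needs columns (lncRNA, mRNA, correlation)")
  r <- suppressWarnings(as.numeric(.normalizeMinus(df[[3]])))
  if (anyNA(r))
    stop("non-numeric correlation at data row ", which(is.na(r))[1])
  data.frame(lncrna = df[[1]], mrna = df[[2]], r = r,
             stringsAsFactors = FALSE)
}
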