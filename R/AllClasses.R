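#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Two-group expression container
#'
#' An \code{ExpressionExperiment} holds a genes-by-samples expression matrix
#' (assay \code{"expr"}) together with optional two-group sample labels
#' (\code{colData} column \code{"group"}, levels \code{control}/\code{case})
#' and a scale flag (\code{"log2"} or \code{"linear"}) in the metadata.
#' Group labels are required by the differential-expression and validation
#' machinery; signature-mixture matrices may be ungrouped.
#'
#' @slot .. inherits all slots from
#'   \linkS4class{SummarizedExperiment}.
#' @seealso [ExpressionExperiment()] for construction,
#'   [exprValues()], [sampleGroups()], [exprScale()] for access.
#' @exportClass ExpressionExperiment
setClass("ExpressionExperiment", contains = "SummarizedExperiment")

setValidity("ExpressionExperiment", function(object) {
  msg <- character()
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    return("assay 'expr' is missing")
  v <- SummarizedExperiment::assay(object, "expr")
  if (!is.numeric(v))
    msg <- c(msg, "expression values must be numeric")
  else if (any(!is.finite(v)))
    msg <- c(msg, "expression values must be finite")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be present and unique")
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("log2", "linear"))
    msg <- c(msg, "metadata()$scale must be 'log2' or 'linear'")
  g <- SummarizedExperiment::colData(object)$group
  if (!is.null(g)) {
    if (anyNA(g) || !all(as.character(g) %in% c("control", "case")))
      msg <- c(msg, "group labels must be 'control' or 'case' for every sample")
    else if (any(table(factor(g, levels = c("control", "case"))) < 2))
      msg <- c(msg, "each group needs at least 2 samples")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionExperiment
#'
#' @param values numeric genes-by-samples matrix with unique row (gene) and
#'   column (sample) names; all values finite.
#' @param groups optional named character vector mapping every sample
#'   identifier to \code{"control"} or \code{"case"}. When supplied, each
#'   group must contain at least 2 samples.
#' @param scale \code{"log2"} (default) if values are already on the log2
#'   scale, \code{"linear"} otherwise. Linear input is log2(x+1)-transformed
#'   on the fly by analyses that operate on log expression.
#' @return A validated [ExpressionExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ee <- ExpressionExperiment(m, groups = c(s1 = "control", s2 = "control",
#'                                          s3 = "case", s4 = "case"))
#' @export
ExpressionExperiment <- function(values, groups = NULL,
                                 scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(groups)) {
    if (is.null(names(groups)))
      stop("'groups' must be a named sample -> group vector")
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("sample(s) with no group label: ", paste(missing, collapse = ", "))
    cd$group <- factor(as.character(groups[colnames(values)]),
                       levels = c("control", "case"))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values), colData = cd)
  metadata(se)$scale <- scale
  new("ExpressionExperiment", se)
}

#' Gene catalog: biotype and immune annotation
#'
#' Maps each gene symbol to a biotype (\code{"mRNA"} or \code{"lncRNA"})
#' and an immune-relatedness flag (ImmPort-style membership). Only mRNAs
#' carry direct immune annotation; lncRNAs acquire immune relevance
#' downstream, by co-expression with immune mRNAs.
#'
#' @slot geneId character, unique gene symbols.
#' @slot biotype character, one of \code{"mRNA"}/\code{"lncRNA"} per gene.
#' @slot isImmune logical, immune-list membership per gene.
#' @exportClass GeneCatalog
setClass("GeneCatalog",
         representation(geneId = "character", biotype = "character",
                        isImmune = "logical"))

setValidity("GeneCatalog", function(object) {
  msg <- character()
  n <- length(object@geneId)
  if (length(object@biotype) != n || length(object@isImmune) != n)
    msg <- c(msg, "geneId, biotype and isImmune must have equal length")
  if (anyDuplicated(object@geneId))
    msg <- c(msg, "duplicate gene identifiers in catalog")
  if (!all(object@biotype %in% c("mRNA", "lncRNA")))
    msg <- c(msg, "biotype must be 'mRNA' or 'lncRNA'")
  if (anyNA(object@isImmune))
    msg <- c(msg, "isImmune must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneCatalog
#' @param geneId character vector of unique gene symbols.
#' @param biotype character vector, \code{"mRNA"} or \code{"lncRNA"}.
#' @param isImmune logical vector; defaults to all \code{FALSE}.
#' @return A [GeneCatalog-class].
#' @export
GeneCatalog <- function(geneId, biotype,
                        isImmune = rep(FALSE, length(geneId))) {
  new("GeneCatalog", geneId = as.character(geneId),
      biotype = as.character(biotype), isImmune = as.logical(isImmune))
}

#' Bipartite miRNA-gene interaction table
#'
#' Deduplicated (miRNA, gene) edges, miRcode-style; the gene side may be a
#' lncRNA or an mRNA. Used for the shared-miRNA join of the ceRNA screen.
#'
#' @slot edges data.frame with character columns \code{mirna}, \code{gene}.
#' @exportClass InteractionTable
setClass("InteractionTable", representation(edges = "data.frame"))

setValidity("InteractionTable", function(object) {
  e <- object@edges
  if (!identical(colnames(e), c("mirna", "gene")))
    return("edges must have columns 'mirna', 'gene'")
  if (nrow(e) && anyDuplicated(paste(e$mirna, e$gene, sep = "\r")))
    return("duplicate edges")
  TRUE
})

#' Construct an InteractionTable
#' @param mirna,gene character vectors of equal length; duplicate
#'   (miRNA, gene) rows are collapsed.
#' @return An [InteractionTable-class].
#' @export
InteractionTable <- function(mirna = character(), gene = character()) {
  e <- unique(data.frame(mirna = as.character(mirna),
                         gene = as.character(gene),
                         stringsAsFactors = FALSE))
  rownames(e) <- NULL
  new("InteractionTable", edges = e)
}

#' ceRNA network (lncRNA / miRNA / mRNA tripartite graph)
#'
#' Nodes are typed (\code{lncRNA}, \code{miRNA}, \code{mRNA}); edges link
#' lncRNAs and mRNAs to the miRNAs they share within admitted ceRNA pairs,
#' labelled \code{"lncRNA-miRNA"} / \code{"mRNA-miRNA"}. In a valid
#' non-empty network every miRNA node has degree >= 2 with at least one
#' lncRNA and one mRNA neighbour.
#'
#' @slot nodes data.frame with columns \code{id}, \code{type}.
#' @slot edges data.frame with columns \code{source}, \code{interaction},
#'   \code{target} (source is the lncRNA/mRNA, target the miRNA).
#' @exportClass CeRNANetwork
setClass("CeRNANetwork",
         representation(nodes = "data.frame", edges = "data.frame"))

setValidity("CeRNANetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (!identical(colnames(nd), c("id", "type")))
    return("nodes must have columns 'id', 'type'")
  if (!identical(colnames(ed), c("source", "interaction", "target")))
    return("edges must have columns 'source', 'interaction', 'target'")
  if (!all(nd$type %in% c("lncRNA", "miRNA", "mRNA")))
    return("node type must be lncRNA, miRNA or mRNA")
  if (anyDuplicated(nd$id)) return("duplicate node identifiers")
  if (!all(c(ed$source, ed$target) %in% nd$id))
    return("edge endpoint missing from node table")
  if (!all(ed$interaction %in% c("lncRNA-miRNA", "mRNA-miRNA")))
    return("interaction labels must be 'lncRNA-miRNA' or 'mRNA-miRNA'")
  mir <- nd$id[nd$type == "miRNA"]
  for (m in mir) {
    nb <- ed$source[ed$target == m]
    tp <- nd$type[match(nb, nd$id)]
    if (!("lncRNA" %in% tp && "mRNA" %in% tp))
      return(sprintf("miRNA node '%s' must link >= 1 lncRNA and >= 1 mRNA", m))
  }
  deg <- table(c(ed$source))
  rna <- nd$id[nd$type != "miRNA"]
  if (length(rna) && !all(rna %in% names(deg)))
    return("every lncRNA/mRNA node must participate in >= 1 edge")
  TRUE
})

#' Construct a CeRNANetwork from typed node and edge tables
#' @param nodes data.frame(id, type).
#' @param edges data.frame(source, interaction, target).
#' @return A validated [CeRNANetwork-class].
#' @export
CeRNANetwork <- function(nodes = data.frame(id = character(),
                                            type = character(),
                                            stringsAsFactors = FALSE),
                         edges = data.frame(source = character(),
                                            interaction = character(),
                                            target = character(),
                                            stringsAsFactors = FALSE)) {
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  new("CeRNANetwork", nodes = nodes, edges = edges)
}

#' Per-sample immune-cell fraction estimates
#'
#' Samples-by-cell-types fractions (non-negative, each row summing to 1
#' within 1e-9) plus per-sample fit diagnostics: root-mean-square error of
#' the reconstruction, Pearson correlation of reconstruction with the
#' observed profile, and (when permutations were run) an empirical p-value.
#'
#' @slot fractions numeric matrix, samples x cell types.
#' @slot diagnostics data.frame with columns \code{sample}, \code{rmse},
#'   \code{r_recon}, \code{p_perm} (NA when no permutations were run).
#' @slot method character, the solver used.
#' @exportClass FractionTable
setClass("FractionTable",
         representation(fractions = "matrix", diagnostics = "data.frame",
                        method = "character"))

setValidity("FractionTable", function(object) {
  f <- object@fractions
  if (!is.numeric(f)) return("fractions must be numeric")
  if (nrow(f)) {
    if (any(f < -1e-12)) return("fractions must be non-negative")
    if (any(abs(rowSums(f) - 1) > 1e-9))
      return("each fraction row must sum to 1 (tolerance 1e-9)")
  }
  if (nrow(object@diagnostics) != nrow(f))
    return("diagnostics must have one row per sample")
  TRUE
})

#' Construct a FractionTable
#' @param fractions samples-by-cell-types numeric matrix; rows must sum to 1.
#' @param diagnostics per-sample data.frame (sample, rmse, r_recon, p_perm);
#'   filled with NA when omitted.
#' @param method label of the estimator that produced the fractions.
#' @return A [FractionTable-class].
#' @export
FractionTable <- function(fractions, diagnostics = NULL, method = "none") {
  fractions <- as.matrix(fractions)
  if (is.null(diagnostics))
    diagnostics <- data.frame(sample = rownames(fractions),
                              rmse = NA_real_, r_recon = NA_real_,
                              p_perm = NA_real_, stringsAsFactors = FALSE)
  rownames(diagnostics) <- NULL
  new("FractionTable", fractions = fractions, diagnostics = diagnostics,
      method = method)
}
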