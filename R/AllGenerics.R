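#' @include AllClasses.R
NULL

#' Accessors for the package's S4 containers
#'
#' \code{exprValues} returns the genes-by-samples matrix;
#' \code{sampleGroups} the named control/case factor (NULL when the matrix
#' is ungrouped); \code{exprScale} the \code{"log2"}/\code{"linear"} flag;
#' \code{geneIds}, \code{geneBiotype}, \code{isImmune} the catalog columns;
#' \code{interactionEdges} the deduplicated (mirna, gene) data.frame;
#' \code{networkNodes}/\code{networkEdges} the typed node and edge tables;
#' \code{cellFractions}/\code{fitDiagnostics} the deconvolution output.
#'
#' @param x one of the package's S4 objects.
#' @return See the individual descriptions above.
#' @name accessors
#' @aliases exprValues sampleGroups exprScale geneIds geneBiotype isImmune
#'   interactionEdges networkNodes networkEdges cellFractions fitDiagnostics
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("geneBiotype", function(x) standardGeneric("geneBiotype"))
#' @rdname accessors
#' @export
setGeneric("isImmune", function(x) standardGeneric("isImmune"))
#' @rdname accessors
#' @export
setGeneric("interactionEdges", function(x) standardGeneric("interactionEdges"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("cellFractions", function(x) standardGeneric("cellFractions"))
#' @rdname accessors
#' @export
setGeneric("fitDiagnostics", function(x) standardGeneric("fitDiagnostics"))

#' @rdname accessors
setMethod("exprValues", "ExpressionExperiment", function(x)
  SummarizedExperiment::assay(x, "expr"))

#' @rdname accessors
setMethod("sampleGroups", "ExpressionExperiment", function(x) {
  g <- SummarizedExperiment::colData(x)$group
  if (is.null(g)) return(NULL)
  stats::setNames(g, colnames(x))
})

#' @rdname accessors
setMethod("exprScale", "ExpressionExperiment", function(x)
  S4Vectors::metadata(x)$scale)

#' @rdname accessors
setMethod("geneIds", "GeneCatalog", function(x) x@geneId)
#' @rdname accessors
setMethod("geneBiotype", "GeneCatalog", function(x)
  stats::setNames(x@biotype, x@geneId))
#' @rdname accessors
setMethod("isImmune", "GeneCatalog", function(x)
  stats::setNames(x@isImmune, x@geneId))

#' @rdname accessors
setMethod("interactionEdges", "InteractionTable", function(x) x@edges)

#' @rdname accessors
setMethod("networkNodes", "CeRNANetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "CeRNANetwork", function(x) x@edges)

#' @rdname accessors
setMethod("cellFractions", "FractionTable", function(x) x@fractions)
#' @rdname accessors
setMethod("fitDiagnostics", "FractionTable", function(x) x@diagnostics)

setMethod("show", "ExpressionExperiment", function(object) {
  g <- SummarizedExperiment::colData(object)$group
  cat(sprintf("ExpressionExperiment: %d genes x %d samples (%s scale)\n",
              nrow(object), ncol(object), exprScale(object)))
  if (is.null(g)) cat("  ungrouped samples\n")
  else cat(sprintf("  groups: %d control / %d case\n",
                   sum(g == "control"), sum(g == "case")))
})

setMethod("show", "GeneCatalog", function(object) {
  cat(sprintf("GeneCatalog: %d genes (%d mRNA, %d lncRNA; %d immune-related)\n",
              length(object@geneId), sum(object@biotype == "mRNA"),
              sum(object@biotype == "lncRNA"), sum(object@isImmune)))
})

setMethod("show", "InteractionTable", function(object) {
  cat(sprintf("InteractionTable: %d miRNA-gene edges (%d miRNAs, %d genes)\n",
              nrow(object@edges), length(unique(object@edges$mirna)),
              length(unique(object@edges$gene))))
})

setMethod("show", "CeRNANetwork", function(object) {
  tp <- table(factor(object@nodes$type, c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf(
    "CeRNANetwork: %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges\n",
    nrow(object@nodes), tp["lncRNA"], tp["miRNA"], tp["mRNA"],
    nrow(object@edges)))
})

setMethod("show", "FractionTable", function(object) {
  cat(sprintf("FractionTable (%s): %d samples x %d cell types\n",
              object@method, nrow(object@fractions), ncol(object@fractions)))
})
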