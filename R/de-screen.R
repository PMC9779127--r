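#' Two-group differential expression
#'
#' Per-gene case-vs-control screening on the log2 scale: the log2 fold
#' change is mean(case) - mean(control) of log2 expression (linear input
#' is log2(x+1)-transformed first), the p-value comes from a two-sided
#' Welch t-test (default) or Kruskal-Wallis test, and
#' Benjamini-Hochberg-adjusted p-values are always computed alongside.
#' Genes with zero variance in both groups get p = 1 with a warning
#' (counted, not per-gene). The direction call uses strict inequalities:
#' \code{up} iff log2FC > lfcCutoff and the selected p < alpha, \code{down}
#' symmetrically, \code{none} otherwise.
#'
#' @param expr a grouped [ExpressionExperiment-class].
#' @param method \code{"welch_t"} or \code{"kruskal"}.
#' @param alpha significance threshold for the direction call.
#' @param lfcCutoff |log2 fold change| threshold (strict).
#' @param useAdjusted use BH-adjusted p for the direction call instead of
#'   the raw p (the raw p is the screening default).
#' @return data.frame (one row per gene): \code{gene}, \code{log2fc},
#'   \code{p}, \code{p_adj}, \code{direction}.
#' @examples
#' sim <- simulateTranscriptome(nGenes = 100, nLncrna = 20, seed = 1)
#' deg <- differentialExpression(sim$expr)
#' head(deg[order(deg$p), ])
#' @export
differentialExpression <- function(expr, method = c("welch_t", "kruskal"),
                                   alpha = 0.05, lfcCutoff = 1,
                                   useAdjusted = FALSE) {
  method <- match.arg(method)
  groups <- .assertGrouped(expr)
  v <- .log2Values(expr)
  ctl <- which(groups == "control")
  cas <- which(groups == "case")

  nDegenerate <- 0L
  res <- t(apply(v, 1, function(x) {
    a <- x[cas]; b <- x[ctl]
    lfc <- mean(a) - mean(b)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      nDegenerate <<- nDegenerate + 1L
      return(c(lfc, 1))
    }
    p <- if (method == "welch_t") {
      stats::t.test(a, b, var.equal = FALSE)$p.value
    } else {
      stats::kruskal.test(list(a, b))$p.value
    }
    c(lfc, p)
  }))
  if (nDegenerate > 0L)
    warning(nDegenerate, " gene(s) with zero within-group variance in both ",
            "groups; p set to 1")
  deg <- data.frame(gene = rownames(v), log2fc = res[, 1], p = res[, 2],
                    p_adj = stats::p.adjust(res[, 2], method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(deg) <- NULL
  pSel <- if (useAdjusted) deg$p_adj else deg$p
  deg$direction <- ifelse(pSel < alpha & deg$log2fc > lfcCutoff, "up",
                          ifelse(pSel < alpha & deg$log2fc < -lfcCutoff,
                                 "down", "none"))
  deg
}

#' Classify DEGs into up / down lists
#'
#' Applies the screening thresholds (strict inequalities, boundary genes
#' excluded) and returns the up- and down-regulated gene lists sorted by
#' ascending p-value.
#'
#' @param deg a DEG table from [differentialExpression()].
#' @param alpha significance threshold (> 0).
#' @param lfcCutoff |log2 fold change| threshold (> 0).
#' @param useAdjusted classify on BH-adjusted p instead of raw p.
#' @return list with character vectors \code{up} and \code{down}.
#' @export
classifyDEGs <- function(deg, alpha = 0.05, lfcCutoff = 1,
                         useAdjusted = FALSE) {
  if (alpha <= 0 || lfcCutoff <= 0) stop("thresholds must be positive")
  p <- if (useAdjusted) deg$p_adj else deg$p
  up <- deg[p < alpha & deg$log2fc > lfcCutoff, , drop = FALSE]
  down <- deg[p < alpha & deg$log2fc < -lfcCutoff, , drop = FALSE]
  pSel <- function(d) if (useAdjusted) d$p_adj else d$p
  list(up = up$gene[order(pSel(up), up$gene)],
       down = down$gene[order(pSel(down), down$gene)])
}

#' Principal-component coordinates of the samples
#'
#' PCA of the sample-centered expression matrix (samples as observations,
#' genes as variables), for quality-control projections of the two-group
#' design. Components are ordered by decreasing explained variance.
#'
#' @param expr an [ExpressionExperiment-class] (>= 2 samples).
#' @param nComponents number of components to return (<= number of
#'   samples).
#' @return list with \code{coordinates} (samples x components matrix) and
#'   \code{explained_variance} (ratios, non-increasing, summing to <= 1).
#' @export
pcaCoordinates <- function(expr, nComponents = 2) {
  v <- .log2Values(expr)
  if (ncol(v) < 2) stop("PCA needs >= 2 samples")
  if (nComponents > ncol(v))
    stop("nComponents exceeds the number of samples")
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k < nComponents) {
    # rank-deficient case: pad with exact-zero components
    pad <- matrix(0, nrow(coords), nComponents - k,
                  dimnames = list(rownames(coords),
                                  paste0("PC", (k + 1):nComponents)))
    coords <- cbind(coords, pad)
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = coords,
       explained_variance = ev[seq_len(min(nComponents, length(ev)))])
}
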