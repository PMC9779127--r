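#' Intersect DEGs with the immune annotation
#'
#' Splits a DEG list into the immune-related mRNAs (biotype mRNA and on
#' the immune list) and the candidate lncRNAs (biotype lncRNA). The
#' immune flag applies only to mRNAs: lncRNAs acquire immune relevance
#' downstream, by co-expression with immune mRNAs. Genes absent from the
#' catalog are dropped with a warning.
#'
#' @param degGenes character vector of DEG symbols.
#' @param catalog a [GeneCatalog-class] covering the genes.
#' @return list with character vectors \code{immune_mrnas} and
#'   \code{candidate_lncrnas} (input order preserved).
#' @export
immuneIntersect <- function(degGenes, catalog) {
  if (!length(degGenes)) {
    warning("empty DEG list; returning empty outputs")
    return(list(immune_mrnas = character(), candidate_lncrnas = character()))
  }
  uncovered <- setdiff(degGenes, geneIds(catalog))
  if (length(uncovered)) {
    warning(length(uncovered), " DEG(s) not in catalog, dropped: ",
            paste(utils::head(uncovered, 5), collapse = ", "))
    degGenes <- degGenes[degGenes %in% geneIds(catalog)]
  }
  bt <- geneBiotype(catalog)[degGenes]
  im <- isImmune(catalog)[degGenes]
  list(immune_mrnas = degGenes[bt == "mRNA" & im],
       candidate_lncrnas = degGenes[bt == "lncRNA"])
}

#' All-pairs Pearson co-expression between two gene sets
#'
#' Computes the Pearson product-moment correlation for every (a, b) pair
#' with a in \code{setA}, b in \code{setB}, a != b, across all samples of
#' the matrix (both groups pooled; pass a subset ExpressionExperiment for
#' per-group correlations). Two-sided p-values come from the t
#' distribution with n - 2 df. A zero-variance gene makes r undefined:
#' such records carry r = 0, p = 1 and \code{degenerate = TRUE}, and are
#' excluded from ceRNA admission downstream.
#'
#' @param expr an [ExpressionExperiment-class]; linear-scale input is
#'   log2(x+1)-transformed first.
#' @param setA,setB character vectors of gene symbols present in
#'   \code{expr} (typically candidate lncRNAs and immune mRNAs).
#' @return data.frame: \code{lncrna} (the setA member), \code{mrna} (the
#'   setB member), \code{r}, \code{p_corr}, \code{degenerate}.
#' @export
pairwiseCorrelation <- function(expr, setA, setB) {
  v <- .log2Values(expr)
  missing <- setdiff(c(setA, setB), rownames(v))
  if (length(missing))
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  n <- ncol(v)
  a <- t(v[setA, , drop = FALSE])
  b <- t(v[setB, , drop = FALSE])
  sdA <- apply(a, 2, stats::sd)
  sdB <- apply(b, 2, stats::sd)
  r <- suppressWarnings(stats::cor(a, b))
  degenerate <- outer(sdA == 0, sdB == 0, `|`)
  r[degenerate] <- 0
  rec <- data.frame(
    lncrna = rep(setA, times = length(setB)),
    mrna = rep(setB, each = length(setA)),
    r = as.vector(r),
    p_corr = as.vector(.corrPvalue(r, n)),
    degenerate = as.vector(degenerate),
    stringsAsFactors = FALSE)
  rec$p_corr[rec$degenerate] <- 1
  rec <- rec[rec$lncrna != rec$mrna, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Admit ceRNA pairs by shared miRNAs and positive correlation
#'
#' A (lncRNA, mRNA) pair is admitted iff (1) the two genes share at least
#' one miRNA in the interaction table and (2) their expression correlation
#' exceeds \code{+rThreshold} (the positivity requirement makes the
#' absolute-value cutoff one-sided: negatively correlated pairs are never
#' admitted, however strong). Output is sorted by r descending, ties
#' broken lexicographically by (lncRNA, mRNA) for reproducibility.
#'
#' @param correlations data.frame from [pairwiseCorrelation()].
#' @param interactions an [InteractionTable-class].
#' @param rThreshold admission threshold in (0, 1); strict inequality.
#' @param corrAlpha optional: additionally require the correlation
#'   p-value < \code{corrAlpha} (admission in the base criteria uses r
#'   only).
#' @return data.frame: \code{lncrna}, \code{mrna}, \code{r},
#'   \code{p_corr}, \code{shared_mirnas} (semicolon-joined, sorted),
#'   \code{n_shared}, \code{tier} (\code{"standard"}).
#' @export
buildCeRNAPairs <- function(correlations, interactions, rThreshold = 0.8,
                            corrAlpha = NULL) {
  if (rThreshold <= 0 || rThreshold >= 1)
    stop("rThreshold must be in (0, 1)")
  cand <- correlations[!correlations$degenerate &
                         correlations$r > rThreshold, , drop = FALSE]
  if (!is.null(corrAlpha))
    cand <- cand[cand$p_corr < corrAlpha, , drop = FALSE]
  e <- interactionEdges(interactions)
  mirOf <- split(e$mirna, e$gene)
  shared <- vapply(seq_len(nrow(cand)), function(i) {
    s <- intersect(mirOf[[cand$lncrna[i]]], mirOf[[cand$mrna[i]]])
    if (length(s)) paste(sort(s), collapse = ";") else NA_character_
  }, character(1))
  keep <- !is.na(shared)
  pairs <- data.frame(lncrna = cand$lncrna[keep], mrna = cand$mrna[keep],
                      r = cand$r[keep], p_corr = cand$p_corr[keep],
                      shared_mirnas = shared[keep],
                      stringsAsFactors = FALSE)
  pairs$n_shared <- vapply(strsplit(pairs$shared_mirnas, ";", fixed = TRUE),
                           length, integer(1))
  pairs$tier <- rep("standard", nrow(pairs))
  ord <- order(-pairs$r, pairs$lncrna, pairs$mrna)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' High-stringency tier filter
#'
#' Retains admitted pairs with |r| strictly above the stringency cutoff
#' (0.91 by default) and marks them \code{tier = "high_stringency"}. The
#' cutoff must not be below the admission threshold used upstream, so the
#' filter composes monotonically with admission.
#'
#' @param pairs data.frame from [buildCeRNAPairs()].
#' @param cutoff stringency cutoff on |r| (strict).
#' @return subset of \code{pairs} with updated \code{tier}.
#' @export
stringencyFilter <- function(pairs, cutoff = 0.91) {
  out <- pairs[abs(pairs$r) > cutoff, , drop = FALSE]
  if (nrow(out)) out$tier <- "high_stringency"
  rownames(out) <- NULL
  out
}

#' Assemble the tripartite ceRNA network from admitted pairs
#'
#' Nodes are all lncRNAs, mRNAs and shared miRNAs of the admitted pairs;
#' each shared miRNA m of a pair contributes the edges (lncRNA, m) and
#' (mRNA, m), deduplicated across pairs. By construction every miRNA node
#' links at least one lncRNA and one mRNA.
#'
#' @param pairs data.frame from [buildCeRNAPairs()] (or
#'   [stringencyFilter()]).
#' @return A [CeRNANetwork-class].
#' @export
assembleNetwork <- function(pairs) {
  if (!nrow(pairs)) return(CeRNANetwork())
  edges <- list()
  for (i in seq_len(nrow(pairs))) {
    mirs <- strsplit(pairs$shared_mirnas[i], ";", fixed = TRUE)[[1]]
    edges[[i]] <- rbind(
      data.frame(source = pairs$lncrna[i], interaction = "lncRNA-miRNA",
                 target = mirs, stringsAsFactors = FALSE),
      data.frame(source = pairs$mrna[i], interaction = "mRNA-miRNA",
                 target = mirs, stringsAsFactors = FALSE))
  }
  ed <- unique(do.call(rbind, edges))
  nd <- unique(rbind(
    data.frame(id = pairs$lncrna, type = "lncRNA", stringsAsFactors = FALSE),
    data.frame(id = pairs$mrna, type = "mRNA", stringsAsFactors = FALSE),
    data.frame(id = unique(ed$target), type = "miRNA",
               stringsAsFactors = FALSE)))
  net <- CeRNANetwork(nodes = nd, edges = ed)
  message(sprintf("ceRNA network: %d nodes, %d edges", nrow(nd), nrow(ed)))
  net
}

#' Write admitted ceRNA pairs as TSV
#' @param pairs data.frame from [buildCeRNAPairs()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCeRNAPairs <- function(pairs, path) {
  .writeTsv(pairs, path)
  invisible(path)
}
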