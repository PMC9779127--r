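#' Simulate a two-group transcriptome with planted ceRNA structure
#'
#' Generates log2-scale expression for a control/case design together with
#' a gene catalog, a miRNA-gene interaction table, and the complete ground
#' truth, so that every downstream stage (differential expression, immune
#' intersection, ceRNA admission, cross-cohort validation) can be tested by
#' parameter recovery.
#'
#' The model: each gene g has a baseline mean mu_g ~ N(baselineMean,
#' baselineSd^2); per-sample values add N(0, noiseSd^2) noise on the log2
#' scale. Planted differentially expressed genes shift their case-group
#' mean by their log2 fold change. Each planted ceRNA pair (one lncRNA, one
#' immune mRNA, both up-regulated) shares a latent per-sample factor f ~
#' N(0,1) entering both members with loading lambda = noiseSd*sqrt(r),
#' while the residual noise shrinks to noiseSd*sqrt(1-r); the within-group
#' Pearson correlation is then exactly the target r = lambda^2 /
#' (lambda^2 + residual variance) and the total within-group variance stays
#' at noiseSd^2, so pair members behave like every other planted DE gene in
#' the screen. Three decoy classes are planted alongside: pairs correlated
#' like a true pair but sharing no miRNA (\code{correlated-no-miRNA});
#' pairs sharing a miRNA but with independent noise and opposite DE
#' directions (\code{miRNA-no-correlation}); and pairs sharing a miRNA with
#' a negatively loaded latent factor and opposite DE directions
#' (\code{anti-correlated}). Decoy members carry the same |log2FC| as true
#' planted genes so they survive the DEG and immune screens and exercise
#' the ceRNA admission criteria themselves.
#'
#' @param nControl,nCase samples per group (>= 3); defaults follow an
#'   11-control vs 15-case lung cohort design.
#' @param nGenes total genes, of which \code{nLncrna} are lncRNAs.
#' @param nLncrna number of lncRNA genes.
#' @param nPairs planted ceRNA pairs.
#' @param nDecoys decoy pairs per decoy class.
#' @param nExtraDE additional planted DE genes (random sign) outside the
#'   pair structure.
#' @param deLfc |log2 fold change| of planted DE genes.
#' @param pairR target within-group Pearson correlation of planted pairs,
#'   in (0, 1].
#' @param pairLfc log2 fold change of pair members (set 0 to study the
#'   correlation structure free of the group shift).
#' @param baselineMean,baselineSd distribution of gene baseline means.
#' @param noiseSd within-group standard deviation on the log2 scale.
#' @param immuneFraction fraction of mRNAs carrying the immune flag
#'   (always includes planted/decoy pair mRNAs).
#' @param nDecoyEdges random miRNA-gene edges added to the interaction
#'   table as background.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param truth reuse the ground truth of a previous call (gene roles,
#'   fold changes, interaction table, baseline means) and redraw only the
#'   noise — the way an independent validation cohort from the same
#'   population is simulated.
#' @return list with elements \code{expr}
#'   ([ExpressionExperiment-class], log2 scale), \code{catalog}
#'   ([GeneCatalog-class]), \code{interactions}
#'   ([InteractionTable-class]) and \code{truth} (list: \code{de_genes}
#'   named log2FC vector, \code{planted_pairs} and \code{decoy_pairs}
#'   data.frames, \code{mu} baseline means, \code{params}).
#' @examples
#' sim <- simulateTranscriptome(nGenes = 200, nLncrna = 40, seed = 7)
#' sim$expr
#' @export
simulateTranscriptome <- function(nControl = 11, nCase = 15, nGenes = 1000,
                                  nLncrna = 100, nPairs = 10, nDecoys = 10,
                                  nExtraDE = 40, deLfc = 2, pairR = 0.95,
                                  pairLfc = deLfc, baselineMean = 6,
                                  baselineSd = 1.5, noiseSd = 0.5,
                                  immuneFraction = 0.3, nDecoyEdges = 150,
                                  seed = 1, truth = NULL) {
  if (nControl < 3 || nCase < 3) stop("need >= 3 samples per group")
  set.seed(seed)
  if (is.null(truth)) {
    if (pairR <= 0 || pairR > 1)
      stop("infeasible target correlation: r must be in (0, 1]")
    nMrna <- nGenes - nLncrna
    nUsed <- nPairs + 3L * nDecoys
    if (nUsed > nLncrna || nUsed > nMrna)
      stop("planted pair + decoy count exceeds available lncRNAs or mRNAs")
    lnc <- sprintf("LNC%04d", seq_len(nLncrna))
    mrna <- sprintf("GENE%04d", seq_len(nMrna))

    take <- function(pool, k, offset) pool[offset + seq_len(k)]
    pairLnc <- take(lnc, nPairs, 0)
    pairMrna <- take(mrna, nPairs, 0)
    decoy <- list(
      `correlated-no-miRNA` = list(lnc = take(lnc, nDecoys, nPairs),
                                   mrna = take(mrna, nDecoys, nPairs)),
      `miRNA-no-correlation` = list(lnc = take(lnc, nDecoys, nPairs + nDecoys),
                                    mrna = take(mrna, nDecoys, nPairs + nDecoys)),
      `anti-correlated` = list(lnc = take(lnc, nDecoys, nPairs + 2 * nDecoys),
                               mrna = take(mrna, nDecoys, nPairs + 2 * nDecoys)))

    deGenes <- c(
      stats::setNames(rep(pairLfc, nPairs), pairLnc),
      stats::setNames(rep(pairLfc, nPairs), pairMrna),
      stats::setNames(rep(deLfc, nDecoys), decoy[[1]]$lnc),
      stats::setNames(rep(deLfc, nDecoys), decoy[[1]]$mrna),
      stats::setNames(rep(deLfc, nDecoys), decoy[[2]]$lnc),
      stats::setNames(rep(-deLfc, nDecoys), decoy[[2]]$mrna),
      stats::setNames(rep(deLfc, nDecoys), decoy[[3]]$lnc),
      stats::setNames(rep(-deLfc, nDecoys), decoy[[3]]$mrna))
    free <- setdiff(c(lnc, mrna), names(deGenes))
    extra <- sample(free, min(nExtraDE, length(free)))
    deGenes <- c(deGenes, stats::setNames(
      deLfc * sample(c(-1, 1), length(extra), replace = TRUE), extra))

    # immune flag: all planted/decoy mRNAs plus random mRNAs up to the target
    immune <- c(pairMrna, decoy[[1]]$mrna, decoy[[2]]$mrna, decoy[[3]]$mrna)
    needed <- max(0L, round(immuneFraction * nMrna) - length(immune))
    immune <- c(immune, sample(setdiff(mrna, immune), min(needed, nMrna)))

    # interaction edges: shared miRNAs for planted pairs and the two
    # miRNA-sharing decoy classes; disjoint private miRNAs for the
    # correlated-no-miRNA class; random background edges
    mirCounter <- 0L
    newMir <- function(k) {
      ids <- sprintf("miR-%03d", mirCounter + seq_len(k))
      mirCounter <<- mirCounter + k
      ids
    }
    edges <- list()
    sharedOf <- function(lncs, mrnas, share = TRUE) {
      out <- character(length(lncs))
      for (i in seq_along(lncs)) {
        if (share) {
          m <- newMir(sample(1:2, 1))
          edges[[length(edges) + 1L]] <<- data.frame(
            mirna = rep(m, 2), gene = rep(c(lncs[i], mrnas[i]), each = length(m)),
            stringsAsFactors = FALSE)
          out[i] <- paste(m, collapse = ";")
        } else {
          m1 <- newMir(1); m2 <- newMir(1)
          edges[[length(edges) + 1L]] <<- data.frame(
            mirna = c(m1, m2), gene = c(lncs[i], mrnas[i]),
            stringsAsFactors = FALSE)
          out[i] <- ""
        }
      }
      out
    }
    pairShared <- sharedOf(pairLnc, pairMrna, TRUE)
    sharedOf(decoy[[1]]$lnc, decoy[[1]]$mrna, FALSE)
    decoyShared2 <- sharedOf(decoy[[2]]$lnc, decoy[[2]]$mrna, TRUE)
    decoyShared3 <- sharedOf(decoy[[3]]$lnc, decoy[[3]]$mrna, TRUE)
    bgMir <- sprintf("miR-bg%03d", seq_len(max(1L, nDecoyEdges %/% 5)))
    bg <- data.frame(mirna = sample(bgMir, nDecoyEdges, replace = TRUE),
                     gene = sample(c(lnc, mrna), nDecoyEdges, replace = TRUE),
                     stringsAsFactors = FALSE)
    edgeDf <- unique(do.call(rbind, c(edges, list(bg))))
    # background edges must not create sharing for correlated-no-miRNA decoys
    for (i in seq_len(nDecoys)) {
      l <- decoy[[1]]$lnc[i]; m <- decoy[[1]]$mrna[i]
      ml <- edgeDf$mirna[edgeDf$gene == l]
      shared <- intersect(ml, edgeDf$mirna[edgeDf$gene == m])
      if (length(shared))
        edgeDf <- edgeDf[!(edgeDf$mirna %in% shared & edgeDf$gene == m), ]
    }
    rownames(edgeDf) <- NULL

    mu <- stats::setNames(stats::rnorm(nGenes, baselineMean, baselineSd),
                          c(lnc, mrna))
    truth <- list(
      de_genes = deGenes,
      planted_pairs = data.frame(lncrna = pairLnc, mrna = pairMrna,
                                 target_r = pairR,
                                 shared_mirnas = pairShared,
                                 stringsAsFactors = FALSE),
      decoy_pairs = data.frame(
        lncrna = c(decoy[[1]]$lnc, decoy[[2]]$lnc, decoy[[3]]$lnc),
        mrna = c(decoy[[1]]$mrna, decoy[[2]]$mrna, decoy[[3]]$mrna),
        class = rep(names(decoy), each = nDecoys),
        shared_mirnas = c(rep("", nDecoys), decoyShared2, decoyShared3),
        stringsAsFactors = FALSE),
      edges = edgeDf,
      biotype = stats::setNames(rep(c("lncRNA", "mRNA"), c(nLncrna, nMrna)),
                                c(lnc, mrna)),
      immune = immune,
      mu = mu,
      params = list(pairR = pairR, noiseSd = noiseSd, pairLfc = pairLfc,
                    deLfc = deLfc))
  }

  expr <- .simulateExpression(truth, nControl, nCase)
  catalog <- GeneCatalog(names(truth$biotype), unname(truth$biotype),
                         names(truth$biotype) %in% truth$immune)
  interactions <- InteractionTable(truth$edges$mirna, truth$edges$gene)
  list(expr = expr, catalog = catalog, interactions = interactions,
       truth = truth)
}

# draw one expression matrix from a fixed ground truth (noise only)
.simulateExpression <- function(truth, nControl, nCase) {
  genes <- names(truth$biotype)
  n <- nControl + nCase
  samples <- c(sprintf("CTRL%02d", seq_len(nControl)),
               sprintf("CASE%02d", seq_len(nCase)))
  groups <- stats::setNames(rep(c("control", "case"), c(nControl, nCase)),
                            samples)
  sigma <- truth$params$noiseSd
  r <- truth$params$pairR
  lambda <- sigma * sqrt(r)
  resid <- sigma * sqrt(1 - r)

  vals <- matrix(stats::rnorm(length(genes) * n, 0, sigma),
                 nrow = length(genes), ncol = n,
                 dimnames = list(genes, samples))
  # latent factors overwrite the iid noise of coupled pair members
  couple <- function(lncs, mrnas, signMrna) {
    for (i in seq_along(lncs)) {
      f <- stats::rnorm(n)
      vals[lncs[i], ] <<- lambda * f + stats::rnorm(n, 0, resid)
      vals[mrnas[i], ] <<- signMrna * lambda * f + stats::rnorm(n, 0, resid)
    }
  }
  pp <- truth$planted_pairs
  couple(pp$lncrna, pp$mrna, 1)
  dp <- truth$decoy_pairs
  corA <- dp[dp$class == "correlated-no-miRNA", ]
  couple(corA$lncrna, corA$mrna, 1)
  anti <- dp[dp$class == "anti-correlated", ]
  couple(anti$lncrna, anti$mrna, -1)

  vals <- vals + truth$mu[genes]
  caseCols <- which(groups == "case")
  de <- truth$de_genes
  vals[names(de), caseCols] <- vals[names(de), caseCols] + de
  ExpressionExperiment(vals, groups = groups, scale = "log2")
}

#' Simulate bulk mixtures from a cell-type signature matrix
#'
#' Per-sample cell-type fractions are drawn from a symmetric Dirichlet
#' (concentration \code{concentration}); each linear-scale sample profile
#' is signature %*% fractions plus additive Gaussian noise truncated at 0.
#'
#' @param signature marker-genes x cell-types numeric matrix (>= 2 cell
#'   types, unique marker rownames, no all-zero column).
#' @param nSamples number of mixture samples.
#' @param noiseSd standard deviation of the additive linear-scale noise
#'   (must be >= 0).
#' @param concentration symmetric Dirichlet concentration (1 = uniform
#'   over the simplex).
#' @param fractions optional samples x cell-types matrix of fractions to
#'   use instead of Dirichlet draws (rows must sum to 1).
#' @param seed integer seed.
#' @return list with \code{expr} (linear-scale ungrouped
#'   [ExpressionExperiment-class]) and \code{fractions} (the true
#'   [FractionTable-class]).
#' @examples
#' sig <- syntheticSignature(seed = 1)
#' mix <- simulateMixtures(sig, nSamples = 5, noiseSd = 1, seed = 2)
#' cellFractions(mix$fractions)
#' @export
simulateMixtures <- function(signature, nSamples = 50, noiseSd = 0,
                             concentration = 1, fractions = NULL, seed = 1) {
  .checkSignature(signature)
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  set.seed(seed)
  k <- ncol(signature)
  if (is.null(fractions)) {
    fractions <- .rdirichlet(nSamples, rep(concentration, k))
  } else {
    fractions <- as.matrix(fractions)
    if (ncol(fractions) != k) stop("fractions must have one column per cell type")
    fractions <- fractions / rowSums(fractions)
    nSamples <- nrow(fractions)
  }
  colnames(fractions) <- colnames(signature)
  rownames(fractions) <- sprintf("MIX%03d", seq_len(nSamples))
  m <- signature %*% t(fractions)
  if (noiseSd > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, noiseSd), nrow(m), ncol(m))
  m <- pmax(m, 0)
  expr <- ExpressionExperiment(m, groups = NULL, scale = "linear")
  list(expr = expr, fractions = FractionTable(fractions, method = "truth"))
}

#' Generate a small synthetic cell-type signature matrix
#'
#' Block-structured marker matrix: each cell type has a set of markers
#' expressed high in that type and low elsewhere — a miniature stand-in
#' for an LM22-style signature, used in examples and simulations.
#'
#' @param nTypes number of cell types (>= 2).
#' @param markersPerType markers per cell type.
#' @param highMean,lowMean linear-scale expression of a marker in its own
#'   vs other cell types.
#' @param seed integer seed.
#' @return marker-genes x cell-types numeric matrix.
#' @export
syntheticSignature <- function(nTypes = 5, markersPerType = 10,
                               highMean = 100, lowMean = 10, seed = 1) {
  if (nTypes < 2) stop("need >= 2 cell types")
  set.seed(seed)
  types <- sprintf("CellType%s", LETTERS[seq_len(nTypes)])
  markers <- as.vector(vapply(seq_len(nTypes), function(j)
    sprintf("MK_%s_%02d", LETTERS[j], seq_len(markersPerType)),
    character(markersPerType)))
  sig <- matrix(stats::runif(length(markers) * nTypes,
                             0.5 * lowMean, 1.5 * lowMean),
                nrow = length(markers), ncol = nTypes,
                dimnames = list(markers, types))
  for (j in seq_len(nTypes)) {
    rows <- (j - 1) * markersPerType + seq_len(markersPerType)
    sig[rows, j] <- stats::runif(markersPerType, 0.8 * highMean,
                                 1.2 * highMean)
  }
  sig
}

#' Read / write a signature matrix TSV
#'
#' First column \code{gene}, remaining columns one per cell type.
#'
#' @param path file path.
#' @return \code{readSignatureMatrix}: marker x cell-type numeric matrix.
#' @export
readSignatureMatrix <- function(path) {
  df <- .readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  .checkSignature(m)
  m
}

#' @rdname readSignatureMatrix
#' @param signature marker x cell-type numeric matrix.
#' @export
writeSignatureMatrix <- function(signature, path) {
  df <- data.frame(gene = rownames(signature), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (s in colnames(signature)) df[[s]] <- signature[, s]
  .writeTsv(df, path)
  invisible(path)
}

.checkSignature <- function(signature) {
  if (!is.matrix(signature) || !is.numeric(signature))
    stop("signature must be a numeric matrix")
  if (ncol(signature) < 2) stop("signature needs >= 2 cell types")
  if (is.null(rownames(signature)) || anyDuplicated(rownames(signature)))
    stop("signature marker genes must be named and unique")
  if (any(colSums(abs(signature)) == 0))
    stop("signature has an all-zero cell-type column")
  invisible(TRUE)
}
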