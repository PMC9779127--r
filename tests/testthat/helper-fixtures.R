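# shared builders for small deterministic fixtures

toyExpr <- function(values, nControl = 2, nCase = 2, scale = "log2") {
  n <- nControl + nCase
  stopifnot(ncol(values) == n)
  samples <- sprintf("S%02d", seq_len(n))
  colnames(values) <- samples
  groups <- stats::setNames(rep(c("control", "case"), c(nControl, nCase)),
                            samples)
  ExpressionExperiment(values, groups = groups, scale = scale)
}

pairKey <- function(df) paste(df$lncrna, df$mrna, sep = "\r")

# exhaustive double-loop ceRNA admission, the brute-force oracle kept
# independent of buildCeRNAPairs()
bruteForcePairs <- function(correlations, interactions, rThreshold) {
  e <- interactionEdges(interactions)
  out <- list()
  for (i in seq_len(nrow(correlations))) {
    rec <- correlations[i, ]
    if (rec$degenerate || rec$r <= rThreshold) next
    ml <- e$mirna[e$gene == rec$lncrna]
    mm <- e$mirna[e$gene == rec$mrna]
    shared <- sort(intersect(ml, mm))
    if (!length(shared)) next
    out[[length(out) + 1L]] <- data.frame(
      lncrna = rec$lncrna, mrna = rec$mrna, r = rec$r,
      shared_mirnas = paste(shared, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(lncrna = character(), mrna = character(),
                      r = numeric(), shared_mirnas = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(-res$r, res$lncrna, res$mrna), , drop = FALSE]
}

# hand-rolled product-moment correlation, the formula oracle
pearsonOracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

fixturePath <- function(name) system.file("extdata", name,
                                          package = "immuneCeRNA")

# random lncRNA/mRNA screening instance with planted correlated pairs
makeRandomInstance <- function(seed, nLnc = 8, nMrna = 12, nSamples = 10,
                               nMir = 6, nEdges = 40) {
  set.seed(seed)
  lnc <- sprintf("L%02d", 1:nLnc)
  mrna <- sprintf("M%02d", 1:nMrna)
  m <- matrix(rnorm((nLnc + nMrna) * nSamples, 6, 1), ncol = nSamples,
              dimnames = list(c(lnc, mrna), sprintf("s%02d", 1:nSamples)))
  # plant a few strongly correlated pairs so admission is non-trivial
  for (i in 1:3) m[mrna[i], ] <- m[lnc[i], ] + rnorm(nSamples, 0, 0.1)
  mir <- sprintf("miR-%d", 1:nMir)
  tab <- InteractionTable(sample(mir, nEdges, replace = TRUE),
                          sample(c(lnc, mrna), nEdges, replace = TRUE))
  list(expr = ExpressionExperiment(m), lnc = lnc, mrna = mrna,
       interactions = tab)
}
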