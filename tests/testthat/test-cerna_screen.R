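test_that("immune intersection splits DEGs by biotype and immune flag", {
  cat3 <- GeneCatalog(c("RABEP1", "JPX", "ACTB"),
                      c("mRNA", "lncRNA", "mRNA"),
                      c(TRUE, FALSE, FALSE))
  ii <- immuneIntersect(c("RABEP1", "JPX", "ACTB"), cat3)
  expect_identical(ii$immune_mrnas, "RABEP1")
  expect_identical(ii$candidate_lncrnas, "JPX")
  # no immune genes anywhere -> empty immune mRNAs
  cat0 <- GeneCatalog(c("A", "B"), c("mRNA", "mRNA"))
  expect_length(immuneIntersect(c("A", "B"), cat0)$immune_mrnas, 0)
  expect_warning(immuneIntersect(character(), cat3), "empty")
  expect_warning(immuneIntersect(c("RABEP1", "GHOST"), cat3), "GHOST")
})

test_that("immune intersection equals the brute-force set algebra", {
  set.seed(12)
  genes <- sprintf("G%03d", 1:80)
  bt <- sample(c("mRNA", "lncRNA"), 80, replace = TRUE)
  im <- sample(c(TRUE, FALSE), 80, replace = TRUE) & bt == "mRNA"
  cat <- GeneCatalog(genes, bt, im)
  degs <- sample(genes, 50)
  ii <- immuneIntersect(degs, cat)
  expect_setequal(ii$immune_mrnas,
                  intersect(degs, genes[bt == "mRNA" & im]))
  expect_setequal(ii$candidate_lncrnas,
                  intersect(degs, genes[bt == "lncRNA"]))
})

test_that("pairwise correlation matches the product-moment formula", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  m <- rbind(L1 = x, L2 = -x + 10, M1 = y, M2 = x, MC = rep(3, 5))
  colnames(m) <- paste0("s", 1:5)
  ee <- ExpressionExperiment(m)
  rec <- pairwiseCorrelation(ee, c("L1", "L2"), c("M1", "M2", "MC"))
  pick <- function(a, b) rec[rec$lncrna == a & rec$mrna == b, ]
  expect_equal(pick("L1", "M1")$r, pearsonOracle(x, y), tolerance = 1e-12)
  expect_equal(pick("L1", "M2")$r, 1, tolerance = 1e-12)   # y = x
  expect_equal(pick("L2", "M2")$r, -1, tolerance = 1e-12)  # y = -x
  # p-value agrees with the t-distribution route of cor.test
  expect_equal(pick("L1", "M1")$p_corr, cor.test(x, y)$p.value,
               tolerance = 1e-10)
  # zero-variance gene flagged degenerate with r = 0
  expect_true(pick("L1", "MC")$degenerate)
  expect_equal(pick("L1", "MC")$r, 0)
  expect_error(pairwiseCorrelation(ee, "L1", "NOPE"), "NOPE")
})

test_that("ceRNA admission equals exhaustive enumeration on random instances", {
  for (seed in c(1, 2, 3)) {
    inst <- makeRandomInstance(seed)
    cors <- pairwiseCorrelation(inst$expr, inst$lnc, inst$mrna)
    got <- buildCeRNAPairs(cors, inst$interactions, rThreshold = 0.8)
    want <- bruteForcePairs(cors, inst$interactions, rThreshold = 0.8)
    expect_equal(nrow(got), nrow(want))
    expect_identical(pairKey(got), pairKey(want))
    expect_identical(got$shared_mirnas, want$shared_mirnas)
    expect_equal(got$r, want$r, tolerance = 1e-15)
  }
})

test_that("ceRNA admission honours both criteria and positivity", {
  m <- rbind(JPX = c(1, 2, 3, 4, 5, 6),
             RABEP1 = c(1.1, 2.2, 2.9, 4.2, 4.9, 6.1),
             NEG = c(6, 5, 4, 3, 2, 1.2),
             LONER = c(1, 2.2, 2.8, 4.1, 5.2, 5.9))
  colnames(m) <- paste0("s", 1:6)
  ee <- ExpressionExperiment(m)
  tab <- InteractionTable(c("miR-145", "miR-145", "miR-24", "miR-24"),
                          c("JPX", "RABEP1", "JPX", "NEG"))
  cors <- pairwiseCorrelation(ee, "JPX", c("RABEP1", "NEG", "LONER"))
  pairs <- buildCeRNAPairs(cors, tab)
  # strong positive correlation + shared miRNA -> admitted
  expect_identical(pairs$lncrna, "JPX")
  expect_identical(pairs$mrna, "RABEP1")
  expect_identical(pairs$shared_mirnas, "miR-145")
  # LONER: r > 0.99 but no shared miRNA -> rejected
  expect_false("LONER" %in% pairs$mrna)
  # NEG: shares miR-24 but strongly anti-correlated -> rejected
  expect_false("NEG" %in% pairs$mrna)
  expect_error(buildCeRNAPairs(cors, tab, rThreshold = 1.5), "rThreshold")
})

test_that("admitted pairs are ordered by r with lexicographic tie-breaks", {
  cors <- data.frame(
    lncrna = c("L2", "L1", "L1"), mrna = c("M1", "M2", "M1"),
    r = c(0.9, 0.9, 0.95), p_corr = 0.001, degenerate = FALSE,
    stringsAsFactors = FALSE)
  tab <- InteractionTable(rep("miR-1", 4), c("L1", "L2", "M1", "M2"))
  pairs <- buildCeRNAPairs(cors, tab)
  expect_identical(paste(pairs$lncrna, pairs$mrna),
                   c("L1 M1", "L1 M2", "L2 M1"))
})

test_that("the stringency tier composes monotonically", {
  pairs <- data.frame(
    lncrna = c("JPX", "L2", "L3"), mrna = c("RABEP1", "M2", "M3"),
    r = c(0.952570119, 0.905, 0.92), p_corr = 1e-5,
    shared_mirnas = "miR-1", n_shared = 1L, tier = "standard",
    stringsAsFactors = FALSE)
  hs <- stringencyFilter(pairs, 0.91)
  expect_true("JPX" %in% hs$lncrna)       # r = 0.952570119 retained
  expect_false("L2" %in% hs$lncrna)       # r = 0.905 dropped
  expect_true(all(hs$tier == "high_stringency"))
  expect_true(all(pairKey(hs) %in% pairKey(pairs)))
  # filtering at 0.8 then 0.91 is the same as 0.91 directly
  expect_identical(stringencyFilter(stringencyFilter(pairs, 0.8), 0.91)$r,
                   stringencyFilter(pairs, 0.91)$r)
})

test_that("network assembly produces a valid tripartite graph", {
  one <- data.frame(lncrna = "L", mrna = "M", r = 0.95, p_corr = 1e-4,
                    shared_mirnas = "miR-9", n_shared = 1L,
                    tier = "standard", stringsAsFactors = FALSE)
  net <- suppressMessages(assembleNetwork(one))
  expect_equal(nrow(networkNodes(net)), 3)
  expect_equal(nrow(networkEdges(net)), 2)
  # every miRNA node of an arbitrary admitted set has degree >= 2
  inst <- makeRandomInstance(4)
  cors <- pairwiseCorrelation(inst$expr, inst$lnc, inst$mrna)
  pairs <- buildCeRNAPairs(cors, inst$interactions, rThreshold = 0.7)
  if (nrow(pairs)) {
    net <- suppressMessages(assembleNetwork(pairs))
    ed <- networkEdges(net)
    for (mir in networkNodes(net)$id[networkNodes(net)$type == "miRNA"])
      expect_gte(sum(ed$target == mir), 2)
  }
  expect_equal(nrow(networkNodes(assembleNetwork(one[0, ]))), 0)
})

test_that("screening on the default synthetic design recovers the truth", {
  recov <- numeric(0); admit <- numeric(0)
  for (seed in 1:5) {
    sim <- simulateTranscriptome(seed = seed)
    deg <- differentialExpression(sim$expr)
    cls <- classifyDEGs(deg)
    ii <- immuneIntersect(c(cls$up, cls$down), sim$catalog)
    cors <- pairwiseCorrelation(sim$expr, ii$candidate_lncrnas,
                                ii$immune_mrnas)
    pairs <- buildCeRNAPairs(cors, sim$interactions)
    recov <- c(recov, mean(pairKey(sim$truth$planted_pairs) %in%
                             pairKey(pairs)))
    admit <- c(admit, mean(pairKey(sim$truth$decoy_pairs) %in%
                             pairKey(pairs)))
  }
  expect_gte(mean(recov), 0.9)
  expect_lte(mean(admit), 0.1)
})
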