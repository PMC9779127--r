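test_that("noise-free mixtures are recovered exactly", {
  sig <- syntheticSignature(nTypes = 4, markersPerType = 8, seed = 1)
  # pure sample -> fraction 1 at that type
  pure <- simulateMixtures(sig, fractions = matrix(c(0, 0, 1, 0), 1),
                           noiseSd = 0)
  f <- cellFractions(estimateFractions(pure$expr, sig))
  expect_equal(unname(f[1, ]), c(0, 0, 1, 0), tolerance = 1e-6)
  # 50/50 two-type mixture
  half <- simulateMixtures(sig, fractions = matrix(c(0.5, 0.5, 0, 0), 1),
                           noiseSd = 0)
  f <- cellFractions(estimateFractions(half$expr, sig))
  expect_equal(unname(f[1, ]), c(0.5, 0.5, 0, 0), tolerance = 1e-9)
})

test_that("both solvers recover noisy Dirichlet mixtures and agree", {
  sig <- syntheticSignature(nTypes = 5, markersPerType = 10, seed = 2)
  mix <- simulateMixtures(sig, nSamples = 50, noiseSd = 2, seed = 3)
  truth <- cellFractions(mix$fractions)
  fN <- estimateFractions(mix$expr, sig, method = "nnls")
  fS <- estimateFractions(mix$expr, sig, method = "nu_svr")
  expect_lte(mean(abs(cellFractions(fN) - truth)), 0.05)
  expect_lte(mean(abs(cellFractions(fS) - truth)), 0.05)
  expect_lte(mean(abs(cellFractions(fN) - cellFractions(fS))), 0.05)
  for (ft in list(fN, fS)) {
    f <- cellFractions(ft)
    expect_true(all(f >= 0))
    expect_true(all(abs(rowSums(f) - 1) <= 1e-9))
  }
})

test_that("marker coverage and degenerate profiles are rejected", {
  sig <- syntheticSignature(nTypes = 3, markersPerType = 6, seed = 4)
  mix <- simulateMixtures(sig, nSamples = 3, seed = 5)
  v <- exprValues(mix$expr)
  few <- v[seq_len(8), , drop = FALSE]  # 8/18 markers < 50%
  expect_error(estimateFractions(few, sig), "50%")
  zero <- v; zero[, 2] <- 0
  expect_error(estimateFractions(zero, sig), "all-zero")
})

test_that("permutation p-values are bounded and track fit quality", {
  sig <- syntheticSignature(nTypes = 4, markersPerType = 8, seed = 6)
  mix <- simulateMixtures(sig, nSamples = 2, noiseSd = 1, seed = 7)
  v <- exprValues(mix$expr)
  # append a pure-noise sample unrelated to the signature
  set.seed(8)
  v <- cbind(v, NOISE = runif(nrow(v), 0, 200))
  ft <- estimateFractions(v, sig, nPerm = 60, seed = 9)
  d <- fitDiagnostics(ft)
  expect_true(all(d$p_perm >= 1 / 61 & d$p_perm <= 1))
  # true mixtures reconstruct better than random-gene profiles
  expect_lt(max(d$p_perm[1:2]), 0.1)
  expect_gt(d$p_perm[3], max(d$p_perm[1:2]) - 1e-12)
  # no permutations -> diagnostics omitted as NA
  expect_true(all(is.na(fitDiagnostics(
    estimateFractions(v, sig, nPerm = 0))$p_perm)))
})

test_that("group comparison of fractions flags the shifted cell type", {
  sig <- syntheticSignature(nTypes = 5, seed = 10)
  hits <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    base <- immuneCeRNA:::.rdirichlet(26, rep(5, 5))
    base[12:26, 1] <- base[12:26, 1] + 0.2   # cases enriched in type 1
    base <- base / rowSums(base)
    rownames(base) <- sprintf("S%02d", 1:26)
    colnames(base) <- colnames(sig)
    groups <- stats::setNames(rep(c("control", "case"), c(11, 15)),
                              rownames(base))
    res <- compareCellFractions(FractionTable(base), groups)
    if (res$p[res$cell_type == colnames(sig)[1]] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("group comparison is order-invariant and null-calibrated", {
  set.seed(20)
  f <- immuneCeRNA:::.rdirichlet(12, rep(2, 4))
  # cases are an exact copy of controls -> no signal, p = 1 everywhere
  f[7:12, ] <- f[1:6, ]
  rownames(f) <- sprintf("S%02d", 1:12)
  colnames(f) <- paste0("T", 1:4)
  groups <- stats::setNames(rep(c("control", "case"), each = 6),
                            rownames(f))
  res <- compareCellFractions(FractionTable(f), groups)
  expect_true(all(res$p > 0.99))
  # permuting sample order changes nothing
  perm <- sample(rownames(f))
  res2 <- compareCellFractions(FractionTable(f[perm, ]), groups)
  expect_equal(res$p, res2$p, tolerance = 1e-12)
  # constant column warns with p = 1 for that column only
  t1 <- 0.75 * f[, 1] / (f[, 1] + f[, 2])
  fc2 <- cbind(T1 = t1, T2 = 0.75 - t1, K = rep(0.25, 12))
  rownames(fc2) <- rownames(f)
  expect_warning(res3 <- compareCellFractions(FractionTable(fc2), groups),
                 "constant")
  expect_equal(res3$p[res3$cell_type == "K"], 1)
})

test_that("cell-type correlation grids have the expected structure", {
  set.seed(30)
  f <- immuneCeRNA:::.rdirichlet(20, rep(1, 4))
  rownames(f) <- sprintf("S%02d", 1:20); colnames(f) <- paste0("T", 1:4)
  cc <- celltypeCorrelations(FractionTable(f))
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 4))
  # element-wise brute-force Pearson oracle
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(cc[i, j], pearsonOracle(f[, i], f[, j]), tolerance = 1e-12)
  # two-type tables are perfectly anti-correlated off the diagonal
  f2 <- cbind(T1 = f[, 1], T2 = 1 - f[, 1])
  cc2 <- celltypeCorrelations(FractionTable(f2))
  expect_equal(cc2[1, 2], -1, tolerance = 1e-12)
  expect_error(celltypeCorrelations(FractionTable(f2[1:2, ])), ">= 3")
})

test_that("pair-fraction association finds engineered dependencies", {
  set.seed(40)
  n <- 20
  x <- rnorm(n, 6, 1)       # lncRNA expression, log2
  y <- x + rnorm(n, 0, 0.2) # mRNA tracks it
  m <- rbind(JPX = x, RABEP1 = y)
  colnames(m) <- sprintf("S%02d", 1:n)
  ee <- ExpressionExperiment(m)
  # fraction column T1 is an affine image of the lncRNA -> r = 1
  t1 <- (x - min(x) + 0.5) / (2 * (max(x) - min(x)) + 1)
  f <- cbind(T1 = t1, T2 = (1 - t1) / 2, T3 = (1 - t1) / 2)
  rownames(f) <- colnames(m)
  res <- pairFractionAssociation(ee, list(lncrna = "JPX", mrna = "RABEP1"),
                                 FractionTable(f))
  expect_equal(nrow(res), 9)                    # 3 members x 3 cell types
  expect_equal(res$r[res$member == "JPX" & res$cell_type == "T1"], 1,
               tolerance = 1e-12)
  expect_true(all(c("JPX", "RABEP1", "pair_mean") %in% res$member))
  expect_true(all(res$p_adj >= res$p - 1e-15))
  # sample mismatch is an error naming the offender
  f2 <- f; rownames(f2)[1] <- "GHOST"
  expect_error(pairFractionAssociation(ee, list(lncrna = "JPX",
                                                mrna = "RABEP1"),
                                       FractionTable(f2)), "GHOST")
})

test_that("independent noise fractions show no systematic association", {
  rs <- numeric(0)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 24
    m <- rbind(L = rnorm(n, 6, 1), M = rnorm(n, 6, 1))
    colnames(m) <- sprintf("S%02d", 1:n)
    f <- immuneCeRNA:::.rdirichlet(n, rep(1, 4))
    rownames(f) <- colnames(m); colnames(f) <- paste0("T", 1:4)
    res <- pairFractionAssociation(ExpressionExperiment(m),
                                   list(lncrna = "L", mrna = "M"),
                                   FractionTable(f))
    rs <- c(rs, res$r)
  }
  expect_lt(mean(abs(rs)), 0.25)
  expect_gt(min(rs), -0.9); expect_lt(max(rs), 0.9)
})
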