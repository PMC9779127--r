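#' Estimate immune-cell fractions from a signature matrix
#'
#' CIBERSORT-style signature regression: for each sample the profile is
#' restricted to the signature's marker genes, a non-negative solution is
#' found either directly by non-negative least squares (\code{"nnls"},
#' the fast default) or by a linear nu-support-vector-regression ensemble
#' (\code{"nu_svr"}: nu in \{0.25, 0.5, 0.75\}, the lowest-RMSE fit kept,
#' negative coefficients clamped to 0), and the coefficients are
#' renormalised to sum to 1. With \code{nPerm > 0} an empirical p-value
#' is attached per sample: profiles of random genes drawn from the whole
#' expression matrix are refit, and p = (1 + #\{permuted reconstruction
#' correlation >= observed\}) / (nPerm + 1).
#'
#' Standardisation (z-scoring the marker vectors, as in the published
#' SVR scheme) defaults to on for \code{nu_svr} and off for \code{nnls};
#' the unstandardised NNLS route recovers noise-free mixtures exactly.
#'
#' @param expr an [ExpressionExperiment-class] or plain genes x samples
#'   matrix; log2-scale input is converted back to the linear scale.
#' @param signature marker-genes x cell-types matrix. At least 50% of its
#'   markers must be present in \code{expr}, else an error.
#' @param method \code{"nnls"} or \code{"nu_svr"}.
#' @param nPerm permutations for the empirical p (0 = skip).
#' @param seed integer seed for the permutations.
#' @param standardize z-score the marker vectors before fitting;
#'   \code{NULL} picks the method default described above.
#' @return A [FractionTable-class] (samples x cell types; rows sum to 1).
#' @examples
#' sig <- syntheticSignature(seed = 1)
#' mix <- simulateMixtures(sig, nSamples = 4, seed = 2)
#' cellFractions(estimateFractions(mix$expr, sig))
#' @export
estimateFractions <- function(expr, signature, method = c("nnls", "nu_svr"),
                              nPerm = 0, seed = 1, standardize = NULL) {
  method <- match.arg(method)
  if (is.null(standardize)) standardize <- method == "nu_svr"
  .checkSignature(signature)
  v <- if (is(expr, "ExpressionExperiment")) .linearValues(expr)
       else as.matrix(expr)
  common <- intersect(rownames(signature), rownames(v))
  if (length(common) < 0.5 * nrow(signature))
    stop(sprintf("only %d/%d signature marker genes present in expression (>= 50%% required)",
                 length(common), nrow(signature)))
  S <- signature[common, , drop = FALSE]
  M <- v[common, , drop = FALSE]
  if (any(colSums(abs(M)) == 0)) stop("all-zero sample profile")
  set.seed(seed)
  allValues <- as.vector(v)

  fitOne <- function(y) {
    if (standardize) {
      Sz <- (S - mean(S)) / stats::sd(S)
      yz <- (y - mean(y)) / stats::sd(y)
    } else {
      Sz <- S; yz <- y
    }
    if (method == "nnls") {
      w <- pracma::lsqnonneg(Sz, yz)$x
    } else {
      best <- NULL; bestRmse <- Inf
      for (nu in c(0.25, 0.5, 0.75)) {
        fit <- e1071::svm(x = Sz, y = yz, type = "nu-regression",
                          kernel = "linear", nu = nu, scale = FALSE)
        w <- drop(t(fit$coefs) %*% fit$SV)
        rmse <- sqrt(mean((drop(Sz %*% w) - yz)^2))
        if (rmse < bestRmse) { bestRmse <- rmse; best <- w }
      }
      w <- pmax(best, 0)
    }
    recon <- drop(Sz %*% w)
    list(w = w, rmse = sqrt(mean((recon - yz)^2)),
         r = if (stats::sd(recon) == 0) 0 else stats::cor(recon, yz))
  }

  k <- ncol(S)
  frac <- matrix(0, ncol(M), k,
                 dimnames = list(colnames(M), colnames(S)))
  diagn <- data.frame(sample = colnames(M), rmse = NA_real_,
                      r_recon = NA_real_, p_perm = NA_real_,
                      stringsAsFactors = FALSE)
  for (j in seq_len(ncol(M))) {
    fit <- fitOne(M[, j])
    w <- fit$w
    if (sum(w) == 0) {
      warning("sample '", colnames(M)[j],
              "': all-zero coefficient vector; uniform fractions returned")
      w <- rep(1, k)
    }
    frac[j, ] <- w / sum(w)
    diagn$rmse[j] <- fit$rmse
    diagn$r_recon[j] <- fit$r
    if (nPerm > 0) {
      rPerm <- vapply(seq_len(nPerm), function(b) {
        fitOne(sample(allValues, length(common)))$r
      }, numeric(1))
      diagn$p_perm[j] <- (1 + sum(rPerm >= fit$r)) / (nPerm + 1)
    }
  }
  FractionTable(frac, diagn, method = method)
}

#' Compare cell-type fractions between groups
#'
#' One Kruskal-Wallis (default) or Wilcoxon rank-sum test per cell type
#' on its fraction column, control vs case, with BH adjustment across
#' cell types. A constant column gets p = 1 with a warning.
#'
#' @param fractions a [FractionTable-class].
#' @param groups named character vector sample -> control/case covering
#'   all fraction rows.
#' @param test \code{"kruskal"} or \code{"wilcoxon"}.
#' @return data.frame: \code{cell_type}, \code{statistic}, \code{p},
#'   \code{p_adj}.
#' @export
compareCellFractions <- function(fractions, groups,
                                 test = c("kruskal", "wilcoxon")) {
  test <- match.arg(test)
  f <- cellFractions(fractions)
  g <- factor(as.character(groups[rownames(f)]),
              levels = c("control", "case"))
  if (anyNA(g)) stop("every fraction row needs a group label")
  if (length(unique(g)) < 2) stop("both groups must be represented")
  rows <- lapply(colnames(f), function(ct) {
    x <- f[, ct]
    if (stats::sd(x) == 0) {
      warning("constant fraction column '", ct, "'; p set to 1")
      return(data.frame(cell_type = ct, statistic = NA_real_, p = 1,
                        stringsAsFactors = FALSE))
    }
    if (test == "kruskal") {
      kt <- stats::kruskal.test(x, g)
      data.frame(cell_type = ct, statistic = unname(kt$statistic),
                 p = kt$p.value, stringsAsFactors = FALSE)
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(x[g == "case"], x[g == "control"]))
      data.frame(cell_type = ct, statistic = unname(wt$statistic),
                 p = wt$p.value, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Cell-type / cell-type correlation structure
#'
#' Symmetric Pearson correlation grid of the fraction columns (unit
#' diagonal). Correlations involving a constant column are undefined and
#' returned as NA (with a warning).
#'
#' @param fractions a [FractionTable-class] with >= 3 samples.
#' @return cell_type x cell_type numeric matrix.
#' @export
celltypeCorrelations <- function(fractions) {
  f <- cellFractions(fractions)
  if (nrow(f) < 3) stop("need >= 3 samples")
  const <- apply(f, 2, stats::sd) == 0
  cc <- suppressWarnings(stats::cor(f))
  if (any(const)) {
    warning("constant fraction column(s): ",
            paste(colnames(f)[const], collapse = ", "),
            "; correlations undefined (NA)")
    cc[const, ] <- NA; cc[, const] <- NA
  }
  diag(cc) <- 1
  cc
}

#' Associate a ceRNA pair's expression with cell-type fractions
#'
#' Correlates each pair member's log2 expression — and the pair mean —
#' with every cell-type fraction across samples, with BH adjustment over
#' all (member, cell type) tests. The fraction rows and expression
#' columns must be the same sample set.
#'
#' @param expr an [ExpressionExperiment-class] containing both members.
#' @param pair one-row data.frame (or named list/vector) with elements
#'   \code{lncrna} and \code{mrna}.
#' @param fractions a [FractionTable-class] on the same samples.
#' @return data.frame: \code{member} (lncRNA symbol, mRNA symbol, or
#'   \code{"pair_mean"}), \code{cell_type}, \code{r}, \code{p},
#'   \code{p_adj}.
#' @export
pairFractionAssociation <- function(expr, pair, fractions) {
  l <- as.character(if (is.data.frame(pair)) pair$lncrna[1] else pair[["lncrna"]])
  m <- as.character(if (is.data.frame(pair)) pair$mrna[1] else pair[["mrna"]])
  f <- cellFractions(fractions)
  mismatch <- c(setdiff(colnames(expr), rownames(f)),
                setdiff(rownames(f), colnames(expr)))
  if (length(mismatch))
    stop("sample sets of expression and fractions differ: ",
         paste(unique(mismatch), collapse = ", "))
  v <- .log2Values(expr)
  if (!all(c(l, m) %in% rownames(v)))
    stop("pair members must be present in the expression matrix")
  f <- f[colnames(v), , drop = FALSE]
  profiles <- list(v[l, ], v[m, ], (v[l, ] + v[m, ]) / 2)
  names(profiles) <- c(l, m, "pair_mean")
  n <- ncol(v)
  rows <- lapply(names(profiles), function(nm) {
    x <- profiles[[nm]]
    r <- vapply(colnames(f), function(ct) {
      y <- f[, ct]
      if (stats::sd(y) == 0 || stats::sd(x) == 0) NA_real_
      else stats::cor(x, y)
    }, numeric(1))
    data.frame(member = nm, cell_type = colnames(f), r = unname(r),
               p = unname(.corrPvalue(r, n)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}
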