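#' Validate admitted ceRNA pairs in an independent cohort
#'
#' Re-tests every admitted pair on a second two-group expression matrix:
#' both members are re-screened for differential expression and the pair
#' correlation is recomputed. Under the default \code{direction = "up"}
#' rule a pair is \code{validated} iff both members are significantly
#' up-regulated in the case group (p < alpha, log2FC > 0) AND the
#' validation correlation is positive with p < alpha — the strictest
#' reading of a confirmation cohort in which all reported pairs were
#' up-regulated. \code{direction = "consistent"} instead requires both
#' members significant with the same sign (either direction). Pairs with
#' a member absent from the validation matrix fail with reason
#' \code{"absent"}.
#'
#' @param pairs data.frame from [buildCeRNAPairs()].
#' @param exprValid grouped validation [ExpressionExperiment-class]
#'   (both groups present, else an error).
#' @param alpha significance threshold.
#' @param test \code{"welch_t"} or \code{"kruskal"}.
#' @param direction \code{"up"} (default) or \code{"consistent"}.
#' @return data.frame: \code{lncrna}, \code{mrna}, \code{lnc_p},
#'   \code{mrna_p}, \code{lnc_dir}, \code{mrna_dir}, \code{r_valid},
#'   \code{p_r_valid}, \code{verdict} (\code{validated}/\code{failed}),
#'   \code{reason}.
#' @export
validatePairs <- function(pairs, exprValid, alpha = 0.05,
                          test = c("welch_t", "kruskal"),
                          direction = c("up", "consistent")) {
  test <- match.arg(test)
  direction <- match.arg(direction)
  .assertGrouped(exprValid)
  if (!nrow(pairs))
    return(data.frame(lncrna = character(), mrna = character(),
                      lnc_p = numeric(), mrna_p = numeric(),
                      lnc_dir = character(), mrna_dir = character(),
                      r_valid = numeric(), p_r_valid = numeric(),
                      verdict = character(), reason = character(),
                      stringsAsFactors = FALSE))
  members <- unique(c(pairs$lncrna, pairs$mrna))
  present <- members[members %in% rownames(exprValid)]
  deg <- NULL
  if (length(present) >= 1) {
    sub <- exprValid[present, ]
    deg <- differentialExpression(sub, method = test, alpha = alpha,
                                  lfcCutoff = 0)
    rownames(deg) <- deg$gene
  }
  dirCall <- function(g) {
    if (!g %in% present) return(NA_character_)
    row <- deg[g, ]
    if (row$p >= alpha) "none" else if (row$log2fc > 0) "up" else "down"
  }
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    l <- pairs$lncrna[i]; m <- pairs$mrna[i]
    if (!(l %in% present) || !(m %in% present))
      return(data.frame(lncrna = l, mrna = m, lnc_p = NA_real_,
                        mrna_p = NA_real_, lnc_dir = NA_character_,
                        mrna_dir = NA_character_, r_valid = NA_real_,
                        p_r_valid = NA_real_, verdict = "failed",
                        reason = "absent", stringsAsFactors = FALSE))
    rc <- pairwiseCorrelation(exprValid[c(l, m), ], l, m)
    ld <- dirCall(l); md <- dirCall(m)
    ok <- if (direction == "up") {
      ld == "up" && md == "up"
    } else {
      ld %in% c("up", "down") && identical(ld, md)
    }
    ok <- ok && !rc$degenerate && rc$r > 0 && rc$p_corr < alpha
    data.frame(lncrna = l, mrna = m,
               lnc_p = deg[l, "p"], mrna_p = deg[m, "p"],
               lnc_dir = ld, mrna_dir = md,
               r_valid = rc$r, p_r_valid = rc$p_corr,
               verdict = if (ok) "validated" else "failed",
               reason = if (ok) "" else "criteria",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  message(sum(res$verdict == "validated"), " / ", nrow(res),
          " pairs validated")
  res
}

#' Per-pair correlation in training and validation cohorts
#'
#' One row per pair with the Pearson correlation and p-value in each
#' matrix, suitable for side-by-side scatter rendering. A pair with a
#' member absent from a matrix gets NA for that cohort.
#'
#' @param pairs data.frame from [buildCeRNAPairs()].
#' @param exprTrain,exprValid the two [ExpressionExperiment-class]
#'   matrices.
#' @return data.frame: \code{lncrna}, \code{mrna}, \code{r_train},
#'   \code{p_train}, \code{r_valid}, \code{p_valid}.
#' @export
correlationReport <- function(pairs, exprTrain, exprValid) {
  corOne <- function(expr, l, m) {
    if (!all(c(l, m) %in% rownames(expr)))
      return(c(NA_real_, NA_real_))
    rc <- pairwiseCorrelation(expr[c(l, m), ], l, m)
    c(rc$r, rc$p_corr)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    l <- pairs$lncrna[i]; m <- pairs$mrna[i]
    tr <- corOne(exprTrain, l, m)
    va <- corOne(exprValid, l, m)
    data.frame(lncrna = l, mrna = m, r_train = tr[1], p_train = tr[2],
               r_valid = va[1], p_valid = va[2], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
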