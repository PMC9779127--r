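# internal helpers shared across modules

# Table-1-style fixtures print the Unicode minus (U+2212); normalise to ASCII
.normalizeMinus <- function(x) gsub("−", "-", x, fixed = TRUE)

# full-precision numeric formatting so write-then-read is bit-identical
.fmtNum <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  out
}

.writeTsv <- function(df, path) {
  out <- df
  isDouble <- vapply(df, is.double, logical(1))
  out[isDouble] <- lapply(df[isDouble], .fmtNum)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
}

.readTsv <- function(path, header = TRUE, colClasses = NA) {
  utils::read.delim(path, header = header, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = colClasses,
                    fileEncoding = "UTF-8")
}

# expression on the log2 scale regardless of input scale (pseudo-count 1)
.log2Values <- function(expr) {
  v <- exprValues(expr)
  if (exprScale(expr) == "linear") log2(v + 1) else v
}

# linear-scale expression (inverse of the log2(x+1) convention)
.linearValues <- function(expr) {
  v <- exprValues(expr)
  if (exprScale(expr) == "log2") pmax(2^v - 1, 0) else v
}

# two-sided p-value for a Pearson correlation, t distribution with n-2 df
.corrPvalue <- function(r, n) {
  df <- n - 2
  denom <- pmax(1 - r^2, .Machine$double.eps)
  tstat <- abs(r) * sqrt(df / denom)
  p <- 2 * stats::pt(tstat, df, lower.tail = FALSE)
  p[r^2 >= 1] <- 0
  pmin(p, 1)
}

# symmetric (or general) Dirichlet draws via normalised gammas
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n), rate = 1),
              nrow = n, ncol = k)
  g / rowSums(g)
}

.assertGrouped <- function(expr) {
  g <- sampleGroups(expr)
  if (is.null(g))
    stop("this analysis needs control/case labels; the ExpressionExperiment ",
         "is ungrouped")
  if (!all(c("control", "case") %in% as.character(g)))
    stop("both 'control' and 'case' groups must be present")
  g
}
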