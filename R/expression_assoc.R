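#' Per-sample AR pathway activity score
#'
#' An accumulation measure of androgen-receptor pathway output: each
#' signature gene's expression is `log2(FPKM + 1)`-transformed and
#' z-scored across samples, and a sample's score is the sum (optionally
#' the mean) of its z-scores over the signature genes found in the
#' matrix. Genes with zero cross-sample variance contribute 0; z-scoring
#' makes the score invariant to per-gene affine rescaling of expression.
#'
#' @param expr Numeric genes x samples matrix with unique rownames
#'   (gene identifiers) and colnames (samples). Values are FPKM unless
#'   `log_transform = FALSE`, in which case they are used as-is (already
#'   log-scale).
#' @param gene_list Character vector of signature genes (canonically a
#'   43-gene AR-regulated set, supplied as an input file rather than
#'   hard-coded).
#' @param log_transform Apply `log2(x + 1)` first (default `TRUE`).
#' @param aggregate `"sum"` (default) or `"mean"` of per-gene z-scores.
#' @return data.frame `sample`, `score`, `n_genes_found`, with the genes
#'   used in the `"gene_list_used"` attribute.
#' @export
ar_activity_score <- function(expr, gene_list, log_transform = TRUE,
                              aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    stop("expr needs unique gene rownames")
  if (ncol(expr) < 2L)
    stop("need at least 2 samples to z-score across samples")
  if (log_transform && any(expr < 0, na.rm = TRUE))
    stop("negative FPKM values are not allowed")
  found <- intersect(gene_list, rownames(expr))
  if (!length(found)) stop("no signature gene found in the matrix")

  m <- expr[found, , drop = FALSE]
  if (log_transform) m <- log2(m + 1)
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sdv == 0, Inf, sdv)  # sd = 0 -> contributes 0
  score <- if (aggregate == "sum") colSums(z) else colMeans(z)
  out <- data.frame(sample = colnames(m), score = unname(score),
                    n_genes_found = length(found),
                    stringsAsFactors = FALSE)
  attr(out, "gene_list_used") <- found
  out
}

#' Simple linear regression of expression on an activity score
#'
#' Ordinary least squares via [stats::lm()]; reports the slope,
#' intercept, coefficient of determination and the two-sided p-value of
#' the slope from the t distribution.
#'
#' @param x Predictor (e.g. per-sample AR activity scores).
#' @param y Response (e.g. per-sample expression of a target gene).
#' @return List of class `linreg_result`: `slope`, `intercept`, `r2`,
#'   `p_value`, `n`.
#' @export
linreg <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("degenerate regression: x has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r2 = sm$r.squared,
         p_value = sm$coefficients[2L, 4L],
         n = length(x)),
    class = "linreg_result"
  )
}

#' @export
print.linreg_result <- function(x, ...) {
  cat(sprintf("<linreg_result> n = %d: y = %.4g x + %.4g, r2 = %.4f, p = %.3g (%s)\n",
              x$n, x$slope, x$intercept, x$r2, x$p_value,
              significance_tier(x$p_value)))
  invisible(x)
}

#' Two-group comparison of per-sample values
#'
#' Two-sided equal-variance Student's t-test between the two groups of a
#' grouping factor, with the package's asterisk significance tiers.
#'
#' @param values Numeric vector.
#' @param groups Vector with exactly two distinct labels, parallel to
#'   `values`; each group needs at least 2 samples.
#' @return List `t`, `df`, `p_value`, `group_means` (named), `tier`.
#' @export
group_compare <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  lv <- unique(as.character(groups))
  if (length(lv) != 2L) stop("groups must have exactly two labels")
  a <- values[groups == lv[1L]]
  b <- values[groups == lv[2L]]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 samples")
  res <- tiered_t_test(a, b)
  list(t = res$t, df = res$df, p_value = res$p_value,
       group_means = stats::setNames(c(res$mean_x, res$mean_y), lv),
       tier = res$tier)
}
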