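#' Tukey two-way median polish
#'
#' Decomposes a two-way table into `overall + row_effects + col_effects +
#' residuals` by alternately sweeping row and column medians (rows first),
#' the robust decomposition underlying the B score used to normalise
#' positional (row/column) artifacts on screening plates. Missing cells
#' (`NA`) are skipped by the medians and carry missing residuals.
#'
#' Iteration stops when the reduction in the sum of absolute residuals
#' falls below `tol`, or after `max_iter` full sweeps. On exit the row and
#' column effects are median-centred and the decomposition reconstructs
#' every non-missing input cell exactly.
#'
#' @param x Numeric matrix (typically 8 x 12 log2 luminescence with
#'   control/empty wells set to `NA`). Non-finite values other than `NA`
#'   are rejected.
#' @param max_iter Maximum number of sweeps (default 10).
#' @param tol Absolute tolerance on the reduction of the sum of absolute
#'   residuals (default 1e-6).
#' @return An object of class `medpolish_fit`: list with `overall`,
#'   `row_effects`, `col_effects`, `residuals`, `iterations`, `converged`.
#' @examples
#' m <- outer(c(-1, 0, 1), c(-2, 0, 2), `+`) + 5
#' fit <- median_polish(m)
#' fit$overall       # 5
#' fit$residuals     # all ~0
#' @export
median_polish <- function(x, max_iter = 10L, tol = 1e-6) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (any(!is.na(x) & !is.finite(x)))
    stop("non-finite values (Inf/NaN) are not allowed; use NA for missing")
  nr <- nrow(x); nc <- ncol(x)
  row_n <- rowSums(!is.na(x)); col_n <- colSums(!is.na(x))
  if (any(row_n == 0L) || any(col_n == 0L))
    stop("degenerate margin: a row or column is fully missing")
  if (any(row_n < 2L) || any(col_n < 2L))
    stop("each row and column needs at least 2 non-missing entries")

  r <- x
  overall <- 0
  row_eff <- numeric(nr)
  col_eff <- numeric(nc)
  oldsum <- sum(abs(r), na.rm = TRUE)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    rdelta <- apply(r, 1L, stats::median, na.rm = TRUE)
    r <- r - rdelta
    row_eff <- row_eff + rdelta
    delta <- stats::median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta

    cdelta <- apply(r, 2L, stats::median, na.rm = TRUE)
    r <- sweep(r, 2L, cdelta)
    col_eff <- col_eff + cdelta
    delta <- stats::median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta

    newsum <- sum(abs(r), na.rm = TRUE)
    if (newsum == 0 || (oldsum - newsum) < tol) { converged <- TRUE; break }
    oldsum <- newsum
  }
  # centre the effect vectors exactly (residuals are untouched)
  d <- stats::median(col_eff); col_eff <- col_eff - d; overall <- overall + d
  d <- stats::median(row_eff); row_eff <- row_eff - d; overall <- overall + d
  structure(
    list(
      overall = overall,
      row_effects = row_eff,
      col_effects = col_eff,
      residuals = r,
      iterations = iter,
      converged = converged
    ),
    class = "medpolish_fit"
  )
}

#' @export
print.medpolish_fit <- function(x, digits = 4, ...) {
  cat("<medpolish_fit> ", nrow(x$residuals), "x", ncol(x$residuals),
      if (x$converged) " (converged in " else " (stopped at ",
      x$iterations, " sweeps)\n", sep = "")
  cat("  overall:", format(x$overall, digits = digits), "\n")
  cat("  row effects:", format(x$row_effects, digits = digits), "\n")
  cat("  col effects:", format(x$col_effects, digits = digits), "\n")
  invisible(x)
}

#' @export
residuals.medpolish_fit <- function(object, ...) object$residuals

#' @export
fitted.medpolish_fit <- function(object, ...) {
  object$overall + outer(object$row_effects, object$col_effects, `+`)
}

#' B scores from a median-polish fit
#'
#' The B score of a well is its median-polish residual divided by the
#' plate's scaled median absolute deviation,
#' `MAD = 1.4826 * median(|r - median(r)|)` over the non-missing residuals
#' of that plate. Division by the MAD makes B scores invariant to
#' plate-wide additive shifts and (on the log scale) multiplicative
#' rescaling of the raw luminescence.
#'
#' @param fit A [median_polish()] fit of one plate's library wells.
#' @param min_wells Minimum number of non-missing residuals (default 6).
#' @return Matrix of B scores, same shape as the residual matrix.
#' @export
b_score <- function(fit, min_wells = 6L) {
  stopifnot(inherits(fit, "medpolish_fit"))
  r <- fit$residuals
  v <- r[!is.na(r)]
  if (length(v) < min_wells)
    stop("need at least ", min_wells, " non-missing residuals")
  mad_r <- 1.4826 * stats::median(abs(v - stats::median(v)))
  if (mad_r == 0)
    stop("degenerate scale: plate MAD is zero (constant residuals)")
  r / mad_r
}
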