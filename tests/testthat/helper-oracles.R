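# Independent oracles used across the suite. Each is coded from the
# definitions directly, without calling the package's implementation
# internals it is meant to check.

ORACLE_COMP <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

oracle_rc <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# Brute-force seed-site scan: tests every UTR offset against each type
# definition independently, then collapses co-registered classifications
# to the strongest type (8mer > 7mer-m8 > 7mer-A1 > 6mer).
oracle_scan <- function(mir_seq, utr_string, types = c("6mer", "7mer-A1",
                                                       "7mer-m8", "8mer")) {
  mir_seq <- toupper(chartr("t", "u", chartr("T", "U", mir_seq)))
  utr <- toupper(chartr("t", "u", chartr("T", "U", utr_string)))
  n <- nchar(utr)
  rc6 <- oracle_rc(substr(mir_seq, 2, 7))
  rc7 <- oracle_rc(substr(mir_seq, 2, 8))
  defs <- list(
    "6mer"    = rc6,
    "7mer-A1" = paste0(rc6, "A"),
    "7mer-m8" = rc7,
    "8mer"    = paste0(rc7, "A")
  )
  rank <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)
  found <- list()
  for (ty in names(defs)) {
    pat <- defs[[ty]]
    w <- nchar(pat)
    for (i in seq_len(max(0, n - w + 1))) {
      if (substr(utr, i, i + w - 1) == pat) {
        # register = start of the 6mer core within the UTR
        core <- if (ty %in% c("7mer-m8", "8mer")) i + 1L else i
        found[[length(found) + 1L]] <- data.frame(
          register = core, start = i, end = i + w - 1L, site_type = ty,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(found))
    return(data.frame(start = integer(), end = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  all <- do.call(rbind, found)
  best <- do.call(rbind, lapply(split(all, all$register), function(d)
    d[which.max(rank[d$site_type]), , drop = FALSE]))
  best <- best[best$site_type %in% types, c("start", "end", "site_type"),
               drop = FALSE]
  best <- best[order(best$start), , drop = FALSE]
  rownames(best) <- NULL
  best
}

# Independently coded row/column median-sweep decomposition with the same
# sweep order (rows first) and the same stopping rule.
oracle_medpolish <- function(x, max_iter = 10L, tol = 1e-6) {
  r <- x
  overall <- 0
  row_eff <- numeric(nrow(x))
  col_eff <- numeric(ncol(x))
  oldsum <- sum(abs(r), na.rm = TRUE)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(nrow(r))) {
      m <- stats::median(r[i, ], na.rm = TRUE)
      r[i, ] <- r[i, ] - m
      row_eff[i] <- row_eff[i] + m
    }
    d <- stats::median(col_eff); col_eff <- col_eff - d; overall <- overall + d
    for (j in seq_len(ncol(r))) {
      m <- stats::median(r[, j], na.rm = TRUE)
      r[, j] <- r[, j] - m
      col_eff[j] <- col_eff[j] + m
    }
    d <- stats::median(row_eff); row_eff <- row_eff - d; overall <- overall + d
    newsum <- sum(abs(r), na.rm = TRUE)
    if (newsum == 0 || (oldsum - newsum) < tol) break
    oldsum <- newsum
  }
  d <- stats::median(col_eff); col_eff <- col_eff - d; overall <- overall + d
  d <- stats::median(row_eff); row_eff <- row_eff - d; overall <- overall + d
  list(overall = overall, row_effects = row_eff, col_effects = col_eff,
       residuals = r)
}

# Closed-form Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Closed-form ordinary least squares with the slope's two-sided t p-value.
oracle_ols <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- slope / se
  r <- oracle_pearson(x, y)
  list(slope = slope, intercept = intercept, r2 = r^2,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Textbook pooled-variance two-sample t statistic and p-value.
oracle_ttest <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tstat, p_value = 2 * stats::pt(-abs(tstat), df = nx + ny - 2))
}

# Random mature miRNA / UTR strings for property tests.
random_mir_seq <- function(len = 22) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
random_utr_string <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
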