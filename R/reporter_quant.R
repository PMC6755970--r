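sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Normalise luciferase reporter activity to beta-galactosidase
#'
#' Per replicate, normalised activity is `luciferase / beta_gal`
#' (correcting for transfection efficiency); per condition, fold change
#' is the mean normalised activity divided by the control condition's
#' mean, so the control's fold is exactly 1.
#'
#' @param measurements data.frame with columns `condition`, `replicate`,
#'   `luciferase` (>= 0) and `beta_gal` (> 0).
#' @param control_condition Label of the control condition.
#' @return data.frame per condition: `condition`, `n`,
#'   `mean_normalized`, `fold` (vs control), `sem_fold`.
#' @export
normalize_reporter <- function(measurements, control_condition) {
  stopifnot(all(c("condition", "luciferase", "beta_gal") %in%
                names(measurements)))
  if (any(!is.finite(measurements$beta_gal) | measurements$beta_gal <= 0))
    stop("beta_gal must be positive")
  if (any(!is.finite(measurements$luciferase) | measurements$luciferase < 0))
    stop("luciferase must be non-negative")
  if (!control_condition %in% measurements$condition)
    stop("control condition '", control_condition, "' not present")
  norm <- measurements$luciferase / measurements$beta_gal
  ctrl_mean <- mean(norm[measurements$condition == control_condition])
  if (ctrl_mean <= 0) stop("control condition has zero mean activity")
  out <- do.call(rbind, lapply(split(norm, measurements$condition), function(v)
    data.frame(n = length(v), mean_normalized = mean(v),
               fold = mean(v) / ctrl_mean, sem_fold = sem(v / ctrl_mean))))
  out <- cbind(condition = rownames(out), out)
  rownames(out) <- NULL
  out$condition <- as.character(out$condition)
  out
}

#' Relative expression by the comparative Ct (2^-ddCt) method
#'
#' For each sample, `dCt(sample, gene) = Ct(gene) - mean(Ct(reference
#' genes))` (several references are combined by the arithmetic mean of
#' their Cts, i.e. the geometric mean of their expression);
#' `ddCt = dCt(sample, gene) - dCt(calibrator, gene)`; fold is
#' `2^-ddCt`, assuming perfect doubling per cycle. The calibrator
#' sample's fold is 1 by construction.
#'
#' @param records data.frame of Ct records: `sample`, `gene`, `ct`,
#'   `role` (`target`/`reference`). Technical replicates of one
#'   (sample, gene) are averaged.
#' @param reference_genes Character vector of endogenous reference genes
#'   (e.g. `U18` for miRNA assays, `L19` for mRNA assays).
#' @param calibrator_sample Sample whose expression defines fold 1.
#' @return data.frame `sample`, `gene`, `delta_ct`, `delta_delta_ct`,
#'   `fold` for every target gene; samples missing a reference gene are
#'   reported in the `"errors"` attribute and excluded, not fatal.
#' @export
delta_delta_ct <- function(records, reference_genes, calibrator_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(records)))
  if (!calibrator_sample %in% records$sample)
    stop("calibrator sample '", calibrator_sample, "' not present")
  if (any(!is.finite(records$ct))) stop("Ct values must be finite")

  # mean Ct per (sample, gene)
  ag <- stats::aggregate(ct ~ sample + gene, data = records, FUN = mean)
  samples <- unique(ag$sample)
  errors <- character()
  ref_ct <- vapply(samples, function(s) {
    cts <- ag$ct[ag$sample == s & ag$gene %in% reference_genes]
    if (length(unique(ag$gene[ag$sample == s & ag$gene %in% reference_genes])) <
        length(reference_genes)) {
      errors <<- c(errors, s)
      return(NA_real_)
    }
    mean(cts)
  }, numeric(1))
  names(ref_ct) <- samples
  if (all(is.na(ref_ct))) stop("no sample has all reference genes")
  if (is.na(ref_ct[[calibrator_sample]]))
    stop("calibrator sample lacks a reference gene")

  targets <- ag[!ag$gene %in% reference_genes, , drop = FALSE]
  targets <- targets[!targets$sample %in% errors, , drop = FALSE]
  targets$delta_ct <- targets$ct - ref_ct[targets$sample]
  cal <- targets[targets$sample == calibrator_sample, , drop = FALSE]
  cal_dct <- stats::setNames(cal$delta_ct, cal$gene)
  targets$delta_delta_ct <- targets$delta_ct - cal_dct[targets$gene]
  targets$fold <- 2^(-targets$delta_delta_ct)
  out <- targets[order(targets$sample, targets$gene),
                 c("sample", "gene", "delta_ct", "delta_delta_ct", "fold")]
  rownames(out) <- NULL
  attr(out, "errors") <- unique(errors)
  out
}

#' RNA-IP enrichment as percent of input
#'
#' `percent = 100 * input_fraction * 2^(ct_input - ct_ip)`: the input Ct
#' is adjusted by `+log2(input_fraction)` because only a fraction of the
#' lysate was assayed as input (equivalently, the measured input amount
#' is divided by the fraction to estimate the total).
#'
#' @param ct_input Ct of the input (pre-IP) lysate.
#' @param ct_ip Ct of the immunoprecipitated material.
#' @param input_fraction Fraction of lysate used as input, in (0, 1]
#'   (default 1 = input and IP assayed at equal scale).
#' @return Percent of input (vectorised). Monotone decreasing in
#'   `ct_ip`.
#' @examples
#' percent_input(25, 25)            # 100
#' percent_input(25, 25 + log2(10)) # 10
#' @export
percent_input <- function(ct_input, ct_ip, input_fraction = 1) {
  if (any(!is.finite(ct_input)) || any(!is.finite(ct_ip)))
    stop("Ct values must be finite")
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop("input_fraction must be in (0, 1]")
  100 * input_fraction * 2^(ct_input - ct_ip)
}

#' Fraction of transcript remaining after transcriptional block
#'
#' Ratio of the (reference-normalised) relative expression after a
#' transcription-inhibitor treatment (e.g. Actinomycin D) to the vehicle
#' control; 1 means a fully stable transcript over the chase. Stability
#' rescue between transfections is the ratio of two such fractions.
#'
#' @param rel_expr_vehicle,rel_expr_actd Positive relative-expression
#'   folds (already ddCt-normalised).
#' @return `rel_expr_actd / rel_expr_vehicle` (vectorised).
#' @export
decay_fraction <- function(rel_expr_vehicle, rel_expr_actd) {
  if (any(!is.finite(rel_expr_vehicle)) || any(rel_expr_vehicle <= 0) ||
      any(!is.finite(rel_expr_actd)) || any(rel_expr_actd <= 0))
    stop("relative expression folds must be positive")
  rel_expr_actd / rel_expr_vehicle
}

#' Growth relative to day 0
#'
#' Per condition and timepoint, mean absorbance fold vs the day-0 mean
#' with SEM. Fold at day 0 is 1; values below 1 indicate net cell loss
#' (cytotoxicity) rather than growth arrest.
#'
#' @param series data.frame with columns `condition`, `day`,
#'   `absorbance` (one row per replicate measurement); must include
#'   day 0 for every condition.
#' @return data.frame `condition`, `day`, `n`, `fold`, `sem_fold`.
#' @export
relative_growth <- function(series) {
  stopifnot(all(c("condition", "day", "absorbance") %in% names(series)))
  if (any(!is.finite(series$absorbance) | series$absorbance < 0))
    stop("absorbance must be non-negative")
  out <- do.call(rbind, lapply(split(series, series$condition), function(d) {
    if (!any(d$day == 0)) stop("condition '", d$condition[1L],
                               "' is missing day 0")
    d0 <- mean(d$absorbance[d$day == 0])
    if (d0 <= 0) stop("day-0 mean absorbance must be positive")
    do.call(rbind, lapply(split(d, d$day), function(t)
      data.frame(condition = t$condition[1L], day = t$day[1L],
                 n = nrow(t), fold = mean(t$absorbance) / d0,
                 sem_fold = sem(t$absorbance / d0),
                 stringsAsFactors = FALSE)))
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$day), , drop = FALSE]
}

#' Significance tier for a p-value
#'
#' Asterisk convention: `*` for p <= 0.05, `**` for p <= 0.005, `***`
#' for p <= 0.0001, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  ifelse(p <= 1e-4, "***", ifelse(p <= 0.005, "**",
  ifelse(p <= 0.05, "*", "ns")))
}

#' Two-sided equal-variance Student's t-test with significance tiers
#'
#' Thin wrapper over [stats::t.test()] (`var.equal = TRUE`) returning
#' the statistic, p-value, group means and the asterisk tier.
#'
#' @param x,y Numeric vectors (>= 2 observations each).
#' @return List `t`, `df`, `p_value`, `mean_x`, `mean_y`, `tier`.
#' @export
tiered_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  df <- length(x) + length(y) - 2L
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # degenerate separation: identical groups give p = 1; distinct
    # constant groups drive p to the machine floor
    if (mean(x) == mean(y)) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(mean(x) - mean(y)) * Inf; p <- .Machine$double.xmin
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    tstat <- unname(ht$statistic); p <- ht$p.value
  }
  list(t = tstat, df = df, p_value = p, mean_x = mean(x), mean_y = mean(y),
       tier = significance_tier(p))
}
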