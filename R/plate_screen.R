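WELL_ROLES <- c("library", "negative_control", "death_control", "empty")

well_names <- function() {
  outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)
}

#' Construct a 96-well plate of raw reporter luminescence
#'
#' An 8 x 12 grid of raw luminescence (RLU) with per-well roles and probe
#' identifiers, the unit of input of the screening pipeline.
#'
#' @param values 8 x 12 numeric matrix of raw RLU; positive or `NA`
#'   (missing reads). Non-empty wells must be positive or `NA`.
#' @param roles 8 x 12 character matrix over
#'   `library/negative_control/death_control/empty`.
#' @param probe_ids 8 x 12 character matrix; non-`NA` exactly on library
#'   wells.
#' @param plate_id,cell_line Identifiers.
#' @param replicate Replicate index (default 1).
#' @return Object of class `plate_grid`.
#' @export
plate_grid <- function(values, roles, probe_ids, plate_id, cell_line,
                       replicate = 1L) {
  stopifnot(is.matrix(values), all(dim(values) == c(8L, 12L)),
            is.matrix(roles), all(dim(roles) == c(8L, 12L)),
            is.matrix(probe_ids), all(dim(probe_ids) == c(8L, 12L)))
  if (!all(roles %in% WELL_ROLES))
    stop("roles must be one of: ", paste(WELL_ROLES, collapse = ", "))
  lib <- roles == "library"
  if (any(lib & is.na(probe_ids)))
    stop("every library well needs a probe_id")
  if (any(!lib & !is.na(probe_ids)))
    stop("probe_ids are only allowed on library wells")
  bad <- !is.na(values) & values <= 0 & roles != "empty"
  if (any(bad))
    stop("non-empty wells must have positive RLU or NA (missing)")
  structure(
    list(values = values, roles = roles, probe_ids = probe_ids,
         plate_id = as.character(plate_id),
         cell_line = as.character(cell_line),
         replicate = as.integer(replicate)),
    class = "plate_grid"
  )
}

#' @export
print.plate_grid <- function(x, ...) {
  cat("<plate_grid>", x$plate_id, "/", x$cell_line,
      "(replicate", paste0(x$replicate, ")"), "\n")
  tab <- table(factor(x$roles, levels = WELL_ROLES))
  cat(" ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Per-well B scores for one plate
#'
#' Log2-transforms the library-well luminescence (controls and empty
#' wells are excluded: they would bias the positional estimates), drops
#' fully-missing rows/columns, runs [median_polish()] on the remaining
#' sub-grid and divides the residuals by the plate MAD ([b_score()]).
#'
#' @param plate A [plate_grid()].
#' @param log2_transform Polish log2(RLU) rather than raw RLU (default
#'   `TRUE`; reporter effects are fold changes).
#' @param max_iter,tol Passed to [median_polish()].
#' @return data.frame with one row per library well: `plate_id`,
#'   `cell_line`, `replicate`, `well`, `probe_id`, `b_score` (`NA` for
#'   missing reads).
#' @export
plate_bscores <- function(plate, log2_transform = TRUE, max_iter = 10L,
                          tol = 1e-6) {
  stopifnot(inherits(plate, "plate_grid"))
  lib <- plate$roles == "library"
  vals <- plate$values
  vals[!lib] <- NA_real_
  y <- if (log2_transform) log2(vals) else vals

  use_row <- rowSums(!is.na(y)) > 0L
  use_col <- colSums(!is.na(y)) > 0L
  fit <- median_polish(y[use_row, use_col, drop = FALSE],
                       max_iter = max_iter, tol = tol)
  b_sub <- b_score(fit)
  b <- matrix(NA_real_, 8L, 12L)
  b[use_row, use_col] <- b_sub

  wells <- well_names()
  idx <- which(lib)
  data.frame(
    plate_id = plate$plate_id, cell_line = plate$cell_line,
    replicate = plate$replicate,
    well = wells[idx], probe_id = plate$probe_ids[idx],
    b_score = b[idx],
    stringsAsFactors = FALSE
  )[order(wells[idx]), , drop = FALSE]
}

#' Aggregate per-well B scores to per-probe scores
#'
#' Within each cell line, a probe's score is the median of its replicate
#' well B scores (robust to a single aberrant replicate); a single
#' replicate passes through unchanged. Probes whose wells are all missing
#' are reported with `b_score = NA` and `status = "no-data"`, never
#' dropped.
#'
#' @param well_scores data.frame as returned by [plate_bscores()]
#'   (rows from several plates/cell lines may be concatenated).
#' @return data.frame with `probe_id`, `cell_line`, `b_score`,
#'   `n_wells`, `status` (`"ok"` or `"no-data"`).
#' @export
aggregate_probe_scores <- function(well_scores) {
  stopifnot(all(c("probe_id", "cell_line", "b_score") %in% names(well_scores)))
  key <- interaction(well_scores$probe_id, well_scores$cell_line, drop = TRUE)
  agg <- lapply(split(well_scores, key), function(d) {
    v <- d$b_score[!is.na(d$b_score)]
    data.frame(
      probe_id = d$probe_id[1L], cell_line = d$cell_line[1L],
      b_score = if (length(v)) stats::median(v) else NA_real_,
      n_wells = nrow(d),
      status = if (length(v)) "ok" else "no-data",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$cell_line, out$probe_id), , drop = FALSE]
}

#' Call screen hits from per-probe B scores
#'
#' A probe is a hit when `|B| >= threshold` in at least one cell line.
#' Direction follows the sign of B: a positive B means the inhibitor
#' increased reporter output, i.e. inhibiting the miRNA increases AR
#' activity. A hit is a common same-direction hit when both (all) cell
#' lines exceed the threshold with equal sign.
#'
#' @param probe_scores data.frame from [aggregate_probe_scores()].
#' @param threshold Positive B-score cutoff (default 6, the stringent
#'   cutoff used for this reporter screen).
#' @return Object of class `screen_hits`: data.frame with one row per
#'   probe (`probe_id`, one `B_<line>` and `direction_<line>` column per
#'   cell line, `is_hit_any_line`, `is_common_same_direction`), plus the
#'   threshold as an attribute. Probes with no data in a line carry `NA`
#'   there and are flagged, not dropped.
#' @export
call_hits <- function(probe_scores, threshold = 6) {
  stopifnot(threshold > 0)
  lines <- sort(unique(probe_scores$cell_line))
  probes <- sort(unique(probe_scores$probe_id))
  if (!length(probes)) {
    out <- data.frame(probe_id = character(), is_hit_any_line = logical(),
                      is_common_same_direction = logical(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("screen_hits", "data.frame"),
                     threshold = threshold, cell_lines = lines))
  }
  B <- matrix(NA_real_, length(probes), length(lines),
              dimnames = list(probes, lines))
  idx <- cbind(match(probe_scores$probe_id, probes),
               match(probe_scores$cell_line, lines))
  B[idx] <- probe_scores$b_score

  hit_line <- !is.na(B) & abs(B) >= threshold
  direction <- ifelse(is.na(B), NA_character_,
               ifelse(!hit_line, "none",
               ifelse(B > 0, "increases_AR_activity",
                      "decreases_AR_activity")))
  is_hit <- rowSums(hit_line) >= 1L
  all_above <- rowSums(hit_line) == length(lines)
  same_sign <- apply(B, 1L, function(b)
    all(!is.na(b)) && (all(b > 0) || all(b < 0)))
  common <- all_above & same_sign & length(lines) >= 2L

  out <- data.frame(probe_id = probes, stringsAsFactors = FALSE)
  for (ln in lines) out[[paste0("B_", ln)]] <- B[, ln]
  for (ln in lines) out[[paste0("direction_", ln)]] <- direction[, ln]
  out$is_hit_any_line <- unname(is_hit)
  out$is_common_same_direction <- unname(common)
  rownames(out) <- NULL
  structure(out, class = c("screen_hits", "data.frame"),
            threshold = threshold, cell_lines = lines)
}

#' @export
print.screen_hits <- function(x, ...) {
  thr <- attr(x, "threshold")
  n_hit <- sum(x$is_hit_any_line)
  cat("<screen_hits> ", nrow(x), " probes, |B| >= ", thr, ": ",
      n_hit, " hits (", sum(x$is_common_same_direction),
      " common same-direction)\n", sep = "")
  if (n_hit) {
    dirs <- x[x$is_hit_any_line, grep("^direction_", names(x)), drop = FALSE]
    up <- sum(apply(dirs == "increases_AR_activity", 1L, any, na.rm = TRUE))
    dn <- sum(apply(dirs == "decreases_AR_activity", 1L, any, na.rm = TRUE))
    cat(sprintf("  inhibitors increasing AR activity: %d (%.0f%%), decreasing: %d (%.0f%%)\n",
                up, 100 * up / n_hit, dn, 100 * dn / n_hit))
  }
  invisible(x)
}

#' @export
summary.screen_hits <- function(object, ...) {
  print(object)
  bc <- grep("^B_", names(object), value = TRUE)
  for (col in bc) {
    v <- object[[col]]
    cat(sprintf("  %s: median %.2f, IQR [%.2f, %.2f], range [%.2f, %.2f]\n",
                col, stats::median(v, na.rm = TRUE),
                stats::quantile(v, .25, na.rm = TRUE),
                stats::quantile(v, .75, na.rm = TRUE),
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  invisible(object)
}

#' @export
plot.screen_hits <- function(x, lines = attr(x, "cell_lines")[1:2], ...) {
  bx <- x[[paste0("B_", lines[1L])]]
  by <- x[[paste0("B_", lines[2L])]]
  thr <- attr(x, "threshold")
  graphics::plot(bx, by, xlab = paste("B score,", lines[1L]),
                 ylab = paste("B score,", lines[2L]),
                 pch = 19, cex = 0.4,
                 col = ifelse(x$is_common_same_direction, "red",
                       ifelse(x$is_hit_any_line, "orange", "grey40")), ...)
  graphics::abline(h = c(-thr, thr), v = c(-thr, thr), lty = 2, col = "grey60")
  invisible(x)
}

#' Cross-cell-line screen concordance
#'
#' Partitions hits between two cell lines into common same-direction,
#' common opposite-direction and line-specific sets, and reports the
#' Pearson correlation of per-probe B scores over the shared probe
#' universe.
#'
#' @param hits A [call_hits()] result covering both lines.
#' @param lineA,lineB Cell-line names (default: the first two lines).
#' @return List with `n_common_same_direction`, `n_common_opposite`,
#'   `n_A_only`, `n_B_only`, `pearson_r_of_B`, `n_shared_probes`.
#' @export
screen_concordance <- function(hits,
                               lineA = attr(hits, "cell_lines")[1],
                               lineB = attr(hits, "cell_lines")[2]) {
  thr <- attr(hits, "threshold")
  bA <- hits[[paste0("B_", lineA)]]
  bB <- hits[[paste0("B_", lineB)]]
  ok <- !is.na(bA) & !is.na(bB)
  if (sum(ok) < 2L)
    stop("fewer than 2 shared probes: correlation undefined")
  hA <- !is.na(bA) & abs(bA) >= thr
  hB <- !is.na(bB) & abs(bB) >= thr
  both <- hA & hB
  list(
    n_common_same_direction = sum(both & sign(bA) == sign(bB)),
    n_common_opposite = sum(both & sign(bA) != sign(bB)),
    n_A_only = sum(hA & !hB),
    n_B_only = sum(hB & !hA),
    pearson_r_of_B = stats::cor(bA[ok], bB[ok]),
    n_shared_probes = sum(ok)
  )
}

#' Run the full plate-screen pipeline
#'
#' Convenience driver: per-plate B scores ([plate_bscores()]) for every
#' plate, per-probe aggregation ([aggregate_probe_scores()]) and hit
#' calling ([call_hits()]).
#'
#' @param plates List of [plate_grid()] objects (all cell lines mixed).
#' @param threshold Hit-calling cutoff on |B| (default 6).
#' @param log2_transform Passed to [plate_bscores()].
#' @return A list of class `screen_result` with `well_scores`,
#'   `probe_scores` and `hits`.
#' @export
screen_bscore <- function(plates, threshold = 6, log2_transform = TRUE) {
  if (inherits(plates, "plate_grid")) plates <- list(plates)
  ws <- do.call(rbind, lapply(plates, plate_bscores,
                              log2_transform = log2_transform))
  ps <- aggregate_probe_scores(ws)
  structure(
    list(well_scores = ws, probe_scores = ps,
         hits = call_hits(ps, threshold = threshold)),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>", nrow(x$well_scores), "library wells,",
      nrow(x$probe_scores), "probe x line scores\n")
  print(x$hits)
  invisible(x)
}
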