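#' Default 96-well screening-plate layout
#'
#' Columns 1 and 12 are reserved for controls: column 1 carries the
#' negative control (8 wells), column 12 four death-control wells (rows
#' A-D) and four empty wells (rows E-H). Columns 2-11 are the 80 library
#' wells, so 13 plates accommodate 1040 >= 983 probes.
#'
#' @return 8 x 12 character matrix of well roles.
#' @export
default_plate_layout <- function() {
  roles <- matrix("library", 8L, 12L)
  roles[, 1L] <- "negative_control"
  roles[1:4, 12L] <- "death_control"
  roles[5:8, 12L] <- "empty"
  roles
}

#' Configuration of a synthetic miRNA-inhibitor screen
#'
#' Describes a full generative model of the reporter screen: per-well
#' log2 luminescence is `baseline + row effect + column effect + probe
#' effect + N(0, noise_sd)`, with row/column effects drawn per plate
#' (additive positional artifacts), probe effects zero except for planted
#' hits and a large fixed negative effect for death-control wells.
#'
#' @param n_probes Number of library probes (default 983, a genome-wide
#'   inhibitor library).
#' @param n_plates Plates per cell line (default 13).
#' @param n_cell_lines Number of cell lines (default 2).
#' @param plate_layout 8 x 12 role matrix (default
#'   [default_plate_layout()]).
#' @param row_effect_sd,col_effect_sd SD of per-plate additive row/column
#'   effects, log2-RLU units (default 0.25).
#' @param noise_sd Per-well log2-RLU noise SD (default 0.25).
#' @param baseline_log2_rlu Plate baseline, log2 RLU (default 10).
#' @param hit_fraction Fraction of probes that are true hits (default
#'   0.02).
#' @param hit_effect_log2 Absolute per-hit log2 effect (default 3); each
#'   hit's sign is random.
#' @param concordance_prob Probability that a hit acts (with the same
#'   signed effect) in each additional cell line (default 1).
#' @param death_effect_log2 Fixed signed effect of death-control wells
#'   (default -6).
#' @param n_replicates Replicate plates per library plate (default 1).
#' @param rng_seed Integer seed.
#' @return Validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_probes = 983L, n_plates = 13L,
                              n_cell_lines = 2L,
                              plate_layout = default_plate_layout(),
                              row_effect_sd = 0.25, col_effect_sd = 0.25,
                              noise_sd = 0.25, baseline_log2_rlu = 10,
                              hit_fraction = 0.02, hit_effect_log2 = 3,
                              concordance_prob = 1,
                              death_effect_log2 = -6,
                              n_replicates = 1L, rng_seed = 1L) {
  stopifnot(n_probes >= 1L, n_plates >= 1L, n_cell_lines >= 1L,
            n_replicates >= 1L,
            row_effect_sd >= 0, col_effect_sd >= 0, noise_sd >= 0,
            hit_fraction >= 0, hit_fraction <= 1,
            concordance_prob >= 0, concordance_prob <= 1)
  stopifnot(is.matrix(plate_layout), all(dim(plate_layout) == c(8L, 12L)),
            all(plate_layout %in% WELL_ROLES))
  lib_per_plate <- sum(plate_layout == "library")
  if (n_probes > n_plates * lib_per_plate)
    stop("layout cannot accommodate n_probes: capacity is ",
         n_plates * lib_per_plate, " (capacity error)")
  structure(
    list(n_probes = as.integer(n_probes), n_plates = as.integer(n_plates),
         n_cell_lines = as.integer(n_cell_lines),
         plate_layout = plate_layout,
         row_effect_sd = row_effect_sd, col_effect_sd = col_effect_sd,
         noise_sd = noise_sd, baseline_log2_rlu = baseline_log2_rlu,
         hit_fraction = hit_fraction, hit_effect_log2 = hit_effect_log2,
         concordance_prob = concordance_prob,
         death_effect_log2 = death_effect_log2,
         n_replicates = as.integer(n_replicates),
         rng_seed = as.integer(rng_seed)),
    class = "screen_sim_config"
  )
}

#' Simulate a full reporter screen with known ground truth
#'
#' Draws per-plate positional effects, per-well noise and planted probe
#' effects per the generative model of [screen_sim_config()], and returns
#' the raw-RLU plates together with the per-probe truth table.
#' Generation is reproducible under `rng_seed`.
#'
#' @param config A [screen_sim_config()].
#' @return List with `plates` (list of [plate_grid()], all cell lines)
#'   and `truth` (data.frame `probe_id`, `cell_line`, `effect_log2`,
#'   `is_hit`).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  withr_seed(config$rng_seed, {
    lines <- paste0("line", seq_len(config$n_cell_lines))
    probes <- sprintf("probe%04d", seq_len(config$n_probes))

    n_hits <- round(config$hit_fraction * config$n_probes)
    hit_probes <- if (n_hits) sample(probes, n_hits) else character()
    base_sign <- sample(c(-1, 1), n_hits, replace = TRUE)
    effect <- matrix(0, config$n_probes, config$n_cell_lines,
                     dimnames = list(probes, lines))
    if (n_hits) {
      effect[hit_probes, 1L] <- base_sign * config$hit_effect_log2
      if (config$n_cell_lines > 1L)
        for (j in 2:config$n_cell_lines) {
          conc <- stats::runif(n_hits) < config$concordance_prob
          effect[hit_probes, j] <- ifelse(conc, effect[hit_probes, 1L], 0)
        }
    }

    layout <- config$plate_layout
    lib_idx <- which(layout == "library")  # column-major: fill top-down, left-right
    # deal probes evenly across plates: a sparsely-populated final plate
    # would leave too few library wells for a stable positional fit
    per_plate <- rep(config$n_probes %/% config$n_plates, config$n_plates)
    extra <- config$n_probes %% config$n_plates
    if (extra) per_plate[seq_len(extra)] <- per_plate[seq_len(extra)] + 1L
    plates <- list()
    for (ln in lines) {
      assigned <- 0L
      for (p in seq_len(config$n_plates)) {
        ids <- matrix(NA_character_, 8L, 12L)
        roles <- layout
        take <- min(per_plate[p], config$n_probes - assigned)
        if (take > 0L)
          ids[lib_idx[seq_len(take)]] <- probes[assigned + seq_len(take)]
        if (take < length(lib_idx))
          roles[lib_idx[seq(take + 1L, length(lib_idx))]] <- "empty"
        assigned <- assigned + take

        probe_eff <- matrix(0, 8L, 12L)
        lib_here <- !is.na(ids)
        probe_eff[lib_here] <- effect[ids[lib_here], ln]
        probe_eff[roles == "death_control"] <- config$death_effect_log2

        for (rep in seq_len(config$n_replicates)) {
          row_eff <- stats::rnorm(8L, 0, config$row_effect_sd)
          col_eff <- stats::rnorm(12L, 0, config$col_effect_sd)
          noise <- matrix(stats::rnorm(96L, 0, config$noise_sd), 8L, 12L)
          log2_rlu <- config$baseline_log2_rlu +
            outer(row_eff, col_eff, `+`) + probe_eff + noise
          vals <- 2^log2_rlu
          vals[roles == "empty"] <- NA_real_
          plates[[length(plates) + 1L]] <- plate_grid(
            vals, roles, ids,
            plate_id = sprintf("%s_plate%02d", ln, p),
            cell_line = ln, replicate = rep
          )
        }
      }
    }
    truth <- data.frame(
      probe_id = rep(probes, times = config$n_cell_lines),
      cell_line = rep(lines, each = config$n_probes),
      effect_log2 = as.vector(effect),
      stringsAsFactors = FALSE
    )
    truth$is_hit <- truth$effect_log2 != 0
    list(plates = plates, truth = truth)
  })
}

#' Configuration of a synthetic 3'UTR with planted seed sites
#'
#' @param length UTR length in nt.
#' @param gc_fraction Background GC content in \[0, 1\] (default 0.45).
#' @param planted_sites data.frame with columns `mir_name`, `site_type`
#'   (one of `6mer/7mer-A1/7mer-m8/8mer`) and `start` (1-based); may have
#'   zero rows. Sites must be non-overlapping and fit inside the UTR.
#' @param rng_seed Integer seed.
#' @return Validated list of class `utr_sim_config`.
#' @export
utr_sim_config <- function(length, gc_fraction = 0.45,
                           planted_sites = data.frame(
                             mir_name = character(), site_type = character(),
                             start = integer()),
                           rng_seed = 1L) {
  stopifnot(length >= 1L, gc_fraction >= 0, gc_fraction <= 1)
  ps <- as.data.frame(planted_sites, stringsAsFactors = FALSE)
  if (nrow(ps)) {
    stopifnot(all(c("mir_name", "site_type", "start") %in% names(ps)))
    if (!all(ps$site_type %in% SITE_TYPES))
      stop("site_type must be one of: ", paste(SITE_TYPES, collapse = ", "))
    ends <- ps$start + SITE_LEN[ps$site_type] - 1L
    if (any(ps$start < 1L) || any(ends > length))
      stop("planted site out of range (planting error)")
    ord <- order(ps$start)
    if (any(ps$start[ord][-1L] <= ends[ord][-nrow(ps)]))
      stop("planted sites overlap (planting error)")
  }
  structure(
    list(length = as.integer(length), gc_fraction = gc_fraction,
         planted_sites = ps, rng_seed = as.integer(rng_seed)),
    class = "utr_sim_config"
  )
}

#' Simulate a 3'UTR with planted seed sites of known type and position
#'
#' Builds a random-background UTR (GC content `gc_fraction`), writes the
#' exact match string of each planted site at its requested start, and
#' places guard bases immediately flanking each site so a planted 6mer is
#' not accidentally upgraded to a 7mer/8mer. The construct is then
#' verified by rescanning with [find_seed_sites()] for every supplied
#' miRNA; if any spurious (unplanted) site appears, the background is
#' rejected and resampled, up to `max_tries` attempts.
#'
#' @param config A [utr_sim_config()].
#' @param mirs List of [mature_mir()] objects; must contain every miRNA
#'   named in `planted_sites`, and the no-spurious-site guarantee covers
#'   all of them.
#' @param id Identifier of the generated UTR.
#' @param max_tries Rejection-sampling cap (default 1000).
#' @return List with `utr` ([utr_seq()]) and `truth` (site data.frame in
#'   [find_seed_sites()] layout, sorted by start).
#' @export
simulate_utr <- function(config, mirs, id = "sim_utr", max_tries = 1000L) {
  stopifnot(inherits(config, "utr_sim_config"))
  if (inherits(mirs, "mature_mir")) mirs <- list(mirs)
  names(mirs) <- vapply(mirs, `[[`, "", "name")
  ps <- config$planted_sites
  if (nrow(ps) && !all(ps$mir_name %in% names(mirs)))
    stop("planted_sites reference miRNAs missing from `mirs`")

  bases <- c("A", "C", "G", "U")
  probs <- c((1 - config$gc_fraction) / 2, config$gc_fraction / 2,
             config$gc_fraction / 2, (1 - config$gc_fraction) / 2)

  truth <- if (nrow(ps)) {
    data.frame(
      mir_name = ps$mir_name, utr_id = id,
      start = as.integer(ps$start),
      end = as.integer(ps$start + SITE_LEN[ps$site_type] - 1L),
      site_type = ps$site_type,
      target_seq = vapply(seq_len(nrow(ps)), function(i)
        site_match_string(mirs[[ps$mir_name[i]]], ps$site_type[i]), ""),
      stringsAsFactors = FALSE
    )
  } else empty_sites()
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL

  planted_mask <- rep(FALSE, config$length)
  for (i in seq_len(nrow(truth)))
    planted_mask[truth$start[i]:truth$end[i]] <- TRUE

  withr_seed(config$rng_seed, {
    for (try in seq_len(max_tries)) {
      chars <- sample(bases, config$length, replace = TRUE, prob = probs)
      for (i in seq_len(nrow(truth))) {
        mir <- mirs[[truth$mir_name[i]]]
        s <- truth$start[i]; e <- truth$end[i]; ty <- truth$site_type[i]
        chars[s:e] <- strsplit(truth$target_seq[i], "")[[1]]
        # guards (background positions only): no m8 pairing 5' of a site
        # lacking it, no A1 adenosine 3' of one
        if (!ty %in% c("7mer-m8", "8mer") && s > 1L && !planted_mask[s - 1L]) {
          m8 <- complement_base(substr(mir$sequence, 8L, 8L))
          if (chars[s - 1L] == m8)
            chars[s - 1L] <- sample(setdiff(bases, m8), 1L)
        }
        if (!ty %in% c("7mer-A1", "8mer") && e < config$length &&
            !planted_mask[e + 1L] && chars[e + 1L] == "A")
          chars[e + 1L] <- sample(c("C", "G", "U"), 1L)
      }
      utr <- utr_seq(id, paste(chars, collapse = ""))
      found <- scan_utrs(mirs, utr)
      rownames(found) <- NULL
      if (identical_site_tables(found, truth)) return(list(utr = utr, truth = truth))
    }
    stop("could not generate a UTR free of spurious sites in ",
         max_tries, " attempts")
  })
}

identical_site_tables <- function(a, b) {
  cols <- c("mir_name", "start", "end", "site_type", "target_seq")
  nrow(a) == nrow(b) &&
    (nrow(a) == 0L ||
     isTRUE(all.equal(a[order(a$start, a$mir_name), cols],
                      b[order(b$start, b$mir_name), cols],
                      check.attributes = FALSE)))
}

#' Configuration of a synthetic qPCR experiment
#'
#' Generative model (perfect amplification efficiency of 2):
#' `Ct(gene, sample) = base_ct(gene) - log2(true_fold) + N(0, ct_noise_sd)`;
#' reference genes have fold 1 in every sample, so their Ct is constant
#' across samples up to noise. The calibrator sample has fold 1 for every
#' gene by construction.
#'
#' @param genes Character vector of target genes.
#' @param samples Character vector of sample labels; the first is the
#'   calibrator unless `calibrator_sample` says otherwise.
#' @param true_fold data.frame (`gene`, `sample`, `fold`) of true
#'   expression fold changes vs the calibrator; omitted pairs default to
#'   fold 1. All folds must be positive.
#' @param reference_genes Character vector (default `c("U18", "L19")`,
#'   small-RNA and ribosomal endogenous references).
#' @param ct_noise_sd Ct noise SD in cycles (default 0.2).
#' @param base_ct Baseline target Ct in the calibrator (default 24).
#' @param ref_ct Reference-gene Ct (default 18).
#' @param calibrator_sample Calibrator label.
#' @param rng_seed Integer seed.
#' @return Validated list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(genes, samples,
                            true_fold = data.frame(gene = character(),
                                                   sample = character(),
                                                   fold = numeric()),
                            reference_genes = c("U18", "L19"),
                            ct_noise_sd = 0.2, base_ct = 24, ref_ct = 18,
                            calibrator_sample = samples[1],
                            rng_seed = 1L) {
  tf <- as.data.frame(true_fold, stringsAsFactors = FALSE)
  stopifnot(length(genes) >= 1L, length(samples) >= 1L,
            ct_noise_sd >= 0, calibrator_sample %in% samples)
  if (nrow(tf)) {
    stopifnot(all(c("gene", "sample", "fold") %in% names(tf)),
              all(tf$gene %in% genes), all(tf$sample %in% samples))
    if (any(tf$fold <= 0)) stop("true folds must be positive")
    if (any(tf$sample == calibrator_sample & tf$fold != 1))
      stop("the calibrator sample's folds are 1 by definition")
  }
  structure(
    list(genes = genes, samples = samples, true_fold = tf,
         reference_genes = reference_genes, ct_noise_sd = ct_noise_sd,
         base_ct = base_ct, ref_ct = ref_ct,
         calibrator_sample = calibrator_sample,
         rng_seed = as.integer(rng_seed)),
    class = "qpcr_sim_config"
  )
}

#' Simulate a table of qPCR Ct records
#'
#' @param config A [qpcr_sim_config()].
#' @return data.frame of Ct records: `sample`, `gene`, `ct`, `role`
#'   (`target`/`reference`), reproducible under the config seed.
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  withr_seed(config$rng_seed, {
    grid <- expand.grid(gene = config$genes, sample = config$samples,
                        stringsAsFactors = FALSE)
    fold <- rep(1, nrow(grid))
    if (nrow(config$true_fold)) {
      key <- paste(grid$gene, grid$sample, sep = "\r")
      tk <- paste(config$true_fold$gene, config$true_fold$sample, sep = "\r")
      m <- match(key, tk)
      fold[!is.na(m)] <- config$true_fold$fold[m[!is.na(m)]]
    }
    targets <- data.frame(
      sample = grid$sample, gene = grid$gene,
      ct = config$base_ct - log2(fold) +
        stats::rnorm(nrow(grid), 0, config$ct_noise_sd),
      role = "target", stringsAsFactors = FALSE
    )
    refs <- expand.grid(gene = config$reference_genes,
                        sample = config$samples, stringsAsFactors = FALSE)
    refs <- data.frame(
      sample = refs$sample, gene = refs$gene,
      ct = config$ref_ct + stats::rnorm(nrow(refs), 0, config$ct_noise_sd),
      role = "reference", stringsAsFactors = FALSE
    )
    out <- rbind(targets, refs)
    out[order(out$sample, out$role, out$gene), , drop = FALSE]
  })
}
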