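#' Mature sequences of the three AR-modulatory miRNAs
#'
#' Reads the bundled miRBase mature sequences of hsa-miR-346,
#' hsa-miR-361-3p and hsa-miR-197-3p.
#'
#' @return Named list of [mature_mir()] objects.
#' @export
ar_modulatory_mirs <- function() {
  read_mir_fasta(system.file("extdata", "mature_mirs.fa",
                             package = "seedscreen", mustWork = TRUE))
}

#' Placeholder AR pathway signature gene list
#'
#' The bundled 43-gene list of androgen-responsive genes used by the
#' package's tests and examples. It is a synthetic placeholder: the AR
#' activity score is defined over a user-supplied signature file, and
#' this list only exercises the machinery.
#'
#' @return Character vector of 43 gene symbols.
#' @export
ar_signature_genes <- function() {
  path <- system.file("extdata", "ar_signature_43_synthetic_placeholder.txt",
                      package = "seedscreen", mustWork = TRUE)
  lines <- readLines(path)
  lines <- trimws(lines[!startsWith(lines, "#")])
  lines[nzchar(lines)]
}

# Planted-site tables of the synthetic stand-in UTR panel. Site starts are
# the published 1-based coordinates for each transcript's 3'UTR; the
# surrounding sequence is random background (the real annotated sequences
# are not redistributed with the package), so the panel exercises the
# scanner and its coordinate conventions, not the annotation itself.
panel_definitions <- function() {
  list(
    AR_3UTR_synthetic = list(
      length = 6800L, seed = 101L,
      sites = data.frame(
        mir_name = c("hsa-miR-361-3p", "hsa-miR-361-3p", "hsa-miR-197-3p",
                     "hsa-miR-346", "hsa-miR-197-3p", "hsa-miR-361-3p",
                     "hsa-miR-361-3p", "hsa-miR-346"),
        site_type = c("6mer", "7mer-m8", "6mer", "7mer-A1", "6mer",
                      "6mer", "6mer", "6mer"),
        start = c(407L, 787L, 3043L, 3185L, 4308L, 5772L, 6070L, 6283L),
        stringsAsFactors = FALSE
      )
    ),
    ARV7_3UTR_synthetic = list(
      length = 1200L, seed = 102L,
      sites = data.frame(
        mir_name = "hsa-miR-361-3p", site_type = "7mer-m8", start = 981L,
        stringsAsFactors = FALSE
      )
    ),
    # AR-v567es is built separately: it reuses the wild-type stand-in
    # sequence verbatim and appends a 3' extension carrying the
    # variant-specific miR-346 site at 8353 (see synthetic_utr_panel).
    ARHGDIA_3UTR_synthetic = list(
      length = 1300L, seed = 104L,
      sites = data.frame(
        mir_name = c("hsa-miR-346", "hsa-miR-346"),
        site_type = c("7mer-m8", "8mer"),
        start = c(556L, 1084L),
        stringsAsFactors = FALSE
      )
    ),
    TAGLN2_3UTR_synthetic = list(
      length = 700L, seed = 105L,
      sites = data.frame(
        mir_name = "hsa-miR-197-3p", site_type = "7mer-m8", start = 511L,
        stringsAsFactors = FALSE
      )
    ),
    YWHAZ_3UTR_synthetic = list(
      length = 1900L, seed = 106L,
      sites = data.frame(
        mir_name = c("hsa-miR-346", "hsa-miR-346"),
        site_type = c("7mer-m8", "8mer"),
        start = c(17L, 1713L),
        stringsAsFactors = FALSE
      )
    )
  )
}

#' Synthetic stand-in 3'UTR panel with sites at published coordinates
#'
#' Deterministically builds synthetic stand-ins for the extended
#' (~6.8 kb) wild-type AR 3'UTR, the AR-V7 and AR-v567es variant 3'UTRs
#' and the ARHGDIA/TAGLN2/YWHAZ 3'UTRs: random background sequence with
#' seed-complementarity sites for the three AR-modulatory miRNAs planted
#' at the 1-based coordinates reported for the real transcripts (e.g.
#' miR-361-3p at 407 and 5772, miR-346 at 3185 and 6283, miR-197 at 3043
#' on the wild-type AR UTR; the variant-specific miR-361-3p site at 981
#' of AR-V7 and miR-346 site at 8353 of AR-v567es; miR-346 at 556 of
#' ARHGDIA, miR-197 at 511 of TAGLN2, miR-346 at 17 of YWHAZ). The
#' sequences are synthetic -- the annotated sequences themselves are not
#' bundled -- so the panel validates scanning and coordinate conventions
#' end-to-end with known ground truth.
#'
#' @param mirs Named list of [mature_mir()] (default
#'   [ar_modulatory_mirs()]).
#' @return List with `utrs` (named list of [utr_seq()]), `truth`
#'   (combined planted-site table) and `mirs`.
#' @export
synthetic_utr_panel <- function(mirs = ar_modulatory_mirs()) {
  defs <- panel_definitions()
  utrs <- list()
  truth <- list()
  for (nm in names(defs)) {
    d <- defs[[nm]]
    cfg <- utr_sim_config(length = d$length, gc_fraction = 0.45,
                          planted_sites = d$sites, rng_seed = d$seed)
    sim <- simulate_utr(cfg, mirs, id = nm)
    utrs[[nm]] <- sim$utr
    truth[[nm]] <- sim$truth
  }

  # AR-v567es: the wild-type stand-in extended at the 3' end, so the
  # retained sites keep identical flanking context, plus one
  # variant-specific miR-346 site at 8353 in the extension
  wt <- utrs$AR_3UTR_synthetic
  v_id <- "ARV567ES_3UTR_synthetic"
  ext_len <- 1800L
  ext_site <- data.frame(mir_name = "hsa-miR-346", site_type = "6mer",
                         start = 8353L - wt$length, stringsAsFactors = FALSE)
  v_truth <- rbind(
    transform(truth$AR_3UTR_synthetic, utr_id = v_id),
    data.frame(mir_name = "hsa-miR-346", utr_id = v_id, start = 8353L,
               end = 8358L, site_type = "6mer",
               target_seq = site_match_string(mirs[["hsa-miR-346"]], "6mer"),
               stringsAsFactors = FALSE)
  )
  for (try in 1:100) {
    ext <- simulate_utr(
      utr_sim_config(length = ext_len, gc_fraction = 0.45,
                     planted_sites = ext_site, rng_seed = 103L + try - 1L),
      mirs, id = "ext")
    cand <- utr_seq(v_id, paste0(wt$sequence, ext$utr$sequence))
    scanned <- scan_utrs(mirs, cand)
    if (identical_site_tables(scanned, v_truth)) {
      utrs[[v_id]] <- cand
      rownames(v_truth) <- NULL
      truth[[v_id]] <- v_truth
      break
    }
  }
  if (is.null(utrs[[v_id]]))
    stop("could not assemble an artifact-free extended variant UTR")

  ord <- c("AR_3UTR_synthetic", "ARV7_3UTR_synthetic", v_id,
           "ARHGDIA_3UTR_synthetic", "TAGLN2_3UTR_synthetic",
           "YWHAZ_3UTR_synthetic")
  utrs <- utrs[ord]
  list(utrs = utrs,
       truth = do.call(rbind, c(unname(truth[ord]), list(empty_sites()))),
       mirs = mirs)
}
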