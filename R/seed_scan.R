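#' @title Canonical seed site taxonomy
#' @description Internal constants for the four canonical site types.
#' Strength ordering: 8mer > 7mer-m8 > 7mer-A1 > 6mer.
#' @name seed-taxonomy
#' @keywords internal
NULL

SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")
SITE_RANK <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer" = 4L)
SITE_LEN <- c("6mer" = 6L, "7mer-A1" = 7L, "7mer-m8" = 7L, "8mer" = 8L)

# The exact UTR substring (5'->3') a site of each type must equal.
# Antiparallel pairing puts miR position 1 opposite the 3'-most site
# nucleotide; the A1 adenosine is therefore appended at the 3' end.
site_match_string <- function(mir, type) {
  switch(type,
    "6mer"    = reverse_complement(mir$seed6),
    "7mer-A1" = paste0(reverse_complement(mir$seed6), "A"),
    "7mer-m8" = reverse_complement(mir$seed7),
    "8mer"    = paste0(reverse_complement(mir$seed7), "A"),
    stop("unknown site type: ", type)
  )
}

empty_sites <- function() {
  data.frame(
    mir_name = character(), utr_id = character(),
    start = integer(), end = integer(),
    site_type = character(), target_seq = character(),
    stringsAsFactors = FALSE
  )
}

#' Scan a 3'UTR for canonical miRNA seed-complementarity sites
#'
#' Finds every Watson-Crick match between the UTR and the miRNA seed
#' region and classifies it into the canonical site taxonomy:
#' \describe{
#'   \item{6mer}{perfect pairing to miRNA positions 2-7;}
#'   \item{7mer-A1}{6mer plus an adenosine opposite miRNA position 1
#'     (the 3'-most site nucleotide);}
#'   \item{7mer-m8}{perfect pairing to positions 2-8;}
#'   \item{8mer}{pairing to 2-8 plus the A1 adenosine.}
#' }
#' Overlapping classifications at one seed register collapse to the
#' strongest type (8mer > 7mer-m8 > 7mer-A1 > 6mer), and only then is the
#' result filtered to the requested `types`. G:U wobble pairs are not
#' accepted, and `N` never matches. The scan covers the full UTR with no
#' length cap, so kilobase-scale extended UTRs produced by alternative
#' polyadenylation are scanned in their entirety.
#'
#' @param mir A [mature_mir()].
#' @param utr A [utr_seq()].
#' @param types Character vector of site types to report (default all
#'   four).
#' @return A data.frame with one row per site, sorted by `start`:
#'   `mir_name`, `utr_id`, `start`, `end` (1-based inclusive),
#'   `site_type`, `target_seq` (the matched UTR substring, RNA alphabet).
#' @examples
#' mir <- mature_mir("toy-miR", "UGCUAGCAAAAA")  # seed6 GCUAGC
#' utr <- utr_seq("toy-utr", "AAAGCUAGCAAA")
#' find_seed_sites(mir, utr)
#' @export
find_seed_sites <- function(mir, utr, types = SITE_TYPES) {
  stopifnot(inherits(mir, "mature_mir"), inherits(utr, "utr_seq"))
  types <- match.arg(types, SITE_TYPES, several.ok = TRUE)
  n <- utr$length
  if (n < 6L) return(empty_sites())

  chars <- strsplit(utr$sequence, "")[[1]]
  core <- strsplit(reverse_complement(mir$seed6), "")[[1]]
  # UTR base opposite miR position 8 when the register extends one nt 5'
  m8_base <- complement_base(substr(mir$sequence, 8L, 8L))

  # all registers p where utr[p..p+5] pairs the seed 2-7
  hit <- rep(TRUE, n - 5L)
  for (k in 1:6) hit <- hit & (chars[seq_len(n - 5L) + (k - 1L)] == core[k])
  reg <- which(hit)
  if (!length(reg)) return(empty_sites())

  has_m8 <- reg > 1L & c(FALSE, chars)[reg] == m8_base  # chars[reg-1]
  has_a1 <- (reg + 6L) <= n & c(chars, FALSE)[reg + 6L] == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", "6mer")))
  start <- ifelse(has_m8, reg - 1L, reg)
  end <- ifelse(has_a1, reg + 6L, reg + 5L)

  keep <- type %in% types
  if (!any(keep)) return(empty_sites())
  out <- data.frame(
    mir_name = mir$name, utr_id = utr$id,
    start = as.integer(start[keep]), end = as.integer(end[keep]),
    site_type = type[keep],
    target_seq = substring(utr$sequence, start[keep], end[keep]),
    stringsAsFactors = FALSE
  )
  out[order(out$start), , drop = FALSE]
}

#' Scan several miRNAs against several UTRs
#'
#' Convenience wrapper around [find_seed_sites()] over all
#' (miRNA, UTR) combinations.
#'
#' @param mirs List of [mature_mir()] objects.
#' @param utrs List of [utr_seq()] objects (or a single one).
#' @param types Site types to report.
#' @return Combined site data.frame, sorted by UTR then start.
#' @export
scan_utrs <- function(mirs, utrs, types = SITE_TYPES) {
  if (inherits(mirs, "mature_mir")) mirs <- list(mirs)
  if (inherits(utrs, "utr_seq")) utrs <- list(utrs)
  res <- list()
  for (u in utrs) for (m in mirs)
    res[[length(res) + 1L]] <- find_seed_sites(m, u, types)
  out <- do.call(rbind, c(res, list(empty_sites())))
  out[order(out$utr_id, out$start), , drop = FALSE]
}

# context string used to decide whether a wt site and a variant site are
# "the same" site: the matched substring plus up to `flank` nt each side
site_context <- function(utr, start, end, flank = 15L) {
  lo <- max(1L, start - flank)
  hi <- min(utr$length, end + flank)
  substring(utr$sequence, lo, hi)
}

#' Compare seed sites between a wild-type and a variant 3'UTR
#'
#' Classifies every site found in either UTR as shared, wild-type-only or
#' variant-only. Two sites are considered the same physical site when they
#' involve the same miRNA and site type and their matched substring plus
#' up to 15 nt of flanking context on each side are identical strings --
#' a pragmatic identity criterion that tolerates coordinate shifts caused
#' by splice-variant-specific 5' ends or 3' extensions.
#'
#' @param wt,variant [utr_seq()] objects.
#' @param mirs List of [mature_mir()] objects to scan with.
#' @param types Site types to consider.
#' @param flank Context width in nt (default 15).
#' @return A list of class `site_comparison` with data.frames `shared`
#'   (paired wt/variant coordinates), `wt_only` and `variant_only`; the
#'   three partition all sites of both UTRs.
#' @export
compare_wt_variant_sites <- function(wt, variant, mirs,
                                     types = SITE_TYPES, flank = 15L) {
  stopifnot(inherits(wt, "utr_seq"), inherits(variant, "utr_seq"))
  ws <- scan_utrs(mirs, wt, types)
  vs <- scan_utrs(mirs, variant, types)
  ws$context <- if (nrow(ws)) mapply(site_context, ws$start, ws$end,
    MoreArgs = list(utr = wt, flank = flank)) else character()
  vs$context <- if (nrow(vs)) mapply(site_context, vs$start, vs$end,
    MoreArgs = list(utr = variant, flank = flank)) else character()

  shared_w <- integer(); shared_v <- integer()
  used_v <- rep(FALSE, nrow(vs))
  for (i in seq_len(nrow(ws))) {
    j <- which(!used_v &
               vs$mir_name == ws$mir_name[i] &
               vs$site_type == ws$site_type[i] &
               vs$context == ws$context[i])
    if (length(j)) {
      j <- j[1L]
      used_v[j] <- TRUE
      shared_w <- c(shared_w, i)
      shared_v <- c(shared_v, j)
    }
  }
  drop_ctx <- function(d) d[, setdiff(names(d), "context"), drop = FALSE]
  shared <- if (length(shared_w)) {
    w <- drop_ctx(ws)[shared_w, , drop = FALSE]
    v <- drop_ctx(vs)[shared_v, , drop = FALSE]
    data.frame(
      mir_name = w$mir_name, site_type = w$site_type,
      wt_start = w$start, wt_end = w$end,
      variant_start = v$start, variant_end = v$end,
      target_seq = w$target_seq, stringsAsFactors = FALSE
    )
  } else data.frame(
    mir_name = character(), site_type = character(),
    wt_start = integer(), wt_end = integer(),
    variant_start = integer(), variant_end = integer(),
    target_seq = character(), stringsAsFactors = FALSE
  )
  structure(
    list(
      shared = shared,
      wt_only = drop_ctx(ws)[setdiff(seq_len(nrow(ws)), shared_w), , drop = FALSE],
      variant_only = drop_ctx(vs)[!used_v, , drop = FALSE]
    ),
    class = "site_comparison"
  )
}

#' @export
print.site_comparison <- function(x, ...) {
  cat("<site_comparison>", nrow(x$shared), "shared,",
      nrow(x$wt_only), "wt-only,", nrow(x$variant_only), "variant-only\n")
  invisible(x)
}

# miR position opposite UTR position q of a site (antiparallel pairing)
mir_position_at <- function(site_start, site_end, site_type, q) {
  base <- if (site_type %in% c("7mer-A1", "8mer")) 1L else 2L
  base + (site_end - q)
}

#' Disrupt a seed site by targeted point substitutions
#'
#' Substitutes `n_mut` nucleotides inside the seed-pairing span of a site
#' (the A1 adenosine, which is not a complementarity position, is never
#' chosen), each to a base that is neither the current base nor the
#' Watson-Crick complement of the opposing miRNA base. The mutated UTR is
#' rescanned; the function retries position/base choices (deterministically
#' under `rng_seed`) until no site of any type for `mir` overlaps the
#' original span and all other sites of `mir` are unchanged.
#'
#' @param utr A [utr_seq()].
#' @param site One row of a [find_seed_sites()] result (data.frame row or
#'   list with `start`, `end`, `site_type`).
#' @param mir The [mature_mir()] the site belongs to.
#' @param n_mut Number of substitutions, at least 3 by the package's
#'   mutagenesis convention.
#' @param rng_seed Integer seed; the design is reproducible.
#' @param max_tries Attempts before giving up.
#' @return The mutated [utr_seq()] (id suffixed `_mut`), with attribute
#'   `"mutated_positions"`.
#' @export
mutate_seed_site <- function(utr, site, mir, n_mut = 3L, rng_seed = 1L,
                             max_tries = 100L) {
  stopifnot(inherits(utr, "utr_seq"), inherits(mir, "mature_mir"))
  start <- as.integer(site$start); end <- as.integer(site$end)
  type <- as.character(site$site_type)
  if (!type %in% SITE_TYPES) stop("unknown site type: ", type)
  if (start < 1L || end > utr$length || end - start + 1L != SITE_LEN[[type]])
    stop("site does not lie within the UTR or has the wrong span")
  # seed-pairing span excludes the 3' A1 adenosine for A1-containing types
  pair_end <- if (type %in% c("7mer-A1", "8mer")) end - 1L else end
  span <- start:pair_end
  if (n_mut < 1L || n_mut > length(span))
    stop("n_mut must be between 1 and the seed-pairing span length (",
         length(span), ")")

  before <- find_seed_sites(mir, utr)
  others <- before[!(before$start <= end & before$end >= start), , drop = FALSE]
  chars <- strsplit(utr$sequence, "")[[1]]
  bases <- c("A", "C", "G", "U")

  res <- withr_seed(rng_seed, {
    for (try in seq_len(max_tries)) {
      pos <- sort(sample(span, n_mut))
      new_chars <- chars
      ok <- TRUE
      for (q in pos) {
        mp <- mir_position_at(start, end, type, q)
        opp <- substr(mir$sequence, mp, mp)
        allowed <- setdiff(bases, c(chars[q], complement_base(opp)))
        if (!length(allowed)) { ok <- FALSE; break }
        new_chars[q] <- sample(allowed, 1L)
      }
      if (!ok) next
      mut <- utr_seq(paste0(utr$id, "_mut"), paste(new_chars, collapse = ""))
      after <- find_seed_sites(mir, mut)
      at_locus <- after[after$start <= end & after$end >= start, , drop = FALSE]
      rest <- after[!(after$start <= end & after$end >= start), , drop = FALSE]
      if (nrow(at_locus) == 0L && identical_sites(rest, others)) {
        attr(mut, "mutated_positions") <- pos
        return(mut)
      }
    }
    NULL
  })
  if (is.null(res))
    stop("could not disrupt the site within ", max_tries,
         " attempts without side effects (mutagenesis error)")
  res
}

identical_sites <- function(a, b) {
  cols <- c("start", "end", "site_type")
  nrow(a) == nrow(b) &&
    (nrow(a) == 0L || isTRUE(all.equal(a[order(a$start), cols],
                                       b[order(b$start), cols],
                                       check.attributes = FALSE)))
}

# run code with a local RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seed-site conservation across an alignment
#'
#' Given a multiple alignment of UTR orthologues (gapped strings of equal
#' width) and a site on the reference sequence, computes the fraction of
#' species carrying an intact site of the same or stronger type at the
#' homologous position. The reference always counts as intact. Each other
#' species' full ungapped sequence is rescanned, and the species is intact
#' if a site of rank >= the reference site's type covers the homologous
#' span (the species positions aligned to the reference site's columns).
#' A site falling entirely into alignment gaps is not intact.
#'
#' @param alignment Named character vector of aligned sequences (equal
#'   nchar, `-` for gaps), including the reference.
#' @param site A site row (needs `start`, `end`, `site_type`) in
#'   reference (ungapped) coordinates.
#' @param mir The [mature_mir()] of the site.
#' @param ref Name of the reference sequence in `alignment`.
#' @return Fraction in \[0, 1\] of species (including the reference) with
#'   an intact site.
#' @export
site_conservation <- function(alignment, site, mir, ref = names(alignment)[1]) {
  stopifnot(is.character(alignment), !is.null(names(alignment)),
            ref %in% names(alignment))
  widths <- unique(nchar(alignment))
  if (length(widths) != 1L) stop("aligned sequences must have equal width")
  refg <- strsplit(alignment[[ref]], "")[[1]]
  ungapped_cols <- which(refg != "-")
  start <- as.integer(site$start); end <- as.integer(site$end)
  type <- as.character(site$site_type)
  if (end > length(ungapped_cols))
    stop("site extends beyond the reference sequence")
  site_cols <- ungapped_cols[start:end]

  intact <- vapply(names(alignment), function(sp) {
    if (sp == ref) return(TRUE)
    spg <- strsplit(alignment[[sp]], "")[[1]]
    non_gap <- spg != "-"
    in_site <- non_gap[site_cols]
    if (!any(in_site)) return(FALSE)  # site maps entirely into gaps
    sp_pos <- cumsum(non_gap)          # species ungapped coordinate per column
    span_lo <- min(sp_pos[site_cols][in_site])
    span_hi <- max(sp_pos[site_cols][in_site])
    sp_seq <- paste(spg[non_gap], collapse = "")
    hits <- find_seed_sites(mir, utr_seq(sp, sp_seq))
    any(SITE_RANK[hits$site_type] >= SITE_RANK[[type]] &
          hits$start <= span_lo & hits$end >= span_hi)
  }, logical(1))
  mean(intact)
}
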