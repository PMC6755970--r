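#' Construct a mature miRNA object
#'
#' Holds a mature miRNA sequence (5'->3') together with its derived seed
#' subsequences: `seed6` (positions 2-7) and `seed7` (positions 2-8).
#' Watson-Crick complementarity of a 3'UTR stretch to these seeds defines
#' the canonical target-site types scanned by [find_seed_sites()].
#'
#' @param name miRNA identifier, e.g. `"hsa-miR-346"`.
#' @param sequence Mature sequence, 5'->3'; DNA or RNA alphabet (normalised
#'   with [normalize_sequence()]). Must be at least 8 nt.
#' @return An object of class `mature_mir` with fields `name`, `sequence`,
#'   `seed6`, `seed7`.
#' @examples
#' mature_mir("hsa-miR-346", "UGUCUGCCCGCAUGCCUGCCUCU")
#' @export
mature_mir <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) < 8L)
    stop("mature miRNA '", name, "' must be at least 8 nt (got ",
         nchar(sequence), ")")
  structure(
    list(
      name = name,
      sequence = sequence,
      seed6 = substr(sequence, 2L, 7L),
      seed7 = substr(sequence, 2L, 8L)
    ),
    class = "mature_mir"
  )
}

#' @export
print.mature_mir <- function(x, ...) {
  cat("<mature_mir>", x$name, "\n")
  cat("  sequence:", x$sequence, "\n")
  cat("  seed 2-7:", x$seed6, "  seed 2-8:", x$seed7, "\n")
  invisible(x)
}

#' Construct a 3'UTR sequence object
#'
#' Coordinates used throughout the package are 1-based inclusive on this
#' sequence, with position 1 the first nucleotide after the stop codon.
#'
#' @param id Transcript/UTR identifier.
#' @param sequence 5'->3' nucleotide string (DNA or RNA alphabet).
#' @return An object of class `utr_seq` with fields `id`, `sequence`
#'   (RNA-normalised) and `length`.
#' @export
utr_seq <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) < 1L) stop("UTR sequence must be non-empty")
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence)),
    class = "utr_seq"
  )
}

#' @export
print.utr_seq <- function(x, ...) {
  cat("<utr_seq>", x$id, "-", x$length, "nt\n")
  prefix <- substr(x$sequence, 1L, 60L)
  cat("  ", prefix, if (x$length > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Read mature miRNA sequences from FASTA
#'
#' @param path Path to a FASTA file of mature miRNA sequences (miRBase
#'   style; U or T alphabet). The first whitespace-delimited token of each
#'   header is used as the name.
#' @return Named list of [mature_mir()] objects.
#' @export
read_mir_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nms <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  out <- lapply(seq_along(set), function(i)
    mature_mir(nms[i], as.character(set[[i]])))
  names(out) <- nms
  out
}

#' Read 3'UTR sequences from FASTA
#'
#' @param path Path to a FASTA file of UTR sequences.
#' @return Named list of [utr_seq()] objects.
#' @export
read_utr_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nms <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  out <- lapply(seq_along(set), function(i)
    utr_seq(nms[i], as.character(set[[i]])))
  names(out) <- nms
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A list of [utr_seq()] or [mature_mir()] objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_seq_fasta <- function(seqs, path) {
  if (inherits(seqs, "utr_seq") || inherits(seqs, "mature_mir"))
    seqs <- list(seqs)
  strings <- vapply(seqs, function(s) s$sequence, "")
  names(strings) <- vapply(seqs, function(s) if (is.null(s$id)) s$name else s$id, "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(strings), path)
  invisible(path)
}
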