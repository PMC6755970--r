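#' Normalise a nucleotide sequence to canonical RNA
#'
#' Uppercases the sequence and converts thymine to uracil so that DNA- and
#' RNA-alphabet inputs scan identically. `N` is retained as an ambiguity
#' code; it never participates in a seed match.
#'
#' @param raw Character vector of nucleotide strings over
#'   `A/C/G/T/U/a/c/g/t/u/N/n`.
#' @return Character vector of the same length over `A/C/G/U/N`.
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw)) stop("sequence must be a character vector")
  out <- chartr("acgtun", "ACGUUN", raw)
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGUN]", "", out[bad]), "")))
    stop("invalid nucleotide characters: ", paste(ch, collapse = ", "))
  }
  out
}

#' Reverse complement of an RNA sequence
#'
#' Watson-Crick reverse complement (A-U, G-C) on the RNA alphabet; `N`
#' maps to `N`. An involution: `reverse_complement(reverse_complement(x))`
#' returns `x`.
#'
#' @param seq Character vector of normalised RNA strings (see
#'   [normalize_sequence()]).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAGGUU")  # "AACCUU"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_sequence(seq)
  comp <- chartr("ACGUN", "UGCAN", seq)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
}

# complement without reversal, used when reasoning position-by-position
complement_base <- function(base) {
  chartr("ACGUN", "UGCAN", base)
}
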