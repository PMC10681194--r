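# IUPAC nucleotide state algebra.
#
# Sanger sequencing of a PCR product amplified from a diploid-Z male reads
# both Tpi alleles at once: a heterozygous position appears as two overlapping
# chromatogram peaks and is base-called as the IUPAC ambiguity letter covering
# both states (e.g. C/T -> Y). These helpers decode and re-encode that
# representation, using the code map shipped with Biostrings.

.iupac_map <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(s) strsplit(s, "")[[1]])
})

.iupac_rev <- local({
  m <- vapply(.iupac_map, function(s) paste(sort(s), collapse = ""), "")
  setNames(names(m), m)
})

.iupac_letters <- c(names(.iupac_map))

#' Decode an IUPAC letter to its nucleotide state set
#'
#' @param letter A single IUPAC nucleotide letter (case-insensitive). `N`
#'   decodes to the full set `{A,C,G,T}`.
#' @return Character vector of unambiguous bases, sorted.
#' @examples
#' iupac_states("Y")  # C, T
#' @export
iupac_states <- function(letter) {
  stopifnot(is.character(letter), length(letter) == 1L, nchar(letter) == 1L)
  up <- toupper(letter)
  if (up == "-") return(character(0))
  states <- .iupac_map[[up]]
  if (is.null(states)) {
    stop("not an IUPAC nucleotide letter: '", letter, "'", call. = FALSE)
  }
  sort(states)
}

#' Encode a nucleotide state set as its IUPAC letter
#'
#' @param states Character vector drawn from `A`, `C`, `G`, `T` (non-empty).
#' @return The single IUPAC letter whose state set equals `unique(states)`.
#' @examples
#' iupac_letter(c("C", "T"))  # "Y"
#' @export
iupac_letter <- function(states) {
  states <- sort(unique(toupper(states)))
  if (length(states) == 0L || !all(states %in% c("A", "C", "G", "T"))) {
    stop("states must be a non-empty subset of A/C/G/T", call. = FALSE)
  }
  unname(.iupac_rev[[paste(states, collapse = "")]])
}

#' Merge two IUPAC letters into the letter covering both state sets
#'
#' Emulates the positionwise overlap of two Sanger traces: equal bases stay
#' themselves, differing bases merge to the covering ambiguity letter.
#'
#' @param a,b Single IUPAC letters.
#' @return A single IUPAC letter.
#' @export
iupac_merge <- function(a, b) {
  iupac_letter(union(iupac_states(a), iupac_states(b)))
}

# Vectorized merge of two equal-length sequences (character scalars).
.merge_seqs <- function(x, y) {
  stopifnot(nchar(x) == nchar(y))
  if (x == y) return(x)
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  diff <- which(xs != ys)
  for (k in diff) xs[k] <- iupac_merge(xs[k], ys[k])
  paste(xs, collapse = "")
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' @param seq Character scalar over the IUPAC alphabet.
#' @return The reverse complement, ambiguity letters complemented setwise
#'   (via [Biostrings::reverseComplement()]).
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.validate_iupac <- function(seq, id = "sequence") {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% .iupac_letters)
  if (length(bad)) {
    stop("record '", id, "': non-IUPAC character '", chars[bad[1]],
         "' at position ", bad[1], call. = FALSE)
  }
  invisible(TRUE)
}
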