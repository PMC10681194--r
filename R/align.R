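# Pairwise global alignment and mapping of annotated sites onto reads.
#
# Replaces the interactive alignment step of the original workflow with a
# deterministic Gotoh affine-gap aligner (compiled, see src/). An IUPAC
# letter scores as a match against a base whenever the base belongs to the
# letter's state set, which keeps heterozygous (overlapping-trace) reads
# alignable at full score.

#' Alignment scoring parameters
#'
#' Defaults suit high-identity Sanger amplicons: match +1, mismatch -1,
#' gap open -2, gap extend -0.5 (a gap run of length k costs
#' `gap_open + k * gap_extend`).
#'
#' @param match,mismatch,gap_open,gap_extend Numeric scores.
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -1,
                          gap_open = -2, gap_extend = -0.5) {
  stopifnot(match > mismatch, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

.seq_of <- function(x) {
  if (is.character(x)) return(unname(x[1]))
  if (!is.null(x$seq)) return(x$seq)
  if (inherits(x, "reference_amplicon")) return(x$sequence)
  stop("cannot extract a sequence from this object", call. = FALSE)
}

#' Global pairwise alignment of a read against a reference
#'
#' @param read Read sequence: a character scalar, a one-row data frame with a
#'   `seq` column, or a list with `$seq`.
#' @param ref A [reference_amplicon()] or character scalar.
#' @param scoring An [align_scoring()] object.
#' @param orientation Orientation label stored on the result.
#' @return An object of class `amplicon_alignment`: `aligned_ref`,
#'   `aligned_read` (equal-length gapped strings), `score`, `orientation`.
#'   Ties during traceback are broken deterministically: diagonal first,
#'   then gap-in-read, then gap-in-ref.
#' @export
global_align <- function(read, ref, scoring = align_scoring(),
                         orientation = "forward") {
  rseq <- .seq_of(read)
  xseq <- .seq_of(ref)
  stopifnot(nchar(rseq) > 0L, nchar(xseq) > 0L)
  res <- .gotoh_align(xseq, rseq, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  structure(list(aligned_ref = res$aligned_ref,
                 aligned_read = res$aligned_read,
                 score = res$score, orientation = orientation),
            class = "amplicon_alignment")
}

#' @export
print.amplicon_alignment <- function(x, ...) {
  cat("Global alignment (", x$orientation, "), score ", x$score, ", ",
      nchar(x$aligned_ref), " columns\n", sep = "")
  invisible(x)
}

#' Orient a read against a reference
#'
#' Aligns the read and its reverse complement; keeps the orientation with the
#' strictly higher score (ties go to forward).
#'
#' @inheritParams global_align
#' @return A list with `seq` (the read in reference orientation),
#'   `orientation` (`"forward"` or `"reverse-complement"`) and `alignment`
#'   (the winning [global_align()] result).
#' @export
orient_read <- function(read, ref, scoring = align_scoring()) {
  rseq <- .seq_of(read)
  fwd <- global_align(rseq, ref, scoring, orientation = "forward")
  rcseq <- revcomp(rseq)
  rev <- global_align(rcseq, ref, scoring, orientation = "reverse-complement")
  if (rev$score > fwd$score) {
    list(seq = rcseq, orientation = "reverse-complement", alignment = rev)
  } else {
    list(seq = rseq, orientation = "forward", alignment = fwd)
  }
}

# Map reference column -> alignment column; returns integer vector over
# alignment columns giving the reference column at each (NA on insertions).
.ref_column_map <- function(alignment) {
  rchars <- strsplit(alignment$aligned_ref, "")[[1]]
  idx <- cumsum(rchars != "-")
  idx[rchars == "-"] <- NA_integer_
  idx
}

# First and last alignment columns covered by the read (non-gap).
.read_span <- function(alignment) {
  dchars <- strsplit(alignment$aligned_read, "")[[1]]
  cov <- which(dchars != "-")
  if (length(cov) == 0L) c(NA_integer_, NA_integer_) else range(cov)
}

#' Call an annotated marker site on an aligned read
#'
#' @param alignment An [global_align()] result for the read against `ref`.
#' @param ref The [reference_amplicon()] used in the alignment.
#' @param site A [marker_site()] belonging to `ref`, or its name.
#' @return An object of class `site_call`: `site_name`, `observed_states`
#'   (nucleotide set decoded from the read's IUPAC letter) and `status`, one
#'   of `unambiguous`, `ambiguous`, `gap`, `uncovered`. `N` in the read
#'   decodes to the full state set and is therefore always `ambiguous`.
#' @export
call_site <- function(alignment, ref, site) {
  if (is.character(site)) site_name <- site else site_name <- site$name
  col <- .site_column(ref, site)
  map <- .ref_column_map(alignment)
  acol <- which(map == col)
  if (length(acol) != 1L) {
    stop("site column ", col, " not present in the alignment", call. = FALSE)
  }
  span <- .read_span(alignment)
  dchar <- substr(alignment$aligned_read, acol, acol)
  if (is.na(span[1]) || acol < span[1] || acol > span[2]) {
    status <- "uncovered"; states <- character(0)
  } else if (dchar == "-") {
    status <- "gap"; states <- character(0)
  } else {
    states <- iupac_states(dchar)
    status <- if (length(states) == 1L) "unambiguous" else "ambiguous"
  }
  structure(list(site_name = site_name, observed_states = states,
                 status = status),
            class = "site_call")
}

#' @export
print.site_call <- function(x, ...) {
  cat("site ", x$site_name, ": ",
      if (length(x$observed_states)) paste(x$observed_states, collapse = "/")
      else "-",
      " (", x$status, ")\n", sep = "")
  invisible(x)
}

#' Construct a site call directly from observed states
#'
#' Mostly useful for examples, simulators and tests; pipeline site calls
#' come from [call_site()].
#'
#' @param site_name Site identifier.
#' @param observed_states Character vector of bases observed at the site.
#' @param status Call status; derived from the state count by default.
#' @return A `site_call` object.
#' @export
site_call <- function(site_name, observed_states,
                      status = if (length(observed_states) == 1L)
                        "unambiguous" else "ambiguous") {
  structure(list(site_name = site_name,
                 observed_states = sort(unique(observed_states)),
                 status = status),
            class = "site_call")
}

# Extract the read bases aligned to reference columns [col_start, col_end],
# including read insertions strictly inside the window; insertions abutting
# either window edge are excluded. Returns list(segment, covered): covered
# is TRUE when the read's aligned span contains the whole window.
.extract_window <- function(alignment, col_start, col_end) {
  map <- .ref_column_map(alignment)
  a <- which(map == col_start)
  b <- which(map == col_end)
  if (length(a) != 1L || length(b) != 1L) {
    stop("window columns not present in the alignment", call. = FALSE)
  }
  span <- .read_span(alignment)
  covered <- !is.na(span[1]) && span[1] <= a && span[2] >= b
  dchars <- strsplit(alignment$aligned_read, "")[[1]][a:b]
  segment <- paste(dchars[dchars != "-"], collapse = "")
  list(segment = segment, covered = covered)
}

# ---------------------------------------------------------------------------
# Star multiple alignment: every sequence is pairwise-aligned to the first
# (center) sequence and the pairwise alignments are merged on the center's
# coordinates ("once a gap, always a gap"). Adequate for haplotype sets that
# are all small edits of a common segment, which is the use here.

#' Jointly align a set of haplotype sequences
#'
#' @param seqs Named character vector of sequences.
#' @param scoring An [align_scoring()].
#' @return Named character vector of equal-length gapped sequences.
#' @export
align_haplotypes <- function(seqs, scoring = align_scoring()) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  center <- seqs[[1]]
  n <- nchar(center)
  # per sequence: base aligned to each center position, and insertion string
  # after each center position (slot 0 = before the first).
  profs <- lapply(seqs, function(s) {
    if (identical(s, center)) {
      list(base = strsplit(center, "")[[1]], ins = rep("", n + 1L))
    } else {
      al <- global_align(s, center, scoring)
      cc <- strsplit(al$aligned_ref, "")[[1]]
      rc <- strsplit(al$aligned_read, "")[[1]]
      pos <- cumsum(cc != "-")
      base <- rep("-", n)
      ins <- rep("", n + 1L)
      for (k in seq_along(cc)) {
        if (cc[k] != "-") base[pos[k]] <- rc[k]
        else if (rc[k] != "-") ins[pos[k] + 1L] <- paste0(ins[pos[k] + 1L], rc[k])
      }
      list(base = base, ins = ins)
    }
  })
  maxins <- apply(vapply(profs, function(p) nchar(p$ins), numeric(n + 1L)),
                  1L, max)
  if (n == 0L) stop("empty center sequence", call. = FALSE)
  out <- vapply(profs, function(p) {
    pieces <- character(0)
    pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
    pieces <- pad(p$ins[1L], maxins[1L])
    for (k in seq_len(n)) {
      pieces <- c(pieces, p$base[k], pad(p$ins[k + 1L], maxins[k + 1L]))
    }
    paste(pieces, collapse = "")
  }, "")
  setNames(out, names(seqs))
}
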