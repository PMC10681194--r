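# Tpi-based strain identification and TpiI4a200 intron haplotyping.
#
# Tpi is Z-linked; male fall armyworm carry two Z chromosomes, so a directly
# sequenced Tpi amplicon is a superposition of two alleles. The exon-4 site
# gTpi183Y is the strain diagnostic: C -> C-strain (C_Tpi), T -> R-strain
# (R_Tpi), and a C/T overlap (IUPAC Y) marks an inter-strain hybrid (H_Tpi).
# The flanking sites gTpi165Y/gTpi168Y are consistency checks only; a
# disagreement is flagged but never overrides the 183-based call.
#
# The adjacent TpiI4 intron is hypervariable with frequent indels; to keep
# more heterozygous-free sequences usable, haplotyping is restricted to the
# first 60% of the intron (the TpiI4a200 segment, ~200 bp). Any IUPAC
# ambiguity inside that window excludes the specimen; H_Tpi specimens are
# excluded from intron haplotyping by policy (they are heterozygous by
# construction).

.STRAIN_TABLE <- list(C = "C_Tpi", T = "R_Tpi", CT = "H_Tpi")

.strain_from_states <- function(states) {
  key <- paste(states, collapse = "")
  out <- .STRAIN_TABLE[[key]]
  if (is.null(out)) "undetermined" else out
}

# Expected states at the consistency sites for each strain call.
.EXPECTED_CHECK <- list(C_Tpi = "C", R_Tpi = "T", H_Tpi = c("C", "T"))

.check_flag <- function(call, strain) {
  expected <- .EXPECTED_CHECK[[strain]]
  if (is.null(expected)) return(NA_character_)
  if (call$status %in% c("gap", "uncovered")) return(NA_character_)
  if (identical(call$observed_states, sort(expected))) "agree" else "disagree"
}

#' Call the Tpi strain from an aligned read
#'
#' @param alignment [global_align()] result of a Tpi read against `ref`.
#' @param ref Tpi [reference_amplicon()] with `gTpi165Y`, `gTpi168Y` and
#'   `gTpi183Y` annotated.
#' @return An object of class `tpi_strain_call`: `strain` (`C_Tpi`, `R_Tpi`,
#'   `H_Tpi` or `undetermined`), the three site calls, and per-site
#'   consistency flags (`agree`/`disagree`/`NA`) for 165 and 168.
#' @export
call_strain <- function(alignment, ref) {
  s165 <- call_site(alignment, ref, "gTpi165Y")
  s168 <- call_site(alignment, ref, "gTpi168Y")
  s183 <- call_site(alignment, ref, "gTpi183Y")
  strain <- if (s183$status %in% c("gap", "uncovered")) "undetermined"
            else .strain_from_states(s183$observed_states)
  structure(list(strain = strain, site183 = s183, site165 = s165,
                 site168 = s168,
                 flag165 = .check_flag(s165, strain),
                 flag168 = .check_flag(s168, strain)),
            class = "tpi_strain_call")
}

#' @export
print.tpi_strain_call <- function(x, ...) {
  cat("Tpi strain call: ", x$strain, " (gTpi183Y = ",
      paste(x$site183$observed_states, collapse = "/"), ")\n", sep = "")
  if (identical(x$flag165, "disagree") || identical(x$flag168, "disagree")) {
    cat("  consistency disagreement at",
        paste(c("gTpi165Y", "gTpi168Y")[c(identical(x$flag165, "disagree"),
                                          identical(x$flag168, "disagree"))],
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Window of the TpiI4a200 segment in reference columns
#'
#' The analysis window is the first `fraction` of the intron:
#' `L = round(fraction * intron_length)` columns starting at the intron
#' boundary.
#'
#' @param ref Tpi [reference_amplicon()] with intron annotation.
#' @param fraction Fraction of the intron analysed (default 0.6).
#' @return `c(first, last)` reference columns of the window.
#' @export
intron_window <- function(ref, fraction = 0.6) {
  if (is.null(ref$intron_boundary) || is.null(ref$intron_length)) {
    stop("reference has no intron annotation", call. = FALSE)
  }
  L <- round(fraction * ref$intron_length)
  c(ref$intron_boundary, ref$intron_boundary + L - 1L)
}

#' Extract the TpiI4a200 intron segment from an aligned read
#'
#' The segment is the read subsequence aligned to the window columns,
#' including read insertions strictly inside the window (insertions at the
#' right edge are excluded). The call is unusable when the read does not
#' span the full window (`incomplete-coverage`) or when any non-A/C/G/T
#' letter occurs in the segment (`ambiguous-base`, the signature of a
#' heterozygous specimen).
#'
#' @param alignment [global_align()] result of a Tpi read against `ref`.
#' @param ref Tpi [reference_amplicon()] with intron annotation.
#' @param fraction Fraction of the intron analysed (default 0.6).
#' @return An object of class `intron_call`: `usable`, `segment`,
#'   `haplotype_label` (`NA`, filled by [classify_intron_haplotype()]) and
#'   `exclusion_reason`.
#' @export
extract_intron_segment <- function(alignment, ref, fraction = 0.6) {
  win <- intron_window(ref, fraction)
  w <- .extract_window(alignment, win[1], win[2])
  if (!w$covered) {
    return(structure(list(usable = FALSE, segment = "",
                          haplotype_label = NA_character_,
                          exclusion_reason = "incomplete-coverage"),
                     class = "intron_call"))
  }
  if (!grepl("^[ACGT]+$", w$segment)) {
    return(structure(list(usable = FALSE, segment = "",
                          haplotype_label = NA_character_,
                          exclusion_reason = "ambiguous-base"),
                     class = "intron_call"))
  }
  structure(list(usable = TRUE, segment = w$segment,
                 haplotype_label = NA_character_,
                 exclusion_reason = NA_character_),
            class = "intron_call")
}

#' @export
print.intron_call <- function(x, ...) {
  if (x$usable) {
    cat("TpiI4a200 segment (", nchar(x$segment), " bp): ",
        if (is.na(x$haplotype_label)) "unclassified" else x$haplotype_label,
        "\n", sep = "")
  } else {
    cat("TpiI4a200: excluded (", x$exclusion_reason, ")\n", sep = "")
  }
  invisible(x)
}

#' Classify a usable intron segment against the iC haplotype registry
#'
#' @param call A usable `intron_call` from [extract_intron_segment()].
#' @param registry A [haplotype_registry()] for marker `"TpiI4a200"`.
#' @return A list with `call` (label filled in) and the updated `registry`;
#'   a novel segment mints the next unused `iCnn` index in discovery order.
#' @export
classify_intron_haplotype <- function(call,
                                      registry = haplotype_registry("TpiI4a200")) {
  if (!isTRUE(call$usable)) {
    stop("classify_intron_haplotype() requires a usable intron call",
         call. = FALSE)
  }
  stopifnot(registry$marker == "TpiI4a200")
  lab <- registry_lookup(registry, call$segment)
  if (is.na(lab)) {
    lab <- .next_intron_label(registry)
    registry <- .registry_add(registry, lab, call$segment)
  }
  call$haplotype_label <- lab
  list(call = call, registry = registry)
}

#' Type Tpi reads: strain call plus TpiI4a200 intron haplotyping
#'
#' @param reads Data frame with `id` and `seq` columns ([read_fasta()]).
#' @param ref Tpi [reference_amplicon()]; the bundled synthetic reference by
#'   default.
#' @param registry Starting TpiI4a200 [haplotype_registry()].
#' @param fraction Fraction of the intron analysed (default 0.6).
#' @param scoring [align_scoring()] parameters.
#' @param orient If `TRUE`, reads are orientation-checked.
#' @param haplotype_hybrids If `FALSE` (default), H_Tpi specimens are never
#'   intron-haplotyped even when their window is clean
#'   (`strain-mismatch-policy`).
#' @return A list with `calls` (one row per read: `specimen_id`, `strain`,
#'   observed state at 183, consistency flags, `intron_usable`,
#'   `intron_haplotype`, `exclusion_reason`, `orientation`) and the updated
#'   `registry`.
#' @export
type_tpi <- function(reads, ref = faw_reference("Tpi"),
                     registry = haplotype_registry("TpiI4a200"),
                     fraction = 0.6, scoring = align_scoring(),
                     orient = TRUE, haplotype_hybrids = FALSE) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  n <- nrow(reads)
  out <- data.frame(specimen_id = reads$id,
                    strain = character(n), state183 = character(n),
                    flag165 = character(n), flag168 = character(n),
                    intron_usable = logical(n),
                    intron_haplotype = NA_character_,
                    exclusion_reason = NA_character_,
                    orientation = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (orient) {
      o <- orient_read(reads$seq[i], ref, scoring)
      al <- o$alignment
    } else {
      al <- global_align(reads$seq[i], ref, scoring)
    }
    sc <- call_strain(al, ref)
    ic <- extract_intron_segment(al, ref, fraction)
    if (ic$usable && !haplotype_hybrids && sc$strain == "H_Tpi") {
      ic$usable <- FALSE
      ic$exclusion_reason <- "strain-mismatch-policy"
      ic$segment <- ""
    }
    if (ic$usable) {
      res <- classify_intron_haplotype(ic, registry)
      ic <- res$call
      registry <- res$registry
    }
    out$strain[i] <- sc$strain
    out$state183[i] <- paste(sc$site183$observed_states, collapse = "")
    out$flag165[i] <- if (is.na(sc$flag165)) NA_character_ else sc$flag165
    out$flag168[i] <- if (is.na(sc$flag168)) NA_character_ else sc$flag168
    out$intron_usable[i] <- ic$usable
    out$intron_haplotype[i] <- ic$haplotype_label
    out$exclusion_reason[i] <- ic$exclusion_reason
    out$orientation[i] <- al$orientation
  }
  list(calls = out, registry = registry)
}
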