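# COIB h-haplotype typing.
#
# The 3' half of the mitochondrial COI gene (COIB, primers c891F/c1472R)
# carries two polymorphic sites, mCOI1164D and mCOI1287R, whose joint state
# defines the h-haplotype categories: T/A is the R-strain marker (R_COIB),
# while A/A (CSh1), A/G (CSh2), G/A (CSh3) and G/G (CSh4) are the C-strain
# categories (collectively C_COIB). Other unambiguous pairs have not been
# observed in the field and are reported as unknown combinations rather
# than rejected. Within each CSh category, additional polymorphisms across
# the segment define lettered variants (CSh2[e], ...) obtained by exact-
# match dereplication against a registry.

.COIB_TABLE <- c("T|A" = "R_COIB", "A|A" = "CSh1", "A|G" = "CSh2",
                 "G|A" = "CSh3", "G|G" = "CSh4")

.CSH_CATEGORIES <- c("CSh1", "CSh2", "CSh3", "CSh4")

#' Classify the COIB h-haplotype category from the two defining sites
#'
#' @param call1164 [call_site()] result for `mCOI1164D`.
#' @param call1287 [call_site()] result for `mCOI1287R`.
#' @return One of `"R_COIB"`, `"CSh1"`..`"CSh4"`, `"unknown_combo"` (an
#'   unambiguous pair outside the defining table), `"ambiguous"` (a
#'   heterozygous/IUPAC or gapped site) or `"no_call"` (site not covered by
#'   the read).
#' @examples
#' classify_coib(site_call("mCOI1164D", "A"), site_call("mCOI1287R", "G"))
#' @export
classify_coib <- function(call1164, call1287) {
  st <- c(call1164$status, call1287$status)
  if (any(st == "uncovered")) return("no_call")
  if (any(st %in% c("ambiguous", "gap"))) return("ambiguous")
  key <- paste(call1164$observed_states, call1287$observed_states, sep = "|")
  cat <- .COIB_TABLE[key]
  if (is.na(cat)) "unknown_combo" else unname(cat)
}

#' Dereplicate classified COIB reads into lettered variants
#'
#' Each fully covered read whose comparison-span sequence is unambiguous
#' (A/C/G/T only) is matched exactly against the registry; a novel sequence
#' in a CSh category mints the next unused letter for that category in
#' discovery order. R_COIB reads and reads with any ambiguity inside the
#' span receive no variant label.
#'
#' @param calls Data frame with columns `specimen_id`, `category`,
#'   `segment` (read sequence over the comparison span) and `segment_ok`
#'   (logical: fully covered and unambiguous), as produced by [type_coib()].
#' @param registry A [haplotype_registry()] for marker `"COIB"` (empty by
#'   default).
#' @return A list with `calls` (input plus a `variant_label` column) and the
#'   updated `registry`.
#' @export
dereplicate_variants <- function(calls,
                                 registry = haplotype_registry("COIB")) {
  stopifnot(inherits(registry, "haplotype_registry"),
            registry$marker == "COIB")
  labels <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (!calls$category[i] %in% .CSH_CATEGORIES) next
    if (!isTRUE(calls$segment_ok[i])) next
    lab <- registry_lookup(registry, calls$segment[i])
    if (is.na(lab)) {
      lab <- .next_coib_label(registry, calls$category[i])
      registry <- .registry_add(registry, lab, calls$segment[i],
                                category = calls$category[i],
                                provenance = calls$specimen_id[i])
    }
    labels[i] <- lab
  }
  calls$variant_label <- labels
  list(calls = calls, registry = registry)
}

#' Type COIB reads: h-haplotype category plus variant dereplication
#'
#' Orients and aligns each read against the COIB reference, calls the two
#' defining sites, classifies the category, and dereplicates CSh variants
#' over the comparison span.
#'
#' @param reads Data frame with `id` and `seq` columns ([read_fasta()]).
#' @param ref COIB [reference_amplicon()]; the bundled synthetic reference
#'   by default.
#' @param registry Starting COIB [haplotype_registry()]; pass a canonical
#'   registry to keep published variant labels stable.
#' @param span Comparison span for dereplication as reference columns
#'   `c(first, last)`; defaults to the full inter-primer interval (the whole
#'   reference).
#' @param scoring [align_scoring()] parameters.
#' @param orient If `TRUE`, reads are orientation-checked against the
#'   reference (reverse-complemented when that aligns better).
#' @return A list with `calls` (one row per read: `specimen_id`, `category`,
#'   `variant_label`, observed states and statuses at both sites,
#'   `orientation`, `segment`, `segment_ok`) and the updated `registry`.
#' @export
type_coib <- function(reads, ref = faw_reference("COI"),
                      registry = haplotype_registry("COIB"),
                      span = NULL, scoring = align_scoring(),
                      orient = TRUE) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  if (is.null(span)) span <- c(1L, nchar(ref$sequence))
  if (span[1] < 1L || span[2] > nchar(ref$sequence) || span[1] > span[2]) {
    stop("comparison span outside the reference", call. = FALSE)
  }
  n <- nrow(reads)
  out <- data.frame(specimen_id = reads$id,
                    category = character(n),
                    state1164 = character(n), status1164 = character(n),
                    state1287 = character(n), status1287 = character(n),
                    orientation = character(n),
                    segment = character(n), segment_ok = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (orient) {
      o <- orient_read(reads$seq[i], ref, scoring)
      al <- o$alignment
    } else {
      al <- global_align(reads$seq[i], ref, scoring)
    }
    c1 <- call_site(al, ref, "mCOI1164D")
    c2 <- call_site(al, ref, "mCOI1287R")
    w <- .extract_window(al, span[1], span[2])
    out$category[i] <- classify_coib(c1, c2)
    out$state1164[i] <- paste(c1$observed_states, collapse = "")
    out$status1164[i] <- c1$status
    out$state1287[i] <- paste(c2$observed_states, collapse = "")
    out$status1287[i] <- c2$status
    out$orientation[i] <- al$orientation
    out$segment[i] <- w$segment
    out$segment_ok[i] <- w$covered && grepl("^[ACGT]+$", w$segment)
  }
  drep <- dereplicate_variants(out, registry)
  drep
}
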