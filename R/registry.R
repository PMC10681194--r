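# Canonical haplotype registries: exact-match sequence -> label maps used to
# dereplicate COIB variants (CSh1[a], CSh2[e], ...) and TpiI4a200 intron
# haplotypes (iC01, iC02, ...). Labels and sequences are both unique; a
# registry built from deposited reference variants keeps the canonical
# labels stable, and novel sequences are minted fresh labels in discovery
# order.

#' Create a haplotype registry
#'
#' @param marker `"COIB"` or `"TpiI4a200"`.
#' @param labels Character vector of unique labels (may be empty).
#' @param sequences Character vector of unique degapped sequences, parallel
#'   to `labels`.
#' @param categories For COIB: the CSh category of each entry (`CSh1` ...
#'   `CSh4`); ignored for TpiI4a200.
#' @param provenance Optional per-entry provenance strings (e.g. accession).
#' @return An object of class `haplotype_registry` with an `entries` data
#'   frame (`label`, `category`, `sequence`, `provenance`) in insertion
#'   order.
#' @export
haplotype_registry <- function(marker = c("COIB", "TpiI4a200"),
                               labels = character(0),
                               sequences = character(0),
                               categories = rep(NA_character_, length(labels)),
                               provenance = rep("", length(labels))) {
  marker <- match.arg(marker)
  stopifnot(length(labels) == length(sequences),
            length(labels) == length(categories))
  if (anyDuplicated(labels)) stop("registry labels must be unique", call. = FALSE)
  if (anyDuplicated(sequences)) {
    stop("registry sequences must be unique", call. = FALSE)
  }
  structure(list(marker = marker,
                 entries = data.frame(label = as.character(labels),
                                      category = as.character(categories),
                                      sequence = as.character(sequences),
                                      provenance = as.character(provenance),
                                      stringsAsFactors = FALSE)),
            class = "haplotype_registry")
}

#' @export
print.haplotype_registry <- function(x, ...) {
  cat("Haplotype registry (", x$marker, "): ", nrow(x$entries),
      " entries\n", sep = "")
  if (nrow(x$entries)) {
    tab <- table(x$entries$category, useNA = "ifany")
    for (k in seq_along(tab)) {
      cat("  ", names(tab)[k], ": ", tab[k], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Look up a sequence in a registry
#'
#' @param registry A [haplotype_registry()].
#' @param sequence Degapped sequence to look up (exact match over the
#'   registry's comparison span).
#' @return The label, or `NA_character_` when absent.
#' @export
registry_lookup <- function(registry, sequence) {
  hit <- match(sequence, registry$entries$sequence)
  if (is.na(hit)) NA_character_ else registry$entries$label[hit]
}

# Next unused lettered variant label within a COIB category: a..z, then
# aa, ab, ... Letters already present in the registry for that category are
# skipped, so canonical labels survive when a published registry is loaded.
.next_coib_label <- function(registry, category) {
  used <- registry$entries$label[registry$entries$category %in% category]
  used_letters <- sub("^.*\\[(.+)\\]$", "\\1", used)
  pool <- c(letters, as.vector(outer(letters, letters, paste0)))
  letter <- pool[!pool %in% used_letters][1]
  if (is.na(letter)) stop("variant letter pool exhausted", call. = FALSE)
  paste0(category, "[", letter, "]")
}

# Next unused iCnn label (two-digit, zero-padded, grows past 99 naturally).
.next_intron_label <- function(registry) {
  used <- registry$entries$label
  nums <- suppressWarnings(as.integer(sub("^iC", "", used)))
  nxt <- if (all(is.na(nums))) 1L else max(nums, na.rm = TRUE) + 1L
  sprintf("iC%02d", nxt)
}

# Add an entry; returns the updated registry.
.registry_add <- function(registry, label, sequence,
                          category = NA_character_, provenance = "") {
  if (label %in% registry$entries$label ||
      sequence %in% registry$entries$sequence) {
    stop("registry collision for label '", label, "'", call. = FALSE)
  }
  registry$entries <- rbind(registry$entries,
                            data.frame(label = label, category = category,
                                       sequence = sequence,
                                       provenance = provenance,
                                       stringsAsFactors = FALSE))
  registry
}

#' Write a registry as FASTA plus TSV sidecar
#'
#' @param registry A [haplotype_registry()].
#' @param prefix Output prefix; writes `<prefix>.fasta` (label as header,
#'   sequence) and `<prefix>.tsv` (label, category, provenance).
#' @return The two paths, invisibly.
#' @export
write_registry <- function(registry, prefix) {
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".tsv")
  write_fasta(setNames(registry$entries$sequence, registry$entries$label), fa)
  .write_tsv(cbind(marker = registry$marker,
                   registry$entries[c("label", "category", "provenance")]),
             tsv)
  invisible(c(fasta = fa, tsv = tsv))
}

#' Read a registry written by [write_registry()]
#'
#' @param prefix Path prefix.
#' @return A [haplotype_registry()].
#' @export
read_registry <- function(prefix) {
  fa <- read_fasta(paste0(prefix, ".fasta"))
  ann <- read.delim(paste0(prefix, ".tsv"), stringsAsFactors = FALSE,
                    colClasses = "character")
  ord <- match(fa$id, ann$label)
  if (anyNA(ord)) stop("registry FASTA/TSV labels disagree", call. = FALSE)
  haplotype_registry(ann$marker[1], labels = fa$id, sequences = fa$seq,
                     categories = ann$category[ord],
                     provenance = ann$provenance[ord])
}
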