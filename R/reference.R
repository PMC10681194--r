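# Annotated reference amplicons and diagnostic marker sites.
#
# Marker positions are carried as explicit annotations in the reference's
# own coordinate system (1-based, fully closed), never derived from primer
# names: the historical site numbering for COI (mCOI1164D, mCOI1287R) and
# Tpi (gTpi165Y etc.) are not mutually consistent coordinate systems, so
# each reference records a coordinate_offset and each site an absolute
# position under that offset.

#' Define a diagnostic marker site
#'
#' @param name Site identifier, e.g. `"mCOI1164D"` or `"gTpi183Y"`.
#' @param gene `"COI"` or `"Tpi"`.
#' @param ref_position 1-based position in the gene-level numbering used by
#'   the site name (interpreted through the reference's `coordinate_offset`).
#' @param allowed_states Non-empty subset of `A/C/G/T`: the unambiguous
#'   states expected at this site.
#' @param role One of `"strain-diagnostic"`, `"h-haplotype-defining"`,
#'   `"consistency-check"`.
#' @return An object of class `marker_site`.
#' @export
marker_site <- function(name, gene, ref_position, allowed_states, role) {
  gene <- match.arg(gene, c("COI", "Tpi"))
  role <- match.arg(role, c("strain-diagnostic", "h-haplotype-defining",
                            "consistency-check"))
  allowed_states <- sort(unique(toupper(allowed_states)))
  stopifnot(length(allowed_states) >= 1L,
            all(allowed_states %in% c("A", "C", "G", "T")),
            is.numeric(ref_position), ref_position >= 1)
  structure(list(name = name, gene = gene,
                 ref_position = as.integer(ref_position),
                 allowed_states = allowed_states, role = role),
            class = "marker_site")
}

#' Build an annotated reference amplicon
#'
#' @param gene `"COI"` or `"Tpi"`.
#' @param sequence Reference sequence, unambiguous `A/C/G/T` only.
#' @param coordinate_offset 1-based gene-level position of the first base;
#'   a site at gene position p sits at column `p - coordinate_offset + 1`.
#' @param sites List of [marker_site()] annotations.
#' @param intron_boundary For Tpi: 1-based column at which the TpiI4 intron
#'   begins.
#' @param intron_length For Tpi: intron length in columns.
#' @param provenance Free-text origin note.
#' @return An object of class `reference_amplicon`. If the two bases at the
#'   intron boundary are not the canonical splice donor `GT`, a warning is
#'   recorded in the object's `warnings` field (and raised).
#' @export
reference_amplicon <- function(gene, sequence, coordinate_offset = 1L,
                               sites = list(), intron_boundary = NULL,
                               intron_length = NULL, provenance = "") {
  gene <- match.arg(gene, c("COI", "Tpi"))
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("reference sequence must contain only A/C/G/T", call. = FALSE)
  }
  len <- nchar(sequence)
  warnings <- character(0)
  for (s in sites) {
    stopifnot(inherits(s, "marker_site"))
    col <- s$ref_position - coordinate_offset + 1L
    if (col < 1L || col > len) {
      stop("site ", s$name, " maps outside the reference amplicon",
           call. = FALSE)
    }
  }
  if (!is.null(intron_boundary)) {
    stopifnot(gene == "Tpi", !is.null(intron_length))
    intron_boundary <- as.integer(intron_boundary)
    intron_length <- as.integer(intron_length)
    if (intron_boundary + intron_length - 1L > len) {
      stop("intron extends past the reference sequence", call. = FALSE)
    }
    donor <- substr(sequence, intron_boundary, intron_boundary + 1L)
    if (donor != "GT") {
      msg <- paste0("intron boundary does not start with canonical splice ",
                    "donor GT (found ", donor, ")")
      warnings <- c(warnings, msg)
      warning(msg, call. = FALSE)
    }
  }
  structure(list(gene = gene, sequence = sequence,
                 coordinate_offset = as.integer(coordinate_offset),
                 sites = setNames(sites, vapply(sites, `[[`, "", "name")),
                 intron_boundary = intron_boundary,
                 intron_length = intron_length,
                 provenance = provenance, warnings = warnings),
            class = "reference_amplicon")
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat("Reference amplicon (", x$gene, "), ", nchar(x$sequence), " bp, offset ",
      x$coordinate_offset, "\n", sep = "")
  for (s in x$sites) {
    cat("  site ", s$name, " @ ", s$ref_position, " [",
        paste(s$allowed_states, collapse = "/"), "] ", s$role, "\n", sep = "")
  }
  if (!is.null(x$intron_boundary)) {
    cat("  intron: columns ", x$intron_boundary, "-",
        x$intron_boundary + x$intron_length - 1L, "\n", sep = "")
  }
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

# Column (1-based, in the reference sequence) of a site.
.site_column <- function(ref, site) {
  if (is.character(site)) {
    if (!site %in% names(ref$sites)) {
      stop("site '", site, "' is not annotated on this reference",
           call. = FALSE)
    }
    site <- ref$sites[[site]]
  }
  site$ref_position - ref$coordinate_offset + 1L
}

# ---------------------------------------------------------------------------
# Bundled synthetic references. These are synthetic stand-ins carrying the
# published site annotations: the COIB segment spans gene positions 891-1472
# (primers c891F/c1472R) with the two h-haplotype-defining sites at 1164 and
# 1287; the Tpi segment spans exon 4 (strain sites at columns 165/168/183),
# the 333-bp TpiI4 intron (columns 201-533) and the start of the next exon.
# Real references can be built from GenBank KT336236/KT336231 with
# reference_amplicon(); the bundled ones exist so nothing depends on
# downloads.

.COIB_REF_SEQ <- paste0(
  "TACACGAGCATATTTTACATCAGTCTGTTATCATCTAGTATCGATGTCCGTGCGTTAAAG",
  "AATACAATGGAACTTTAGGACATGCAGTTGGGTCAAAAGACGCAGCCTGTCACAGGCCTA",
  "AGTGGCCATGATACAACCCGACGATTCCATCGGGTCGGGGTAAATGATATCGTGTACAAT",
  "TTTCTATCTACCAAATGGAAAAGGTCCATCTATCAGGCTGCGGCGATATCACAACACTGA",
  "TAATAGCGCGCGGTCATGCCATCATTGGCGCCTAGGCAATATCTGTTCAAACGACTGGAC",
  "AAATGGTACGTGATGGCATAGGGTGTCCCTTCCGTAACCTAAAGTAGGTGTGATCAGGCT",
  "TCCTATTAGAAACAGTTCTCCCCTGCATTCGCTGTAGGAACTAGGCGGTTGCTTTGCTAT",
  "CTTTCCGGATGTCGACTTGCTGGTGGCGTCTTTTTCTCCGTCGTCGGTGGGTGTTTATAA",
  "CCCTAAACGGAAGTCCTCAGTTTGGATACAGGCCGTTCGCGAATCCTCGTAAGGTAGAAT",
  "CCGCCTTAGCCGTGTTAATCGATATCAAAATTTACCACCAGC")

.TPI_REF_SEQ <- paste0(
  "CCGGACTGAAGGTTATCGCTTGCTAGTTGCCAAATAAACAGACGATTACTATTATATTGT",
  "TAAGGCCGCCAATATGCAGTGATGCTCTGATCGACAGTATGCCTTCTATTACGAACGAAT",
  "CTTCTCACCGTCCAGCACTGGAGGCGCGACCCGAATCAAGACGCCGACTCCAATCTCGAA",
  "GACGCAAACGTTCATACGAAGTGACTCTCAGTAAACGAAGATCAATTGATGGGCTCGTGG",
  "AAGCTGCAAGTCGGAACCTCAACTATGCCATGTGCACAAAACTGGGCTGGGAACATCGGT",
  "GGATGGATCCCTTTTACAATATATGCCAATCTCCCGAGGATACGCCCCTCCCCGCTTGTG",
  "CATGCGCACATCACACTAGTTGGATGAAACGTTCACGCCTATCTTGCTATGTTCGTACGT",
  "TTAATATACTATTTTCTCATTTTTATACTGCGCCGACAATGAAGGAGCCACGTCAAATAA",
  "TATGAAATTTTGACTCGGTGTTGTAACACCCAGACGTAGCGCACCCTGGGTAGCTAATCC",
  "TTGGCTTCGCCGGACGGGCTTTACTCATCGCTAGGAACAGTATCAATTCGCGGTTGTCAG",
  "CGAATGCTTCCGC")

#' Bundled synthetic reference amplicons
#'
#' Returns the packaged synthetic reference for a gene, carrying the field's
#' site annotations: for COIB the h-haplotype-defining sites `mCOI1164D`
#' (observed states A/G/T) and `mCOI1287R` (A/G); for Tpi the strain sites
#' `gTpi165Y`, `gTpi168Y` and the diagnostic `gTpi183Y` (all C/T), plus the
#' TpiI4 intron annotation (columns 201-533, 333 bp). The sequences are
#' synthetic stand-ins, not GenBank-derived.
#'
#' @param gene `"COI"` or `"Tpi"`.
#' @return A [reference_amplicon()].
#' @export
faw_reference <- function(gene = c("COI", "Tpi")) {
  gene <- match.arg(gene)
  if (gene == "COI") {
    reference_amplicon(
      gene = "COI", sequence = .COIB_REF_SEQ, coordinate_offset = 891L,
      sites = list(
        marker_site("mCOI1164D", "COI", 1164L, c("A", "G", "T"),
                    "h-haplotype-defining"),
        marker_site("mCOI1287R", "COI", 1287L, c("A", "G"),
                    "h-haplotype-defining")),
      provenance = "synthetic stand-in, COIB segment c891F/c1472R")
  } else {
    reference_amplicon(
      gene = "Tpi", sequence = .TPI_REF_SEQ, coordinate_offset = 1L,
      sites = list(
        marker_site("gTpi165Y", "Tpi", 165L, c("C", "T"), "consistency-check"),
        marker_site("gTpi168Y", "Tpi", 168L, c("C", "T"), "consistency-check"),
        marker_site("gTpi183Y", "Tpi", 183L, c("C", "T"), "strain-diagnostic")),
      intron_boundary = 201L, intron_length = 333L,
      provenance = "synthetic stand-in, Tpi exon4 + TpiI4 intron, t412F/t1140R")
  }
}

#' Write a reference amplicon as FASTA plus annotation sidecar
#'
#' @param ref A [reference_amplicon()].
#' @param prefix Output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.sites.tsv`.
#' @return The two paths, invisibly.
#' @export
write_reference <- function(ref, prefix) {
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".sites.tsv")
  write_fasta(setNames(ref$sequence, ref$gene), fa)
  sites <- do.call(rbind, lapply(ref$sites, function(s) {
    data.frame(gene = ref$gene, coordinate_offset = ref$coordinate_offset,
               site = s$name, position = s$ref_position,
               allowed_states = paste(s$allowed_states, collapse = ""),
               role = s$role,
               intron_boundary = if (is.null(ref$intron_boundary)) NA_integer_
                                 else ref$intron_boundary,
               intron_length = if (is.null(ref$intron_length)) NA_integer_
                               else ref$intron_length,
               stringsAsFactors = FALSE)
  }))
  .write_tsv(sites, tsv)
  invisible(c(fasta = fa, sites = tsv))
}

#' Read a reference amplicon from FASTA plus annotation sidecar
#'
#' @param prefix Path prefix as used by [write_reference()].
#' @param provenance Provenance note for the rebuilt object.
#' @return A [reference_amplicon()].
#' @export
read_reference <- function(prefix, provenance = "") {
  fa <- read_fasta(paste0(prefix, ".fasta"))
  ann <- read.delim(paste0(prefix, ".sites.tsv"), stringsAsFactors = FALSE)
  gene <- ann$gene[1]
  sites <- lapply(seq_len(nrow(ann)), function(i) {
    marker_site(ann$site[i], gene, ann$position[i],
                strsplit(ann$allowed_states[i], "")[[1]], ann$role[i])
  })
  ib <- ann$intron_boundary[1]
  il <- ann$intron_length[1]
  reference_amplicon(gene, fa$seq[1], ann$coordinate_offset[1], sites,
                     intron_boundary = if (is.na(ib)) NULL else ib,
                     intron_length = if (is.na(il)) NULL else il,
                     provenance = provenance)
}
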