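# FASTA and metadata I/O.
#
# Reads are amplicon consensus sequences from directly sequenced PCR
# products, so the alphabet is the 15-letter IUPAC set (plus N); gaps are
# not allowed in input reads.

#' Read amplicon consensus sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param gene Optional gene tag (`"COI"` or `"Tpi"`) attached to every read.
#' @return A data frame with columns `id` (header token before the first
#'   whitespace), `seq` (upper-cased sequence) and `gene`, one row per FASTA
#'   entry in file order.
#' @details Parsing is delegated to [Biostrings::readBStringSet()]; the
#'   alphabet is then validated so that a non-IUPAC character is reported
#'   with its record and position.
#' @export
read_fasta <- function(path, gene = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      gene = character(0), stringsAsFactors = FALSE))
  }
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, "", 1L)
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record '", ids[which(nchar(seqs) == 0L)[1]], "'",
         call. = FALSE)
  }
  for (k in seq_along(seqs)) .validate_iupac(seqs[k], ids[k])
  if (anyDuplicated(ids)) {
    stop("duplicated record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  data.frame(id = unname(ids), seq = unname(seqs),
             gene = rep(gene, length(ids)), stringsAsFactors = FALSE)
}

#' Write reads to a FASTA file
#'
#' @param reads Data frame with columns `id` and `seq` (as from
#'   [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path, width = 70L) {
  if (is.character(reads)) {
    reads <- data.frame(id = names(reads), seq = unname(reads),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq") %in% names(reads)))
  set <- Biostrings::BStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' @param path Path to a tab-separated table with header columns
#'   `specimen_id`, `population`, `year`, `habitat`, `collection_type`.
#' @return A validated data frame. `collection_type` must be one of `T`
#'   (pheromone trap), `C` (colony) or `L` (larval collection).
#' @export
read_specimen_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  meta <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("specimen_id", "population", "year", "habitat", "collection_type")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("metadata is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  meta$year <- as.integer(meta$year)
  bad <- !meta$collection_type %in% c("T", "C", "L")
  if (any(bad)) {
    stop("collection_type must be T, C or L; offending specimens: ",
         paste(head(meta$specimen_id[bad], 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$specimen_id)) {
    stop("duplicated specimen_id in metadata", call. = FALSE)
  }
  meta
}

#' Write a specimen metadata table
#'
#' @param meta Data frame as returned by [read_specimen_metadata()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_specimen_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
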