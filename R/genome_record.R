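#' Create a genome record
#'
#' The in-memory unit for a contig or genome: an identifier, an uppercase
#' A/C/G/T/N sequence, and a hint whether the molecule should be interpreted
#' circularly. All coordinates used throughout the package are 0-based
#' half-open; conversion to 1-based formats happens only in writers.
#'
#' @param id character identifier (unique within a set).
#' @param sequence nucleotide string; lowercase is normalized to uppercase,
#'   IUPAC ambiguity codes other than N are collapsed to N (with a warning
#'   giving the count).
#' @param circular_hint logical; TRUE if the molecule is circularly
#'   interpretable (e.g. a contig from a terminally redundant genome).
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, circular_hint = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L, is.logical(circular_hint))
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    warning(sprintf("record '%s': %d non-ACGTN characters collapsed to N",
                    id, nchar(bad)))
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  structure(list(id = id, sequence = sequence,
                 circular_hint = isTRUE(circular_hint)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp%s\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular_hint) " (circular)" else ""))
  invisible(x)
}

#' @export
length.genome_record <- function(x) nchar(x$sequence)

#' Read a FASTA file into a list of genome records
#'
#' @param path file path.
#' @param circular_hint logical applied to all records.
#' @return List of `genome_record`; empty list for an empty file.
#' @export
read_fasta <- function(path, circular_hint = FALSE) {
  if (file.info(path)$size == 0) return(list())
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]), circular_hint)
  })
}

#' Write genome records to FASTA
#'
#' @param records list of `genome_record` (or a single record).
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "genome_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$sequence, character(1))
  ids <- vapply(records, function(r) r$id, character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read paired or single FASTQ
#'
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame with columns id, sequence, quality.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(set)),
             sequence = as.character(set),
             quality = as.character(S4Vectors::mcols(set)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param ids,sequences,qualities parallel character vectors.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(ids, sequences, qualities, path) {
  stopifnot(length(ids) == length(sequences),
            length(ids) == length(qualities))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(ids)) {
    writeLines(paste0("@", ids, "\n", sequences, "\n+\n", qualities), con,
               sep = "\n")
  }
  invisible(path)
}
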