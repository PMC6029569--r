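# Collection register and summary statistics.

#' Basic genome statistics
#'
#' @param contig a `genome_record`.
#' @param orfs optional ORF table for the CDS count.
#' @return List: length, gc_percent (100*(G+C)/(A+C+G+T), N excluded from
#'   the denominator, 4 decimals), cds_count (NA without `orfs`).
#' @export
genome_stats <- function(contig, orfs = NULL) {
  counts <- table(strsplit(contig$sequence, "")[[1]])
  n_of <- function(b) if (b %in% names(counts)) counts[[b]] else 0L
  acgt <- n_of("A") + n_of("C") + n_of("G") + n_of("T")
  gc <- round_half_up(100 * (n_of("G") + n_of("C")) / acgt, 4L)
  list(length = nchar(contig$sequence), gc_percent = gc,
       cds_count = if (is.null(orfs)) NA_integer_ else nrow(orfs))
}

#' Read the bundled collection register
#'
#' A transcription of the published register of 283 curated phage genome
#' records (251 unique isolates plus sub-lineage and technical-replicate
#' assemblies) with per-genome coverage, length, GC, CDS/tRNA/CRISPR
#' counts, morphotype and head-neck-tail classification.
#'
#' @param path optional override of the bundled TSV.
#' @return data.frame with an `is_sublineage` logical column derived from
#'   the register's sub-lineage note.
#' @export
read_collection_register <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "collection_register.tsv",
                        package = "phagestd", mustWork = TRUE)
  }
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$is_sublineage <- df$sublineage_note != "no"
  df
}

#' Collection-level summary statistics
#'
#' @param rows a register data.frame (see [read_collection_register()])
#'   with columns genome_length, gc_percent, is_sublineage, trna_count,
#'   crispr_count.
#' @return List of summary statistics: genome-length min/max/median over
#'   all and over unique (non-sub-lineage) rows, GC min/max/median plus
#'   the integer-rounded GC range, unique and sub-lineage row counts, and
#'   counts of rows carrying tRNAs or CRISPR features.
#' @export
collection_summary <- function(rows) {
  if (!nrow(rows)) stop("empty collection register")
  uniq <- rows[!rows$is_sublineage, , drop = FALSE]
  list(
    n_rows = nrow(rows),
    n_unique = nrow(uniq),
    n_sublineage = sum(rows$is_sublineage),
    length_min = min(rows$genome_length),
    length_max = max(rows$genome_length),
    length_median_all = median(rows$genome_length),
    length_median_unique = median(uniq$genome_length),
    gc_min = min(rows$gc_percent),
    gc_max = max(rows$gc_percent),
    gc_range_rounded = c(round(min(rows$gc_percent)),
                         round(max(rows$gc_percent))),
    gc_median = median(rows$gc_percent),
    n_with_trna = sum(rows$trna_count >= 1),
    n_with_crispr = sum(rows$crispr_count >= 1),
    n_unique_with_trna = sum(uniq$trna_count >= 1),
    n_unique_with_crispr = sum(uniq$crispr_count >= 1)
  )
}
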