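# bedGraph / GFF3 / SAM adapters. In-memory coordinates are 0-based
# half-open everywhere; GFF3 (1-based inclusive) and SAM (1-based) conversion
# is localized to these writers/readers.

#' Construct a per-base coverage profile
#'
#' @param contig_id contig identifier.
#' @param depth integer vector of per-base read depth (length = contig
#'   length).
#' @param circular logical; whether the contig is circularly interpretable.
#' @return A `coverage_profile` object.
#' @export
coverage_profile <- function(contig_id, depth, circular = FALSE) {
  stopifnot(length(depth) > 0, all(depth >= 0), all(is.finite(depth)))
  structure(list(contig_id = contig_id, depth = as.numeric(depth),
                 circular = isTRUE(circular)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %d bp, median depth %.1f%s\n",
              x$contig_id, length(x$depth), median(x$depth),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Read a bedGraph file into a coverage profile
#'
#' Intervals are 0-based half-open and must tile `[0, contig_len)` after
#' expansion; gaps are filled with depth 0. Overlapping intervals or
#' intervals beyond `contig_len` are errors.
#'
#' @param path bedGraph path.
#' @param contig_len contig length in bases.
#' @param contig_id optional id; defaults to the first column of the file.
#' @param circular circularity flag for the resulting profile.
#' @return A `coverage_profile`.
#' @export
read_bedgraph_coverage <- function(path, contig_len, contig_id = NULL,
                                   circular = FALSE) {
  depth <- numeric(contig_len)
  if (file.info(path)$size > 0) {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (nrow(df)) {
      stopifnot(ncol(df) >= 4)
      names(df)[1:4] <- c("chrom", "start", "end", "value")
      if (is.null(contig_id)) contig_id <- df$chrom[1]
      if (any(df$end > contig_len)) {
        stop("bedGraph interval beyond contig length ", contig_len)
      }
      df <- df[order(df$start), , drop = FALSE]
      if (any(df$start[-1] < df$end[-nrow(df)])) {
        stop("overlapping bedGraph intervals")
      }
      for (i in seq_len(nrow(df))) {
        if (df$end[i] > df$start[i]) {
          depth[(df$start[i] + 1L):df$end[i]] <- df$value[i]
        }
      }
    }
  }
  if (is.null(contig_id)) contig_id <- "contig"
  coverage_profile(contig_id, depth, circular)
}

#' Write a coverage profile as bedGraph
#'
#' @param profile a `coverage_profile`.
#' @param path output path.
#' @export
write_bedgraph <- function(profile, path) {
  r <- rle(profile$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  writeLines(sprintf("%s\t%d\t%d\t%g", profile$contig_id, starts, ends,
                     r$values), path)
  invisible(path)
}

#' Write ORF calls as GFF3
#'
#' @param orfs data.frame as returned by [find_orfs()].
#' @param path output path.
#' @export
write_gff3 <- function(orfs, path) {
  lines <- "##gff-version 3"
  if (nrow(orfs)) {
    lines <- c(lines, sprintf(
      "%s\tphagestd\tCDS\t%d\t%d\t.\t%s\t0\tID=orf%d",
      orfs$contig_id, orfs$start + 1L, orfs$end, orfs$strand,
      seq_len(nrow(orfs))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 of ORF calls written by [write_gff3()]
#'
#' @param path GFF3 path.
#' @return data.frame with contig_id, start, end (0-based half-open), strand.
#' @export
read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln)) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  data.frame(contig_id = vapply(f, `[`, "", 1L),
             start = as.integer(vapply(f, `[`, "", 4L)) - 1L,
             end = as.integer(vapply(f, `[`, "", 5L)),
             strand = vapply(f, `[`, "", 7L),
             stringsAsFactors = FALSE)
}

#' Write read placements as minimal SAM
#'
#' @param placements data.frame from [map_reads()].
#' @param contig the `genome_record` mapped against.
#' @param path output path.
#' @export
write_sam_placements <- function(placements, contig, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contig$id, nchar(contig$sequence)))
  body <- character(0)
  if (nrow(placements)) {
    flag <- ifelse(placements$strand == "-", 16L, 0L)
    body <- sprintf("%s/%d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                    placements$read_id, placements$mate, flag, contig$id,
                    placements$pos + 1L, placements$len)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
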