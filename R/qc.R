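# Technical-validation analytics: replicate-assembly comparison,
# prophage screening of viruses against their isolation hosts, and a
# k-mer-order synteny score.

#' Replicate average nucleotide identity from mismatch counts
#'
#' ANI between two replicate assemblies is one minus the mean mismatch
#' count over the mean length, reported half-up-rounded to 7 decimals:
#' `1 - ((qm + sm)/2) / ((ql + sl)/2)`.
#'
#' @param qm,sm query/subject mismatch counts (bases).
#' @param ql,sl query/subject lengths (bases).
#' @return ANI fraction in [0, 1], rounded to 7 decimals.
#' @export
ani_from_counts <- function(qm, sm, ql, sl) {
  stopifnot(qm >= 0, sm >= 0, ql > 0, sl > 0)
  round_half_up(1 - ((qm + sm) / 2) / ((ql + sl) / 2), 7L)
}

#' Compare two replicate assemblies
#'
#' Globally aligns the two sequences (match 1, mismatch -2, gap open -10,
#' extend -0.5), counts substituted and gapped columns, attributes gapped
#' positions to the sequence bearing the insertion, and reports ANI via
#' [ani_from_counts()].
#'
#' @param a,b `genome_record`s (query and subject).
#' @param k k-mer length for the relatedness gate.
#' @param min_shared minimum fraction of shared k-mers (of the smaller
#'   set) below which the pair is considered unalignable (error, not a
#'   zero-ANI result).
#' @return A `replicate_comparison` list mirroring the replicate-table
#'   columns: query/subject ids, lengths, mismatch counts, ani, snp,
#'   indel_bases, start_variation, length_variation.
#' @export
compare_replicates <- function(a, b, k = 31L, min_shared = 0.9) {
  ka_ <- unique(kmers(a$sequence, k))
  kb_ <- unique(kmers(b$sequence, k))
  shared <- length(intersect(ka_, kb_)) / min(length(ka_), length(kb_))
  if (shared < min_shared) {
    stop(sprintf("sequences share only %.1f%% of %d-mers: not replicates",
                 100 * shared, k))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a$sequence), Biostrings::DNAString(b$sequence),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap_a <- pa == "-"
  gap_b <- pb == "-"
  subst <- !gap_a & !gap_b & pa != pb
  snp <- sum(subst)
  indel_bases <- sum(gap_a | gap_b)
  # a gap in the subject row means the query carries the inserted bases
  qm <- snp + sum(gap_b)
  sm <- snp + sum(gap_a)
  lead_gaps <- match(FALSE, gap_a | gap_b, nomatch = 1L) - 1L
  ql <- nchar(a$sequence); sl <- nchar(b$sequence)
  structure(list(query_id = a$id, subject_id = b$id,
                 query_len = ql, subject_len = sl,
                 query_mismatch = qm, subject_mismatch = sm,
                 ani = ani_from_counts(qm, sm, ql, sl),
                 snp = snp, indel_bases = indel_bases,
                 start_variation = lead_gaps,
                 length_variation = abs(ql - sl)),
            class = "replicate_comparison")
}

#' @export
print.replicate_comparison <- function(x, ...) {
  cat(sprintf(
    "<replicate_comparison> %s vs %s: ANI %.7f (%d SNP, %d indel bases)\n",
    x$query_id, x$subject_id, x$ani, x$snp, x$indel_bases))
  invisible(x)
}

#' Screen a virus genome against host genomes for prophage identity
#'
#' Shared 31-mers between virus and host are chained along diagonals
#' (gaps up to `max_gap` tolerated); maximal chains of at least `min_len`
#' bases at `min_identity` are reported, and the virus is flagged as a
#' putative induced prophage when the chained fraction of its genome
#' reaches `flag_cover`.
#'
#' @param virus a `genome_record`.
#' @param hosts list of host `genome_record`s (empty list gives an empty
#'   report).
#' @param min_identity minimum chain identity.
#' @param min_len minimum chain length (bases).
#' @param k seed k-mer length.
#' @param max_gap maximum within-diagonal seed gap bridged into one chain.
#' @param flag_cover virus-cover fraction at which a hit is flagged.
#' @return data.frame: virus_id, host_contig_id, match_len, identity,
#'   virus_cover, host_contig_len, flagged.
#' @export
prophage_screen <- function(virus, hosts, min_identity = 0.95,
                            min_len = 5000L, k = 31L, max_gap = 100L,
                            flag_cover = 0.9) {
  empty <- data.frame(virus_id = character(0), host_contig_id = character(0),
                      match_len = integer(0), identity = numeric(0),
                      virus_cover = numeric(0), host_contig_len = integer(0),
                      flagged = logical(0), stringsAsFactors = FALSE)
  if (!length(hosts)) return(empty)
  vk <- kmers(virus$sequence, k)
  vlen <- nchar(virus$sequence)
  out <- list()
  for (h in hosts) {
    hk <- kmers(h$sequence, k)
    hit <- match(vk, hk)
    ok <- which(!is.na(hit))
    if (!length(ok)) next
    diag_id <- hit[ok] - ok
    for (d in unique(diag_id)) {
      vpos <- ok[diag_id == d]
      # chain seed positions along this diagonal, bridging small gaps
      breaks <- which(diff(vpos) > max_gap)
      starts <- c(1L, breaks + 1L)
      ends <- c(breaks, length(vpos))
      for (ci in seq_along(starts)) {
        v0 <- vpos[starts[ci]]; v1 <- vpos[ends[ci]] + k - 1L
        span <- v1 - v0 + 1L
        if (span < min_len) next
        vs <- substr(virus$sequence, v0, v1)
        hs <- substr(h$sequence, v0 + d, v1 + d)
        ident <- 1 - str_mismatches(vs, hs) / span
        if (ident < min_identity) next
        cover <- span / vlen
        out[[length(out) + 1L]] <- data.frame(
          virus_id = virus$id, host_contig_id = h$id,
          match_len = span, identity = ident, virus_cover = cover,
          host_contig_len = nchar(h$sequence),
          flagged = cover >= flag_cover, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(-res$match_len), , drop = FALSE]
}

#' Collinearity score between two standardized genomes
#'
#' Fraction of shared unique k-mers whose order is preserved (longest
#' increasing subsequence over total shared); 1.0 for identical gene
#' order, lower for rearranged or differently rotated genomes.
#'
#' @param a,b `standardized_genome` or `genome_record` objects.
#' @param k k-mer length.
#' @return Numeric score in [0, 1]; NA when no unique k-mers are shared.
#' @export
synteny_check <- function(a, b, k = 31L) {
  seq_of <- function(x) if (inherits(x, "standardized_genome"))
    x$contig$sequence else x$sequence
  sa <- seq_of(a); sb <- seq_of(b)
  ka_ <- kmers(sa, k)
  kb_ <- kmers(sb, k)
  ua <- !(duplicated(ka_) | duplicated(ka_, fromLast = TRUE))
  ub <- !(duplicated(kb_) | duplicated(kb_, fromLast = TRUE))
  hit <- match(ka_, kb_)
  keep <- which(!is.na(hit) & ua & ub[ifelse(is.na(hit), 1L, hit)])
  if (!length(keep)) return(NA_real_)
  lis_length(hit[keep]) / length(keep)
}
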