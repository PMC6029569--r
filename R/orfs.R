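# Simple six-frame ORF caller (translation table 11, start codons
# ATG/GTG/TTG, maximal ORFs from the first start after each stop).
# Deliberately minimal: no ribosome-binding-site scoring or GC-frame model.

.stop_codons <- c("TAA", "TAG", "TGA")
.start_codons <- c("ATG", "GTG", "TTG")

# ORFs in frames 0..2 of a single strand; returns 0-based half-open
# coordinates on that strand's own sequence.
scan_strand_orfs <- function(seq, min_aa, require_preceding_stop = FALSE) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    n_cod <- (n - frame) %/% 3L
    if (n_cod < min_aa + 1L) next
    starts_nt <- frame + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(seq, starts_nt + 1L, starts_nt + 3L)
    is_stop <- codons %in% .stop_codons
    is_start <- codons %in% .start_codons
    # segment id between stops
    seg <- cumsum(c(TRUE, is_stop[-n_cod]))
    # first start codon within each segment
    cand <- which(is_start & !is_stop)
    if (require_preceding_stop) cand <- cand[seg[cand] > 1L]
    if (!length(cand)) next
    first_start <- tapply(cand, seg[cand], min)
    stops <- which(is_stop)
    next_stop <- stops[findInterval(as.integer(first_start), stops) + 1L]
    keep <- !is.na(next_stop)
    fs <- as.integer(first_start)[keep]
    ns <- next_stop[keep]
    aa_len <- ns - fs  # codons before the stop
    sel <- aa_len >= min_aa
    fs <- fs[sel]; ns <- ns[sel]
    if (!length(fs)) next
    out[[length(out) + 1L]] <- data.frame(
      start = starts_nt[fs], end = starts_nt[ns] + 3L)
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  do.call(rbind, out)
}

translate_orf <- function(seq, start, end) {
  cds <- substr(seq, start + 1L, end)
  p <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  p <- sub("\\*$", "", p)
  # initiator codon convention: report M regardless of ATG/GTG/TTG
  paste0("M", substr(p, 2L, nchar(p)))
}

#' Call open reading frames on a contig
#'
#' Scans all six frames; on circular contigs the doubled sequence is
#' scanned and calls de-duplicated modulo L, so ORFs spanning the origin
#' are reported. Coordinates are 0-based half-open on the forward strand;
#' for ORFs wrapping the origin of a circular contig `end` exceeds L.
#'
#' @param contig a `genome_record`.
#' @param circular scan circularly.
#' @param min_aa minimum protein length (residues, excluding the stop).
#' @return data.frame: contig_id, start, end, strand, protein; sorted by
#'   start.
#' @export
find_orfs <- function(contig, circular = contig$circular_hint,
                      min_aa = 60L) {
  S <- contig$sequence
  L <- nchar(S)
  stopifnot(L >= 3L * min_aa)
  scan_one <- function(seq, strand, circ) {
    # on the doubled circular sequence only segments with an in-window
    # preceding stop are kept, so calls are rotation-equivariant
    hits <- scan_strand_orfs(seq, min_aa, require_preceding_stop = circ)
    if (!nrow(hits)) return(NULL)
    hits$strand <- strand
    hits
  }
  if (circular) {
    SS <- paste0(S, S)
    fwd <- scan_one(SS, "+", TRUE)
    rev <- scan_one(revcomp(SS), "-", TRUE)
    fix <- function(h, seqlen) {
      if (is.null(h)) return(NULL)
      if (h$strand[1] == "-") {
        # map coordinates on the reverse strand back to forward
        tmp <- data.frame(start = seqlen - h$end, end = seqlen - h$start,
                          strand = h$strand)
        h <- tmp
      }
      # keep calls whose start lies in the first copy; drop spans > L
      h <- h[h$end - h$start <= L, , drop = FALSE]
      h$start2 <- h$start %% L
      h$end2 <- h$start2 + (h$end - h$start)
      h <- h[!duplicated(paste(h$start2, h$end2, h$strand)), , drop = FALSE]
      data.frame(start = h$start2, end = h$end2, strand = h$strand)
    }
    hits <- rbind(fix(fwd, 2L * L), fix(rev, 2L * L))
    seq_for <- SS
  } else {
    fwd <- scan_one(S, "+", FALSE)
    rev <- scan_one(revcomp(S), "-", FALSE)
    if (!is.null(rev)) {
      rev <- data.frame(start = L - rev$end, end = L - rev$start,
                        strand = rev$strand)
    }
    hits <- rbind(fwd, rev)
    seq_for <- S
  }
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  prot <- vapply(seq_len(nrow(hits)), function(i) {
    s <- hits$start[i]; e <- hits$end[i]
    if (hits$strand[i] == "+") {
      translate_orf(seq_for, s, e)
    } else {
      cds <- revcomp(substr(seq_for, s + 1L, e))
      translate_orf(cds, 0L, nchar(cds))
    }
  }, character(1))
  data.frame(contig_id = contig$id, start = as.integer(hits$start),
             end = as.integer(hits$end), strand = hits$strand,
             protein = prot, stringsAsFactors = FALSE)
}
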