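# Exact-seed read mapper for synthetic/low-error data.
#
# Each mate is placed by a k-mer seed followed by ungapped extension with
# soft clipping: the aligned span is the contiguous stretch around the
# seed uninterrupted by a run of `clip_break` consecutive mismatches, so
# reads running off a molecule junction (cohesive-end chemistry, Mu host
# flanks) contribute their aligned portion, as a local aligner would.
# Circular contigs are mapped against the doubled sequence and coordinates
# folded mod L. Multi-mapping mates go to the leftmost hit (deterministic;
# ambiguity counted), unplaced mates are counted. This stands in for a
# production short-read mapper and is only intended for the simulator's
# error-free or low-error reads.

#' Map read pairs to a contig
#'
#' @param reads a `read_pairs` data.frame (or any data.frame with `id`,
#'   `mate1`, `mate2` character columns).
#' @param contig a `genome_record`.
#' @param circular treat the contig as circular (map against the doubled
#'   sequence, fold placements mod L).
#' @param k seed k-mer length (must not exceed the read length).
#' @param max_mismatch_frac maximum mismatches tolerated within the
#'   aligned (clipped) span, as a fraction of its length.
#' @param clip_break a run of this many consecutive mismatches ends the
#'   aligned span (soft clip).
#' @return data.frame of placements (read_id, mate, pos, len, strand,
#'   mismatches; pos 0-based, len = aligned span after clipping) with
#'   attributes `n_unplaced`, `n_ambiguous`, and `contig_len`.
#' @export
map_reads <- function(reads, contig, circular = contig$circular_hint,
                      k = 31L, max_mismatch_frac = 0.1, clip_break = 3L) {
  mates <- c(reads$mate1, reads$mate2)
  mate_no <- rep(c(1L, 2L), each = nrow(reads))
  read_id <- rep(reads$id, 2L)
  if (length(mates) && any(nchar(mates) < k)) {
    stop("seed length k = ", k, " exceeds the shortest mate length")
  }
  S <- contig$sequence
  L <- nchar(S)
  target <- if (circular) paste0(S, S) else S
  tab <- kmers(target, k)
  # ambiguity = seed occurs more than once among the contig's own k-mers
  # (one wrap copy for circular contigs)
  own <- if (circular) tab[seq_len(L)] else tab
  amb_seeds <- unique(own[duplicated(own)])

  n <- length(mates)
  pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  mm <- rep(NA_integer_, n)
  alen <- rep(NA_integer_, n)
  ambiguous <- logical(n)
  if (n) {
    rc <- revcomp_all(mates)
    lens <- nchar(mates)
    max_mm <- floor(max_mismatch_frac * lens)
    todo <- seq_len(n)
    for (off in c(0L, k, 2L * k)) {
      if (!length(todo)) break
      ok_off <- todo[lens[todo] >= off + k]
      if (!length(ok_off)) break
      for (ori in c("+", "-")) {
        if (!length(ok_off)) break
        qry <- if (ori == "+") mates[ok_off] else rc[ok_off]
        seed <- substr(qry, off + 1L, off + k)
        hit <- match(seed, tab)  # leftmost occurrence
        cand <- which(!is.na(hit))
        if (!length(cand)) next
        p <- hit[cand] - 1L - off          # 0-based placement
        idx <- ok_off[cand]
        inb <- p >= 0 & p + lens[idx] <= nchar(target)
        cand <- cand[inb]; p <- p[inb]; idx <- idx[inb]
        if (!length(cand)) next
        ref <- substring(target, p + 1L, p + lens[idx])
        q <- if (ori == "+") mates[idx] else rc[idx]
        nmm <- integer(length(idx))
        cs <- rep(0L, length(idx))           # clip offset within the mate
        cl <- lens[idx]                      # aligned span length
        ne <- which(ref != q)
        for (w in ne) {
          clip <- clip_span(ref[w], q[w], seed_lo = off + 1L,
                            seed_hi = off + k, clip_break = clip_break)
          cs[w] <- clip$start - 1L
          cl[w] <- clip$len
          nmm[w] <- clip$mismatches
        }
        pass <- cl >= k & nmm <= floor(max_mismatch_frac * cl)
        idx <- idx[pass]; p <- p[pass]; nmm <- nmm[pass]
        cs <- cs[pass]; cl <- cl[pass]
        sd <- substr(if (ori == "+") mates[idx] else rc[idx],
                     off + 1L, off + k)
        if (length(idx)) {
          pp <- p + cs
          pos[idx] <- if (circular) pp %% L else pp
          strand[idx] <- ori
          alen[idx] <- cl
          mm[idx] <- nmm
          ambiguous[idx] <- sd %in% amb_seeds
          ok_off <- setdiff(ok_off, idx)
          todo <- setdiff(todo, idx)
        }
      }
    }
  }
  placed <- !is.na(pos)
  out <- data.frame(read_id = read_id[placed], mate = mate_no[placed],
                    pos = pos[placed], len = alen[placed],
                    strand = strand[placed], mismatches = mm[placed],
                    stringsAsFactors = FALSE)
  attr(out, "n_unplaced") <- sum(!placed)
  attr(out, "n_ambiguous") <- sum(ambiguous)
  attr(out, "contig_len") <- L
  out
}

# Soft-clip an ungapped extension: the aligned span is the contiguous
# region containing the seed, bounded by runs of >= clip_break consecutive
# mismatches, with flanking mismatches trimmed. 1-based coordinates within
# the mate.
clip_span <- function(ref, q, seed_lo, seed_hi, clip_break) {
  m <- charToRaw(ref) == charToRaw(q)
  n <- length(m)
  r <- rle(!m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  brk <- which(r$values & r$lengths >= clip_break)
  lo <- 1L; hi <- n
  for (b in brk) {
    if (ends[b] < seed_lo) lo <- max(lo, ends[b] + 1L)
    if (starts[b] > seed_hi) hi <- min(hi, starts[b] - 1L)
  }
  # trim flanking mismatches
  while (lo <= hi && !m[lo]) lo <- lo + 1L
  while (hi >= lo && !m[hi]) hi <- hi - 1L
  if (hi < lo) return(list(start = seed_lo, len = 0L, mismatches = n))
  list(start = lo, len = hi - lo + 1L,
       mismatches = sum(!m[lo:hi]))
}

#' Per-base coverage from read placements
#'
#' `depth[i]` counts the mates whose placement interval contains position i
#' (0-based); intervals extending past the end of a circular contig wrap.
#'
#' @param placements data.frame from [map_reads()].
#' @param contig_len contig length.
#' @param circular wrap placements mod contig_len.
#' @param contig_id id recorded on the profile.
#' @return A `coverage_profile`.
#' @export
per_base_coverage <- function(placements, contig_len,
                              circular = FALSE, contig_id = "contig") {
  L <- as.integer(contig_len)
  delta <- numeric(L + 1L)
  if (nrow(placements)) {
    s <- placements$pos
    e <- placements$pos + placements$len
    if (any(s < 0) || (!circular && any(e > L))) {
      stop("placement outside contig bounds")
    }
    for (i in seq_along(s)) {
      if (e[i] <= L) {
        delta[s[i] + 1L] <- delta[s[i] + 1L] + 1
        delta[e[i] + 1L] <- delta[e[i] + 1L] - 1
      } else {  # wraps the origin
        delta[s[i] + 1L] <- delta[s[i] + 1L] + 1
        delta[L + 1L] <- delta[L + 1L] - 1
        delta[1L] <- delta[1L] + 1
        delta[e[i] - L + 1L] <- delta[e[i] - L + 1L] - 1
      }
    }
  }
  prof <- coverage_profile(contig_id, cumsum(delta[seq_len(L)]), circular)
  # clip pileups: placements starting/ending at each base (reads soft
  # clipped at a molecule junction all start or end at the same base,
  # which locates cohesive-end features precisely)
  starts <- integer(L)
  ends <- integer(L)
  if (nrow(placements)) {
    st <- tabulate(placements$pos %% L + 1L, nbins = L)
    en <- tabulate((placements$pos + placements$len - 1L) %% L + 1L,
                   nbins = L)
    starts <- st
    ends <- en
  }
  prof$clip_starts <- starts
  prof$clip_ends <- ends
  prof
}
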