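# Shared fixture builders. Everything is generated in code; no binary data.

# deterministic random genome record
toy_genome <- function(n = 5000L, gc = 0.45, seed = 1L, id = "toy",
                       circular = TRUE) {
  phagestd:::with_seed(seed, {
    genome_record(id, phagestd:::random_dna(n, gc), circular)
  })
}

# plant a subsequence at a 0-based position
plant_at <- function(seq, insert, pos) {
  paste0(substr(seq, 1L, pos), insert,
         substr(seq, pos + nchar(insert) + 1L, nchar(seq)))
}

# brute-force per-base coverage oracle
coverage_oracle <- function(placements, L, circular = FALSE) {
  depth <- integer(L)
  for (i in seq_len(nrow(placements))) {
    idx <- placements$pos[i] + seq_len(placements$len[i]) - 1L
    if (circular) idx <- idx %% L
    idx <- idx[idx < L]
    depth[idx + 1L] <- depth[idx + 1L] + 1L
  }
  depth
}

# quadratic longest-strictly-increasing-subsequence oracle
lis_oracle <- function(x) {
  n <- length(x)
  if (n == 0L) return(0L)
  best <- rep(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i]) best[i] <- max(best[i], best[j] + 1L)
    }
  }
  max(best)
}

# minimal read-pairs data.frame from explicit mate sequences
reads_from <- function(mate1, mate2 = phagestd:::revcomp_all(mate1),
                       id = sprintf("r%03d", seq_along(mate1))) {
  data.frame(id = id, mate1 = mate1, mate2 = mate2,
             stringsAsFactors = FALSE)
}

expected_signature <- c(headful_pac = "gradual_shift",
                        cos_5 = "cos_peak",
                        cos_3 = "cos_valley",
                        dtr = "short_internal_peak",
                        mu_like = "terminal_drop_mu",
                        itr = "even")

# circular distance between two coordinates
circ_dist <- function(a, b, L) {
  d <- abs(a - b) %% L
  min(d, L - d)
}

# locate the origin of a rotated/flipped sequence on its reference circle;
# returns the 0-based reference coordinate or NA
locate_origin <- function(std_seq, ref_seq) {
  probe <- substr(std_seq, 1L, 80L)
  pos <- regexpr(probe, paste0(ref_seq, ref_seq), fixed = TRUE)
  if (pos > 0) return((as.integer(pos) - 1L) %% nchar(ref_seq))
  rc <- phagestd::revcomp(ref_seq)
  pos <- regexpr(probe, paste0(rc, rc), fixed = TRUE)
  if (pos > 0) {
    # convert a position on the reverse strand back to forward coordinates
    p <- (as.integer(pos) - 1L) %% nchar(ref_seq)
    return((nchar(ref_seq) - p) %% nchar(ref_seq))
  }
  NA_integer_
}
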