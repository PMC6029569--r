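# Synthetic packaged-genome simulator.
#
# Generates reference phage genomes with a planted terminase marker gene,
# populations of packaged virion monomers for each packaging strategy, and
# paired-end reads with ground truth, so the whole curation engine is
# testable without external sequencing data.
#
# Packaging models (all coordinates 0-based on the reference circle):
#  * headful_pac: series of k monomers cut from a concatemer; virion i of a
#    series starts at (pac + i*floor(f*L)) mod L and spans floor(f*L) bases
#    (terminal redundancy floor(f*L) - L).
#  * cos_5 / cos_3: exact unit-length monomers opened at the cos coordinate;
#    end chemistry (end-fill/exonuclease) is applied by end_chemistry().
#  * dtr: L + d bases, the first d bases duplicated at the 3' end.
#  * itr: fixed-end linear genomes whose first r bases equal the reverse
#    complement of the last r (the reference itself carries the repeat).
#  * mu_like: genome flanked by variable stretches of host DNA drawn from a
#    supplied host sequence.

# one fixed sense codon per amino acid (translation table 11 compatible)
.codon_of <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
               S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

.non_stop_codons <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

# Reverse-translate a protein into a coding sequence.
reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  unknown <- setdiff(aa, names(.codon_of))
  if (length(unknown)) stop("cannot reverse-translate: ", paste(unknown, collapse = ""))
  paste(.codon_of[aa], collapse = "")
}

#' Specification for a simulated reference genome
#'
#' @param length genome length in bases (>= 1000). Realistic values for
#'   tailed phages run from ~10 kb to ~350 kb.
#' @param gc GC fraction in (0, 1).
#' @param terminase_class packaging strategy whose terminase archetype is
#'   planted ("headful_pac", "cos_5", "cos_3", "dtr", "mu_like"), "itr"
#'   (no terminase; an inverted terminal repeat is planted instead), or
#'   NULL for a plain random genome.
#' @param pac_site 0-based packaging-initiation coordinate, or NULL to place
#'   it inside the planted small-terminase stand-in gene.
#' @param itr_len inverted-terminal-repeat length planted when
#'   `terminase_class == "itr"`.
#' @param marker_mut_rate per-residue substitution rate applied to the
#'   planted terminase marker (0 = exact archetype copy).
#' @param seed integer seed controlling all randomness in [make_genome()].
#' @return A `sim_genome_spec` list.
#' @export
sim_genome_spec <- function(length = 40000L, gc = 0.43,
                            terminase_class = NULL, pac_site = NULL,
                            itr_len = 100L, marker_mut_rate = 0,
                            seed = 1L) {
  if (!is.numeric(length) || length < 1000) {
    stop("invalid genome length (must be >= 1000): ", length)
  }
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) stop("invalid gc fraction: ", gc)
  if (!is.null(pac_site) && pac_site >= length) {
    stop("pac_site must be < length")
  }
  if (!is.null(terminase_class)) {
    terminase_class <- match.arg(terminase_class,
      c("headful_pac", "cos_5", "cos_3", "dtr", "mu_like", "itr"))
  }
  structure(list(length = as.integer(length), gc = gc,
                 terminase_class = terminase_class,
                 pac_site = if (is.null(pac_site)) NULL else as.integer(pac_site),
                 itr_len = as.integer(itr_len),
                 marker_mut_rate = marker_mut_rate,
                 seed = as.integer(seed)),
            class = "sim_genome_spec")
}

# Substitute residues of a protein at the given per-residue rate.
mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  aa <- strsplit(protein, "")[[1]]
  hit <- which(stats::runif(length(aa)) < rate)
  for (i in hit) {
    aa[i] <- sample(setdiff(names(.codon_of), aa[i]), 1L)
  }
  paste(aa, collapse = "")
}

#' Generate a simulated reference genome
#'
#' Produces a random genome of the requested length and GC content with a
#' terminase marker gene (an exact or mutagenized copy of the bundled
#' archetype for the requested class) planted in frame, preceded by a small
#' random open reading frame standing in for the terminase small subunit;
#' the packaging-initiation (pac) site is placed inside that small gene, as
#' is typical for headful phages. For `terminase_class = "itr"` an inverted
#' terminal repeat is planted instead and no terminase is inserted.
#'
#' @param spec a [sim_genome_spec()].
#' @return A `genome_record` carrying a `sim_truth` element with the planted
#'   coordinates (terl_start/terl_end, ters_start/ters_end, pac_site,
#'   itr_len, archetype name).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_genome_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    seq <- random_dna(L, spec$gc)
    truth <- list(terminase_class = spec$terminase_class, pac_site = NULL,
                  terl_start = NULL, terl_end = NULL, ters_start = NULL,
                  ters_end = NULL, itr_len = NULL, archetype = NULL)
    cls <- spec$terminase_class
    if (!is.null(cls) && cls == "itr") {
      r <- spec$itr_len
      stopifnot(r * 2 < L)
      prefix <- substr(seq, 1L, r)
      seq <- paste0(substr(seq, 1L, L - r), revcomp(prefix))
      truth$itr_len <- r
    } else if (!is.null(cls)) {
      refs <- terminase_archetypes()
      cand <- refs$name[refs$packaging_class == cls]
      if (!length(cand)) stop("no bundled archetype for class ", cls)
      arch <- cand[1L]
      prot <- mutate_protein(refs$protein[refs$name == arch],
                             spec$marker_mut_rate)
      # leading stop codons pin the reported ORF starts to the planted ATGs
      terl_cds <- paste0("TAA", reverse_translate(prot), "TAA")
      n_ters <- 99L
      ters_prot <- paste0("M", paste(sample(setdiff(names(.codon_of), "M"),
                                            n_ters - 1L, replace = TRUE),
                                     collapse = ""))
      ters_cds <- paste0("TAA", reverse_translate(ters_prot), "TAA")
      gap <- 18L
      cassette <- paste0(ters_cds, strrep("A", 0), random_dna(gap, spec$gc),
                         terl_cds)
      pos <- floor(0.55 * L)  # 0-based insert position
      stopifnot(pos + nchar(cassette) <= L)
      seq <- paste0(substr(seq, 1L, pos),
                    cassette,
                    substr(seq, pos + nchar(cassette) + 1L, L))
      truth$archetype <- arch
      truth$ters_start <- pos + 3L
      truth$ters_end <- pos + nchar(ters_cds)
      truth$terl_start <- pos + nchar(ters_cds) + gap + 3L
      truth$terl_end <- pos + nchar(cassette)
      truth$pac_site <- if (!is.null(spec$pac_site)) spec$pac_site else
        truth$ters_start + 50L
    }
    if (is.null(truth$pac_site)) {
      truth$pac_site <- if (!is.null(spec$pac_site)) spec$pac_site else 0L
    }
    g <- genome_record(sprintf("simgenome_%s_seed%d",
                               if (is.null(cls)) "plain" else cls,
                               spec$seed),
                       seq, circular_hint = !identical(cls, "itr"))
    g$sim_truth <- truth
    g
  })
}

#' Packaging parameters
#'
#' Defaults reflect the simulated study conditions: headful fraction 1.05
#' with series length 5 (the generic headful bound is ~110% of genome
#' length), 12-base cohesive overhangs (lambda-like scale), 800-base direct
#' terminal repeats, and Mu-like host flanks of 50-150 bp (left) and
#' 500-3000 bp (right).
#'
#' @param headful_f capsid fill fraction, in (1.00, 1.10].
#' @param series_k number of monomers cut per concatemer series.
#' @param cos_len cohesive-end overhang length (bases).
#' @param cos_pos 0-based cos coordinate; NULL places it at floor(L/3).
#' @param dtr_len,dtr_pos direct terminal repeat length and 0-based start;
#'   NULL places the repeat at floor(L/3).
#' @param mu_left,mu_right inclusive ranges (length-2 integer vectors) for
#'   Mu-like host flank lengths.
#' @param p_chem fraction of cos molecules subject to end chemistry
#'   (end-fill for 5' overhangs, exonucleolytic loss for 3').
#' @param p_lig fraction of cos molecules re-circularized by cohesive-end
#'   annealing/ligation before shearing.
#' @return List of packaging parameters.
#' @export
packaging_params <- function(headful_f = 1.05, series_k = 5L, cos_len = 12L,
                             cos_pos = NULL, dtr_len = 800L, dtr_pos = NULL,
                             mu_left = c(50L, 150L), mu_right = c(500L, 3000L),
                             p_chem = 0.8, p_lig = 0.9) {
  list(headful_f = headful_f, series_k = as.integer(series_k),
       cos_len = as.integer(cos_len), cos_pos = cos_pos,
       dtr_len = as.integer(dtr_len), dtr_pos = dtr_pos,
       mu_left = as.integer(mu_left), mu_right = as.integer(mu_right),
       p_chem = p_chem, p_lig = p_lig)
}

new_virion <- function(sequence, truth_start, end_type, flank_left = 0L,
                       flank_right = 0L, circular = FALSE) {
  list(sequence = sequence, truth_start = as.integer(truth_start),
       truth_end_type = end_type, host_flank_left = as.integer(flank_left),
       host_flank_right = as.integer(flank_right), circular = circular)
}

#' Package virion monomers from a reference genome
#'
#' @param genome a `genome_record` (circularly interpretable except for
#'   "itr").
#' @param strategy one of "headful_pac", "cos_5", "cos_3", "dtr", "itr",
#'   "mu_like".
#' @param params a [packaging_params()] list.
#' @param n number of virions to produce.
#' @param seed integer seed.
#' @param host a `genome_record` supplying host DNA for "mu_like" flanks.
#' @return List of virions (sequence, truth_start, truth_end_type,
#'   host_flank_left/right, circular).
#' @export
package_virions <- function(genome, strategy, params = packaging_params(),
                            n = 50L, seed = 1L, host = NULL) {
  strategy <- match.arg(strategy, c("headful_pac", "cos_5", "cos_3", "dtr",
                                    "itr", "mu_like"))
  L <- nchar(genome$sequence)
  circle <- paste0(genome$sequence, genome$sequence, genome$sequence)
  pac <- if (!is.null(genome$sim_truth)) genome$sim_truth$pac_site else 0L
  feature_pos <- function(p) if (is.null(p)) as.integer(floor(L / 3)) else as.integer(p)
  with_seed(seed, {
    switch(strategy,
      headful_pac = {
        f <- params$headful_f
        if (f <= 1 || f > 1.1) {
          stop("headful fraction must lie in (1.00, 1.10], got ", f)
        }
        M <- as.integer(floor(f * L))
        k <- params$series_k
        idx <- rep(seq_len(k) - 1L, length.out = n)  # position within series
        starts <- (pac + idx * M) %% L
        lapply(seq_len(n), function(i) {
          s <- starts[i]
          new_virion(substr(circle, s + 1L, s + M), s, strategy)
        })
      },
      cos_5 = ,
      cos_3 = {
        t0 <- feature_pos(params$cos_pos)
        v <- rotate_seq(genome$sequence, t0)
        lapply(seq_len(n), function(i) new_virion(v, t0, strategy))
      },
      dtr = {
        t0 <- feature_pos(params$dtr_pos)
        d <- params$dtr_len
        v <- substr(circle, t0 + 1L, t0 + L + d)
        lapply(seq_len(n), function(i) new_virion(v, t0, strategy))
      },
      itr = {
        lapply(seq_len(n), function(i) new_virion(genome$sequence, 0L,
                                                  strategy))
      },
      mu_like = {
        if (is.null(host)) {
          stop("mu_like packaging requires a host genome for flank DNA")
        }
        H <- nchar(host$sequence)
        stopifnot(H >= max(params$mu_right) + 1L)
        lapply(seq_len(n), function(i) {
          lf <- sample(params$mu_left[1]:params$mu_left[2], 1L)
          rf <- sample(params$mu_right[1]:params$mu_right[2], 1L)
          lp <- sample.int(H - lf, 1L)
          rp <- sample.int(H - rf, 1L)
          new_virion(paste0(substr(host$sequence, lp, lp + lf - 1L),
                            genome$sequence,
                            substr(host$sequence, rp, rp + rf - 1L)),
                     0L, strategy, lf, rf)
        })
      })
  })
}

#' Apply cohesive-end library chemistry to cos virions
#'
#' Models what library preparation does to cohesive termini: on a fraction
#' `p_chem` of molecules the overhang bases are duplicated by end-fill (5'
#' overhangs, producing a coverage peak after mapping) or removed by 3'->5'
#' exonuclease activity (3' overhangs, producing a valley); subsequently a
#' fraction `p_lig` of molecules re-circularize via their cohesive ends, so
#' reads may span the junction.
#'
#' @param virions list of virions from [package_virions()].
#' @param strategy "cos_5" or "cos_3".
#' @param cos_len overhang length c.
#' @param p_chem fraction of molecules with end chemistry applied.
#' @param p_lig fraction of molecules circularized before shearing.
#' @param seed integer seed.
#' @return Modified virion list.
#' @export
end_chemistry <- function(virions, strategy, cos_len = 12L, p_chem = 0.8,
                          p_lig = 0.9, seed = 1L) {
  if (!strategy %in% c("cos_5", "cos_3")) {
    stop("end chemistry applies only to cos strategies, got ", strategy)
  }
  stopifnot(p_chem >= 0, p_chem <= 1, p_lig >= 0, p_lig <= 1)
  c_len <- as.integer(cos_len)
  with_seed(seed, {
    chem <- stats::runif(length(virions)) < p_chem
    lig <- stats::runif(length(virions)) < p_lig
    lapply(seq_along(virions), function(i) {
      v <- virions[[i]]
      if (chem[i]) {
        n <- nchar(v$sequence)
        v$sequence <- if (strategy == "cos_5") {
          paste0(v$sequence, substr(v$sequence, 1L, c_len))  # end-fill
        } else {
          substr(v$sequence, 1L, n - c_len)  # 3' overhang degraded
        }
        v$chem_applied <- TRUE
      } else {
        v$chem_applied <- FALSE
      }
      v$circular <- lig[i]
      v
    })
  })
}

#' Shear virions into paired-end reads
#'
#' Fragments are drawn uniformly along each virion (wrapping for
#' circularized molecules), insert sizes uniformly in
#' `[insert_min, insert_max]`, and mates are `read_len` bases from either
#' fragment end (mate 2 reverse-complemented); base-call errors are i.i.d.
#' substitutions at `error_rate`.
#'
#' @param virions list of virions.
#' @param n_pairs total number of read pairs (allocated to virions in
#'   proportion to their lengths).
#' @param insert_min,insert_max insert size bounds (bases).
#' @param read_len read length (bases).
#' @param error_rate substitution error rate in [0, 0.05].
#' @param seed integer seed.
#' @return data.frame of class `read_pairs`: id, mate1, mate2, quality1,
#'   quality2, virion, frag_start (0-based on the virion), insert.
#' @export
shear_reads <- function(virions, n_pairs, insert_min = 100L,
                        insert_max = 300L, read_len = 150L, error_rate = 0,
                        seed = 1L) {
  if (error_rate < 0 || error_rate > 0.05) {
    stop("error_rate must lie in [0, 0.05], got ", error_rate)
  }
  empty <- data.frame(id = character(0), mate1 = character(0),
                      mate2 = character(0), quality1 = character(0),
                      quality2 = character(0), virion = integer(0),
                      frag_start = integer(0), insert = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("read_pairs", "data.frame")
  if (!length(virions) || n_pairs < 1) return(empty)
  lens <- vapply(virions, function(v) nchar(v$sequence), integer(1))
  with_seed(seed, {
    vi <- sample.int(length(virions), n_pairs, replace = TRUE,
                     prob = lens / sum(lens))
    ins <- sample(insert_min:insert_max, n_pairs, replace = TRUE)
    frag <- character(n_pairs)
    fs <- integer(n_pairs)
    for (u in unique(vi)) {
      sel <- which(vi == u)
      v <- virions[[u]]
      n <- lens[u]
      if (v$circular %||% FALSE) {
        s <- sample.int(n, length(sel), replace = TRUE) - 1L
        doubled <- paste0(v$sequence, v$sequence)
        frag[sel] <- substring(doubled, s + 1L, s + ins[sel])
      } else {
        ins[sel] <- pmin(ins[sel], n)
        s <- vapply(n - ins[sel] + 1L,
                    function(m) sample.int(m, 1L) - 1L, integer(1))
        frag[sel] <- substring(v$sequence, s + 1L, s + ins[sel])
      }
      fs[sel] <- s
    }
    m1 <- substr(frag, 1L, pmin(read_len, ins))
    m2 <- revcomp_all(substring(frag, pmax(1L, ins - read_len + 1L), ins))
    if (error_rate > 0) {
      m1 <- mutate_reads(m1, error_rate)
      m2 <- mutate_reads(m2, error_rate)
    }
    q <- if (error_rate == 0) 30L else {
      as.integer(round(-10 * log10(error_rate)))
    }
    qc <- rawToChar(as.raw(q + 33L))
    out <- data.frame(id = sprintf("rp%06d", seq_len(n_pairs)),
                      mate1 = m1, mate2 = m2,
                      quality1 = strrep(qc, nchar(m1)),
                      quality2 = strrep(qc, nchar(m2)),
                      virion = vi, frag_start = fs, insert = ins,
                      stringsAsFactors = FALSE)
    class(out) <- c("read_pairs", "data.frame")
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# i.i.d. substitution errors over a character vector of reads.
mutate_reads <- function(reads, rate) {
  total <- sum(nchar(reads))
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0L) return(reads)
  flat <- strsplit(paste(reads, collapse = ""), "")[[1]]
  pos <- sample.int(total, n_err)
  alt <- c("A", "C", "G", "T")
  for (p in pos) {
    flat[p] <- sample(setdiff(alt, flat[p]), 1L)
  }
  joined <- paste(flat, collapse = "")
  ends <- cumsum(nchar(reads))
  substring(joined, c(1L, head(ends, -1L) + 1L), ends)
}

#' Write read pairs to a pair of FASTQ files
#'
#' @param reads a `read_pairs` data.frame.
#' @param prefix output prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` (add ".gz" via `gzip = TRUE`).
#' @param gzip compress outputs.
#' @return Character vector of the two paths.
#' @export
write_read_pairs <- function(reads, prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- paste0(prefix, "_R1", ext)
  p2 <- paste0(prefix, "_R2", ext)
  write_fastq(paste0(reads$id, "/1"), reads$mate1, reads$quality1, p1)
  write_fastq(paste0(reads$id, "/2"), reads$mate2, reads$quality2, p2)
  c(p1, p2)
}

#' Write the simulation truth table
#'
#' @param virions list of virions.
#' @param path output TSV path.
#' @export
write_virion_truth <- function(virions, path) {
  df <- data.frame(
    virion = seq_along(virions),
    strategy = vapply(virions, function(v) v$truth_end_type, character(1)),
    truth_start = vapply(virions, function(v) v$truth_start, integer(1)),
    length = vapply(virions, function(v) nchar(v$sequence), integer(1)),
    host_flank_left = vapply(virions, function(v) v$host_flank_left, integer(1)),
    host_flank_right = vapply(virions, function(v) v$host_flank_right, integer(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Produce the draft contig an assembler would report for simulated virions
#'
#' Stands in for de novo assembly (out of scope): terminally redundant or
#' cohesive-end genomes assemble into a circularly interpretable contig at
#' an arbitrary rotation (with a direct terminal repeat collapsed to one
#' copy); Mu-like virions assemble into the genome flanked by host DNA from
#' one virion; ITR genomes assemble as the linear genome.
#'
#' @param genome the simulated reference `genome_record`.
#' @param virions the packaged virions.
#' @param strategy packaging strategy used.
#' @param seed seed for the arbitrary rotation.
#' @return A `genome_record` with a `draft_truth` element (`offset`:
#'   reference coordinate at contig origin; `core_start`/`core_end`: phage
#'   core within a Mu-like contig).
#' @export
stand_in_assembly <- function(genome, virions, strategy, seed = 1L) {
  L <- nchar(genome$sequence)
  with_seed(seed, {
    if (strategy %in% c("headful_pac", "cos_5", "cos_3", "dtr")) {
      off <- sample.int(L, 1L) - 1L
      contig <- genome_record(paste0(genome$id, "_draft"),
                              rotate_seq(genome$sequence, off),
                              circular_hint = TRUE)
      contig$draft_truth <- list(offset = off, core_start = 0L, core_end = L)
    } else if (strategy == "mu_like") {
      v <- virions[[1L]]
      contig <- genome_record(paste0(genome$id, "_draft"), v$sequence,
                              circular_hint = FALSE)
      contig$draft_truth <- list(offset = 0L,
                                 core_start = v$host_flank_left,
                                 core_end = v$host_flank_left + L)
    } else {  # itr
      contig <- genome_record(paste0(genome$id, "_draft"), genome$sequence,
                              circular_hint = FALSE)
      contig$draft_truth <- list(offset = 0L, core_start = 0L, core_end = L)
    }
    contig
  })
}
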