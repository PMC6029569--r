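# Contig standardization engine.
#
# One of six strategies is chosen per genome (group consensus over
# terminase class and coverage pattern) and applied; every strategy except
# Mu-end trimming conserves the base multiset (output is an exact rotation
# and/or reverse complement of the input), which is asserted on every call.

.plan_strategies <- c("relinearize_at_terl_upstream_orf",
                      "cut_at_coverage_feature", "scaffold_to_reference",
                      "maintain_original", "trim_mu_ends",
                      "select_itr_contig")

new_plan <- function(strategy, cut_pos = NA_integer_,
                     orientation = "keep", trim_left = 0L, trim_right = 0L,
                     reference_id = NA_character_, rationale = list()) {
  strategy <- match.arg(strategy, .plan_strategies)
  structure(list(strategy = strategy, cut_pos = cut_pos,
                 orientation = orientation, trim_left = trim_left,
                 trim_right = trim_right, reference_id = reference_id,
                 rationale = rationale),
            class = "rearrangement_plan")
}

new_standardized <- function(contig, plan, original_id, log) {
  structure(list(contig = contig, plan = plan,
                 provenance = list(original_id = original_id, log = log)),
            class = "standardized_genome")
}

#' @export
print.standardized_genome <- function(x, ...) {
  cat(sprintf("<standardized_genome> %s (%d bp) via %s\n", x$contig$id,
              nchar(x$contig$sequence), x$plan$strategy))
  invisible(x)
}

# conservation guard for rotation/flip strategies
assert_rotation_flip <- function(input_seq, output_seq, what) {
  if (!is_rotation_or_flip(input_seq, output_seq)) {
    stop("internal error: ", what,
         " output is not a rotation/flip of its input")
  }
  invisible(TRUE)
}

#' Pick the target viral contig from a multi-contig assembly
#'
#' The highest mean-coverage contig is the target genome; lower-coverage
#' contigs are treated as contamination. Coverage ties break toward the
#' longer contig.
#'
#' @param contigs list of `genome_record`.
#' @param coverages numeric mean depth per contig (parallel to `contigs`).
#' @return The selected `genome_record`, with attribute `discarded` naming
#'   the others.
#' @export
select_primary_contig <- function(contigs, coverages) {
  stopifnot(length(contigs) >= 1L, length(coverages) == length(contigs))
  lens <- vapply(contigs, function(x) nchar(x$sequence), integer(1))
  ord <- order(-coverages, -lens)
  pick <- contigs[[ord[1L]]]
  attr(pick, "discarded") <- vapply(contigs[ord[-1L]],
                                    function(x) x$id, character(1))
  pick
}

#' Re-linearize a circular contig at the ORF upstream of TerL
#'
#' The contig is treated as circular; if TerL lies on the reverse strand
#' the contig is reverse-complemented first so TerL transcribes left to
#' right, and the new origin is the start of the ORF immediately preceding
#' TerL in genome order (wrapping). Output is an exact rotation/flip of
#' the input.
#'
#' @param contig a `genome_record`.
#' @param orfs ORF table for this contig (from [find_orfs()]).
#' @param terl a `terminase_assignment` for one of those ORFs.
#' @return A `standardized_genome`.
#' @export
relinearize_at_terl_upstream_orf <- function(contig, orfs, terl) {
  stopifnot(inherits(terl, "terminase_assignment"))
  L <- nchar(contig$sequence)
  seq <- contig$sequence
  flip <- identical(terl$orf$strand, "-")
  if (flip) {
    seq <- revcomp(seq)
    orfs <- flip_orfs(orfs, L)
  }
  terl_start <- if (flip) (L - terl$orf$end) %% L else terl$orf$start %% L
  starts <- orfs$start %% L
  prior <- starts[starts != terl_start]
  log <- character(0)
  if (!length(prior)) {
    origin <- terl_start
    log <- "TerL is the only ORF; origin set to TerL start"
  } else {
    before <- prior[prior < terl_start]
    origin <- if (length(before)) max(before) else max(prior)  # wrap
  }
  out_seq <- rotate_seq(seq, origin)
  assert_rotation_flip(contig$sequence, out_seq, "relinearize")
  plan <- new_plan("relinearize_at_terl_upstream_orf", cut_pos = origin,
                   orientation = if (flip) "flip" else "keep",
                   rationale = list(terminase_class = terl$packaging_class,
                                    reference_name = terl$reference_name))
  new_standardized(genome_record(contig$id, out_seq, TRUE), plan,
                   contig$id, c(log, sprintf("rotated to origin %d%s",
                                             origin,
                                             if (flip) " after flip" else "")))
}

flip_orfs <- function(orfs, L) {
  if (!nrow(orfs)) return(orfs)
  ns <- (L - orfs$end) %% L
  ne <- ns + (orfs$end - orfs$start)
  out <- orfs
  out$start <- as.integer(ns)
  out$end <- as.integer(ne)
  out$strand <- ifelse(orfs$strand == "+", "-", "+")
  out[order(out$start, out$end), , drop = FALSE]
}

#' Re-linearize a circular contig at a coverage peak or valley
#'
#' Cuts in the middle of the short aberrant-coverage run located by
#' [classify_pattern()] (cohesive-end or direct-terminal-repeat
#' signatures).
#'
#' @param contig a `genome_record`.
#' @param pattern a `pattern_call` with label short_internal_peak,
#'   cos_peak or cos_valley and a set anchor.
#' @return A `standardized_genome`.
#' @export
cut_at_coverage_feature <- function(contig, pattern) {
  stopifnot(inherits(pattern, "pattern_call"))
  if (!pattern$label %in% c("short_internal_peak", "cos_peak",
                            "cos_valley", "multiple_peaks")) {
    stop("cut_at_coverage_feature requires a peak/valley pattern, got ",
         pattern$label)
  }
  if (is.na(pattern$anchor)) stop("pattern has no locatable anchor")
  out_seq <- rotate_seq(contig$sequence, pattern$anchor)
  assert_rotation_flip(contig$sequence, out_seq, "cut_at_coverage_feature")
  plan <- new_plan("cut_at_coverage_feature", cut_pos = pattern$anchor,
                   rationale = list(pattern_label = pattern$label))
  new_standardized(genome_record(contig$id, out_seq, TRUE), plan,
                   contig$id,
                   sprintf("cut at %s midpoint %d", pattern$label,
                           pattern$anchor))
}

#' Trim variable host-DNA ends from a Mu-like contig
#'
#' With group members supplied, trims to the maximal interval conserved
#' (shared 31-mers, small gaps tolerated) across all members; otherwise
#' trims each terminal segment whose smoothed depth is at most
#' `depth_ratio` of the interior median.
#'
#' @param contig a `genome_record` (linear draft with host flanks).
#' @param profile the contig's `coverage_profile` (coverage route).
#' @param group_alignment optional list of related `genome_record`s
#'   (conserved-region route).
#' @param depth_ratio terminal-drop threshold relative to interior median.
#' @param k k-mer length for the conserved-region route.
#' @param config classifier configuration (smoothing window).
#' @return A `standardized_genome` with trim_left/trim_right recorded.
#' @export
trim_mu_ends <- function(contig, profile = NULL, group_alignment = NULL,
                         depth_ratio = 0.25, k = 31L,
                         config = pattern_config()) {
  L <- nchar(contig$sequence)
  if (!is.null(group_alignment) && length(group_alignment) >= 1L) {
    mark <- rep(TRUE, L - k + 1L)
    own <- kmers(contig$sequence, k)
    for (g in group_alignment) {
      mark <- mark & (own %in% kmers(g$sequence, k))
    }
    runs <- logical_runs(mark, circular = FALSE)
    if (!nrow(runs)) stop("no conserved interval shared with group members")
    # tolerate isolated mismatches between members
    runs <- merge_runs(runs, gap = 2L * k, L = L, circular = FALSE)
    run <- runs[which.max(runs$len), ]
    trim_left <- run$start
    trim_right <- L - (run$end + k - 1L)
  } else {
    stopifnot(inherits(profile, "coverage_profile"))
    depth <- profile$depth
    stopifnot(length(depth) == L)
    w <- smoothing_window(L, config)
    sm <- smooth_depth(depth, w, circular = FALSE)
    ex <- min(config$edge_exclude, floor(L / 4))
    thr <- depth_ratio * median(sm[(ex + 1L):(L - ex)])
    trim_left <- match(FALSE, sm <= thr, nomatch = 1L) - 1L
    trim_right <- match(FALSE, rev(sm) <= thr, nomatch = 1L) - 1L
    if (trim_left + trim_right >= L) stop("trim would remove entire contig")
  }
  out_seq <- substr(contig$sequence, trim_left + 1L, L - trim_right)
  plan <- new_plan("trim_mu_ends", trim_left = as.integer(trim_left),
                   trim_right = as.integer(trim_right),
                   rationale = list(route = if (is.null(group_alignment))
                     "coverage" else "conserved_region"))
  new_standardized(genome_record(contig$id, out_seq, FALSE), plan,
                   contig$id,
                   sprintf("trimmed %d left / %d right host-derived bases",
                           trim_left, trim_right))
}

#' Detect an inverted terminal repeat
#'
#' Longest r such that the first r bases equal the reverse complement of
#' the last r bases (exact match when `max_mismatch = 0`).
#'
#' @param contig a `genome_record`.
#' @param min_len minimum reportable repeat length.
#' @param max_mismatch tolerated mismatches within the repeat.
#' @return Integer repeat length, or NULL if shorter than `min_len`.
#' @export
detect_itr <- function(contig, min_len = 30L, max_mismatch = 0L) {
  S <- contig$sequence
  L <- nchar(S)
  half <- L %/% 2L
  a <- charToRaw(substr(S, 1L, half))
  b <- charToRaw(revcomp(substr(S, L - half + 1L, L)))
  mism <- cumsum(a != b)
  ok <- which(mism <= max_mismatch)
  if (!length(ok)) return(NULL)
  r <- max(ok)
  if (r == half) {
    warning("sequence is palindromic to its midpoint; ITR capped at L/2")
  }
  if (r < min_len) NULL else as.integer(r)
}

#' Choose the final contig for an ITR-bearing linear genome
#'
#' Among candidates exhibiting an inverted terminal repeat, the longest is
#' chosen; with no ITR anywhere, the longest contig overall. Ties break by
#' lexicographic id.
#'
#' @param candidates list of `genome_record`.
#' @param min_len minimum ITR length (passed to [detect_itr()]).
#' @return The chosen `genome_record`, with attribute `itr_len`.
#' @export
select_itr_contig <- function(candidates, min_len = 30L) {
  stopifnot(length(candidates) >= 1L)
  itr <- lapply(candidates, detect_itr, min_len = min_len)
  has <- !vapply(itr, is.null, logical(1))
  pool <- if (any(has)) which(has) else seq_along(candidates)
  lens <- vapply(candidates[pool], function(x) nchar(x$sequence), integer(1))
  ids <- vapply(candidates[pool], function(x) x$id, character(1))
  pick <- pool[order(-lens, ids)][1L]
  out <- candidates[[pick]]
  attr(out, "itr_len") <- if (has[pick]) itr[[pick]] else NULL
  out
}

#' Rotate/flip a contig onto a standardized reference
#'
#' Orientation is chosen to maximize the shared k-mer count, rotation so
#' that the modal offset between shared unique k-mers is zero; used for
#' genomes whose own signal is uninformative but which share their full
#' proteome with an already-standardized relative.
#'
#' @param contig a `genome_record`.
#' @param reference a `standardized_genome` (or `genome_record`) to match.
#' @param k k-mer length.
#' @param min_shared minimum shared unique k-mers required.
#' @return A `standardized_genome`.
#' @export
scaffold_to_reference <- function(contig, reference, k = 31L,
                                  min_shared = 10L) {
  ref_rec <- if (inherits(reference, "standardized_genome"))
    reference$contig else reference
  R <- ref_rec$sequence
  rk <- kmers(R, k)
  ref_unique <- !(duplicated(rk) | duplicated(rk, fromLast = TRUE))
  shared_offsets <- function(seq) {
    qk <- kmers(seq, k)
    q_unique <- !(duplicated(qk) | duplicated(qk, fromLast = TRUE))
    hit <- match(qk, rk)
    ok <- which(!is.na(hit) & q_unique & ref_unique[ifelse(is.na(hit), 1L, hit)])
    list(n = length(ok),
         offsets = (ok - hit[ok]) %% nchar(seq))
  }
  fwd <- shared_offsets(contig$sequence)
  rc_seq <- revcomp(contig$sequence)
  rev <- shared_offsets(rc_seq)
  use_rev <- rev$n > fwd$n
  res <- if (use_rev) rev else fwd
  if (res$n < min_shared) {
    stop("fewer than ", min_shared,
         " shared unique k-mers: not closely related to reference")
  }
  tab <- table(res$offsets)
  delta <- as.integer(names(tab)[which.max(tab)])
  seq0 <- if (use_rev) rc_seq else contig$sequence
  out_seq <- rotate_seq(seq0, delta)
  assert_rotation_flip(contig$sequence, out_seq, "scaffold_to_reference")
  plan <- new_plan("scaffold_to_reference", cut_pos = delta,
                   orientation = if (use_rev) "flip" else "keep",
                   reference_id = ref_rec$id,
                   rationale = list(shared_kmers = res$n))
  new_standardized(genome_record(contig$id, out_seq, contig$circular_hint),
                   plan, contig$id,
                   sprintf("scaffolded to %s (%d shared unique %d-mers)",
                           ref_rec$id, res$n, k))
}

#' Keep the original assembly
#'
#' @param contig a `genome_record`.
#' @param why free-text rationale recorded in the plan.
#' @return A `standardized_genome` with the input sequence unchanged.
#' @export
maintain_original <- function(contig, why = "no distinct pattern") {
  plan <- new_plan("maintain_original", rationale = list(note = why))
  new_standardized(contig, plan, contig$id, "original assembly maintained")
}
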