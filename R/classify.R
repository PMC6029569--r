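# Coverage-pattern classification.
#
# Makes explicit, as a deterministic decision cascade, the visual criteria
# used to sort phage read-coverage profiles into packaging signatures:
#   1. terminal_drop_mu  - both termini of a linear contig drop sharply to a
#                          low plateau (variable host-DNA ends).
#   2. cos_peak /          one narrow sharp-edged cohesive-end feature, or
#      short_internal_peak  one broad elevated run (collapsed direct
#                          terminal repeat).
#   3. cos_valley        - one narrow sharp-edged depleted run.
#   4. multiple_peaks    - two or more disjoint elevated features.
#   5. gradual_shift     - a circular declining trend, or a single elevated
#                          plateau with sharp-edged steps (headful series);
#                          step shifts are folded into this class because
#                          both are headful-consistent.
#   6. even              - flat profile (away from linear-contig shear
#                          edges).
#   7. none.
#
# Narrow cohesive-end features are located by their clip edges: with one
# alignment per read, reads running over a cohesive-end junction are soft
# clipped at the same base, producing single-base depth jumps far larger
# than shear noise (which varies on the fragment-length scale). Broad
# features are located on a wide running median, whose noise ceiling is
# far below the two-fold plateau of a collapsed terminal repeat.
# All thresholds are named configuration keys; they are calibrations of
# visual criteria, not biological constants.

#' Classifier configuration
#'
#' @param smooth_window_div main median-filter window is
#'   `max(101, L/smooth_window_div)` (odd).
#' @param edge_jump_min,edge_jump_frac a sharp edge is a depth change of at
#'   least `max(edge_jump_min, edge_jump_frac * median depth)` within
#'   `edge_lag` bases (clip edges are single-base; shear noise measured at
#'   50x stays below ~7 per base).
#' @param edge_lag maximum span (bases) of a sharp edge.
#' @param narrow_max_len maximum narrow-feature width (bases) between a
#'   down edge and its partner up edge.
#' @param valley_fold narrow-valley floor threshold relative to the median.
#' @param shadow_window,shadow_max_fold a cos peak must be followed by its
#'   clipped-tail dip: mean depth over `shadow_window` bases after the
#'   clip-end pile at most `shadow_max_fold` of the median (rejects stray
#'   pileups in undisturbed coverage, where this ratio is ~1).
#' @param peak_left_min_fold minimum mean depth (relative to median) over
#'   the narrow window preceding a cos-peak down edge.
#' @param broad_window running-median window for broad features.
#' @param broad_peak_fold broad elevated-run threshold relative to the
#'   median; a collapsed direct terminal repeat plateaus at 2x, while the
#'   400-base noise ceiling at 50x is ~1.4x.
#' @param broad_min_len minimum broad-run length (bases).
#' @param max_run_frac maximum feature-run length, as a fraction of L.
#' @param cos_peak_max_len features at most this wide are labelled
#'   cos_peak; wider elevated runs are short_internal_peak.
#' @param mu_terminal_frac maximum terminal-segment length as a fraction of
#'   L (Mu-like host flanks may reach ~3 kb on a ~40 kb genome).
#' @param mu_depth_ratio terminal segments count as dropped when their
#'   smoothed depth is at most this fraction of the interior median.
#' @param mu_step_fold,mu_step_span the drop must recover by
#'   `mu_step_fold` within `mu_step_span` multiples of the smoothing
#'   window (sharp step, not a gradual shear-edge ramp).
#' @param mu_min_flank at least one terminal drop must be longer than this
#'   (bases), so plain shear edge ramps on linear contigs do not qualify;
#'   default is insert size + read length.
#' @param trend_min_r2 minimum variance explained by the circular
#'   log-linear trend.
#' @param trend_min_frac minimum fraction of L over which the profile must
#'   be non-increasing from its maximum.
#' @param shift_min_fold minimum elevated/baseline fold for the step-shift
#'   route.
#' @param shift_min_score minimum normalized segmentation contrast
#'   (standard-error-scaled contrast per unit median depth) for the
#'   step-shift route; a genuine headful plateau integrates its whole
#'   series (scores ~15-20 at the defaults) while chance elevated regions
#'   stay well below 10.
#' @param shift_run_frac admissible elevated-plateau length range as
#'   fractions of L.
#' @param flat_max_fold maximum max/min ratio of the smoothed profile for
#'   the `even` label.
#' @param edge_exclude bases excluded at each end of a *linear* contig when
#'   computing interior statistics (library shear edge artifacts).
#' @param min_len,min_median_depth preconditions on the profile.
#' @return Named list of configuration values.
#' @export
pattern_config <- function(smooth_window_div = 400,
                           edge_jump_min = 12, edge_jump_frac = 0.25,
                           edge_lag = 3L, narrow_max_len = 40L,
                           valley_fold = 0.5, shadow_window = 50L,
                           shadow_max_fold = 0.85, peak_left_min_fold = 0.9,
                           broad_window = 401L, broad_peak_fold = 1.55,
                           broad_min_len = 150L, max_run_frac = 0.02,
                           cos_peak_max_len = 100L,
                           mu_terminal_frac = 0.10, mu_depth_ratio = 0.25,
                           mu_step_fold = 4, mu_step_span = 2,
                           mu_min_flank = 450L, trend_min_r2 = 0.5,
                           trend_min_frac = 0.6, shift_min_fold = 1.1,
                           shift_min_score = 10,
                           shift_run_frac = c(0.03, 0.7),
                           flat_max_fold = 1.5, edge_exclude = 450L,
                           min_len = 1000L, min_median_depth = 5) {
  as.list(environment())
}

smoothing_window <- function(L, config = pattern_config()) {
  odd_at_least(max(101, round(L / config$smooth_window_div)))
}

# median filter honoring circularity
smooth_depth <- function(depth, w, circular) {
  if (circular) circ_runmed(depth, w)
  else as.numeric(runmed(depth, odd_at_least(w), endrule = "median"))
}

new_pattern_call <- function(label, anchor, features) {
  structure(list(label = label,
                 anchor = if (is.null(anchor)) NA_integer_ else as.integer(anchor),
                 features = features),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("<pattern_call> %s%s (median depth %.1f, fold %.2f)\n",
              x$label,
              if (!is.na(x$anchor)) sprintf(" @ %d", x$anchor) else "",
              x$features$median_depth, x$features$fold_change))
  invisible(x)
}

# circular-aware window mean over [i, i+len) (0-based i)
win_mean <- function(depth, i, len, L, circular) {
  idx <- i + seq_len(len) - 1L
  if (circular) idx <- idx %% L
  idx <- idx[idx >= 0L & idx < L]
  if (!length(idx)) return(NA_real_)
  mean(depth[idx + 1L])
}

# Narrow cohesive-end features.
#
# Preferred route (profiles produced by this package's mapper): clip-start
# and clip-end pileups. Reads soft-clipped at a cohesive-end junction all
# start or end at the same base; a clip-end pileup *followed* by a nearby
# clip-start pileup brackets deleted overhang bases (3' chemistry ->
# valley), while a clip-start pileup followed by a clip-end pileup
# brackets duplicated bases (5' end-fill -> peak). Fallback route
# (imported profiles without pileups): sharp depth edges.
detect_narrow_features <- function(profile, L, circular, m0, config) {
  depth <- profile$depth
  if (!is.null(profile$clip_starts) && !is.null(profile$clip_ends)) {
    res <- narrow_from_pileups(profile, L, circular, m0, config)
    return(res)
  }
  narrow_from_edges(depth, L, circular, m0, config)
}

# pileup route
narrow_from_pileups <- function(profile, L, circular, m0, config) {
  depth <- profile$depth
  ce <- profile$clip_ends
  cs <- profile$clip_starts
  # primary clip-end piles: single-base count >= max(8, local depth / 6);
  # thresholds scale with local depth so coverage clumps cannot chain into
  # spurious clusters
  idx <- which(ce >= 8)
  if (!circular && length(idx)) {
    ex <- min(config$edge_exclude, floor(L / 4))
    idx <- idx[idx > ex & idx <= L - ex]
  }
  if (!length(idx)) return(NULL)
  keep <- vapply(idx, function(i) {
    local_bg <- win_mean(depth, i - 201L, 400L, L, circular)
    ce[i] >= max(8, local_bg / 6)
  }, logical(1))
  idx <- idx[keep]
  if (!length(idx)) return(NULL)
  # collapse jittered piles within 4 bases to the strongest
  grp <- cumsum(c(1L, diff(idx) > 4L))
  prim <- vapply(split(idx, grp), function(g) g[which.max(ce[g])], integer(1))
  wl <- config$narrow_max_len
  out <- list()
  for (e in prim[order(-ce[prim])]) {
    e0 <- e - 1L  # 0-based coordinate of the pile base
    side_sum <- function(lo, hi) {
      w <- (lo:hi)
      if (circular) w <- w %% L
      w <- w[w >= 0 & w < L] + 1L
      v <- cs[w]
      list(total = sum(v[v >= 3]),
           pos = if (any(v >= 3)) w[which.max(v)] - 1L else NA_integer_)
    }
    left <- side_sum(e0 - wl, e0 - 1L)    # clip starts before the pile
    right <- side_sum(e0 + 1L, e0 + wl)   # clip starts after the pile
    if (max(left$total, right$total) < 4) {
      # no clip-start partner: a deleted-overhang (3') junction always
      # leaves a strong downstream partner, so an unpartnered pile with a
      # depressed downstream shadow is a 5' end-fill peak
      shadow <- win_mean(depth, e0 + 1L, config$shadow_window, L, circular)
      near <- win_mean(depth, e0 + 1L, 15L, L, circular)
      if (!is.na(shadow) && shadow <= config$shadow_max_fold * m0 &&
          !is.na(near) && near <= 0.6 * m0) {
        out[[length(out) + 1L]] <- data.frame(
          type = "peak", anchor = (e0 - 6L) %% L,
          fold = win_mean(depth, e0 - 11L, 12L, L, circular) / m0,
          width = 12L, strength = ce[e])
      }
      next
    }
    if (right$total > left$total) {
      # clip-end pile, then clip-start pile: deleted bases between (3')
      s0 <- right$pos
      gap <- if (circular) (s0 - e0) %% L else s0 - e0
      fl <- win_mean(depth, e0 + 1L, max(gap - 1L, 1L), L, circular)
      if (!is.na(fl) && fl <= config$valley_fold * m0) {
        out[[length(out) + 1L]] <- data.frame(
          type = "valley", anchor = (e0 + as.integer(gap) %/% 2L) %% L,
          fold = fl / m0, width = as.integer(gap),
          strength = ce[e] + right$total)
      }
    } else {
      # clip-start pile, then clip-end pile: duplicated bases between (5')
      s0 <- left$pos
      wd <- if (circular) (e0 - s0) %% L else e0 - s0
      wd <- as.integer(wd) + 1L
      shadow <- win_mean(depth, e0 + 1L, config$shadow_window, L, circular)
      if (!is.na(shadow) && shadow <= config$shadow_max_fold * m0) {
        out[[length(out) + 1L]] <- data.frame(
          type = "peak", anchor = (s0 + wd %/% 2L) %% L,
          fold = win_mean(depth, s0, wd, L, circular) / m0, width = wd,
          strength = ce[e] + left$total)
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(-res$strength), , drop = FALSE]
}

# depth-edge fallback route; returns the same candidate layout
narrow_from_edges <- function(depth, L, circular, m0, config) {
  jump_at <- function(lag) {
    if (circular) depth[(seq_len(L) - 1L + lag) %% L + 1L] - depth
    else c(depth[(1L + lag):L] - depth[seq_len(L - lag)], rep(0, lag))
  }
  jmax <- jump_at(1L)
  if (config$edge_lag > 1L) {
    for (lag in 2L:config$edge_lag) {
      j <- jump_at(lag)
      jmax <- ifelse(abs(j) > abs(jmax), j, jmax)
    }
  }
  thr <- max(config$edge_jump_min, config$edge_jump_frac * m0)
  if (!circular) {
    ex <- min(config$edge_exclude, floor(L / 4))
    jmax[seq_len(ex)] <- 0
    jmax[(L - ex + 1L):L] <- 0
  }
  ups <- which(jmax >= thr)       # depth rises after position i (0-based i-1)
  downs <- which(jmax <= -thr)
  # collapse adjacent edge calls to the strongest
  collapse <- function(idx, j) {
    if (!length(idx)) return(integer(0))
    grp <- cumsum(c(1L, diff(idx) > config$edge_lag))
    vapply(split(idx, grp), function(g) g[which.max(abs(j[g]))], integer(1))
  }
  ups <- collapse(ups, jmax)
  downs <- collapse(downs, jmax)
  if (!length(downs)) return(NULL)
  out <- list()
  used_up <- integer(0)
  for (d0 in downs[order(jmax[downs])]) {   # strongest (most negative) first
    gap_to <- if (circular) (ups - d0) %% L else ups - d0
    cand <- ups[gap_to >= 1L & gap_to <= config$narrow_max_len]
    if (length(cand)) {
      u0 <- cand[which.min(if (circular) (cand - d0) %% L else cand - d0)]
      width <- if (circular) (u0 - d0) %% L else u0 - d0
      floor_mean <- win_mean(depth, d0, width, L, circular)
      if (!is.na(floor_mean) && floor_mean <= config$valley_fold * m0) {
        out[[length(out) + 1L]] <- data.frame(
          type = "valley", anchor = (d0 + width %/% 2L) %% L,
          fold = floor_mean / m0, width = width,
          strength = abs(jmax[d0]) + abs(jmax[u0]))
        used_up <- c(used_up, u0)
        next
      }
    }
    # unpaired down edge: cos-peak candidate (bump then clipped-tail dip)
    wl <- config$narrow_max_len
    left <- win_mean(depth, d0 - wl, wl, L, circular)
    right <- win_mean(depth, d0, config$shadow_window, L, circular)
    if (!is.na(left) && !is.na(right) &&
        left >= config$peak_left_min_fold * m0 &&
        right <= config$shadow_max_fold * m0) {
      out[[length(out) + 1L]] <- data.frame(
        type = "peak", anchor = (d0 - wl %/% 2L) %% L,
        fold = left / m0, width = wl, strength = abs(jmax[d0]))
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(-res$strength), , drop = FALSE]
}

# Broad elevated/depleted runs on a wide running median.
detect_broad_runs <- function(depth, L, circular, m0, config, direction) {
  smB <- smooth_depth(depth, config$broad_window, circular)
  # background from a much wider window, so a run is judged against its
  # local neighborhood (a coverage clump atop an elevated headful plateau
  # must not register as a peak)
  bgB <- pmax(smooth_depth(depth, 10L * config$broad_window + 1L, circular),
              1e-9)
  mask <- if (direction == "up") smB >= config$broad_peak_fold * bgB
          else smB <= config$valley_fold * bgB
  if (!circular) {
    ex <- min(config$edge_exclude, floor(L / 4))
    mask[seq_len(ex)] <- FALSE
    mask[(L - ex + 1L):L] <- FALSE
  }
  runs <- logical_runs(mask, circular)
  if (nrow(runs)) runs <- merge_runs(runs, gap = 50L, L = L,
                                     circular = circular)
  runs[runs$len >= config$broad_min_len &
         runs$len <= config$max_run_frac * L, , drop = FALSE]
}

#' Classify a coverage pattern
#'
#' Applies the decision cascade described above to a per-base coverage
#' profile and returns a single label with, where the label has a locatable
#' feature, a 0-based anchor coordinate (feature midpoint, or the upstream
#' edge / maximum of a headful shift).
#'
#' @param profile a `coverage_profile`.
#' @param config a [pattern_config()] list.
#' @return A `pattern_call` (label, anchor, features).
#' @export
classify_pattern <- function(profile, config = pattern_config()) {
  stopifnot(inherits(profile, "coverage_profile"))
  depth <- profile$depth
  L <- length(depth)
  if (all(depth == 0)) stop("all-zero coverage profile: no reads mapped")
  med_all <- median(depth)
  base_feats <- function(fold = 1, width = NA_integer_, slope = NA_real_) {
    list(median_depth = med_all, run_width = width, fold_change = fold,
         trend_slope = slope)
  }
  if (L < config$min_len || med_all < config$min_median_depth) {
    warning("profile too short or too shallow for classification")
    return(new_pattern_call("none", NULL, base_feats()))
  }
  circular <- profile$circular
  w <- smoothing_window(L, config)
  sm <- smooth_depth(depth, w, circular)

  interior_idx <- if (circular) seq_len(L) else {
    ex <- min(config$edge_exclude, floor(L / 4))
    (ex + 1L):(L - ex)
  }
  m0 <- median(sm[interior_idx])

  # (1) Mu-like terminal drops: linear contigs only
  if (!circular) {
    thr <- config$mu_depth_ratio * m0
    left_len <- match(FALSE, sm <= thr, nomatch = L + 1L) - 1L
    right_len <- match(FALSE, rev(sm) <= thr, nomatch = L + 1L) - 1L
    cap <- config$mu_terminal_frac * L
    if (left_len > 0 && right_len > 0 &&
        left_len <= cap && right_len <= cap &&
        max(left_len, right_len) >= config$mu_min_flank) {
      span <- round(config$mu_step_span * w)
      # sharp step: within `span` bases of the drop edge the profile must
      # recover to mu_step_fold/2 times the drop threshold (= 0.5x the
      # interior median at the defaults)
      recov <- config$mu_step_fold / 2 * thr
      sharp <- function(inner_idx) {
        inner_idx <- min(max(inner_idx, 1L), L)
        sm[inner_idx] >= recov
      }
      if (sharp(left_len + span) && sharp(L - right_len + 1L - span)) {
        return(new_pattern_call(
          "terminal_drop_mu", NULL,
          base_feats(fold = median(sm[c(seq_len(left_len),
                                        (L - right_len + 1L):L)]) / m0,
                     width = left_len + right_len)))
      }
    }
  }

  narrow <- detect_narrow_features(profile, L, circular, m0, config)
  broad_peaks <- detect_broad_runs(depth, L, circular, m0, config, "up")
  n_narrow_peak <- if (is.null(narrow)) 0L else sum(narrow$type == "peak")
  n_narrow_valley <- if (is.null(narrow)) 0L else sum(narrow$type == "valley")
  n_peaks <- n_narrow_peak + nrow(broad_peaks)

  # (2) single peak feature
  if (n_peaks == 1L && n_narrow_peak == 1L) {
    f <- narrow[narrow$type == "peak", ][1L, ]
    label <- if (f$width <= config$cos_peak_max_len) "cos_peak"
             else "short_internal_peak"
    return(new_pattern_call(label, f$anchor,
                            base_feats(fold = f$fold, width = f$width)))
  }
  if (n_peaks == 1L && nrow(broad_peaks) == 1L) {
    run <- broad_peaks[1L, ]
    label <- if (run$len <= config$cos_peak_max_len) "cos_peak"
             else "short_internal_peak"
    smB <- smooth_depth(depth, config$broad_window, circular)
    idx <- (run$start:(run$end - 1L)) %% L + 1L
    return(new_pattern_call(label, (run$start + run$len %/% 2L) %% L,
                            base_feats(fold = max(smB[idx]) / m0,
                                       width = run$len)))
  }
  # (3) narrow valley
  if (n_narrow_valley >= 1L && n_peaks < 2L) {
    f <- narrow[narrow$type == "valley", ][1L, ]
    return(new_pattern_call("cos_valley", f$anchor,
                            base_feats(fold = f$fold, width = f$width)))
  }
  # (4) multiple peaks
  if (n_peaks >= 2L) {
    widths <- c(if (n_narrow_peak) narrow$width[narrow$type == "peak"],
                broad_peaks$len)
    anchor <- if (n_narrow_peak) narrow$anchor[narrow$type == "peak"][1L]
              else (broad_peaks$start[1L] + broad_peaks$len[1L] %/% 2L) %% L
    return(new_pattern_call("multiple_peaks", anchor,
                            base_feats(fold = NA_real_,
                                       width = sum(widths))))
  }

  # (5) headful gradual decline / step shift: circular contigs only
  if (circular) {
    shift <- detect_gradual_shift(depth, L, w, config)
    if (!is.null(shift)) return(shift)
  }

  # (6) flat
  smF <- smooth_depth(depth, odd_at_least(max(2001, round(L / 20))), circular)
  rng <- range(smF[interior_idx])
  if (rng[2] / max(rng[1], 1e-9) <= config$flat_max_fold) {
    return(new_pattern_call("even", NULL,
                            base_feats(fold = rng[2] / max(rng[1], 1e-9))))
  }
  new_pattern_call("none", NULL, base_feats())
}

# Rule 5: step-shift route first (max-contrast circular segmentation:
# the best elevated plateau integrates the whole headful series, so it is
# found reliably where per-edge detection is not), then the circular
# log-linear trend route (anchor at the maximum).
detect_gradual_shift <- function(depth, L, w, config) {
  w2 <- odd_at_least(max(1001, round(L / 40)))
  d <- circ_runmed(depth, w2)
  med_all <- median(depth)
  feats <- function(fold, width = NA_integer_, slope = NA_real_) {
    list(median_depth = med_all, run_width = width, fold_change = fold,
         trend_slope = slope)
  }
  seg <- best_plateau(d, L, config)
  if (!is.null(seg)) {
    # matched-filter edge check at *refined* edge positions: a genuine
    # headful plateau steps sharply at both edges, while a chance
    # elevated region rises and falls on the fragment-clump scale; the
    # absolute floor keeps weak-contrast chance regions out
    h <- seg$mean_in - seg$mean_out
    seg <- refine_plateau(depth, L, seg, span = 2600L, step = 50L)
    seg <- refine_plateau(depth, L, seg, span = 60L, step = 5L)
    up <- seg$start
    # raw-depth window means either side of the refined anchor edge
    csum <- c(0, cumsum(c(depth, depth)))
    wmean <- function(i, len) {
      i <- ((i %% L) + L) %% L
      (csum[i + len + 1L] - csum[i + 1L]) / len
    }
    up_edge <- wmean(up, w2) - wmean(up - w2, w2)
    if (seg$mean_in / max(seg$mean_out, 1e-9) >= config$shift_min_fold &&
        seg$score / max(med_all, 1e-9) >= config$shift_min_score &&
        up_edge >= 0.3 * h) {
      return(new_pattern_call("gradual_shift", up,
                              feats(seg$mean_in / seg$mean_out,
                                    width = seg$len)))
    }
  }
  # circular trend route: rotate the maximum to the origin, regress
  # log-depth on position
  sm <- circ_runmed(depth, w)
  mx <- which.max(d) - 1L
  rot <- c(sm[(mx + 1L):L], sm[seq_len(mx)])
  x <- seq_len(L)
  y <- log(pmax(rot, 0.5))
  if (stats::var(y) < 1e-12) return(NULL)  # flat profile: no trend
  fit <- lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- coef(fit)[[2L]]
  rot2 <- c(d[(mx + 1L):L], d[seq_len(mx)])
  noninc <- mean(rot2 <= cummin(rot2) * 1.05)
  if (r2 >= config$trend_min_r2 && slope < 0 &&
      noninc >= config$trend_min_frac) {
    return(new_pattern_call("gradual_shift", mx,
                            feats(fold = max(rot2) / max(min(rot2), 1e-9),
                                  slope = slope)))
  }
  NULL
}

# Exhaustive two-level circular segmentation: over a grid of run lengths
# and all offsets, maximize the in/out mean contrast via prefix sums.
best_plateau <- function(d, L, config) {
  lens <- unique(round(L * seq(config$shift_run_frac[1],
                               config$shift_run_frac[2], by = 0.02)))
  lens <- lens[lens >= 2 & lens < L]
  if (!length(lens)) return(NULL)
  cs <- c(0, cumsum(c(d, d)))   # doubled prefix sums
  total <- sum(d)
  best <- NULL
  for (len in lens) {
    win <- cs[(len + 1L):(len + L)] - cs[1:L]   # sums of [i, i+len)
    contrast <- win / len - (total - win) / (L - len)
    # normalize by the standard error so long plateaus are not outscored
    # by short high-variance noise windows
    score <- contrast / sqrt(1 / len + 1 / (L - len))
    i <- which.max(score)
    if (is.null(best) || score[i] > best$score) {
      best <- list(start = i - 1L, len = len, score = score[i],
                   mean_in = win[i] / len,
                   mean_out = (total - win[i]) / (L - len))
    }
  }
  best
}

# merge runs separated by gaps <= gap (wrap-around merging when circular)
merge_runs <- function(runs, gap, L, circular = TRUE) {
  if (nrow(runs) <= 1L) return(runs)
  runs <- runs[order(runs$start), , drop = FALSE]
  merged <- runs[1L, , drop = FALSE]
  for (i in 2L:nrow(runs)) {
    last <- nrow(merged)
    if (runs$start[i] - merged$end[last] <= gap) {
      merged$end[last] <- max(merged$end[last], runs$end[i])
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  # wrap-around merge
  if (circular && nrow(merged) > 1L) {
    first <- merged[1L, ]
    last <- nrow(merged)
    if (first$start + L - merged$end[last] <= gap) {
      merged$end[last] <- first$end + L
      merged <- merged[-1L, , drop = FALSE]
    }
  }
  merged$len <- pmin(merged$end - merged$start, L)
  merged
}


# Jointly refine a plateau's (start, length) around a coarse segmentation
# by maximizing the standard-error-normalized contrast on the raw depth.
refine_plateau <- function(depth, L, seg, span, step) {
  cs <- c(0, cumsum(c(depth, depth)))
  total <- sum(depth)
  starts <- seq(seg$start - span, seg$start + span, by = step)
  lens <- seq(max(seg$len - span, 2L * step), seg$len + span, by = step)
  best <- seg
  best$score <- -Inf
  for (len in lens) {
    s_mod <- ((starts %% L) + L) %% L
    win <- cs[s_mod + len + 1L] - cs[s_mod + 1L]
    contrast <- win / len - (total - win) / (L - len)
    score <- contrast / sqrt(1 / len + 1 / (L - len))
    i <- which.max(score)
    if (score[i] > best$score) {
      best <- list(start = s_mod[i], len = len, score = score[i],
                   mean_in = win[i] / len,
                   mean_out = (total - win[i]) / (L - len))
    }
  }
  best
}

# Refine a step edge: within +/- span of the coarse edge position, fit
# the best changepoint of a finely smoothed profile against the mid level
# between the plateau and the baseline.
refine_step_edge <- function(depth, coarse, span, hi, lo, L,
                             rising = TRUE) {
  fine <- circ_runmed(depth, 501L)
  idx0 <- (coarse - span):(coarse + span)      # 0-based, may wrap
  vals <- fine[(idx0 %% L) + 1L]
  mid <- (hi + lo) / 2
  above <- if (rising) vals >= mid else vals < mid
  n <- length(above)
  # changepoint t: positions < t should violate `above`, >= t satisfy it
  lead_above <- c(0, cumsum(above))[seq_len(n)]
  trail_below <- rev(c(0, cumsum(rev(!above))))[seq_len(n)]
  t_best <- which.min(lead_above + trail_below)
  (idx0[t_best] %% L)
}
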