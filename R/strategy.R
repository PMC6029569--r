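# Group-consensus strategy selection.
#
# All members of a genome group receive a common inferred packaging
# category, decided by majority vote over (terminase class, coverage
# pattern) evidence with fixed precedence:
#   mu evidence > itr evidence > headful > cos/DTR > maintain-original.
# Within a headful group, members lacking a terminase are scaffolded to a
# resolved member when they share 100% of their proteins with one;
# singletons with no terminase and no distinct pattern keep their original
# assembly.

.headful_patterns <- c("gradual_shift", "even")
.feature_patterns <- c("cos_peak", "cos_valley", "short_internal_peak",
                       "multiple_peaks")

#' Choose a standardization strategy for every genome, by group
#'
#' @param groups list of character vectors of genome ids (a partition, as
#'   returned by [group_genomes()]).
#' @param assignments named list: genome id -> `terminase_assignment` or
#'   NULL.
#' @param patterns named list: genome id -> `pattern_call`.
#' @param itr_lengths named list/vector: genome id -> detected ITR length
#'   or NULL (from [detect_itr()]).
#' @param identical_pairs data.frame (genome_a, genome_b) of
#'   full-proteome-sharing pairs (from [identical_proteome_pairs()]);
#'   used for scaffold eligibility.
#' @return data.frame: genome, group, category, strategy, reference_id,
#'   trace (one row per genome). The decision trace explains each vote.
#' @export
select_strategy <- function(groups, assignments, patterns,
                            itr_lengths = list(),
                            identical_pairs = NULL) {
  all_ids <- unlist(groups, use.names = FALSE)
  missing_pat <- setdiff(all_ids, names(patterns))
  if (length(missing_pat)) {
    stop("every genome needs a pattern call; missing: ",
         paste(missing_pat, collapse = ", "))
  }
  cls_of <- function(id) {
    a <- assignments[[id]]
    if (is.null(a)) NA_character_ else a$packaging_class
  }
  pat_of <- function(id) patterns[[id]]$label
  itr_of <- function(id) {
    v <- itr_lengths[[id]]
    !is.null(v) && !is.na(v)
  }
  has_partner <- function(id, resolved) {
    if (is.null(identical_pairs) || !nrow(identical_pairs)) return(FALSE)
    p <- c(identical_pairs$genome_b[identical_pairs$genome_a == id],
           identical_pairs$genome_a[identical_pairs$genome_b == id])
    any(p %in% resolved)
  }

  rows <- list()
  for (gi in seq_along(groups)) {
    ids <- groups[[gi]]
    cls <- vapply(ids, cls_of, character(1))
    pat <- vapply(ids, pat_of, character(1))
    mu_members <- !is.na(cls) & cls == "mu_like"
    nonmu_terminase <- !is.na(cls) & cls != "mu_like"
    if (any(mu_members) && any(nonmu_terminase)) {
      stop(sprintf(
        "group %d mixes Mu-like and non-Mu terminases (%s): manual review",
        gi, paste(ids, collapse = ", ")))
    }
    trace0 <- sprintf("group %d: classes [%s], patterns [%s]", gi,
                      paste(ifelse(is.na(cls), ".", cls), collapse = ","),
                      paste(pat, collapse = ","))
    if (any(mu_members) || any(pat == "terminal_drop_mu")) {
      category <- "mu_like"
      strategy <- rep("trim_mu_ends", length(ids))
      ref <- rep(NA_character_, length(ids))
    } else if (all(is.na(cls)) && any(vapply(ids, itr_of, logical(1)))) {
      category <- "itr"
      strategy <- rep("select_itr_contig", length(ids))
      ref <- rep(NA_character_, length(ids))
    } else {
      headful_votes <- sum((!is.na(cls) & cls == "headful_pac") |
                             pat %in% .headful_patterns)
      feature_votes <- sum((!is.na(cls) & cls %in% c("cos_5", "cos_3", "dtr")) |
                             pat %in% .feature_patterns)
      if (length(ids) == 1L && is.na(cls[1L]) && pat[1L] == "none") {
        category <- "unresolved"
        strategy <- "maintain_original"
        ref <- NA_character_
      } else if (headful_votes >= feature_votes && headful_votes > 0L) {
        category <- "headful_pac"
        with_terl <- ids[!is.na(cls)]
        strategy <- character(length(ids))
        ref <- rep(NA_character_, length(ids))
        for (j in seq_along(ids)) {
          if (!is.na(cls[j])) {
            strategy[j] <- "relinearize_at_terl_upstream_orf"
          } else if (length(with_terl) && has_partner(ids[j], with_terl)) {
            strategy[j] <- "scaffold_to_reference"
            part <- c(identical_pairs$genome_b[identical_pairs$genome_a == ids[j]],
                      identical_pairs$genome_a[identical_pairs$genome_b == ids[j]])
            ref[j] <- intersect(part, with_terl)[1L]
          } else {
            strategy[j] <- "maintain_original"
          }
        }
      } else if (feature_votes > 0L) {
        category <- "cos_dtr"
        strategy <- ifelse(pat %in% .feature_patterns,
                           "cut_at_coverage_feature", "maintain_original")
        ref <- rep(NA_character_, length(ids))
        # members without their own locatable feature scaffold to a
        # resolved member when proteome-identical
        resolved <- ids[strategy == "cut_at_coverage_feature"]
        for (j in seq_along(ids)) {
          if (strategy[j] == "maintain_original" &&
              has_partner(ids[j], resolved)) {
            strategy[j] <- "scaffold_to_reference"
            part <- c(identical_pairs$genome_b[identical_pairs$genome_a == ids[j]],
                      identical_pairs$genome_a[identical_pairs$genome_b == ids[j]])
            ref[j] <- intersect(part, resolved)[1L]
          }
        }
      } else {
        category <- "unresolved"
        strategy <- rep("maintain_original", length(ids))
        ref <- rep(NA_character_, length(ids))
      }
    }
    rows[[gi]] <- data.frame(genome = ids, group = gi, category = category,
                             strategy = strategy, reference_id = ref,
                             trace = trace0, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
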