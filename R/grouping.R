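# Proteome clustering and genome grouping.
#
# Protein clusters are connected components of the cross-genome
# reciprocal-best-hit (RBH) graph (local alignment, BLOSUM62, gap 11/1,
# E <= 1e-5, alignment covering >= 75% of the longer protein); genome
# groups are connected components of the genome graph thresholded on the
# Jaccard index of shared protein clusters. Connected components replace
# Markov/FT clustering: simpler, deterministic, and sufficient for
# group-consensus strategy selection.

# All-vs-all best hits between two proteomes; returns index pairs that are
# reciprocal best hits passing the E-value and coverage gates.
rbh_between <- function(prot_a, prot_b, evalue_max, min_cover, mat) {
  na <- length(prot_a); nb <- length(prot_b)
  la <- nchar(prot_a); lb <- nchar(prot_b)
  db_ab <- sum(lb); db_ba <- sum(la)
  score <- matrix(NA_real_, na, nb)
  cover <- matrix(NA_real_, na, nb)
  subj <- Biostrings::AAStringSet(prot_b)
  for (i in seq_len(na)) {
    aln <- Biostrings::pairwiseAlignment(
      rep(Biostrings::AAStringSet(prot_a[i]), nb), subj,
      type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1)
    score[i, ] <- Biostrings::score(aln)
    # span of the alignment in the longer of the two proteins
    span_a <- IRanges::width(Biostrings::pattern(aln))
    span_b <- IRanges::width(Biostrings::subject(aln))
    longer_is_a <- la[i] >= lb
    cover[i, ] <- ifelse(longer_is_a, span_a / la[i], span_b / lb)
  }
  ev_ab <- matrix(ka_evalue(score, rep(la, nb), db_ab)$evalue, na, nb)
  ev_ba <- matrix(ka_evalue(score, rep(lb, each = na), db_ba)$evalue, na, nb)
  pass <- ev_ab <= evalue_max & ev_ba <= evalue_max & cover >= min_cover
  score_pass <- ifelse(pass, score, -Inf)
  if (!any(pass)) return(NULL)
  best_b_of_a <- max.col(score_pass, ties.method = "first")
  best_a_of_b <- max.col(t(score_pass), ties.method = "first")
  a_idx <- which(vapply(seq_len(na), function(i) {
    j <- best_b_of_a[i]
    is.finite(score_pass[i, j]) && best_a_of_b[j] == i
  }, logical(1)))
  if (!length(a_idx)) return(NULL)
  cbind(a = a_idx, b = best_b_of_a[a_idx])
}

#' Cluster proteins across genomes by reciprocal best hits
#'
#' @param proteomes named list: genome id -> character vector of protein
#'   sequences (e.g. the `protein` column of [find_orfs()] output).
#' @param evalue_max maximum E-value for an RBH edge.
#' @param min_cover minimum alignment coverage of the longer protein.
#' @return List of protein clusters; each a data.frame (genome, orf_index).
#'   Singleton proteins form singleton clusters. The partition property
#'   (every protein in exactly one cluster) holds by construction.
#' @export
reciprocal_best_hits <- function(proteomes, evalue_max = 1e-5,
                                 min_cover = 0.75) {
  stopifnot(length(proteomes) >= 2L, !is.null(names(proteomes)))
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  gs <- names(proteomes)
  node_id <- function(g, i) paste0(g, "#", i)
  nodes <- unlist(lapply(gs, function(g)
    vapply(seq_along(proteomes[[g]]), node_id, "", g = g)))
  edges <- character(0)
  for (i in seq_along(gs)) {
    for (j in seq_along(gs)) {
      if (j <= i) next
      hits <- rbh_between(proteomes[[gs[i]]], proteomes[[gs[j]]],
                          evalue_max, min_cover, mat)
      if (!is.null(hits)) {
        edges <- c(edges, rbind(node_id(gs[i], hits[, "a"]),
                                node_id(gs[j], hits[, "b"])))
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  split_ids <- split(nodes, comp$membership)
  clusters <- lapply(unname(split_ids), function(v) {
    parts <- strsplit(v, "#", fixed = TRUE)
    data.frame(genome = vapply(parts, `[`, "", 1L),
               orf_index = as.integer(vapply(parts, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  })
  # deterministic order: by first member
  ord <- order(vapply(clusters, function(cl)
    paste(cl$genome[1], sprintf("%06d", cl$orf_index[1])), ""))
  clusters[ord]
}

# cluster index sets per genome
cluster_sets <- function(clusters) {
  genomes <- unique(unlist(lapply(clusters, function(cl) cl$genome)))
  sets <- setNames(vector("list", length(genomes)), genomes)
  for (ci in seq_along(clusters)) {
    for (g in unique(clusters[[ci]]$genome)) {
      sets[[g]] <- c(sets[[g]], ci)
    }
  }
  sets
}

#' Group genomes by shared protein clusters
#'
#' Genome-genome similarity is the Jaccard index of their protein-cluster
#' sets; groups are connected components of the graph thresholded at
#' `min_jaccard`.
#'
#' @param clusters output of [reciprocal_best_hits()].
#' @param min_jaccard edge threshold.
#' @param genomes optional character vector forcing the genome universe
#'   (genomes with no proteins become singleton groups).
#' @return List of character vectors of genome ids (a partition).
#' @export
group_genomes <- function(clusters, min_jaccard = 0.35, genomes = NULL) {
  sets <- cluster_sets(clusters)
  ids <- union(names(sets), genomes %||% character(0))
  n <- length(ids)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, n, name = ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        a <- sets[[ids[i]]]; b <- sets[[ids[j]]]
        if (is.null(a) || is.null(b)) next
        jac <- length(intersect(a, b)) / length(union(a, b))
        if (jac >= min_jaccard) g <- igraph::add_edges(g, c(ids[i], ids[j]))
      }
    }
  }
  comp <- igraph::components(g)
  unname(lapply(split(ids, comp$membership), sort))
}

#' Genome pairs sharing their complete proteomes
#'
#' Pairs whose protein-cluster sets are equal and whose every shared
#' cluster contains members from both genomes; such pairs are eligible for
#' scaffolded standardization.
#'
#' @param clusters output of [reciprocal_best_hits()].
#' @return data.frame (genome_a, genome_b), lexicographically ordered.
#' @export
identical_proteome_pairs <- function(clusters) {
  sets <- cluster_sets(clusters)
  ids <- sort(names(sets))
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      a <- ids[i]; b <- ids[j]
      if (!setequal(sets[[a]], sets[[b]])) next
      both <- all(vapply(sets[[a]], function(ci) {
        m <- clusters[[ci]]$genome
        a %in% m && b %in% m
      }, logical(1)))
      if (both) out[[length(out) + 1L]] <- data.frame(
        genome_a = a, genome_b = b, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(genome_a = character(0), genome_b = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
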