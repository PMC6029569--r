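# End-to-end pipeline over simulated genomes:
# simulate -> map -> classify -> gene-call -> group -> select strategy ->
# standardize -> QC, with a manifest capturing inputs, seeds and
# thresholds so reruns are bit-identical.

#' Pipeline configuration for synthetic mode
#'
#' @param strategies packaging strategies to simulate.
#' @param genome_length,gc reference genome parameters.
#' @param depth target mean read depth.
#' @param n_virions virions packaged per genome.
#' @param read_len,insert_min,insert_max read simulation parameters.
#' @param error_rate substitution error rate.
#' @param params [packaging_params()] list.
#' @param pattern_cfg [pattern_config()] list.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param out_dir optional directory for FASTA/TSV/bedGraph artifacts.
#' @return Config list for [run_pipeline()].
#' @export
pipeline_config <- function(strategies = c("headful_pac", "cos_5", "cos_3",
                                           "dtr", "itr", "mu_like"),
                            genome_length = 40000L, gc = 0.43, depth = 50,
                            n_virions = 50L, read_len = 150L,
                            insert_min = 100L, insert_max = 300L,
                            error_rate = 0, params = packaging_params(),
                            pattern_cfg = pattern_config(), seed = 1L,
                            out_dir = NULL) {
  as.list(environment())
}

# derive a bounded per-stage seed from the master seed
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 7919 + stage_index * 104729) %% 2147483647)
}

#' Simulate one genome and its curation inputs
#'
#' Runs simulate/package/shear/map/classify/gene-call for a single
#' packaging strategy and returns the evidence the standardization engine
#' needs, together with the planted truth.
#'
#' @param strategy packaging strategy.
#' @param config a [pipeline_config()].
#' @param seed seed for this genome (defaults to a derivation from the
#'   config seed).
#' @param with_genes also run ORF calling and terminase assignment (the
#'   expensive stages; skip when only the coverage pattern is needed).
#' @return List: genome, virions, contig (draft), reads, placements,
#'   profile, pattern, orfs, terl, itr_len, truth.
#' @export
simulate_genome_case <- function(strategy, config = pipeline_config(),
                                 seed = NULL, with_genes = TRUE) {
  si <- match(strategy, c("headful_pac", "cos_5", "cos_3", "dtr", "itr",
                          "mu_like"))
  if (is.null(seed)) seed <- derive_seed(config$seed, si)
  spec <- sim_genome_spec(length = config$genome_length, gc = config$gc,
                          terminase_class = strategy,
                          seed = derive_seed(seed, 1L))
  genome <- make_genome(spec)
  host <- NULL
  if (strategy == "mu_like") {
    host <- with_seed(derive_seed(seed, 2L),
                      genome_record("sim_host", random_dna(200000L, 0.45)))
  }
  virions <- package_virions(genome, strategy, config$params,
                             n = config$n_virions,
                             seed = derive_seed(seed, 3L), host = host)
  if (strategy %in% c("cos_5", "cos_3")) {
    virions <- end_chemistry(virions, strategy,
                             cos_len = config$params$cos_len,
                             p_chem = config$params$p_chem,
                             p_lig = config$params$p_lig,
                             seed = derive_seed(seed, 4L))
  }
  contig <- stand_in_assembly(genome, virions, strategy,
                              seed = derive_seed(seed, 5L))
  n_pairs <- ceiling(config$depth * nchar(contig$sequence) /
                       (2 * config$read_len))
  reads <- shear_reads(virions, n_pairs, config$insert_min,
                       config$insert_max, config$read_len,
                       config$error_rate, seed = derive_seed(seed, 6L))
  placements <- map_reads(reads, contig, circular = contig$circular_hint)
  profile <- per_base_coverage(placements, nchar(contig$sequence),
                               circular = contig$circular_hint,
                               contig_id = contig$id)
  pattern <- classify_pattern(profile, config$pattern_cfg)
  if (with_genes) {
    orfs <- find_orfs(contig, circular = contig$circular_hint)
    terl <- if (strategy == "itr") NULL else
      suppressWarnings(assign_terminase(orfs))
  } else {
    orfs <- NULL
    terl <- NULL
  }
  itr_len <- detect_itr(contig)
  list(strategy = strategy, genome = genome, virions = virions,
       contig = contig, reads = reads, placements = placements,
       profile = profile, pattern = pattern, orfs = orfs, terl = terl,
       itr_len = itr_len, truth = genome$sim_truth, seed = seed)
}

# apply a decided strategy to a simulated case
apply_plan <- function(case, strategy_row, references = list()) {
  switch(strategy_row$strategy,
    relinearize_at_terl_upstream_orf =
      relinearize_at_terl_upstream_orf(case$contig, case$orfs, case$terl),
    cut_at_coverage_feature =
      cut_at_coverage_feature(case$contig, case$pattern),
    trim_mu_ends =
      trim_mu_ends(case$contig, case$profile),
    select_itr_contig = {
      pick <- select_itr_contig(list(case$contig))
      std <- maintain_original(pick, "longest ITR-bearing contig")
      std$plan$strategy <- "select_itr_contig"
      std
    },
    scaffold_to_reference =
      scaffold_to_reference(case$contig,
                            references[[strategy_row$reference_id]]),
    maintain_original = maintain_original(case$contig))
}

#' Run the full pipeline over simulated genomes
#'
#' @param config a [pipeline_config()].
#' @return List with `cases` (per-genome evidence), `decisions`
#'   (strategy table), `standardized` (named list of
#'   `standardized_genome`), and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cases <- lapply(config$strategies, simulate_genome_case, config = config)
  names(cases) <- vapply(cases, function(x) x$contig$id, character(1))
  groups <- as.list(names(cases))  # each simulated genome is a singleton
  assignments <- lapply(cases, function(x) x$terl)
  patterns <- lapply(cases, function(x) x$pattern)
  itrs <- lapply(cases, function(x) x$itr_len)
  decisions <- select_strategy(groups, assignments, patterns, itrs)
  standardized <- list()
  for (i in seq_len(nrow(decisions))) {
    id <- decisions$genome[i]
    standardized[[id]] <- apply_plan(cases[[id]], decisions[i, ])
  }
  manifest <- list(config = config[setdiff(names(config), "pattern_cfg")],
                   thresholds = config$pattern_cfg,
                   seeds = vapply(cases, function(x) x$seed, integer(1)),
                   outputs = vapply(standardized, function(s)
                     nchar(s$contig$sequence), integer(1)))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(lapply(standardized, function(s) s$contig),
                file.path(config$out_dir, "standardized.fasta"))
    write.table(decisions, file.path(config$out_dir, "plans.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(cases = cases, decisions = decisions, standardized = standardized,
       manifest = manifest)
}
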