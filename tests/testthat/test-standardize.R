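test_that("select_primary_contig takes highest coverage, ties to longest", {
  a <- toy_genome(40000, seed = 1, id = "a")
  b <- toy_genome(30000, seed = 2, id = "b")
  expect_identical(select_primary_contig(list(a), 10)$id, "a")
  pick <- select_primary_contig(list(a, b), c(200, 15))
  expect_identical(pick$id, "a")
  expect_identical(attr(pick, "discarded"), "b")
  expect_identical(select_primary_contig(list(b, a), c(30, 30))$id, "a")
})

sim_case_for_relinearize <- function(seed) {
  g <- make_genome(sim_genome_spec(length = 12000,
                                   terminase_class = "headful_pac",
                                   seed = seed))
  orfs <- find_orfs(g)
  list(g = g, orfs = orfs, terl = assign_terminase(orfs))
}

test_that("TerL re-linearization is a fixed point and rotation-invariant", {
  cs <- sim_case_for_relinearize(41)
  std1 <- relinearize_at_terl_upstream_orf(cs$g, cs$orfs, cs$terl)
  # fixed point: re-running on the standardized output reproduces it
  orfs2 <- find_orfs(std1$contig)
  terl2 <- assign_terminase(orfs2)
  std2 <- relinearize_at_terl_upstream_orf(std1$contig, orfs2, terl2)
  expect_identical(std2$contig$sequence, std1$contig$sequence)

  # any rotation of the input yields the same output sequence
  L <- nchar(cs$g$sequence)
  for (k in c(123L, 7777L)) {
    rot <- genome_record("rot", phagestd:::rotate_seq(cs$g$sequence, k), TRUE)
    orfs_r <- find_orfs(rot)
    terl_r <- assign_terminase(orfs_r)
    std_r <- relinearize_at_terl_upstream_orf(rot, orfs_r, terl_r)
    expect_identical(std_r$contig$sequence, std1$contig$sequence, info = k)
  }

  # flipping the contig puts TerL on the minus strand; output is unchanged
  flip <- genome_record("flip", revcomp(cs$g$sequence), TRUE)
  orfs_f <- find_orfs(flip)
  terl_f <- assign_terminase(orfs_f)
  expect_identical(terl_f$orf$strand, "-")
  std_f <- relinearize_at_terl_upstream_orf(flip, orfs_f, terl_f)
  expect_identical(std_f$contig$sequence, std1$contig$sequence)
  expect_identical(std_f$plan$orientation, "flip")
})

test_that("re-linearization conserves the base multiset (rotation/flip)", {
  cs <- sim_case_for_relinearize(42)
  std <- relinearize_at_terl_upstream_orf(cs$g, cs$orfs, cs$terl)
  expect_true(phagestd:::is_rotation_or_flip(cs$g$sequence,
                                             std$contig$sequence))
})

test_that("cut_at_coverage_feature cuts at the anchor and validates input", {
  g <- toy_genome(8000, seed = 43)
  pat <- structure(list(label = "cos_valley", anchor = 1050L,
                        features = list()), class = "pattern_call")
  std <- cut_at_coverage_feature(g, pat)
  expect_identical(std$contig$sequence,
                   phagestd:::rotate_seq(g$sequence, 1050))
  expect_identical(std$plan$cut_pos, 1050L)

  bad <- structure(list(label = "even", anchor = NA_integer_,
                        features = list()), class = "pattern_call")
  expect_error(cut_at_coverage_feature(g, bad), "peak/valley")
  noanchor <- structure(list(label = "cos_peak", anchor = NA_integer_,
                             features = list()), class = "pattern_call")
  expect_error(cut_at_coverage_feature(g, noanchor), "anchor")
})

test_that("conserved-region trimming recovers a shared core exactly", {
  core <- toy_genome(6000, seed = 44, id = "core")$sequence
  mk <- function(seed, lf, rf) {
    phagestd:::with_seed(seed, genome_record(
      paste0("m", seed),
      paste0(phagestd:::random_dna(lf, 0.45), core,
             phagestd:::random_dna(rf, 0.45)), FALSE))
  }
  a <- mk(45, 120, 1500)
  b <- mk(46, 80, 900)
  std <- trim_mu_ends(a, group_alignment = list(b))
  expect_identical(std$contig$sequence, core)
  expect_equal(std$plan$trim_left, 120L)
  expect_equal(std$plan$trim_right, 1500L)
})

test_that("coverage-route trimming leaves flat profiles untouched", {
  g <- toy_genome(5000, seed = 47, circular = FALSE)
  prof <- coverage_profile(g$id, rep(40, 5000))
  std <- trim_mu_ends(g, profile = prof)
  expect_identical(std$contig$sequence, g$sequence)
  expect_equal(std$plan$trim_left + std$plan$trim_right, 0L)
})

test_that("detect_itr finds planted repeats and rejects chance ones", {
  base <- toy_genome(10000, seed = 48, circular = FALSE)$sequence
  L <- nchar(base)
  itr <- substr(base, 1, 100)
  seq <- paste0(substr(base, 1, L - 100), revcomp(itr))
  # pin the repeat length: position 101 must not chance-extend it, so set
  # it equal to its partner base (a base never equals its own complement)
  partner <- substr(seq, L - 100, L - 100)
  seq <- paste0(substr(seq, 1, 100), partner, substr(seq, 102, L))
  g <- genome_record("itr", seq, circular_hint = FALSE)
  expect_equal(detect_itr(g), 100L)

  expect_null(detect_itr(toy_genome(10000, seed = 49, circular = FALSE)))

  pal <- paste0(base, revcomp(base))
  expect_warning(r <- detect_itr(genome_record("pal", pal, FALSE)),
                 "palindromic")
  expect_equal(r, nchar(pal) %/% 2L)
})

test_that("select_itr_contig prefers ITR-bearing contigs over longer ones", {
  base <- toy_genome(10000, seed = 50, circular = FALSE)$sequence
  with_itr <- genome_record(
    "itr10", paste0(substr(base, 1, 9900), revcomp(substr(base, 1, 100))),
    FALSE)
  longer <- toy_genome(12000, seed = 51, id = "no_itr", circular = FALSE)
  pick <- select_itr_contig(list(longer, with_itr))
  expect_identical(pick$id, "itr10")
  expect_gte(attr(pick, "itr_len"), 100L)

  expect_identical(select_itr_contig(list(longer,
                                          toy_genome(8000, seed = 52,
                                                     id = "short",
                                                     circular = FALSE)))$id,
                   "no_itr")
  expect_identical(select_itr_contig(list(with_itr))$id, "itr10")
})

test_that("scaffolding recovers rotation and orientation against a reference", {
  ref <- toy_genome(15000, seed = 53, id = "ref")
  rot <- genome_record("rot", phagestd:::rotate_seq(ref$sequence, 4321), TRUE)
  std <- scaffold_to_reference(rot, ref)
  expect_identical(std$contig$sequence, ref$sequence)

  rc <- genome_record("rc", revcomp(phagestd:::rotate_seq(ref$sequence,
                                                          987)), TRUE)
  std2 <- scaffold_to_reference(rc, ref)
  expect_identical(std2$contig$sequence, ref$sequence)
  expect_identical(std2$plan$orientation, "flip")

  # 1% substitutions: the modal offset still recovers the exact rotation
  mut <- phagestd:::with_seed(54, {
    s <- strsplit(phagestd:::rotate_seq(ref$sequence, 2222), "")[[1]]
    hit <- sample(length(s), 150)
    s[hit] <- vapply(s[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    genome_record("mut", paste(s, collapse = ""), TRUE)
  })
  std3 <- scaffold_to_reference(mut, ref)
  # the modal-offset rotation must land on the reference origin exactly
  expect_identical(std3$plan$cut_pos, (15000L - 2222L) %% 15000L)
  expect_identical(std3$contig$sequence,
                   phagestd:::rotate_seq(mut$sequence, 15000L - 2222L))

  alien <- toy_genome(15000, seed = 55, id = "alien")
  expect_error(scaffold_to_reference(alien, ref), "shared unique")
})
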