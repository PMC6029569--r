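test_that("count-based ANI has identity and symmetry properties", {
  expect_equal(ani_from_counts(0, 0, 31617, 31617), 1.0)
  set.seed(61)
  for (i in 1:20) {
    qm <- sample(0:100, 1); sm <- sample(0:100, 1)
    ql <- sample(10000:80000, 1); sl <- sample(10000:80000, 1)
    expect_identical(ani_from_counts(qm, sm, ql, sl),
                     ani_from_counts(sm, qm, sl, ql))
  }
  expect_error(ani_from_counts(-1, 0, 100, 100))
})

test_that("self-comparison of an arbitrary genome is a perfect replicate", {
  for (seed in c(62, 63)) {
    g <- toy_genome(2000, seed = seed, circular = FALSE)
    cmp <- compare_replicates(g, g)
    expect_equal(cmp$snp, 0L)
    expect_equal(cmp$indel_bases, 0L)
    expect_equal(cmp$ani, 1.0)
    expect_equal(cmp$length_variation, 0L)
  }
})

test_that("substitutions and indels are counted and attributed", {
  g <- toy_genome(3000, seed = 64, circular = FALSE)
  s <- strsplit(g$sequence, "")[[1]]
  for (p in c(500, 1500, 2500)) {
    s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  }
  b <- genome_record("b", paste(s, collapse = ""), FALSE)
  cmp <- compare_replicates(g, b)
  expect_equal(cmp$snp, 3L)
  expect_equal(cmp$indel_bases, 0L)
  expect_equal(cmp$ani, ani_from_counts(3, 3, 3000, 3000))

  # 10-base insertion in the query: gap columns charged to the query
  ins <- genome_record("ins", paste0(substr(g$sequence, 1, 1000),
                                     strrep("A", 10),
                                     substr(g$sequence, 1001, 3000)), FALSE)
  cmp2 <- compare_replicates(ins, g)
  expect_equal(cmp2$indel_bases, 10L)
  expect_equal(cmp2$query_mismatch - cmp2$snp, 10L)
  expect_equal(cmp2$subject_mismatch, cmp2$snp)
  expect_equal(cmp2$length_variation, 10L)
})

test_that("unalignable pairs error rather than reporting a low ANI", {
  a <- toy_genome(2000, seed = 65, circular = FALSE)
  b <- toy_genome(2000, seed = 66, circular = FALSE, id = "other")
  expect_error(compare_replicates(a, b), "not replicates")
})

test_that("an embedded virus is detected and flagged by the screen", {
  host <- toy_genome(12000, seed = 67, id = "host", circular = FALSE)
  tail_seq <- toy_genome(200, seed = 68, id = "x", circular = FALSE)
  virus <- genome_record("v", paste0(substr(host$sequence, 2001, 5000),
                                     tail_seq$sequence), FALSE)
  hits <- prophage_screen(virus, list(host), min_len = 1000)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$match_len, 3000L)
  expect_equal(hits$identity, 1.0)
  expect_true(hits$flagged)   # virus cover 3000/3200 = 0.94
})

test_that("unrelated sequences and full containment behave as expected", {
  virus <- toy_genome(3000, seed = 69, id = "v", circular = FALSE)
  host <- toy_genome(12000, seed = 70, id = "h", circular = FALSE)
  expect_equal(nrow(prophage_screen(virus, list(host), min_len = 1000)), 0L)
  expect_equal(nrow(prophage_screen(virus, list(), min_len = 1000)), 0L)

  contained <- genome_record("c", substr(host$sequence, 3001, 6000), FALSE)
  hits <- prophage_screen(contained, list(host), min_len = 1000)
  expect_equal(hits$virus_cover, 1.0)
  expect_true(hits$flagged)
})

test_that("synteny score is 1 for identical order and drops for blocks", {
  g <- toy_genome(6000, seed = 71, circular = FALSE)
  expect_equal(synteny_check(g, g), 1.0)

  rot <- genome_record("rot", phagestd:::rotate_seq(g$sequence, 3000), FALSE)
  score <- synteny_check(g, rot)
  # two collinear blocks: the longest increasing subsequence is one block
  expect_lt(score, 0.6)
  expect_gt(score, 0.4)

  rc <- genome_record("rc", revcomp(g$sequence), FALSE)
  score_rc <- synteny_check(g, rc)
  expect_true(is.na(score_rc) || score_rc < 0.05)
})

test_that("the LIS engine matches a quadratic oracle", {
  set.seed(72)
  for (i in 1:10) {
    x <- sample(100, sample(5:40, 1))
    expect_equal(phagestd:::lis_length(x), lis_oracle(x), info = i)
  }
})
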