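test_that("error-free reads map back to their truth positions", {
  g <- toy_genome(6000, seed = 1, circular = FALSE)
  pos <- c(0L, 1234L, 5000L, 5850L)
  reads <- reads_from(vapply(pos, function(p)
    substr(g$sequence, p + 1, p + 150), character(1)))
  pl <- map_reads(reads, g, circular = FALSE)
  expect_equal(nrow(pl), 8L)  # both mates of all pairs
  m1 <- pl[pl$mate == 1, ]
  expect_equal(m1$pos[order(m1$pos)], pos)
  expect_true(all(pl$mismatches == 0))
  expect_equal(attr(pl, "n_unplaced"), 0L)
})

test_that("reads spanning the origin of a circular contig fold mod L", {
  g <- toy_genome(4000, seed = 2)
  dd <- paste0(g$sequence, g$sequence)
  rd <- substr(dd, 4000 - 49, 4000 - 49 + 149)  # covers [3950,4000)+[0,100)
  pl <- map_reads(reads_from(rd), g, circular = TRUE)
  expect_equal(pl$pos[pl$mate == 1], 3950L)
  prof <- per_base_coverage(pl, 4000, circular = TRUE)
  expect_equal(sum(prof$depth), 2L * 150L)
  expect_equal(prof$depth[1:100], rep(2, 100))     # wrapped portion
  expect_equal(prof$depth[3951:4000], rep(2, 50))
  expect_equal(sum(prof$depth[101:3950]), 0)
})

test_that("reads from unrelated sequence stay unplaced", {
  g <- toy_genome(5000, seed = 3)
  alien <- toy_genome(200, seed = 99, id = "alien")
  pl <- map_reads(reads_from(substr(alien$sequence, 1, 150)), g,
                  circular = TRUE)
  expect_equal(nrow(pl), 0L)
  expect_equal(attr(pl, "n_unplaced"), 2L)
})

test_that("k larger than the read length is a parameter error", {
  g <- toy_genome(2000, seed = 4)
  expect_error(map_reads(reads_from(substr(g$sequence, 1, 20)), g, k = 31),
               "seed length")
})

test_that("soft clipping maps the aligned span of a chimeric read", {
  g <- toy_genome(3000, seed = 5, circular = FALSE)
  alien <- toy_genome(300, seed = 98, id = "x")
  # 90 genome bases + 60 foreign bases
  rd <- paste0(substr(g$sequence, 501, 590), substr(alien$sequence, 1, 60))
  pl <- map_reads(reads_from(rd, rd), g, circular = FALSE)
  expect_true(all(pl$pos == 500L))
  expect_true(all(pl$len <= 95))
  expect_true(all(pl$len >= 85))
})

test_that("multi-mapping mates take the leftmost hit and are counted", {
  core <- toy_genome(500, seed = 6)$sequence
  dup <- paste0(core, toy_genome(800, seed = 7)$sequence, core)
  g <- genome_record("dup", dup, circular_hint = FALSE)
  rd <- substr(core, 101, 250)
  pl <- map_reads(reads_from(rd), g, circular = FALSE)
  expect_equal(pl$pos[pl$mate == 1], 100L)
  expect_equal(attr(pl, "n_ambiguous"), 2L)
})

test_that("per-base coverage matches a brute-force counting oracle", {
  set.seed(11)
  for (rep in 1:5) {
    L <- 400L
    n <- 60L
    pl <- data.frame(read_id = sprintf("r%d", 1:n),
                     mate = rep(1L, n),
                     pos = sample.int(L, n) - 1L,
                     len = sample(20:80, n, replace = TRUE),
                     strand = "+", mismatches = 0L)
    circ <- rep %% 2 == 0
    if (!circ) pl$len <- pmin(pl$len, L - pl$pos)
    prof <- per_base_coverage(pl, L, circular = circ)
    expect_equal(prof$depth, as.numeric(coverage_oracle(pl, L, circ)))
    expect_equal(sum(prof$depth), sum(pl$len))
  }
})

test_that("empty placements give a zero profile and stacking adds depth", {
  empty <- data.frame(read_id = character(0), mate = integer(0),
                      pos = integer(0), len = integer(0),
                      strand = character(0), mismatches = integer(0))
  expect_equal(per_base_coverage(empty, 50)$depth, rep(0, 50))
  two <- data.frame(read_id = c("a", "b"), mate = 1L, pos = 10L, len = 20L,
                    strand = "+", mismatches = 0L)
  prof <- per_base_coverage(two, 50)
  expect_equal(prof$depth[11:30], rep(2, 20))
  expect_equal(sum(prof$depth), 40)
})
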