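test_that("make_genome is deterministic and honors length and GC", {
  spec <- sim_genome_spec(length = 40000, gc = 0.43, seed = 7)
  g1 <- make_genome(spec)
  g2 <- make_genome(spec)
  expect_identical(g1$sequence, g2$sequence)
  expect_equal(nchar(g1$sequence), 40000L)
  gc <- genome_stats(g1)$gc_percent / 100
  # binomial bound at n = 40,000: +/-0.02 around the target
  expect_gt(gc, 0.41)
  expect_lt(gc, 0.45)
})

test_that("make_genome validates its parameters", {
  expect_error(sim_genome_spec(length = 500), "length")
  expect_error(sim_genome_spec(gc = 1.2), "gc")
  expect_error(sim_genome_spec(pac_site = 50000), "pac_site")
})

test_that("the planted terminase marker round-trips through assignment", {
  for (cls in c("headful_pac", "cos_3", "mu_like")) {
    g <- make_genome(sim_genome_spec(length = 20000, terminase_class = cls,
                                     seed = 3))
    orfs <- find_orfs(g)
    terl <- assign_terminase(orfs)
    expect_false(is.null(terl))
    expect_identical(terl$packaging_class, cls)
    expect_lt(terl$evalue, 1e-20)
    expect_equal(terl$orf$start %% nchar(g$sequence),
                 g$sim_truth$terl_start %% nchar(g$sequence))
  }
})

test_that("headful packaging enumerates concatemer cuts exactly", {
  g <- toy_genome(10000, seed = 4)
  g$sim_truth <- list(pac_site = 0L)
  v <- package_virions(g, "headful_pac",
                       packaging_params(headful_f = 1.05, series_k = 4),
                       n = 4, seed = 1)
  starts <- vapply(v, function(x) x$truth_start, integer(1))
  expect_equal(starts, c(0L, 500L, 1000L, 1500L))
  expect_true(all(vapply(v, function(x) nchar(x$sequence), integer(1)) ==
                    10500L))
  # conservation oracle: each virion equals its window of the rolled-out
  # concatemer
  concat <- strrep(g$sequence, 3)
  for (i in seq_along(v)) {
    s <- (0L + (i - 1L) * 10500L) %% 10000L
    expect_identical(v[[i]]$sequence, substr(concat, s + 1, s + 10500))
  }
})

test_that("headful fraction outside (1, 1.1] is a parameter error", {
  g <- toy_genome(10000, seed = 4)
  expect_error(package_virions(g, "headful_pac",
                               packaging_params(headful_f = 1.0), n = 2),
               "headful fraction")
  expect_error(package_virions(g, "headful_pac",
                               packaging_params(headful_f = 1.2), n = 2),
               "headful fraction")
})

test_that("ITR virions carry the planted inverted repeat", {
  g <- make_genome(sim_genome_spec(length = 10000, terminase_class = "itr",
                                   itr_len = 100, seed = 9))
  v <- package_virions(g, "itr", n = 5, seed = 2)
  for (x in v) {
    expect_identical(substr(x$sequence, 1, 100),
                     revcomp(substr(x$sequence, nchar(x$sequence) - 99,
                                    nchar(x$sequence))))
  }
})

test_that("mu_like flanks fall in the configured ranges and vary", {
  g <- toy_genome(10000, seed = 5)
  host <- toy_genome(20000, seed = 6, id = "host")
  v <- package_virions(g, "mu_like", n = 100, seed = 3, host = host)
  lf <- vapply(v, function(x) x$host_flank_left, integer(1))
  rf <- vapply(v, function(x) x$host_flank_right, integer(1))
  expect_true(all(lf >= 50 & lf <= 150))
  expect_true(all(rf >= 500 & rf <= 3000))
  expect_gt(length(unique(paste(lf, rf))), 90)
  expect_error(package_virions(g, "mu_like", n = 2, seed = 1),
               "host genome")
})

test_that("cos end chemistry shortens, duplicates or leaves molecules", {
  g <- toy_genome(10000, seed = 7)
  v <- package_virions(g, "cos_3", n = 20, seed = 4)
  n0 <- nchar(v[[1]]$sequence)
  chewed <- end_chemistry(v, "cos_3", cos_len = 12, p_chem = 1, p_lig = 0,
                          seed = 1)
  expect_true(all(vapply(chewed, function(x) nchar(x$sequence),
                         integer(1)) == n0 - 12L))
  expect_false(any(vapply(chewed, `[[`, logical(1), "circular")))

  same <- end_chemistry(v, "cos_3", p_chem = 0, p_lig = 0, seed = 1)
  expect_identical(vapply(same, `[[`, "", "sequence"),
                   vapply(v, `[[`, "", "sequence"))

  filled <- end_chemistry(v, "cos_5", cos_len = 12, p_chem = 1, p_lig = 1,
                          seed = 1)
  expect_true(all(vapply(filled, function(x) nchar(x$sequence),
                         integer(1)) == n0 + 12L))
  expect_identical(substr(filled[[1]]$sequence, n0 + 1, n0 + 12),
                   substr(v[[1]]$sequence, 1, 12))
  expect_error(end_chemistry(v, "headful_pac"), "cos")
})

test_that("error-free mates are exact substrings of their virions", {
  g <- toy_genome(8000, seed = 8)
  v <- package_virions(g, "cos_5", n = 3, seed = 5)
  reads <- shear_reads(v, 200, seed = 6)
  for (i in seq_len(50)) {
    virion <- v[[reads$virion[i]]]$sequence
    expect_true(grepl(reads$mate1[i], virion, fixed = TRUE))
    expect_true(grepl(revcomp(reads$mate2[i]), virion, fixed = TRUE))
  }
})

test_that("read simulation hits the Lander-Waterman expected depth", {
  g <- toy_genome(40000, seed = 9)
  v <- package_virions(g, "cos_5", n = 10, seed = 1)
  n_pairs <- ceiling(50 * 40000 / (2 * 150))
  reads <- shear_reads(v, n_pairs, seed = 2)
  pl <- map_reads(reads, g, circular = TRUE)
  prof <- per_base_coverage(pl, 40000, circular = TRUE)
  expect_gt(mean(prof$depth), 45)
  expect_lt(mean(prof$depth), 55)
})

test_that("shearing is deterministic and FASTQ output byte-identical", {
  g <- toy_genome(5000, seed = 10)
  v <- package_virions(g, "cos_3", n = 2, seed = 1)
  r1 <- shear_reads(v, 100, seed = 42)
  r2 <- shear_reads(v, 100, seed = 42)
  expect_identical(r1, r2)
  d <- withr::local_tempdir()
  p1 <- write_read_pairs(r1, file.path(d, "a"))
  p2 <- write_read_pairs(r2, file.path(d, "b"))
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_identical(readLines(p1[2]), readLines(p2[2]))

  expect_error(shear_reads(v, 10, error_rate = -0.1), "error_rate")
  expect_equal(nrow(shear_reads(list(), 10)), 0L)
})
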