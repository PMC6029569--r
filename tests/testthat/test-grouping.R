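random_protein <- function(n, seed) {
  phagestd:::with_seed(seed, {
    paste0("M", paste(sample(strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]],
                             n - 1, replace = TRUE), collapse = ""))
  })
}

test_that("identical proteomes cluster pairwise; singletons stay alone", {
  prots <- vapply(1:8, function(i) random_protein(90, 100 + i), "")
  pm <- list(A = prots, B = prots)
  cl <- reciprocal_best_hits(pm)
  expect_length(cl, 8L)
  expect_true(all(vapply(cl, nrow, integer(1)) == 2L))

  pm2 <- list(A = c(prots, random_protein(100, 200)), B = prots)
  cl2 <- reciprocal_best_hits(pm2)
  sizes <- vapply(cl2, nrow, integer(1))
  expect_equal(sum(sizes == 2L), 8L)
  expect_equal(sum(sizes == 1L), 1L)
})

test_that("partition property: every protein lies in exactly one cluster", {
  pm <- list(A = vapply(1:5, function(i) random_protein(80, 300 + i), ""),
             B = vapply(1:4, function(i) random_protein(80, 310 + i), ""),
             C = vapply(1:3, function(i) random_protein(80, 303 + i), ""))
  pm$B[1] <- pm$A[1]          # one shared protein
  cl <- reciprocal_best_hits(pm)
  members <- do.call(rbind, cl)
  keys <- paste(members$genome, members$orf_index)
  expect_false(anyDuplicated(keys) > 0)
  expect_equal(nrow(members), 12L)
})

test_that("coverage-gated chains form one connected component", {
  full <- random_protein(200, 400)
  b <- substr(full, 1, 160)     # 80% of A: passes
  c_ <- substr(full, 1, 120)    # 60% of A: fails; 75% of B: passes
  cl <- reciprocal_best_hits(list(A = full, B = b, C = c_))
  sizes <- sort(vapply(cl, nrow, integer(1)))
  expect_equal(sizes, 3L)       # A-B and B-C edges bridge into one cluster
})

test_that("RBH clusters match a brute-force oracle on toy proteomes", {
  pm <- list(A = vapply(1:4, function(i) random_protein(70, 500 + i), ""),
             B = vapply(1:4, function(i) random_protein(70, 520 + i), ""))
  pm$B[2] <- pm$A[3]
  pm$B[4] <- phagestd:::with_seed(99, phagestd:::mutate_protein(pm$A[1], 0.05))
  cl <- reciprocal_best_hits(pm)

  # oracle: exhaustive all-pairs alignment + manual RBH enumeration
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  score <- matrix(NA_real_, 4, 4)
  cover <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pm$A[i]), Biostrings::AAString(pm$B[j]),
      type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1)
    score[i, j] <- Biostrings::score(aln)
    longer <- max(nchar(pm$A[i]), nchar(pm$B[j]))
    cover[i, j] <- Biostrings::nchar(aln) / longer
  }
  ev <- phagestd:::ka_evalue(score, rep(nchar(pm$A), 4),
                             sum(nchar(pm$B)))$evalue
  ev2 <- phagestd:::ka_evalue(score, rep(nchar(pm$B), each = 4),
                              sum(nchar(pm$A)))$evalue
  pass <- matrix(ev <= 1e-5, 4, 4) & matrix(ev2 <= 1e-5, 4, 4) &
    cover >= 0.75
  edges <- list()
  for (i in 1:4) {
    js <- which(pass[i, ])
    if (!length(js)) next
    j <- js[which.max(score[i, js])]
    is <- which(pass[, j])
    if (is[which.max(score[is, j])] == i) {
      edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  expected_pairs <- length(edges)
  sizes <- vapply(cl, nrow, integer(1))
  expect_equal(sum(sizes == 2L), expected_pairs)
  expect_equal(sum(sizes), 8L)
  expect_equal(expected_pairs, 2L)  # the planted identical + mutated pairs
})

test_that("RBH output is invariant to genome order (symmetry)", {
  pm <- list(A = vapply(1:4, function(i) random_protein(75, 600 + i), ""),
             B = vapply(1:4, function(i) random_protein(75, 602 + i), ""))
  key <- function(cl) {
    sort(vapply(cl, function(x)
      paste(sort(paste(x$genome, x$orf_index)), collapse = "|"), ""))
  }
  expect_identical(key(reciprocal_best_hits(pm)),
                   key(reciprocal_best_hits(rev(pm))))
})

test_that("genome grouping follows Jaccard components", {
  prots <- vapply(1:10, function(i) random_protein(85, 700 + i), "")
  pm <- list(A = prots[1:6], B = prots[1:6], C = prots[7:10])
  cl <- reciprocal_best_hits(pm)
  groups <- group_genomes(cl)
  expect_length(groups, 2L)
  expect_true(any(vapply(groups, function(g)
    setequal(g, c("A", "B")), logical(1))))
  expect_true(any(vapply(groups, identical, logical(1), "C")))
})

test_that("chained Jaccard links form a single group", {
  prots <- vapply(1:12, function(i) random_protein(85, 800 + i), "")
  pm <- list(A = prots[1:6], B = prots[3:8], C = prots[5:10])
  # Jaccard(A,B) = 4/8 = 0.5; (B,C) = 4/8 = 0.5; (A,C) = 2/10 = 0.2
  cl <- reciprocal_best_hits(pm)
  groups <- group_genomes(cl)
  expect_length(groups, 1L)
  expect_setequal(groups[[1]], c("A", "B", "C"))
})

test_that("identical-proteome pairs require full mutual content", {
  prots <- vapply(1:6, function(i) random_protein(90, 900 + i), "")
  mut <- phagestd:::with_seed(91, vapply(prots, function(p)
    phagestd:::mutate_protein(p, 0.05), ""))
  pm <- list(A = prots, B = unname(mut), C = c(prots, random_protein(95, 950)))
  cl <- reciprocal_best_hits(pm)
  pairs <- identical_proteome_pairs(cl)
  expect_equal(nrow(pairs), 1L)
  expect_setequal(c(pairs$genome_a, pairs$genome_b), c("A", "B"))
})
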