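# Group-consensus strategy selection.

fake_terl <- function(cls) {
  structure(list(orf_index = 1L, orf = NULL, reference_name = "x",
                 packaging_class = cls, bit_score = 500, evalue = 1e-50),
            class = "terminase_assignment")
}
fake_pat <- function(label, anchor = 100L) {
  structure(list(label = label, anchor = anchor, features = list()),
            class = "pattern_call")
}

test_that("headful groups re-linearize even with mixed even/shift patterns", {
  out <- select_strategy(
    groups = list(c("g1", "g2", "g3")),
    assignments = list(g1 = fake_terl("headful_pac"),
                       g2 = fake_terl("headful_pac"),
                       g3 = fake_terl("headful_pac")),
    patterns = list(g1 = fake_pat("gradual_shift"),
                    g2 = fake_pat("gradual_shift"),
                    g3 = fake_pat("even")))
  expect_true(all(out$strategy == "relinearize_at_terl_upstream_orf"))
  expect_true(all(out$category == "headful_pac"))
})

test_that("unresolved singletons keep their original assembly", {
  out <- select_strategy(groups = list("solo"),
                         assignments = list(solo = NULL),
                         patterns = list(solo = fake_pat("none", NA)))
  expect_identical(out$strategy, "maintain_original")
})

test_that("a terminase-less member scaffolds to a proteome-identical peer", {
  ids <- c("a", "b", "c", "d")
  assignments <- list(a = fake_terl("headful_pac"),
                      b = fake_terl("headful_pac"),
                      c = fake_terl("headful_pac"), d = NULL)
  patterns <- setNames(rep(list(fake_pat("gradual_shift")), 4), ids)
  pairs <- data.frame(genome_a = "b", genome_b = "d",
                      stringsAsFactors = FALSE)
  out <- select_strategy(list(ids), assignments, patterns,
                         identical_pairs = pairs)
  expect_identical(out$strategy[out$genome == "d"], "scaffold_to_reference")
  expect_identical(out$reference_id[out$genome == "d"], "b")
  expect_true(all(out$strategy[out$genome != "d"] ==
                    "relinearize_at_terl_upstream_orf"))
  # the inferred packaging category is shared by the whole group
  expect_equal(length(unique(out$category)), 1L)
})

test_that("cos/DTR evidence cuts at the coverage feature", {
  out <- select_strategy(
    groups = list(c("x", "y")),
    assignments = list(x = fake_terl("cos_3"), y = fake_terl("cos_3")),
    patterns = list(x = fake_pat("cos_valley"), y = fake_pat("cos_valley")))
  expect_true(all(out$strategy == "cut_at_coverage_feature"))
})

test_that("Mu evidence trims; ITR evidence selects the ITR contig", {
  out <- select_strategy(groups = list("m"),
                         assignments = list(m = fake_terl("mu_like")),
                         patterns = list(m = fake_pat("terminal_drop_mu", NA)))
  expect_identical(out$strategy, "trim_mu_ends")

  out2 <- select_strategy(groups = list("i"),
                          assignments = list(i = NULL),
                          patterns = list(i = fake_pat("even", NA)),
                          itr_lengths = list(i = 100L))
  expect_identical(out2$strategy, "select_itr_contig")
})

test_that("mixed Mu / non-Mu groups are flagged for manual review", {
  expect_error(select_strategy(
    groups = list(c("m", "h")),
    assignments = list(m = fake_terl("mu_like"),
                       h = fake_terl("headful_pac")),
    patterns = list(m = fake_pat("terminal_drop_mu", NA),
                    h = fake_pat("gradual_shift"))),
    "manual review")
})

test_that("missing pattern calls are an input error", {
  expect_error(select_strategy(groups = list("z"),
                               assignments = list(z = NULL),
                               patterns = list()),
               "pattern")
})
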