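# Unit tests on constructed coverage profiles (no read simulation);
# end-to-end signature recovery is exercised in test-acceptance.R.

test_that("constant depth classifies as even and degenerate inputs error", {
  prof <- coverage_profile("c", rep(50, 20000), circular = TRUE)
  expect_identical(classify_pattern(prof)$label, "even")

  expect_error(classify_pattern(coverage_profile("c", rep(0, 2000))),
               "no reads mapped")
  expect_warning(out <- classify_pattern(coverage_profile("c", rep(2, 2000))),
                 "shallow")
  expect_identical(out$label, "none")
  expect_warning(out <- classify_pattern(coverage_profile("c", rep(50, 500))),
                 "short")
  expect_identical(out$label, "none")
})

# helper: profile with a sharp-edged narrow valley plus its clip pileups
valley_profile <- function(L = 20000, at = 8000, width = 12, seed = 1) {
  phagestd:::with_seed(seed, {
    depth <- round(rnorm(L, 50, 3))
    depth[(at + 1):(at + width)] <- round(rnorm(width, 8, 1))
    prof <- coverage_profile("v", pmax(depth, 0), circular = TRUE)
    prof$clip_starts <- integer(L)
    prof$clip_ends <- integer(L)
    prof$clip_ends[at] <- 25L          # reads end just before the gap
    prof$clip_starts[at + width + 1] <- 12L
    prof
  })
}

test_that("a sharp narrow depleted run with clip piles is a cos valley", {
  prof <- valley_profile()
  call <- classify_pattern(prof)
  expect_identical(call$label, "cos_valley")
  expect_lt(circ_dist(call$anchor, 8006, 20000), 15)
})

test_that("classification is invariant under circular rotation", {
  prof <- valley_profile()
  L <- length(prof$depth)
  base <- classify_pattern(prof)
  for (k in c(500L, 7990L, 12345L)) {
    rot <- prof
    idx <- c((k + 1):L, 1:k)
    rot$depth <- prof$depth[idx]
    rot$clip_starts <- prof$clip_starts[idx]
    rot$clip_ends <- prof$clip_ends[idx]
    call <- classify_pattern(rot)
    expect_identical(call$label, base$label, info = k)
    expect_lt(circ_dist(call$anchor, (base$anchor - k) %% L, L), 3)
  }
})

test_that("a broad elevated run is a short internal peak; two are multiple", {
  phagestd:::with_seed(2, {
    L <- 30000
    depth <- round(rnorm(L, 50, 3))
    depth[10001:10600] <- round(rnorm(600, 95, 4))
    one <- coverage_profile("p", depth, circular = TRUE)
    call <- classify_pattern(one)
    expect_identical(call$label, "short_internal_peak")
    expect_lt(circ_dist(call$anchor, 10300, L), 300)

    depth[20001:20600] <- round(rnorm(600, 95, 4))
    two <- coverage_profile("p2", depth, circular = TRUE)
    expect_identical(classify_pattern(two)$label, "multiple_peaks")
  })
})

test_that("linear contigs with long sharp low terminal plateaus are Mu-like", {
  phagestd:::with_seed(3, {
    core <- round(rnorm(40000, 50, 3))
    left <- round(rnorm(100, 1.2, 0.5))
    right <- round(rnorm(2000, 1.2, 0.5))
    prof <- coverage_profile("mu", pmax(c(left, core, right), 0),
                             circular = FALSE)
    expect_identical(classify_pattern(prof)$label, "terminal_drop_mu")

    # plain shear edge ramps (short, gradual) must not qualify
    ramp <- round(seq(2, 50, length.out = 250))
    prof2 <- coverage_profile("lin", c(ramp, core, rev(ramp)),
                              circular = FALSE)
    expect_identical(classify_pattern(prof2)$label, "even")
  })
})

test_that("a sharp-edged elevated plateau on a circular contig is a shift", {
  phagestd:::with_seed(4, {
    L <- 40000
    depth <- round(rnorm(L, 50, 3))
    depth[5001:15000] <- depth[5001:15000] + 10
    prof <- coverage_profile("hf", depth, circular = TRUE)
    call <- classify_pattern(prof)
    expect_identical(call$label, "gradual_shift")
    expect_lt(circ_dist(call$anchor, 5000, L), 500)
  })
})
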