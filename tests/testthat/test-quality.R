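test_that("segmentation covers the recording exactly at each window
           length", {
  rec <- generate_cfae(clean_params(1))
  for (w in c(1, 2, 4)) {
    segs <- segment_signal(rec, w)
    expect_length(segs, 16 / w)
    expect_equal(unique(lengths(segs)), w * 1000)
    expect_identical(unlist(segs), rec$samples)
  }
  expect_error(segment_signal(rec, 3), "1, 2 or 4")
})

test_that("a confined drift discards exactly its second and propagates to
           the covering coarse segments", {
  q1 <- build_q1(fig2a_recording())
  expect_equal(q1$bits, as.integer(c(1, 1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 1,
                                     1, 1, 1, 1)))
  expect_equal(which(propagate_quality(q1, 2)$bits == 0), 3L)
  expect_equal(which(propagate_quality(q1, 4)$bits == 0), 2L)
})

test_that("a three-second signal loss discards its seconds and the covering
           coarse segments", {
  q1 <- build_q1(fig2b_recording())
  expect_equal(which(q1$bits == 0), c(6L, 7L, 8L))
  expect_equal(which(propagate_quality(q1, 2)$bits == 0), c(3L, 4L))
  expect_equal(which(propagate_quality(q1, 4)$bits == 0), 2L)
})

test_that("clean recordings pass the quality screen and re-running is
           idempotent", {
  rec <- generate_cfae(clean_params(8))
  q1 <- build_q1(rec)
  expect_true(all(q1$bits == 1L))
  expect_identical(build_q1(rec)$bits, q1$bits)
})

test_that("drift below the abnormal-amplitude threshold is not discarded", {
  base <- generate_cfae(clean_params(9))
  small <- inject_artifacts(base, artifact_schedule(
    drift = data.frame(start = 5, end = 6, amp = 0.3, freq = 0.5)))
  expect_true(all(build_q1(small)$bits == 1L))
})

test_that("the signal-loss flag uses a strict range inequality", {
  seg <- seq(0, 0.5, length.out = 1000)
  expect_false(signal_loss_flag(seg, threshold_mv = 0.5))   # at threshold
  expect_true(signal_loss_flag(seg, threshold_mv = 0.6))
  expect_false(signal_loss_flag(seg * 2, threshold_mv = 0.5))
})

test_that("manual override replaces the automated bits and is validated", {
  rec <- fig2a_recording()
  ov <- rep(1L, 16); ov[2] <- 0L
  expect_equal(which(build_q1(rec, override = ov)$bits == 0), 2L)
  expect_error(build_q1(rec, override = rep(1L, 8)), "16")
  expect_error(quality_vector(rep(2L, 16), 1), "0 or 1")
  expect_error(quality_vector(rep(1L, 16), 3), "1, 2 or 4")
})

test_that("product propagation is monotone: coarse vectors never recover a
           discarded second", {
  q_all <- quality_vector(rep(1L, 16), 1)
  expect_true(all(propagate_quality(q_all, 2)$bits == 1L))
  expect_true(all(propagate_quality(q_all, 4)$bits == 1L))
  set.seed(42)
  for (k in 1:50) {
    bits <- rbinom(16, 1, 0.8)
    q1 <- quality_vector(bits, 1)
    frac <- vapply(c(1, 2, 4), function(w) {
      qw <- if (w == 1) q1 else propagate_quality(q1, w)
      mean(qw$bits == 0)
    }, numeric(1))
    expect_true(all(diff(frac) >= 0))
    # zero-coverage containment: every discarded second stays inside a
    # discarded coarse segment
    for (w in c(2, 4)) {
      qw <- propagate_quality(q1, w)
      covered <- rep(qw$bits, each = w)
      expect_true(all(covered[bits == 0] == 0))
    }
  }
})

test_that("discard percentages and embedded information loss follow the
           worked single-artifact example", {
  bits <- rep(1L, 16); bits[6] <- 0L
  q1 <- quality_vector(bits, 1)
  ds <- discard_summary(list(q1))
  expect_equal(ds$discard_pct, c(1 / 16, 1 / 8, 1 / 4) * 100)
  expect_equal(ds$info_loss_pct[ds$w == 2], 100 * 1 / 16)
  expect_equal(ds$info_loss_pct[ds$w == 4], 100 * 3 / 16)
  expect_error(discard_summary(list()), "empty")
})

test_that("discard summaries break down by site and AF type", {
  q_bad <- quality_vector(c(0L, rep(1L, 15)), 1)
  q_good <- quality_vector(rep(1L, 16), 1)
  meta <- data.frame(site = c("ANT", "POS"),
                     af_type = c("ParAF", "PerAF"))
  ds <- discard_summary(list(q_bad, q_good), meta)
  ant <- ds[ds$group_type == "site" & ds$group == "ANT" & ds$w == 1, ]
  pos <- ds[ds$group_type == "site" & ds$group == "POS" & ds$w == 1, ]
  expect_equal(ant$discard_pct, 100 / 16)
  expect_equal(pos$discard_pct, 0)
})

test_that("quality vectors round-trip through their delimited-text form", {
  qs <- list(quality_vector(replace(rep(1L, 16), 6, 0L), 1, "r1"),
             quality_vector(c(1L, 0L, 1L, 1L), 4, "r2"))
  path <- tempfile(fileext = ".csv")
  write_quality_vectors(qs, path)
  back <- read_quality_vectors(path)
  expect_equal(back[[1]]$bits, qs[[1]]$bits)
  expect_equal(back[[2]]$w, 4)
  expect_equal(back[[2]]$recording_id, "r2")
})
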