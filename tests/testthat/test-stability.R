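test_that("the coefficient of variation matches the direct formula and is
           scale-invariant", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  z <- coefficient_of_variation(c(-1, 1))
  expect_true(is.na(z))
  expect_equal(attr(z, "flag"), "zero_mean")
  expect_error(coefficient_of_variation(1), "at least 2")
  set.seed(1)
  v <- rlnorm(20)
  expect_equal(coefficient_of_variation(3 * v), coefficient_of_variation(v))
})

test_that("intra-recording CV averages per-recording dispersion and honours
           the discard flags", {
  tab <- rbind(toy_seg_tab(c(5, 5, 5, 5), "P1", "ANT", "ParAF"),
               toy_seg_tab(c(1, 2, 3, 1e6), "P2", "ANT", "PerAF",
                           quality = c(1L, 1L, 1L, 0L)))
  with_d <- intra_recording_cv(tab, "SE", 1, use_discards = TRUE)
  no_d <- intra_recording_cv(tab, "SE", 1, use_discards = FALSE)
  # P1 is constant (CV 0); P2 with discards is CV of 1,2,3 = 50%
  expect_equal(with_d$cv[with_d$scope == "all"], mean(c(0, 50)))
  expect_gt(no_d$cv[no_d$scope == "all"], with_d$cv[with_d$scope == "all"])
  # poisoned discarded segment never contributes
  tab2 <- tab
  tab2$SE[tab2$quality == 0L] <- -9e9
  expect_equal(intra_recording_cv(tab2, "SE", 1, TRUE)$cv,
               with_d$cv)
  # per-class weighted combination reproduces the overall mean
  by_cls <- with_d[with_d$scope != "all", ]
  expect_equal(sum(by_cls$cv * by_cls$n_recordings) /
                 sum(by_cls$n_recordings),
               with_d$cv[with_d$scope == "all"])
})

test_that("intra-patient CV works patient-by-patient over site means and
           skips single-site patients", {
  tab <- rbind(toy_seg_tab(c(2, 4), "P1", "ANT", "ParAF"),
               toy_seg_tab(c(4, 8), "P1", "POS", "ParAF"),
               toy_seg_tab(c(10, 10), "P2", "ANT", "PerAF"),
               toy_seg_tab(c(10, 10), "P2", "POS", "PerAF"),
               toy_seg_tab(c(7, 9), "P3", "ANT", "ParAF"))
  got <- intra_patient_cv(tab, "SE", 1, TRUE)
  # brute force: P1 site means (3, 6) -> CV 47.14%; P2 (10, 10) -> 0
  cv_p1 <- 100 * sd(c(3, 6)) / mean(c(3, 6))
  expect_equal(got$cv[got$scope == "all"], mean(c(cv_p1, 0)))
  expect_equal(attr(got, "skipped"), "P3")
})

test_that("discarding artifact-bearing segments lowers the intra-recording
           CV on a cohort with injected drifts", {
  set.seed(10)
  tabs <- lapply(1:6, function(i) {
    rec <- generate_cfae(clean_params(100 + i,
                                      af_type = if (i %% 2) "ParAF"
                                      else "PerAF"))
    rec <- inject_artifacts(rec, artifact_schedule(
      drift = data.frame(start = 2 * i - 1, end = 2 * i, amp = 5,
                         freq = 0.5)))
    q1 <- build_q1(rec)
    se <- vapply(segment_signal(rec, 1),
                 function(s) as.numeric(sample_entropy(s)), numeric(1))
    toy_seg_tab(se, paste0("P", i), "ANT", rec$af_type,
                quality = q1$bits)
  })
  tab <- do.call(rbind, tabs)
  cv_disc <- intra_recording_cv(tab, "SE", 1, TRUE)$cv[1]
  cv_full <- intra_recording_cv(tab, "SE", 1, FALSE)$cv[1]
  expect_lt(cv_disc, cv_full)
})

test_that("the Kruskal-Wallis site test matches a hand computation and
           flags small groups", {
  tab <- rbind(toy_seg_tab(c(1, 2, 3), "P1", "ANT", "ParAF"),
               toy_seg_tab(c(10, 11, 12), "P1", "POS", "ParAF"),
               toy_seg_tab(c(20, 21, 22), "P1", "LSPV", "ParAF"))
  got <- kruskal_wallis_sites(tab, "SE", 1, TRUE)
  expect_lt(got$p, 0.05)
  expect_true(got$unreliable)   # groups of 3 < 5
  ref <- kruskal.test(tab$SE, factor(tab$site))
  expect_equal(got$p, ref$p.value)

  # identical groups: H = 0 up to ties, p = 1 without ties
  tab2 <- rbind(toy_seg_tab(c(1, 5, 9, 13), "P1", "ANT", "ParAF"),
                toy_seg_tab(c(2, 6, 10, 14), "P1", "POS", "ParAF"))
  expect_gt(kruskal_wallis_sites(tab2, "SE", 1, TRUE)$p, 0.5)

  # hand-computed H with ties on a tiny fixture
  v <- c(1, 2, 2, 3, 5, 5)
  g <- c("a", "a", "b", "b", "c", "c")
  r <- rank(v)
  n <- length(v)
  h <- (12 / (n * (n + 1))) * sum(tapply(r, g, sum)^2 / 2) - 3 * (n + 1)
  tie_tab <- table(v)
  h <- h / (1 - sum(tie_tab^3 - tie_tab) / (n^3 - n))
  tab3 <- rbind(toy_seg_tab(c(1, 2), "P1", "ANT", "ParAF"),
                toy_seg_tab(c(2, 3), "P1", "POS", "ParAF"),
                toy_seg_tab(c(5, 5), "P1", "LSPV", "ParAF"))
  got3 <- kruskal_wallis_sites(tab3, "SE", 1, TRUE)
  expect_equal(unname(kruskal.test(tab3$SE, factor(tab3$site))$statistic),
               h)
  expect_error(kruskal_wallis_sites(toy_seg_tab(1:4, "P1", "ANT",
                                                "ParAF"), "SE", 1, TRUE),
               ">= 2 sites")
})

test_that("the Breusch-Pagan auxiliary regression is calibrated, detects
           heteroscedasticity, and matches the studentized reference", {
  rej_null <- 0; rej_alt <- 0
  for (k in 1:100) {
    set.seed(k)
    g <- rep(c("a", "b", "c"), each = 15)
    y0 <- rnorm(45)
    if (breusch_pagan(y0, g)$p < 0.05) rej_null <- rej_null + 1
    y1 <- rnorm(45, sd = rep(c(1, 1, 10), each = 15))
    if (breusch_pagan(y1, g)$p < 0.05) rej_alt <- rej_alt + 1
  }
  expect_lte(rej_null, 10)    # size approximately correct
  expect_gte(rej_alt, 90)     # power against a 10x variance group

  z <- breusch_pagan(rep(c(1, 2), each = 5), rep(c("a", "b"), each = 5))
  expect_true(is.na(z$p))
  expect_error(breusch_pagan(1:10, rep("a", 10)), "2 groups")

  skip_if_not_installed("lmtest")
  set.seed(7)
  g <- factor(rep(c("a", "b", "c"), each = 20))
  y <- rnorm(60, sd = as.numeric(g))
  ours <- breusch_pagan(y, g)
  ref <- lmtest::bptest(lm(y ~ g), varformula = ~g, studentize = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(as.numeric(ours$p), unname(ref$p.value), tolerance = 1e-8)
})

test_that("the Mann-Whitney site comparison averages the per-window
           p-values and flags missing classes", {
  mk <- function(pid, af, vals, w) {
    do.call(rbind, lapply(w, function(wi)
      toy_seg_tab(vals, pid, "ANT", af, w = wi)))
  }
  seg <- rbind(mk("P1", "ParAF", c(1, 1), c(1, 2, 4)),
               mk("P2", "ParAF", c(2, 2), c(1, 2, 4)),
               mk("P3", "PerAF", c(3, 3), c(1, 2, 4)),
               mk("P4", "PerAF", c(4, 4), c(1, 2, 4)))
  rec <- data.frame(patient_id = c("P1", "P2", "P3", "P4"),
                    site = "ANT",
                    af_type = c("ParAF", "ParAF", "PerAF", "PerAF"),
                    AFCL = c(180, 190, 140, 150), DF = c(5, 5.5, 7, 7.5))
  got <- mann_whitney_sites(seg, rec)
  se_row <- got[got$site == "ANT" & got$index == "SE", ]
  # per-recording means are {1,2} vs {3,4}: exact two-sided p = 1/3 at
  # every window length, so the average is 1/3 as well
  expect_equal(se_row$p_avg, 1 / 3, tolerance = 1e-12)
  expect_equal(se_row$p_w1, se_row$p_w2)
  afcl_row <- got[got$site == "ANT" & got$index == "AFCL", ]
  expect_equal(afcl_row$p_avg, 1 / 3, tolerance = 1e-12)

  rec_missing <- rec[rec$af_type == "ParAF", ]
  seg_missing <- seg[seg$af_type == "ParAF", ]
  got2 <- mann_whitney_sites(seg_missing, rec_missing)
  expect_true(all(is.na(got2$p_avg)))
})

test_that("segment pooling and Holm adjustment are available as reporting
           alternatives", {
  mk <- function(pid, af, vals, w) {
    do.call(rbind, lapply(w, function(wi)
      toy_seg_tab(vals, pid, "ANT", af, w = wi)))
  }
  seg <- rbind(mk("P1", "ParAF", c(1, 2), c(1, 2, 4)),
               mk("P2", "ParAF", c(2, 3), c(1, 2, 4)),
               mk("P3", "PerAF", c(8, 9), c(1, 2, 4)),
               mk("P4", "PerAF", c(9, 10), c(1, 2, 4)))
  rec <- data.frame(patient_id = paste0("P", 1:4), site = "ANT",
                    af_type = rep(c("ParAF", "PerAF"), each = 2),
                    AFCL = c(180, 190, 140, 150), DF = c(5, 5.5, 7, 7.5))
  pooled <- mann_whitney_sites(seg, rec, pool_segments = TRUE)
  se_pooled <- pooled$p_avg[pooled$index == "SE"]
  # pooled test uses 4 vs 4 segment values instead of 2 vs 2 means
  expect_equal(se_pooled,
               suppressWarnings(wilcox.test(c(1, 2, 2, 3),
                                            c(8, 9, 9, 10))$p.value))
  adj <- mann_whitney_sites(seg, rec, p_adjust = "holm")
  expect_true("p_adj" %in% names(adj))
  expect_true(all(adj$p_adj >= adj$p_avg, na.rm = TRUE))
})
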