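make_planted_fm <- function(n = 24, n_noise = 9, sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- as.data.frame(matrix(rnorm(n * n_noise), n, n_noise))
  names(X) <- paste0("noise", seq_len(n_noise))
  X$signal <- y * sep + rnorm(n, 0, 0.5)
  list(X = X, y = y, ids = sprintf("P%02d", seq_len(n)))
}

test_that("the feature matrix has one row per patient, 24 labelled columns,
           and ignores discarded segments", {
  seg <- do.call(rbind, lapply(c("P1", "P2", "P3", "P4"), function(pid) {
    af <- if (pid %in% c("P1", "P2")) "ParAF" else "PerAF"
    do.call(rbind, lapply(c("LSPV", "LIPV", "RSPV", "RIPV", "ANT", "POS"),
                          function(s) toy_seg_tab(c(1, 2, 3, 1000), pid,
                                                  s, af,
                                                  quality = c(1, 1, 1, 0))))
  }))
  rec <- unique(seg[, c("patient_id", "site", "af_type")])
  rec$AFCL <- 160; rec$DF <- 6
  fm <- build_feature_matrix(seg, rec, w = 1)
  expect_equal(nrow(fm), 4L)
  expect_length(feature_columns(fm), 24L)
  expect_equal(fm$TYPE, c(0L, 0L, 1L, 1L))
  # the poisoned discarded segment (value 1000) never reaches a cell
  expect_true(all(fm$SE_ANT == 2))
  fm_all <- build_feature_matrix(seg, rec, w = 1, use_discards = FALSE)
  expect_true(all(fm_all$SE_ANT > 2))
})

test_that("averaged correlation matrices are idempotent, flag duplicates,
           and match the pairwise formula", {
  set.seed(2)
  fm <- data.frame(patient_id = sprintf("P%d", 1:5),
                   a = rnorm(5), b = rnorm(5), c = rnorm(5), d = rnorm(5),
                   TYPE = c(0, 0, 1, 1, 1))
  single <- averaged_correlation_matrix(list(fm))
  avg <- averaged_correlation_matrix(list(fm, fm, fm))
  expect_equal(avg, single)
  expect_equal(diag(avg), rep(1, 4), ignore_attr = TRUE)
  for (i in 1:3) for (j in (i + 1):4) {
    xi <- fm[[i + 1L]]; xj <- fm[[j + 1L]]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(avg[i, j], r, tolerance = 1e-12)
  }
  fm2 <- fm; fm2$b <- fm2$a
  expect_equal(averaged_correlation_matrix(list(fm2))["a", "b"], 1)
})

test_that("the correlation filter drops the more redundant member of each
           offending pair and nothing else", {
  set.seed(3)
  n <- 40
  x1 <- rnorm(n)
  fm <- data.frame(X1 = x1, X2 = x1 + rnorm(n, 0, 0.2), X3 = rnorm(n))
  cm <- cor(fm)
  kept <- correlation_filter(cm, selection_config(corr_cutoff = 0.6))
  expect_true("X3" %in% kept)
  expect_length(kept, 2L)
  drop <- setdiff(c("X1", "X2"), kept)
  m <- abs(cm); diag(m) <- 0
  expect_equal(unname(which.max(rowMeans(m)[c("X1", "X2")])),
               match(drop, c("X1", "X2")))

  low <- diag(3)                          # identity: no correlation
  dimnames(low) <- list(letters[1:3], letters[1:3])
  expect_equal(correlation_filter(low, selection_config()), letters[1:3])

  # invariant to positive rescaling of a column
  fm_scaled <- fm; fm_scaled$X1 <- 100 * fm_scaled$X1
  expect_identical(correlation_filter(cor(fm_scaled),
                                      selection_config(corr_cutoff = 0.6)),
                   kept)
})

test_that("Random-Forest ranking scores the planted feature at 100 and
           collapses under label permutation", {
  pl <- make_planted_fm(n = 60, seed = 4)
  sc <- rf_rank(pl$X, pl$y, selection_config(seed = 4))
  expect_equal(max(sc), 100)
  expect_equal(names(which.max(sc)), "signal")
  expect_true(all(sc[names(sc) != "signal"] < 40))
  expect_identical(attr(sc, "selected"), "signal")

  set.seed(5)
  sc_perm <- rf_rank(pl$X, sample(pl$y), selection_config(seed = 5))
  expect_lt(sc_perm["signal"] - max(sc_perm[names(sc_perm) != "signal"]),
            50)
  expect_error(rf_rank(pl$X, rep(0, 60), selection_config()), "two classes")
})

test_that("coarse trees are capped at four splits and degrade to majority
           stumps", {
  sep <- data.frame(x = c(1:10, 101:110))
  y <- rep(c("a", "b"), each = 10)
  fit <- coarse_tree_fit(sep, y)
  expect_equal(cfae:::n_splits(fit), 1L)
  expect_equal(as.character(predict(fit, sep, type = "class")), y)

  const <- data.frame(x = rep(1, 20))
  expect_equal(cfae:::n_splits(coarse_tree_fit(const, y)), 0L)

  set.seed(6)
  noisy <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  fit2 <- coarse_tree_fit(noisy, rbinom(40, 1, 0.5))
  expect_lte(cfae:::n_splits(fit2), 4L)
  expect_error(coarse_tree_fit(data.frame()[1:5, , drop = FALSE], y[1:5]),
               "empty")
})

test_that("leave-one-patient-out folds never leak the test patient and the
           accuracy matches a brute-force fold loop", {
  pl <- make_planted_fm(n = 6, n_noise = 1, sep = 10, seed = 7)
  acc <- lopo_accuracy(pl$X["signal"], pl$y, pl$ids)
  expect_equal(as.numeric(acc), 100)
  folds <- attr(acc, "folds")
  for (f in folds) expect_false(f$test_id %in% f$train_ids)

  # brute-force oracle on the same fixture
  brute <- mean(vapply(seq_along(pl$ids), function(k) {
    train <- -k
    fit <- coarse_tree_fit(pl$X[train, "signal", drop = FALSE],
                           pl$y[train])
    pred <- predict(fit, pl$X[k, "signal", drop = FALSE], type = "class")
    as.character(pred) == as.character(pl$y[k])
  }, logical(1))) * 100
  expect_equal(as.numeric(acc), brute)
  expect_error(lopo_accuracy(pl$X, pl$y, rep("P1", 6)), "3 patients")
})

test_that("label-independent features score near the majority rate under
           LOPO", {
  set.seed(8)
  n <- 30
  X <- data.frame(a = rnorm(n))
  y <- rep(c(0, 1), each = n / 2)
  acc <- as.numeric(lopo_accuracy(X, y, sprintf("P%02d", 1:n)))
  expect_lt(abs(acc - 50), 25)
})

test_that("the subset search enumerates all subsets and prefers minimal
           winning sets", {
  pl <- make_planted_fm(n = 24, n_noise = 4, sep = 8, seed = 9)
  res <- subset_search(pl$X, pl$y, pl$ids)
  expect_equal(nrow(res$table), 2^5 - 1)
  expect_true("signal" %in% res$best$features)
  best_rows <- res$table[res$table$accuracy == res$best$accuracy, ]
  expect_equal(length(res$best$features), min(best_rows$size))
  expect_true(res$mean_acc <= 100 && res$sd_acc >= 0)
  too_many <- as.data.frame(matrix(rnorm(24 * 13), 24))
  expect_error(subset_search(too_many, pl$y, pl$ids), "12")
})

test_that("single-feature accuracies rank the planted feature first with
           one row per feature", {
  pl <- make_planted_fm(n = 24, n_noise = 5, sep = 8, seed = 10)
  tab <- single_feature_accuracies(pl$X, pl$y, pl$ids)
  expect_equal(nrow(tab), ncol(pl$X))
  expect_equal(tab$feature[1], "signal")
  expect_setequal(tab$feature, names(pl$X))
})
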