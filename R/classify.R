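#' Feature-selection configuration
#'
#' @param corr_cutoff absolute-correlation threshold of the redundancy
#'   filter (default 0.60).
#' @param importance_cutoff Random-Forest score threshold on the 0-100
#'   scale (default 40).
#' @param n_trees forest size (default 500).
#' @param seed RNG seed for the forest.
#' @return object of class `cfae_selection_config`.
#' @export
selection_config <- function(corr_cutoff = 0.60, importance_cutoff = 40,
                             n_trees = 500L, seed = 1L) {
  if (corr_cutoff <= 0 || corr_cutoff >= 1)
    stop("corr_cutoff must be in (0, 1)")
  if (importance_cutoff < 0 || importance_cutoff > 100)
    stop("importance_cutoff must be in [0, 100]")
  structure(list(corr_cutoff = corr_cutoff,
                 importance_cutoff = importance_cutoff,
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "cfae_selection_config")
}

#' Build the patients x (index, site) feature matrix
#'
#' One row per patient; 24 feature columns (`SE`, `DET`, `AFCL`, `DF` at
#' each of the six sites, named `<index>_<site>`) plus the class label
#' `TYPE` (0 = ParAF, 1 = PerAF). SE and DET are summarized per recording
#' as the mean over usable segments of length `w`; AFCL and DF come from
#' the 16 s computation. Missing cells (e.g. a site with all segments
#' discarded) are `NA`, never imputed; a patient missing every site is
#' excluded (listed in the `excluded` attribute).
#'
#' @param seg_tab segment index table (see [intra_recording_cv()]).
#' @param rec_tab per-recording table with `patient_id`, `site`, `af_type`,
#'   `AFCL`, `DF`.
#' @param w window length used for the SE/DET summaries.
#' @param sites site order of the columns.
#' @param use_discards exclude zero-quality segments from the summaries.
#' @return data.frame with `patient_id`, 24 feature columns and `TYPE`.
#' @export
build_feature_matrix <- function(seg_tab, rec_tab, w,
                                 sites = c("LSPV", "LIPV", "RSPV", "RIPV",
                                           "ANT", "POS"),
                                 use_discards = TRUE) {
  pats <- unique(rec_tab[, c("patient_id", "af_type")])
  fm <- data.frame(patient_id = pats$patient_id, stringsAsFactors = FALSE)
  seg_w <- usable_rows(seg_tab, "SE", w, use_discards)
  seg_w_det <- usable_rows(seg_tab, "DET", w, use_discards)
  for (index in c("SE", "DET", "AFCL", "DF")) {
    for (site in sites) {
      col <- paste0(index, "_", site)
      fm[[col]] <- vapply(pats$patient_id, function(pid) {
        if (index %in% c("SE", "DET")) {
          tab <- if (index == "SE") seg_w else seg_w_det
          v <- tab[[index]][tab$patient_id == pid & tab$site == site]
          if (length(v) == 0L) NA_real_ else mean(v)
        } else {
          v <- rec_tab[[index]][rec_tab$patient_id == pid &
                                  rec_tab$site == site]
          if (length(v) == 0L) NA_real_ else v[1L]
        }
      }, numeric(1))
    }
  }
  fm$TYPE <- ifelse(pats$af_type == "PerAF", 1L, 0L)
  feat <- fm[, setdiff(names(fm), c("patient_id", "TYPE")), drop = FALSE]
  all_missing <- apply(feat, 1L, function(r) all(is.na(r)))
  attr(fm, "excluded") <- fm$patient_id[all_missing]
  fm[!all_missing, , drop = FALSE]
}

feature_columns <- function(fm)
  setdiff(names(fm), c("patient_id", "TYPE"))

#' Average the feature correlation matrices of several window lengths
#'
#' Element-wise mean of the Pearson correlation matrices of the supplied
#' feature matrices (label and id columns excluded); symmetric with unit
#' diagonal. Constant columns have undefined correlations and produce `NA`
#' entries with a warning.
#'
#' @param fm_list list of feature matrices sharing columns (one per window
#'   length).
#' @param include_label include the `TYPE` column in the matrix.
#' @return averaged correlation matrix.
#' @export
averaged_correlation_matrix <- function(fm_list, include_label = FALSE) {
  mats <- lapply(fm_list, function(fm) {
    cols <- feature_columns(fm)
    if (include_label) cols <- c(cols, "TYPE")
    X <- as.matrix(fm[, cols, drop = FALSE])
    suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  })
  ref <- colnames(mats[[1L]])
  for (m in mats) stopifnot(identical(colnames(m), ref))
  avg <- Reduce(`+`, mats) / length(mats)
  if (anyNA(avg)) warning("constant column: correlation undefined (NA)")
  avg
}

#' Greedy correlation redundancy filter
#'
#' While any feature pair exceeds `|r| > corr_cutoff`, the member of the
#' worst (largest `|r|`) pair with the larger mean absolute correlation to
#' all remaining features is dropped; ties are broken by column order. The
#' result is deterministic and invariant to row order and positive
#' rescaling of columns.
#'
#' @param corr_mat symmetric correlation matrix.
#' @param cfg a [selection_config()] (only `corr_cutoff` is used).
#' @return character vector of retained column names.
#' @export
correlation_filter <- function(corr_mat, cfg = selection_config()) {
  stopifnot(isTRUE(all.equal(corr_mat, t(corr_mat), tolerance = 1e-8)))
  keep <- colnames(corr_mat)
  m <- abs(corr_mat)
  diag(m) <- 0
  m[is.na(m)] <- 0
  repeat {
    if (length(keep) < 2L) break
    sub <- m[keep, keep, drop = FALSE]
    worst <- max(sub)
    if (worst <= cfg$corr_cutoff) break
    idx <- which(sub == worst, arr.ind = TRUE)[1L, ]
    pair <- keep[sort(unname(idx))]
    mean_abs <- rowMeans(sub[pair, , drop = FALSE])
    drop <- pair[which.max(mean_abs)]   # ties: which.max takes the first
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Random-Forest Gini relevance ranking
#'
#' Seeded Random Forest (stratified bootstrap) on the labelled features;
#' mean-decrease-Gini importances are rescaled linearly so the maximum is
#' 100. The selected set is `{score > importance_cutoff}`. Rows with
#' missing feature values are dropped with a warning (never imputed).
#'
#' @param features data.frame or matrix of feature columns.
#' @param labels class labels (two classes required).
#' @param cfg a [selection_config()].
#' @return named numeric scores on a 0-100 scale, with attribute
#'   `selected`.
#' @export
rf_rank <- function(features, labels, cfg = selection_config()) {
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("labels must contain two classes")
  X <- as.data.frame(features)
  ok <- stats::complete.cases(X)
  if (!all(ok)) {
    warning(sum(!ok), " rows with missing features dropped from the ranking")
    X <- X[ok, , drop = FALSE]
    y <- y[ok]
  }
  if (min(table(y)) < 2L) stop("need >= 2 patients per class")
  set.seed(cfg$seed)
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = cfg$n_trees,
    strata = y, sampsize = as.vector(table(y)))
  imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
  if (max(imp) <= 0) {
    scores <- imp * 0
  } else {
    scores <- 100 * imp / max(imp)
  }
  structure(scores,
            selected = names(scores)[scores > cfg$importance_cutoff])
}

#' Fit a coarse classification tree
#'
#' Binary Gini decision tree with at most 4 splits (the established meaning
#' of a "coarse" tree): an unconstrained tree is grown and then pruned back
#' to the largest complexity-parameter table entry with at most 4 splits.
#' A constant feature (or unsplittable data) yields a majority-class stump.
#'
#' @param features data.frame of feature columns.
#' @param labels class labels.
#' @param max_splits split cap (default 4).
#' @return an `rpart` tree.
#' @export
coarse_tree_fit <- function(features, labels, max_splits = 4L) {
  X <- as.data.frame(features)
  if (ncol(X) == 0L) stop("empty feature subset")
  dat <- cbind(.y = factor(labels), X)
  fit <- rpart::rpart(.y ~ ., data = dat, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        cp = 0, minsplit = 2L, minbucket = 1L,
                        maxdepth = max_splits, xval = 0L,
                        maxcompete = 0L, maxsurrogate = 0L))
  cpt <- fit$cptable
  ok <- cpt[, "nsplit"] <= max_splits
  row <- max(which(ok))
  if (cpt[row, "nsplit"] < max(cpt[, "nsplit"]))
    fit <- rpart::prune(fit, cp = cpt[row, "CP"] + 1e-12)
  fit
}

n_splits <- function(tree) sum(tree$frame$var != "<leaf>")

#' Leave-one-patient-out cross-validated accuracy
#'
#' One fold per patient: the tree is refit with every row of the held-out
#' patient removed from the training partition and its rows are then
#' predicted. Folds whose training partition lacks a class are flagged and
#' their rows counted as errors. Fold bookkeeping (train/test ids) is
#' attached for leakage auditing.
#'
#' @param features data.frame of feature columns.
#' @param labels class labels.
#' @param patient_ids fold grouping (one fold per unique id).
#' @param max_splits tree split cap.
#' @return accuracy in percent, with attributes `folds` (per-fold detail)
#'   and `flagged_folds`.
#' @export
lopo_accuracy <- function(features, labels, patient_ids, max_splits = 4L) {
  X <- as.data.frame(features)
  y <- factor(labels)
  ids <- as.character(patient_ids)
  u <- unique(ids)
  if (length(u) < 3L) stop("need at least 3 patients for LOPO-CV")
  correct <- 0L
  total <- 0L
  folds <- vector("list", length(u))
  flagged <- character(0)
  for (k in seq_along(u)) {
    test <- ids == u[k]
    if (nlevels(droplevels(y[!test])) < 2L) {
      flagged <- c(flagged, u[k])
      total <- total + sum(test)
      folds[[k]] <- list(test_id = u[k], train_ids = unique(ids[!test]),
                         pred = rep(NA_character_, sum(test)))
      next
    }
    fit <- coarse_tree_fit(X[!test, , drop = FALSE], y[!test], max_splits)
    pred <- predict(fit, newdata = X[test, , drop = FALSE], type = "class")
    correct <- correct + sum(as.character(pred) == as.character(y[test]))
    total <- total + sum(test)
    folds[[k]] <- list(test_id = u[k], train_ids = unique(ids[!test]),
                       pred = as.character(pred))
  }
  structure(100 * correct / total, folds = folds, flagged_folds = flagged)
}

#' Exhaustive coarse-tree subset search
#'
#' Evaluates the LOPO-CV accuracy of every non-empty subset of the selected
#' features (at most 12, guarding the 2^k enumeration) and returns the best
#' model; ties are broken toward the smaller subset and then by column
#' order, so the minimal feature set is preferred. The mean and SD accuracy
#' over all evaluated subsets are also reported.
#'
#' @param features data.frame restricted to the selected feature columns.
#' @param labels class labels.
#' @param patient_ids fold grouping.
#' @param max_splits tree split cap.
#' @return list with `best` (features, accuracy, tree), `table`
#'   (per-subset accuracies), `mean_acc`, `sd_acc`.
#' @export
subset_search <- function(features, labels, patient_ids, max_splits = 4L) {
  X <- as.data.frame(features)
  k <- ncol(X)
  if (k < 1L) stop("no selected features")
  if (k > 12L)
    stop("refusing to enumerate 2^", k, " subsets; reduce the selected ",
         "set (tighten the importance cutoff) to at most 12 features")
  subsets <- unlist(lapply(seq_len(k), function(s)
    utils::combn(k, s, simplify = FALSE)), recursive = FALSE)
  acc <- vapply(subsets, function(cols)
    as.numeric(lopo_accuracy(X[, cols, drop = FALSE], labels, patient_ids,
                             max_splits)), numeric(1))
  size <- lengths(subsets)
  ord <- order(-acc, size, vapply(subsets, function(s)
    paste(sprintf("%03d", s), collapse = ""), character(1)))
  best_idx <- ord[1L]
  best_cols <- names(X)[subsets[[best_idx]]]
  best_tree <- coarse_tree_fit(X[, subsets[[best_idx]], drop = FALSE],
                               labels, max_splits)
  tab <- data.frame(
    subset = vapply(subsets, function(s) paste(names(X)[s], collapse = "+"),
                    character(1)),
    size = size, accuracy = acc)
  list(best = list(features = best_cols, accuracy = acc[best_idx],
                   tree = best_tree),
       table = tab, mean_acc = mean(acc), sd_acc = sd(acc))
}

#' Single-feature coarse-tree accuracies
#'
#' LOPO-CV accuracy of a one-input coarse tree for every feature column,
#' sorted descending; the mean and SD over features are attached.
#'
#' @param features data.frame of all feature columns.
#' @param labels class labels.
#' @param patient_ids fold grouping.
#' @param max_splits tree split cap.
#' @return data.frame `feature`, `accuracy`, with attributes `mean_acc`,
#'   `sd_acc`.
#' @export
single_feature_accuracies <- function(features, labels, patient_ids,
                                      max_splits = 4L) {
  X <- as.data.frame(features)
  acc <- vapply(names(X), function(col)
    as.numeric(lopo_accuracy(X[, col, drop = FALSE], labels, patient_ids,
                             max_splits)), numeric(1))
  out <- data.frame(feature = names(X), accuracy = unname(acc))
  out <- out[order(-out$accuracy, out$feature), ]
  rownames(out) <- NULL
  structure(out, mean_acc = mean(acc), sd_acc = sd(acc))
}
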