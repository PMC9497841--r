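#' Coefficient of variation
#'
#' `100 * sd(x) / |mean(x)|`, with the sample (n-1) standard deviation.
#' A zero mean gives a flagged `NA` rather than an error, mirroring the
#' discard philosophy used for undefined index values.
#'
#' @param x numeric vector with at least two values.
#' @return CV in percent (>= 0), or flagged `NA`.
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values for a CV")
  m <- mean(x)
  if (m == 0) return(structure(NA_real_, flag = "zero_mean"))
  100 * sd(x) / abs(m)
}

## Filter a segment index table down to usable rows for one index/w.
usable_rows <- function(seg_tab, index, w, use_discards) {
  tab <- seg_tab[seg_tab$w == w & !is.na(seg_tab[[index]]), , drop = FALSE]
  if (use_discards) tab <- tab[tab$quality == 1L, , drop = FALSE]
  tab
}

cv_by_group <- function(values, groups) {
  cvs <- tapply(values, groups, function(v) {
    if (length(v) < 2L) return(NA_real_)
    as.numeric(coefficient_of_variation(v))
  })
  cvs[!is.na(cvs)]
}

#' Intra-recording coefficient of variation
#'
#' CV of an index across the segments of each recording (optionally
#' excluding discarded segments), averaged over recordings with equal
#' weight; recordings with fewer than two usable segments are skipped.
#' Reported overall and per AF class.
#'
#' @param seg_tab segment index table: data.frame with columns
#'   `patient_id`, `site`, `af_type`, `w`, `segment`, `quality`, `SE`,
#'   `DET`.
#' @param index `"SE"` or `"DET"`.
#' @param w window length, s.
#' @param use_discards if TRUE, zero-quality segments are excluded.
#' @return data.frame with columns `scope` (`all` / `ParAF` / `PerAF`),
#'   `cv`, `n_recordings`; attribute `skipped` lists skipped recordings.
#' @export
intra_recording_cv <- function(seg_tab, index = c("SE", "DET"), w,
                               use_discards = TRUE) {
  index <- match.arg(index)
  tab <- usable_rows(seg_tab, index, w, use_discards)
  if (nrow(tab) == 0L) stop("no eligible recordings")
  rec_id <- paste(tab$patient_id, tab$site, sep = "_")
  cvs <- cv_by_group(tab[[index]], rec_id)
  if (length(cvs) == 0L) stop("no recording has >= 2 usable segments")
  cls <- tapply(tab$af_type, rec_id, `[`, 1L)[names(cvs)]
  out <- data.frame(scope = "all", cv = mean(cvs),
                    n_recordings = length(cvs))
  for (g in c("ParAF", "PerAF")) {
    sel <- cls == g
    if (any(sel))
      out <- rbind(out, data.frame(scope = g, cv = mean(cvs[sel]),
                                   n_recordings = sum(sel)))
  }
  all_ids <- unique(paste(seg_tab$patient_id, seg_tab$site, sep = "_"))
  attr(out, "skipped") <- setdiff(all_ids, names(cvs))
  out
}

#' Intra-patient coefficient of variation
#'
#' For each patient, the per-site mean index values of its recordings are
#' computed first; the CV is then taken across sites and averaged over
#' patients with equal weight. Patients with fewer than two sites are
#' skipped (listed in the `skipped` attribute).
#'
#' @inheritParams intra_recording_cv
#' @return data.frame as in [intra_recording_cv()], with `n_patients`.
#' @export
intra_patient_cv <- function(seg_tab, index = c("SE", "DET"), w,
                             use_discards = TRUE) {
  index <- match.arg(index)
  tab <- usable_rows(seg_tab, index, w, use_discards)
  if (nrow(tab) == 0L) stop("no eligible patients")
  site_mean <- stats::aggregate(tab[[index]],
                                list(patient_id = tab$patient_id,
                                     site = tab$site,
                                     af_type = tab$af_type), mean)
  cvs <- tapply(site_mean$x, site_mean$patient_id, function(v) {
    if (length(v) < 2L) return(NA_real_)
    as.numeric(coefficient_of_variation(v))
  })
  skipped <- names(cvs)[is.na(cvs)]
  cvs <- cvs[!is.na(cvs)]
  if (length(cvs) == 0L) stop("no patient has >= 2 sites")
  cls <- tapply(site_mean$af_type, site_mean$patient_id, `[`, 1L)[names(cvs)]
  out <- data.frame(scope = "all", cv = mean(cvs), n_patients = length(cvs))
  for (g in c("ParAF", "PerAF")) {
    sel <- cls == g
    if (any(sel))
      out <- rbind(out, data.frame(scope = g, cv = mean(cvs[sel]),
                                   n_patients = sum(sel)))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Stability report (intra-recording and intra-patient CV with and without
#' discards)
#'
#' Assembles, for each index and window length, the intra-recording and
#' intra-patient CV with and without the discard step, and the relative
#' change `delta_cv_pct = 100 * (CV_discard - CV_nodiscard) /
#' CV_nodiscard`.
#'
#' @param seg_tab segment index table (see [intra_recording_cv()]).
#' @param w_values window lengths to include.
#' @return data.frame with one row per (level, index, w, scope).
#' @export
stability_report <- function(seg_tab, w_values = c(1, 2, 4)) {
  rows <- list()
  for (level in c("intra_recording", "intra_patient")) {
    f <- if (level == "intra_recording") intra_recording_cv else
      intra_patient_cv
    for (index in c("SE", "DET")) {
      for (w in w_values) {
        no_d <- f(seg_tab, index, w, use_discards = FALSE)
        wi_d <- f(seg_tab, index, w, use_discards = TRUE)
        m <- merge(no_d[, 1:2], wi_d[, 1:2], by = "scope",
                   suffixes = c("_nodiscard", "_discard"))
        m$delta_cv_pct <- 100 * (m$cv_discard - m$cv_nodiscard) /
          m$cv_nodiscard
        rows[[length(rows) + 1L]] <-
          cbind(level = level, index = index, w = w, m)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis test of index homogeneity across a patient's sites
#'
#' For each patient, tests whether the segment-level index values at the
#' different recording sites originate from the same distribution
#' (rank-based H statistic with tie correction, chi-square reference with
#' `sites - 1` degrees of freedom). The result is flagged unreliable when
#' any site contributes fewer than 5 segment values, since the chi-square
#' approximation degrades at small group sizes.
#'
#' @inheritParams intra_recording_cv
#' @return data.frame: `patient_id`, `af_type`, `p`, `n_sites`,
#'   `unreliable`.
#' @export
kruskal_wallis_sites <- function(seg_tab, index = c("SE", "DET"), w,
                                 use_discards = TRUE) {
  index <- match.arg(index)
  tab <- usable_rows(seg_tab, index, w, use_discards)
  pats <- unique(tab$patient_id)
  rows <- lapply(pats, function(pid) {
    sub <- tab[tab$patient_id == pid, ]
    counts <- table(sub$site)
    counts <- counts[counts > 0]
    if (length(counts) < 2L || any(counts < 2L)) return(NULL)
    kt <- stats::kruskal.test(sub[[index]], factor(sub$site))
    data.frame(patient_id = pid, af_type = sub$af_type[1L],
               p = kt$p.value, n_sites = length(counts),
               unreliable = any(counts < 5L))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no patient with >= 2 sites of >= 2 segments")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Breusch-Pagan test of homoscedasticity across groups
#'
#' Auxiliary-regression form: the squared residuals of the group-means
#' model are regressed on the group indicators and the Lagrange-multiplier
#' statistic `n * R^2` is referred to a chi-square distribution with
#' `groups - 1` degrees of freedom. Degenerate inputs (all residuals zero)
#' return a flagged `NA`.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 levels).
#' @return list with `statistic`, `df`, `p`.
#' @export
breusch_pagan <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (length(values) <= nlevels(g)) stop("degenerate design")
  fit <- stats::lm(values ~ g)
  u2 <- stats::residuals(fit)^2
  if (all(u2 < .Machine$double.eps))
    return(list(statistic = NA_real_, df = nlevels(g) - 1L,
                p = structure(NA_real_, flag = "zero_residual_variance")))
  aux <- stats::lm(u2 ~ g)
  r2 <- summary(aux)$r.squared
  lm_stat <- length(values) * r2
  df <- nlevels(g) - 1L
  list(statistic = lm_stat, df = df,
       p = stats::pchisq(lm_stat, df, lower.tail = FALSE))
}

#' Mann-Whitney comparison of ParAF vs PerAF per site and index
#'
#' For each recording site and index, the two AF classes are compared with
#' a two-sided rank-sum test. SE and DET are summarized per recording as
#' the mean over usable segments before testing, separately for each window
#' length; AFCL and DF come from the 16 s computation and are identical
#' across window lengths. The three per-window p-values are then averaged -
#' the reporting convention adopted here, not a combined inference. A class
#' absent at a site yields flagged `NA`s.
#'
#' @param seg_tab segment index table (see [intra_recording_cv()]).
#' @param rec_tab per-recording table with columns `patient_id`, `site`,
#'   `af_type`, `AFCL`, `DF`.
#' @param w_values window lengths averaged over.
#' @param use_discards exclude zero-quality segments from the summaries.
#' @param pool_segments if TRUE, segment-level SE/DET values are pooled
#'   into the test instead of being summarized per recording first.
#' @param p_adjust `"none"` (default, matching the convention of reporting
#'   unadjusted p-values) or `"holm"`, applied to the averaged p-values
#'   across sites within each index (column `p_adj`).
#' @return data.frame: `site`, `index`, `p_avg` and one `p_w<w>` column per
#'   window length.
#' @export
mann_whitney_sites <- function(seg_tab, rec_tab, w_values = c(1, 2, 4),
                               use_discards = TRUE,
                               pool_segments = FALSE,
                               p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  sites <- unique(c(seg_tab$site, rec_tab$site))
  mw_p <- function(v, cls) {
    x <- v[cls == "ParAF"]
    y <- v[cls == "PerAF"]
    if (length(x) == 0L || length(y) == 0L)
      return(structure(NA_real_, flag = "class_missing"))
    suppressWarnings(stats::wilcox.test(x, y, exact = NULL)$p.value)
  }
  rows <- list()
  for (site in sites) {
    for (index in c("SE", "DET", "AFCL", "DF")) {
      ps <- numeric(length(w_values))
      for (k in seq_along(w_values)) {
        if (index %in% c("SE", "DET")) {
          tab <- usable_rows(seg_tab, index, w_values[k], use_discards)
          tab <- tab[tab$site == site, , drop = FALSE]
          if (pool_segments) {
            ps[k] <- mw_p(tab[[index]], tab$af_type)
          } else {
            agg <- stats::aggregate(tab[[index]],
                                    list(patient_id = tab$patient_id,
                                         af_type = tab$af_type), mean)
            ps[k] <- mw_p(agg$x, agg$af_type)
          }
        } else {
          sub <- rec_tab[rec_tab$site == site & !is.na(rec_tab[[index]]), ]
          ps[k] <- mw_p(sub[[index]], sub$af_type)
        }
      }
      row <- data.frame(site = site, index = index, p_avg = mean(ps))
      for (k in seq_along(w_values))
        row[[paste0("p_w", w_values[k])]] <- ps[k]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "holm") {
    out$p_adj <- NA_real_
    for (index in unique(out$index)) {
      sel <- out$index == index
      out$p_adj[sel] <- stats::p.adjust(out$p_avg[sel], method = "holm")
    }
  }
  rownames(out) <- NULL
  out
}
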