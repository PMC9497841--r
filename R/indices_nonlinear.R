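#' Sample entropy parameters
#'
#' @param m template length in samples (default 2).
#' @param r_factor tolerance multiplier on the segment standard deviation
#'   (default 0.35); the tolerance is `r_factor` times `sd(segment)`.
#' @return object of class `cfae_se_params`.
#' @export
se_params <- function(m = 2L, r_factor = 0.35) {
  if (m < 1) stop("m must be >= 1")
  if (r_factor <= 0) stop("r_factor must be positive")
  structure(list(m = as.integer(m), r_factor = r_factor),
            class = "cfae_se_params")
}

#' Sample entropy of a segment
#'
#' `SE = -log(A / B)` where `B` and `A` are the numbers of pairs of
#' templates of length `m` and `m + 1` whose Chebyshev (maximum absolute
#' coordinate) distance is within `r = r_factor * sd(segment)`,
#' self-matches excluded; both template lengths range over the same
#' `N - m` starting points, so the normalizing constants cancel in the
#' ratio. Degenerate cases are returned as `NA` with a `flag` attribute
#' rather than clamped: a constant segment (`sd = 0`, flag `"constant"`)
#' and a segment with no `(m+1)`-matches (flag `"no_matches"`); such
#' segments are treated as discarded downstream.
#'
#' @param x numeric segment.
#' @param p an [se_params()] object.
#' @return non-negative sample entropy, or flagged `NA`.
#' @export
sample_entropy <- function(x, p = se_params()) {
  stopifnot(inherits(p, "cfae_se_params"))
  if (length(x) <= p$m + 1) stop("segment too short: need N > m + 1")
  sdx <- sd(x)
  if (sdx == 0) return(structure(NA_real_, flag = "constant"))
  cnt <- sampen_counts_cpp(as.numeric(x), p$m, p$r_factor * sdx)
  if (cnt[1] == 0 || cnt[2] == 0)
    return(structure(NA_real_, flag = "no_matches"))
  -log(cnt[2] / cnt[1])
}

#' Embedding parameters for recurrence analysis
#'
#' @param d embedding dimension (>= 1).
#' @param tau embedding delay, samples (>= 1).
#' @param eps_frac recurrence threshold as a fraction of the phase-space
#'   scale (default 0.10).
#' @param lmin minimum diagonal length, in recurrence points (default 50).
#' @param eps_mode how the phase-space scale is measured: `"diameter"`
#'   (max pairwise distance among embedded points, the default) or
#'   `"mean_dist"` (mean pairwise distance). With realistic additive noise
#'   the mean-distance rule puts the threshold at the noise-cloud scale and
#'   determinism degenerates toward zero; the diameter rule keeps it on the
#'   attractor scale.
#' @return object of class `cfae_embedding_params`.
#' @export
embedding_params <- function(d, tau, eps_frac = 0.10, lmin = 50L,
                             eps_mode = c("diameter", "mean_dist")) {
  if (d < 1 || tau < 1) stop("d and tau must be >= 1")
  if (eps_frac <= 0 || eps_frac >= 1) stop("eps_frac must be in (0, 1)")
  if (lmin < 2) stop("lmin must be >= 2")
  eps_mode <- match.arg(eps_mode)
  structure(list(d = as.integer(d), tau = as.integer(tau),
                 eps_frac = eps_frac, lmin = as.integer(lmin),
                 eps_mode = eps_mode),
            class = "cfae_embedding_params")
}

## Equiprobable 16-bin mutual information at one lag, in nats.
mi_at_lag <- function(x, lag, n_bins = 16L) {
  n <- length(x) - lag
  edges <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                           names = FALSE)
  u <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(factor(u[seq_len(n)], levels = seq_len(n_bins)),
                 factor(u[seq_len(n) + lag], levels = seq_len(n_bins))) / n
  pr <- rowSums(joint)
  pc <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pr, pc)[nz]))
}

#' Embedding delay from the auto mutual information
#'
#' Computes the mutual information between `x(t)` and `x(t + tau)` from a
#' 16-bin equiprobable two-dimensional histogram, for lags `1..max_lag`,
#' and returns the smallest lag at a local minimum of the MI curve. Because
#' the histogram estimate carries bin-alignment jitter, a local minimum is
#' required to hold over a `half_width`-lag neighbourhood (the estimate at
#' the candidate lag must not exceed any estimate within `half_width` lags
#' on either side), which suppresses spurious single-lag wiggles. If no
#' such minimum exists the argmin over all lags is returned. The MI curve
#' is attached as attribute `"mi"`.
#'
#' @param x numeric segment (non-constant).
#' @param max_lag largest lag scanned; must be below `length(x) / 2`.
#' @param n_bins number of equiprobable bins per axis.
#' @param half_width neighbourhood half-width of the local-minimum rule.
#' @return integer delay, with attribute `mi`.
#' @export
auto_mutual_information <- function(x, max_lag = 100L, n_bins = 16L,
                                    half_width = 3L) {
  if (sd(x) == 0) stop("constant segment: mutual information undefined")
  if (max_lag >= length(x) / 2) stop("max_lag must be below N / 2")
  mi <- vapply(seq_len(max_lag), function(l) mi_at_lag(x, l, n_bins),
               numeric(1))
  tau <- NA_integer_
  for (t in 2:(max_lag - 1L)) {
    lo <- max(1L, t - half_width)
    hi <- min(max_lag, t + half_width)
    if (mi[t] <= min(mi[lo:hi]) && mi[t] < mi[t - 1L]) { tau <- t; break }
  }
  if (is.na(tau)) tau <- which.min(mi)
  structure(as.integer(tau), mi = mi)
}

#' Embedding dimension from false nearest neighbours
#'
#' Classical criterion: at each candidate dimension `d`, the nearest
#' neighbour of every embedded point (temporal neighbours within a Theiler
#' window excluded) is checked against the `(d+1)`-th delay coordinate; the
#' neighbour is false when the extra-coordinate distance exceeds `rtol`
#' times the in-space distance. Returns the first `d` with a false-neighbour
#' fraction below `tol`, else `max_d` (with attribute `saturated = TRUE`,
#' the signature of a noise-dominated segment). The per-dimension fractions
#' are attached as attribute `"fractions"`. Two numerical safeguards: the
#' denominator of the distance ratio is floored at `dmin_frac` times the
#' segment SD, so near-coincident returns of a noiseless orbit are not
#' declared false by a 0/0-type ratio; and the all-pairs search is
#' restricted to the first `max_n` embedded points (contiguous truncation
#' preserves the dynamics while bounding the quadratic cost).
#'
#' @param x numeric segment.
#' @param tau embedding delay, samples.
#' @param max_d largest dimension tried.
#' @param rtol distance-ratio threshold (default 10).
#' @param tol acceptable false-neighbour fraction (default 0.01).
#' @param theiler temporal exclusion window for the neighbour search;
#'   defaults to `tau`.
#' @param max_n cap on the number of embedded points searched.
#' @param dmin_frac floor on the neighbour distance, as a fraction of the
#'   segment SD.
#' @param atol attractor-size criterion threshold (default 2): a neighbour
#'   is also false when the augmented distance exceeds `atol` times the
#'   segment SD.
#' @return integer dimension with attributes `fractions` and `saturated`.
#' @export
false_nearest_neighbors <- function(x, tau, max_d = 8L, rtol = 10,
                                    tol = 0.01, theiler = tau,
                                    max_n = 800L, dmin_frac = 1e-3,
                                    atol = 2) {
  if (length(x) - max_d * tau < 10L)
    stop("segment too short for FNN up to max_d")
  x <- x[seq_len(min(length(x), max_n + max_d * tau))]
  ra <- sd(x)
  dmin <- dmin_frac * ra
  fr <- numeric(max_d)
  for (d in seq_len(max_d)) {
    fr[d] <- fnn_fraction_cpp(as.numeric(x), d, as.integer(tau), rtol,
                              as.integer(theiler), dmin, atol, ra)
    if (fr[d] < tol) {
      return(structure(as.integer(d), fractions = fr[seq_len(d)],
                       saturated = FALSE))
    }
  }
  structure(as.integer(max_d), fractions = fr, saturated = TRUE)
}

#' Select a global embedding for a set of segments
#'
#' Applies the mutual-information delay and FNN dimension estimators to
#' every segment and adopts the most frequent values (ties broken toward
#' the smaller value) as the common embedding for the whole dataset, so all
#' recurrence plots of a given window length share one phase space.
#'
#' @param segments non-empty list of numeric segments.
#' @param max_lag,max_d,rtol,tol,max_n passed to the per-segment estimators.
#' @param eps_frac,lmin recurrence parameters carried into the result.
#' @return an [embedding_params()] object, with per-segment votes attached
#'   as attributes `d_votes` and `tau_votes`.
#' @export
select_global_embedding <- function(segments, max_lag = 100L, max_d = 8L,
                                    rtol = 10, tol = 0.01, max_n = 800L,
                                    eps_frac = 0.10, lmin = 50L,
                                    eps_mode = "diameter") {
  if (length(segments) == 0L) stop("no segments supplied")
  taus <- integer(length(segments))
  ds <- integer(length(segments))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (sd(s) == 0) { taus[i] <- NA_integer_; ds[i] <- NA_integer_; next }
    taus[i] <- as.integer(auto_mutual_information(s, max_lag))
    ds[i] <- as.integer(false_nearest_neighbors(s, taus[i], max_d, rtol,
                                                tol, max_n = max_n))
  }
  e <- embedding_params(mode_smallest(ds), mode_smallest(taus),
                        eps_frac = eps_frac, lmin = lmin,
                        eps_mode = eps_mode)
  attr(e, "d_votes") <- ds
  attr(e, "tau_votes") <- taus
  e
}

## Delay embedding as an (N - (d-1) tau) x d matrix.
delay_embed <- function(x, d, tau) {
  n <- length(x) - (d - 1L) * tau
  if (n < 2L) stop("segment too short for this embedding")
  vapply(seq_len(d), function(a) x[seq_len(n) + (a - 1L) * tau],
         numeric(n))
}

#' Recurrence matrix of a segment
#'
#' Binary matrix over the delay-embedded points: `R[i, j] = 1` iff the
#' Euclidean distance between embedded points `i` and `j` is within
#' `eps = eps_frac *` (phase-space scale, per `e$eps_mode`). The matrix is
#' symmetric with a unit main diagonal. Intended for inspection and small
#' inputs; the pipeline uses the streaming [rqa_determinism()].
#'
#' @param x numeric segment.
#' @param e an [embedding_params()].
#' @return binary integer matrix with attribute `eps`.
#' @export
recurrence_matrix <- function(x, e) {
  stopifnot(inherits(e, "cfae_embedding_params"))
  emb <- delay_embed(x, e$d, e$tau)
  if (nrow(emb) < e$lmin) stop("too few embedded points (< lmin)")
  D <- as.matrix(stats::dist(emb))
  scale <- if (e$eps_mode == "diameter") max(D) else mean(D[upper.tri(D)])
  eps <- e$eps_frac * scale
  R <- (D <= eps) * 1L
  structure(R, eps = eps)
}

#' Determinism of a recurrence matrix
#'
#' Fraction of recurrence points that lie on diagonal lines of length at
#' least `lmin`, with the line of identity excluded from both counts;
#' returns 0 when there are no off-diagonal recurrence points. Works on any
#' square binary matrix (both triangles are scanned, so symmetry is not
#' assumed).
#'
#' @param R square binary matrix.
#' @param lmin minimum diagonal length in recurrence points.
#' @return determinism in `[0, 1]`.
#' @export
determinism <- function(R, lmin = 50L) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) stop("R must be square")
  if (!all(R %in% c(0L, 1L))) stop("R must be binary")
  n <- nrow(R)
  rec <- 0
  det_pts <- 0
  count_diag <- function(v) {
    r <- rle(v)
    rec <<- rec + sum(r$lengths[r$values == 1])
    det_pts <<- det_pts + sum(r$lengths[r$values == 1 & r$lengths >= lmin])
  }
  for (k in seq_len(n - 1L)) {
    i <- seq_len(n - k)
    count_diag(R[cbind(i, i + k)])
    count_diag(R[cbind(i + k, i)])
  }
  if (rec == 0) return(0)
  det_pts / rec
}

#' Streaming recurrence determinism of a segment
#'
#' Computes the determinism of a segment directly from its delay embedding
#' without materializing the recurrence matrix, making 4 s (4000-sample)
#' segments tractable. Equals
#' `determinism(recurrence_matrix(x, e), e$lmin)` exactly.
#'
#' @param x numeric segment.
#' @param e an [embedding_params()].
#' @return list with `det`, `eps`, `n_embedded`, `recurrence_rate`.
#' @export
rqa_determinism <- function(x, e) {
  stopifnot(inherits(e, "cfae_embedding_params"))
  n_emb <- length(x) - (e$d - 1L) * e$tau
  if (n_emb < e$lmin) stop("too few embedded points (< lmin)")
  rqa_det_cpp(as.numeric(x), e$d, e$tau, e$eps_frac, e$lmin, 1L,
              if (e$eps_mode == "diameter") 0L else 1L)
}
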