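# Independent brute-force oracles, kept deliberately naive: plain loops and
# direct formulas, sharing no code with the package's fast paths.

# Sample entropy by explicit double loop over template pairs (Chebyshev
# distance, self-matches excluded, both lengths over the first N - m
# starting points).
sampen_brute <- function(x, m = 2L, r_factor = 0.35) {
  r <- r_factor * sd(x)
  M <- length(x) - m
  B <- 0; A <- 0
  for (i in seq_len(M - 1L)) {
    for (j in (i + 1L):M) {
      dm <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (dm <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Histogram mutual information at one lag by explicit cell counting with
# the same equiprobable-edge rule (left-closed bins, last bin closed).
mi_brute <- function(x, lag, n_bins = 16L) {
  n <- length(x) - lag
  edges <- quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                    names = FALSE)
  bin_of <- function(v) {
    for (b in seq_len(n_bins)) {
      hi_ok <- if (b == n_bins) v <= edges[b + 1L] else v < edges[b + 1L]
      if (v >= edges[b] && hi_ok) return(b)
    }
    if (v < edges[1L]) 1L else n_bins
  }
  counts <- matrix(0, n_bins, n_bins)
  for (t in seq_len(n)) {
    i <- bin_of(x[t]); j <- bin_of(x[t + lag])
    counts[i, j] <- counts[i, j] + 1
  }
  p <- counts / n
  pr <- rowSums(p); pc <- colSums(p)
  s <- 0
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (pr[i] * pc[j]))
  }
  s
}

# FNN fraction at one dimension via explicit embedding and matrix algebra
# (a different route from the C++ scan: full distance matrix, no early
# exits).
fnn_brute <- function(x, d, tau, rtol = 10, theiler = tau,
                      dmin_frac = 1e-3, atol = 2) {
  n <- length(x) - d * tau
  emb <- sapply(seq_len(d), function(a) x[seq_len(n) + (a - 1L) * tau])
  emb <- matrix(emb, nrow = n)
  D2 <- as.matrix(dist(emb))^2
  for (i in seq_len(n)) D2[i, abs(seq_len(n) - i) <= theiler] <- Inf
  ra <- sd(x)
  dmin <- dmin_frac * ra
  nf <- 0
  for (i in seq_len(n)) {
    j <- which.min(D2[i, ])
    dist_ij <- sqrt(D2[i, j])
    extra <- abs(x[i + d * tau] - x[j + d * tau])
    crit1 <- extra / max(dist_ij, dmin) > rtol
    crit2 <- sqrt(dist_ij^2 + extra^2) / ra > atol
    if (crit1 || crit2) nf <- nf + 1
  }
  nf / n
}

# Recurrence matrix from the embedded points by direct pairwise formula.
rp_brute <- function(x, d, tau, eps_frac = 0.10, eps_mode = "diameter") {
  n <- length(x) - (d - 1L) * tau
  emb <- sapply(seq_len(d), function(a) x[seq_len(n) + (a - 1L) * tau])
  emb <- matrix(emb, nrow = n)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((emb[i, ] - emb[j, ])^2))
  scale <- if (eps_mode == "diameter") max(D) else mean(D[upper.tri(D)])
  eps <- eps_frac * scale
  (D <= eps) * 1L
}

# Determinism by scanning every diagonal of the matrix with an explicit
# run counter (no rle).
det_brute <- function(R, lmin) {
  n <- nrow(R)
  rec <- 0; det_pts <- 0
  for (k in seq_len(n - 1L)) {
    for (sgn in c(1L, -1L)) {
      run <- 0
      len <- n - k
      for (t in seq_len(len)) {
        i <- if (sgn == 1L) t else t + k
        j <- if (sgn == 1L) t + k else t
        v <- R[i, j]
        if (v == 1L) { run <- run + 1; rec <- rec + 1 }
        if (v == 0L || t == len) {
          if (run >= lmin) det_pts <- det_pts + run
          run <- 0
        }
      }
    }
  }
  if (rec == 0) return(0)
  det_pts / rec
}

# Welch PSD by literal section-by-section periodogram averaging.
welch_brute <- function(x, fs = 1000, n_window = 4096, overlap = 0.5,
                        n_fft = 8192) {
  w <- signal::hamming(n_window)
  step <- n_window - floor(overlap * n_window)
  starts <- seq(1L, length(x) - n_window + 1L, by = step)
  n_keep <- n_fft %/% 2L + 1L
  P <- matrix(0, length(starts), n_keep)
  for (s in seq_along(starts)) {
    seg <- x[starts[s]:(starts[s] + n_window - 1L)] * w
    X <- fft(c(seg, rep(0, n_fft - n_window)))
    pk <- Mod(X[seq_len(n_keep)])^2 / (fs * sum(w^2))
    pk[2:(n_keep - 1L)] <- 2 * pk[2:(n_keep - 1L)]
    P[s, ] <- pk
  }
  list(freq = (seq_len(n_keep) - 1L) * fs / n_fft, power = colMeans(P))
}
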