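# Independent brute-force oracles shared across the suite. Each is written
# from the defining formula and kept free of package internals so it can
# stand as a second opinion on the implementation.

# Per-pixel set enumeration over a named list of logical matrices:
# total/unique/overlap by explicit coverage counting.
oracle_algebra <- function(masks) {
  labs <- names(masks)
  cov <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  uniq <- vapply(labs, function(e) sum(masks[[e]] & cov == 1L), 0L)
  list(total = sum(cov >= 1L),
       unique = uniq,
       overlap = sum(cov >= 2L))
}

# Exhaustive Otsu: for every candidate histogram split compute class
# weights/means directly and maximise between-class variance; ties go to
# the smallest threshold. Mirrors the binning contract (n_bins equal-width
# bins, threshold = upper bin edge).
oracle_otsu <- function(v, n_bins = 256L) {
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, n_bins)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  best_t <- NA_real_; best_v <- -Inf
  for (t in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:t]); n1 <- sum(counts) - n0
    if (n0 == 0L || n1 == 0L) next
    mu0 <- sum(counts[1:t] * centers[1:t]) / n0
    mu1 <- sum(counts[(t + 1L):n_bins] * centers[(t + 1L):n_bins]) / n1
    bcv <- n0 * n1 * (mu0 - mu1)^2
    if (bcv > best_v) { best_v <- bcv; best_t <- edges[t + 1L] }
  }
  best_t
}

# Direct 1-D discrete Gaussian convolution with symmetric reflection.
oracle_gauss_conv_1d <- function(x, sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  n <- length(x)
  refl <- function(p) { while (p < 1 || p > n) p <- if (p < 1) 1 - p else 2 * n + 1 - p; p }
  vapply(seq_len(n), function(i) {
    sum(vapply(seq_along(k), function(j) k[j] * x[refl(i + j - r - 1L)], 0))
  }, 0)
}

# Stack-based flood fill component counter (8-connected), structured
# differently from the package's frontier expansion.
oracle_component_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1L] + dr; c <- p[2L] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  count
}

# Rasterised disc mask for fixtures.
disc_mask <- function(nr, nc, cr, cc, radius) {
  m <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if ((r - cr)^2 + (c - cc)^2 <= radius^2) m[r, c] <- TRUE
  m
}

# Toy pixel-interval masks on a 4x5 grid: A = pixels 1-10, B = 6-15,
# C = 11-20 (linear indices).
toy_interval_masks <- function() {
  mk <- function(lo, hi) { m <- matrix(FALSE, 4, 5); m[lo:hi] <- TRUE; m }
  list(A = mk(1, 10), B = mk(6, 15), C = mk(11, 20))
}

random_mask <- function(nr, nc, p = 0.3) matrix(stats::runif(nr * nc) < p, nr, nc)

quiet_region_analysis <- function(...) {
  suppressMessages(run_region_analysis(...))
}
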