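# Naive brute-force oracles, intentionally independent of the package's
# vectorized implementations.

oracle_box_counts <- function(mask, eps) {
  nr <- nrow(mask); nc <- ncol(mask)
  count <- 0L
  masses <- numeric(0)
  all_masses <- numeric(0)
  for (r0 in seq(1, nr, by = eps)) {
    for (c0 in seq(1, nc, by = eps)) {
      blk <- mask[r0:min(nr, r0 + eps - 1), c0:min(nc, c0 + eps - 1), drop = FALSE]
      m <- sum(blk)
      all_masses <- c(all_masses, m)
      if (m > 0) {
        count <- count + 1L
        masses <- c(masses, m)
      }
    }
  }
  list(count = count, masses = masses, all_masses = all_masses)
}

oracle_dbc <- function(img, eps) {
  nr <- nrow(img); nc <- ncol(img)
  h <- eps * 256 / min(nr, nc)
  ns <- numeric(0)
  for (r0 in seq(1, nr, by = eps)) {
    for (c0 in seq(1, nc, by = eps)) {
      blk <- img[r0:min(nr, r0 + eps - 1), c0:min(nc, c0 + eps - 1)]
      ns <- c(ns, floor((max(blk) - min(blk)) / h) + 1)
    }
  }
  ns
}

oracle_outline <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  bg_at <- function(r, c) {
    if (r < 1 || r > nr || c < 1 || c > nc) return(TRUE)
    !mask[r, c]
  }
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!mask[r, c]) next
      out[r, c] <- bg_at(r - 1, c) || bg_at(r + 1, c) ||
        bg_at(r, c - 1) || bg_at(r, c + 1)
    }
  }
  out
}

# All fixed points of the iterative-intermeans map over candidate thresholds.
oracle_isodata_fixed_points <- function(img) {
  v <- as.integer(img)
  step <- function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    mu0 <- if (length(lo)) mean(lo) else mean(hi)
    mu1 <- if (length(hi)) mean(hi) else mean(lo)
    min(254L, as.integer(floor((mu0 + mu1) / 2)))
  }
  Filter(function(t) step(t) == t, 0:254)
}

oracle_lacunarity <- function(mask, scales) {
  vals <- sapply(scales, function(eps) {
    m <- oracle_box_counts(mask, eps)$all_masses
    mu <- mean(m)
    sdev <- sqrt(mean(m^2) - mean(m)^2)
    (sdev / mu)^2
  })
  mean(vals)
}

seeded_mask <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n) < p, n, n)
}

seeded_gray <- function(n, seed = 1) {
  set.seed(seed)
  matrix(sample(0:255, n * n, replace = TRUE), n, n)
}

# 2D multiplicative binomial cascade measure with fixed quadrant weights
cascade_measure <- function(p = c(0.4, 0.3, 0.2, 0.1), depth = 6) {
  m <- matrix(1, 1, 1)
  for (d in seq_len(depth)) {
    m <- rbind(cbind(m * p[1], m * p[2]), cbind(m * p[3], m * p[4]))
  }
  m
}

cascade_dq_closed_form <- function(q, p = c(0.4, 0.3, 0.2, 0.1)) {
  ifelse(
    abs(q - 1) < 1e-9,
    -sum(p * log2(p)),
    log2(sapply(q, function(qq) sum(p^qq))) / (1 - q)
  )
}
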