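# Independent oracles, each coded directly from the defining formula with a
# different mechanism than the implementation under test.

# exhaustive between-class-variance scan over all 256 candidate levels
oracle_otsu <- function(s) {
  v <- as.integer(round(s))
  best <- -Inf
  best_t <- 0L
  for (t in 0:254) {
    g0 <- v[v <= t]
    g1 <- v[v > t]
    if (length(g0) == 0 || length(g1) == 0) next
    w0 <- length(g0) / length(v)
    sb <- w0 * (1 - w0) * (mean(g0) - mean(g1))^2
    if (sb > best + 1e-12) {
      best <- sb
      best_t <- t
    }
  }
  best_t
}

# breadth-first search from the seed sites over the 8-neighbourhood
oracle_connected <- function(cluster) {
  m <- matrix(FALSE, cluster$lattice_size, cluster$lattice_size)
  m[cluster$occupied] <- TRUE
  seen <- matrix(FALSE, cluster$lattice_size, cluster$lattice_size)
  queue <- cluster$seed_sites
  seen[queue] <- TRUE
  sh <- expand.grid(dr = -1:1, dc = -1:1)
  sh <- sh[!(sh$dr == 0 & sh$dc == 0), ]
  while (nrow(queue) > 0) {
    nxt <- do.call(rbind, lapply(seq_len(nrow(sh)), function(i) {
      cbind(queue[, 1] + sh$dr[i], queue[, 2] + sh$dc[i])
    }))
    nxt <- nxt[nxt[, 1] >= 1 & nxt[, 1] <= nrow(m) &
                 nxt[, 2] >= 1 & nxt[, 2] <= ncol(m), , drop = FALSE]
    keep <- m[nxt] & !seen[nxt]
    nxt <- unique(nxt[keep, , drop = FALSE])
    seen[nxt] <- TRUE
    queue <- nxt
  }
  all(seen[cluster$occupied])
}

# direct transcriptions of the SP 800-22 closed forms
oracle_frequency <- function(b) {
  n <- length(b)
  sobs <- abs(sum(2 * b - 1)) / sqrt(n)
  2 * (1 - stats::pnorm(sobs))  # erfc(x / sqrt(2)) = 2 (1 - Phi(x))
}

oracle_block_frequency <- function(b, M) {
  N <- length(b) %/% M
  chi2 <- 0
  for (i in seq_len(N)) {
    pi_i <- sum(b[((i - 1) * M + 1):(i * M)]) / M
    chi2 <- chi2 + 4 * M * (pi_i - 0.5)^2
  }
  stats::pgamma(chi2 / 2, N / 2, lower.tail = FALSE)
}

oracle_cusum <- function(b, reverse = FALSE) {
  x <- 2 * b - 1
  if (reverse) x <- rev(x)
  n <- length(x)
  z <- max(abs(cumsum(x)))
  s1 <- 0
  for (k in floor((-n / z + 1) / 4):floor((n / z - 1) / 4)) {
    s1 <- s1 + pnorm((4 * k + 1) * z / sqrt(n)) - pnorm((4 * k - 1) * z / sqrt(n))
  }
  s2 <- 0
  for (k in floor((-n / z - 3) / 4):floor((n / z - 1) / 4)) {
    s2 <- s2 + pnorm((4 * k + 3) * z / sqrt(n)) - pnorm((4 * k + 1) * z / sqrt(n))
  }
  1 - s1 + s2
}

oracle_runs <- function(b) {
  n <- length(b)
  pi_ <- mean(b)
  if (abs(pi_ - 0.5) >= 2 / sqrt(n)) return(NA_real_)
  vn <- 1
  for (i in 2:n) if (b[i] != b[i - 1]) vn <- vn + 1
  x <- abs(vn - 2 * n * pi_ * (1 - pi_)) / (2 * sqrt(2 * n) * pi_ * (1 - pi_))
  2 * (1 - stats::pnorm(sqrt(2) * x))  # erfc(x) = 2 (1 - Phi(sqrt(2) x))
}

oracle_longest_run <- function(b) {
  stopifnot(length(b) >= 128, length(b) < 6272)
  N <- length(b) %/% 8
  pi_ref <- c(0.2148, 0.3672, 0.2305, 0.1875)
  nu <- c(0, 0, 0, 0)
  for (i in seq_len(N)) {
    blk <- b[((i - 1) * 8 + 1):(i * 8)]
    longest <- 0
    cur <- 0
    for (bit in blk) {
      cur <- if (bit == 1) cur + 1 else 0
      longest <- max(longest, cur)
    }
    cat_i <- if (longest <= 1) 1 else if (longest >= 4) 4 else longest
    nu[cat_i] <- nu[cat_i] + 1
  }
  chi2 <- sum((nu - N * pi_ref)^2 / (N * pi_ref))
  stats::pgamma(chi2 / 2, 3 / 2, lower.tail = FALSE)
}

# template counting by string matching on the cyclically extended sequence
oracle_apen <- function(b, m) {
  n <- length(b)
  phi <- function(mm) {
    s <- paste(c(b, b[seq_len(mm - 1)]), collapse = "")
    pats <- vapply(0:(2^mm - 1), function(v) {
      paste(rev(as.integer(intToBits(v)[seq_len(mm)])), collapse = "")
    }, character(1))
    counts <- vapply(pats, function(p) {
      sum(vapply(1:n, function(i) substr(s, i, i + mm - 1) == p, logical(1)))
    }, numeric(1))
    c_i <- counts[counts > 0] / n
    sum(c_i * log(c_i))
  }
  ap <- phi(m) - phi(m + 1)
  chi2 <- 2 * n * (log(2) - ap)
  stats::pgamma(chi2 / 2, 2^(m - 1), lower.tail = FALSE)
}

# naive two-pass quantization
oracle_quantize <- function(x) {
  eps <- sum(x) / length(x)
  out <- integer(length(x))
  for (i in seq_along(x)) out[i] <- if (x[i] > eps) 1L else 0L
  out
}

# pairwise Von Neumann extraction by explicit loop
oracle_von_neumann <- function(b) {
  out <- integer(0)
  i <- 1
  while (i + 1 <= length(b)) {
    pair <- b[c(i, i + 1)]
    if (pair[1] == 0 && pair[2] == 1) out <- c(out, 1L)
    if (pair[1] == 1 && pair[2] == 0) out <- c(out, 0L)
    i <- i + 2
  }
  out
}
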