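# Six NIST SP 800-22 statistical tests (frequency, block frequency,
# cumulative sums in both directions, runs, longest run of ones, approximate
# entropy), implemented from their closed forms. erfc and the regularized
# upper incomplete gamma come from base R (pnorm / pgamma); everything else
# is computed directly. Keys in this pipeline are short (128/256 bits),
# below some of NIST's recommended minima; tests are still applied at these
# lengths, as is conventional for PUF evaluation, and results carry an
# `applicable` flag where a prerequisite fails.

.erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
.igamc <- function(a, x) stats::pgamma(x, shape = a, lower.tail = FALSE)

.nist_result <- function(test_name, statistic, p_value, alpha,
                         applicable = TRUE, note = NA_character_) {
  p_value <- min(max(p_value, 0), 1)
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, passed = applicable && p_value >= alpha,
                 alpha = alpha, applicable = applicable, note = note),
            class = "nist_result")
}

#' @export
print.nist_result <- function(x, ...) {
  cat(sprintf("<nist_result> %s: statistic %.6g, p = %.6g -> %s%s\n",
              x$test_name, x$statistic, x$p_value,
              if (x$passed) "pass" else "fail",
              if (!x$applicable) " (not applicable)" else ""))
  invisible(x)
}

#' @export
as.data.frame.nist_result <- function(x, ...) {
  data.frame(test_name = x$test_name, statistic = x$statistic,
             p_value = x$p_value, passed = x$passed,
             applicable = x$applicable, stringsAsFactors = FALSE)
}

.check_bits <- function(bits, n_min = 1) {
  b <- as.integer(bits)
  if (length(b) == 0) stop("empty bit sequence")
  if (length(b) < n_min) stop(sprintf("need at least %d bits", n_min))
  b
}

#' Frequency (monobit) test
#'
#' Tests whether the proportion of ones is consistent with a fair source:
#' `S_n` is the sum of the +/-1-mapped bits and
#' `p = erfc(|S_n| / sqrt(n) / sqrt(2))`.
#'
#' @param bits A [bit_vector()] or 0/1 vector (>= 10 bits; fewer than 100
#'   bits is noted on the result).
#' @param alpha Significance level.
#' @return A `nist_result`.
#' @export
frequency_test <- function(bits, alpha = 0.01) {
  b <- .check_bits(bits, 10)
  n <- length(b)
  s_n <- sum(2L * b - 1L)
  s_obs <- abs(s_n) / sqrt(n)
  .nist_result("frequency", s_obs, .erfc(s_obs / sqrt(2)), alpha,
               note = if (n < 100) "n below the recommended 100" else NA)
}

#' Frequency test within a block
#'
#' Splits the sequence into `N = floor(n/M)` blocks of `M` bits (trailing
#' bits discarded), computes each block's proportion of ones and
#' `chi2 = 4 M sum (pi_i - 1/2)^2`; `p = igamc(N/2, chi2/2)`.
#'
#' @inheritParams frequency_test
#' @param M Block size (>= 2, <= n). Default 32 for sequences of >= 256
#'   bits, 16 otherwise.
#' @return A `nist_result`.
#' @export
block_frequency_test <- function(bits, M = NULL, alpha = 0.01) {
  b <- .check_bits(bits)
  n <- length(b)
  if (is.null(M)) M <- if (n >= 256) 32L else 16L
  if (M < 2) stop("block size M must be >= 2")
  if (M > n) stop("block size M exceeds the sequence length")
  N <- n %/% M
  pi_i <- vapply(seq_len(N), function(i) mean(b[((i - 1) * M + 1):(i * M)]),
                 numeric(1))
  chi2 <- 4 * M * sum((pi_i - 0.5)^2)
  .nist_result("block_frequency", chi2, .igamc(N / 2, chi2 / 2), alpha)
}

#' Cumulative sums test
#'
#' Maximal excursion of the random walk of the +/-1-mapped bits (the
#' sequence is reversed first in `"reverse"` mode); the p-value is the
#' normal-CDF series for the distribution of the maximum partial sum.
#'
#' @inheritParams frequency_test
#' @param mode `"forward"` or `"reverse"`.
#' @return A `nist_result` (test name `cumulative_sums_fwd` / `_rev`).
#' @export
cumulative_sums_test <- function(bits, mode = c("forward", "reverse"),
                                 alpha = 0.01) {
  mode <- match.arg(mode)
  b <- .check_bits(bits, 10)
  n <- length(b)
  x <- 2L * b - 1L
  if (mode == "reverse") x <- rev(x)
  z <- max(abs(cumsum(x)))
  sn <- sqrt(n)
  k1 <- seq(floor((-n / z + 1) / 4), floor((n / z - 1) / 4))
  k2 <- seq(floor((-n / z - 3) / 4), floor((n / z - 1) / 4))
  p <- 1 -
    sum(stats::pnorm((4 * k1 + 1) * z / sn) -
          stats::pnorm((4 * k1 - 1) * z / sn)) +
    sum(stats::pnorm((4 * k2 + 3) * z / sn) -
          stats::pnorm((4 * k2 + 1) * z / sn))
  .nist_result(paste0("cumulative_sums_",
                      if (mode == "forward") "fwd" else "rev"), z, p, alpha)
}

#' Runs test
#'
#' Counts the observed number of runs `V_n` and compares it with the
#' expectation under independence. The prerequisite frequency check
#' `|pi - 1/2| < 2/sqrt(n)` must hold; otherwise the test is reported as not
#' applicable with p = 0.
#'
#' @inheritParams frequency_test
#' @return A `nist_result`.
#' @export
runs_test <- function(bits, alpha = 0.01) {
  b <- .check_bits(bits, 10)
  n <- length(b)
  pi_ <- mean(b)
  if (abs(pi_ - 0.5) >= 2 / sqrt(n)) {
    return(.nist_result("runs", NA_real_, 0, alpha, applicable = FALSE,
                        note = "prerequisite frequency check failed"))
  }
  v_n <- 1L + sum(b[-1] != b[-n])
  num <- abs(v_n - 2 * n * pi_ * (1 - pi_))
  den <- 2 * sqrt(2 * n) * pi_ * (1 - pi_)
  .nist_result("runs", v_n, .erfc(num / den), alpha)
}

# Reference category probabilities for the longest-run-of-ones test.
.longest_run_setup <- function(n) {
  if (n < 128) stop("longest_run_test requires at least 128 bits")
  if (n < 6272) {
    list(M = 8L, K = 3L, lo = 1L, hi = 4L,
         pi = c(0.2148, 0.3672, 0.2305, 0.1875))
  } else if (n < 750000) {
    list(M = 128L, K = 5L, lo = 4L, hi = 9L,
         pi = c(0.1174, 0.2430, 0.2493, 0.1752, 0.1027, 0.1124))
  } else {
    list(M = 10000L, K = 6L, lo = 10L, hi = 16L,
         pi = c(0.0882, 0.2092, 0.2483, 0.1933, 0.1208, 0.0675, 0.0727))
  }
}

.max_run_of_ones <- function(x) {
  r <- rle(x)
  m <- r$lengths[r$values == 1L]
  if (length(m) == 0) 0L else max(m)
}

#' Longest run of ones test
#'
#' Splits the sequence into blocks (block size 8 for 128 <= n < 6272),
#' tabulates each block's longest run of ones into the SP 800-22 reference
#' categories and compares with the reference probabilities by chi-square;
#' `p = igamc(K/2, chi2/2)`.
#'
#' @inheritParams frequency_test
#' @return A `nist_result`.
#' @export
longest_run_test <- function(bits, alpha = 0.01) {
  b <- .check_bits(bits, 128)
  n <- length(b)
  s <- .longest_run_setup(n)
  N <- n %/% s$M
  runs <- vapply(seq_len(N), function(i) {
    .max_run_of_ones(b[((i - 1) * s$M + 1):(i * s$M)])
  }, integer(1))
  cats <- pmin(pmax(runs, s$lo), s$hi) - s$lo + 1L
  nu <- tabulate(cats, nbins = s$K + 1L)
  chi2 <- sum((nu - N * s$pi)^2 / (N * s$pi))
  .nist_result("longest_run", chi2, .igamc(s$K / 2, chi2 / 2), alpha)
}

# Overlapping m-bit template frequencies with cyclic extension.
.phi_m <- function(b, m) {
  if (m == 0) return(0)
  n <- length(b)
  aug <- c(b, b[seq_len(m - 1)])
  idx <- integer(n)
  for (j in 0:(m - 1)) idx <- idx * 2L + aug[(1 + j):(n + j)]
  cnt <- tabulate(idx + 1L, nbins = 2L^m)
  c_i <- cnt[cnt > 0] / n
  sum(c_i * log(c_i))
}

#' Approximate entropy test
#'
#' Compares the frequencies of overlapping `m`- and `(m+1)`-bit templates
#' (cyclically extended): `ApEn(m) = phi(m) - phi(m+1)`,
#' `chi2 = 2 n (ln 2 - ApEn)`, `p = igamc(2^(m-1), chi2/2)`.
#'
#' @inheritParams frequency_test
#' @param m Template length (>= 1; values with `m + 1 >= log2(n)` are
#'   computable but under-sampled and are flagged on the result); default 2,
#'   suitable for 128- and 256-bit keys.
#' @return A `nist_result`.
#' @export
approximate_entropy_test <- function(bits, m = 2L, alpha = 0.01) {
  b <- .check_bits(bits)
  n <- length(b)
  if (m < 1) stop("template length m must be >= 1")
  if (m + 1L >= n) stop("template length m + 1 must be below n")
  note <- if (m + 1 >= log2(n)) "m above recommended m + 1 < log2(n)" else NA
  ap_en <- .phi_m(b, m) - .phi_m(b, m + 1L)
  chi2 <- 2 * n * (log(2) - ap_en)
  .nist_result("approximate_entropy", chi2, .igamc(2^(m - 1), chi2 / 2),
               alpha, note = note)
}

#' Run the full battery of tests on one bit sequence
#'
#' Applies the six selected SP 800-22 tests, with the cumulative sums test
#' counted as two results (forward and reverse), giving seven rows.
#'
#' @inheritParams frequency_test
#' @param M Block size for the block frequency test (NULL for the
#'   length-based default).
#' @param m Template length for the approximate entropy test.
#' @return A tibble with columns `test_name`, `statistic`, `p_value`,
#'   `passed`, `applicable`.
#' @export
nist_battery <- function(bits, alpha = 0.01, M = NULL, m = 2L) {
  res <- list(
    frequency_test(bits, alpha),
    block_frequency_test(bits, M, alpha),
    cumulative_sums_test(bits, "forward", alpha),
    cumulative_sums_test(bits, "reverse", alpha),
    runs_test(bits, alpha),
    longest_run_test(bits, alpha),
    approximate_entropy_test(bits, m, alpha))
  dplyr::bind_rows(lapply(res, as.data.frame)) |> tibble::as_tibble()
}

#' Bit uniformity (fractional Hamming weight)
#'
#' Sum of the key bits divided by the key length; 0.5 is ideal.
#'
#' @param key A [bit_vector()] or 0/1 vector.
#' @return The fraction of 1-bits.
#' @examples
#' bit_uniformity(c(1, 0, 1, 1, 0, 0, 0, 0))  # 0.375
#' @export
bit_uniformity <- function(key) {
  b <- .check_bits(key)
  mean(b)
}

#' Pairwise inter-device Hamming distances
#'
#' Normalized Hamming distance between every unordered pair of keys:
#' the mean over all `m(m-1)/2` pairs is the library's uniqueness score
#' (ideal 0.5 for independent keys).
#'
#' @param keys List of equal-length [bit_vector()]s (m >= 2).
#' @return A list with `mean`, `sd`, `n_pairs`, and `pairs` (tibble with
#'   `id_a`, `id_b`, `distance`).
#' @export
inter_hd <- function(keys) {
  m <- length(keys)
  if (m < 2) stop("need at least two keys")
  lens <- vapply(keys, length, integer(1))
  if (length(unique(lens)) != 1) stop("keys must all have equal length")
  n <- lens[1]
  ids <- vapply(seq_len(m), function(i) {
    id <- attr(keys[[i]], "source_id")
    if (is.null(id)) paste0("key-", i) else id
  }, character(1))
  mat <- do.call(rbind, lapply(keys, as.integer))
  pr <- utils::combn(m, 2)
  d <- colSums(t(abs(mat[pr[1, ], , drop = FALSE] -
                       mat[pr[2, ], , drop = FALSE]))) / n
  list(mean = mean(d), sd = stats::sd(d), n_pairs = ncol(pr),
       pairs = tibble::tibble(id_a = ids[pr[1, ]], id_b = ids[pr[2, ]],
                              distance = d))
}
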