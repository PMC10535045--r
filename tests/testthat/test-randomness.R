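test_that("frequency test matches the closed form and its worked example", {
  expect_equal(frequency_test(bitstr("1011010101"))$p_value, 0.527089,
               tolerance = 1e-6)
  alt <- rep(c(1L, 0L), 128)
  expect_equal(frequency_test(alt)$p_value, 1.0)
  ones <- frequency_test(rep(1L, 256))
  expect_lt(ones$p_value, 1e-50)
  expect_false(ones$passed)
  expect_error(frequency_test(integer(0)), "empty")
})

test_that("block frequency test matches the worked example and degenerate cases", {
  r <- block_frequency_test(bitstr("0110011010"), M = 3)
  expect_equal(r$statistic, 1.0)
  expect_equal(r$p_value, 0.801252, tolerance = 1e-6)
  expect_equal(block_frequency_test(rep(c(1L, 0L), 64), M = 4)$p_value, 1.0)
  expect_lt(block_frequency_test(rep(0L, 256), M = 32)$p_value, 1e-30)
  expect_error(block_frequency_test(bitstr("0101"), M = 8), "exceeds")
})

test_that("cumulative sums test matches the series formula both ways", {
  r <- cumulative_sums_test(bitstr("1011010111"), "forward")
  expect_equal(r$statistic, 4)
  expect_equal(r$p_value, 0.4115847, tolerance = 1e-6)
  expect_gt(cumulative_sums_test(rep(c(1L, 0L), 128))$p_value, 0.99)
  expect_lt(cumulative_sums_test(rep(1L, 128))$p_value, 1e-20)
  rev_r <- cumulative_sums_test(bitstr("1011010111"), "reverse")
  expect_equal(rev_r$p_value, oracle_cusum(bitstr("1011010111"), TRUE))
})

test_that("runs test matches the worked example and its prerequisite gate", {
  r <- runs_test(bitstr("1001101011"))
  expect_equal(r$statistic, 7)
  expect_equal(r$p_value, 0.147232, tolerance = 1e-5)
  na <- runs_test(rep(0L, 100))
  expect_false(na$applicable)
  expect_equal(na$p_value, 0)
  expect_false(na$passed)
  # perfect alternation is too regular: p = erfc(2.2360...) ~ 0.00157
  alt10 <- runs_test(bitstr("1010101010"))
  expect_equal(alt10$p_value,
               2 * (1 - pnorm(sqrt(2) * 5 / (2 * sqrt(20) * 0.25))),
               tolerance = 1e-9)
  expect_lt(alt10$p_value, 0.01)
  expect_false(alt10$passed)
})

test_that("longest-run test matches its published example and saturates", {
  eps <- paste0("11001100000101010110110001001100111000000000001001",
                "00110101010001000100111101011010000000110101111100",
                "1100111001101101100010110010")
  r <- longest_run_test(bitstr(eps))
  expect_equal(r$p_value, 0.180609, tolerance = 1e-4)
  expect_lt(longest_run_test(rep(1L, 128))$p_value, 1e-10)
  expect_lt(longest_run_test(rep(c(1L, 0L), 64))$p_value, 1e-10)
  expect_error(longest_run_test(rep(1L, 100)), "128")
})

test_that("approximate entropy matches the worked example and degenerates", {
  r <- approximate_entropy_test(bitstr("0100110101"), m = 3)
  expect_equal(r$p_value, 0.261961, tolerance = 1e-5)
  z <- approximate_entropy_test(rep(0L, 256), m = 2)
  expect_equal(z$statistic, 2 * 256 * log(2), tolerance = 1e-9)
  expect_lt(z$p_value, 1e-50)
})

test_that("every test agrees with its independent oracle on random inputs", {
  set.seed(303)
  for (i in 1:50) {
    b <- rbinom(256, 1, 0.5)
    rel <- function(a, b) abs(a - b) / max(abs(b), 1e-300)
    expect_lt(rel(frequency_test(b)$p_value, oracle_frequency(b)), 1e-10)
    expect_lt(rel(block_frequency_test(b, 32)$p_value,
                  oracle_block_frequency(b, 32)), 1e-10)
    expect_lt(rel(cumulative_sums_test(b, "forward")$p_value,
                  oracle_cusum(b)), 1e-10)
    expect_lt(rel(cumulative_sums_test(b, "reverse")$p_value,
                  oracle_cusum(b, TRUE)), 1e-10)
    ro <- oracle_runs(b)
    if (!is.na(ro)) expect_lt(rel(runs_test(b)$p_value, ro), 1e-10)
    expect_lt(rel(longest_run_test(b)$p_value, oracle_longest_run(b)), 1e-10)
    expect_lt(rel(approximate_entropy_test(b, 2)$p_value, oracle_apen(b, 2)),
              1e-10)
  }
})

test_that("p-values are valid probabilities with consistent pass flags", {
  set.seed(55)
  for (i in 1:25) {
    res <- nist_battery(rbinom(256, 1, runif(1, 0.3, 0.7)))
    expect_true(all(res$p_value >= 0 & res$p_value <= 1))
    expect_identical(res$passed, res$applicable & res$p_value >= 0.01)
  }
})

test_that("bit uniformity counts the fraction of ones", {
  expect_equal(bit_uniformity(rep(1L, 256)), 1.0)
  expect_equal(bit_uniformity(rep(c(0L, 1L), 128)), 0.5)
  expect_equal(bit_uniformity(bitstr("10110000")), 0.375)
  expect_error(bit_uniformity(integer(0)), "empty")
})

test_that("inter-HD covers all unordered pairs with exact extremes", {
  k <- bit_vector(rep(c(0L, 1L), 64), "key", "a")
  same <- inter_hd(list(k, k))
  expect_equal(same$mean, 0)
  comp <- inter_hd(list(k, bit_vector(1L - as.integer(k), "key", "b")))
  expect_equal(comp$mean, 1)
  set.seed(8)
  keys <- lapply(1:10, function(i) bit_vector(rbinom(64, 1, 0.5), "key"))
  r <- inter_hd(keys)
  expect_equal(r$n_pairs, 45)
  expect_equal(nrow(r$pairs), 45)
  expect_true(all(r$pairs$distance >= 0 & r$pairs$distance <= 1))
  expect_error(inter_hd(list(k)), "two keys")
  expect_error(inter_hd(list(k, bit_vector(0:1, "key"))), "equal length")
})

test_that("evaluate_library aggregates uniformity, distances and NIST rows", {
  set.seed(21)
  keys <- lapply(1:8, function(i) {
    bit_vector(rbinom(256, 1, 0.5), "key", sprintf("k%02d", i))
  })
  rep_ <- evaluate_library(keys)
  expect_s3_class(rep_, "library_report")
  expect_equal(rep_$inter$n_pairs, 8 * 7 / 2)
  expect_equal(nrow(rep_$nist), 8 * 7)
  expect_equal(nrow(rep_$proportions), 7)
  # i.i.d. uniform keys: mean inter-HD within 3 SE of 0.5 (conservative SE
  # treats pairs as independent binomials)
  se <- 0.5 / sqrt(256 * rep_$inter$n_pairs)
  expect_lt(abs(rep_$inter$mean - 0.5), 3 * se * sqrt(8))
  g <- glance(rep_)
  expect_equal(g$n_keys, 8)
  td <- tidy(rep_)
  expect_true(all(c("device_id", "test_name", "p_value") %in% names(td)))

  ident <- evaluate_library(lapply(1:3, function(i) keys[[1]]))
  expect_equal(ident$inter$mean, 0)
})

test_that("library reports serialize to JSON and CSV", {
  set.seed(4)
  keys <- lapply(1:4, function(i) bit_vector(rbinom(128, 1, 0.5), "key",
                                             paste0("d", i)))
  rep_ <- evaluate_library(keys)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_library_report(rep_, jp, cp)
  j <- jsonlite::read_json(jp)
  expect_equal(length(j$inter_hd_pairs), 6)
  expect_equal(nrow(utils::read.csv(cp)), 4 * 7)
})
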