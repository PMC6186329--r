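test_that("start-up removal keeps strides at or after the cutoff", {
  rec <- make_flat_record(5, time = c(0, 10, 19.9, 20, 25))
  out <- remove_startup(rec, 20)
  expect_equal(out$time, c(20, 25))
  expect_equal(remove_startup(rec, 0)$time, rec$time)   # cutoff 0: identity
  expect_equal(n_strides(remove_startup(rec, 30)), 0L)  # all strides early
})

test_that("median outlier filter flags strides beyond k SDs of the median", {
  # 10-point column: rep(1, 9) and one 9.0
  # median = 1, sd = 2.530..., 3 sd = 7.59 < |9 - 1| = 8 -> flagged
  v <- c(rep(1, 9), 9)
  expect_true(abs(9 - median(v)) > 3 * sd(v))     # hand-checked oracle
  rec <- make_flat_record(10)
  rec$features[, "left_stride"] <- v
  rec$time <- cumsum(rec$features[, "left_stride"])
  out <- median_outlier_filter(rec)
  expect_equal(n_strides(out), 9L)
  expect_true(all(out$features[, "left_stride"] == 1))

  # constant columns: zero SD, zero deviation, nothing removed
  flat <- make_flat_record(10)
  expect_equal(n_strides(median_outlier_filter(flat)), 10L)

  # k = Inf is the identity
  expect_equal(n_strides(median_outlier_filter(rec, k = Inf)), 10L)
})

test_that("median outlier filter skips records shorter than 3 strides", {
  rec <- make_flat_record(2)
  expect_warning(out <- median_outlier_filter(rec), "fewer than 3")
  expect_equal(n_strides(out), 2L)
})

test_that("longest turn-free segment matches a brute-force scan", {
  # exhaustive scan over every (start, end) window
  brute_longest <- function(n, flag_idx) {
    best <- NULL
    for (i in seq_len(n)) for (j in i:n) {
      if (any(flag_idx >= i & flag_idx <= j)) next
      if (is.null(best) || (j - i) > (best[2L] - best[1L]))
        best <- c(i, j)
    }
    best
  }
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    stride <- runif(n, 1.0, 1.2)
    flags <- sort(sample(n, sample(0:5, 1)))
    stride[flags] <- 3.5  # unambiguous spikes
    rec <- make_flat_record(n)
    rec$features[, "left_stride"] <- stride
    rec$features[, "right_stride"] <- stride
    rec$time <- cumsum(stride)
    exp_rng <- brute_longest(n, flags)
    if (is.null(exp_rng) || exp_rng[2L] - exp_rng[1L] < 1L) {
      expect_error(longest_turn_free_segment(rec, "absolute",
                                             threshold = 2.0))
    } else {
      out <- longest_turn_free_segment(rec, "absolute", threshold = 2.0)
      expect_equal(attr(out, "segment"), exp_rng)
    }
  }
})

test_that("turn segmentation handles no-turn and tie cases", {
  rec <- make_flat_record(6)
  rec$features[, "left_stride"] <- c(1.1, 1.1, 2.9, 1.1, 1.1, 1.1)
  rec$features[, "right_stride"] <- rec$features[, "left_stride"]
  rec$time <- cumsum(rec$features[, "left_stride"])
  out <- longest_turn_free_segment(rec, "absolute", threshold = 2.0)
  expect_equal(attr(out, "segment"), c(4L, 6L))

  # no flagged strides: the whole record comes back
  flat <- make_flat_record(10)
  out <- longest_turn_free_segment(flat, "absolute", threshold = 2.0)
  expect_equal(attr(out, "segment"), c(1L, 10L))

  # two equal runs: the earlier wins
  rec$features[, "left_stride"] <- c(1.1, 1.1, 2.9, 1.1, 1.1, 2.9)
  rec$features[, "right_stride"] <- rec$features[, "left_stride"]
  rec$time <- cumsum(rec$features[, "left_stride"])
  out <- longest_turn_free_segment(rec, "absolute", threshold = 2.0)
  expect_equal(attr(out, "segment"), c(1L, 2L))
})

test_that("the robust turn rule flags spikes above median + 3 SD", {
  set.seed(9)
  stride <- runif(60, 1.05, 1.15)
  stride[c(15, 40)] <- stride[c(15, 40)] + 8 * sd(stride)
  rec <- make_flat_record(60)
  rec$features[, "left_stride"] <- stride
  rec$features[, "right_stride"] <- stride
  rec$time <- cumsum(stride)
  out <- longest_turn_free_segment(rec, "robust")
  expect_equal(attr(out, "segment"), c(16L, 39L))
})

test_that("observations preserve values and demand the five model columns", {
  set.seed(13)
  rec <- make_record(
    left_stride = runif(50, 1, 1.2), right_stride = runif(50, 1, 1.2),
    left_stance = runif(50, 0.6, 0.8), right_stance = runif(50, 0.6, 0.8),
    double_support = runif(50, 0.2, 0.4))
  obs <- to_observations(rec)
  expect_equal(nrow(obs$X), 50L)
  expect_identical(obs$X, rec$features[, MODEL_FEATURES])  # bit-exact

  rec$features <- rec$features[, 1:4]
  expect_error(to_observations(rec), "double_support")
})

test_that("the preprocessing chain only deletes rows and is idempotent", {
  set.seed(21)
  n <- 120
  # bounded noise keeps a second filter pass from firing
  base <- 1.1 + 0.05 * (2 * runif(n) - 1)
  rec <- make_record(left_stride = base, right_stride = base,
                     left_stance = base * 0.65, right_stance = base * 0.65,
                     double_support = base * 0.3, time = cumsum(base))
  rec$features[c(40, 80), c("left_stride", "right_stride")] <- 3.0
  rec$time <- cumsum(rec$features[, "left_stride"])
  out <- preprocess_record(rec)
  # every surviving row exists verbatim in the input
  key_in <- apply(rec$features, 1, paste, collapse = "|")
  key_out <- apply(out$features, 1, paste, collapse = "|")
  expect_true(all(key_out %in% key_in))
  expect_false(is.unsorted(match(key_out, key_in)))
  # idempotence on its own output (startup already removed, no turns left)
  again <- preprocess_record(out, preprocess_config(startup_cutoff_s = 0))
  expect_equal(again$features, out$features)
})
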