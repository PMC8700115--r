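# Entropy, conditional entropy, per-channel information gain, discretisation,
# per-sensor aggregation and greedy top-n selection.

test_that("entropy matches closed forms", {
  expect_equal(shannon_entropy(c(5, 5)), 1.0)
  expect_equal(shannon_entropy(c(4)), 0.0)
  expect_equal(shannon_entropy(c(2, 1, 1)), 1.5)
  expect_equal(shannon_entropy(c(1, 1, 1, 1), base = 4), 1.0)
  expect_error(shannon_entropy(c(0, 0)), "zero")
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")
})

test_that("conditional entropy weights per-feature-value entropies", {
  expect_equal(conditional_entropy(diag(c(3, 4, 5))), 0.0)
  expect_equal(conditional_entropy(matrix(2, 2, 2)), 1.0)
  # frozen from the enumeration oracle: 0.75 * H(2/3, 1/3)
  expect_equal(conditional_entropy(rbind(c(2, 1), c(0, 1))),
               0.6887218755408672, tolerance = 1e-12)
  expect_equal(conditional_entropy(rbind(c(0, 0), c(3, 3))), 1.0)
  expect_error(conditional_entropy(rbind(c(-1, 2), c(0, 1))), "non-negative")
})

test_that("channel information gain matches hand-checked cases", {
  expect_equal(channel_info_gain(rep(1, 8), rep_len(0:1, 8)), 0.0)
  expect_equal(channel_info_gain(c(0, 0, 1, 1), c("A", "A", "B", "B")), 1.0)
  # frozen from the enumeration oracle: 1 - 0.75 * H(2/3, 1/3)
  expect_equal(channel_info_gain(c(0, 0, 0, 1), c("A", "A", "B", "B")),
               0.3112781244591328, tolerance = 1e-12)
  expect_error(channel_info_gain(1:3, 1:4), "equal length")
})

test_that("information gain is bounded, symmetric and permutation-invariant", {
  withr::with_seed(42, {
    for (k in 1:300) {
      nf <- sample(2:6, 1)
      nc <- sample(2:6, 1)
      n <- sample(5:200, 1)
      f <- sample(nf, n, replace = TRUE)
      a <- sample(nc, n, replace = TRUE)
      ig <- channel_info_gain(f, a)
      expect_equal(ig, max(oracle_info_gain(f, a), 0), tolerance = 1e-9)
      expect_lte(ig, min(shannon_entropy(table(a)),
                         shannon_entropy(table(f))) + 1e-9)
      expect_gte(ig, 0)
      # symmetric form: H(A) - H(A|F) = H(F) - H(F|A)
      expect_equal(ig, channel_info_gain(a, f), tolerance = 1e-9)
      # joint permutation leaves IG unchanged
      p <- sample(n)
      expect_equal(channel_info_gain(f[p], a[p]), ig, tolerance = 1e-12)
    }
  })
})

test_that("shuffling labels against a predictive feature destroys the gain", {
  withr::with_seed(7, {
    a <- rep_len(0:1, 2000)
    f <- a                                   # perfectly predictive
    expect_equal(channel_info_gain(f, a), 1.0)
    shuffled <- replicate(20, channel_info_gain(f, sample(a)))
    expect_lt(mean(shuffled), 0.01)
  })
})

test_that("equal-frequency discretisation balances bins and clamps outliers", {
  disc <- fit_discretization(1:100, n_bins = 4)
  bins <- apply_discretization(1:100, disc)
  expect_equal(unname(table(bins)), rep(25L, 4), ignore_attr = TRUE)
  expect_equal(apply_discretization(c(-1e6, 1e6), disc), c(1L, 4L))

  const <- fit_discretization(rep(3, 50), n_bins = 20)
  ids <- apply_discretization(rep(3, 50), const)
  expect_equal(length(unique(ids)), 1)
  expect_equal(channel_info_gain(ids, rep_len(0:1, 50)), 0.0)

  ew <- fit_discretization(c(0, 10), n_bins = 5, strategy = "equal_width")
  expect_equal(apply_discretization(7.2, ew), 4L)   # 0-based bin 3
})

test_that("sensor aggregation sums channels and ranks with stable ties", {
  layout <- sensor_layout(list(a = 1L, b = 2:3, c = 4:5))
  rep_ <- sensor_info_gain(c(0.4, 0.2, 0.3, 0.25, 0.25), layout)
  tab <- rep_$table
  expect_equal(tab$gain_sum, c(0.4, 0.5, 0.5))
  expect_equal(tab$gain_mean, c(0.4, 0.25, 0.25))
  # single-channel sensor: sum = mean = channel gain
  expect_equal(tab$gain_sum[1], tab$gain_mean[1])
  # tie between b and c broken by declaration order
  expect_equal(rep_$ranking_sum, c("b", "c", "a"))
  expect_equal(rep_$ranking_mean, c("a", "b", "c"))
  expect_error(sensor_info_gain(c(0.1, 0.2), layout), "total channels")
})

test_that("greedy top-n selection returns nested channel sets in layout order", {
  layout <- sensor_layout(list(a = 1:2, b = 3:4, c = 5:6))
  rep_ <- sensor_info_gain(c(0.1, 0.1, 0.9, 0.9, 0.5, 0.5), layout)
  expect_equal(select_top_sensors(rep_, 1, "sum"), c(3L, 4L))
  expect_equal(select_top_sensors(rep_, 2, "sum"), 3:6)
  expect_equal(select_top_sensors(rep_, 3, "sum"), 1:6)
  expect_error(select_top_sensors(rep_, 0), "n must lie")
  expect_error(select_top_sensors(rep_, 4), "n must lie")
})

test_that("rank_sensors recovers a planted informativeness gradient", {
  spec <- synthetic_spec(T = 10000L, seed = 1, missing_rate = 0)
  rec <- generate_recording(spec)
  report <- rank_sensors(rec, synthetic_layout(spec), task = "activity")
  expect_equal(report$ranking_sum, planted_ranking(spec))
  expect_true(all(report$per_channel_gain >= 0))
  expect_equal(report$table$gain_sum,
               vapply(synthetic_layout(spec)$sensors,
                      function(ix) sum(report$per_channel_gain[ix]), 0),
               ignore_attr = TRUE)
})

test_that("infogain report exports a per-sensor CSV", {
  layout <- sensor_layout(list(a = 1:2, b = 3:4))
  rep_ <- sensor_info_gain(c(0.1, 0.2, 0.3, 0.4), layout)
  path <- tempfile(fileext = ".csv")
  write_infogain_csv(rep_, path)
  got <- utils::read.csv(path)
  expect_equal(got$sensor, c("a", "b"))
  expect_equal(got$gain_sum, c(0.3, 0.7))
  expect_equal(got$rank_sum, c(2L, 1L))
  unlink(path)
})
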