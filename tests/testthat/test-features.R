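test_that("descriptor examples evaluate to their closed forms", {
  expect_equal(mav(c(1, -1, 2, -2)), 1.5)
  expect_equal(mav(c(0, 0, 0)), 0)
  expect_equal(stdev(c(1, 1, 1)), 0)
  expect_equal(stdev(c(0, 2)), 1)
  expect_equal(skewness(c(-1, 0, 1)), 0)
  expect_equal(skewness(c(0, 0, 3)), 1 / sqrt(2))
  expect_equal(kurtosis(c(-1, 1)), 1)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(mav_ratio(c(1, 1), c(2, 2)), 0.5)
  expect_equal(mav_ratio(c(3, -4), c(3, -4)), 1)
  expect_equal(hjorth_activity(c(0, 2)), 1)
  expect_equal(hjorth_activity(rep(5, 10)), 0)
  expect_error(mav(numeric()), "empty")
  expect_error(rms(numeric()), "empty")
})

test_that("all nine descriptors match independent definitional oracles", {
  set.seed(41)
  for (i in 1:100) {
    y <- rnorm(sample(10:200, 1), sd = 10^runif(1, -2, 2))
    z <- rnorm(length(y))
    expect_equal(mav(y), oracle_mav(y), tolerance = 1e-10)
    expect_equal(stdev(y), oracle_stdev(y), tolerance = 1e-10)
    expect_equal(skewness(y), oracle_skewness(y), tolerance = 1e-10)
    expect_equal(kurtosis(y), oracle_kurtosis(y), tolerance = 1e-10)
    expect_equal(rms(y), oracle_rms(y), tolerance = 1e-10)
    expect_equal(mav_ratio(y, z), oracle_mav_ratio(y, z), tolerance = 1e-10)
    expect_equal(hjorth_activity(y), oracle_activity(y), tolerance = 1e-10)
    expect_equal(hjorth_mobility(y), oracle_mobility(y), tolerance = 1e-10)
    expect_equal(hjorth_complexity(y), oracle_complexity(y), tolerance = 1e-10)
  }
})

test_that("descriptors obey their scale and symmetry laws", {
  set.seed(42)
  for (i in 1:20) {
    y <- rnorm(100)
    c_ <- runif(1, 0.1, 50) * sample(c(-1, 1), 1)
    expect_equal(mav(c_ * y), abs(c_) * mav(y))
    expect_equal(stdev(c_ * y), abs(c_) * stdev(y))
    expect_equal(rms(c_ * y), abs(c_) * rms(y))
    expect_equal(hjorth_activity(c_ * y), c_^2 * hjorth_activity(y))
    expect_equal(hjorth_mobility(c_ * y), hjorth_mobility(y))
    expect_equal(hjorth_complexity(c_ * y), hjorth_complexity(y))
    expect_equal(skewness(-y), -skewness(y))
    expect_equal(kurtosis(c_ * y), kurtosis(y))
    # fourth-moment inequality: kurtosis >= skewness^2 + 1
    expect_gte(kurtosis(y), skewness(y)^2 + 1)
    # algebraic identity: rms^2 = stdev^2 + mean^2
    expect_equal(rms(y)^2, stdev(y)^2 + mean(y)^2)
    # reciprocity of the band ratio
    z <- rnorm(80)
    expect_equal(mav_ratio(y, z) * mav_ratio(z, y), 1)
  }
})

test_that("moment statistics converge to their distributional values", {
  set.seed(43)
  g <- rnorm(1e5)
  expect_equal(kurtosis(g), 3, tolerance = 0.1 / 3)
  expect_equal(hjorth_mobility(g), sqrt(2), tolerance = 0.03)
  expect_gt(hjorth_complexity(g), 1)  # white noise differences are "faster"

  w <- 2 * pi * 5 / 1e4
  s <- sin(w * seq_len(1e4))
  expect_equal(hjorth_mobility(s), 2 * sin(w / 2), tolerance = 0.01)
  expect_equal(hjorth_complexity(s), 1, tolerance = 0.02)
})

test_that("degenerate sub-bands hit the zero guards, not NaN", {
  expect_identical(skewness(rep(2, 5)), 0)
  expect_identical(kurtosis(rep(2, 5)), 0)
  expect_identical(hjorth_mobility(rep(2, 5)), 0)
  expect_identical(hjorth_complexity(rep(2, 5)), 0)
  expect_identical(mav_ratio(c(1, 2), c(0, 0)), 0)
})

test_that("the as-printed moment variant takes the outer square root", {
  set.seed(44)
  y <- rexp(200)  # right-skewed
  expect_equal(skewness(y, "as_printed"), sqrt(oracle_skewness(y)))
  expect_equal(kurtosis(y, "as_printed"), sqrt(oracle_kurtosis(y)))
  expect_identical(skewness(-y, "as_printed"), 0)  # negative skew guards to 0
})

test_that("the feature vector has 143 uniquely named finite entries", {
  set.seed(45)
  sb <- swt_packet(rnorm(256))
  v <- extract_vector(sb, "normal")
  expect_length(v, 143L)
  expect_length(unique(names(v)), 143L)
  expect_true(all(is.finite(v)))
  expect_identical(attr(v, "label"), "normal")
  expect_identical(names(v)[1:2], c("n00.mav", "n00.stdev"))
  expect_identical(names(v)[143], "ratio.n14_n15")
  # determinism
  expect_identical(extract_vector(sb, "normal"), v)
})

test_that("identical leaves give unit band ratios; leaf-count contract holds", {
  y <- rnorm(64)
  sb <- structure(list(leaves = rep(list(y), 16), wavelet = "db4", depth = 4L,
                       tree = "packet16", freq_order = 1:16),
                  class = "subband_set")
  v <- extract_vector(sb)
  expect_true(all(v[grep("^ratio", names(v))] == 1))
})

test_that("table extraction is uniform, labeled, and shaped n x 144", {
  ds <- generate_dataset(synthetic_spec(n_per_class = 2, duration_s = 2, seed = 3))
  tab <- extract_table(ds)
  expect_identical(dim(tab), c(6L, 144L))
  expect_identical(names(tab)[1:143], feature_names())
  expect_identical(names(tab)[144], "label")
  expect_true(all(vapply(tab[1:143], is.numeric, logical(1))))

  single <- eeg_dataset(list(generate_record("ictal", synthetic_spec(duration_s = 2), 1)))
  expect_identical(dim(extract_table(single)), c(1L, 144L))
})
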