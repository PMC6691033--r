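test_that("reference white, black point and grays behave in Luv and Lab", {
  w_luv <- rgb_to_luv(c(255, 255, 255))
  expect_equal(unname(w_luv[1, "L"]), 100, tolerance = 1e-4)
  expect_equal(unname(w_luv[1, c("u", "v")]), c(0, 0), tolerance = 1e-4)

  w_lab <- rgb_to_lab(c(255, 255, 255))
  expect_equal(unname(w_lab[1, "L"]), 100, tolerance = 1e-4)
  expect_equal(unname(w_lab[1, c("a", "b")]), c(0, 0), tolerance = 1e-4)

  expect_equal(unname(rgb_to_luv(c(0, 0, 0))[1, "L"]), 0, tolerance = 1e-8)
  expect_equal(unname(rgb_to_lab(c(0, 0, 0))[1, "L"]), 0, tolerance = 1e-8)

  for (k in c(1, 64, 119, 200, 254)) {
    gl <- rgb_to_luv(c(k, k, k))
    gb <- rgb_to_lab(c(k, k, k))
    expect_equal(unname(gl[1, c("u", "v")]), c(0, 0), tolerance = 1e-6)
    expect_equal(unname(gb[1, c("a", "b")]), c(0, 0), tolerance = 1e-6)
  }
})

test_that("conversions agree with an independent reference implementation", {
  skip_if_not_installed("farver")
  # reference color libraries round the sRGB matrix and white point
  # differently and disagree among themselves at the ~1e-2 level, so the
  # cross-library check runs at 0.02 absolute per coordinate
  set.seed(11)
  rgb <- matrix(sample.int(256, 300, replace = TRUE) - 1L, ncol = 3)
  ref_lab <- as.matrix(farver::convert_colour(rgb, "rgb", "lab"))
  ref_luv <- as.matrix(farver::convert_colour(rgb, "rgb", "luv"))
  expect_lt(max(abs(unname(rgb_to_lab(rgb)) - unname(ref_lab))), 0.02)
  expect_lt(max(abs(unname(rgb_to_luv(rgb)) - unname(ref_luv))), 0.02)
})

test_that("L is in [0, 100] and identical between Luv and Lab", {
  set.seed(21)
  rgb <- rbind(matrix(sample.int(256, 300, replace = TRUE) - 1L, ncol = 3),
               c(0, 0, 0), c(255, 255, 255))
  luv <- rgb_to_luv(rgb)
  lab <- rgb_to_lab(rgb)
  expect_true(all(luv[, "L"] >= 0 & luv[, "L"] <= 100 + 1e-9))
  expect_true(all(lab[, "L"] >= 0 & lab[, "L"] <= 100 + 1e-9))
  expect_equal(luv[, "L"], lab[, "L"], tolerance = 1e-10)
})

test_that("non-integer and out-of-range RGB are rejected", {
  expect_error(rgb_to_luv(c(0.5, 10, 10)), "integers")
  expect_error(rgb_to_lab(c(-1, 0, 0)), "\\[0, 255\\]")
  expect_error(rgb_to_luv(c(0, 0, 256)), "\\[0, 255\\]")
  expect_error(rgb_to_luv(c(0, NA, 0)), "missing")
})

test_that("lab_to_rgb inverts rgb_to_lab up to integer rounding", {
  set.seed(31)
  rgb <- matrix(sample.int(256, 150, replace = TRUE) - 1L, ncol = 3)
  back <- lab_to_rgb(rgb_to_lab(rgb))
  expect_true(all(abs(back - rgb) <= 1))
})

test_that("Luv distance is Euclidean and metric-sane", {
  expect_equal(luv_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(luv_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(41)
  for (i in 1:20) {
    p <- runif(3, -100, 100); q <- runif(3, -100, 100)
    expect_equal(luv_distance(p, q), sqrt(sum((p - q)^2)))
    expect_equal(luv_distance(p, q), luv_distance(q, p))
    expect_gte(luv_distance(p, q), 0)
  }
})

test_that("CIEDE2000 reproduces the published verification pairs to 4 dp", {
  # Standard verification dataset for the formula (expected values
  # recomputed independently with farver::compare_colour, which matches
  # the published table to 4 decimals).
  pairs <- rbind(
    c(50, 2.6772, -79.7751, 50, 0, -82.7485, 2.0425),
    c(50, 3.1571, -77.2803, 50, 0, -82.7485, 2.8615),
    c(50, 2.8361, -74.0200, 50, 0, -82.7485, 3.4412),
    c(50, -1.3802, -84.2814, 50, 0, -82.7485, 1.0000),
    c(50, -1.1848, -84.8006, 50, 0, -82.7485, 1.0000),
    c(50, -0.9009, -85.5211, 50, 0, -82.7485, 1.0000),
    c(50, 0, 0, 50, -1, 2, 2.3669),
    c(50, -1, 2, 50, 0, 0, 2.3669),
    c(50, 2.49, -0.001, 50, -2.49, 0.0009, 7.1792),
    c(50, 2.49, -0.001, 50, -2.49, 0.0010, 7.1792),
    c(50, 2.49, -0.001, 50, -2.49, 0.0011, 7.2195),
    c(50, 2.49, -0.001, 50, -2.49, 0.0012, 7.2195),
    c(50, -0.001, 2.49, 50, 0.0009, -2.49, 4.8045),
    c(50, -0.001, 2.49, 50, 0.0010, -2.49, 4.8045),
    c(50, -0.001, 2.49, 50, 0.0011, -2.49, 4.7461),
    c(50, 2.5, 0, 50, 0, -2.5, 4.3065),
    c(50, 2.5, 0, 73, 25, -18, 27.1492),
    c(50, 2.5, 0, 61, -5, 29, 22.8977),
    c(50, 2.5, 0, 56, -27, -3, 31.9030),
    c(50, 2.5, 0, 58, 24, 15, 19.4535),
    c(50, 2.5, 0, 50, 3.1736, 0.5854, 1.0000),
    c(50, 2.5, 0, 50, 3.2972, 0, 1.0000),
    c(50, 2.5, 0, 50, 1.8634, 0.5757, 1.0000),
    c(50, 2.5, 0, 50, 3.2592, 0.3350, 1.0000),
    c(60.2574, -34.0099, 36.2677, 60.4626, -34.1751, 39.4387, 1.2644),
    c(63.0109, -31.0961, -5.8663, 62.8187, -29.7946, -4.0864, 1.2630),
    c(61.2901, 3.7196, -5.3901, 61.4292, 2.2480, -4.9620, 1.8731),
    c(35.0831, -44.1164, 3.7933, 35.0232, -40.0716, 1.5901, 1.8645),
    c(22.7233, 20.0904, -46.6940, 23.0331, 14.9730, -42.5619, 2.0373),
    c(36.4612, 47.8580, 18.3852, 36.2715, 50.5065, 21.2231, 1.4146),
    c(90.8027, -2.0831, 1.4410, 91.1528, -1.6435, 0.0447, 1.4441),
    c(90.9257, -0.5406, -0.9208, 88.6381, -0.8985, -0.7239, 1.5381),
    c(6.7747, -0.2908, -2.4247, 5.8714, -0.0985, -2.2286, 0.6377),
    c(2.0776, 0.0795, -1.1350, 0.9033, -0.0636, -0.5514, 0.9082))
  got <- delta_e2000(pairs[, 1:3], pairs[, 4:6])
  expect_equal(round(got, 4), pairs[, 7])
})

test_that("CIEDE2000 is symmetric, nonnegative, zero iff identical", {
  set.seed(51)
  lab <- cbind(runif(40, 0, 100), runif(40, -90, 90), runif(40, -90, 90))
  a <- lab[1:20, ]; b <- lab[21:40, ]
  expect_equal(delta_e2000(a, b), delta_e2000(b, a))
  expect_true(all(delta_e2000(a, b) > 0))
  expect_equal(delta_e2000(a, a), rep(0, 20))
})

test_that("CIEDE2000 matches an independent implementation on random pairs", {
  skip_if_not_installed("farver")
  set.seed(61)
  a <- cbind(runif(50, 0, 100), runif(50, -90, 90), runif(50, -90, 90))
  b <- cbind(runif(50, 0, 100), runif(50, -90, 90), runif(50, -90, 90))
  ref <- vapply(seq_len(50), function(i) {
    farver::compare_colour(a[i, , drop = FALSE], b[i, , drop = FALSE],
                           from_space = "lab", method = "cie2000")[1, 1]
  }, numeric(1))
  expect_equal(delta_e2000(a, b), ref, tolerance = 1e-6)
})
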