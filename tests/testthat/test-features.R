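test_that("sub-window aggregation of a constant signal is exact", {
  w <- constant_window(0.5, 0, -1, n = 15000)
  agg <- subwindow_aggregate(w)
  expect_equal(nrow(agg), 120)
  expect_true(all(agg$ave_x == 0.5 & agg$ave_y == 0 & agg$ave_z == -1))
  expect_true(all(agg$abs_x == 0.5 & agg$abs_y == 0 & agg$abs_z == 1))
  expect_true(all(agg$std_x == 0 & agg$std_y == 0 & agg$std_z == 0))
})

test_that("a square wave has closed-form sub-window moments", {
  # +/- 1 G alternating; 4 s sub-windows hold an even sample count
  n <- 25 * 8
  w <- tibble::tibble(
    x_g = rep(c(1, -1), n / 2), y_g = rep(0, n), z_g = rep(-1, n)
  )
  agg <- subwindow_aggregate(w, tsw = 4)
  expect_equal(agg$ave_x, rep(0, 2))
  expect_equal(agg$abs_x, rep(1, 2))
  expect_equal(agg$std_x, rep(1, 2))
})

test_that("indivisible windows are rejected", {
  w <- constant_window(0, 0, -1, n = 15000 + 1)
  expect_error(subwindow_aggregate(w), "divisible")
})

test_that("normalization divides by the in-window maximum", {
  expect_equal(as.numeric(normalize_series(c(2, -4, 1))), c(0.5, -1, 0.25))
  z <- normalize_series(rep(0, 5))
  expect_true(all(z == 0))
  expect_true(attr(z, "degenerate"))
  set.seed(2)
  for (i in 1:20) {
    v <- rnorm(50, sd = runif(1, 0.1, 3))
    expect_equal(max(abs(normalize_series(v))), 1)
  }
})

test_that("a static gravity window has closed-form features", {
  w <- constant_window(0, 0, -1)
  f <- extract_features(w)
  expect_equal(ncol(f), 23)
  expect_equal(f$vebda, 1)
  expect_equal(f$obda, 0)
  expect_equal(f$vstd_std_x, 0)
  expect_equal(f$vmax_std_z, 0)
  # constant series are degenerate for correlation
  expect_equal(f$rho_xy, 0)
  expect_true(attr(f, "degenerate"))
})

test_that("identical axes correlate perfectly", {
  set.seed(3)
  v <- rnorm(1500, 0, 0.3)
  w <- tibble::tibble(x_g = v, y_g = v, z_g = rnorm(1500, -1, 0.1))
  f <- extract_features(w, tsw = 5)
  expect_equal(f$rho_xy, 1)
})

test_that("feature extraction matches the per-sample oracle", {
  for (seed in 1:20) {
    w <- random_window(n = 3000, seed = seed)
    got <- as.numeric(extract_features(w))
    want <- unname(naive_features(w))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("vstd and vmax scale linearly with gain; rho is gain-invariant", {
  w <- random_window(n = 3000, seed = 4)
  f1 <- extract_features(w)
  gain <- 2.7
  f2 <- extract_features(dplyr::mutate(w, x_g = gain * x_g))
  x_feats <- grep("_x$", feature_names()[1:18], value = TRUE)
  for (nm in x_feats) expect_equal(f2[[nm]], gain * f1[[nm]], tolerance = 1e-12)
  for (nm in c("rho_xy", "rho_xz", "rho_yz")) {
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-12)
  }
})

test_that("the feature vector has 23 entries, 18 from the statistical stage", {
  expect_length(feature_names(), 23)
  expect_equal(sum(grepl("^(vstd|vmax)_", feature_names())), 18)
  f <- extract_features(random_window(n = 1500, seed = 5))
  expect_identical(names(f), feature_names())
})

test_that("perfectly correlated copies collapse to one retained feature", {
  set.seed(6)
  base <- rnorm(100)
  feats <- tibble::tibble(
    vstd_ave_x = base, vmax_ave_x = 2 * base + 1, # clones of each other
    vebda = rnorm(100), obda = rnorm(100)
  )
  red <- reduce_features(feats, threshold = 0.75)
  expect_length(intersect(red$selected, c("vstd_ave_x", "vmax_ave_x")), 1)
  expect_true(all(c("vebda", "obda") %in% red$selected))
})

test_that("mutually independent features all survive screening", {
  set.seed(7)
  feats <- tibble::as_tibble(
    stats::setNames(as.data.frame(matrix(rnorm(200 * 23), 200)), feature_names())
  )
  red <- reduce_features(feats, threshold = 0.75)
  expect_length(red$selected, 23)
})

test_that("a clone triplet among ten features leaves eight retained", {
  set.seed(8)
  base <- rnorm(200)
  nm <- feature_names()[1:10]
  cols <- c(
    list(base, base * 3, -base),                  # three clones (incl. anti-correlated)
    lapply(1:7, function(i) rnorm(200))           # seven independent
  )
  feats <- tibble::as_tibble(stats::setNames(as.data.frame(cols), nm))
  red <- reduce_features(feats, threshold = 0.75)
  expect_length(red$selected, 8)
  expect_length(intersect(red$selected, nm[1:3]), 1)
})

test_that("raising the threshold never shrinks the retained set", {
  study <- small_study()
  counts <- vapply(seq(0.5, 0.95, by = 0.05), function(thr) {
    length(suppressWarnings(reduce_features(study$features, thr))$selected)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("reduction validates its input size", {
  f <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(rnorm(23), 1)), feature_names()
  ))
  expect_error(reduce_features(f), "at least 2")
  f10 <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(rnorm(230), 10)), feature_names()
  ))
  expect_warning(reduce_features(f10), "fewer than 30")
})
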