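test_that("Shapiro-Wilk W is affine invariant and errors are raised", {
  set.seed(1)
  x <- rnorm(50)
  expect_equal(shapiro_wilk(x)$W, shapiro_wilk(5 * x + 2)$W,
               tolerance = 1e-12)
  expect_error(shapiro_wilk(c(1, 2)), class = "zoopcurves_input_error")
  expect_error(shapiro_wilk(rep(1, 10)), class = "zoopcurves_input_error")
})

test_that("the normality test separates null from skewed alternatives", {
  null_pass <- alt_reject <- 0
  for (s in 1:100) {
    set.seed(s)
    if (shapiro_wilk(rnorm(50))$p > 0.05) null_pass <- null_pass + 1
    if (shapiro_wilk(stats::rexp(50))$p < 0.05) alt_reject <- alt_reject + 1
  }
  expect_gte(null_pass, 90)
  expect_gte(alt_reject, 90)
})

test_that("transform selection follows the priority tie rule", {
  set.seed(3)
  x <- exp(rnorm(200))
  ch <- select_transform(x)
  # ln and log10 tie exactly (affine-related); ln is listed first
  expect_equal(ch$transform, "ln")
  p_ln <- ch$results$p[ch$results$transform == "ln"]
  p_l10 <- ch$results$p[ch$results$transform == "log10"]
  expect_equal(p_ln, p_l10, tolerance = 1e-9)
  expect_error(select_transform(c(-1, -2, -3), candidates = c("sqrt", "ln")),
               class = "zoopcurves_input_error")
})

test_that("element-wise transforms hit their fixed points", {
  expect_equal(apply_transform(27, "cbrt"), 3)
  expect_equal(apply_transform(1, "ln"), 0)
  expect_equal(apply_transform(0, "sqrt"), 0)
  expect_equal(apply_transform(100, "log10"), 2)
  expect_error(apply_transform(c(1, 0), "ln"),
               class = "zoopcurves_input_error")
})

test_that("significance stars follow the legend rule", {
  expect_equal(stars(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", "ns"))
})

test_that("Spearman matrix matches the rank formula and permutation oracle", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  sm <- spearman_matrix(data.frame(x = x, y = y))
  expect_equal(sm$rho["x", "y"], 0.8)
  expect_equal(sm$rho["x", "x"], 1)
  sm2 <- spearman_matrix(data.frame(a = x, b = -x))
  expect_equal(sm2$rho["a", "b"], -1)
  # symmetry and unit diagonal
  expect_equal(sm$rho, t(sm$rho))
  # monotone-transform invariance
  sm3 <- spearman_matrix(data.frame(x = exp(x), y = y^3))
  expect_equal(sm3$rho["x", "y"], 0.8)
  # exact-permutation oracle for small n (tie-free)
  set.seed(7)
  for (i in 1:20) {
    a <- sample(100, 6); b <- sample(100, 6)
    sp <- spearman_matrix(data.frame(a = a, b = b))
    or <- spearman_perm(a, b)
    expect_equal(sp$rho["a", "b"], or$rho, tolerance = 1e-12)
  }
  # pairwise-complete handling flags under-observed cells
  smna <- spearman_matrix(data.frame(a = c(1, 2, NA, NA, NA),
                                     b = c(2, 1, NA, NA, NA)))
  expect_true(is.na(smna$rho["a", "b"]))
})

test_that("collinearity filter keeps the more normal member", {
  set.seed(5)
  x <- rnorm(150)
  # strongly collinear with x, but logistic-squashed: none of the four
  # candidate transforms can normalize it
  y <- stats::plogis(2 * (x + rnorm(150, 0, 0.3)))
  z <- rnorm(150)                            # independent
  df <- data.frame(temperature = x + rnorm(150, 0, 3),
                   oxygen = -x + rnorm(150, 0, 3),
                   x = x, y = y, z = z)
  out <- collinearity_filter(df)
  expect_true("x" %in% out$temperature_set)
  expect_false("y" %in% out$temperature_set)
  expect_true("z" %in% out$temperature_set)
  expect_false("oxygen" %in% out$temperature_set)
  expect_false("temperature" %in% out$oxygen_set)
})

test_that("uncorrelated covariates pass the filter untouched", {
  set.seed(9)
  df <- as.data.frame(matrix(rnorm(500), 100, 5))
  names(df) <- c("temperature", "oxygen", "a", "b", "c")
  out <- collinearity_filter(df)
  expect_setequal(out$temperature_set, c("temperature", "a", "b", "c"))
  expect_setequal(out$oxygen_set, c("oxygen", "a", "b", "c"))
})

test_that("generator nutrients resolve to NO2NO3 and sets decollinearize", {
  st <- generate_stations(transect_config(n_stations = 300), seed = 21)
  env <- c("temperature", "salinity", "oxygen", "mld", "par", "no2no3",
           "po4", "sio2", "chl_a", "bbp470", "pct_micro", "pct_nano",
           "pct_pico", "dist_coast")
  out <- collinearity_filter(as.data.frame(st[, env]))
  expect_true("no2no3" %in% out$temperature_set)
  expect_false("po4" %in% out$temperature_set)
  expect_false("sio2" %in% out$temperature_set)
  # every retained pair in each set is below the threshold
  for (set in list(out$temperature_set, out$oxygen_set)) {
    sub <- out$rho[set, set]
    diag(sub) <- 0
    expect_lt(max(abs(sub)), 0.7)
  }
})
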