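test_that("a noiseless linear signal is fitted exactly", {
  set.seed(1)
  x <- runif(80)
  y <- 1 + 2 * x
  fit <- fit_additive_model(y, data.frame(x = x), k = 10)
  expect_gte(fit$pct_dev, 0.999)
  cv <- extract_curves(fit)
  line <- 2 * cv$x - mean(2 * cv$x)
  expect_lt(sqrt(mean((cv$value - line)^2)), 1e-3)
})

test_that("deviance accounting matches direct RSS/TSS computation", {
  set.seed(2)
  n <- 90
  df <- data.frame(x1 = runif(n), x2 = runif(n))
  y <- sin(4 * df$x1) + rnorm(n, 0, 0.3)
  fit <- fit_additive_model(y, df)
  rss <- sum((y - fit$fitted)^2)
  tss <- sum((y - mean(y))^2)
  expect_equal(fit$pct_dev, 1 - rss / tss, tolerance = 1e-10)
  expect_equal(fit$adj_r2,
               1 - (rss / (n - fit$edf_total)) / (tss / (n - 1)),
               tolerance = 1e-10)
})

test_that("a sine signal is recovered within tolerance", {
  set.seed(4)
  n <- 200
  x <- runif(n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.1)
  fit <- fit_additive_model(y, data.frame(x = x))
  cv <- extract_curves(fit)
  truth <- sin(2 * pi * cv$x)
  truth <- truth - mean(truth)
  expect_lt(sqrt(mean((cv$value - truth)^2)), 0.1)
})

test_that("full shrinkage drives predictions to the sample mean", {
  set.seed(5)
  df <- data.frame(x = runif(60))
  y <- sin(6 * df$x) + rnorm(60, 0.5, 0.2)
  fit <- fit_additive_model(y, df, lambda_grid = 1e12)
  expect_lt(max(abs(fit$fitted - mean(y))), 1e-3)
  expect_lt(fit$pct_dev, 0.01)
})

test_that("term ranking puts planted signal first, invariant to order", {
  set.seed(6)
  n <- 150
  df <- data.frame(s = runif(n), n1 = runif(n), n2 = runif(n))
  y <- 2 * sin(2 * pi * df$s) + rnorm(n, 0, 0.3)
  fit <- fit_additive_model(y, df)
  tt <- term_significance(fit)
  expect_equal(tt$term[1], "s")
  # zero-coefficient term contract
  drop_fit <- fit_additive_model(y, df, removed = c("n1", "n2"))
  ttd <- term_significance(drop_fit)
  expect_equal(ttd$F[ttd$term == "n1"], 0)
  expect_equal(ttd$p[ttd$term == "n1"], 1)
  # permutation invariance of the ranking
  fit2 <- fit_additive_model(y, df[, c("n2", "s", "n1")])
  tt2 <- term_significance(fit2)
  expect_equal(tt$term[1], tt2$term[1])
  expect_equal(sort(tt$F), sort(tt2$F), tolerance = 1e-6)
})

test_that("backward selection removes noise terms, keeps signal", {
  set.seed(7)
  n <- 150
  df <- data.frame(s = runif(n), n1 = runif(n))
  y <- 2 * sin(2 * pi * df$s) + rnorm(n, 0, 0.3)
  fit <- backward_select(fit_additive_model(y, df))
  kept <- fit$terms$term[!fit$terms$dropped]
  expect_true("s" %in% kept)
  # all-significant model is unchanged
  df2 <- data.frame(a = runif(n), b = runif(n))
  y2 <- 2 * df2$a + 3 * sin(2 * pi * df2$b) + rnorm(n, 0, 0.2)
  f0 <- fit_additive_model(y2, df2)
  if (all(f0$terms$p < 0.05)) {
    f1 <- backward_select(f0)
    expect_equal(f1$terms, f0$terms)
  }
})

test_that("pure-noise responses collapse to the intercept-only model", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    df <- data.frame(x1 = runif(60), x2 = runif(60))
    y <- rnorm(60)
    fit <- backward_select(fit_additive_model(y, df))
    if (all(fit$terms$dropped)) hits <- hits + 1
  }
  expect_gte(hits, 13)  # clear majority
  # intercept-only deviance is zero by definition
  set.seed(1)
  f <- fit_additive_model(rnorm(40), data.frame(x = runif(40)),
                          removed = "x")
  expect_equal(f$pct_dev, 0)
})

test_that("latitude model predicts flat for constant responses", {
  lat <- seq(-60, 70, length.out = 40)
  lg <- fit_latitude_gam(rep(2.5, 40), lat)
  expect_lte(lg$adj_r2, 0)
  expect_lt(max(abs(lg$prediction$fit - 2.5)), 1e-8)
})

test_that("latitude model resolves a planted bimodal gradient", {
  set.seed(8)
  lat <- runif(120, -70, 80)
  y <- exp(-((lat - 70) / 10)^2) + 0.8 * exp(-(lat / 10)^2) +
    rnorm(120, 0, 0.05)
  lg <- fit_latitude_gam(y, lat)
  f <- lg$prediction$fit
  ispeak <- which(diff(sign(diff(f))) == -2) + 1
  expect_gte(length(ispeak), 2)
  # prediction at observed stations reproduces fitted values
  pred_obs <- predict(lg$fit, data.frame(latitude = lat))
  expect_equal(pred_obs, lg$fit$fitted, tolerance = 1e-8)
  expect_error(fit_latitude_gam(y[1:20], lat[1:20]),
               class = "zoopcurves_model_error")
})

test_that("curves span 100 points, centre to zero, ramp for linear effects", {
  set.seed(9)
  n <- 100
  df <- data.frame(a = runif(n, 2, 7), b = runif(n))
  y <- 3 * df$a + rnorm(n, 0, 0.1)
  fit <- fit_additive_model(y, df)
  cv <- extract_curves(fit)
  expect_equal(as.integer(table(cv$covariate)), c(100L, 100L))
  expect_lt(abs(sum(cv$value[cv$covariate == "a"])), 1e-6)
  ca <- cv$value[cv$covariate == "a"]
  expect_equal(max(ca) - min(ca), 3 * diff(range(df$a)), tolerance = 1e-2)
  # removed term gives the all-zero curve
  fit2 <- fit_additive_model(y, df, removed = "b")
  cv2 <- extract_curves(fit2)
  expect_true(all(cv2$value[cv2$covariate == "b"] == 0))
})

test_that("fits are invariant to affine covariate rescaling", {
  set.seed(10)
  n <- 120
  x <- runif(n, 0, 1)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.2)
  f1 <- fit_additive_model(y, data.frame(x = x))
  f2 <- fit_additive_model(y, data.frame(x = 100 * x - 40))
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-6)
  c1 <- extract_curves(f1); c2 <- extract_curves(f2)
  expect_equal(c1$value, c2$value, tolerance = 1e-6)
})

test_that("curve shapes agree with an independent thin-plate REML fit", {
  skip_if_not_installed("mgcv")
  set.seed(11)
  n <- 200
  df <- data.frame(x = runif(n), z = runif(n))
  y <- sin(2 * pi * df$x) + 2 * df$z + rnorm(n, 0, 0.2)
  fit <- fit_additive_model(y, df)
  g <- mgcv::gam(y ~ s(x, bs = "ts") + s(z, bs = "ts"), data = df,
                 method = "REML")
  cv <- extract_curves(fit)
  for (v in c("x", "z")) {
    sub <- cv[cv$covariate == v, ]
    nd <- df[rep(1, 100), ]
    nd[[v]] <- sub$x
    pt <- stats::predict(g, nd, type = "terms")[, paste0("s(", v, ")")]
    expect_gte(cor(sub$value, pt - mean(pt)), 0.98)
  }
  expect_lt(abs(fit$pct_dev - (1 - g$deviance / g$null.deviance)), 0.05)
})
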