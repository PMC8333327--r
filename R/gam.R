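# Penalized-spline additive models: per-term smoothing parameters by
# profiled REML (or GCV) on a log-lambda grid, null-space shrinkage so the
# smoothing parameter can remove a term entirely, Wald-type F statistics,
# and backward removal of insignificant terms.

#' Fit a penalized-spline additive model
#'
#' `y = intercept + sum_j f_j(x_j) + e`, each `f_j` a penalized B-spline
#' (second-difference penalty plus a null-space shrinkage ridge, so
#' `lambda -> Inf` drives the whole term to zero).  Smoothing parameters are
#' selected term-by-term on a log-spaced 40-point grid by coordinate descent
#' (two sweeps), minimizing the profiled Gaussian restricted likelihood
#' (REML, the default) or GCV.  Rows with any missing value are dropped.
#'
#' @param y Response vector.
#' @param covariates Data frame of covariates (one smooth term each).
#' @param k Basis dimension per term; `NULL` applies
#'   [basis_dimension_rule()] capped at the number of distinct values - 1.
#' @param method `"REML"` or `"GCV"`.
#' @param shrinkage Add the null-space shrinkage ridge (default TRUE).
#' @param shrink_eps Relative size of the null-space ridge.
#' @param lambda_grid Candidate smoothing parameters (log-spaced).
#' @param sweeps Coordinate-descent sweeps over the terms.
#' @param removed Terms recorded as removed by backward selection; they are
#'   kept in the model's vocabulary (zero curves) but not fitted.
#' @return A `zc_gam`: terms table (`term`, `k`, `lambda`, `edf`, `F`, `p`,
#'   `dropped`), coefficients, covariance, fitted values, `pct_dev`
#'   (1 - RSS/TSS), `adj_r2`, `sigma2`, `n`.
#' @export
fit_additive_model <- function(y, covariates, k = NULL,
                               method = c("REML", "GCV"), shrinkage = TRUE,
                               shrink_eps = 0.1,
                               lambda_grid = 10^seq(-6, 9, length.out = 40),
                               sweeps = 2, removed = character(0)) {
  method <- match.arg(method)
  covariates <- as.data.frame(covariates)
  terms_all <- names(covariates)
  active <- setdiff(terms_all, removed)
  ok <- is.finite(y)
  for (v in active) ok <- ok & is.finite(covariates[[v]])
  n_dropped_rows <- sum(!ok)
  y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  n <- length(y)
  p <- length(active)
  if (p > 0 && n < 10 + p)
    abort("too few complete observations for the number of terms",
          class = "zoopcurves_model_error")

  tss <- sum((y - mean(y))^2)

  # ranges of every term (including removed ones) for curve extraction
  ranges <- lapply(terms_all, function(v) range(covariates[[v]],
                                                na.rm = TRUE))
  names(ranges) <- terms_all

  # a constant response carries no signal: return the flat model
  if (tss <= 0) {
    removed <- terms_all
    active <- character(0)
    p <- 0L
  }

  if (p == 0) {  # intercept-only model
    empty_terms <- if (length(removed) > 0)
      tibble::tibble(term = removed, k = NA_integer_, lambda = Inf,
                     edf = 0, F = 0, p = 1, dropped = TRUE)
    else
      tibble::tibble(term = character(0), k = integer(0),
                     lambda = numeric(0), edf = numeric(0),
                     F = numeric(0), p = numeric(0), dropped = logical(0))
    fit <- list(
      terms = empty_terms,
      vocabulary = terms_all, removed = removed, ranges = ranges,
      intercept = mean(y), beta = mean(y), bases = list(),
      colmeans = list(), blocks = list(),
      Vb = matrix(tss / max(n - 1, 1) / n, 1, 1),
      fitted = rep(mean(y), n), residuals = y - mean(y), y = y,
      covariates = covariates, n = n, rss = tss, tss = tss,
      pct_dev = 0, adj_r2 = 0, edf_total = 1,
      sigma2 = tss / max(n - 1, 1), method = method,
      n_dropped_rows = n_dropped_rows, k = k,
      call_args = list(k = k, method = method, shrinkage = shrinkage,
                       shrink_eps = shrink_eps, lambda_grid = lambda_grid,
                       sweeps = sweeps))
    class(fit) <- "zc_gam"
    return(fit)
  }

  kv <- if (is.null(k)) basis_dimension_rule(n, p) else k
  bases <- list()
  blocks <- list()
  colmeans <- list()
  Xs <- list()
  Ss <- list()
  pos <- 2L  # col 1 = intercept
  for (v in active) {
    ndist <- length(unique(covariates[[v]]))
    kj <- min(kv, ndist - 1L)
    if (kj < 3)
      abort(paste0("covariate '", v, "' has too few distinct values"),
            class = "zoopcurves_basis_error")
    bs <- build_basis(covariates[[v]], kj)
    cm <- colMeans(bs$B)
    Xc <- sweep(bs$B, 2, cm)
    XtXb <- crossprod(Xc)
    Sj <- if (shrinkage) shrinkage_penalty(bs$S, XtXb, shrink_eps)
          else {
            sc <- norm(XtXb, "F") / norm(bs$S, "F")
            bs$S * sc + diag(1e-7 * norm(XtXb, "F") / kj, kj)
          }
    bases[[v]] <- bs
    colmeans[[v]] <- cm
    Xs[[v]] <- Xc
    Ss[[v]] <- Sj
    blocks[[v]] <- c(start = pos, size = kj)
    pos <- pos + kj
  }
  X <- cbind(1, do.call(cbind, Xs))
  bstart <- vapply(blocks, `[[`, numeric(1), "start") - 1L  # 0-based
  bsize <- vapply(blocks, `[[`, numeric(1), "size")

  res <- penreg_fit_cpp(X, y, as.integer(bstart), as.integer(bsize),
                        unname(Ss), lambda_grid, as.integer(sweeps), method)

  beta <- as.numeric(res$beta)
  rss <- res$rss
  edf_total <- res$edf_total
  sigma2 <- rss / max(n - edf_total, 1)
  Vb <- res$Ainv * sigma2

  tt <- lapply(seq_along(active), function(j) {
    v <- active[j]
    s <- blocks[[v]]["start"]; kj <- blocks[[v]]["size"]
    bj <- beta[s:(s + kj - 1)]
    fj <- Xs[[v]] %*% bj
    edf_j <- res$edf[j]
    qf <- sum(fj^2)
    if (qf < 1e-12 * max(tss, 1e-12) || edf_j < 0.01) {
      Fj <- 0; pj <- 1
    } else {
      # reference df floored at 1: an F test on a fraction of a degree of
      # freedom degenerates to a point mass and would call any shrunk
      # remnant significant
      df1 <- max(edf_j, 1)
      Fj <- (qf / df1) / sigma2
      pj <- pf(Fj, df1, max(n - edf_total, 1), lower.tail = FALSE)
    }
    tibble::tibble(term = v, k = as.integer(kj), lambda = res$lambda[j],
                   edf = edf_j, F = Fj, p = pj, dropped = FALSE)
  })
  terms_tbl <- dplyr::bind_rows(tt)
  if (length(removed) > 0) {
    terms_tbl <- dplyr::bind_rows(
      terms_tbl,
      tibble::tibble(term = removed, k = NA_integer_, lambda = Inf,
                     edf = 0, F = 0, p = 1, dropped = TRUE))
  }

  fitted <- as.numeric(X %*% beta)
  fit <- list(
    terms = terms_tbl, vocabulary = terms_all, removed = removed,
    ranges = ranges, intercept = beta[1], beta = beta, bases = bases,
    colmeans = colmeans, blocks = blocks, Vb = Vb, fitted = fitted,
    residuals = y - fitted, y = y, covariates = covariates, n = n,
    rss = rss, tss = tss,
    pct_dev = 1 - rss / tss,
    adj_r2 = 1 - (rss / max(n - edf_total, 1)) / (tss / (n - 1)),
    edf_total = edf_total, sigma2 = sigma2, method = method,
    n_dropped_rows = n_dropped_rows, k = k,
    call_args = list(k = k, method = method, shrinkage = shrinkage,
                     shrink_eps = shrink_eps, lambda_grid = lambda_grid,
                     sweeps = sweeps))
  class(fit) <- "zc_gam"
  fit
}

#' @export
print.zc_gam <- function(x, ...) {
  cat("Penalized-spline additive model (", x$method, "), n = ", x$n,
      ", %Dev = ", round(100 * x$pct_dev, 1), "%, adj R2 = ",
      round(x$adj_r2, 3), "\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' Predict from a fitted additive model
#'
#' @param object A `zc_gam`.
#' @param newdata Data frame with the model's active covariates; defaults to
#'   the training data.
#' @param se.fit Also return pointwise standard errors.
#' @param ... Unused.
#' @return Vector of predictions, or a list with `fit` and `se.fit`.
#' @export
predict.zc_gam <- function(object, newdata = NULL, se.fit = FALSE, ...) {
  if (is.null(newdata)) newdata <- object$covariates
  n <- nrow(newdata)
  X <- matrix(1, n, 1)
  for (v in names(object$bases)) {
    B <- eval_basis(object$bases[[v]], newdata[[v]])
    X <- cbind(X, sweep(B, 2, object$colmeans[[v]]))
  }
  fit <- as.numeric(X %*% object$beta)
  if (!se.fit) return(fit)
  se <- sqrt(pmax(rowSums((X %*% object$Vb) * X), 0))
  list(fit = fit, se.fit = se)
}

#' Per-term significance and F ranking
#'
#' Wald-type F per smooth term (quadratic form of the term's fitted values
#' over its effective degrees of freedom, scaled by the residual variance),
#' ranked by descending F; removed terms rank last with p = 1.
#'
#' @param fit A `zc_gam`.
#' @return Tibble `term`, `edf`, `F`, `p`, `dropped`, `rank`.
#' @export
term_significance <- function(fit) {
  tt <- fit$terms[order(fit$terms$dropped, -fit$terms$F), ]
  tt$rank <- seq_len(nrow(tt))
  tt[, c("term", "edf", "F", "p", "dropped", "rank")]
}

#' Backward removal of insignificant terms
#'
#' Iteratively refits, removing the single least-significant term with
#' `p >= alpha`, until every remaining term has `p < alpha`.  Removed terms
#' stay in the model vocabulary with zero curves.  If everything goes, the
#' intercept-only model is returned.
#'
#' @param fit A `zc_gam`.
#' @param alpha Removal threshold (default 0.05).
#' @return A reduced `zc_gam` with a `history` attribute logging removals.
#' @export
backward_select <- function(fit, alpha = 0.05) {
  history <- tibble::tibble(term = character(0), p = numeric(0))
  repeat {
    act <- fit$terms[!fit$terms$dropped, ]
    if (nrow(act) == 0) break
    worst <- act[which.max(act$p), ]
    if (worst$p < alpha) break
    history <- dplyr::bind_rows(history,
                                tibble::tibble(term = worst$term,
                                               p = worst$p))
    removed <- c(fit$removed, worst$term)
    ca <- fit$call_args
    fit <- fit_additive_model(fit$y, fit$covariates, k = ca$k,
                              method = ca$method, shrinkage = ca$shrinkage,
                              shrink_eps = ca$shrink_eps,
                              lambda_grid = ca$lambda_grid,
                              sweeps = ca$sweeps, removed = removed)
  }
  attr(fit, "history") <- history
  fit
}

#' Latitude-only additive model
#'
#' Single-smooth model of a transformed community metric against station
#' latitude, with a prediction curve and standard-error ribbon on an evenly
#' spaced latitude grid spanning the observed range.
#'
#' @param y Response (already transformed).
#' @param latitude Station latitudes.
#' @param min_stations Minimum observations (default 30).
#' @param n_grid Grid length for the prediction curve.
#' @param method Smoothness selection criterion.
#' @return List with `fit` (`zc_gam`), `prediction` (tibble `latitude`,
#'   `fit`, `se`), `adj_r2` and `p_smooth`.
#' @export
fit_latitude_gam <- function(y, latitude, min_stations = 30, n_grid = 100,
                             method = "REML") {
  ok <- is.finite(y) & is.finite(latitude)
  if (sum(ok) < min_stations)
    abort(paste0("needs at least ", min_stations, " stations"),
          class = "zoopcurves_model_error")
  y <- y[ok]; latitude <- latitude[ok]
  n <- length(y)
  kcap <- length(unique(latitude)) - 1L
  k <- min(max(3, n), kcap)
  fit <- fit_additive_model(y, data.frame(latitude = latitude), k = k,
                            method = method)
  grid <- seq(min(latitude), max(latitude), length.out = n_grid)
  pr <- predict(fit, data.frame(latitude = grid), se.fit = TRUE)
  list(fit = fit,
       prediction = tibble::tibble(latitude = grid, fit = pr$fit,
                                   se = pr$se.fit),
       adj_r2 = fit$adj_r2,
       p_smooth = if (nrow(fit$terms) > 0) fit$terms$p[1] else 1)
}
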