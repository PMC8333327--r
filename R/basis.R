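# Penalized B-spline building blocks for the additive-model engine.

#' Basis dimension rule
#'
#' The per-term basis dimension is the number of available observations
#' divided by the number of covariates (floored), never below `k_min`.
#' Callers additionally cap k at the number of distinct covariate values
#' minus one to avoid rank deficiency.
#'
#' @param n_obs Number of observations.
#' @param n_covariates Number of smooth terms.
#' @param k_min Lower bound (default 3).
#' @return Integer basis dimension.
#' @export
#' @examples
#' basis_dimension_rule(100, 10)  # 10
basis_dimension_rule <- function(n_obs, n_covariates, k_min = 3) {
  if (n_covariates < 1 || n_obs <= n_covariates)
    abort("need n_obs > n_covariates >= 1", class = "zoopcurves_model_error")
  max(k_min, floor(n_obs / n_covariates))
}

#' Build a penalized B-spline basis
#'
#' Cubic B-splines (quadratic when `k = 3`) on equally spaced knots over the
#' observed range, with a second-difference penalty on the coefficients.
#' With equally spaced knots the penalty's null space contains exactly the
#' constant and linear functions, and the basis functions form a partition
#' of unity.
#'
#' @param x Covariate values.
#' @param k Basis dimension (>= 3); needs at least `k` distinct values.
#' @return A `zc_basis`: list with the basis matrix `B` (n x k), penalty `S`
#'   (k x k), `knots`, `degree`, `k` and the data range.
#' @export
build_basis <- function(x, k) {
  x <- as.numeric(x)
  ux <- unique(x[is.finite(x)])
  if (k < 3) abort("k must be >= 3", class = "zoopcurves_basis_error")
  if (length(ux) < k)
    abort(paste0("need at least k = ", k, " distinct values"),
          class = "zoopcurves_basis_error")
  degree <- if (k >= 4) 3L else 2L
  n_int <- k - degree - 1L
  rng <- range(ux)
  inner <- seq(rng[1], rng[2], length.out = n_int + 2L)
  h <- diff(rng) / (n_int + 1L)
  knots <- c(rng[1] - degree:1 * h, inner, rng[2] + 1:degree * h)
  B <- splines::splineDesign(knots, x, ord = degree + 1L, outer.ok = TRUE)
  D <- diff(diag(k), differences = 2)
  S <- crossprod(D)
  out <- list(B = B, S = S, knots = knots, degree = degree, k = k, range = rng)
  class(out) <- "zc_basis"
  out
}

# Evaluate a zc_basis at new points (clamped to the training range so the
# spline stays inside its knot span).
eval_basis <- function(basis, x) {
  x <- pmin(pmax(as.numeric(x), basis$range[1]), basis$range[2])
  splines::splineDesign(basis$knots, x, ord = basis$degree + 1L,
                        outer.ok = TRUE)
}

# Augment the second-difference penalty with a null-space shrinkage ridge so
# that lambda -> Inf removes the whole term (constant/linear parts included),
# then normalize so lambdas are comparable across terms.
shrinkage_penalty <- function(S, XtX_block, eps = 0.1) {
  eg <- eigen(S, symmetric = TRUE)
  vals <- eg$values
  pos <- vals > max(vals) * 1e-8
  vals[!pos] <- eps * min(vals[pos])
  St <- eg$vectors %*% (vals * t(eg$vectors))
  St <- (St + t(St)) / 2
  St * (norm(XtX_block, "F") / norm(St, "F"))
}
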