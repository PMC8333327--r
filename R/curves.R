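# Covariate-specific smooth curves on a common 1-100 index and their
# assembly into multivariate series for shape clustering.

#' Extract covariate-specific smooth curves
#'
#' Evaluates each term's centred partial effect at 100 evenly spaced points
#' between the covariate's observed minimum and maximum (an index scale of
#' 1-100 spanning the observed range).  Curves are centred to zero mean over
#' the grid; terms removed by backward selection yield the zero curve.
#'
#' @param fit A `zc_gam`.
#' @param n_grid Number of grid points (default 100).
#' @return A `zc_curves` tibble: `covariate`, `grid_index`, `x`, `value`,
#'   `se`.
#' @export
extract_curves <- function(fit, n_grid = 100) {
  out <- lapply(fit$vocabulary, function(v) {
    rng <- fit$ranges[[v]]
    xg <- seq(rng[1], rng[2], length.out = n_grid)
    if (v %in% names(fit$bases)) {
      Bc <- sweep(eval_basis(fit$bases[[v]], xg), 2, fit$colmeans[[v]])
      s <- fit$blocks[[v]]["start"]; kj <- fit$blocks[[v]]["size"]
      bj <- fit$beta[s:(s + kj - 1)]
      val <- as.numeric(Bc %*% bj)
      Vj <- fit$Vb[s:(s + kj - 1), s:(s + kj - 1)]
      se <- sqrt(pmax(rowSums((Bc %*% Vj) * Bc), 0))
      val <- val - mean(val)
    } else {
      val <- rep(0, n_grid)
      se <- rep(0, n_grid)
    }
    tibble::tibble(covariate = v, grid_index = seq_len(n_grid), x = xg,
                   value = val, se = se)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("zc_curves", class(out))
  out
}

#' Assemble fitted-curve sets into multivariate series
#'
#' Models with explained deviance above `dev_threshold` become one
#' multivariate series each: the per-covariate 100-point curves are stacked
#' as dimensions in a fixed covariate order shared across the comparison
#' set, and scaled so that dynamic time warping compares response shapes
#' rather than response-scale units.  Covariates a model never fitted are
#' zero-filled.
#'
#' Scaling modes: `"model"` (default) divides all of a model's curves by one
#' factor (the largest per-curve standard deviation), removing the response
#' scale while preserving the relative amplitudes of the model's covariate
#' responses; `"curve"` z-scores every curve to unit variance (which also
#' amplifies weakly supported, near-flat curves into full-weight
#' dimensions); `"none"` keeps raw amplitudes.
#'
#' @param curve_sets Named list of `zc_curves`, one per model.
#' @param pct_dev Numeric vector of explained deviances, aligned with
#'   `curve_sets`.
#' @param dev_threshold Retain models with `pct_dev > dev_threshold`
#'   (default 0.40).
#' @param standardize `"model"`, `"curve"` or `"none"`.
#' @return A `zc_series` list of `(100 x d)` matrices with attributes
#'   `ids` and `covariates`.
#' @export
assemble_series <- function(curve_sets, pct_dev, dev_threshold = 0.40,
                            standardize = c("model", "curve", "none")) {
  standardize <- match.arg(standardize)
  stopifnot(length(curve_sets) == length(pct_dev))
  keep <- which(pct_dev > dev_threshold)
  if (length(keep) < 3)
    abort("fewer than 3 models above the deviance threshold",
          class = "zoopcurves_cluster_error")
  vocab <- unique(unlist(lapply(curve_sets[keep],
                                function(cs) unique(cs$covariate))))
  series <- lapply(keep, function(i) {
    cs <- curve_sets[[i]]
    mat <- sapply(vocab, function(v) {
      sub <- cs[cs$covariate == v, ]
      if (nrow(sub) == 0) return(rep(0, 100))
      val <- sub$value[order(sub$grid_index)]
      if (standardize == "curve") {
        s <- sd(val)
        val <- if (s > 1e-12) (val - mean(val)) / s else val * 0
      }
      val
    })
    mat <- matrix(mat, ncol = length(vocab),
                  dimnames = list(NULL, vocab))
    if (standardize == "model") {
      s <- max(apply(mat, 2, sd))
      if (s > 1e-12) mat <- mat / s
    }
    mat
  })
  names(series) <- names(curve_sets)[keep]
  attr(series, "ids") <- names(curve_sets)[keep]
  attr(series, "covariates") <- vocab
  class(series) <- "zc_series"
  series
}
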