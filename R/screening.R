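# Normality-based transform selection, Spearman correlation screens, and the
# collinearity filter that defines the parallel modelling covariate sets.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper returning the W statistic and p-value; W is invariant under
#' affine transforms of the sample.
#'
#' @param x Numeric sample, 3 <= n <= 5000, not all identical.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3)
    abort("need at least 3 finite values", class = "zoopcurves_input_error")
  if (length(x) > 5000)
    abort("n must be <= 5000", class = "zoopcurves_input_error")
  if (var(x) == 0)
    abort("zero variance sample", class = "zoopcurves_input_error")
  ht <- shapiro.test(x)
  list(W = unname(ht$statistic), p = unname(ht$p.value))
}

transform_funs <- list(
  sqrt = sqrt,
  ln = log,
  log10 = log10,
  cbrt = function(x) sign(x) * abs(x)^(1 / 3)
)

#' Apply one of the four candidate transforms
#'
#' `sqrt`, `ln`, `log10` or `cbrt` (cube root, the normalising reading of a
#' "cubic" transform for right-skewed abundances).
#'
#' @param x Numeric vector.
#' @param transform One of `"sqrt"`, `"ln"`, `"log10"`, `"cbrt"`.
#' @return Transformed values.
#' @export
apply_transform <- function(x, transform) {
  if (!transform %in% names(transform_funs))
    abort(paste0("unknown transform: ", transform),
          class = "zoopcurves_input_error")
  bad <- switch(transform,
                sqrt = x < 0, ln = x <= 0, log10 = x <= 0,
                cbrt = rep(FALSE, length(x)))
  if (any(bad, na.rm = TRUE))
    abort(paste0("transform '", transform, "' undefined at ",
                 sum(bad, na.rm = TRUE), " value(s)"),
          class = "zoopcurves_input_error")
  transform_funs[[transform]](x)
}

#' Pick the transform giving the most normal distribution
#'
#' Applies each candidate (skipping those undefined for the data), runs a
#' Shapiro-Wilk test, and returns the candidate with the largest p-value.
#' `ln` and `log10` always tie (they are affine-related, so W is identical);
#' ties are broken by the fixed priority order `sqrt < ln < log10 < cbrt`
#' (first listed wins).
#'
#' @param x Positive numeric sample.
#' @param candidates Subset of the four transform names.
#' @return List with `transform` (chosen id) and `results` (tibble of
#'   per-candidate W and p).
#' @export
select_transform <- function(x, candidates = c("sqrt", "ln", "log10", "cbrt")) {
  x <- x[is.finite(x)]
  if (length(x) < 3)
    abort("need at least 3 values", class = "zoopcurves_input_error")
  res <- lapply(candidates, function(tr) {
    ok <- switch(tr, sqrt = all(x >= 0), ln = all(x > 0),
                 log10 = all(x > 0), cbrt = TRUE)
    if (!ok) return(tibble::tibble(transform = tr, W = NA_real_, p = -Inf))
    y <- transform_funs[[tr]](x)
    if (var(y) == 0) return(tibble::tibble(transform = tr, W = NA_real_, p = -Inf))
    sw <- shapiro_wilk(y)
    tibble::tibble(transform = tr, W = sw$W, p = sw$p)
  })
  res <- dplyr::bind_rows(res)
  if (all(res$p == -Inf))
    abort("no applicable transform", class = "zoopcurves_input_error")
  best <- res$p >= max(res$p) - 1e-9  # ties at numerical precision
  list(transform = res$transform[which(best)[1]], results = res)
}

#' Significance stars
#'
#' `p < 0.001` = `***`, `p < 0.01` = `**`, `p < 0.05` = `*`, else `ns`.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @return Character label(s).
#' @export
stars <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# Spearman rho with t-approximation p for one pair (pairwise-complete)
spearman_pair <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rank(x[ok]), rank(y[ok]))  # Pearson on mid-ranks
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Pairwise Spearman rank-correlation matrix
#'
#' Rho is the Pearson correlation of mid-ranks (average ranks for ties),
#' computed on pairwise-complete observations; p-values use the
#' t-approximation with n - 2 degrees of freedom; significance labels follow
#' [stars()].
#'
#' @param df Data frame of numeric variables.
#' @return List of matrices `rho`, `p`, `n`, `stars`, plus a long-format
#'   tibble `table` (`var1`, `var2`, `rho`, `p`, `stars`, `n`).
#' @export
spearman_matrix <- function(df) {
  df <- as.data.frame(df)
  vars <- names(df)
  k <- length(vars)
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    rho[i, i] <- 1; p[i, i] <- 0; nmat[i, i] <- sum(is.finite(df[[i]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      sp <- spearman_pair(df[[i]], df[[j]])
      rho[i, j] <- rho[j, i] <- sp$rho
      p[i, j] <- p[j, i] <- sp$p
      nmat[i, j] <- nmat[j, i] <- sp$n
    }
  }
  st <- matrix(stars(p), k, k, dimnames = list(vars, vars))
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  p_vec <- p[idx]
  tab <- tibble::tibble(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
                        rho = rho[idx], p = p_vec, stars = stars(p_vec),
                        n = nmat[idx])
  list(rho = rho, p = p, n = nmat, stars = st, table = tab)
}

#' Collinearity filter with a forced temperature/oxygen split
#'
#' Covariate pairs with `|rho| >= threshold` are resolved iteratively
#' (largest `|rho|` first) by dropping the member whose best-transform
#' distribution is further from normality (Shapiro-Wilk p of the
#' best-scoring transform among the four candidates); on near-equal
#' normality the member with more missing values is dropped, then the later
#' one alphabetically.  The forced pair is never mutually resolved: two
#' parallel covariate sets are returned, one containing temperature, one
#' oxygen.
#'
#' @param df Data frame of covariates (must contain both members of
#'   `forced_pair`).
#' @param threshold Absolute rank-correlation threshold (default 0.7).
#' @param forced_pair The two covariates to keep in parallel sets.
#' @return List with `temperature_set`, `oxygen_set` (character vectors),
#'   `dropped` (tibble log of removals), and `rho` (the full matrix).
#' @export
collinearity_filter <- function(df, threshold = 0.7,
                                forced_pair = c("temperature", "oxygen")) {
  df <- as.data.frame(df)
  if (!all(forced_pair %in% names(df)))
    abort("forced pair not in covariate table", class = "zoopcurves_input_error")
  sm <- spearman_matrix(df)
  # normality score: the best Shapiro-Wilk p over the identity and the four
  # candidate transforms (covariates, unlike responses, may legitimately be
  # used untransformed)
  normality <- vapply(names(df), function(v) {
    x <- df[[v]][is.finite(df[[v]])]
    p_id <- tryCatch(shapiro_wilk(x)$p, error = function(e) 0)
    p_tr <- tryCatch(max(select_transform(x)$results$p),
                     error = function(e) 0)
    max(p_id, p_tr, 0)
  }, numeric(1))
  n_missing <- vapply(df, function(x) sum(!is.finite(x)), numeric(1))

  resolve <- function(keep, forced_member, excluded_member) {
    dropped <- tibble::tibble(dropped = character(0), kept = character(0),
                              rho = numeric(0), reason = character(0))
    keep <- setdiff(keep, excluded_member)
    repeat {
      sub <- sm$rho[keep, keep, drop = FALSE]
      diag(sub) <- 0
      if (all(abs(sub) < threshold, na.rm = TRUE)) break
      ij <- which(abs(sub) == max(abs(sub), na.rm = TRUE), arr.ind = TRUE)[1, ]
      a <- keep[ij[1]]; b <- keep[ij[2]]
      # never drop the forced member of this set
      cand <- c(a, b)
      if (forced_member %in% cand) {
        drop <- setdiff(cand, forced_member)
        reason <- "collinear with forced covariate"
      } else if (abs(normality[a] - normality[b]) >= 1e-6) {
        drop <- if (normality[a] < normality[b]) a else b
        reason <- "less normal"
      } else if (n_missing[a] != n_missing[b]) {
        drop <- if (n_missing[a] > n_missing[b]) a else b
        reason <- "more missing values"
      } else {
        drop <- sort(cand)[2]
        reason <- "alphabetical tie-break"
      }
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        dropped = drop, kept = setdiff(cand, drop),
        rho = sub[ij[1], ij[2]], reason = reason))
      keep <- setdiff(keep, drop)
    }
    list(keep = keep, dropped = dropped)
  }

  all_vars <- names(df)
  tset <- resolve(all_vars, forced_pair[1], forced_pair[2])
  oset <- resolve(all_vars, forced_pair[2], forced_pair[1])
  list(temperature_set = tset$keep,
       oxygen_set = oset$keep,
       dropped = dplyr::bind_rows(
         dplyr::mutate(tset$dropped, set = forced_pair[1]),
         dplyr::mutate(oset$dropped, set = forced_pair[2])),
       rho = sm$rho)
}
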