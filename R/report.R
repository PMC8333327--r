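# Cross-model statistics, cross-net agreement, recovery scoring against the
# simulator's ground truth, and the summary tables.

#' Kruskal-Wallis rank test
#'
#' H from mid-ranks with the standard tie correction, referred to a
#' chi-squared distribution with (groups - 1) degrees of freedom (the
#' convention under which H is reported as a Chi2 statistic).
#'
#' @param samples List of numeric vectors (>= 2 groups).
#' @return List: `statistic` (H), `df`, `p`, `sizes`.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2)
    abort("need at least 2 groups", class = "zoopcurves_input_error")
  values <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  if (length(values) < 3)
    abort("need at least 3 values in total", class = "zoopcurves_input_error")
  ht <- kruskal.test(values, g)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), sizes = lengths(samples))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics from the pooled mid-rank means with tie-corrected
#' variance, two-sided normal p-values, and Bonferroni adjustment over all
#' pairs (capped at 1).
#'
#' @param samples Named list of numeric vectors.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return Tibble: `group1`, `group2`, `z`, `p`, `p_adjusted`.
#' @export
dunn_posthoc <- function(samples, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  gnames <- names(samples) %||% as.character(seq_along(samples))
  values <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), lengths(samples))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  nn <- lengths(samples)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(seq_along(samples), 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(c2) {
    i <- pairs[1, c2]; j <- pairs[2, c2]
    sigma <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / nn[i] + 1 / nn[j]))
    z <- (rbar[i] - rbar[j]) / sigma
    p <- 2 * pnorm(-abs(z))
    tibble::tibble(group1 = gnames[i], group2 = gnames[j],
                   z = unname(z), p = unname(p))
  })
  out <- dplyr::bind_rows(out)
  out$p_adjusted <- if (adjust == "bonferroni") pmin(1, out$p * m) else out$p
  out
}

#' Compare explained deviance across model groupings
#'
#' Kruskal-Wallis plus Dunn/Bonferroni on the %Dev of fitted models grouped
#' by net or by covariate variant, with per-group medians and interquartile
#' ranges.
#'
#' @param models Tibble with columns `pct_dev` and the grouping column.
#' @param grouping `"net_id"` or `"variant"`.
#' @return List: `test` (Kruskal-Wallis), `posthoc` (Dunn table, NULL with
#'   two groups or fewer... always computed), `summary` (medians +- IQR).
#' @export
compare_dev <- function(models, grouping = c("net_id", "variant")) {
  grouping <- match.arg(grouping)
  grp <- split(models$pct_dev, models[[grouping]])
  grp <- grp[lengths(grp) >= 2]
  if (length(grp) < 2)
    abort("need >= 2 groups with >= 2 models each",
          class = "zoopcurves_input_error")
  summ <- tibble::tibble(
    group = names(grp),
    n = lengths(grp),
    median = vapply(grp, median, numeric(1)),
    iqr = vapply(grp, stats::IQR, numeric(1)))
  list(test = kruskal_wallis(grp), posthoc = dunn_posthoc(grp),
       summary = summ)
}

#' Cross-net agreement of station metrics
#'
#' Spearman correlation per group between two nets' station-matched series
#' of a metric (abundance or median ESD).
#'
#' @param metricsA,metricsB [station_group_metrics()] tables of two nets.
#' @param metric Column to compare (default `"abundance"`).
#' @param min_shared Minimum shared stations per group (default 3).
#' @return Tibble: `group`, `rho`, `p`, `n`.
#' @export
cross_net_correlation <- function(metricsA, metricsB, metric = "abundance",
                                  min_shared = 3) {
  groups <- intersect(unique(metricsA$group), unique(metricsB$group))
  out <- lapply(groups, function(g) {
    a <- metricsA[metricsA$group == g, c("station_id", metric)]
    b <- metricsB[metricsB$group == g, c("station_id", metric)]
    j <- dplyr::inner_join(a, b, by = "station_id", suffix = c("_a", "_b"))
    j <- j[is.finite(j[[2]]) & is.finite(j[[3]]), ]
    if (nrow(j) < min_shared) return(NULL)
    sp <- spearman_pair(j[[2]], j[[3]])
    tibble::tibble(group = g, rho = sp$rho, p = sp$p, n = sp$n)
  })
  dplyr::bind_rows(out)
}

#' Adjusted Rand index between two partitions
#'
#' Standard pair-counting ARI with the expected-index correction: 1 for
#' identical partitions, ~0 for independent ones.
#'
#' @param a,b Cluster label vectors over the same items.
#' @return The ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    abort("partitions must cover the same items",
          class = "zoopcurves_input_error")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  ntot <- comb2(length(a))
  expected <- sum_a * sum_b / ntot
  maxidx <- (sum_a + sum_b) / 2
  if (abs(maxidx - expected) < 1e-300) return(0)
  (sum_ij - expected) / (maxidx - expected)
}

#' Summary table of fitted models
#'
#' Per (group, net, metric, variant): the first-ranked term, %Dev, adjusted
#' R2, the significant smooth terms ranked by F, and the cluster id for
#' models above the clustering deviance threshold (a dash otherwise).
#'
#' @param models Tibble of model metadata (columns `model_id`, `group`,
#'   `net_id`, `metric`, `variant`, `pct_dev`, `adj_r2`) .
#' @param fits Named list of `zc_gam` by `model_id`.
#' @param assignment Optional named cluster assignment by `model_id`.
#' @param alpha Significance cut for listed terms.
#' @param dev_threshold Clustering threshold for the cluster column.
#' @return A publication-style model-summary tibble.
#' @export
summarize_models <- function(models, fits, assignment = NULL, alpha = 0.05,
                             dev_threshold = 0.40) {
  rows <- lapply(seq_len(nrow(models)), function(i) {
    id <- models$model_id[i]
    tt <- term_significance(fits[[id]])
    sig <- tt[!tt$dropped & tt$p < alpha, ]
    first <- if (nrow(sig) > 0) sig$term[1] else "-"
    cl <- "-"
    if (!is.null(assignment) && id %in% names(assignment) &&
        models$pct_dev[i] > dev_threshold)
      cl <- as.character(assignment[[id]])
    tibble::tibble(
      group = models$group[i], net_id = models$net_id[i],
      metric = models$metric[i], variant = models$variant[i],
      first_term = first,
      pct_dev = models$pct_dev[i], adj_r2 = models$adj_r2[i],
      significant_terms = paste(sig$term, collapse = ", "),
      cluster = cl)
  })
  dplyr::bind_rows(rows)
}

#' Score recovery of the planted structure
#'
#' Compares a recovered clustering with the planted family labels (adjusted
#' Rand index) and scores recovery of each planted temperature-response sign
#' from the fitted temperature curves: a model whose temperature term was
#' removed or is insignificant counts as "null"; otherwise the sign of the
#' curve's endpoint difference is compared with the planted sign.
#'
#' @param truth A `zc_truth`.
#' @param assignment Named cluster assignment by model id (names must start
#'   with the group name, see `model_id` convention `group|net|...`).
#' @param fits Named list of `zc_gam` by model id.
#' @param model_groups Named character vector mapping model id -> group.
#' @param metric `"abundance"` (planted sign from the response shapes) or
#'   `"median_esd"` (planted sign is the temperature-size-rule sign).
#' @param alpha Significance threshold for calling a response non-null.
#' @return List: `ari`, `sign_recovery` (tibble per model), `sign_rate`
#'   (fraction of non-null planted temperature responses recovered).
#' @export
evaluate_recovery <- function(truth, assignment, fits, model_groups,
                              metric = "abundance", alpha = 0.05) {
  planted <- setNames(truth$groups$family, truth$groups$group)
  ids <- names(assignment)
  ari <- adjusted_rand_index(unname(planted[model_groups[ids]]),
                             unname(assignment))

  planted_sign <- vapply(names(fits), function(id) {
    g <- model_groups[[id]]
    if (metric == "median_esd") {
      gi <- truth$groups[truth$groups$group == g, ]
      return(if (nrow(gi) == 0) 0 else as.numeric(gi$tsr_sign[1]))
    }
    sh <- truth$shapes[truth$shapes$group == g &
                         truth$shapes$covariate == "temperature", ]
    if (nrow(sh) == 0 || sh$shape[1] %in% c("null", "unimodal")) 0
    else sign(sh$amplitude[1])
  }, numeric(1))
  fitted_sign <- vapply(names(fits), function(id) {
    fit <- fits[[id]]
    tt <- fit$terms[fit$terms$term == "temperature", ]
    if (nrow(tt) == 0 || tt$dropped[1] || tt$p[1] >= alpha) return(0)
    cv <- extract_curves(fit)
    cv <- cv[cv$covariate == "temperature", ]
    sign(cv$value[nrow(cv)] - cv$value[1])
  }, numeric(1))
  tab <- tibble::tibble(model_id = names(fits),
                        planted = planted_sign, fitted = fitted_sign,
                        recovered = planted_sign == fitted_sign)
  nonnull <- tab[tab$planted != 0, ]
  list(ari = ari, sign_recovery = tab,
       sign_rate = if (nrow(nonnull) > 0) mean(nonnull$recovered) else NA_real_)
}
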