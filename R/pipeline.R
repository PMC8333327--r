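# End-to-end orchestration: simulate -> ingest -> screen -> fit -> cluster
# -> report, with every stage seeded from one master seed.

#' Run the full analysis pipeline
#'
#' Simulates a virtual transect (or accepts a pre-built `zc_transect`),
#' computes rolled-up station x group x net metrics, screens covariates
#' (transform choice by Shapiro-Wilk, collinearity filter with the
#' temperature/oxygen split), fits penalized-spline additive models for
#' every retained (group, net, metric, variant) series with optional
#' backward term removal, clusters the fitted response curves by DTW + PAM
#' with the validity-index vote, embeds the distances by classical MDS, and
#' scores recovery against the simulator's ground truth.
#'
#' @param config A [transect_config()] (ignored when `transect` is given).
#' @param seed Master seed; stage seeds derive from it via [stage_seed()].
#' @param transect Optional pre-simulated `zc_transect`.
#' @param metrics Which community metrics to model.
#' @param variants Covariate-set variants to fit.
#' @param min_stations,min_n Retention thresholds.
#' @param groups Optional character vector restricting which groups are
#'   modelled (e.g. only the simulator's leaf groups in recovery runs).
#' @param dev_threshold Deviance threshold for curve clustering.
#' @param backward Apply backward removal of insignificant terms.
#' @param k_range Candidate cluster numbers.
#' @param out_dir Optional directory; when given, all tables are written.
#' @return A `zc_pipeline` list bundling every stage's outputs.
#' @export
run_pipeline <- function(config = transect_config(), seed = 1,
                         transect = NULL,
                         metrics = c("abundance", "median_esd"),
                         variants = c("temperature", "oxygen"),
                         min_stations = 30, min_n = 20, groups = NULL,
                         dev_threshold = 0.40, backward = TRUE,
                         k_range = 2:10, out_dir = NULL) {
  sim <- transect %||% simulate_transect(config, seed)
  registry <- sim$config$registry
  stations <- sim$stations

  # ingest: rollup + per-net metrics
  metr <- dplyr::bind_rows(lapply(names(sim$objects), function(net) {
    obj <- rollup_annotate(sim$objects[[net]], registry)
    vols <- setNames(sim$samples[[net]]$volume_m3,
                     sim$samples[[net]]$station_id)
    station_group_metrics(obj, vols, min_n = min_n)
  }))
  retained <- retain_groups(metr, min_stations = min_stations, min_n = min_n)
  retained <- retained[retained$metric %in% metrics, ]
  if (!is.null(groups))
    retained <- retained[retained$group %in% groups, ]

  # screening
  env_vars <- c("temperature", "salinity", "oxygen", "mld", "par", "no2no3",
                "po4", "sio2", "chl_a", "bbp470", "pct_micro", "pct_nano",
                "pct_pico", "dist_coast")
  covtab <- as.data.frame(stations[, env_vars])
  covsets <- collinearity_filter(covtab)
  correlations <- spearman_matrix(covtab)$table

  # one transform per metric, by majority vote over the retained series
  pick_transform <- function(metric) {
    col <- if (metric == "abundance") "abundance" else "median_esd_um"
    sel <- retained[retained$metric == metric, ]
    if (nrow(sel) == 0) return(NA_character_)
    ch <- vapply(seq_len(nrow(sel)), function(i) {
      ser <- metr[metr$group == sel$group[i] & metr$net_id == sel$net_id[i],
                  col, drop = TRUE]
      ser <- ser[is.finite(ser) & ser > 0]
      tryCatch(select_transform(ser)$transform, error = function(e) NA_character_)
    }, character(1))
    ch <- ch[!is.na(ch)]
    if (length(ch) == 0) return("ln")
    names(sort(table(ch), decreasing = TRUE))[1]
  }
  transforms <- setNames(vapply(metrics, pick_transform, character(1)),
                         metrics)

  # model fitting
  fits <- list()
  curve_sets <- list()
  model_rows <- list()
  for (i in seq_len(nrow(retained))) {
    g <- retained$group[i]; net <- retained$net_id[i]
    metric <- retained$metric[i]
    col <- if (metric == "abundance") "abundance" else "median_esd_um"
    ser <- metr[metr$group == g & metr$net_id == net,
                c("station_id", col)]
    ser <- ser[is.finite(ser[[col]]) & ser[[col]] > 0, ]
    df <- dplyr::inner_join(ser, stations, by = "station_id")
    y <- apply_transform(df[[col]], transforms[[metric]])
    for (variant in variants) {
      vars <- if (variant == "temperature") covsets$temperature_set
              else covsets$oxygen_set
      covs <- as.data.frame(df[, vars])
      id <- paste(g, net, metric, variant, sep = "|")
      fit <- tryCatch({
        f <- fit_additive_model(y, covs)
        if (backward) backward_select(f) else f
      }, error = function(e) NULL)
      if (is.null(fit)) next
      fits[[id]] <- fit
      curve_sets[[id]] <- extract_curves(fit)
      model_rows[[id]] <- tibble::tibble(
        model_id = id, group = g, net_id = net, metric = metric,
        variant = variant, pct_dev = fit$pct_dev, adj_r2 = fit$adj_r2,
        n = fit$n)
    }
  }
  models <- dplyr::bind_rows(model_rows)

  # clustering per metric
  clustering <- list()
  for (metric in metrics) {
    ids <- models$model_id[models$metric == metric]
    if (length(ids) == 0) next
    cl <- tryCatch({
      series <- assemble_series(curve_sets[ids],
                                models$pct_dev[match(ids, models$model_id)],
                                dev_threshold = dev_threshold)
      D <- dtw_matrix(series)
      ck <- choose_k(D, k_range = k_range, seed = stage_seed(seed, 20))
      pam <- ck$clusterings[[as.character(ck$k)]]
      mds <- classical_mds(D, dim = 2)
      list(D = D, choose_k = ck, k = ck$k, pam = pam,
           assignment = pam$assignment, mds = mds)
    }, error = function(e) NULL)
    clustering[[metric]] <- cl
  }

  # reporting
  assignment_all <- unlist(lapply(clustering,
                                  function(cl) if (is.null(cl)) NULL
                                  else cl$assignment))
  names(assignment_all) <- unlist(lapply(clustering, function(cl)
    if (is.null(cl)) NULL else names(cl$assignment)))
  summary_tbl <- summarize_models(models, fits,
                                  assignment = assignment_all,
                                  dev_threshold = dev_threshold)
  dev_by_variant <- if (length(variants) > 1 && nrow(models) >= 4)
    tryCatch(compare_dev(models, "variant"), error = function(e) NULL)
  else NULL
  dev_by_net <- if (length(unique(models$net_id)) > 1)
    tryCatch(compare_dev(models, "net_id"), error = function(e) NULL)
  else NULL

  recovery <- NULL
  truth <- sim$truth
  if (!is.null(truth) && "family" %in% names(truth$groups)) {
    recovery <- lapply(metrics, function(metric) {
      cl <- clustering[[metric]]
      if (is.null(cl)) return(NULL)
      ids <- names(cl$assignment)
      mg <- setNames(models$group[match(ids, models$model_id)], ids)
      fit_ids <- models$model_id[models$metric == metric]
      mg_all <- setNames(models$group[match(fit_ids, models$model_id)],
                         fit_ids)
      evaluate_recovery(truth, cl$assignment, fits[fit_ids], mg_all,
                        metric = metric)
    })
    names(recovery) <- metrics
  }

  out <- list(transect = sim, metrics_table = metr, retained = retained,
              covariate_sets = covsets, correlations = correlations,
              transforms = transforms, models = models, fits = fits,
              curves = curve_sets, clustering = clustering,
              summary = summary_tbl, dev_by_variant = dev_by_variant,
              dev_by_net = dev_by_net, recovery = recovery, seed = seed)
  class(out) <- "zc_pipeline"
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' Write pipeline outputs
#'
#' Writes the simulated dataset plus `group_metrics.csv`,
#' `correlations.csv`, `covariate_sets.json`, `models.csv`, `curves.csv`,
#' per-metric `distances_<metric>.csv` / `clusters_<metric>.csv` /
#' `indices_<metric>.csv` / `mds_<metric>.csv`, `summary.csv`,
#' `recovery.json` (when ground truth is available) and a `run_log.json`.
#'
#' @param pipeline A `zc_pipeline`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(pipeline, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(pipeline$transect, file.path(out_dir, "data"))
  readr::write_csv(pipeline$metrics_table,
                   file.path(out_dir, "group_metrics.csv"))
  readr::write_csv(pipeline$correlations,
                   file.path(out_dir, "correlations.csv"))
  jsonlite::write_json(pipeline$covariate_sets[c("temperature_set",
                                                 "oxygen_set")],
                       file.path(out_dir, "covariate_sets.json"))
  readr::write_csv(pipeline$models, file.path(out_dir, "models.csv"))
  curves_long <- dplyr::bind_rows(lapply(names(pipeline$curves), function(id)
    dplyr::mutate(pipeline$curves[[id]], model_id = id)))
  readr::write_csv(curves_long, file.path(out_dir, "curves.csv"))
  for (metric in names(pipeline$clustering)) {
    cl <- pipeline$clustering[[metric]]
    if (is.null(cl)) next
    dm <- as.data.frame(cl$D)
    dm <- cbind(model_id = rownames(cl$D), dm)
    readr::write_csv(dm, file.path(out_dir,
                                   sprintf("distances_%s.csv", metric)))
    readr::write_csv(tibble::tibble(model_id = names(cl$assignment),
                                    cluster = unname(cl$assignment)),
                     file.path(out_dir, sprintf("clusters_%s.csv", metric)))
    readr::write_csv(cl$choose_k$table,
                     file.path(out_dir, sprintf("indices_%s.csv", metric)))
    readr::write_csv(tibble::tibble(model_id = rownames(cl$mds$points),
                                    dim1 = cl$mds$points[, 1],
                                    dim2 = cl$mds$points[, 2]),
                     file.path(out_dir, sprintf("mds_%s.csv", metric)))
  }
  readr::write_csv(pipeline$summary, file.path(out_dir, "summary.csv"))
  if (!is.null(pipeline$recovery)) {
    rec <- lapply(pipeline$recovery, function(r) {
      if (is.null(r)) return(NULL)
      list(ari = r$ari, sign_rate = r$sign_rate)
    })
    jsonlite::write_json(rec, file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(seed = pipeline$seed, transforms = as.list(pipeline$transforms),
         n_models = nrow(pipeline$models)),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Latitudinal-pattern plot for one fitted latitude model
#'
#' @param latgam Output of [fit_latitude_gam()].
#' @param observed Optional tibble with `latitude` and `y` points.
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_latitude_gam <- function(latgam, observed = NULL, ylab = "metric") {
  p <- ggplot2::ggplot(latgam$prediction,
                       ggplot2::aes(x = .data$latitude, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fit - .data$se,
                                      ymax = .data$fit + .data$se),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Latitude (deg)", y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(observed))
    p <- p + ggplot2::geom_point(data = observed,
                                 ggplot2::aes(y = .data$y), alpha = 0.4)
  p
}

#' Stacked composition bars by latitudinal band
#'
#' @param composition Output of [composition_by_band()].
#' @return A ggplot object, one bar per band, faceted by net.
#' @export
plot_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$band, y = .data$fraction,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~net_id) +
    ggplot2::labs(x = NULL, y = "Relative abundance") +
    ggplot2::theme_minimal()
}

#' MDS scatter of clustered response-curve models
#'
#' @param mds Output of [classical_mds()].
#' @param assignment Cluster labels aligned with the MDS rows.
#' @return A ggplot object.
#' @export
plot_mds <- function(mds, assignment) {
  df <- tibble::tibble(dim1 = mds$points[, 1], dim2 = mds$points[, 2],
                       cluster = factor(assignment),
                       id = rownames(mds$points))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}
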