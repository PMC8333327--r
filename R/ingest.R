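# Per-object tables -> per-station, per-group, per-net abundance and
# median-ESD metrics, with nested taxonomic rollups.

#' Equivalent spherical diameter from ellipse axes
#'
#' Area-equivalent definition: the diameter of the circle whose area equals
#' that of the best-fit ellipse, `sqrt(major * minor)`.  This is the standard
#' plankton-imaging convention; every size result downstream depends on it.
#'
#' @param major_um,minor_um Ellipse axes in micrometres; `major >= minor > 0`.
#' @return ESD in micrometres.
#' @export
#' @examples
#' compute_esd(400, 100)  # 200
compute_esd <- function(major_um, minor_um) {
  if (any(!is.finite(major_um)) || any(!is.finite(minor_um)) ||
      any(minor_um <= 0) || any(major_um <= 0))
    abort("ellipse axes must be positive", class = "zoopcurves_input_error")
  if (any(major_um < minor_um))
    abort("major axis smaller than minor axis", class = "zoopcurves_input_error")
  sqrt(major_um * minor_um)
}

#' Read an object table and its companion volume table
#'
#' Expects the tab-separated Ecotaxa-flavoured object format
#' (`object_id`, `station_id`, `net_id`, `taxon`, `ellipse_major_um`,
#' `ellipse_minor_um`) and a CSV of filtered volumes (`station_id`,
#' `volume_m3`).  Unknown columns are ignored with a warning; `esd_um` is
#' computed on read.
#'
#' @param path Path to the objects TSV.
#' @param samples_path Path to the samples CSV.
#' @return List with `objects` (tibble incl. `esd_um`) and `volumes`
#'   (named numeric vector by station).
#' @export
read_object_table <- function(path, samples_path) {
  need <- c("object_id", "station_id", "net_id", "taxon",
            "ellipse_major_um", "ellipse_minor_um")
  obj <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(need, names(obj))
  if (length(miss) > 0)
    abort(paste0("missing mandatory column(s): ", paste(miss, collapse = ", ")),
          class = "zoopcurves_format_error")
  extra <- setdiff(names(obj), need)
  if (length(extra) > 0) {
    warn(paste0("ignoring unknown column(s): ", paste(extra, collapse = ", ")))
    obj <- obj[, need]
  }
  bad <- !is.finite(obj$ellipse_major_um) | !is.finite(obj$ellipse_minor_um) |
    obj$ellipse_major_um <= 0 | obj$ellipse_minor_um <= 0
  if (any(bad))
    abort(paste0("non-positive ellipse axes for object(s): ",
                 paste(head(obj$object_id[bad], 5), collapse = ", ")),
          class = "zoopcurves_validation_error")
  obj$esd_um <- compute_esd(obj$ellipse_major_um, obj$ellipse_minor_um)

  smp <- readr::read_csv(samples_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("station_id", "volume_m3") %in% names(smp)))
    abort("samples file must have station_id and volume_m3",
          class = "zoopcurves_format_error")
  list(objects = obj, volumes = setNames(smp$volume_m3, smp$station_id))
}

#' Annotate objects with their full ancestor-group list
#'
#' Each object contributes to its own group and to every ancestor up to
#' total Zooplankton, exactly once per level, so that nested groups account
#' for all the individuals of their sub-groups.
#'
#' @param objects Object tibble (needs a `taxon` column).
#' @param registry Taxonomic registry.
#' @param strict Error on unresolvable taxa (otherwise they are mapped to the
#'   root with a warning).
#' @return The objects tibble expanded to one row per (object, group) with a
#'   new `group` column.
#' @export
rollup_annotate <- function(objects, registry, strict = TRUE) {
  taxa <- unique(objects$taxon)
  unknown <- setdiff(taxa, registry$taxon)
  if (length(unknown) > 0) {
    if (strict)
      abort(paste0("unresolvable taxa: ", paste(unknown, collapse = ", ")),
            class = "zoopcurves_taxonomy_error")
    warn(paste0("mapping unresolvable taxa to root: ",
                paste(unknown, collapse = ", ")))
  }
  chains <- lapply(taxa, function(tx) {
    if (tx %in% registry$taxon) registry_ancestors(registry, tx)
    else registry$taxon[is.na(registry$parent)]
  })
  names(chains) <- taxa
  reps <- lengths(chains)[objects$taxon]
  out <- objects[rep(seq_len(nrow(objects)), reps), ]
  out$group <- unlist(chains[objects$taxon], use.names = FALSE)
  out
}

#' Station x group x net abundance and median-size metrics
#'
#' Abundance is the individual count divided by the filtered volume
#' (ind m^-3); the median ESD is reported only where at least `min_n`
#' individuals were measured (abundance is still reported below the
#' threshold).  Input objects should already be rollup-annotated so that
#' parent groups include their children's individuals.
#'
#' @param objects Rollup-annotated object tibble (column `group`).
#' @param volumes Named numeric vector of filtered volumes (m^3) by station.
#' @param min_n Minimum individuals for a median ESD (default 20).
#' @return Tibble `station_id`, `net_id`, `group`, `n_individuals`,
#'   `abundance`, `median_esd_um` (NA below `min_n`).
#' @export
station_group_metrics <- function(objects, volumes, min_n = 20) {
  sts <- unique(objects$station_id)
  if (!all(sts %in% names(volumes)))
    abort("volume missing for some stations", class = "zoopcurves_input_error")
  if (any(volumes[sts] <= 0))
    abort("volumes must be positive", class = "zoopcurves_input_error")
  out <- objects |>
    dplyr::group_by(.data$station_id, .data$net_id, .data$group) |>
    dplyr::summarise(n_individuals = dplyr::n(),
                     median_esd_um = median(.data$esd_um),
                     .groups = "drop")
  out$abundance <- out$n_individuals / unname(volumes[out$station_id])
  out$median_esd_um[out$n_individuals < min_n] <- NA_real_
  out[, c("station_id", "net_id", "group", "n_individuals", "abundance",
          "median_esd_um")]
}

#' Retention rule for modelling
#'
#' A (group, net) series enters size-structure modelling only if at least
#' `min_stations` stations have at least `min_n` measured individuals; it
#' enters abundance modelling if the group was observed at `min_stations`
#' stations.
#'
#' @param metrics Tibble from [station_group_metrics()].
#' @param min_stations Station threshold (inclusive, default 30).
#' @param min_n Individual threshold for size metrics (default 20).
#' @return Tibble `group`, `net_id`, `metric` of retained series.
#' @export
retain_groups <- function(metrics, min_stations = 30, min_n = 20) {
  if (nrow(metrics) == 0)
    return(tibble::tibble(group = character(0), net_id = character(0),
                          metric = character(0)))
  ab <- metrics |>
    dplyr::filter(.data$n_individuals > 0) |>
    dplyr::count(.data$group, .data$net_id) |>
    dplyr::filter(.data$n >= min_stations) |>
    dplyr::mutate(metric = "abundance")
  sz <- metrics |>
    dplyr::filter(.data$n_individuals >= min_n) |>
    dplyr::count(.data$group, .data$net_id) |>
    dplyr::filter(.data$n >= min_stations) |>
    dplyr::mutate(metric = "median_esd")
  dplyr::bind_rows(ab, sz)[, c("group", "net_id", "metric")]
}

#' Copepod composition by latitudinal band
#'
#' Relative abundance of copepod orders or families within tropical
#' (|lat| <= 30), temperate (30 < |lat| <= 60) and polar (|lat| > 60) bands,
#' per net.  Taxa below `lump_below` of the copepod total are lumped into an
#' `"other"` bucket; fractions (including `"other"`) sum to 1.  Unidentified
#' buckets are excluded from family-level composition (they are shown at
#' order level only).
#'
#' @param metrics Tibble from [station_group_metrics()].
#' @param stations Station table (for latitudes).
#' @param registry Taxonomic registry.
#' @param level `"order"` or `"family"`.
#' @param lump_below Lumping threshold as a fraction (default 0.01).
#' @return Tibble `band`, `net_id`, `group`, `fraction`.
#' @export
composition_by_band <- function(metrics, stations, registry,
                                level = c("family", "order"),
                                lump_below = 0.01) {
  level <- match.arg(level)
  keep <- registry$taxon[registry$level == level &
                           !(level == "family" & registry$bucket)]
  lat <- setNames(stations$latitude, stations$station_id)
  df <- metrics
  df$band <- cut(abs(lat[df$station_id]), c(-Inf, 30, 60, Inf),
                 labels = c("tropical", "temperate", "polar"))
  cop <- df |>
    dplyr::filter(.data$group == "Copepoda") |>
    dplyr::group_by(.data$band, .data$net_id) |>
    dplyr::summarise(cop_total = sum(.data$abundance), .groups = "drop")
  out <- df |>
    dplyr::filter(.data$group %in% keep) |>
    dplyr::group_by(.data$band, .data$net_id, .data$group) |>
    dplyr::summarise(total = sum(.data$abundance), .groups = "drop") |>
    dplyr::inner_join(cop, by = c("band", "net_id"))
  empty <- cop$cop_total <= 0
  if (any(empty)) {
    warn("band(s) without copepods omitted")
    out <- out[out$cop_total > 0, ]
  }
  out$fraction <- out$total / out$cop_total
  out$group[out$fraction < lump_below] <- "other"
  res <- out |>
    dplyr::group_by(.data$band, .data$net_id, .data$group) |>
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop")
  # remainder not covered by the listed level (e.g. order-level leftovers)
  cover <- res |>
    dplyr::group_by(.data$band, .data$net_id) |>
    dplyr::summarise(f = sum(.data$fraction), .groups = "drop")
  rem <- cover[cover$f < 1 - 1e-12, ]
  if (nrow(rem) > 0) {
    rem <- tibble::tibble(band = rem$band, net_id = rem$net_id,
                          group = "other", fraction = 1 - rem$f)
    res <- dplyr::bind_rows(res, rem) |>
      dplyr::group_by(.data$band, .data$net_id, .data$group) |>
      dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop")
  }
  res
}
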