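#' Plankton-net registry
#'
#' The three nets used to sample overlapping zooplankton size ranges, with
#' their mesh sizes and mouth openings: WP2 (200 um, 0.57 m2, vertical tow
#' from 100 m), Bongo (300 um, 0.57 m2, oblique tow from 500 m) and Regent
#' (680 um, 1.12 m2, oblique tow from 500 m).  `retention_steepness` is the
#' dimensionless slope of the logistic mesh-retention curve used by the
#' simulator (see [retention_prob()]); its default, `log(99)`, puts retention
#' at 0.5 for an organism exactly at mesh size and at 0.99 at twice mesh size.
#'
#' @return A tibble with columns `net_id`, `mesh_um`, `opening_m2`, `tow`,
#'   `retention_steepness`.
#' @export
#' @examples
#' net_registry()
net_registry <- function() {
  tibble::tibble(
    net_id = c("WP2", "Bongo", "Regent"),
    mesh_um = c(200, 300, 680),
    opening_m2 = c(0.57, 0.57, 1.12),
    tow = c("vertical_0_100m", "oblique_0_500m", "oblique_0_500m"),
    retention_steepness = log(99)
  )
}

#' Nested taxonomic registry for the analysis groups
#'
#' A forest rooted at `"Zooplankton"` covering the 36 analysis groups:
#' total zooplankton, the Copepoda broken into their five main orders
#' (Calanoida, Cyclopoida, Poecilostomatoida, Harpacticoida, Monstrilloida)
#' and into families where the imaging resolution allows it, two
#' "unidentified" buckets (unidentified Copepoda, small unidentified
#' Calanoida), the Rhizaria split into Foraminifera and Radiolaria, and the
#' remaining broad groups (Chaetognatha, Cnidaria, Tunicata, Eumalacostraca,
#' Pteropoda, Cladocera, Ostracoda, Nauplii).
#'
#' Buckets roll up to their order/class for abundance accounting but are
#' excluded from family-level composition summaries.
#'
#' @return A tibble with columns `taxon`, `parent` (NA for the root), `level`
#'   (`root`, `class`, `order`, `family` or `group`) and `bucket` (logical).
#' @export
#' @examples
#' reg <- taxon_registry()
#' nrow(reg)  # 36 groups
taxon_registry <- function() {
  fam <- function(name, parent) tibble::tibble(taxon = name, parent = parent,
                                               level = "family", bucket = FALSE)
  out <- dplyr::bind_rows(
    tibble::tibble(taxon = "Zooplankton", parent = NA_character_,
                   level = "root", bucket = FALSE),
    tibble::tibble(taxon = "Copepoda", parent = "Zooplankton",
                   level = "class", bucket = FALSE),
    tibble::tibble(taxon = c("Calanoida", "Cyclopoida", "Poecilostomatoida",
                             "Harpacticoida", "Monstrilloida"),
                   parent = "Copepoda", level = "order", bucket = FALSE),
    fam(c("Calanidae", "Paracalanidae", "Eucalanidae", "Euchaetidae",
          "Candaciidae", "Temoridae", "Augaptilidae", "Acartiidae",
          "Clausocalanidae", "Metridinidae", "Centropagidae", "Pontellidae"),
        "Calanoida"),
    tibble::tibble(taxon = "small unidentified Calanoida", parent = "Calanoida",
                   level = "family", bucket = TRUE),
    fam("Oithonidae", "Cyclopoida"),
    fam(c("Oncaeidae", "Corycaeidae", "Sapphirinidae"), "Poecilostomatoida"),
    tibble::tibble(taxon = "unidentified Copepoda", parent = "Copepoda",
                   level = "order", bucket = TRUE),
    tibble::tibble(taxon = "Rhizaria", parent = "Zooplankton",
                   level = "group", bucket = FALSE),
    tibble::tibble(taxon = c("Foraminifera", "Radiolaria"), parent = "Rhizaria",
                   level = "group", bucket = FALSE),
    tibble::tibble(taxon = c("Chaetognatha", "Cnidaria", "Tunicata",
                             "Eumalacostraca", "Pteropoda", "Cladocera",
                             "Ostracoda", "Nauplii"),
                   parent = "Zooplankton", level = "group", bucket = FALSE)
  )
  validate_registry(out)
  out
}

validate_registry <- function(registry) {
  par <- setNames(registry$parent, registry$taxon)
  if (anyDuplicated(registry$taxon))
    abort("duplicate taxon names in registry", class = "zoopcurves_taxonomy_error")
  roots <- registry$taxon[is.na(registry$parent)]
  if (length(roots) != 1L)
    abort("registry must have exactly one root", class = "zoopcurves_taxonomy_error")
  for (tx in registry$taxon) {
    seen <- character(0)
    cur <- tx
    while (!is.na(par[[cur]])) {
      if (cur %in% seen)
        abort(paste0("cycle in registry at ", cur), class = "zoopcurves_taxonomy_error")
      seen <- c(seen, cur)
      nxt <- par[[cur]]
      if (!nxt %in% registry$taxon)
        abort(paste0("parent '", nxt, "' of '", cur, "' not in registry"),
              class = "zoopcurves_taxonomy_error")
      cur <- nxt
    }
  }
  invisible(registry)
}

#' Ancestor chain of a taxon
#'
#' @param registry A registry tibble from [taxon_registry()].
#' @param taxon Taxon name.
#' @return Character vector from the taxon itself up to the root, inclusive.
#' @export
registry_ancestors <- function(registry, taxon) {
  par <- setNames(registry$parent, registry$taxon)
  if (!taxon %in% names(par))
    abort(paste0("unknown taxon: ", taxon), class = "zoopcurves_taxonomy_error")
  chain <- taxon
  while (!is.na(par[[chain[length(chain)]]]))
    chain <- c(chain, par[[chain[length(chain)]]])
  chain
}

#' Leaf groups of a registry
#'
#' @param registry A registry tibble.
#' @return Character vector of taxa that are nobody's parent.
#' @export
registry_leaves <- function(registry) {
  setdiff(registry$taxon, registry$parent[!is.na(registry$parent)])
}
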