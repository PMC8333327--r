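# Virtual ocean transect generator: stations with a planted collinearity
# structure, nested communities with known response shapes, and net-specific
# per-object tables with full ground-truth bookkeeping.

#' Transect simulation settings
#'
#' Defaults reproduce the study conditions the pipeline is meant to exercise:
#' 168 stations sampled unevenly between hemispheres (denser in the north),
#' a temperature-oxygen rank correlation of -0.95, nutrient inter-correlations
#' of 0.95 (PO4) and 0.87 (SiO2) with NO2NO3, a copepod dominance target of
#' 74% of total abundance, and a temperature-size rule on individual sizes.
#'
#' @param n_stations Number of stations (>= 4).
#' @param lat_range Latitude limits, decimal degrees.
#' @param north_fraction Fraction of stations placed in the northern
#'   hemisphere (the sampling is deliberately uneven).
#' @param rho_temp_oxy Target rank correlation between temperature and oxygen.
#' @param rho_no2no3_po4,rho_no2no3_sio2 Target rank correlations of PO4 and
#'   SiO2 with NO2NO3.
#' @param dominance Copepod share of total abundance aimed for (fraction).
#' @param noise_sd Standard deviation of the log-abundance noise.
#' @param esd_sdlog Log-scale spread of individual sizes within a group.
#' @param aliquot Fraction of the filtered volume effectively imaged
#'   (sub-sampling of the net catch); the written `volume_m3` is the
#'   effective volume `tow length x opening x aliquot`.
#' @param nets Net registry (see [net_registry()]).
#' @param registry Taxonomic registry (see [taxon_registry()]).
#' @param truth Optional truth bundle; built by [default_truth()] if `NULL`.
#' @param coastline Coastline vertex list for distance-to-coast.
#' @return A list of settings (class `zc_config`).
#' @export
transect_config <- function(n_stations = 168,
                            lat_range = c(-70, 80),
                            north_fraction = 0.65,
                            rho_temp_oxy = -0.95,
                            rho_no2no3_po4 = 0.95,
                            rho_no2no3_sio2 = 0.87,
                            dominance = 0.74,
                            noise_sd = 0.4,
                            esd_sdlog = 0.35,
                            aliquot = 0.125,
                            nets = net_registry(),
                            registry = taxon_registry(),
                            truth = NULL,
                            coastline = synthetic_coastline()) {
  cfg <- list(n_stations = n_stations, lat_range = lat_range,
              north_fraction = north_fraction, rho_temp_oxy = rho_temp_oxy,
              rho_no2no3_po4 = rho_no2no3_po4,
              rho_no2no3_sio2 = rho_no2no3_sio2, dominance = dominance,
              noise_sd = noise_sd, esd_sdlog = esd_sdlog, aliquot = aliquot,
              nets = nets, registry = registry, truth = truth,
              coastline = coastline)
  class(cfg) <- "zc_config"
  cfg
}

#' The ten modelling covariates
#' @return Character vector naming the covariates entering the
#'   temperature-set additive models (oxygen replaces temperature in the
#'   oxygen set).
#' @export
model_covariates <- function() {
  c("temperature", "salinity", "mld", "par", "no2no3", "chl_a", "bbp470",
    "pct_micro", "pct_nano", "dist_coast")
}

# Planted response shapes, evaluated on the covariate scaled to [0, 1].
# Amplitude is signed; "unimodal" is a centred bell, "monotone" a logistic
# ramp, "linear" a straight ramp, "null" identically zero.
shape_value <- function(shape, amplitude, u) {
  switch(shape,
    null = rep(0, length(u)),
    linear = amplitude * (2 * u - 1),
    monotone = amplitude * 2 * (stats::plogis(8 * (u - 0.5)) - 0.5),
    unimodal = amplitude * (exp(-(u - 0.5)^2 / (2 * 0.15^2)) -
                              mean(exp(-(seq(0, 1, length.out = 201) - 0.5)^2 /
                                         (2 * 0.15^2)))),
    abort(paste0("unknown shape: ", shape), class = "zoopcurves_config_error")
  )
}

#' Generate a virtual transect's station table
#'
#' One record per station: coordinates, temperature (10 m), salinity, oxygen,
#' mixed layer depth, PAR, macronutrients (NO2NO3, PO4, SiO2), integrated
#' chlorophyll a, particle backscattering (bbp470), phytoplankton size
#' fractions (closing to 100%), and distance to a synthetic coastline.
#' Temperature decreases smoothly away from the equator; oxygen is a
#' decreasing affine function of temperature plus noise scaled so the rank
#' correlation hits the configured target; PO4 and SiO2 derive from NO2NO3
#' the same way; %Pico rises and %Micro falls with temperature.
#'
#' @param config A [transect_config()].
#' @param seed Integer seed; fixed seed gives a bit-identical table.
#' @return A tibble, one row per station.
#' @export
generate_stations <- function(config = transect_config(), seed = 1) {
  n <- config$n_stations
  lr <- config$lat_range
  if (n < 4)
    abort("n_stations must be >= 4", class = "zoopcurves_config_error")
  if (lr[1] < -90 || lr[2] > 90 || lr[1] >= lr[2])
    abort("invalid latitude range", class = "zoopcurves_config_error")

  # noise s.d. giving (approximately) rank correlation rho against a signal
  # with spread `s` on the latent additive scale
  noise_for_rho <- function(s, rho) s * sqrt(1 / rho^2 - 1)
  skewed <- function(n, sdv) {
    z <- rnorm(n)
    sdv * (z + 0.35 * (z^2 - 1)) / sqrt(1 + 2 * 0.35^2)
  }

  with_seed(seed, {
    n_north <- round(config$north_fraction * n)
    lat <- c(runif(n_north, max(0, lr[1]), lr[2]),
             runif(n - n_north, lr[1], min(0, lr[2])))
    lon <- runif(n, -180, 180)
    absl <- abs(lat)

    temperature <- pmax(-1.9, 29.5 - 30 * (absl / 75)^1.7 + rnorm(n, 0, 1))
    oxy_signal <- 370 - 6.2 * temperature
    oxygen <- oxy_signal +
      rnorm(n, 0, noise_for_rho(sd(oxy_signal), abs(config$rho_temp_oxy)))
    salinity <- 33.6 + 1.5 * exp(-((absl - 25) / 16)^2) -
      0.03 * pmax(absl - 50, 0) + rnorm(n, 0, 0.6)
    mld <- exp(3.0 + 0.012 * absl + rnorm(n, 0, 0.5))
    par <- pmax(1.5, 52 * cos(pmin(absl, 89) * pi / 180)^1.4 *
                  exp(rnorm(n, 0, 0.75)))
    ln_no3 <- -2.1 + 0.055 * absl + rnorm(n, 0, 1.75)
    no2no3 <- exp(ln_no3)
    # PO4 and SiO2 derive from NO2NO3 with skewed noise and a detection-limit
    # floor, so NO2NO3 is by construction the most normal of the trio under
    # every candidate transform (this is what lets the collinearity filter
    # retain the nutrient axis through NO2NO3).
    po4 <- pmax(exp(ln_no3 - log(16) +
                      skewed(n, noise_for_rho(sd(ln_no3),
                                              config$rho_no2no3_po4))),
                0.02)
    sio2 <- pmax(exp(ln_no3 + 0.25 +
                       skewed(n, noise_for_rho(sd(ln_no3),
                                               config$rho_no2no3_sio2))),
                 0.5)
    chl_a <- exp(2.9 + 0.3 * (ln_no3 - mean(ln_no3)) + rnorm(n, 0, 0.85))
    bbp470 <- exp(-7.1 + 0.45 * (log(chl_a) - mean(log(chl_a))) +
                    rnorm(n, 0, 0.8))

    t0 <- (temperature - 15) / 10
    z1 <- rnorm(n)
    # %Micro and %Pico are strongly opposed (shared noise, opposite
    # temperature signs); %Pico additionally carries episodic crashes
    # (left-skewed reversed-exponential logit noise), so the pair exercises
    # the collinearity filter while staying clear of the threshold against
    # temperature itself.
    l_micro <- 0.55 - 0.45 * t0 + 1.0 * z1
    l_pico <- -0.10 + 0.72 * t0 - 0.8 * z1 + 0.85 * (1 - stats::rexp(n))
    l_nano <- 0.45 + rnorm(n, 0, 0.30)
    es <- exp(cbind(l_micro, l_nano, l_pico))
    frac <- 100 * es / rowSums(es)

    tibble::tibble(
      station_id = sprintf("st%03d", seq_len(n)),
      latitude = lat, longitude = lon,
      temperature = temperature, salinity = salinity, oxygen = oxygen,
      mld = mld, par = par, no2no3 = no2no3, po4 = po4, sio2 = sio2,
      chl_a = chl_a, bbp470 = bbp470,
      pct_micro = frac[, 1], pct_nano = frac[, 2], pct_pico = frac[, 3],
      dist_coast = distance_to_coast(lat, lon, config$coastline)
    )
  })
}

#' Construct a truth bundle
#'
#' Ground-truth bookkeeping for the simulator: per-group response
#' coefficients (shape and signed amplitude per covariate), the planted
#' cluster label (`family`), the base abundance and size, and the
#' temperature-size rule slope.
#'
#' @param groups Tibble with columns `group`, `family` (planted cluster
#'   label, integer), `intercept_ind_m3`, `base_esd_um`, `tsr_sign`
#'   (-1, 0 or +1; -1 means smaller when warmer), `tsr_b` (|d ln ESD / dT|).
#' @param shapes Tibble with columns `group`, `covariate`, `shape`
#'   (`null`, `linear`, `monotone`, `unimodal`) and `amplitude` (signed,
#'   natural-log units across the covariate range).
#' @param k_true Number of planted response-shape families.
#' @param dominance_target Copepod share of total abundance to calibrate to,
#'   or `NULL` to skip calibration.
#' @param seed Seed recorded for reproducibility bookkeeping.
#' @return A `zc_truth` object.
#' @export
make_truth <- function(groups, shapes, k_true = length(unique(groups$family)),
                       dominance_target = NULL, seed = NULL) {
  stopifnot(all(c("group", "family", "intercept_ind_m3", "base_esd_um",
                  "tsr_sign", "tsr_b") %in% names(groups)))
  stopifnot(all(c("group", "covariate", "shape", "amplitude") %in%
                  names(shapes)))
  if (!all(shapes$group %in% groups$group))
    abort("shapes refer to unknown groups", class = "zoopcurves_config_error")
  out <- list(groups = groups, shapes = shapes, k_true = k_true,
              dominance_target = dominance_target, seed = seed)
  class(out) <- "zc_truth"
  out
}

# The four planted response-shape archetypes over the modelling covariates.
family_archetypes <- function() {
  list(
    `1` = tibble::tribble(
      ~covariate, ~shape, ~amplitude,
      "temperature", "linear", -2.0,
      "no2no3", "linear", 1.2,
      "chl_a", "linear", 0.8),
    `2` = tibble::tribble(
      ~covariate, ~shape, ~amplitude,
      "temperature", "monotone", 2.0,
      "par", "unimodal", 1.5,
      "dist_coast", "linear", -0.8),
    `3` = tibble::tribble(
      ~covariate, ~shape, ~amplitude,
      "chl_a", "monotone", 2.0,
      "bbp470", "linear", 1.2,
      "pct_micro", "unimodal", 1.5),
    `4` = tibble::tribble(
      ~covariate, ~shape, ~amplitude,
      "mld", "unimodal", 2.0,
      "salinity", "linear", -1.5,
      "dist_coast", "monotone", 1.2)
  )
}

# deterministic mild amplitude jitter so family members are not clones
jitter_amp <- function(shapes, idx) {
  shapes$amplitude <- shapes$amplitude * (0.85 + 0.15 * (idx %% 3))
  shapes
}

#' Default truth bundle for the full taxonomic registry
#'
#' Assigns each leaf group a response-shape family (poleward calanoids and
#' other cold-water groups to the "polar" archetype; small cyclopoids,
#' poecilostomatoids and Rhizaria to the "tropical" one; grazers to the
#' "productivity" one; gelatinous carnivores and Eumalacostraca to the
#' "coastal/mixed-layer" one), a base abundance and size, and a
#' temperature-size slope (negative for most copepods, positive for the
#' small warm-water poecilostomatoids).
#'
#' @param registry Taxonomic registry.
#' @param seed Seed recorded in the bundle.
#' @param dominance_target Copepod dominance fraction.
#' @return A `zc_truth` object.
#' @export
default_truth <- function(registry = taxon_registry(), seed = NULL,
                          dominance_target = 0.74) {
  leaves <- registry_leaves(registry)
  anc <- lapply(leaves, registry_ancestors, registry = registry)
  names(anc) <- leaves
  under <- function(g, node) node %in% anc[[g]]

  fam_of <- vapply(leaves, function(g) {
    if (under(g, "Calanoida")) 1L
    else if (under(g, "Cyclopoida") || under(g, "Poecilostomatoida") ||
             under(g, "Harpacticoida") || under(g, "Monstrilloida") ||
             g == "unidentified Copepoda" || under(g, "Rhizaria") ||
             g == "Pteropoda") 2L
    else if (g %in% c("Tunicata", "Cladocera", "Ostracoda", "Nauplii",
                      "Chaetognatha")) 3L
    else 4L  # Cnidaria, Eumalacostraca
  }, integer(1))

  base_abund <- c(
    Calanidae = 3, Paracalanidae = 2.5, Eucalanidae = 0.6, Euchaetidae = 0.6,
    Candaciidae = 0.5, Temoridae = 0.6, Augaptilidae = 0.4, Acartiidae = 0.6,
    Clausocalanidae = 1.2, Metridinidae = 0.6, Centropagidae = 0.5,
    Pontellidae = 0.3, `small unidentified Calanoida` = 4, Oithonidae = 3,
    Oncaeidae = 2.5, Corycaeidae = 1.5, Sapphirinidae = 0.4,
    Harpacticoida = 0.3, Monstrilloida = 0.15,
    `unidentified Copepoda` = 2, Foraminifera = 0.5, Radiolaria = 0.6,
    Chaetognatha = 0.8, Cnidaria = 0.5, Tunicata = 1.0, Eumalacostraca = 0.4,
    Pteropoda = 0.4, Cladocera = 0.5, Ostracoda = 0.6, Nauplii = 1.5)
  base_esd <- c(
    Calanidae = 1400, Paracalanidae = 700, Eucalanidae = 1600,
    Euchaetidae = 1500, Candaciidae = 1100, Temoridae = 800,
    Augaptilidae = 1300, Acartiidae = 700, Clausocalanidae = 600,
    Metridinidae = 1200, Centropagidae = 900, Pontellidae = 1000,
    `small unidentified Calanoida` = 300, Oithonidae = 320, Oncaeidae = 300,
    Corycaeidae = 320, Sapphirinidae = 450, Harpacticoida = 350,
    Monstrilloida = 400, `unidentified Copepoda` = 400, Foraminifera = 500,
    Radiolaria = 700, Chaetognatha = 2500, Cnidaria = 3000, Tunicata = 1500,
    Eumalacostraca = 2800, Pteropoda = 600, Cladocera = 400, Ostracoda = 500,
    Nauplii = 150)

  tsr_sign <- vapply(leaves, function(g) {
    if (under(g, "Poecilostomatoida")) 1L else -1L
  }, integer(1))

  groups <- tibble::tibble(
    group = leaves,
    family = fam_of,
    intercept_ind_m3 = unname(base_abund[leaves]),
    base_esd_um = unname(base_esd[leaves]),
    tsr_sign = tsr_sign,
    tsr_b = ifelse(vapply(leaves, under, logical(1), node = "Calanoida"),
                   0.025, 0.02)
  )
  arch <- family_archetypes()
  shapes <- dplyr::bind_rows(lapply(seq_along(leaves), function(i) {
    sh <- jitter_amp(arch[[groups$family[i]]], i)
    sh$group <- leaves[i]
    sh
  }))
  make_truth(groups, shapes, k_true = 4L,
             dominance_target = dominance_target, seed = seed)
}

#' Recovery-design configuration: 24 groups, 4 planted families
#'
#' A flat community of 24 simulated groups, six per response-shape family,
#' sampled with the WP2 net over a reduced transect.  This is the design used
#' to measure end-to-end cluster recovery (adjusted Rand index between the
#' planted family labels and the clusters recovered from the fitted response
#' curves) and temperature-size-rule sign recovery.
#'
#' @param n_stations Stations on the reduced transect.
#' @param n_groups Number of simulated groups (multiple of 4).
#' @return A `zc_config` whose registry is flat and whose truth plants
#'   `n_groups / 4` models per family, all with negative temperature-size
#'   slopes.
#' @export
recovery_config <- function(n_stations = 120, n_groups = 24) {
  stopifnot(n_groups %% 4 == 0)
  gnames <- sprintf("SimGroup%02d", seq_len(n_groups))
  registry <- tibble::tibble(
    taxon = c("Zooplankton", gnames),
    parent = c(NA_character_, rep("Zooplankton", n_groups)),
    level = c("root", rep("group", n_groups)),
    bucket = FALSE)
  fam <- rep(1:4, each = n_groups / 4)
  groups <- tibble::tibble(
    group = gnames, family = fam,
    intercept_ind_m3 = 5,
    base_esd_um = 300 + 50 * (seq_len(n_groups) - 1),
    tsr_sign = -1L, tsr_b = 0.025)
  arch <- family_archetypes()
  shapes <- dplyr::bind_rows(lapply(seq_len(n_groups), function(i) {
    sh <- jitter_amp(arch[[fam[i]]], i)
    sh$group <- gnames[i]
    sh
  }))
  truth <- make_truth(groups, shapes, k_true = 4L, dominance_target = NULL)
  transect_config(n_stations = n_stations, registry = registry, truth = truth,
                  nets = net_registry()[net_registry()$net_id == "WP2", ])
}

#' Simulate per-station true abundances for every leaf group
#'
#' Log-abundance is the group intercept plus the planted covariate responses
#' (each evaluated on the covariate scaled to its observed range) plus
#' Gaussian noise.  When the truth bundle carries a dominance target and the
#' registry contains Copepoda, copepod intercepts are rescaled so the
#' expected copepod share of total abundance matches the target.
#'
#' @param stations Station table from [generate_stations()].
#' @param registry Taxonomic registry; every leaf must appear in `truth`.
#' @param truth A `zc_truth`.
#' @param seed Integer seed.
#' @param noise_sd Log-scale noise s.d.; 0 gives a deterministic function of
#'   the covariates.
#' @return Tibble `station_id`, `group`, `abundance` (ind m^-3).
#' @export
simulate_group_abundances <- function(stations, registry, truth, seed = 1,
                                      noise_sd = 0.4) {
  leaves <- registry_leaves(registry)
  missing <- setdiff(leaves, truth$groups$group)
  if (length(missing) > 0)
    abort(paste0("groups missing from truth: ",
                 paste(missing, collapse = ", ")),
          class = "zoopcurves_config_error")

  covs <- intersect(unique(truth$shapes$covariate), names(stations))
  u <- lapply(covs, function(cv) {
    x <- stations[[cv]]
    (x - min(x)) / (max(x) - min(x))
  })
  names(u) <- covs

  n <- nrow(stations)
  gi <- truth$groups[match(leaves, truth$groups$group), ]
  # deterministic expected log-abundance
  loga <- matrix(log(gi$intercept_ind_m3), n, length(leaves), byrow = TRUE)
  for (i in seq_along(leaves)) {
    sh <- truth$shapes[truth$shapes$group == leaves[i], ]
    for (r in seq_len(nrow(sh))) {
      if (!sh$covariate[r] %in% covs) next
      loga[, i] <- loga[, i] +
        shape_value(sh$shape[r], sh$amplitude[r], u[[sh$covariate[r]]])
    }
  }

  # dominance calibration on the noise-free expectation
  if (!is.null(truth$dominance_target) && "Copepoda" %in% registry$taxon) {
    is_cop <- vapply(leaves, function(g)
      "Copepoda" %in% registry_ancestors(registry, g), logical(1))
    if (any(is_cop) && any(!is_cop)) {
      tot_cop <- sum(exp(loga[, is_cop]))
      tot_oth <- sum(exp(loga[, !is_cop]))
      d <- truth$dominance_target
      loga[, is_cop] <- loga[, is_cop] +
        log(d * tot_oth / ((1 - d) * tot_cop))
    }
  }

  ab <- with_seed(seed, {
    if (noise_sd > 0) loga <- loga + rnorm(n * length(leaves), 0, noise_sd)
    exp(loga)
  })
  tibble::tibble(
    station_id = rep(stations$station_id, times = length(leaves)),
    group = rep(leaves, each = n),
    abundance = as.vector(ab)
  )
}

#' Mesh retention probability
#'
#' Logistic retention centred on the mesh size:
#' `plogis(steepness * (esd - mesh) / mesh)`.  An organism exactly at mesh
#' size is retained with probability 0.5; with the default steepness
#' `log(99)` retention reaches 0.99 at twice the mesh size.
#'
#' @param esd_um Equivalent spherical diameter(s), um.
#' @param mesh_um Mesh size, um.
#' @param steepness Dimensionless logistic slope.
#' @return Retention probability in (0, 1).
#' @export
retention_prob <- function(esd_um, mesh_um, steepness = log(99)) {
  stats::plogis(steepness * (esd_um - mesh_um) / mesh_um)
}

#' Sample imaged individuals for one net
#'
#' For each station and leaf group, the number of encountered individuals is
#' Poisson with mean `abundance x volume`; individual sizes are lognormal
#' with a median following the group's temperature-size rule
#' `ln(median ESD) = ln(base) + tsr_sign * tsr_b * (T - 15)`;
#' each individual is retained by the mesh with probability
#' [retention_prob()]; retained individuals are emitted as ellipse records
#' with `major = ESD * sqrt(r)`, `minor = ESD / sqrt(r)` and aspect ratio `r`
#' uniform on `[1, 4]`.
#'
#' @param abundances Tibble from [simulate_group_abundances()].
#' @param stations Station table.
#' @param net One row of [net_registry()].
#' @param truth A `zc_truth`.
#' @param seed Integer seed.
#' @param aliquot Effective sub-sampling fraction of the filtered volume.
#' @param esd_sdlog Within-group log-size spread.
#' @return List with `objects` (tibble: `object_id`, `station_id`, `net_id`,
#'   `taxon`, `ellipse_major_um`, `ellipse_minor_um`, `esd_um`) and `samples`
#'   (tibble: `station_id`, `volume_m3`).
#' @export
sample_individuals <- function(abundances, stations, net, truth, seed = 1,
                               aliquot = 0.125, esd_sdlog = 0.35) {
  if (any(abundances$abundance < 0))
    abort("negative abundance", class = "zoopcurves_input_error")
  tow_len <- if (grepl("0_100m", net$tow)) 100 else 500
  with_seed(seed, {
    vol <- tow_len * net$opening_m2 * aliquot *
      exp(rnorm(nrow(stations), 0, 0.15))
    samples <- tibble::tibble(station_id = stations$station_id,
                              volume_m3 = vol)
    ab <- dplyr::left_join(abundances, samples, by = "station_id")
    ab <- dplyr::left_join(
      ab, stations[, c("station_id", "temperature")], by = "station_id")
    gi <- truth$groups[match(ab$group, truth$groups$group), ]
    ab$n_raw <- rpois(nrow(ab), ab$abundance * ab$volume_m3)

    idx <- rep(seq_len(nrow(ab)), ab$n_raw)
    if (length(idx) == 0) {
      objects <- tibble::tibble(object_id = character(0),
                                station_id = character(0),
                                net_id = character(0), taxon = character(0),
                                ellipse_major_um = numeric(0),
                                ellipse_minor_um = numeric(0),
                                esd_um = numeric(0))
      return(list(objects = objects, samples = samples))
    }
    meanlog <- log(gi$base_esd_um[idx]) +
      gi$tsr_sign[idx] * gi$tsr_b[idx] * (ab$temperature[idx] - 15)
    esd <- rlnorm(length(idx), meanlog, esd_sdlog)
    keep <- runif(length(idx)) <
      retention_prob(esd, net$mesh_um, net$retention_steepness)
    idx <- idx[keep]
    esd <- esd[keep]
    r <- runif(length(idx), 1, 4)
    objects <- tibble::tibble(
      object_id = sprintf("%s_%s_%07d", net$net_id,
                          ab$station_id[idx], seq_along(idx)),
      station_id = ab$station_id[idx],
      net_id = net$net_id,
      taxon = ab$group[idx],
      ellipse_major_um = esd * sqrt(r),
      ellipse_minor_um = esd / sqrt(r),
      esd_um = esd
    )
    list(objects = objects, samples = samples)
  })
}

#' Simulate a complete virtual transect
#'
#' Stations, truth bundle, per-group true abundances and per-net object
#' tables, all reproducible from one seed (stage seeds are derived with
#' [stage_seed()]).
#'
#' @param config A [transect_config()].
#' @param seed Master seed.
#' @return A `zc_transect` bundle: `stations`, `truth`, `abundances`,
#'   `objects` (named list per net), `samples` (named list per net),
#'   `config`, `seed`.
#' @export
simulate_transect <- function(config = transect_config(), seed = 1) {
  stations <- generate_stations(config, seed = stage_seed(seed, 1))
  truth <- config$truth %||%
    default_truth(config$registry, seed = seed,
                  dominance_target = config$dominance)
  truth$seed <- seed
  abundances <- simulate_group_abundances(
    stations, config$registry, truth, seed = stage_seed(seed, 2),
    noise_sd = config$noise_sd)
  nets <- config$nets
  objects <- list()
  samples <- list()
  for (i in seq_len(nrow(nets))) {
    s <- sample_individuals(abundances, stations, nets[i, ], truth,
                            seed = stage_seed(seed, 10 + i),
                            aliquot = config$aliquot,
                            esd_sdlog = config$esd_sdlog)
    objects[[nets$net_id[i]]] <- s$objects
    samples[[nets$net_id[i]]] <- s$samples
  }
  out <- list(stations = stations, truth = truth, abundances = abundances,
              objects = objects, samples = samples, config = config,
              seed = seed)
  class(out) <- "zc_transect"
  out
}

#' Write a simulated transect to disk
#'
#' Writes `stations.csv`, per-net `objects_<net>.tsv` (Ecotaxa-flavoured) and
#' `samples_<net>.csv`, `truth.json`, and a `manifest.json` recording the
#' seed and a hash of the configuration.
#'
#' @param bundle A `zc_transect`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    abort(paste0("cannot create ", out_dir), class = "zoopcurves_io_error")
  readr::write_csv(bundle$stations, file.path(out_dir, "stations.csv"))
  for (net in names(bundle$objects)) {
    obj <- bundle$objects[[net]][, c("object_id", "station_id", "net_id",
                                     "taxon", "ellipse_major_um",
                                     "ellipse_minor_um")]
    readr::write_tsv(obj, file.path(out_dir, sprintf("objects_%s.tsv", net)))
    readr::write_csv(bundle$samples[[net]],
                     file.path(out_dir, sprintf("samples_%s.csv", net)))
  }
  tr <- bundle$truth
  jsonlite::write_json(
    list(groups = tr$groups, shapes = tr$shapes, k_true = tr$k_true,
         dominance_target = tr$dominance_target, seed = tr$seed),
    file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(seed = bundle$seed,
         config_hash = rlang::hash(bundle$config),
         n_stations = nrow(bundle$stations),
         nets = names(bundle$objects)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
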