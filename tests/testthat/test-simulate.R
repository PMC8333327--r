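test_that("fixed seed reproduces the dataset bit-for-bit", {
  cfg <- transect_config(n_stations = 60)
  expect_identical(generate_stations(cfg, seed = 7),
                   generate_stations(cfg, seed = 7))
  small <- transect_config(n_stations = 30)
  s1 <- simulate_transect(small, seed = 3)
  s2 <- simulate_transect(small, seed = 3)
  expect_identical(s1$stations, s2$stations)
  expect_identical(s1$abundances, s2$abundances)
  expect_identical(s1$objects, s2$objects)
})

test_that("phytoplankton fractions close to 100 at every station", {
  st <- generate_stations(transect_config(n_stations = 80), seed = 2)
  expect_lt(max(abs(st$pct_micro + st$pct_nano + st$pct_pico - 100)), 1e-9)
  expect_true(all(st$no2no3 >= 0 & st$chl_a >= 0 & st$mld >= 0))
  expect_true(all(abs(st$latitude) <= 90))
})

test_that("planted collinearity reaches its rank-correlation targets", {
  st <- generate_stations(transect_config(n_stations = 500), seed = 7)
  expect_lte(cor(st$temperature, st$oxygen, method = "spearman"), -0.9)
  expect_gte(cor(st$no2no3, st$po4, method = "spearman"), 0.8)
  expect_gte(cor(st$no2no3, st$sio2, method = "spearman"), 0.8)
})

test_that("configuration errors are caught", {
  expect_error(generate_stations(transect_config(n_stations = 3)),
               class = "zoopcurves_config_error")
  expect_error(generate_stations(transect_config(lat_range = c(-100, 80))),
               class = "zoopcurves_config_error")
})

test_that("mesh retention is a logistic in size, ordered across nets", {
  nets <- net_registry()
  for (i in seq_len(nrow(nets))) {
    m <- nets$mesh_um[i]
    expect_equal(retention_prob(m, m), 0.5)
    expect_gte(retention_prob(10 * m, m), 0.99)
    esd <- seq(10, 5000, by = 10)
    expect_true(all(diff(retention_prob(esd, m)) >= 0))
  }
  # for any fixed community, expected retention: Regent <= Bongo <= WP2
  esd <- rlnorm(5000, log(600), 0.6)
  mr <- sapply(nets$mesh_um, function(m) mean(retention_prob(esd, m)))
  names(mr) <- nets$net_id
  expect_lte(mr[["Regent"]], mr[["Bongo"]])
  expect_lte(mr[["Bongo"]], mr[["WP2"]])
})

test_that("zero noise makes abundance a deterministic monotone function", {
  cfg <- transect_config(n_stations = 40)
  st <- generate_stations(cfg, seed = 1)
  reg <- tibble::tibble(taxon = c("Zooplankton", "G1"),
                        parent = c(NA, "Zooplankton"),
                        level = c("root", "group"), bucket = FALSE)
  truth <- make_truth(
    groups = tibble::tibble(group = "G1", family = 1L,
                            intercept_ind_m3 = 2, base_esd_um = 500,
                            tsr_sign = -1L, tsr_b = 0.02),
    shapes = tibble::tibble(group = "G1", covariate = "temperature",
                            shape = "monotone", amplitude = -2))
  ab <- simulate_group_abundances(st, reg, truth, seed = 1, noise_sd = 0)
  ord <- order(st$temperature)
  expect_true(all(diff(ab$abundance[ord]) < 0))
  ab2 <- simulate_group_abundances(st, reg, truth, seed = 1, noise_sd = 0)
  expect_identical(ab, ab2)
  # missing truth record is a configuration error
  reg2 <- dplyr::bind_rows(reg, tibble::tibble(taxon = "G2",
                                               parent = "Zooplankton",
                                               level = "group",
                                               bucket = FALSE))
  expect_error(simulate_group_abundances(st, reg2, truth, seed = 1),
               class = "zoopcurves_config_error")
})

test_that("realized copepod dominance approaches the configured target", {
  cfg <- transect_config(n_stations = 200)
  sim <- simulate_transect(cfg, seed = 11)
  reg <- cfg$registry
  is_cop <- vapply(unique(sim$abundances$group), function(g)
    "Copepoda" %in% registry_ancestors(reg, g), logical(1))
  tot <- sum(sim$abundances$abundance)
  cop <- sum(sim$abundances$abundance[is_cop[sim$abundances$group]])
  expect_lt(abs(cop / tot - 0.74), 0.05)
})

test_that("emitted ellipse axes reconstruct the drawn ESD", {
  cfg <- recovery_config(n_stations = 20)
  sim <- simulate_transect(cfg, seed = 4)
  obj <- sim$objects$WP2
  expect_gt(nrow(obj), 100)
  expect_equal(sqrt(obj$ellipse_major_um * obj$ellipse_minor_um),
               obj$esd_um, tolerance = 1e-9)
  expect_true(all(obj$ellipse_major_um >= obj$ellipse_minor_um))
})

test_that("mean retained count matches the thinned-Poisson expectation", {
  st <- generate_stations(transect_config(n_stations = 4), seed = 1)
  reg <- tibble::tibble(taxon = c("Zooplankton", "G1"),
                        parent = c(NA, "Zooplankton"),
                        level = c("root", "group"), bucket = FALSE)
  truth <- make_truth(
    groups = tibble::tibble(group = "G1", family = 1L,
                            intercept_ind_m3 = 2, base_esd_um = 500,
                            tsr_sign = 0L, tsr_b = 0),
    shapes = tibble::tibble(group = "G1", covariate = "temperature",
                            shape = "null", amplitude = 0))
  ab <- simulate_group_abundances(st, reg, truth, seed = 1, noise_sd = 0)
  net <- net_registry()[1, ]
  sdlog <- 0.35
  counts <- vapply(1:1000, function(s) {
    nrow(sample_individuals(ab, st, net, truth, seed = s,
                            esd_sdlog = sdlog)$objects)
  }, numeric(1))
  # closed form: lambda = abundance * E[volume] * E[retention under the
  # lognormal size law]
  e_vol <- 100 * net$opening_m2 * 0.125 * exp(0.15^2 / 2)
  e_ret <- stats::integrate(function(e)
    retention_prob(e, net$mesh_um) * stats::dlnorm(e, log(500), sdlog),
    0, Inf)$value
  lambda <- sum(ab$abundance) * e_vol * e_ret
  se <- sqrt(lambda / 1000)  # Poisson variance, Monte Carlo standard error
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("a written dataset reads back field-for-field", {
  cfg <- recovery_config(n_stations = 15)
  sim <- simulate_transect(cfg, seed = 9)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  st <- readr::read_csv(file.path(dir, "stations.csv"),
                        show_col_types = FALSE)
  expect_equal(as.data.frame(st), as.data.frame(sim$stations),
               tolerance = 1e-12)
  rd <- read_object_table(file.path(dir, "objects_WP2.tsv"),
                          file.path(dir, "samples_WP2.csv"))
  expect_equal(nrow(rd$objects), nrow(sim$objects$WP2))
  expect_equal(rd$objects$esd_um, sim$objects$WP2$esd_um, tolerance = 1e-9)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 9)
})
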