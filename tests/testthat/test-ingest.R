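test_that("ESD is the area-equivalent diameter of the ellipse", {
  expect_equal(compute_esd(200, 200), 200)
  expect_equal(compute_esd(400, 100), 200)
  expect_equal(compute_esd(1000, 10), 100)
  expect_error(compute_esd(100, 0), class = "zoopcurves_input_error")
  expect_error(compute_esd(100, -5), class = "zoopcurves_input_error")
  expect_error(compute_esd(100, 200), class = "zoopcurves_input_error")
})

test_that("object tables parse, validate and warn on unknown columns", {
  dir <- withr::local_tempdir()
  obj <- tibble::tibble(object_id = c("a", "b", "c"), station_id = "st001",
                        net_id = "WP2", taxon = "Calanidae",
                        ellipse_major_um = c(400, 300, 250),
                        ellipse_minor_um = c(100, 300, 160))
  readr::write_tsv(obj, file.path(dir, "objects.tsv"))
  readr::write_csv(tibble::tibble(station_id = "st001", volume_m3 = 2),
                   file.path(dir, "samples.csv"))
  rd <- read_object_table(file.path(dir, "objects.tsv"),
                          file.path(dir, "samples.csv"))
  expect_equal(nrow(rd$objects), 3)
  expect_equal(rd$objects$esd_um[1], 200)

  readr::write_tsv(dplyr::mutate(obj, extra_col = 1),
                   file.path(dir, "objects2.tsv"))
  expect_warning(read_object_table(file.path(dir, "objects2.tsv"),
                                   file.path(dir, "samples.csv")),
                 "extra_col")

  obj$ellipse_minor_um[2] <- 0
  readr::write_tsv(obj, file.path(dir, "objects3.tsv"))
  expect_error(read_object_table(file.path(dir, "objects3.tsv"),
                                 file.path(dir, "samples.csv")),
               "b", class = "zoopcurves_validation_error")

  readr::write_tsv(obj[, -4], file.path(dir, "objects4.tsv"))
  expect_error(read_object_table(file.path(dir, "objects4.tsv"),
                                 file.path(dir, "samples.csv")),
               "taxon", class = "zoopcurves_format_error")
})

test_that("rollup annotation walks the full ancestor chain once per level", {
  reg <- toy_registry()
  out <- rollup_annotate(toy_objects("Calanidae"), reg)
  expect_setequal(out$group,
                  c("Calanidae", "Calanoida", "Copepoda", "Zooplankton"))
  expect_equal(nrow(out), 4)
  out_root <- rollup_annotate(toy_objects("Zooplankton"), reg)
  expect_equal(out_root$group, "Zooplankton")
  expect_error(rollup_annotate(toy_objects("Nonsense"), reg),
               "Nonsense", class = "zoopcurves_taxonomy_error")
})

test_that("rollup conserves counts: leaves sum to the root", {
  reg <- toy_registry()
  taxa <- sample(c("Calanidae", "Oithonidae", "Chaetognatha"), 60,
                 replace = TRUE)
  out <- rollup_annotate(toy_objects(taxa), reg)
  m <- station_group_metrics(out, c(st001 = 2))
  expect_equal(m$n_individuals[m$group == "Zooplankton"], 60)
  leaves <- c("Calanidae", "Oithonidae", "Chaetognatha")
  expect_equal(sum(m$n_individuals[m$group %in% leaves]), 60)
})

test_that("metrics divide counts by volume and respect the size threshold", {
  flat <- function(o) dplyr::mutate(o, group = .data$taxon)
  objs <- flat(toy_objects(rep("Calanidae", 50), esd = seq(100, 590, 10)))
  m <- station_group_metrics(objs, c(st001 = 2))
  expect_equal(m$abundance[m$group == "Calanidae"], 25)

  objs3 <- flat(toy_objects(rep("Calanidae", 3), esd = c(100, 200, 300)))
  m3 <- station_group_metrics(objs3, c(st001 = 1), min_n = 3)
  expect_equal(m3$median_esd_um, 200)

  objs19 <- flat(toy_objects(rep("Calanidae", 19),
                             esd = seq(100, 280, by = 10)))
  m19 <- station_group_metrics(objs19, c(st001 = 1), min_n = 20)
  expect_equal(m19$abundance, 19)
  expect_true(is.na(m19$median_esd_um))

  expect_error(station_group_metrics(objs3, c(st001 = 0)),
               class = "zoopcurves_input_error")
})

test_that("metrics are invariant to object order and medians stay bounded", {
  reg <- toy_registry()
  set.seed(42)
  taxa <- sample(c("Calanidae", "Oithonidae"), 80, replace = TRUE)
  esd <- rlnorm(80, log(300), 0.4)
  objs <- rollup_annotate(toy_objects(taxa, esd = esd), reg)
  m1 <- station_group_metrics(objs, c(st001 = 2), min_n = 5)
  perm <- sample(nrow(objs))
  m2 <- station_group_metrics(objs[perm, ], c(st001 = 2), min_n = 5)
  expect_equal(dplyr::arrange(m1, .data$group),
               dplyr::arrange(m2, .data$group))
  # parent median within its members' range
  med_cop <- m1$median_esd_um[m1$group == "Copepoda"]
  expect_gte(med_cop, min(esd))
  expect_lte(med_cop, max(esd))
})

test_that("retention thresholds are inclusive at 30 stations", {
  mk <- function(n_st, n_ind) tibble::tibble(
    station_id = sprintf("st%03d", seq_len(n_st)), net_id = "WP2",
    group = "G", n_individuals = n_ind,
    abundance = 1, median_esd_um = 100)
  r29 <- retain_groups(mk(29, 25))
  expect_false(any(r29$metric == "abundance"))
  r30 <- retain_groups(mk(30, 25))
  expect_setequal(r30$metric, c("abundance", "median_esd"))
  # stations below min_n count for abundance but not for size structure
  r_small <- retain_groups(mk(30, 10))
  expect_equal(r_small$metric, "abundance")
  expect_equal(nrow(retain_groups(mk(0, 0))), 0)
})

test_that("band composition normalizes, lumps rare taxa, assigns band edges", {
  reg <- toy_registry()
  st <- tibble::tibble(station_id = c("s1", "s2"), latitude = c(10, 30))
  metrics <- tibble::tibble(
    station_id = "s1", net_id = "WP2",
    group = c("Copepoda", "Calanidae", "Oithonidae"),
    n_individuals = c(40, 30, 10),
    abundance = c(4, 3, 1), median_esd_um = NA)
  cb <- composition_by_band(metrics, st, reg, level = "family")
  expect_equal(cb$fraction[cb$group == "Calanidae"], 0.75)
  expect_equal(cb$fraction[cb$group == "Oithonidae"], 0.25)
  expect_true(all(cb$band == "tropical"))  # |lat| = 10 and the <=30 rule
  sums <- tapply(cb$fraction, paste(cb$band, cb$net_id), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # a family at 0.5% moves to "other"
  metrics2 <- tibble::tibble(
    station_id = "s1", net_id = "WP2",
    group = c("Copepoda", "Calanidae", "Oithonidae"),
    n_individuals = 1, abundance = c(200, 199, 1), median_esd_um = NA)
  cb2 <- composition_by_band(metrics2, st, reg, level = "family")
  expect_false("Oithonidae" %in% cb2$group)
  expect_equal(cb2$fraction[cb2$group == "other"], 0.005, tolerance = 1e-9)
})
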