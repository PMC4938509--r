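# Small synthetic study used across tests: 4 fields/region, 2 visits,
# 2 bushes/transect, reduced species pools. Cheap to generate, still
# exercises every schema.
tinyConfig <- function(...) {
  base <- simulationConfig(
    n_fields_per_region = 4L,
    visits = c(BC = 2L, MI = 2L),
    design = list(bushes_per_transect = 2L, focal_bushes = 2L,
                  focal_berries = 3L, flowers_mean = 8),
    pools = list(BC = list(pool = 6L, x = 0.5),
                 MI = list(pool = 20L, x = 0.9)),
    specimens_per_field = c(BC = 15, MI = 25))
  modifyList(base, list(...))
}

tinyStudy <- function(seed = 42L, ...) simulateStudy(tinyConfig(...), seed)$study

# A minimal hand-built bundle with fully controlled numbers.
handBundle <- function() {
  fields <- data.frame(
    field_id = c("f1", "f2"), region = c("BC", "MI"),
    stocking_rate = c(10, 5), row_orientation = c("parallel", "perpendicular"),
    bush_spacing = 1.2, row_spacing = 3, canes_per_bush = 10,
    clusters_per_cane = 20, berries_per_cluster = 5, price = c(3.3, 2.84))
  surveys <- data.frame(
    field_id = rep(c("f1", "f2"), each = 2L),
    distance = c(0L, 25L, 0L, 25L),
    date = "2013-05-05", time_block = "morning", duration = 10L,
    honey_bee = c(3L, 1L, 5L, 2L), bumble_bee = c(1L, 0L, 0L, 1L),
    other_bee = 0L, other_visitor = 0L)
  specimens <- data.frame(
    field_id = c("f1", "f1", "f2"),
    species_id = c("bombus_a", "andrena_b", "andrena_b"),
    count = c(4L, 1L, 2L))
  clusters <- data.frame(
    field_id = rep(c("f1", "f2"), each = 3L), distance = 0L, bush_id = 1L,
    cluster_id = paste0(rep(c("e", "o", "h"), 2L), "_1"),
    treatment = rep(c("excluded", "open", "hand"), 2L),
    n_flowers = 10L, n_fruit = c(3L, 6L, 9L, 2L, 8L, 8L),
    cluster_weight = c(4.5, 12, 19.8, 3.0, 16, 16.8))
  berries <- data.frame(
    field_id = "f1", distance = 0L, bush_id = 1L, cluster_id = "o_1",
    berry_id = 1:2, weight = c(2.0, 2.2), mature_seeds = c(14L, 16L))
  landscape <- data.frame(
    field_id = rep(c("f1", "f2"), each = 3L),
    radius_m = rep(c(300L, 1000L, 2000L), 2L),
    cover_class = "woodland",
    area_m2 = c(0.1, 0.2, 0.25, 0.5, 0.55, 0.6) * pi *
      rep(c(300, 1000, 2000)^2, 2L))
  extra <- data.frame(
    field_id = rep(c("f1", "f2"), each = 3L),
    radius_m = rep(c(300L, 1000L, 2000L), 2L),
    cover_class = "urban",
    area_m2 = c(0.9, 0.8, 0.75, 0.5, 0.45, 0.4) * pi *
      rep(c(300, 1000, 2000)^2, 2L))
  StudyBundle(fields = fields, surveys = surveys, specimens = specimens,
              clusters = clusters, berries = berries,
              landscape = rbind(landscape, extra))
}
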