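test_that("region detection follows threshold, connectivity and size rules", {
  zero <- grid_snapshot(matrix(0, 10, 10), "A.B")
  expect_length(detect_regions(zero, region_params(0.5, 1)), 0L)

  block <- make_shape_grid(list(list(type = "rect", row = 3, col = 2,
                                     height = 3, width = 5)), 10, 10,
                           scale_subsystem = "A.B")
  regs <- detect_regions(block, region_params(0.5, 1))
  expect_length(regs, 1L)
  expect_identical(nrow(regs[[1]]$cells), 15L)

  # diagonal contact joins under the Moore neighbourhood
  diag2 <- matrix(0, 6, 6); diag2[2, 2] <- 1; diag2[3, 3] <- 1
  expect_length(detect_regions(grid_snapshot(diag2, "A.B"),
                               region_params(0.5, 1)), 1L)

  # strict size filter: a component of exactly min_size cells is discarded
  two <- matrix(0, 6, 6); two[2, 2:3] <- 1
  expect_length(detect_regions(grid_snapshot(two, "A.B"),
                               region_params(0.5, 2)), 0L)
  expect_length(detect_regions(grid_snapshot(two, "A.B"),
                               region_params(0.5, 1)), 1L)
})

test_that("cluster detection matches the DBSCAN contract on stated examples", {
  expect_length(detect_clusters(list(), cluster_params(1, 1)), 0L)

  # three regions with pairwise centroid distance 1 -> one cluster
  regs <- list(point_region(0, 0), point_region(0, 1), point_region(0, 2))
  cl <- detect_clusters(regs, cluster_params(1, 2))
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$member_indices, 1:3)

  # two regions far apart with min_regions 1 -> two singleton clusters
  far <- list(point_region(0, 0), point_region(0, 100))
  cl2 <- detect_clusters(far, cluster_params(2, 1))
  expect_length(cl2, 2L)
  expect_identical(attr(cl2, "noise"), integer(0))

  # min_regions too high -> all noise
  cl3 <- detect_clusters(far, cluster_params(2, 2))
  expect_length(cl3, 0L)
  expect_identical(attr(cl3, "noise"), 1:2)
})

test_that("measures hit their closed-form values on simple shapes", {
  block <- make_shape_grid(list(list(type = "rect", row = 3, col = 2,
                                     height = 3, width = 5)), 10, 10,
                           scale_subsystem = "A.B")
  reg <- detect_regions(block, region_params(0.5, 1))[[1]]
  m <- compute_measures(reg, block)
  expect_identical(m[["area"]], 15)
  expect_identical(m[["perimeter"]], 12)     # boundary path through centers
  expect_identical(m[["clusteredness"]], 1)  # no holes
  expect_equal(m[["rectangleMeasure"]], 1, tolerance = 1e-9)
  expect_identical(m[["density"]], 1)
  expect_identical(m[["centroidX"]], 3)      # cols 1..5, 0-based
  expect_identical(m[["centroidY"]], 3)      # rows 2..4, 0-based

  faint <- make_shape_grid(list(list(type = "rect", row = 2, col = 2,
                                     height = 2, width = 3, value = 0.4)),
                           8, 8, scale_subsystem = "A.B")
  mf <- compute_measures(detect_regions(faint, region_params(0.3, 1))[[1]],
                         faint)
  expect_identical(mf[["density"]], 0.4)

  # rasterized disc: closest to a circle, farther from a triangle
  disc <- make_shape_grid(list(list(type = "disc", row = 21, col = 21,
                                    radius = 8)), 41, 41,
                          scale_subsystem = "A.B")
  md <- compute_measures(detect_regions(disc, region_params(0.5, 1))[[1]],
                         disc)
  expect_gte(md[["circleMeasure"]], 0.9)
  expect_gt(md[["circleMeasure"]], md[["triangleMeasure"]])
  expect_identical(md[["angle"]], 360)       # grid centre inside the disc

  # annulus: hole makes clusteredness < 1
  ring <- make_shape_grid(list(list(type = "ring", row = 11, col = 11,
                                    outer = 7, inner = 4)), 21, 21,
                          scale_subsystem = "A.B")
  mr <- compute_measures(detect_regions(ring, region_params(0.5, 1))[[1]],
                         ring)
  expect_lt(mr[["clusteredness"]], 1)
})

test_that("translation and scaling affect the expected measures only", {
  base <- make_shape_grid(list(list(type = "rect", row = 3, col = 3,
                                    height = 4, width = 6)), 40, 40,
                          scale_subsystem = "A.B")
  moved <- make_shape_grid(list(list(type = "rect", row = 13, col = 19,
                                     height = 4, width = 6)), 40, 40,
                           scale_subsystem = "A.B")
  m1 <- compute_measures(detect_regions(base, region_params(0.5, 1))[[1]], base)
  m2 <- compute_measures(detect_regions(moved, region_params(0.5, 1))[[1]],
                         moved)
  unchanged <- setdiff(names(m1), c("centroidX", "centroidY",
                                    "distanceFromOrigin", "angle"))
  expect_equal(m1[unchanged], m2[unchanged], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(m1[["centroidX"]], m2[["centroidX"]])))

  doubled <- make_shape_grid(list(list(type = "rect", row = 3, col = 3,
                                       height = 8, width = 12)), 40, 40,
                             scale_subsystem = "A.B")
  m4 <- compute_measures(detect_regions(doubled, region_params(0.5, 1))[[1]],
                         doubled)
  expect_equal(m4[["area"]], 4 * m1[["area"]], tolerance = 0.1)

  disc <- make_shape_grid(list(list(type = "disc", row = 20, col = 20,
                                    radius = 5)), 40, 40,
                          scale_subsystem = "A.B")
  disc2 <- make_shape_grid(list(list(type = "disc", row = 20, col = 20,
                                     radius = 10)), 40, 40,
                           scale_subsystem = "A.B")
  a1 <- compute_measures(detect_regions(disc, region_params(0.5, 1))[[1]],
                         disc)[["area"]]
  a2 <- compute_measures(detect_regions(disc2, region_params(0.5, 1))[[1]],
                         disc2)[["area"]]
  expect_lt(abs(a2 / a1 - 4) / 4, 0.1)   # rasterization tolerance 10%
})

test_that("snapshot analysis composes detection and measurement", {
  zero <- grid_snapshot(matrix(0, 10, 10), "A.B")
  expect_length(analyse_snapshot(zero), 0L)

  block <- make_shape_grid(list(list(type = "rect", row = 3, col = 2,
                                     height = 3, width = 5)), 10, 10,
                           scale_subsystem = "Organ.Liver")
  recs <- analyse_snapshot(block, region_params(0.5, 1), cluster_params(2, 1))
  expect_length(recs, 2L)   # one region + one singleton cluster
  expect_identical(recs[[1]]$entity_type, "regions")
  expect_identical(recs[[2]]$entity_type, "clusters")
  expect_true(all(vapply(recs, function(r) r$scale_subsystem, character(1)) ==
                    "Organ.Liver"))
  reg <- detect_regions(block, region_params(0.5, 1))[[1]]
  expect_identical(recs[[1]]$measures, compute_measures(reg, block))

  tab <- entity_records_table(recs)
  expect_identical(nrow(tab), 2L)
  expect_true("area" %in% names(tab))
})

test_that("spatial configuration files reproduce and constrain the registry", {
  default <- default_spatial_registry()
  path <- withr::local_tempfile(fileext = ".xml")
  write_spatial_config(default, path)
  reloaded <- read_spatial_config(path)
  expect_identical(reloaded$entity_types, default$entity_types)
  expect_identical(reloaded$measures$name, default$measures$name)
  expect_identical(reloaded$measures$min, default$measures$min)
  expect_identical(reloaded$measures$max, default$measures$max)

  # regions-only registry: cluster entities in MSTML then fail validation
  regions_only <- read_spatial_config(paste0(
    '<spatialConfig><entityType name="regions" tag="region" detector="regions"/>',
    paste(sprintf('<measure name="%s" procedure="%s" min="%g" max="%g"/>',
                  default$measures$name, default$measures$procedure,
                  default$measures$min, default$measures$max),
          collapse = ""),
    "</spatialConfig>"))
  expect_error(read_mstml(listing_trace_xml(), regions_only),
               class = "mstmc_error_format")

  expect_error(read_spatial_config(paste0(
    '<spatialConfig><entityType name="regions" detector="regions"/>',
    '<measure name="volume" procedure="volume" min="0" max="1"/>',
    "</spatialConfig>")), class = "mstmc_error_config")
  expect_error(read_spatial_config(paste0(
    '<spatialConfig><entityType name="regions" detector="regions"/>',
    '<measure name="area" procedure="area" min="2" max="1"/>',
    "</spatialConfig>")), class = "mstmc_error_config")
})

test_that("region detection agrees with the label-propagation oracle", {
  set.seed(404)
  for (rep in 1:60) {
    m <- sample(4:18, 1L); n <- sample(4:18, 1L)
    vals <- matrix(stats::runif(m * n), m, n)
    thr <- stats::runif(1, 0.3, 0.7)
    min_size <- sample(1:3, 1L)
    gs <- grid_snapshot(vals, "A.B")
    got <- detect_regions(gs, region_params(thr, min_size))
    want <- Filter(function(cc) nrow(cc) > min_size,
                   oracle_components8(vals >= thr))
    expect_identical(length(got), length(want))
    for (k in seq_along(got))
      expect_identical(unname(got[[k]]$cells), unname(want[[k]]))
  }
})

test_that("cluster detection agrees with the closure oracle", {
  set.seed(505)
  for (rep in 1:60) {
    n <- sample(1:25, 1L)
    pts <- cbind(sample(0:40, n, replace = TRUE),
                 sample(0:40, n, replace = TRUE))
    regs <- lapply(seq_len(n), function(i) point_region(pts[i, 1], pts[i, 2]))
    eps <- stats::runif(1, 0.5, 15)
    minr <- sample(1:4, 1L)
    got <- detect_clusters(regs, cluster_params(eps, minr))
    want <- oracle_dbscan(cbind(pts[, 2], pts[, 1]), eps, minr)
    expect_identical(lapply(got, `[[`, "member_indices"), want$clusters)
    expect_identical(attr(got, "noise"), which(is.na(want$assignment)))
  }
})
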