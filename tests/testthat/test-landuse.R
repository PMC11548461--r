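square <- function(x0, y0, side = 1) {
  cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
}

test_that("legend harmonisation is total and deterministic", {
  mapping <- c(homefields = "homefields", cropland_a = "bushfields",
               cropland_b = "bushfields", savannah = "rangelands")
  expect_equal(harmonize_legend(c("homefields", "savannah"), mapping),
               c("homefields", "rangelands"))
  # two raw cropland classes collapse to the same coarse unit
  expect_equal(harmonize_legend(c("cropland_a", "cropland_b"), mapping),
               c("bushfields", "bushfields"))
  expect_error(harmonize_legend(c("cropland_a", "mystery"), mapping),
               "mystery")
  expect_error(harmonize_legend("x", c(x = "wetlands")), "unknown unit")
})

test_that("point-in-polygon join honours priority and id order", {
  fine <- landuse_map(list(list(id = 1, label = "hf", coords = square(0, 0))),
                      c(hf = "homefields"), priority = 2,
                      resolution_tag = "fine")
  coarse <- landuse_map(list(list(id = 1, label = "bf",
                                  coords = square(-1, -1, 3))),
                        c(bf = "bushfields"), priority = 1,
                        resolution_tag = "coarse")
  fx <- data.frame(lon = c(0.5, -0.5, 5), lat = c(0.5, -0.5, 5))
  out <- join_fixes(fx, list(coarse, fine))
  # inside both -> fine layer wins; inside coarse only -> coarse;
  # inside none -> unclassified
  expect_equal(out$unit, c("homefields", "bushfields", "unclassified"))
  expect_equal(out$source_layer, c("fine", "coarse", NA))
  # same-priority overlap: lowest polygon id wins
  twin <- landuse_map(list(
    list(id = 2, label = "b", coords = square(0, 0)),
    list(id = 1, label = "a", coords = square(0.25, 0.25, 0.5))),
    c(a = "fallows", b = "lowlands"), priority = 1)
  expect_equal(join_fixes(data.frame(lon = 0.5, lat = 0.5), twin)$unit,
               "fallows")
})

test_that("boundary points resolve deterministically as inside", {
  m <- landuse_map(list(list(id = 1, label = "u", coords = square(0, 0))),
                   c(u = "rangelands"))
  edge <- data.frame(lon = c(0, 1, 0.5), lat = c(0.5, 0.5, 0))
  for (rep in 1:3)
    expect_equal(join_fixes(edge, m)$unit, rep("rangelands", 3))
})

test_that("the join is a function of position and is idempotent", {
  surv <- small_survey()
  fx <- head(surv$gps[, c("lon", "lat")], 200)
  j1 <- join_fixes(fx, surv$landuse)
  j2 <- join_fixes(j1, surv$landuse)
  expect_equal(j1$unit, j2$unit)
  expect_equal(length(j1$unit), nrow(fx)) # exactly one unit per fix
  # the home-centred survey fixes are nearly all classified
  expect_gt(mean(j1$unit != "unclassified"), 0.99)
})

test_that("geojson round-trips polygons, legend and priority", {
  m <- landuse_map(list(
    list(id = 1, label = "hf", coords = square(-16.51, 14.49, 0.01)),
    list(id = 2, label = "sv", coords = square(-16.6, 14.4, 0.2))),
    c(hf = "homefields", sv = "rangelands"), priority = 3,
    resolution_tag = "test")
  path <- tempfile(fileext = ".geojson")
  write_landuse_geojson(m, path)
  m2 <- read_landuse_geojson(path)
  expect_equal(m2$priority, 3L)
  expect_equal(m2$legend[order(names(m2$legend))],
               m$legend[order(names(m$legend))])
  fx <- data.frame(lon = c(-16.505, -16.5), lat = c(14.495, 14.3))
  expect_equal(join_fixes(fx, m2)$unit, join_fixes(fx, m)$unit)
  expect_error(landuse_map(list(list(id = 1, label = "x",
                                     coords = matrix(1, 2, 2))),
                           c(x = "other")), "invalid geometry")
})

test_that("legend yaml reader returns a named mapping", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("cropland_a: bushfields", "swamp: lowlands"), p)
  lg <- read_legend_yaml(p)
  expect_equal(lg[["swamp"]], "lowlands")
  expect_equal(harmonize_legend("cropland_a", lg), "bushfields")
})
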