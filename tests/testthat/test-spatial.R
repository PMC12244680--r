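test_that("ESRI ASCII grids read headers, nodata and round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0", "cellsize 30",
    "NODATA_value -9999",
    "100 100 100", "100 100 100", "100 100 100"
  ), path)
  g <- load_grid(path)
  expect_equal(g$n_rows, 3)
  expect_equal(g$cell_size, 30)
  expect_true(all(g$elevation == 100))
  expect_false(anyNA(g$elevation))

  writeLines(c(
    "ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0", "cellsize 30",
    "NODATA_value -9999",
    "100 100 100", "100 -9999 100", "100 100 100"
  ), path)
  g2 <- load_grid(path)
  expect_true(is.na(g2$elevation[2, 2]))
  expect_equal(sum(is.na(g2$elevation)), 1)

  writeLines(c("ncols three", "nrows 3"), path)
  expect_error(load_grid(path), "ncols")

  # write/read round trip on a synthetic 50x50 fixture is bit-exact
  ws <- make_synthetic_watershed(seed = 42, n_rows = 50, n_cols = 50)
  p2 <- withr::local_tempfile(fileext = ".asc")
  write_grid(ws$grid, p2)
  back <- load_grid(p2)
  expect_identical(back$elevation, ws$grid$elevation)
  expect_equal(back$cell_size, ws$grid$cell_size)
})

test_that("D8 flow directions: ramps, pits and acyclicity", {
  # inclined plane dipping east: every interior cell points east (slot 1)
  z <- matrix(rep(seq(10, 1, length.out = 10), each = 8), 8, 10)
  fd <- flow_directions(af_grid(z))
  expect_true(all(fd[, 1:9] == 1L))
  expect_true(all(fd[, 10] == 0L)) # eastern edge has no lower neighbor

  # single central pit: all 8 neighbors drain to the center, center is a sink
  z <- matrix(5, 3, 3)
  z[2, 2] <- 1
  fd <- flow_directions(af_grid(z))
  expect_equal(fd[2, 2], 0L)
  ds <- aridfarm:::.downstream_index(fd, 3, 3)
  nb <- setdiff(seq_len(9), 5)
  expect_true(all(ds[nb] == 5))

  # random surfaces route acyclically: following downstream pointers from any
  # cell terminates within n_cells steps
  for (seed in 1:5) {
    z <- matrix(with_seed(seed, stats::runif(400)), 20, 20)
    g <- af_grid(z)
    fd <- flow_directions(g)
    ds <- aridfarm:::.downstream_index(fd, 20, 20)
    for (start in seq(1, 400, by = 37)) {
      cur <- start
      steps <- 0
      while (ds[cur] > 0) {
        cur <- ds[cur]
        steps <- steps + 1
        expect_lt(steps, 401)
      }
    }
  }
})

test_that("synthetic watershed is reproducible and drains to the channel", {
  a <- make_synthetic_watershed(seed = 42)
  b <- make_synthetic_watershed(seed = 42)
  expect_identical(a$grid$elevation, b$grid$elevation)
  expect_identical(a$soil, b$soil)
  expect_error(make_synthetic_watershed(seed = 1, n_rows = 5, n_cols = 5),
               ">= 10")

  # every hillslope cell has a strictly descending path reaching the channel
  ws <- small_watershed()
  fd <- flow_directions(ws$grid)
  nr <- ws$grid$n_rows
  ds <- aridfarm:::.downstream_index(fd, nr, ws$grid$n_cols)
  chan_col <- ws$channel_col
  on_channel <- function(i) (((i - 1) %/% nr) + 1) == chan_col
  reaches <- vapply(seq_along(ds), function(i) {
    cur <- i
    while (!on_channel(cur) && ds[cur] > 0) cur <- ds[cur]
    on_channel(cur)
  }, logical(1))
  expect_true(all(reaches))

  # valley-floor cells carry the high-runoff silt-loam class (CN 92)
  tab <- soil_class_table()
  expect_true(all(ws$soil[, chan_col] == "R"))
  expect_equal(tab$cn[tab$code == "R"], 92L)
  expect_equal(tab$group[tab$code == "R"], "D")
})

test_that("land-use assignment links exactly r disjoint upslope catchment cells", {
  ws <- small_watershed()
  lu <- assign_land_use(ws, runoff_ratio = 5, wheat_ratio = 5, n_farms = 2,
                        grape_per_farm = 1, wheat_per_farm = 1,
                        reserve_sites = 0)
  expect_true(all(lengths(lu$catchments) == 5))

  # catchment cells are upslope of their terrace (strictly higher elevation)
  z <- ws$grid$elevation
  for (i in seq_len(nrow(lu$terraces))) {
    expect_true(all(z[lu$catchments[[i]]] > z[lu$terraces$cell[i]]))
  }

  # terraces sharing the hillslope have disjoint catchment sets
  all_cells <- unlist(lu$catchments)
  expect_equal(length(all_cells), length(unique(all_cells)))

  # requested ratio achieved exactly at r = 30 on the full-size fixture
  ws2 <- make_synthetic_watershed(seed = 1)
  lu30 <- assign_land_use(ws2, runoff_ratio = 30)
  grape <- lu30$terraces$crop == "grape"
  expect_equal(mean(lengths(lu30$catchments)[grape]), 30)

  # cells are conserved across categories
  counts <- table(lu30$category)
  expect_equal(sum(counts), ws2$grid$n_rows * ws2$grid$n_cols)

  # infeasible demand errors instead of silently shorting a terrace
  expect_error(
    assign_land_use(ws, runoff_ratio = 30, n_farms = 8, grape_per_farm = 3,
                    wheat_per_farm = 1),
    "catchment|channel"
  )
  expect_error(assign_land_use(ws, runoff_ratio = 50), "runoff_ratio")
})

test_that("soil rasters and land-use maps export as integer ASCII grids", {
  ws <- small_watershed()
  p <- withr::local_tempfile(fileext = ".asc")
  write_soil_asc(ws$soil, p)
  expect_identical(load_soil_asc(p), ws$soil)
  lu <- assign_land_use(ws, runoff_ratio = 8, n_farms = 2, grape_per_farm = 1,
                        wheat_per_farm = 1, reserve_sites = 0)
  p2 <- withr::local_tempfile(fileext = ".asc")
  write_landuse_asc(lu, p2)
  expect_identical(load_grid(p2)$elevation, matrix(as.numeric(lu$category),
                                                   nrow(lu$category)))
})
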