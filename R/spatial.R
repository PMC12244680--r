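# Gridded watershed: ESRI ASCII I/O, D8 routing, land-use assignment and a
# synthetic-watershed generator.
#
# Conventions (fixed here, used everywhere): row 1 = north edge, 0-based grid
# maths are avoided — all indices are 1-based R indices; cell centers sit at
# ((col - 0.5) * cell_size, (row - 0.5) * cell_size) from the NW corner.

# D8 neighbor table in tie-break priority order: E, S, W, N, SE, SW, NW, NE.
.d8_dr <- c(0L, 1L, 0L, -1L, 1L, 1L, -1L, -1L)
.d8_dc <- c(1L, 0L, -1L, 0L, 1L, -1L, -1L, 1L)
.d8_dist <- function(cell_size) cell_size * c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))

# Land-use integer codes used in exported rasters.
.lu_codes <- c(
  natural = 0L, catchment_cleared = 1L, catchment_mounds = 2L,
  terrace_grape = 3L, terrace_wheat = 4L, channel = 5L, settlement = 6L
)

#' Construct a grid object
#'
#' @param elevation Numeric matrix (row 1 = north). `NA` marks nodata cells.
#' @param cell_size Cell edge length in meters (default 30).
#' @param xll,yll Coordinates of the lower-left corner (meters).
#' @return An object of class `af_grid`.
#' @export
af_grid <- function(elevation, cell_size = 30, xll = 0, yll = 0) {
  if (!is.matrix(elevation) || !is.numeric(elevation)) {
    stop_af("elevation must be a numeric matrix")
  }
  if (cell_size <= 0) stop_af("cell_size must be positive")
  if (all(is.na(elevation))) stop_af("empty domain: all cells are nodata")
  if (any(!is.finite(elevation) & !is.na(elevation))) {
    stop_af("non-finite elevation in non-masked cells")
  }
  structure(
    list(
      elevation = elevation, n_rows = nrow(elevation), n_cols = ncol(elevation),
      cell_size = cell_size, xll = xll, yll = yll
    ),
    class = "af_grid"
  )
}

#' @export
print.af_grid <- function(x, ...) {
  cat(sprintf(
    "<af_grid> %d x %d cells, %g m resolution, elevation %.1f-%.1f m, %d nodata\n",
    x$n_rows, x$n_cols, x$cell_size,
    min(x$elevation, na.rm = TRUE), max(x$elevation, na.rm = TRUE),
    sum(is.na(x$elevation))
  ))
  invisible(x)
}

#' Read an ESRI ASCII grid raster
#'
#' Honors `NODATA_value` (cells become `NA`) and accepts `xllcorner` or
#' `xllcenter` headers.
#'
#' @param path Path to a `.asc` file.
#' @return An [af_grid()] object.
#' @export
load_grid <- function(path) {
  if (!file.exists(path)) stop_af("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  data_start <- 1L
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c(
      "ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
      "yllcenter", "cellsize", "nodata_value"
    )) {
      val <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(val)) stop_af("malformed header field '%s' in %s", key, path)
      hdr[[key]] <- val
      data_start <- i + 1L
    } else {
      break
    }
  }
  for (req in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[req]])) stop_af("missing header field '%s' in %s", req, path)
  }
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  if (nc < 1 || nr < 1) stop_af("malformed header field 'ncols/nrows' in %s", path)
  vals <- scan(text = paste(lines[data_start:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop_af("data block has %d values, header promises %d (ncols x nrows)",
            length(vals), nr * nc)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  cs <- hdr$cellsize
  xll <- hdr$xllcorner %||% (if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2 else 0)
  yll <- hdr$yllcorner %||% (if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2 else 0)
  af_grid(m, cell_size = cs, xll = xll, yll = yll)
}

#' Write a matrix or grid as an ESRI ASCII raster
#'
#' @param x An [af_grid()] object or a numeric matrix.
#' @param path Output path.
#' @param cell_size,xll,yll Used when `x` is a bare matrix.
#' @param nodata_value Value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_grid <- function(x, path, cell_size = 30, xll = 0, yll = 0,
                       nodata_value = -9999) {
  if (inherits(x, "af_grid")) {
    m <- x$elevation
    cell_size <- x$cell_size
    xll <- x$xll
    yll <- x$yll
  } else {
    m <- x
  }
  m[is.na(m)] <- nodata_value
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.6g", xll),
    sprintf("yllcorner %.6g", yll),
    sprintf("cellsize %.10g", cell_size),
    sprintf("NODATA_value %.10g", nodata_value)
  )
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Soil classification table
#'
#' Default mapping of soil-class codes to hydrologic soil groups and curve
#' numbers for loessial desert catchments: valley silt loams (R, group D,
#' CN 92), loam hillslopes (S, group C, CN 85) and rocky upper slopes
#' (X, group B, CN 77).
#'
#' @return A data.frame with columns `code`, `texture`, `group`, `cn`.
#' @export
soil_class_table <- function() {
  data.frame(
    code = c("R", "S", "X"),
    texture = c("silt loam (very fine)", "loam", "rocks and gravel (loam)"),
    group = c("D", "C", "B"),
    cn = c(92L, 85L, 77L),
    stringsAsFactors = FALSE
  )
}

# linear index helpers (column-major, as R matrices)
.cell_id <- function(r, c, nr) (c - 1L) * nr + r

#' Compute terrain slope in degrees
#'
#' Steepest-descent slope toward any of the 8 neighbors; cells with no lower
#' neighbor have slope 0.
#'
#' @param grid An [af_grid()].
#' @return Matrix of slopes in degrees.
#' @export
slope_degrees <- function(grid) {
  fd <- flow_directions(grid)
  z <- grid$elevation
  nr <- grid$n_rows
  nc <- grid$n_cols
  dist <- .d8_dist(grid$cell_size)
  out <- matrix(0, nr, nc)
  idx <- which(fd > 0)
  if (length(idx)) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    k <- fd[idx]
    nb <- .cell_id(r + .d8_dr[k], c + .d8_dc[k], nr)
    out[idx] <- atan((z[idx] - z[nb]) / dist[k]) * 180 / pi
  }
  out[is.na(z)] <- NA_real_
  out
}

#' D8 flow directions
#'
#' Each cell points to its steepest-descent neighbor among the 8 adjacent
#' cells; only strictly lower neighbors qualify, so flats and pits are sinks.
#' Ties are broken by a fixed priority order (E, S, W, N, SE, SW, NW, NE) for
#' determinism.
#'
#' @param grid An [af_grid()].
#' @return Integer matrix: 0 for sinks/outlets, otherwise the neighbor slot
#'   1-8 in priority order; `NA` on nodata cells.
#' @export
flow_directions <- function(grid) {
  z <- grid$elevation
  nr <- grid$n_rows
  nc <- grid$n_cols
  dist <- .d8_dist(grid$cell_size)
  best_grad <- matrix(0, nr, nc) # require strictly positive drop
  fd <- matrix(0L, nr, nc)
  for (k in 1:8) {
    zn <- matrix(NA_real_, nr, nc)
    rs <- (1 + max(0, -.d8_dr[k])):(nr - max(0, .d8_dr[k]))
    cs <- (1 + max(0, -.d8_dc[k])):(nc - max(0, .d8_dc[k]))
    zn[rs, cs] <- z[rs + .d8_dr[k], cs + .d8_dc[k]]
    grad <- (z - zn) / dist[k]
    better <- !is.na(grad) & grad > best_grad
    best_grad[better] <- grad[better]
    fd[better] <- k
  }
  fd[is.na(z)] <- NA_integer_
  fd
}

# downstream linear index per cell (0 = sink), from a flow-direction matrix
.downstream_index <- function(fd, nr, nc) {
  ds <- integer(nr * nc)
  idx <- which(fd > 0)
  if (length(idx)) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    k <- fd[idx]
    ds[idx] <- .cell_id(r + .d8_dr[k], c + .d8_dc[k], nr)
  }
  ds
}

#' Flow accumulation
#'
#' Number of cells draining through each cell (including itself), obtained by
#' accumulating along the D8 routing graph in decreasing elevation order.
#'
#' @param grid An [af_grid()].
#' @param fd Optional precomputed [flow_directions()] matrix.
#' @return Integer matrix of upslope cell counts.
#' @export
flow_accumulation <- function(grid, fd = flow_directions(grid)) {
  nr <- grid$n_rows
  nc <- grid$n_cols
  ds <- .downstream_index(fd, nr, nc)
  acc <- rep(1L, nr * nc)
  acc[is.na(grid$elevation)] <- 0L
  ord <- order(grid$elevation, decreasing = TRUE, na.last = NA)
  for (i in ord) {
    if (ds[i] > 0L) acc[ds[i]] <- acc[ds[i]] + acc[i]
  }
  matrix(acc, nr, nc)
}

#' Generate a synthetic headwater watershed
#'
#' Builds a reproducible V-shaped valley draining south to a single channel
#' outlet: two concave hillslopes, a low-gradient channel along the valley
#' axis, small seeded roughness, and soil classes banded by local slope
#' (valley floor R, mid-slopes S, steep upper slopes X), emulating a small
#' loess-desert headwater catchment.
#'
#' @param seed Integer seed (same seed, same raster, bit for bit).
#' @param n_rows,n_cols Grid dimensions (>= 10 each).
#' @param relief_m Total hillslope relief from channel to ridge (m).
#' @param channel_slope Down-valley gradient of the channel (m/m).
#' @param noise_sd Standard deviation of cell-scale roughness (m).
#' @param cell_size Cell size in meters.
#' @return A list of class `af_watershed` with elements `grid` ([af_grid()]),
#'   `soil` (character matrix of codes R/S/X) and `soil_table`.
#' @export
make_synthetic_watershed <- function(seed = 1, n_rows = 60, n_cols = 50,
                                     relief_m = 120, channel_slope = 0.01,
                                     noise_sd = 0.1, cell_size = 30) {
  if (n_rows < 10 || n_cols < 10) stop_af("watershed dimensions must be >= 10 x 10")
  c0 <- ceiling(n_cols / 2)
  d <- abs(matrix(rep(seq_len(n_cols), each = n_rows), n_rows, n_cols) - c0)
  d_max <- max(d)
  # concave hillslope: slope increases away from the channel
  cross <- relief_m * (d / d_max)^1.7
  along <- outer((n_rows - seq_len(n_rows)), rep(1, n_cols)) *
    channel_slope * cell_size
  noise <- with_seed(seed, matrix(stats::rnorm(n_rows * n_cols, 0, noise_sd),
                                  n_rows, n_cols))
  noise[, c0] <- 0 # keep the channel monotone
  z <- 100 + cross + along + noise
  grid <- af_grid(z, cell_size = cell_size)
  sl <- slope_degrees(grid)
  soil <- matrix("S", n_rows, n_cols)
  soil[sl < 3] <- "R"
  soil[sl >= 10] <- "X"
  soil[, c0] <- "R" # valley floor
  structure(
    list(grid = grid, soil = soil, soil_table = soil_class_table(),
         channel_col = c0, seed = seed),
    class = "af_watershed"
  )
}

#' Write / read a soil-class raster as ESRI ASCII integer codes
#'
#' Codes: 1 = R, 2 = S, 3 = X.
#' @param soil Character matrix of soil codes.
#' @param path File path.
#' @param cell_size Cell size in meters.
#' @return `path` (write) or a character matrix (read).
#' @export
write_soil_asc <- function(soil, path, cell_size = 30) {
  codes <- matrix(match(soil, c("R", "S", "X")), nrow(soil), ncol(soil))
  write_grid(codes, path, cell_size = cell_size)
}

#' @rdname write_soil_asc
#' @export
load_soil_asc <- function(path) {
  g <- load_grid(path)
  m <- matrix(c("R", "S", "X")[g$elevation], g$n_rows, g$n_cols)
  if (any(is.na(m) & !is.na(g$elevation))) stop_af("invalid soil codes in %s", path)
  m
}

#' Assign land use: terraces, linked runoff catchments, channel, settlement
#'
#' Terraces are placed on channel cells from the outlet upstream (cultivation
#' in the riverbed); each terrace is linked to exactly `runoff_ratio`
#' (grapevine) or `wheat_ratio` (wheat) catchment cells drawn nearest-first
#' from its upslope contributing area. Catchment cells are flagged as mound
#' catchments when `mounds = TRUE`. Additional feasible sites are reserved as
#' expansion slots for the farm agents.
#'
#' @param watershed An `af_watershed` (or list with `grid`, `soil`).
#' @param runoff_ratio Catchment cells per grapevine terrace (5-30).
#' @param wheat_ratio Catchment cells per wheat terrace.
#' @param n_farms Number of farms.
#' @param grape_per_farm,wheat_per_farm Initial terraces per farm.
#' @param mounds Flag catchment cells as cleared-with-mounds.
#' @param reserve_sites Extra terrace sites (with catchments) kept for
#'   vineyard expansion.
#' @param channel_min_cells Flow-accumulation threshold defining the channel.
#' @return An object of class `af_landuse`.
#' @export
assign_land_use <- function(watershed, runoff_ratio = 20, wheat_ratio = 5,
                            n_farms = 10, grape_per_farm = 2, wheat_per_farm = 2,
                            mounds = TRUE, reserve_sites = 15,
                            channel_min_cells = 40) {
  if (runoff_ratio < 5 || runoff_ratio > 30) {
    stop_af("runoff_ratio must lie in [5, 30], got %g", runoff_ratio)
  }
  grid <- watershed$grid
  soil <- watershed$soil
  nr <- grid$n_rows
  nc <- grid$n_cols
  fd <- flow_directions(grid)
  facc <- flow_accumulation(grid, fd)
  ds <- .downstream_index(fd, nr, nc)

  # donors: reverse adjacency of the routing graph
  has_ds <- which(ds > 0L)
  donors <- split(has_ds, ds[has_ds])

  channel <- which(facc >= channel_min_cells & !is.na(grid$elevation))
  if (!length(channel)) stop_af("no channel cells at threshold %d", channel_min_cells)
  channel <- channel[order(facc[channel], decreasing = TRUE)] # outlet first

  n_initial <- n_farms * (grape_per_farm + wheat_per_farm)
  if (length(channel) < n_initial) {
    stop_af("only %d channel cells for %d requested terraces",
            length(channel), n_initial)
  }

  category <- matrix(.lu_codes[["natural"]], nr, nc)
  category[channel] <- .lu_codes[["channel"]]
  category[is.na(grid$elevation)] <- NA_integer_

  assigned <- matrix(FALSE, nr, nc) # catchment cells already linked
  catch_code <- if (mounds) .lu_codes[["catchment_mounds"]] else .lu_codes[["catchment_cleared"]]

  rows_of <- function(i) ((i - 1L) %% nr) + 1L
  cols_of <- function(i) ((i - 1L) %/% nr) + 1L

  # nearest-first harvest of `need` unassigned non-channel cells from the
  # upslope contributing area of `cell` (breadth-first through donors,
  # each frontier sorted by Euclidean distance to the terrace)
  harvest_catchment <- function(cell, need) {
    got <- integer(0)
    frontier <- cell
    seen <- c(cell)
    r0 <- rows_of(cell)
    c0 <- cols_of(cell)
    while (length(got) < need && length(frontier)) {
      nxt <- unlist(donors[as.character(frontier)], use.names = FALSE)
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) break
      dist2 <- (rows_of(nxt) - r0)^2 + (cols_of(nxt) - c0)^2
      nxt <- nxt[order(dist2)]
      seen <- c(seen, nxt)
      ok <- nxt[!assigned[nxt] & category[nxt] == .lu_codes[["natural"]]]
      take <- utils::head(ok, need - length(got))
      got <- c(got, take)
      frontier <- nxt
    }
    got
  }

  place_terrace <- function(site, crop, ratio, strict, id) {
    cells <- harvest_catchment(site, ratio)
    if (length(cells) < ratio) {
      if (strict) {
        stop_af("terrace %d at (%d,%d): only %d of %d catchment cells available",
                id, rows_of(site), cols_of(site), length(cells), ratio)
      }
      return(NULL)
    }
    assigned[cells] <<- TRUE
    category[cells] <<- catch_code
    category[site] <<- if (crop == "grape") .lu_codes[["terrace_grape"]] else .lu_codes[["terrace_wheat"]]
    cells
  }

  sites <- channel
  terr <- list()
  catchments <- list()
  id <- 0L
  site_i <- 0L
  for (f in seq_len(n_farms)) {
    crops <- c(rep("grape", grape_per_farm), rep("wheat", wheat_per_farm))
    for (crop in crops) {
      site_i <- site_i + 1L
      id <- id + 1L
      site <- sites[site_i]
      ratio <- if (crop == "grape") runoff_ratio else wheat_ratio
      cells <- place_terrace(site, crop, ratio, strict = TRUE, id = id)
      terr[[id]] <- list(id = id, cell = site, row = rows_of(site),
                         col = cols_of(site), farm = f, crop = crop)
      catchments[[id]] <- cells
    }
  }

  # reserve expansion slots (vineyards), as many as feasible
  slots <- list()
  slot_catch <- list()
  while (length(slots) < reserve_sites && site_i < length(sites)) {
    site_i <- site_i + 1L
    site <- sites[site_i]
    cells <- place_terrace(site, "grape", runoff_ratio, strict = FALSE,
                           id = id + length(slots) + 1L)
    if (is.null(cells)) next
    k <- length(slots) + 1L
    slots[[k]] <- list(cell = site, row = rows_of(site), col = cols_of(site))
    slot_catch[[k]] <- cells
    # reserved slots stay channel cells until an agent builds on them
    category[site] <- .lu_codes[["channel"]]
  }

  terraces <- do.call(rbind, lapply(terr, function(t) {
    data.frame(id = t$id, cell = t$cell, row = t$row, col = t$col,
               farm = t$farm, crop = t$crop, stringsAsFactors = FALSE)
  }))

  # settlement: one farmstead cell per farm next to its first terrace
  for (f in seq_len(n_farms)) {
    home <- terraces$cell[terraces$farm == f][1]
    r <- rows_of(home)
    c <- cols_of(home)
    for (k in 1:8) {
      rr <- r + .d8_dr[k]
      cc <- c + .d8_dc[k]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      i <- .cell_id(rr, cc, nr)
      if (!is.na(category[i]) && category[i] == .lu_codes[["natural"]]) {
        category[i] <- .lu_codes[["settlement"]]
        break
      }
    }
  }

  # downstream terrace chain: follow flow path to the next terrace downstream
  terrace_at <- integer(nr * nc)
  terrace_at[terraces$cell] <- terraces$id
  downstream_terrace <- integer(nrow(terraces))
  for (i in seq_len(nrow(terraces))) {
    cur <- ds[terraces$cell[i]]
    while (cur > 0L && terrace_at[cur] == 0L) cur <- ds[cur]
    downstream_terrace[i] <- if (cur > 0L) terrace_at[cur] else 0L
  }
  terraces$downstream <- downstream_terrace

  structure(
    list(
      category = category, terraces = terraces, catchments = catchments,
      slots = slots, slot_catchments = slot_catch,
      runoff_ratio = runoff_ratio, wheat_ratio = wheat_ratio,
      mounds = mounds, soil = soil, fd = fd, facc = facc
    ),
    class = "af_landuse"
  )
}

#' @export
print.af_landuse <- function(x, ...) {
  cat(sprintf(
    "<af_landuse> %d terraces (%d grape, %d wheat), %d catchment cells, %d expansion slots\n",
    nrow(x$terraces), sum(x$terraces$crop == "grape"), sum(x$terraces$crop == "wheat"),
    sum(lengths(x$catchments)), length(x$slots)
  ))
  invisible(x)
}

#' Export the land-use map as an integer-coded ESRI ASCII raster
#'
#' Codes: 0 natural, 1 cleared catchment, 2 mound catchment, 3 grape terrace,
#' 4 wheat terrace, 5 channel, 6 settlement.
#'
#' @param landuse An `af_landuse` object.
#' @param path Output path.
#' @param cell_size Cell size in meters.
#' @return `path`, invisibly.
#' @export
write_landuse_asc <- function(landuse, path, cell_size = 30) {
  write_grid(landuse$category, path, cell_size = cell_size)
}
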