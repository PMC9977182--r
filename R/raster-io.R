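#' Co-registered raster stack of a wetland landscape
#'
#' Container for the 30-m gridded substrate of the landscape model: a binary
#' water mask, temperature, and NDVI per biweekly time step, plus a static
#' two-class land-cover grid. Rows index northing (row 1 = top), columns
#' easting. All grids must share the same shape; dynamic variables must share
#' the same step count.
#'
#' @param water_mask Integer/logical array `[nrow, ncol, n_steps]` (1 = wet).
#' @param temperature Numeric array `[nrow, ncol, n_steps]`, degC.
#' @param ndvi Numeric array `[nrow, ncol, n_steps]`, dimensionless.
#' @param land_cover Integer matrix `[nrow, ncol]`; codes index
#'   `land_cover_levels`.
#' @param pixel_size Pixel edge length (m), default 30.
#' @param step_length Time-step length (days), default 14.
#' @param window A [frost_free_window()] the steps span.
#' @param origin Numeric `c(x, y)` of the lower-left corner (m).
#' @param crs Free-text CRS tag carried through I/O.
#' @param land_cover_levels Land-cover code labels.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(water_mask, temperature, ndvi, land_cover,
                         pixel_size = 30, step_length = 14,
                         window = frost_free_window(80, 345),
                         origin = c(0, 0), crs = "local-metric",
                         land_cover_levels = c("grassland", "cropland")) {
  dims <- dim(water_mask)
  if (length(dims) != 3L) stop_domain("water_mask must be a 3-d array")
  if (!identical(dim(temperature), dims) || !identical(dim(ndvi), dims))
    stop_domain("alignment error: dynamic grids differ in shape or step count")
  if (!identical(dim(land_cover), dims[1:2]))
    stop_domain("alignment error: land_cover shape differs from dynamic grids")
  storage.mode(water_mask) <- "integer"
  if (!all(water_mask %in% c(0L, 1L))) stop_domain("water_mask must be binary")
  structure(list(water_mask = water_mask, temperature = temperature,
                 ndvi = ndvi, land_cover = land_cover,
                 pixel_size = pixel_size, step_length = step_length,
                 window = window, origin = origin, crs = crs,
                 land_cover_levels = land_cover_levels),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$water_mask)
  cat(sprintf("raster_stack: %d x %d pixels (%g m), %d steps of %g days\n",
              d[1], d[2], x$pixel_size, d[3], x$step_length))
  cat(sprintf("  frost-free window: day %d-%d (%d days); wet fraction step 1: %.3f\n",
              x$window$start_day, x$window$end_day, x$window$length,
              mean(x$water_mask[, , 1])))
  invisible(x)
}

n_steps <- function(stack) dim(stack$water_mask)[3]

#' Write / read a single grid as ESRI ASCII raster
#'
#' Plain-text ESRI ASCII grid (`ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header followed by rows of values, top row first). Values are
#' written with 17 significant digits so doubles round-trip exactly; `NA`
#' cells are written as the nodata value and restored on read.
#'
#' @param grid Numeric matrix (row 1 = top/north).
#' @param path Output file path.
#' @param xll,yll Lower-left corner coordinates (m).
#' @param cellsize Pixel size (m).
#' @param nodata Nodata sentinel written for `NA` cells.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   numeric matrix with attributes `xll`, `yll`, `cellsize`.
#' @export
write_raster <- function(grid, path, xll = 0, yll = 0, cellsize = 30,
                         nodata = -9999) {
  stopifnot(is.matrix(grid))
  g <- grid
  g[is.na(g)] <- nodata
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(grid)),
               sprintf("nrows %d", nrow(grid)),
               sprintf("xllcorner %.10g", xll),
               sprintf("yllcorner %.10g", yll),
               sprintf("cellsize %.10g", cellsize),
               sprintf("NODATA_value %.10g", nodata)), con)
  writeLines(apply(g, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(hdr, "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA_real_
  attr(m, "xll") <- h[["xllcorner"]]
  attr(m, "yll") <- h[["yllcorner"]]
  attr(m, "cellsize") <- h[["cellsize"]]
  m
}

#' Write / read a full raster stack as ASCII grids plus JSON metadata
#'
#' One `.asc` file per variable and time step (`water_01.asc`, ...,
#' `temperature_01.asc`, `ndvi_01.asc`, `land_cover.asc`) and a
#' `stack_meta.json` sidecar holding pixel size, step length, the frost-free
#' window, origin, CRS tag, and land-cover level labels. Round-trips values
#' exactly.
#'
#' @param stack A [raster_stack()].
#' @param dir Directory to write into (created if absent).
#' @return `write_raster_stack` returns `dir` invisibly; `read_raster_stack`
#'   returns a [raster_stack()].
#' @export
write_raster_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "raster_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ns <- n_steps(stack)
  for (t in seq_len(ns)) {
    write_raster(stack$water_mask[, , t] + 0,
                 file.path(dir, sprintf("water_%02d.asc", t)),
                 xll = stack$origin[1], yll = stack$origin[2],
                 cellsize = stack$pixel_size)
    write_raster(stack$temperature[, , t],
                 file.path(dir, sprintf("temperature_%02d.asc", t)),
                 xll = stack$origin[1], yll = stack$origin[2],
                 cellsize = stack$pixel_size)
    write_raster(stack$ndvi[, , t],
                 file.path(dir, sprintf("ndvi_%02d.asc", t)),
                 xll = stack$origin[1], yll = stack$origin[2],
                 cellsize = stack$pixel_size)
  }
  write_raster(stack$land_cover + 0, file.path(dir, "land_cover.asc"),
               xll = stack$origin[1], yll = stack$origin[2],
               cellsize = stack$pixel_size)
  meta <- list(n_steps = ns, pixel_size = stack$pixel_size,
               step_length = stack$step_length,
               window = list(start_day = stack$window$start_day,
                             end_day = stack$window$end_day),
               origin = stack$origin, crs = stack$crs,
               land_cover_levels = stack$land_cover_levels)
  jsonlite::write_json(meta, file.path(dir, "stack_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_raster_stack
#' @export
read_raster_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack_meta.json"),
                              simplifyVector = TRUE)
  ns <- meta$n_steps
  read3 <- function(prefix) {
    grids <- lapply(seq_len(ns), function(t)
      read_raster(file.path(dir, sprintf("%s_%02d.asc", prefix, t))))
    shapes <- vapply(grids, dim, integer(2))
    if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
      stop_domain("alignment error: %s grids differ in shape", prefix)
    array(unlist(grids), dim = c(dim(grids[[1]]), ns))
  }
  lc <- read_raster(file.path(dir, "land_cover.asc"))
  lc <- matrix(as.integer(lc), nrow(lc), ncol(lc))
  raster_stack(water_mask = read3("water"), temperature = read3("temperature"),
               ndvi = read3("ndvi"), land_cover = lc,
               pixel_size = meta$pixel_size, step_length = meta$step_length,
               window = frost_free_window(meta$window$start_day, meta$window$end_day),
               origin = as.numeric(meta$origin), crs = meta$crs,
               land_cover_levels = meta$land_cover_levels)
}
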