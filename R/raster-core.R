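#' Land-use class legend
#'
#' Integer codes of the six land-use classes used throughout the package.
#' The order matches the class order of every transition/transfer matrix.
#'
#' @format Named integer vector of length 6.
#' @export
LU_CLASSES <- c(
  arable = 1L, woodland = 2L, grassland = 3L,
  water = 4L, construction = 5L, unused = 6L
)

#' Number of land-use classes
#' @export
N_CLASSES <- 6L

#' Categorical land-use grid
#'
#' A rectangular grid of integer land-use codes (1..6: arable, woodland,
#' grassland, water, construction, unused) on a projected CRS. Row 1 is the
#' top of the map; `origin` is the map coordinate of the upper-left corner.
#'
#' @param codes Integer matrix of class codes (nodata allowed).
#' @param cell_size Cell edge length in meters (> 0).
#' @param origin Numeric length-2, (x, y) of the upper-left corner.
#' @param nodata Integer nodata code (must not collide with 1..6).
#' @return An object of class `land_grid`.
#' @export
land_grid <- function(codes, cell_size = 30, origin = c(0, 0), nodata = -9999L) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  stopifnot(nrow(codes) > 0, ncol(codes) > 0, cell_size > 0, length(origin) == 2)
  nodata <- as.integer(nodata)
  if (nodata %in% LU_CLASSES)
    stop("nodata code collides with a land-use class code")
  ok <- codes == nodata | codes %in% LU_CLASSES
  if (!all(ok, na.rm = TRUE) || anyNA(codes))
    stop("land_grid: undeclared land-use code present (legal codes: 1..6 and nodata)")
  structure(
    list(codes = codes, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = nodata),
    class = "land_grid"
  )
}

#' Continuous-valued grid
#'
#' @param values Numeric matrix.
#' @param cell_size Cell edge length in meters.
#' @param origin (x, y) of the upper-left corner.
#' @param nodata Numeric nodata value.
#' @return An object of class `cont_grid`.
#' @export
cont_grid <- function(values, cell_size = 30, origin = c(0, 0), nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(nrow(values) > 0, ncol(values) > 0, cell_size > 0, length(origin) == 2)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "cont_grid"
  )
}

#' Binary mask sharing a parent grid's frame
#'
#' @param bits Logical matrix.
#' @param cell_size Cell edge length in meters.
#' @param origin (x, y) of the upper-left corner.
#' @return An object of class `bin_mask`.
#' @export
bin_mask <- function(bits, cell_size = 30, origin = c(0, 0)) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "logical"
  bits[is.na(bits)] <- FALSE
  structure(
    list(bits = bits, cell_size = as.numeric(cell_size), origin = as.numeric(origin)),
    class = "bin_mask"
  )
}

#' @export
print.land_grid <- function(x, ...) {
  cat(sprintf("<land_grid> %d x %d cells @ %g m, origin (%g, %g)\n",
              nrow(x$codes), ncol(x$codes), x$cell_size, x$origin[1], x$origin[2]))
  tab <- table(factor(x$codes[x$codes != x$nodata], levels = LU_CLASSES,
                      labels = names(LU_CLASSES)))
  print(tab)
  invisible(x)
}

#' @export
print.cont_grid <- function(x, ...) {
  v <- x$values[x$values != x$nodata]
  cat(sprintf("<cont_grid> %d x %d cells @ %g m, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              min(v), max(v)))
  invisible(x)
}

#' @export
print.bin_mask <- function(x, ...) {
  cat(sprintf("<bin_mask> %d x %d cells @ %g m, %d set\n",
              nrow(x$bits), ncol(x$bits), x$cell_size, sum(x$bits)))
  invisible(x)
}

grid_matrix <- function(g) {
  if (inherits(g, "land_grid")) g$codes
  else if (inherits(g, "cont_grid")) g$values
  else if (inherits(g, "bin_mask")) g$bits
  else stop("not a grid object")
}

#' Assert that two grids share the same frame
#'
#' Shape and cell size must agree; origins must agree where both are set.
#' @param a,b Grid objects.
#' @return Invisibly TRUE; stops on mismatch.
#' @export
check_same_frame <- function(a, b) {
  ma <- grid_matrix(a); mb <- grid_matrix(b)
  if (!all(dim(ma) == dim(mb)) || a$cell_size != b$cell_size)
    stop("grids do not share a frame (shape/cell size mismatch)")
  invisible(TRUE)
}

#' Map coordinates of cell centers
#'
#' @param g A grid object.
#' @param cells Two-column matrix of (row, col) indices; defaults to all cells.
#' @return Two-column matrix of (x, y) center coordinates in meters.
#' @export
cell_centers <- function(g, cells = NULL) {
  m <- grid_matrix(g)
  if (is.null(cells)) {
    cells <- cbind(rep(seq_len(nrow(m)), ncol(m)),
                   rep(seq_len(ncol(m)), each = nrow(m)))
  }
  x <- g$origin[1] + (cells[, 2] - 0.5) * g$cell_size
  y <- g$origin[2] - (cells[, 1] - 0.5) * g$cell_size
  cbind(x = x, y = y)
}

#' Area helpers
#'
#' Convert a cell count on a grid to hm^2 or km^2 (1 hm^2 = 0.01 km^2).
#' @param n_cells Cell count.
#' @param cell_size Cell edge in meters.
#' @return Area in the named unit.
#' @export
cells_to_hm2 <- function(n_cells, cell_size) n_cells * cell_size^2 / 1e4

#' @rdname cells_to_hm2
#' @export
cells_to_km2 <- function(n_cells, cell_size) n_cells * cell_size^2 / 1e6

#' Read an ESRI ASCII grid
#'
#' Parses the standard 6-line header (ncols, nrows, xllcorner/xllcenter,
#' yllcorner/yllcenter, cellsize, NODATA_value) followed by row-major values,
#' top row first. Categorical grids are validated against the 6-class legend.
#'
#' @param path File path.
#' @param type "landuse" for a [land_grid], "continuous" for a [cont_grid],
#'   "mask" for a [bin_mask] (nonzero = TRUE).
#' @return A grid object with cell size / origin populated from the header.
#' @export
read_ascii_grid <- function(path, type = c("landuse", "continuous", "mask")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("cannot read raster: file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("malformed ESRI ASCII grid: missing header")
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII grid: header lacks geotransform (ncols/nrows/cellsize)")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  if (is.null(xll) || is.null(yll))
    stop("malformed ESRI ASCII grid: header lacks corner coordinates")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("malformed ESRI ASCII grid: expected ", nr * nc, " values, got ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  origin <- c(xll, yll + nr * cs)
  switch(type,
    landuse = land_grid(m, cell_size = cs, origin = origin, nodata = as.integer(nodata)),
    continuous = cont_grid(m, cell_size = cs, origin = origin, nodata = nodata),
    mask = bin_mask(m != 0 & m != nodata, cell_size = cs, origin = origin)
  )
}

#' Write a grid as an ESRI ASCII grid
#'
#' Integer grids are written as integers so that the read/write round trip is
#' bit-faithful; nodata is preserved.
#'
#' @param g A [land_grid], [cont_grid] or [bin_mask].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path) {
  m <- grid_matrix(g)
  nr <- nrow(m); nc <- ncol(m)
  nodata <- if (inherits(g, "bin_mask")) -9999 else g$nodata
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2] - nr * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", as.numeric(nodata))
  )
  if (inherits(g, "bin_mask")) m <- m * 1L
  fmt <- if (is.integer(m)) function(r) paste(r, collapse = " ")
         else function(r) paste(format(r, trim = TRUE, scientific = FALSE, digits = 10),
                                collapse = " ")
  body <- vapply(seq_len(nr), function(i) fmt(m[i, ]), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Euclidean distance field to a mask
#'
#' Exact Euclidean distance (meters) from every cell center to the nearest
#' TRUE cell of the mask; TRUE cells hold 0.
#'
#' @param mask A [bin_mask] with at least one TRUE cell.
#' @return A [cont_grid] of distances in meters.
#' @export
euclidean_distance_field <- function(mask) {
  if (!any(mask$bits)) stop("euclidean_distance_field: mask has no TRUE cell")
  d <- EBImage::distmap(1 - mask$bits, metric = "euclidean")
  cont_grid(as.matrix(d) * mask$cell_size,
            cell_size = mask$cell_size, origin = mask$origin)
}

#' Nearest-neighbor resampling to a finer resolution
#'
#' Replicates each source cell into an integer block of target cells, the
#' nearest-neighbor rule for resolutions that divide evenly (e.g. 1000 m
#' population density onto a 30 m-class grid uses the enclosing coarse cell).
#'
#' @param g A [cont_grid].
#' @param factor Integer subdivision factor per axis.
#' @return A [cont_grid] at cell size `g$cell_size / factor`.
#' @export
resample_nearest <- function(g, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  m <- g$values
  out <- m[rep(seq_len(nrow(m)), each = factor), rep(seq_len(ncol(m)), each = factor),
           drop = FALSE]
  cont_grid(out, cell_size = g$cell_size / factor, origin = g$origin, nodata = g$nodata)
}
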