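#' MSPA class codes
#'
#' Integer codes of the morphological spatial pattern analysis classes:
#' 0 background plus the seven mutually exclusive foreground classes.
#'
#' @format Named integer vector.
#' @export
MSPA_CLASSES <- c(
  background = 0L, core = 1L, islet = 2L, perforation = 3L,
  edge = 4L, bridge = 5L, loop = 6L, branch = 7L
)

#' Ecological foreground mask
#'
#' Woodland and grassland form the ecological foreground (habitat); all other
#' classes and nodata form the background. The 6-class legend does not split
#' grassland by coverage, so all grassland counts as foreground; the class
#' list is configurable.
#'
#' @param landuse A [land_grid].
#' @param classes Character vector of foreground class names.
#' @return A [bin_mask].
#' @export
make_foreground <- function(landuse, classes = c("woodland", "grassland")) {
  codes <- LU_CLASSES[classes]
  bits <- matrix(landuse$codes %in% codes, nrow(landuse$codes))
  bin_mask(bits, cell_size = landuse$cell_size, origin = landuse$origin)
}

#' Morphological spatial pattern analysis
#'
#' Partitions a binary foreground into the seven MSPA classes using
#' 8-connectivity and an edge width measured in 8-connected erosion
#' iterations (Chebyshev distance):
#' \itemize{
#'   \item core: foreground farther than `edge_width` (Chebyshev) from
#'     background (grid outside counts as background);
#'   \item islet: foreground component containing no core;
#'   \item edge: non-core foreground in the boundary zone of a core (within
#'     `edge_width` of core) lying within `edge_width` of outer background;
#'   \item perforation: like edge but toward a background hole enclosed by
#'     the foreground (background components not reachable from the grid
#'     border by 4-connected flood fill);
#'   \item bridge: remaining connector component touching >= 2 distinct cores;
#'   \item loop: connector touching one core at >= 2 separate contact regions;
#'   \item branch: all remaining foreground.
#' }
#' Edge takes precedence over perforation where a cell is within reach of
#' both. The result is an exact 7-way partition of the foreground.
#'
#' @param mask Foreground [bin_mask].
#' @param edge_width Edge width in cells (>= 1).
#' @return An `mspa_result`: list with `classes` (integer matrix of
#'   [MSPA_CLASSES] codes), `edge_width`, `cell_size`, `origin`.
#' @export
classify_mspa <- function(mask, edge_width = 1) {
  if (edge_width < 1) stop("edge_width must be >= 1")
  fg <- mask$bits
  nr <- nrow(fg); nc <- ncol(fg)
  cls <- matrix(MSPA_CLASSES[["background"]], nr, nc)

  core <- erode_bits(fg, edge_width)
  bg <- !fg
  bglab <- label_components(bg, connectivity = 4)
  border_labs <- unique(c(bglab[1, ], bglab[nr, ], bglab[, 1], bglab[, nc]))
  border_labs <- border_labs[border_labs != 0]
  outer_bg <- bg & (bglab %in% border_labs)
  hole_bg <- bg & !outer_bg

  # cells within Chebyshev edge_width of each background type; the outside of
  # the grid is outer background, handled by dilating with outside = TRUE
  near_outer <- dilate_bits(outer_bg, edge_width, outside = TRUE)
  near_hole <- dilate_bits(hole_bg, edge_width, outside = FALSE)
  near_core <- dilate_bits(core, edge_width)

  fglab <- label_components(fg, connectivity = 8)
  core_comp_ids <- unique(fglab[core])
  islet <- fg & !(fglab %in% core_comp_ids)

  # edge/perforation form the boundary zone around cores; non-core cells
  # beyond that zone are connector material (so thin corridors stay bridges)
  rem <- fg & !core & !islet
  edge <- rem & near_core & near_outer
  perf <- rem & near_core & !edge & near_hole
  resid <- rem & !edge & !perf

  cls[core] <- MSPA_CLASSES[["core"]]
  cls[islet] <- MSPA_CLASSES[["islet"]]
  cls[edge] <- MSPA_CLASSES[["edge"]]
  cls[perf] <- MSPA_CLASSES[["perforation"]]

  if (any(resid)) {
    # connector subclass decided per non-core component: which cores does the
    # component reach through the non-core tissue?
    nclab <- label_components(rem, connectivity = 8)
    corelab <- label_components(core, connectivity = 8)
    for (id in unique(nclab[resid])) {
      comp <- nclab == id
      halo <- dilate_bits(comp, 1)
      touched <- unique(corelab[halo & core])
      touched <- touched[touched != 0]
      code <- if (length(touched) >= 2) {
        MSPA_CLASSES[["bridge"]]
      } else if (length(touched) == 1) {
        contact <- (corelab == touched) & halo
        n_contacts <- max(label_components(contact, connectivity = 8))
        if (n_contacts >= 2) MSPA_CLASSES[["loop"]] else MSPA_CLASSES[["branch"]]
      } else {
        MSPA_CLASSES[["branch"]]
      }
      cls[comp & resid] <- code
    }
  }
  structure(list(classes = cls, edge_width = edge_width,
                 cell_size = mask$cell_size, origin = mask$origin),
            class = "mspa_result")
}

#' @export
print.mspa_result <- function(x, ...) {
  cat(sprintf("<mspa_result> %d x %d, edge width %d\n",
              nrow(x$classes), ncol(x$classes), x$edge_width))
  print(table(factor(x$classes, levels = MSPA_CLASSES, labels = names(MSPA_CLASSES))))
  invisible(x)
}

#' Extract core patches above an area threshold
#'
#' 8-connected components of the MSPA core class with area at or above
#' `min_area` hm^2, with per-patch area and boundary cells.
#'
#' @param result An `mspa_result`.
#' @param min_area Minimum patch area in hm^2 (default 100, i.e. 1 km^2).
#' @return A [patch_set].
#' @export
extract_cores <- function(result, min_area = 100) {
  stopifnot(min_area >= 0)
  core <- result$classes == MSPA_CLASSES[["core"]]
  patch_set_from_mask(core, result$cell_size, result$origin, min_area = min_area)
}

#' Patch set: labeled connected components
#'
#' Builds a set of 8-connected patches from a logical matrix; each patch
#' carries its id, area in hm^2, cell list and boundary-cell list.
#'
#' @param bits Logical matrix.
#' @param cell_size Cell edge in meters.
#' @param origin Frame origin.
#' @param min_area Minimum area in hm^2 to retain a patch.
#' @return A `patch_set`: list with `patches` (list of patch records),
#'   `cell_size`, `origin`, `shape`.
#' @export
patch_set_from_mask <- function(bits, cell_size, origin = c(0, 0), min_area = 0) {
  lab <- label_components(bits, connectivity = 8)
  patches <- list()
  if (max(lab) > 0) {
    cell_hm2 <- cell_size^2 / 1e4
    keep_id <- 1L
    for (id in seq_len(max(lab))) {
      comp <- lab == id
      n <- sum(comp)
      area <- n * cell_hm2
      if (area < min_area) next
      cells <- which(comp, arr.ind = TRUE)
      patches[[length(patches) + 1]] <- list(
        id = keep_id, area_hm2 = area, cells = cells,
        boundary = patch_boundary(comp))
      keep_id <- keep_id + 1L
    }
  }
  structure(list(patches = patches, cell_size = cell_size, origin = origin,
                 shape = dim(bits)), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches, total %.2f hm^2\n",
              length(x$patches), sum(patch_areas(x))))
  invisible(x)
}

#' Patch areas in hm^2
#' @param ps A `patch_set`.
#' @return Numeric vector of areas.
#' @export
patch_areas <- function(ps) vapply(ps$patches, `[[`, numeric(1), "area_hm2")

#' Mask covered by a patch set
#' @param ps A `patch_set`.
#' @return A [bin_mask].
#' @export
patch_set_mask <- function(ps) {
  bits <- matrix(FALSE, ps$shape[1], ps$shape[2])
  for (p in ps$patches) bits[p$cells] <- TRUE
  bin_mask(bits, ps$cell_size, ps$origin)
}

#' Write an MSPA class raster
#'
#' @param result An `mspa_result`.
#' @param path Destination (ESRI ASCII grid; codes per [MSPA_CLASSES]).
#' @export
write_mspa <- function(result, path) {
  g <- cont_grid(result$classes, result$cell_size, result$origin)
  g$values <- result$classes  # keep integer
  storage.mode(g$values) <- "integer"
  write_ascii_grid(g, path)
}
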