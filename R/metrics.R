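#' Center of gravity of a land-use class
#'
#' Unweighted mean of the class's cell-center map coordinates.
#'
#' @param lu A [land_grid].
#' @param class Class name or code (default "construction").
#' @return Numeric (x, y) in meters.
#' @export
center_of_gravity <- function(lu, class = "construction") {
  code <- if (is.character(class)) LU_CLASSES[[class]] else as.integer(class)
  cells <- which(lu$codes == code, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("class has no cells")
  colMeans(cell_centers(lu, cells))
}

#' Quadrant and ring zonings around a center
#'
#' Quadrants are split by the north-south and east-west lines through the
#' center (NE: x >= cx and y >= cy; then NW, SW, SE counter-clockwise; cells
#' exactly on an axis join the first quadrant counter-clockwise). Ring k
#' covers Euclidean distances \[(k-1) w, k w) from the center; cells beyond
#' the outermost ring are labeled NA ("outside").
#'
#' @param center Numeric (x, y) in meters.
#' @param frame A grid object supplying the frame.
#' @param n_rings Number of rings (default 12).
#' @param ring_width Ring width in meters (default 5000).
#' @return A `zoning` list: `quadrant` (character matrix NE/NW/SW/SE),
#'   `ring` (integer matrix 1..n_rings or NA), `center`, `ring_width`.
#' @export
make_zonings <- function(center, frame, n_rings = 12, ring_width = 5000) {
  m <- grid_matrix(frame)
  xy <- cell_centers(frame)
  dx <- xy[, 1] - center[1]; dy <- xy[, 2] - center[2]
  quad <- ifelse(dx >= 0 & dy >= 0, "NE",
          ifelse(dx < 0 & dy >= 0, "NW",
          ifelse(dx < 0 & dy < 0, "SW", "SE")))
  quadrant <- matrix(quad, nrow(m), ncol(m))
  dist <- sqrt(dx^2 + dy^2)
  ring <- floor(dist / ring_width) + 1
  ring[ring > n_rings] <- NA
  ring <- matrix(as.integer(ring), nrow(m), ncol(m))
  structure(list(quadrant = quadrant, ring = ring, center = center,
                 ring_width = ring_width, n_rings = n_rings),
            class = "zoning")
}

#' Annual increase index (AI)
#'
#' AI = (A_end - A_start) / d: the absolute expansion speed, in km^2 per
#' year when areas are km^2.
#'
#' @param a_start,a_end Areas at the start and end of the period.
#' @param d Period length in years (> 0).
#' @return AI.
#' @export
compute_ai <- function(a_start, a_end, d) {
  stopifnot(d > 0)
  (a_end - a_start) / d
}

#' Average annual growth rate (AGR)
#'
#' AGR = 100 ((A_end / A_start)^(1/d) - 1) percent: the compound relative
#' expansion rate.
#'
#' @param a_start Area at the start (> 0).
#' @param a_end Area at the end.
#' @param d Period length in years (> 0).
#' @return AGR in percent.
#' @export
compute_agr <- function(a_start, a_end, d) {
  stopifnot(a_start > 0, d > 0)
  100 * ((a_end / a_start)^(1 / d) - 1)
}

zone_labels <- function(zoning, which = c("quadrant", "ring")) {
  which <- match.arg(which)
  if (which == "quadrant") zoning$quadrant else zoning$ring
}

#' Zonal expansion series
#'
#' Per zone and epoch: class area (km^2) and proportion of the zone area;
#' per consecutive epoch pair: AI and AGR. AGR is NA when the class is absent
#' at the period start; both are 0 when the area did not change.
#'
#' @param grids Named list of [land_grid]s; names are the epoch years.
#' @param zoning A `zoning` from [make_zonings()].
#' @param class Class name or code (default "construction").
#' @param zones "quadrant" or "ring".
#' @return data.frame with columns zone, epoch/period fields, area_km2,
#'   proportion_pct, and for periods ai and agr_pct.
#' @export
zonal_series <- function(grids, zoning, class = "construction",
                         zones = c("quadrant", "ring")) {
  zones <- match.arg(zones)
  code <- if (is.character(class)) LU_CLASSES[[class]] else as.integer(class)
  years <- as.numeric(names(grids))
  stopifnot(!anyNA(years))
  lab <- zone_labels(zoning, zones)
  g1 <- grids[[1]]
  valid <- g1$codes != g1$nodata & !is.na(lab)
  zl <- sort(unique(lab[valid]))
  cs <- g1$cell_size
  per_epoch <- do.call(rbind, lapply(seq_along(grids), function(e) {
    g <- grids[[e]]
    do.call(rbind, lapply(zl, function(z) {
      inz <- valid & lab == z
      a <- cells_to_km2(sum(inz & g$codes == code), cs)
      tot <- cells_to_km2(sum(inz), cs)
      data.frame(zone = z, year = years[e], area_km2 = a,
                 zone_area_km2 = tot, proportion_pct = 100 * a / tot)
    }))
  }))
  periods <- NULL
  if (length(grids) >= 2) {
    periods <- do.call(rbind, lapply(seq_len(length(grids) - 1), function(e) {
      d <- years[e + 1] - years[e]
      do.call(rbind, lapply(zl, function(z) {
        a0 <- per_epoch$area_km2[per_epoch$zone == z & per_epoch$year == years[e]]
        a1 <- per_epoch$area_km2[per_epoch$zone == z & per_epoch$year == years[e + 1]]
        data.frame(zone = z, from = years[e], to = years[e + 1],
                   ai = compute_ai(a0, a1, d),
                   agr_pct = if (a0 > 0) compute_agr(a0, a1, d) else NA_real_)
      }))
    }))
  }
  structure(per_epoch, periods = periods, class = c("zonal_metrics", "data.frame"))
}

#' Validate a simulation against observed land use
#'
#' Draws a seeded uniform sample of non-nodata cells, cross-tabulates
#' observed vs simulated classes, and reports the kappa coefficient
#' (p_o - p_e)/(1 - p_e) with p_e from the marginal products, the overall
#' accuracy (trace share), and per-class accuracy (recall by observed
#' class).
#'
#' @param actual,simulated [land_grid]s on one frame.
#' @param fraction Sampling fraction in (0, 1] (default 0.1).
#' @param seed Integer seed.
#' @return A `validation_report`: kappa, overall_accuracy, per_class
#'   (named vector), confusion (6x6 table), n, fraction, seed.
#' @export
kappa_validate <- function(actual, simulated, fraction = 0.1, seed = 1) {
  check_same_frame(actual, simulated)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  ok <- which(actual$codes != actual$nodata & simulated$codes != simulated$nodata)
  set.seed(seed)
  idx <- if (fraction >= 1) ok else sample(ok, round(fraction * length(ok)))
  a <- factor(actual$codes[idx], levels = LU_CLASSES, labels = names(LU_CLASSES))
  s <- factor(simulated$codes[idx], levels = LU_CLASSES, labels = names(LU_CLASSES))
  conf <- table(observed = a, simulated = s)
  n <- sum(conf)
  p_o <- sum(diag(conf)) / n
  p_e <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 0
  per_class <- diag(conf) / pmax(rowSums(conf), 1)
  per_class[rowSums(conf) == 0] <- NA
  structure(list(kappa = kappa, overall_accuracy = p_o,
                 per_class = per_class, confusion = conf, n = n,
                 fraction = fraction, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> kappa %.3f, overall accuracy %.3f (n = %d)\n",
              x$kappa, x$overall_accuracy, x$n))
  invisible(x)
}
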