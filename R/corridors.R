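#' Default ecological resistance scores
#'
#' Land-use resistance scores and topographic-relief score bins with their
#' weights (land use 0.7, relief 0.3). Woodland and water are the most
#' permeable (1), construction land the least (100); flat terrain resists
#' movement (relief < 8 scores 90) while rugged terrain is permeable
#' (relief >= 50 scores 1).
#'
#' @export
RESISTANCE_DEFAULTS <- list(
  lu_scores = c(arable = 50, woodland = 1, grassland = 30,
                water = 1, construction = 100, unused = 90),
  relief_breaks = c(-Inf, 8, 17, 27, 37, 50, Inf),
  relief_scores = c(90, 70, 50, 30, 10, 1),
  w_lu = 0.7, w_relief = 0.3
)

#' Build a movement-resistance surface
#'
#' Per-cell resistance = w_lu * land-use score + w_relief * relief score.
#' Relief bins are left-closed: \[8, 17) scores 70, etc.; relief >= 50
#' scores 1.
#'
#' @param landuse A [land_grid].
#' @param relief A [cont_grid] of topographic relief (same frame).
#' @param scores List like [RESISTANCE_DEFAULTS].
#' @return A `resistance_surface`: values plus the component score grids and
#'   weights.
#' @export
build_resistance <- function(landuse, relief, scores = RESISTANCE_DEFAULTS) {
  check_same_frame(landuse, relief)
  codes <- landuse$codes
  if (!all(codes %in% c(LU_CLASSES, landuse$nodata)))
    stop("undeclared land-use code")
  lu_score <- matrix(NA_real_, nrow(codes), ncol(codes))
  for (cl in names(LU_CLASSES))
    lu_score[codes == LU_CLASSES[[cl]]] <- scores$lu_scores[[cl]]
  bin <- cut(relief$values, breaks = scores$relief_breaks, right = FALSE,
             labels = FALSE)
  relief_score <- matrix(scores$relief_scores[bin], nrow(codes))
  vals <- scores$w_lu * lu_score + scores$w_relief * relief_score
  vals[codes == landuse$nodata] <- NA_real_
  structure(list(values = vals, lu_score = lu_score, relief_score = relief_score,
                 w_lu = scores$w_lu, w_relief = scores$w_relief,
                 cell_size = landuse$cell_size, origin = landuse$origin),
            class = "resistance_surface")
}

# Weighted 8-connected grid graph over non-NA resistance cells. Edge weight =
# mean of the two cells' resistance times the metric step length (cell_size,
# or cell_size * sqrt(2) diagonally). Returns the igraph plus the cell-index
# <-> vertex mapping.
grid_graph <- function(res) {
  v <- res$values
  nr <- nrow(v); nc <- ncol(v)
  ok <- !is.na(v)
  vid <- matrix(0L, nr, nc)
  vid[ok] <- seq_len(sum(ok))
  dirs <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  efrom <- integer(0); eto <- integer(0); ew <- numeric(0)
  for (d in dirs) {
    nb_ok <- shift_mat(ok, -d[1], -d[2], FALSE)
    nb_val <- shift_mat(v, -d[1], -d[2], NA)
    both <- which(ok & nb_ok)
    if (length(both)) {
      nbi <- both + d[1] + d[2] * nr
      efrom <- c(efrom, vid[both]); eto <- c(eto, vid[nbi])
      ew <- c(ew, (v[both] + nb_val[both]) / 2 * d[3] * res$cell_size)
    }
  }
  g <- igraph::make_graph(c(rbind(efrom, eto)), n = sum(ok), directed = FALSE)
  igraph::E(g)$weight <- ew
  list(g = g, vid = vid, ok = ok, nr = nr, nc = nc)
}

#' Minimum cumulative resistance (cost distance) from source cells
#'
#' Per-cell minimum over 8-connected paths from any source cell of the sum of
#' step length times step resistance (mean of the two cells' values); source
#' cells hold 0. This is the accumulated-cost surface of the minimum
#' cumulative resistance model.
#'
#' @param resistance A `resistance_surface`.
#' @param sources A [bin_mask] with >= 1 TRUE cell.
#' @return A [cont_grid] of cumulative costs (NA where unreachable/nodata).
#' @export
cost_distance <- function(resistance, sources) {
  if (!any(sources$bits)) stop("cost_distance: empty source mask")
  gg <- grid_graph(resistance)
  src <- gg$vid[sources$bits & gg$ok]
  if (length(src) == 0) stop("cost_distance: no source cell on valid terrain")
  g2 <- igraph::add_vertices(gg$g, 1)
  aux <- igraph::vcount(g2)
  g2 <- igraph::add_edges(g2, c(rbind(aux, src)), weight = 0)
  d <- igraph::distances(g2, v = aux, algorithm = "dijkstra")[1, ]
  out <- matrix(NA_real_, gg$nr, gg$nc)
  out[gg$ok] <- d[seq_len(sum(gg$ok))]
  out[!is.finite(out)] <- NA_real_
  cont_grid(out, cell_size = resistance$cell_size, origin = resistance$origin)
}

#' Least-cost corridor between two patches
#'
#' Minimal-cumulative-cost cell path between any boundary cell of patch i and
#' any boundary cell of patch j on the resistance surface.
#'
#' @param resistance A `resistance_surface`.
#' @param patch_i,patch_j Patch records.
#' @return A `corridor_path`: `i`, `j`, `cells` (row/col polyline), `cost`
#'   (cumulative resistance L_ij) and `length_m` (metric path length).
#' @export
least_cost_path <- function(resistance, patch_i, patch_j) {
  gg <- grid_graph(resistance)
  bi <- gg$vid[patch_i$boundary]; bi <- bi[bi > 0]
  bj <- gg$vid[patch_j$boundary]; bj <- bj[bj > 0]
  if (!length(bi) || !length(bj))
    stop("least_cost_path: patch lies entirely on nodata terrain")
  g2 <- igraph::add_vertices(gg$g, 1)
  aux <- igraph::vcount(g2)
  g2 <- igraph::add_edges(g2, c(rbind(aux, bi)), weight = 0)
  dj <- igraph::distances(g2, v = aux, to = bj, algorithm = "dijkstra")[1, ]
  if (!any(is.finite(dj))) stop("least_cost_path: no finite path between patches")
  best <- bj[which.min(dj)]
  sp <- igraph::shortest_paths(g2, from = aux, to = best, output = "vpath")
  vpath <- as.integer(sp$vpath[[1]])
  vpath <- vpath[vpath != aux]
  # vertex id -> (row, col)
  cellidx <- which(gg$ok)
  cells <- cbind(row = (cellidx[vpath] - 1L) %% gg$nr + 1L,
                 col = (cellidx[vpath] - 1L) %/% gg$nr + 1L)
  steps <- diff(cells)
  len <- if (nrow(cells) > 1)
    sum(sqrt(rowSums(steps^2))) * resistance$cell_size else 0
  structure(list(i = patch_i$id, j = patch_j$id, cells = cells,
                 cost = min(dj, na.rm = TRUE), length_m = len),
            class = "corridor_path")
}

#' Gravity-model interaction between two patches
#'
#' G_ij = \[ln(S_i)/P_i\] \[ln(S_j)/P_j\] (L_max / L_ij)^2: larger, less
#' resistant patches joined by cheaper corridors interact more strongly.
#' Touching patches (L_ij = 0) get +Inf and are always retained.
#'
#' @param s_i,s_j Patch areas in hm^2 (> 0).
#' @param p_i,p_j Patch resistance (mean resistance-surface value over the
#'   patch cells).
#' @param l_ij Cumulative corridor resistance.
#' @param l_max Maximum cumulative resistance over all corridors.
#' @return Interaction strength G (>= 0 for areas > 1 hm^2).
#' @export
gravity_interaction <- function(s_i, s_j, p_i, p_j, l_ij, l_max) {
  stopifnot(s_i > 0, s_j > 0)
  if (l_ij == 0) return(Inf)
  (log(s_i) / p_i) * (log(s_j) / p_j) * (l_max / l_ij)^2
}

#' Gravity matrix over a corridor set
#'
#' @param paths List of `corridor_path`s.
#' @param sources Source `patch_set` (ids as referenced by the paths).
#' @param resistance A `resistance_surface` (for patch resistance P_i).
#' @return data.frame with i, j, L, G; attribute `"l_max"`.
#' @export
gravity_matrix <- function(paths, sources, resistance) {
  ids <- vapply(sources$patches, `[[`, integer(1), "id")
  S <- patch_areas(sources)
  P <- vapply(sources$patches, function(p) mean(resistance$values[p$cells],
                                                na.rm = TRUE), numeric(1))
  L <- vapply(paths, `[[`, numeric(1), "cost")
  l_max <- max(L)
  G <- vapply(seq_along(paths), function(k) {
    pi_ <- match(paths[[k]]$i, ids); pj <- match(paths[[k]]$j, ids)
    gravity_interaction(S[pi_], S[pj], P[pi_], P[pj], L[k], l_max)
  }, numeric(1))
  out <- data.frame(i = vapply(paths, `[[`, integer(1), "i"),
                    j = vapply(paths, `[[`, integer(1), "j"),
                    L = L, G = G)
  attr(out, "l_max") <- l_max
  out
}

#' Select important corridors
#'
#' Ranks corridors by gravity interaction and keeps them by top-k or a G
#' threshold; a minimum spanning set over the sources (minimum total L) is
#' always retained so no source is isolated from the network.
#'
#' @param paths List of `corridor_path`s (one per source pair).
#' @param gravity data.frame from [gravity_matrix()] (same order).
#' @param rule "top_k" or "threshold".
#' @param k Number kept under "top_k".
#' @param g_min Threshold under "threshold".
#' @return Sub-list of `paths`, attribute `"selected"` = logical over input.
#' @export
select_corridors <- function(paths, gravity, rule = c("top_k", "threshold"),
                             k = length(paths), g_min = 0) {
  rule <- match.arg(rule)
  n <- length(paths)
  keep <- if (rule == "top_k") {
    rank(-gravity$G, ties.method = "first") <= k
  } else gravity$G >= g_min
  # spanning safety net: MST over the source nodes with weight L
  verts <- sort(unique(c(gravity$i, gravity$j)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(gravity$i, verts), to = match(gravity$j, verts),
               weight = gravity$L),
    directed = FALSE, vertices = data.frame(id = seq_along(verts)))
  mst <- igraph::mst(g)
  mste <- igraph::as_edgelist(mst)
  for (r in seq_len(nrow(mste))) {
    a <- verts[as.integer(mste[r, 1])]; b <- verts[as.integer(mste[r, 2])]
    hit <- (gravity$i == a & gravity$j == b) | (gravity$i == b & gravity$j == a)
    keep[hit] <- TRUE
  }
  out <- paths[keep]
  attr(out, "selected") <- keep
  out
}

#' Buffer corridor polylines into a corridor mask
#'
#' Cells whose centers lie within `radius` meters of any path cell center
#' (path cells themselves always included).
#'
#' @param paths List of `corridor_path`s.
#' @param radius Buffer radius in meters (e.g. 100).
#' @param frame A grid object supplying shape/cell size.
#' @return A [bin_mask].
#' @export
buffer_paths <- function(paths, radius, frame) {
  m <- grid_matrix(frame)
  bits <- matrix(FALSE, nrow(m), ncol(m))
  for (p in paths) bits[p$cells] <- TRUE
  if (!any(bits) || radius <= 0)
    return(bin_mask(bits, frame$cell_size, frame$origin))
  d <- euclidean_distance_field(bin_mask(bits, frame$cell_size, frame$origin))
  bin_mask(d$values <= radius, frame$cell_size, frame$origin)
}

#' River corridors
#'
#' Water components qualifying as corridor rivers: estimated major-axis
#' length above `min_length` and mean width (area / length) above
#' `min_width`.
#'
#' @param water_mask [bin_mask] of water cells.
#' @param min_width Minimum mean width in meters (default 30).
#' @param min_length Minimum length in meters (default 5000).
#' @return A [bin_mask] of qualifying river cells.
#' @export
river_corridors <- function(water_mask, min_width = 30, min_length = 5000) {
  lab <- label_components(water_mask$bits, connectivity = 8)
  bits <- matrix(FALSE, nrow(lab), ncol(lab))
  if (max(lab) > 0) {
    for (id in seq_len(max(lab))) {
      cells <- which(lab == id, arr.ind = TRUE)
      sm <- patch_shape_metrics(cells, water_mask$cell_size)
      if (sm$length_m > min_length && sm$width_m > min_width) bits[cells] <- TRUE
    }
  }
  bin_mask(bits, water_mask$cell_size, water_mask$origin)
}

#' Select ecological nodes (stepping stones)
#'
#' Non-source core patches ranked by area; optionally only patches within
#' `max_dist` meters of the selected corridor mask are eligible. Node choice
#' is traditionally expert-driven; this rule-based surrogate keeps the
#' "relatively large patches near the network" intent reproducible.
#'
#' @param cores Core `patch_set`.
#' @param sources Source `patch_set` (patches to exclude).
#' @param n Number of nodes to keep.
#' @param corridor_mask Optional [bin_mask] of corridors.
#' @param max_dist Maximum distance to a corridor in meters (default Inf).
#' @return A `patch_set` of node patches.
#' @export
select_nodes <- function(cores, sources, n = 7, corridor_mask = NULL,
                         max_dist = Inf) {
  src_mask <- patch_set_mask(sources)$bits
  cand <- Filter(function(p) !any(src_mask[p$cells]), cores$patches)
  if (!is.null(corridor_mask) && is.finite(max_dist) && any(corridor_mask$bits)) {
    d <- euclidean_distance_field(corridor_mask)$values
    cand <- Filter(function(p) min(d[p$cells]) <= max_dist, cand)
  }
  if (length(cand) && n > 0) {
    areas <- vapply(cand, `[[`, numeric(1), "area_hm2")
    cand <- cand[order(areas, decreasing = TRUE)][seq_len(min(n, length(cand)))]
  } else cand <- list()
  for (i in seq_along(cand)) cand[[i]]$id <- i
  structure(list(patches = cand, cell_size = cores$cell_size,
                 origin = cores$origin, shape = cores$shape),
            class = "patch_set")
}

#' Assemble the ecological security pattern
#'
#' Unions the source, corridor (including river corridors) and node masks on
#' their shared frame; the union is the restricted area for constrained
#' simulation.
#'
#' @param sources,corridors,rivers,nodes [bin_mask]s on one frame (`rivers`
#'   and `nodes` may be NULL).
#' @return An `esp` object with masks `sources`, `corridors`, `nodes`,
#'   `restricted`.
#' @export
assemble_esp <- function(sources, corridors, rivers = NULL, nodes = NULL) {
  check_same_frame(sources, corridors)
  corr <- corridors$bits
  if (!is.null(rivers)) { check_same_frame(sources, rivers); corr <- corr | rivers$bits }
  nb <- if (!is.null(nodes)) { check_same_frame(sources, nodes); nodes$bits }
        else matrix(FALSE, nrow(sources$bits), ncol(sources$bits))
  restricted <- sources$bits | corr | nb
  structure(list(
    sources = sources,
    corridors = bin_mask(corr, sources$cell_size, sources$origin),
    nodes = bin_mask(nb, sources$cell_size, sources$origin),
    restricted = bin_mask(restricted, sources$cell_size, sources$origin)),
    class = "esp")
}

#' @export
print.esp <- function(x, ...) {
  cat(sprintf("<esp> sources %d, corridors %d, nodes %d, restricted %d cells\n",
              sum(x$sources$bits), sum(x$corridors$bits), sum(x$nodes$bits),
              sum(x$restricted$bits)))
  invisible(x)
}

#' Write corridor polylines as GeoJSON LineStrings
#'
#' @param paths List of `corridor_path`s.
#' @param gravity Optional data.frame from [gravity_matrix()] aligned with
#'   `paths` for L/G properties.
#' @param frame Grid object for the coordinate transform.
#' @param path Destination file.
#' @export
write_corridors_geojson <- function(paths, gravity = NULL, frame, path) {
  feats <- lapply(seq_along(paths), function(k) {
    p <- paths[[k]]
    xy <- cell_centers(frame, p$cells)
    props <- list(i = p$i, j = p$j, L = p$cost)
    if (!is.null(gravity)) props$G <- gravity$G[k]
    list(type = "Feature", properties = props,
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(xy)),
                                              function(r) c(xy[r, 1], xy[r, 2]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
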