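#' Minimum edge-to-edge distance between two patches
#'
#' Minimum Euclidean distance (meters) between boundary-cell centers of the
#' two patches; 0 when the patches touch (share an 8-neighborhood) or are the
#' same patch.
#'
#' @param a,b Patch records (elements of a `patch_set$patches`).
#' @param cell_size Cell edge in meters.
#' @return Distance in meters.
#' @export
patch_distance <- function(a, b, cell_size) {
  if (identical(a$id, b$id) && identical(dim(a$cells), dim(b$cells)) &&
      all(a$cells == b$cells)) return(0)
  ba <- a$boundary; bb <- b$boundary
  dr <- outer(ba[, 1], bb[, 1], "-")
  dc <- outer(ba[, 2], bb[, 2], "-")
  cheb <- pmax(abs(dr), abs(dc))
  if (min(cheb) <= 1) return(0)
  sqrt(min(dr^2 + dc^2)) * cell_size
}

#' Direct dispersal probability at a distance
#'
#' Negative-exponential kernel calibrated so that the probability equals
#' `p_thr` at the distance `threshold` (the standard reading of a
#' threshold/probability parameter pair, e.g. 1500 m / 0.5):
#' p(d) = exp(-k d) with k = -ln(p_thr)/threshold. A hard-threshold mode
#' (p = `p_thr` within the threshold, 0 beyond) is available.
#'
#' @param d Distance in meters (vectorized).
#' @param threshold Calibration distance in meters.
#' @param p_thr Probability at the calibration distance.
#' @param mode "kernel" (default) or "hard".
#' @return Probability in \[0, 1\].
#' @export
direct_probability <- function(d, threshold = 1500, p_thr = 0.5,
                               mode = c("kernel", "hard")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, p_thr > 0, p_thr <= 1)
  if (mode == "kernel") {
    k <- -log(p_thr) / threshold
    exp(-k * d)
  } else {
    ifelse(d <= threshold, p_thr, 0)
  }
}

#' Build a patch connectivity graph
#'
#' Computes all pairwise patch distances, converts them to direct dispersal
#' probabilities, and records areas and the normalizing area AL.
#'
#' @param ps A `patch_set`.
#' @param threshold,p_thr,mode See [direct_probability()].
#' @param al_mode "patch_sum" (AL = sum of patch areas, the definitional
#'   reading) or "landscape" (AL = total landscape area, the convention of
#'   some reference software; requires `landscape_area`).
#' @param landscape_area Total landscape area in hm^2 for `al_mode =
#'   "landscape"`.
#' @param prune Direct probabilities below this are treated as 0 in the path
#'   graph (default 1e-9).
#' @return A `connectivity_graph`: areas (hm^2), symmetric direct-probability
#'   matrix, AL, and the kernel parameters.
#' @export
build_connectivity_graph <- function(ps, threshold = 1500, p_thr = 0.5,
                                     mode = "kernel", al_mode = "patch_sum",
                                     landscape_area = NULL, prune = 1e-9) {
  a <- patch_areas(ps)
  n <- length(a)
  P <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- patch_distance(ps$patches[[i]], ps$patches[[j]], ps$cell_size)
        p <- direct_probability(d, threshold, p_thr, mode)
        if (p < prune) p <- 0
        P[i, j] <- P[j, i] <- p
      }
    }
  }
  AL <- if (al_mode == "patch_sum") sum(a) else {
    if (is.null(landscape_area)) stop("landscape_area required for al_mode='landscape'")
    landscape_area
  }
  structure(list(areas = a, pij_direct = P, AL = AL,
                 distance_threshold = threshold, p_at_threshold = p_thr,
                 ids = vapply(ps$patches, `[[`, integer(1), "id")),
            class = "connectivity_graph")
}

# Maximum product-of-probabilities over paths for all pairs, via shortest
# paths on -log(p) edge weights. `drop` removes a patch (its paths are lost).
max_product_matrix <- function(P, drop = NULL) {
  keep <- setdiff(seq_len(nrow(P)), drop)
  Q <- P[keep, keep, drop = FALSE]
  n <- nrow(Q)
  if (n == 0) return(Q)
  W <- -log(Q)
  W[Q <= 0] <- 0              # zero entries carry no edge in the igraph adjacency
  W[Q > 0 & W <= 0] <- 1e-12  # p = 1 edges (touching patches) get epsilon weight
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  M <- exp(-D)
  M[!is.finite(D)] <- 0
  diag(M) <- 1
  M
}

#' Maximum path probability between two patches
#'
#' Maximum over all patch paths of the product of direct step probabilities,
#' computed as a shortest path on -ln(p) edge weights.
#'
#' @param graph A `connectivity_graph`.
#' @param i,j Patch indices (positions in the graph).
#' @return Probability in \[0, 1\]; 1 when `i == j`, 0 when unreachable.
#' @export
max_product_probability <- function(graph, i, j) {
  if (i == j) return(1)
  M <- max_product_matrix(graph$pij_direct)
  M[i, j]
}

#' Probability of connectivity (PC)
#'
#' PC = sum_i sum_j p*_ij a_i a_j / AL^2 over all ordered pairs (i = j
#' included), with p*_ij the maximum product-path probability.
#'
#' @param graph A `connectivity_graph`.
#' @return PC in (0, 1] when AL is the patch-area sum.
#' @export
compute_pc <- function(graph) {
  M <- max_product_matrix(graph$pij_direct)
  a <- graph$areas
  sum(M * outer(a, a)) / graph$AL^2
}

#' Per-patch importance dPC
#'
#' dPC_k = 100 (PC - PC_remove,k) / PC, where PC_remove,k re-solves the
#' maximum-product paths without patch k while AL stays fixed (only paths
#' through k are lost), keeping dPC in \[0, 100\].
#'
#' @param graph A `connectivity_graph`.
#' @param k Patch index to remove; `NULL` computes all patches.
#' @return Numeric dPC (percent), or a data.frame for `k = NULL` with columns
#'   id, area_hm2, dPC.
#' @export
compute_dpc <- function(graph, k = NULL) {
  a <- graph$areas
  PC <- compute_pc(graph)
  one <- function(k) {
    keep <- setdiff(seq_along(a), k)
    Mk <- max_product_matrix(graph$pij_direct, drop = k)
    PCk <- sum(Mk * outer(a[keep], a[keep])) / graph$AL^2
    100 * (PC - PCk) / PC
  }
  if (!is.null(k)) return(one(k))
  data.frame(id = graph$ids, area_hm2 = a,
             dPC = vapply(seq_along(a), one, numeric(1)))
}

#' Select ecological sources
#'
#' Union of core patches whose dPC exceeds `dpc_min` and large non-river
#' water patches. A water patch counts as a river when its elongation
#' (major-axis length squared over area) exceeds `elongation_max` or it
#' intersects `river_mask`.
#'
#' @param cores Core `patch_set` (same order as the dPC table).
#' @param dpc data.frame from [compute_dpc()] (`k = NULL`).
#' @param water_patches Water `patch_set` (may be empty).
#' @param dpc_min dPC threshold in percent (default 1).
#' @param water_min_area Minimum water-patch area in hm^2 (default 100).
#' @param elongation_max River elongation threshold (default 10).
#' @param river_mask Optional [bin_mask] of the mapped river network.
#' @return A `patch_set` of sources with per-patch `type` ("core"/"water");
#'   attribute `"table"` holds the selection table.
#' @export
select_sources <- function(cores, dpc, water_patches = NULL, dpc_min = 1,
                           water_min_area = 100, elongation_max = 10,
                           river_mask = NULL) {
  sel <- list()
  tab <- data.frame(id = integer(), type = character(), area_hm2 = numeric(),
                    dPC = numeric(), selected = logical())
  for (i in seq_along(cores$patches)) {
    p <- cores$patches[[i]]
    keep <- dpc$dPC[i] > dpc_min
    tab <- rbind(tab, data.frame(id = p$id, type = "core", area_hm2 = p$area_hm2,
                                 dPC = dpc$dPC[i], selected = keep))
    if (keep) { p$type <- "core"; sel[[length(sel) + 1]] <- p }
  }
  if (!is.null(water_patches)) {
    for (p in water_patches$patches) {
      sm <- patch_shape_metrics(p$cells, water_patches$cell_size)
      is_river <- sm$elongation > elongation_max
      if (!is_river && !is.null(river_mask))
        is_river <- any(river_mask$bits[p$cells])
      keep <- p$area_hm2 > water_min_area && !is_river
      tab <- rbind(tab, data.frame(id = p$id, type = "water", area_hm2 = p$area_hm2,
                                   dPC = NA_real_, selected = keep))
      if (keep) { p$type <- "water"; sel[[length(sel) + 1]] <- p }
    }
  }
  for (i in seq_along(sel)) sel[[i]]$id <- i
  structure(list(patches = sel, cell_size = cores$cell_size, origin = cores$origin,
                 shape = cores$shape, table = tab),
            class = "patch_set")
}
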