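# Internal gridded-matrix primitives shared across modules.

# Shift a matrix by (di, dj), filling vacated cells with `fill`.
shift_mat <- function(m, di, dj, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + di):min(nr, nr + di)
  sc <- max(1, 1 + dj):min(nc, nc + dj)
  if (length(sr) < 1 || length(sc) < 1) return(out)
  out[sr, sc] <- m[sr - di, sc - dj]
  out
}

NEIGH8 <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
NEIGH4 <- cbind(di = c(-1, 0, 0, 1), dj = c(0, -1, 1, 0))

# One 3x3 min filter (8-connected erosion); outside the grid counts as `fill`.
min_filter3 <- function(m, fill) {
  out <- m
  for (k in seq_len(nrow(NEIGH8)))
    out <- pmin(out, shift_mat(m, NEIGH8[k, 1], NEIGH8[k, 2], fill))
  out
}

max_filter3 <- function(m, fill) {
  out <- m
  for (k in seq_len(nrow(NEIGH8)))
    out <- pmax(out, shift_mat(m, NEIGH8[k, 1], NEIGH8[k, 2], fill))
  out
}

# Morphological erosion/dilation of a logical matrix with the 3x3 box
# structuring element iterated `iters` times (Chebyshev metric). Outside the
# grid is treated as background.
erode_bits <- function(bits, iters = 1) {
  m <- bits
  for (i in seq_len(iters)) m <- min_filter3(m, FALSE) & m
  m
}

dilate_bits <- function(bits, iters = 1, outside = FALSE) {
  m <- bits
  for (i in seq_len(iters)) m <- max_filter3(m, outside) | m
  m
}

# Sum of `m` over the (2r+1)x(2r+1) window centered on each cell (zero padded),
# via an integral image.
box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  w <- 2L * r + 1L
  P <- matrix(0, nr + 2 * r, nc + 2 * r)
  P[(r + 1):(r + nr), (r + 1):(r + nc)] <- m
  cs <- apply(P, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  I <- matrix(0, nrow(cs) + 1, ncol(cs) + 1)
  I[-1, -1] <- cs
  I[(w + 1):(w + nr), (w + 1):(w + nc)] -
    I[1:nr, (w + 1):(w + nc)] -
    I[(w + 1):(w + nr), 1:nc] +
    I[1:nr, 1:nc]
}

# Label connected components of a logical matrix. Returns an integer matrix
# with 0 for FALSE cells and 1..n component ids otherwise.
label_components <- function(bits, connectivity = 8) {
  nr <- nrow(bits); nc <- ncol(bits)
  idx <- which(bits)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(lab)
  vid <- matrix(0L, nr, nc)
  vid[idx] <- seq_along(idx)
  dirs <- if (connectivity == 8) {
    list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  } else list(c(0, 1), c(1, 0))
  efrom <- integer(0); eto <- integer(0)
  for (d in dirs) {
    a <- bits
    b <- shift_mat(bits, -d[1], -d[2], FALSE)   # neighbor at +d
    both <- which(a & b)
    if (length(both)) {
      nb <- both + d[1] + d[2] * nr
      efrom <- c(efrom, vid[both]); eto <- c(eto, vid[nb])
    }
  }
  g <- igraph::make_graph(c(rbind(efrom, eto)), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Boundary cells of a labeled patch: cells with an 8-neighbor outside the patch
# (grid border cells count as boundary).
patch_boundary <- function(bits) {
  interior <- erode_bits(bits, 1)
  which(bits & !interior, arr.ind = TRUE)
}

# Shape metrics of a patch given its cells: estimated major-axis length and
# mean width. Length = max pairwise Euclidean distance between boundary cell
# centers plus one cell (to span cell extent); width = area / length.
patch_shape_metrics <- function(cells, cell_size) {
  b <- cells
  n <- nrow(b)
  area_m2 <- n * cell_size^2
  if (n == 1) {
    len <- cell_size
  } else {
    ch <- grDevices::chull(b[, 2], b[, 1])
    hb <- b[ch, , drop = FALSE]
    dr <- outer(hb[, 1], hb[, 1], "-")
    dc <- outer(hb[, 2], hb[, 2], "-")
    len <- sqrt(max(dr^2 + dc^2)) * cell_size + cell_size
  }
  list(length_m = len, width_m = area_m2 / len,
       elongation = len^2 / area_m2, area_m2 = area_m2)
}
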