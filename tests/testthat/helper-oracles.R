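# Independent brute-force oracles and tiny fixture builders used across the
# suite. Everything here is deliberately naive (exhaustive scans, explicit
# enumeration) and shares no code with the implementation it checks.

# Exhaustive all-pairs Euclidean distance field (meters).
bf_distance_field <- function(bits, cell_size) {
  pts <- which(bits, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(bits), ncol(bits))
  for (i in seq_len(nrow(bits))) for (j in seq_len(ncol(bits))) {
    out[i, j] <- sqrt(min((i - pts[, 1])^2 + (j - pts[, 2])^2)) * cell_size
  }
  out
}

# Exhaustive focal range (max - min) with window clamped at the border.
bf_focal_range <- function(m, window) {
  r <- (window - 1) %/% 2
  out <- m * 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ri <- max(1, i - r):min(nrow(m), i + r)
    rj <- max(1, j - r):min(ncol(m), j + r)
    out[i, j] <- max(m[ri, rj]) - min(m[ri, rj])
  }
  out
}

# Exhaustive count of flood-fill components (8-connectivity), recursion-free.
bf_count_components <- function(bits) {
  seen <- matrix(FALSE, nrow(bits), ncol(bits))
  n <- 0
  for (s in which(bits)) {
    if (seen[s]) next
    n <- n + 1
    stack <- s
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[cur]) next
      seen[cur] <- TRUE
      ci <- (cur - 1) %% nrow(bits) + 1; cj <- (cur - 1) %/% nrow(bits) + 1
      for (di in -1:1) for (dj in -1:1) {
        ni <- ci + di; nj <- cj + dj
        if (ni >= 1 && ni <= nrow(bits) && nj >= 1 && nj <= ncol(bits)) {
          ncur <- ni + (nj - 1) * nrow(bits)
          if (bits[ncur] && !seen[ncur]) stack <- c(stack, ncur)
        }
      }
    }
  }
  n
}

# Maximum product-of-probability over all simple paths by explicit
# enumeration (feasible for <= 6 patches).
bf_max_product <- function(P, i, j) {
  n <- nrow(P)
  if (i == j) return(1)
  best <- 0
  explore <- function(path, prob) {
    cur <- path[length(path)]
    if (cur == j) { best <<- max(best, prob); return() }
    for (nxt in setdiff(seq_len(n), path)) {
      p <- P[cur, nxt]
      if (p > 0) explore(c(path, nxt), prob * p)
    }
  }
  explore(i, 1)
  best
}

# PC by naive double sum over the enumeration-based max-product matrix.
bf_pc <- function(P, a, AL) {
  n <- length(a)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    tot <- tot + bf_max_product(P, i, j) * a[i] * a[j]
  tot / AL^2
}

# Exact single-source shortest path on an explicitly built 8-connected grid
# graph (Bellman-Ford style relaxation; independent of igraph).
bf_cost_distance <- function(res_values, src_cells, cell_size) {
  nr <- nrow(res_values); nc <- ncol(res_values)
  dist <- matrix(Inf, nr, nc)
  dist[src_cells] <- 0
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ni <- i + di; nj <- j + dj
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        step <- sqrt(di^2 + dj^2) * cell_size *
          (res_values[i, j] + res_values[ni, nj]) / 2
        if (dist[ni, nj] + step < dist[i, j] - 1e-12) {
          dist[i, j] <- dist[ni, nj] + step
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist
}

# Naive 3x3 neighborhood count (center included), used to roughen random
# masks into structured ones.
box_sum_test <- function(bits) {
  out <- matrix(0, nrow(bits), ncol(bits))
  for (i in seq_len(nrow(bits))) for (j in seq_len(ncol(bits))) {
    ri <- max(1, i - 1):min(nrow(bits), i + 1)
    rj <- max(1, j - 1):min(ncol(bits), j + 1)
    out[i, j] <- sum(bits[ri, rj])
  }
  out
}

# Build a land grid with given class codes laid out in a matrix.
lg <- function(m, cell_size = 30) land_grid(as.matrix(m), cell_size = cell_size)

# A single-patch record from a logical matrix (mimics patch_set entries).
one_patch <- function(bits, cell_size = 30, id = 1L) {
  ps <- patch_set_from_mask(bits, cell_size)
  stopifnot(length(ps$patches) == 1)
  p <- ps$patches[[1]]
  p$id <- id
  p
}

# A mildly urbanizing per-step transition matrix for evolution fixtures.
default_transition_within_test <- function() {
  M <- diag(6)
  M[1, 1] <- 0.9; M[1, 5] <- 0.1
  M[3, 3] <- 0.92; M[3, 5] <- 0.08
  M[6, 6] <- 0.9; M[6, 5] <- 0.1
  M
}

# Uniform resistance surface of value r over an nr x nc grid.
uniform_resistance <- function(nr, nc, r = 1, cell_size = 30) {
  lu <- land_grid(matrix(LU_CLASSES[["woodland"]], nr, nc), cell_size = cell_size)
  relief <- cont_grid(matrix(60, nr, nc), cell_size = cell_size)
  rs <- build_resistance(lu, relief)
  rs$values[] <- r
  rs
}
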