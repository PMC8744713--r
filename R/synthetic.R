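#' Specification of a synthetic landscape
#'
#' @param shape Integer (rows, cols).
#' @param cell_size Cell edge in meters (default 30, the study resolution).
#' @param class_fractions Named numeric vector of target class shares
#'   (names from `names(LU_CLASSES)`), non-negative, summing to 1.
#' @param autocorrelation_range Spatial correlation range in cells of the
#'   latent fields; larger values give larger, smoother patches.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A `landscape_spec` object.
#' @export
landscape_spec <- function(shape, cell_size = 30, class_fractions,
                           autocorrelation_range = 12, seed = 1) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% names(LU_CLASSES)))
    stop("class_fractions must be named by land-use class")
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must be >= 0 and sum to 1")
  structure(
    list(shape = as.integer(shape), cell_size = cell_size,
         class_fractions = class_fractions,
         autocorrelation_range = autocorrelation_range, seed = as.integer(seed)),
    class = "landscape_spec"
  )
}

# Smooth Gaussian random field: white noise convolved with a Gaussian kernel
# of standard deviation `range` cells, via FFT (periodic boundary).
gaussian_field <- function(nr, nc, range) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range <= 0) return(noise)
  kr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  kc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  kern <- exp(-outer(kr^2, kc^2, "+") / (2 * range^2))
  kern <- kern / sum(kern)
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) / (nr * nc)
  f
}

#' Generate a spatially autocorrelated categorical landscape
#'
#' Draws one smooth latent field per class and assigns cells by quota: classes
#' are processed in decreasing target share and each claims its strongest
#' unassigned cells, so realized shares match the targets to rounding (well
#' within +/-2 percent of cells) while patches stay spatially coherent.
#'
#' @param spec A [landscape_spec].
#' @return A [land_grid]; deterministic given `spec$seed`.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  n <- nr * nc
  fr <- spec$class_fractions[spec$class_fractions > 0]
  set.seed(spec$seed)
  fields <- lapply(seq_along(fr), function(i)
    gaussian_field(nr, nc, spec$autocorrelation_range))
  names(fields) <- names(fr)
  # largest-remainder quotas
  raw <- fr * n
  quota <- floor(raw)
  rem <- n - sum(quota)
  if (rem > 0) {
    ord <- order(raw - quota, decreasing = TRUE)
    quota[ord[seq_len(rem)]] <- quota[ord[seq_len(rem)]] + 1
  }
  codes <- matrix(NA_integer_, nr, nc)
  unassigned <- rep(TRUE, n)
  for (cl in names(sort(quota, decreasing = TRUE))) {
    q <- quota[[cl]]
    if (q == 0) next
    f <- fields[[cl]]
    cand <- which(unassigned)
    take <- cand[order(f[cand], decreasing = TRUE)[seq_len(q)]]
    codes[take] <- LU_CLASSES[[cl]]
    unassigned[take] <- FALSE
  }
  land_grid(codes, cell_size = spec$cell_size)
}

#' Specification of a landscape evolution
#'
#' @param transition_matrix 6x6 row-stochastic per-step transition matrix in
#'   class order (arable, woodland, grassland, water, construction, unused).
#' @param steps Number of steps to simulate.
#' @param spatial_kernel_size Odd window size for the neighborhood modulation
#'   of conversions (new cells of a class form preferentially next to existing
#'   ones); `NULL` disables it (i.i.d. mode, the analytically verifiable limit).
#' @param seed Integer seed.
#' @return An `evolution_spec` object.
#' @export
evolution_spec <- function(transition_matrix, steps = 1,
                           spatial_kernel_size = 3, seed = 1) {
  M <- as.matrix(transition_matrix)
  if (!all(dim(M) == c(N_CLASSES, N_CLASSES)))
    stop("transition matrix must be 6 x 6")
  if (any(M < 0) || any(M > 1) || any(abs(rowSums(M) - 1) > 1e-9))
    stop("transition matrix must be row-stochastic")
  if (!is.null(spatial_kernel_size) && spatial_kernel_size %% 2 != 1)
    stop("spatial_kernel_size must be odd")
  structure(list(transition_matrix = M, steps = as.integer(steps),
                 spatial_kernel_size = spatial_kernel_size, seed = as.integer(seed)),
            class = "evolution_spec")
}

#' Evolve a landscape under a known transition matrix
#'
#' Each step, every cell changes class with the probabilities of its row of
#' the transition matrix. With the spatial kernel enabled, the off-diagonal
#' probabilities are re-weighted by the local abundance of the target class
#' (keeping the total leave-probability fixed), so conversions clump next to
#' existing patches; with it disabled transitions are i.i.d. and empirical
#' frequencies converge to the matrix entries.
#'
#' @param initial A [land_grid].
#' @param evo An [evolution_spec].
#' @return List of [land_grid]s of length `steps + 1` (initial included).
#' @export
evolve_landscape <- function(initial, evo) {
  stopifnot(inherits(initial, "land_grid"), inherits(evo, "evolution_spec"))
  M <- evo$transition_matrix
  nr <- nrow(initial$codes); nc <- ncol(initial$codes)
  set.seed(evo$seed)
  out <- vector("list", evo$steps + 1)
  out[[1]] <- initial
  cur <- initial$codes
  valid <- cur != initial$nodata
  for (s in seq_len(evo$steps)) {
    P <- M[cur[valid], , drop = FALSE]
    if (!is.null(evo$spatial_kernel_size)) {
      r <- (evo$spatial_kernel_size - 1L) %/% 2L
      W <- sapply(seq_len(N_CLASSES), function(k)
        box_sum((cur == k) * 1, r)[valid] + 0.5)
      leave <- 1 - P[cbind(seq_len(nrow(P)), cur[valid])]
      P2 <- P * W
      P2[cbind(seq_len(nrow(P2)), cur[valid])] <- 0
      rs <- rowSums(P2)
      scale <- ifelse(rs > 0, leave / rs, 0)
      P2 <- P2 * scale
      P2[cbind(seq_len(nrow(P2)), cur[valid])] <- 1 - leave
      P <- P2
    }
    cp <- t(apply(P, 1, cumsum))
    u <- stats::runif(nrow(P))
    nxt <- 1L + as.integer(rowSums(cp < u))
    nxt[nxt > N_CLASSES] <- N_CLASSES
    new <- cur
    new[valid] <- nxt
    cur <- new
    out[[s + 1]] <- land_grid(cur, cell_size = initial$cell_size,
                              origin = initial$origin, nodata = initial$nodata)
  }
  out
}

#' Focal-range topographic relief
#'
#' Relief = max - min of elevation within an odd square window around each
#' cell (edge cells use edge replication).
#'
#' @param elevation A [cont_grid].
#' @param window Odd window size in cells (default 3).
#' @return A [cont_grid] of relief values.
#' @export
generate_relief <- function(elevation, window = 3) {
  stopifnot(window %% 2 == 1, window >= 1)
  r <- (window - 1L) %/% 2L
  m <- elevation$values
  mx <- m; mn <- m
  for (i in seq_len(r)) {
    mx <- max_filter3(mx, -Inf)
    mn <- min_filter3(mn, Inf)
  }
  # edge replication: -Inf/Inf fills never win against real values, so the
  # border windows simply see fewer cells, equivalent to clamping
  cont_grid(mx - mn, cell_size = elevation$cell_size, origin = elevation$origin)
}

normalize01 <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(m * 0)
  (m - rng[1]) / diff(rng)
}

# A thin random polyline mask crossing the grid left to right (used for the
# synthetic river/road/railway networks).
polyline_mask <- function(nr, nc, width = 1, jitter = 0.6) {
  row <- numeric(nc)
  row[1] <- stats::runif(1, nr * 0.2, nr * 0.8)
  steps <- stats::rnorm(nc - 1, 0, jitter)
  row <- pmin(pmax(cumsum(c(row[1], steps)), 1), nr)
  bits <- matrix(FALSE, nr, nc)
  for (j in seq_len(nc)) {
    r0 <- round(row[j])
    rr <- max(1, r0 - (width - 1) %/% 2):min(nr, r0 + width %/% 2)
    bits[rr, j] <- TRUE
  }
  bits
}

#' Generate a stack of driving-factor layers
#'
#' Nine layers mirroring the drivers used for urban-growth suitability
#' modeling: a smooth elevation field raised under woodland, slope and focal
#' relief derived from it, Euclidean distance fields to synthetic river, road,
#' railway and residential masks, and night-light and population-density
#' fields that decay with distance to construction (so class occurrence is
#' learnable from the stack). All layers are min-max normalized to \[0, 1\].
#'
#' @param landuse A [land_grid].
#' @param seed Integer seed.
#' @return Named list of nine [cont_grid]s, with the generating masks attached
#'   as attribute `"masks"` (river, road, railway, residential).
#' @export
generate_factors <- function(landuse, seed = 1) {
  set.seed(seed)
  nr <- nrow(landuse$codes); nc <- ncol(landuse$codes)
  cs <- landuse$cell_size
  wood <- landuse$codes == LU_CLASSES[["woodland"]]
  constr <- landuse$codes == LU_CLASSES[["construction"]]
  elev_raw <- gaussian_field(nr, nc, 10) + 1.5 * gaussian_field(nr, nc, 25) +
    2 * normalize01(box_sum(wood * 1, 5) / (11^2))
  elev <- normalize01(elev_raw)
  # slope: central-difference gradient magnitude
  gx <- (shift_mat(elev, 0, -1, NA) - shift_mat(elev, 0, 1, NA)) / 2
  gy <- (shift_mat(elev, -1, 0, NA) - shift_mat(elev, 1, 0, NA)) / 2
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  slope <- normalize01(sqrt(gx^2 + gy^2))
  relief <- normalize01(generate_relief(cont_grid(elev, cs), 3)$values)

  river <- polyline_mask(nr, nc, width = 2)
  road <- polyline_mask(nr, nc, width = 1, jitter = 0.3)
  railway <- t(polyline_mask(nc, nr, width = 1, jitter = 0.3))
  resid_src <- if (any(constr)) constr else matrix(FALSE, nr, nc)
  if (!any(resid_src)) resid_src[sample(nr * nc, max(1, nr * nc %/% 100))] <- TRUE

  dfield <- function(bits) {
    d <- euclidean_distance_field(bin_mask(bits, cs))$values
    d
  }
  d_river <- dfield(river); d_road <- dfield(road)
  d_rail <- dfield(railway); d_resid <- dfield(resid_src)

  d_constr <- dfield(if (any(constr)) constr else resid_src)
  night <- normalize01(exp(-d_constr / (30 * cs)) + 0.15 * gaussian_field(nr, nc, 6))
  dens <- normalize01(exp(-d_constr / (50 * cs)) + 0.25 * gaussian_field(nr, nc, 10))

  norm_keep0 <- function(d) if (max(d) == 0) d else d / max(d)
  layers <- list(
    elevation = cont_grid(elev, cs), slope = cont_grid(slope, cs),
    relief = cont_grid(relief, cs),
    dist_river = cont_grid(norm_keep0(d_river), cs),
    dist_road = cont_grid(norm_keep0(d_road), cs),
    dist_railway = cont_grid(norm_keep0(d_rail), cs),
    dist_residential = cont_grid(norm_keep0(d_resid), cs),
    night_light = cont_grid(night, cs),
    pop_density = cont_grid(dens, cs)
  )
  attr(layers, "masks") <- list(river = bin_mask(river, cs), road = bin_mask(road, cs),
                                railway = bin_mask(railway, cs),
                                residential = bin_mask(resid_src, cs))
  layers
}

#' Generate a multi-epoch synthetic study system
#'
#' Convenience wrapper producing the inputs the full pipeline needs: an
#' initial landscape, an epoch sequence evolved under a known transition
#' matrix, a relief grid and the driving-factor stack for the base epoch.
#'
#' @param spec A [landscape_spec].
#' @param evo An [evolution_spec].
#' @return List with elements `epochs` (list of [land_grid]),
#'   `factors`, `relief` and `truth` (the generating transition matrix).
#' @export
generate_study_system <- function(spec, evo) {
  lu0 <- generate_landscape(spec)
  epochs <- evolve_landscape(lu0, evo)
  base <- epochs[[length(epochs)]]
  factors <- generate_factors(base, seed = spec$seed + 1L)
  relief_norm <- factors$relief
  # resistance scoring expects relief in meters-like units; rescale to 0-80
  relief <- cont_grid(relief_norm$values * 80, base$cell_size, base$origin)
  list(epochs = epochs, factors = factors, relief = relief,
       truth = evo$transition_matrix)
}
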