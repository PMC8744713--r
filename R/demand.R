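#' Estimate a land-use transition matrix from two epochs
#'
#' Entry (i, j) is the share of class-i cells at the first epoch found in
#' class j at the second; classes absent at the first epoch get an identity
#' row. This is the Markov-chain stage of CA-Markov demand prediction: the
#' forecast depends only on the previous state and the estimated transition
#' frequencies.
#'
#' @param lu_t1,lu_t2 [land_grid]s on one frame.
#' @param interval_years Years between the two epochs (default 1).
#' @return A `transition_matrix`: 6x6 row-stochastic matrix with attribute
#'   `interval_years`.
#' @export
estimate_transition_matrix <- function(lu_t1, lu_t2, interval_years = 1) {
  check_same_frame(lu_t1, lu_t2)
  ok <- lu_t1$codes != lu_t1$nodata & lu_t2$codes != lu_t2$nodata
  a <- factor(lu_t1$codes[ok], levels = LU_CLASSES)
  b <- factor(lu_t2$codes[ok], levels = LU_CLASSES)
  tab <- table(a, b)
  M <- unclass(tab / pmax(rowSums(tab), 1))
  empty <- rowSums(tab) == 0
  M[empty, ] <- 0
  M[cbind(which(empty), which(empty))] <- 1
  dimnames(M) <- list(names(LU_CLASSES), names(LU_CLASSES))
  structure(M, interval_years = interval_years, class = c("transition_matrix", "matrix"))
}

# Matrix power M^t for real t >= 0 via eigendecomposition; NULL when the
# result is not a valid stochastic matrix (complex/negative beyond tolerance).
matrix_power_frac <- function(M, t) {
  if (abs(t - round(t)) < 1e-12) {
    t <- round(t)
    out <- diag(nrow(M))
    for (i in seq_len(t)) out <- out %*% M
    return(out)
  }
  e <- eigen(M)
  Vt <- tryCatch(solve(e$vectors), error = function(e) NULL)
  if (is.null(Vt)) return(NULL)
  out <- e$vectors %*% diag(as.complex(e$values)^t) %*% Vt
  if (max(abs(Im(out))) > 1e-8) return(NULL)
  out <- Re(out)
  if (min(out) < -1e-8) return(NULL)
  out[out < 0] <- 0
  out / rowSums(out)
}

# Largest-remainder rounding of non-negative targets to integers summing to
# `total`.
round_preserve_sum <- function(x, total) {
  x <- pmax(x, 0)
  if (sum(x) == 0) x[] <- total / length(x) else x <- x * total / sum(x)
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Project per-class land demand to a horizon
#'
#' Propagates the base-epoch class counts with the transition matrix raised
#' to horizon_years / interval_years. Non-integer powers use the
#' eigendecomposition root; when that root is not a valid stochastic matrix
#' the projection falls back to whole-interval steps with linear
#' interpolation of counts between the bracketing steps. Counts are rounded
#' by largest remainder so they sum exactly to the non-nodata cell total.
#'
#' @param matrix A `transition_matrix`.
#' @param base A [land_grid] for the base epoch.
#' @param horizon_years Years ahead of the base epoch (> 0).
#' @return Named integer vector of per-class target cell counts (a demand
#'   vector).
#' @export
project_demand <- function(matrix, base, horizon_years) {
  stopifnot(horizon_years > 0)
  interval <- attr(matrix, "interval_years")
  t <- horizon_years / interval
  ok <- base$codes != base$nodata
  counts <- tabulate(base$codes[ok], nbins = N_CLASSES)
  Mt <- matrix_power_frac(unclass(matrix), t)
  target <- if (!is.null(Mt)) {
    as.numeric(counts %*% Mt)
  } else {
    lo <- floor(t); hi <- ceiling(t)
    Mlo <- matrix_power_frac(unclass(matrix), lo)
    Mhi <- matrix_power_frac(unclass(matrix), hi)
    w <- t - lo
    as.numeric(counts %*% Mlo) * (1 - w) + as.numeric(counts %*% Mhi) * w
  }
  out <- round_preserve_sum(target, sum(counts))
  names(out) <- names(LU_CLASSES)
  out
}

#' Demand in km^2
#' @param demand Demand vector in cells.
#' @param cell_size Cell edge in meters.
#' @return Named numeric vector in km^2.
#' @export
demand_km2 <- function(demand, cell_size) cells_to_km2(demand, cell_size)
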