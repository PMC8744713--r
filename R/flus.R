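#' Default neighborhood weights
#'
#' Per-class neighborhood weights of the cellular-automata stage (class order
#' arable, woodland, grassland, water, construction, unused). Construction
#' land has the strongest neighborhood attraction (1), arable the weakest
#' (0.1).
#'
#' @export
NEIGHBORHOOD_WEIGHTS <- c(arable = 0.1, woodland = 0.23, grassland = 0.35,
                          water = 0.5, construction = 1, unused = 0.4)

#' Scenario transfer matrices
#'
#' 0/1 matrices declaring which class-to-class conversions each scenario
#' permits (rows = from, cols = to, class order arable, woodland, grassland,
#' water, construction, unused). The unconstrained ("natural") scenario only
#' bans conversions into water/unused from most classes; the ecological
#' scenario additionally bans woodland to arable/construction and grassland
#' to arable.
#'
#' @export
TRANSFER_MATRICES <- local({
  cls <- c("arable", "woodland", "grassland", "water", "construction", "unused")
  nat <- matrix(c(
    1, 1, 1, 1, 1, 0,
    1, 1, 1, 0, 1, 0,
    1, 1, 1, 0, 1, 1,
    1, 1, 1, 1, 1, 1,
    1, 1, 1, 0, 1, 0,
    1, 1, 1, 1, 1, 1), 6, 6, byrow = TRUE, dimnames = list(cls, cls))
  eco <- matrix(c(
    1, 1, 1, 1, 1, 0,
    0, 1, 1, 0, 0, 0,
    0, 1, 1, 0, 1, 1,
    1, 1, 1, 1, 1, 1,
    1, 1, 1, 0, 1, 0,
    1, 1, 1, 1, 1, 1), 6, 6, byrow = TRUE, dimnames = list(cls, cls))
  list(natural = nat, ecological = eco)
})

#' Scenario configuration for the allocator
#'
#' @param transfer_matrix 6x6 0/1 matrix with unit diagonal.
#' @param restricted Optional [bin_mask]: cells the allocator may never
#'   change.
#' @param neighborhood_weights Named per-class positive weights.
#' @param window Odd neighborhood window in cells (default 3, the Moore
#'   neighborhood).
#' @param max_iterations Sweep cap (default 200).
#' @param tolerance Allowed residual demand in cells (default 0).
#' @param seed Integer seed for the roulette draws.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(transfer_matrix = TRANSFER_MATRICES$natural,
                            restricted = NULL,
                            neighborhood_weights = NEIGHBORHOOD_WEIGHTS,
                            window = 3, max_iterations = 200, tolerance = 0,
                            seed = 1) {
  M <- as.matrix(transfer_matrix)
  stopifnot(all(dim(M) == N_CLASSES), all(M %in% c(0, 1)))
  if (any(diag(M) != 1)) stop("transfer matrix diagonal must be all 1")
  stopifnot(window %% 2 == 1, all(neighborhood_weights > 0))
  structure(list(transfer_matrix = M, restricted = restricted,
                 neighborhood_weights = neighborhood_weights, window = window,
                 max_iterations = max_iterations, tolerance = tolerance,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Sample training cells for the suitability model
#'
#' Seeded uniform sample of non-nodata cells with their driving-factor vector
#' and observed class label.
#'
#' @param lu A [land_grid].
#' @param factors Named list of [cont_grid]s.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return data.frame with one factor column per layer and a `class` factor.
#' @export
sample_training <- function(lu, factors, fraction = 0.05, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  ok <- which(lu$codes != lu$nodata)
  set.seed(seed)
  n <- round(fraction * length(ok))
  idx <- if (fraction >= 1) ok else sort(sample(ok, n))
  X <- vapply(factors, function(f) f$values[idx], numeric(length(idx)))
  df <- as.data.frame(X)
  df$class <- factor(lu$codes[idx], levels = LU_CLASSES, labels = names(LU_CLASSES))
  df
}

#' Fit the occurrence-probability network
#'
#' Single-hidden-layer feed-forward network with softmax output over the six
#' classes (the ANN stage of the simulation), fitted on a training sample.
#'
#' @param training data.frame from [sample_training()].
#' @param hidden_units Hidden-layer size (default 12).
#' @param maxit Optimizer iterations (default 200).
#' @param seed Seed for the weight initialization.
#' @return A `suitability_model`.
#' @export
fit_suitability <- function(training, hidden_units = 12, maxit = 200, seed = 1) {
  present <- levels(droplevels(training$class))
  if (length(present) < 2) stop("training data contains a single class")
  x <- as.matrix(training[, setdiff(names(training), "class"), drop = FALSE])
  y <- nnet::class.ind(droplevels(training$class))
  set.seed(seed)
  fit <- nnet::nnet(x, y, size = hidden_units, softmax = TRUE, maxit = maxit,
                    decay = 0.05, trace = FALSE, MaxNWts = 5000)
  structure(list(fit = fit, classes = present,
                 features = colnames(x)), class = "suitability_model")
}

#' Predict the per-class suitability stack
#'
#' @param model A `suitability_model`.
#' @param factors Named list of [cont_grid]s (must include the training
#'   features).
#' @return A `suitability_stack`: array (rows x cols x 6) of probabilities
#'   summing to 1 per cell (classes unseen in training get a vanishing
#'   floor).
#' @export
predict_suitability <- function(model, factors) {
  f1 <- factors[[model$features[1]]]
  nr <- nrow(f1$values); nc <- ncol(f1$values)
  X <- vapply(model$features, function(nm) as.numeric(factors[[nm]]$values),
              numeric(nr * nc))
  p <- stats::predict(model$fit, X)
  out <- matrix(1e-8, nr * nc, N_CLASSES,
                dimnames = list(NULL, names(LU_CLASSES)))
  out[, model$classes] <- p + 1e-8
  out <- out / rowSums(out)
  arr <- array(out, dim = c(nr, nc, N_CLASSES),
               dimnames = list(NULL, NULL, names(LU_CLASSES)))
  structure(arr, class = "suitability_stack")
}

#' Neighborhood effect of a class
#'
#' Fraction of class-k cells in the (window x window) neighborhood of each
#' cell (center excluded), scaled by the class's neighborhood weight.
#'
#' @param lu A [land_grid].
#' @param k Class code (1..6).
#' @param window Odd window size.
#' @param weight Class weight.
#' @return Numeric matrix.
#' @export
neighborhood_effect <- function(lu, k, window = 3, weight = 1) {
  r <- (window - 1L) %/% 2L
  cnt <- box_sum((lu$codes == k) * 1, r) - (lu$codes == k)
  weight * cnt / (window^2 - 1)
}

#' Adaptive inertia update
#'
#' Standard self-adaptive rule driven by the residual demand
#' D_k = demand_k - current count_k of the last two sweeps: unchanged when
#' |D^(t-1)| <= |D^(t-2)|; scaled by D^(t-2)/D^(t-1) when
#' D^(t-1) < D^(t-2) < 0 (shortfall deepening); scaled by D^(t-1)/D^(t-2)
#' when 0 < D^(t-2) < D^(t-1) (surplus growing).
#'
#' @param inertia Current coefficient.
#' @param d_prev D at sweep t-1.
#' @param d_prev2 D at sweep t-2.
#' @return Updated coefficient.
#' @export
update_inertia <- function(inertia, d_prev, d_prev2) {
  if (abs(d_prev) <= abs(d_prev2)) {
    inertia
  } else if (d_prev < d_prev2 && d_prev2 < 0) {
    inertia * d_prev2 / d_prev
  } else if (d_prev > d_prev2 && d_prev2 > 0) {
    inertia * d_prev / d_prev2
  } else inertia
}

#' Combined allocation probability of one cell/class
#'
#' suitability x neighborhood x inertia x transfer(current -> k); 0 when the
#' cell is restricted (and k differs from its current class) or the transfer
#' is forbidden.
#'
#' @param suit Suitability of the cell for class k.
#' @param neigh Neighborhood effect of class k at the cell.
#' @param inertia Class-k inertia coefficient.
#' @param transfer_ok 0/1 transfer permission current -> k.
#' @param restricted Is the cell inside the restricted area?
#' @param is_current Is k the cell's current class?
#' @return Non-negative score.
#' @export
combined_probability <- function(suit, neigh, inertia, transfer_ok,
                                 restricted = FALSE, is_current = FALSE) {
  if (restricted && !is_current) return(0)
  suit * neigh * inertia * transfer_ok
}

#' Allocate land-use change to meet a demand vector
#'
#' The cellular-automata competition stage: each sweep recomputes the
#' neighborhood effects and adaptive inertia, visits candidate cells in
#' seeded random order, draws a class by roulette proportional to the
#' combined probability (suitability x neighborhood x inertia x transfer
#' permission), and commits a change only while the drawn class still has
#' positive residual demand and the cell's current class has a surplus.
#' Restricted cells and forbidden transfers never change. Stops when every
#' residual is within tolerance, after `max_iterations` sweeps, or after 25
#' consecutive sweeps without a commit (infeasible demand under the
#' constraints); the result always carries the residual diagnostics.
#'
#' @param base A [land_grid].
#' @param suitability A `suitability_stack`.
#' @param demand Named integer demand vector (cells; must sum to the
#'   non-nodata cell count).
#' @param scenario A [scenario_config()].
#' @return A [land_grid] with attributes `residual` (per-class cells),
#'   `iterations` and `converged`.
#' @export
allocate <- function(base, suitability, demand, scenario) {
  codes <- base$codes
  nr <- nrow(codes); nc <- ncol(codes)
  valid <- codes != base$nodata
  if (sum(demand) != sum(valid))
    stop("demand must sum to the non-nodata cell count")
  restricted <- if (!is.null(scenario$restricted)) scenario$restricted$bits
                else matrix(FALSE, nr, nc)
  Tm <- scenario$transfer_matrix
  w <- scenario$neighborhood_weights[names(LU_CLASSES)]
  suit <- matrix(suitability, nr * nc, N_CLASSES)
  cur <- codes
  counts <- tabulate(cur[valid], nbins = N_CLASSES)
  resid <- as.numeric(demand) - counts
  inertia <- rep(1, N_CLASSES)
  d_hist <- list(resid, resid)
  set.seed(scenario$seed)
  cand_all <- which(valid & !restricted)
  iter <- 0L
  stalled <- 0L
  eps_neigh <- 1e-4   # keeps demand-driven growth feasible away from seeds
  while (iter < scenario$max_iterations && stalled < 25L &&
         any(abs(resid) > scenario$tolerance)) {
    iter <- iter + 1L
    if (iter > 2) {
      for (k in seq_len(N_CLASSES))
        inertia[k] <- update_inertia(inertia[k], d_hist[[2]][k], d_hist[[1]][k])
    }
    lu_now <- land_grid(cur, base$cell_size, base$origin, base$nodata)
    neigh <- vapply(seq_len(N_CLASSES), function(k)
      as.numeric(neighborhood_effect(lu_now, k, scenario$window, w[k])),
      numeric(nr * nc))
    # candidates: cells of oversupplied classes only can shed, but visiting
    # all keeps the roulette faithful; restrict to shedding cells for speed
    shed <- which(resid < 0)
    cand <- cand_all[cur[cand_all] %in% shed]
    if (!length(cand)) break
    cand <- sample(cand)
    P <- suit[cand, , drop = FALSE] * (neigh[cand, , drop = FALSE] + eps_neigh) *
      matrix(inertia, length(cand), N_CLASSES, byrow = TRUE) *
      Tm[cur[cand], , drop = FALSE]
    rs <- rowSums(P)
    u <- stats::runif(length(cand)) * rs
    cp <- P
    for (k in 2:N_CLASSES) cp[, k] <- cp[, k] + cp[, k - 1]
    draw <- 1L + as.integer(rowSums(cp < u))
    draw[draw > N_CLASSES] <- N_CLASSES
    committed <- 0L
    for (m in seq_along(cand)) {
      i <- cand[m]; k <- draw[m]; c0 <- cur[i]
      if (k == c0) next
      if (resid[k] > 0 && resid[c0] < 0 && Tm[c0, k] == 1) {
        cur[i] <- k
        resid[k] <- resid[k] - 1; resid[c0] <- resid[c0] + 1
        counts[k] <- counts[k] + 1; counts[c0] <- counts[c0] - 1
        committed <- committed + 1L
      }
      if (all(abs(resid) <= scenario$tolerance)) break
    }
    stalled <- if (committed == 0L) stalled + 1L else 0L
    d_hist <- list(d_hist[[2]], resid)
  }
  out <- land_grid(cur, base$cell_size, base$origin, base$nodata)
  attr(out, "residual") <- stats::setNames(resid, names(LU_CLASSES))
  attr(out, "iterations") <- iter
  attr(out, "converged") <- all(abs(resid) <= scenario$tolerance)
  if (!attr(out, "converged"))
    warning("allocation stopped at max_iterations with residual demand: ",
            paste(names(LU_CLASSES), resid, collapse = ", "))
  out
}

#' Simulate a scenario end to end
#'
#' Wires the stages together: estimates the transition matrix from the last
#' two epochs, projects demand to the horizon, fits the suitability network
#' on the base (latest) epoch, and allocates. The "natural" scenario uses the
#' unconstrained transfer matrix and no restricted area; the "ecological"
#' scenario uses the constrained matrix plus the ecological security pattern
#' as restricted area.
#'
#' @param epochs List of >= 2 [land_grid]s in time order.
#' @param factors Driving-factor stack for the base epoch.
#' @param scenario "natural" or "ecological", or a ready [scenario_config()].
#' @param horizon_years Years beyond the base epoch.
#' @param epoch_interval Years between the two calibration epochs.
#' @param esp An `esp` object (required for "ecological").
#' @param ann List of ANN settings: `fraction`, `hidden_units`, `maxit`.
#' @param seed Integer seed (fans out to sampling, fitting and allocation).
#' @return List: `grid` (simulated [land_grid]), `demand`, `matrix`,
#'   `suitability`, `scenario`.
#' @export
simulate_scenario <- function(epochs, factors, scenario = "natural",
                              horizon_years, epoch_interval = 1, esp = NULL,
                              ann = list(fraction = 0.05, hidden_units = 12,
                                         maxit = 200),
                              seed = 1) {
  stopifnot(length(epochs) >= 2)
  n <- length(epochs)
  base <- epochs[[n]]
  M <- estimate_transition_matrix(epochs[[n - 1]], base, epoch_interval)
  demand <- project_demand(M, base, horizon_years)
  if (is.character(scenario)) {
    name <- match.arg(scenario, c("natural", "ecological"))
    restricted <- NULL
    if (name == "ecological") {
      if (is.null(esp)) stop("ecological scenario requires an esp")
      restricted <- esp$restricted
    }
    scenario <- scenario_config(TRANSFER_MATRICES[[name]], restricted = restricted,
                                seed = seed + 3L)
  }
  train <- sample_training(base, factors, fraction = ann$fraction, seed = seed + 1L)
  model <- fit_suitability(train, hidden_units = ann$hidden_units,
                           maxit = ann$maxit, seed = seed + 2L)
  suit <- predict_suitability(model, factors)
  grid <- allocate(base, suit, demand, scenario)
  list(grid = grid, demand = demand, matrix = M, suitability = suit,
       scenario = scenario)
}
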