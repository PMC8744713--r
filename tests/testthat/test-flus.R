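make_system <- function(shape = c(60, 60), seed = 2) {
  fr <- c(arable = .3, woodland = .3, grassland = .1, water = .1,
          construction = .15, unused = .05)
  g <- generate_landscape(landscape_spec(shape, class_fractions = fr, seed = seed))
  fac <- generate_factors(g, seed = seed + 1)
  list(lu = g, factors = fac)
}

test_that("training samples are sized and seeded as requested", {
  sys <- make_system(c(50, 50))
  t1 <- sample_training(sys$lu, sys$factors, fraction = 1, seed = 1)
  expect_equal(nrow(t1), 2500)
  t2 <- sample_training(sys$lu, sys$factors, fraction = 0.1, seed = 5)
  expect_equal(nrow(t2), 250)
  t3 <- sample_training(sys$lu, sys$factors, fraction = 0.1, seed = 5)
  expect_identical(t2, t3)
})

test_that("suitability probabilities are valid and recover injected signal", {
  sys <- make_system()
  train <- sample_training(sys$lu, sys$factors, fraction = 0.3, seed = 3)
  model <- fit_suitability(train, hidden_units = 10, maxit = 150, seed = 4)
  suit <- predict_suitability(model, sys$factors)
  sums <- apply(suit, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(suit >= 0))

  # held-out accuracy materially above the majority-class rate
  hold <- sample_training(sys$lu, sys$factors, fraction = 0.2, seed = 99)
  Xh <- as.matrix(hold[, setdiff(names(hold), "class")])
  ph <- stats::predict(model$fit, Xh)
  acc <- mean(model$classes[apply(ph, 1, which.max)] == as.character(hold$class))
  majority <- max(table(hold$class)) / nrow(hold)
  expect_gt(acc, majority + 0.1)

  # no-information limit: constant factors give ~class-frequency probabilities
  const <- lapply(sys$factors, function(f) { f$values[] <- 0.5; f })
  tr <- sample_training(sys$lu, const, fraction = 0.5, seed = 6)
  m0 <- fit_suitability(tr, hidden_units = 4, maxit = 100, seed = 7)
  s0 <- predict_suitability(m0, const)
  freqs <- table(tr$class) / nrow(tr)
  for (k in seq_len(6))
    expect_equal(unname(s0[1, 1, k]), unname(freqs[k]), tolerance = 0.05)

  single <- train[train$class == train$class[1], ]
  expect_error(fit_suitability(single), "single class")
})

test_that("neighborhood effect matches closed forms and the window scan", {
  g <- lg(matrix(2, 10, 10))
  ne <- neighborhood_effect(g, 2, 3, weight = 0.23)
  expect_true(all(abs(ne[2:9, 2:9] - 0.23) < 1e-12))

  g2 <- lg({ m <- matrix(1, 9, 9); m[5, 5] <- 5; m })
  ne2 <- neighborhood_effect(g2, 5, 3, weight = 1)
  expect_equal(ne2[4, 4], 1 / 8)
  expect_equal(ne2[5, 6], 1 / 8)
  expect_equal(ne2[5, 5], 0)

  set.seed(71)
  m <- matrix(sample(1:6, 144, TRUE), 12, 12)
  ne3 <- neighborhood_effect(lg(m), 3, 5, weight = 0.35)
  for (probe in list(c(3, 3), c(1, 1), c(12, 7))) {
    i <- probe[1]; j <- probe[2]
    ri <- max(1, i - 2):min(12, i + 2); rj <- max(1, j - 2):min(12, j + 2)
    cnt <- sum(m[ri, rj] == 3) - (m[i, j] == 3)
    expect_equal(ne3[i, j], 0.35 * cnt / 24)
  }
})

test_that("adaptive inertia follows the residual-demand rule", {
  expect_equal(update_inertia(1, -10, -10), 1)
  expect_equal(update_inertia(1, -10, -20), 1)       # |D| shrinking
  expect_equal(update_inertia(2, -40, -20), 2 * (-20) / (-40))
  expect_equal(update_inertia(1, 40, 10), 4)
  expect_equal(update_inertia(3, 10, 40), 3)
})

test_that("combined probability honors restrictions and bans", {
  expect_equal(combined_probability(.5, .3, 1.2, 1, restricted = TRUE), 0)
  expect_equal(combined_probability(.5, .3, 1.2, 0), 0)
  expect_equal(combined_probability(.5, .3, 2, 1), .5 * .3 * 2)
  # a restricted cell may keep its current class
  expect_gt(combined_probability(.5, .3, 1, 1, restricted = TRUE,
                                 is_current = TRUE), 0)
})

test_that("allocation meets demand exactly and never violates constraints", {
  set.seed(72)
  codes <- matrix(sample(c(1L, 2L, 5L), 2500, TRUE, c(.5, .3, .2)), 50)
  base <- land_grid(codes)
  suit <- structure(array(1 / 6, c(50, 50, 6)), class = "suitability_stack")
  demand <- tabulate(codes, 6)
  demand[1] <- demand[1] - 200; demand[5] <- demand[5] + 200
  names(demand) <- names(LU_CLASSES)
  sc <- scenario_config(TRANSFER_MATRICES$natural, seed = 7)
  out <- allocate(base, suit, demand, sc)
  expect_true(attr(out, "converged"))
  expect_equal(tabulate(out$codes, 6), unname(demand))
  changed <- which(out$codes != codes)
  expect_true(all(TRANSFER_MATRICES$natural[cbind(codes[changed],
                                                  out$codes[changed])] == 1))

  # fixed point: demand = base counts, only self-transfers allowed
  sc_id <- scenario_config(diag(6) * 0 + diag(6), seed = 1)
  d0 <- stats::setNames(tabulate(codes, 6), names(LU_CLASSES))
  out0 <- allocate(base, suit, d0, sc_id)
  expect_identical(out0$codes, codes)

  # full restriction: output = base regardless of demand
  all_r <- bin_mask(matrix(TRUE, 50, 50), 30)
  sc_r <- scenario_config(TRANSFER_MATRICES$natural, restricted = all_r, seed = 2)
  expect_warning(outr <- allocate(base, suit, demand, sc_r), "residual")
  expect_identical(outr$codes, codes)

  expect_error(allocate(base, suit, demand + 1, sc), "sum")
})

test_that("forbidden transfers are never used even under demand pressure", {
  set.seed(73)
  codes <- matrix(sample(c(2, 3, 5), 1600, TRUE, c(.6, .2, .2)), 40)
  base <- land_grid(codes)
  suit <- structure(array(1 / 6, c(40, 40, 6)), class = "suitability_stack")
  demand <- tabulate(codes, 6)
  demand[5] <- demand[5] + 150; demand[2] <- demand[2] - 150
  names(demand) <- names(LU_CLASSES)
  # ecological matrix bans woodland -> construction
  sc <- scenario_config(TRANSFER_MATRICES$ecological, seed = 8, max_iterations = 60)
  out <- suppressWarnings(allocate(base, suit, demand, sc))
  changed <- which(out$codes != codes)
  if (length(changed))
    expect_true(all(TRANSFER_MATRICES$ecological[cbind(codes[changed],
                                                       out$codes[changed])] == 1))
  expect_false(any(codes == 2 & out$codes == 5))
})

test_that("scenario simulation is deterministic and honors the restricted area", {
  sys <- make_system(c(60, 60), seed = 5)
  M <- default_transition_within_test()
  epochs <- evolve_landscape(sys$lu, evolution_spec(M, steps = 2, seed = 6))
  fac <- generate_factors(epochs[[3]], seed = 9)
  restricted <- bin_mask(matrix(FALSE, 60, 60), 30)
  restricted$bits[1:30, 1:30] <- TRUE
  esp <- assemble_esp(restricted, bin_mask(matrix(FALSE, 60, 60), 30))
  ann <- list(fraction = 0.2, hidden_units = 8, maxit = 100)

  eco1 <- suppressWarnings(simulate_scenario(epochs, fac, "ecological",
                                             horizon_years = 1, esp = esp,
                                             ann = ann, seed = 11))
  eco2 <- suppressWarnings(simulate_scenario(epochs, fac, "ecological",
                                             horizon_years = 1, esp = esp,
                                             ann = ann, seed = 11))
  expect_identical(eco1$grid$codes, eco2$grid$codes)

  base <- epochs[[3]]
  inside <- esp$restricted$bits
  expect_identical(eco1$grid$codes[inside], base$codes[inside])

  nat <- suppressWarnings(simulate_scenario(epochs, fac, "natural",
                                            horizon_years = 1, ann = ann,
                                            seed = 11))
  growth_in <- function(g) sum(g$codes[inside] == 5) - sum(base$codes[inside] == 5)
  expect_gte(growth_in(nat$grid), growth_in(eco1$grid))
  expect_equal(growth_in(eco1$grid), 0)
})
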