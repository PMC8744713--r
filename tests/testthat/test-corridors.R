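test_that("resistance surface combines land-use and relief scores", {
  lu <- lg(matrix(c(2, 5), 1, 2))            # woodland, construction
  relief <- cont_grid(matrix(c(60, 5), 1, 2), 30)
  rs <- build_resistance(lu, relief)
  expect_equal(rs$values[1, 1], 0.7 * 1 + 0.3 * 1)     # 1.0
  expect_equal(rs$values[1, 2], 0.7 * 100 + 0.3 * 90)  # 97.0

  set.seed(51)
  lu <- lg(matrix(sample(1:6, 100, TRUE), 10, 10))
  relief <- cont_grid(matrix(runif(100, 0, 80), 10, 10), 30)
  rs <- build_resistance(lu, relief)
  expect_true(all(rs$values >= 1 & rs$values <= 100))
  expect_equal(rs$values, rs$w_lu * rs$lu_score + rs$w_relief * rs$relief_score)
})

test_that("cost distance matches one-step closed forms and the explicit-graph oracle", {
  rs <- uniform_resistance(5, 5, r = 3)
  src <- matrix(FALSE, 5, 5); src[3, 3] <- TRUE
  cd <- cost_distance(rs, bin_mask(src, 30))
  expect_equal(cd$values[3, 3], 0)
  expect_equal(cd$values[3, 4], 3 * 30)            # orthogonal step
  expect_equal(cd$values[4, 4], 3 * 30 * sqrt(2))  # diagonal step

  set.seed(52)
  rs <- uniform_resistance(8, 8)
  rs$values[] <- matrix(runif(64, 1, 100), 8, 8)
  src <- matrix(FALSE, 8, 8); src[1, 1] <- TRUE; src[8, 3] <- TRUE
  cd <- cost_distance(rs, bin_mask(src, 30))
  oracle <- bf_cost_distance(rs$values, which(src), 30)
  expect_equal(cd$values, oracle, tolerance = 1e-9)

  # monotonicity: raising any cell's resistance never lowers any cost
  rs2 <- rs; rs2$values[4, 4] <- rs2$values[4, 4] + 50
  cd2 <- cost_distance(rs2, bin_mask(src, 30))
  expect_true(all(cd2$values - cd$values >= -1e-9))

  expect_error(cost_distance(rs, bin_mask(matrix(FALSE, 8, 8), 30)), "empty")
})

test_that("least-cost paths follow cheap channels and agree with cost distance", {
  # a low-resistance channel in a high-resistance field
  vals <- matrix(80, 7, 12)
  vals[4, ] <- 1
  rs <- uniform_resistance(7, 12); rs$values <- vals
  pa <- one_patch({ b <- matrix(FALSE, 7, 12); b[4, 1] <- TRUE; b }, id = 1L)
  pb <- one_patch({ b <- matrix(FALSE, 7, 12); b[4, 12] <- TRUE; b }, id = 2L)
  cp <- least_cost_path(rs, pa, pb)
  expect_true(all(cp$cells[, 1] == 4))   # stays in the channel
  expect_equal(cp$cost, 11 * 30 * 1)

  # symmetry and agreement with the cost-distance value at the far patch
  cp_rev <- least_cost_path(rs, pb, pa)
  expect_equal(cp$cost, cp_rev$cost)
  cd <- cost_distance(rs, patch_set_mask(structure(
    list(patches = list(pa), cell_size = 30, origin = c(0, 0), shape = c(7, 12)),
    class = "patch_set")))
  expect_equal(min(cd$values[pb$cells]), cp$cost)

  # adjacent patches: one orthogonal step
  rs2 <- uniform_resistance(3, 4, r = 2)
  p1 <- one_patch({ b <- matrix(FALSE, 3, 4); b[2, 1] <- TRUE; b }, id = 1L)
  p2 <- one_patch({ b <- matrix(FALSE, 3, 4); b[2, 2] <- TRUE; b }, id = 2L)
  expect_equal(least_cost_path(rs2, p1, p2)$cost, 2 * 30)
})

test_that("gravity interaction follows the definitional closed form", {
  expect_equal(gravity_interaction(exp(1), exp(1), 1, 1, 10, 10), 1)
  g1 <- gravity_interaction(100, 200, 2, 3, 50, 80)
  g2 <- gravity_interaction(200, 100, 3, 2, 50, 80)
  expect_equal(g1, g2)   # symmetry
  # halving L quadruples G
  expect_equal(gravity_interaction(100, 200, 2, 3, 25, 80), 4 * g1)
  expect_equal(gravity_interaction(10, 10, 1, 1, 0, 5), Inf)
})

test_that("corridor selection keeps top-k but never isolates a source", {
  paths <- lapply(list(c(1L, 2L), c(1L, 3L), c(2L, 3L)), function(ij)
    structure(list(i = ij[1], j = ij[2], cells = cbind(1, 1:2),
                   cost = sum(ij), length_m = 30), class = "corridor_path"))
  grav <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                     L = c(3, 4, 5), G = c(10, 1, 0.1))
  all_kept <- select_corridors(paths, grav, "top_k", k = 3)
  expect_length(all_kept, 3)

  # k = 1 would drop patch 3; the spanning net must keep a link to it
  kept <- select_corridors(paths, grav, "top_k", k = 1)
  ij <- cbind(vapply(kept, `[[`, integer(1), "i"), vapply(kept, `[[`, integer(1), "j"))
  expect_true(3 %in% ij)
  # threshold above max G falls back to the spanning set
  kept2 <- select_corridors(paths, grav, "threshold", g_min = 100)
  expect_gte(length(kept2), 2)
  g <- igraph::graph_from_edgelist(do.call(rbind, lapply(kept2, function(p)
    c(p$i, p$j))), directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
})

test_that("path buffering matches a distance-field threshold", {
  cellsq <- cbind(4, 2:9)
  path <- structure(list(i = 1L, j = 2L, cells = cellsq, cost = 1,
                         length_m = 210), class = "corridor_path")
  frame <- cont_grid(matrix(0, 9, 10), 30)
  b0 <- buffer_paths(list(path), 0, frame)
  expect_equal(sum(b0$bits), nrow(cellsq))
  expect_true(all(b0$bits[cellsq]))

  b100 <- buffer_paths(list(path), 100, frame)
  bits <- matrix(FALSE, 9, 10); bits[cellsq] <- TRUE
  d <- bf_distance_field(bits, 30)
  expect_equal(b100$bits, d <= 100)
  expect_true(all(b100$bits[cellsq]))
})

test_that("river-corridor shape rules admit channels and reject ponds and lakes", {
  pond <- matrix(FALSE, 10, 10); pond[5, 5] <- TRUE
  expect_false(any(river_corridors(bin_mask(pond, 30))$bits))

  chan <- matrix(FALSE, 6, 210); chan[3:4, 6:205] <- TRUE  # 2 x 200 cells
  rc <- river_corridors(bin_mask(chan, 30), min_width = 30, min_length = 5000)
  expect_true(all(rc$bits[chan]))

  lake <- matrix(FALSE, 60, 60); lake[6:55, 6:55] <- TRUE  # 50 x 50 square
  expect_false(any(river_corridors(bin_mask(lake, 30))$bits))
})

test_that("node selection ranks non-source cores by area", {
  bits <- matrix(FALSE, 30, 60)
  bits[2:11, 2:11] <- TRUE     # 100 cells
  bits[2:8, 20:27] <- TRUE     # 56 cells
  bits[2:6, 35:40] <- TRUE     # 30 cells
  bits[2:4, 50:52] <- TRUE     # 9 cells
  cores <- patch_set_from_mask(bits, 30)
  src_bits <- matrix(FALSE, 30, 60); src_bits[2:11, 2:11] <- TRUE
  sources <- patch_set_from_mask(src_bits, 30)
  nodes <- select_nodes(cores, sources, n = 2)
  expect_length(nodes$patches, 2)
  expect_equal(sort(vapply(nodes$patches, function(p) nrow(p$cells), integer(1))),
               c(30, 56))
  expect_length(select_nodes(cores, sources, n = 0)$patches, 0)
})

test_that("the assembled pattern is the union of its components", {
  m <- function(ij) { b <- matrix(FALSE, 6, 6); b[ij] <- TRUE; bin_mask(b, 30) }
  s <- m(cbind(1:2, 1:2)); co <- m(cbind(3, 1:4)); no <- m(cbind(5, 5))
  esp <- assemble_esp(s, co, rivers = NULL, nodes = no)
  expect_equal(sum(esp$restricted$bits),
               sum(s$bits | co$bits | no$bits))
  expect_true(all(esp$restricted$bits[s$bits]))
  # idempotent under re-assembly
  esp2 <- assemble_esp(esp$sources, esp$corridors, nodes = esp$nodes)
  expect_identical(esp2$restricted$bits, esp$restricted$bits)

  empty <- m(cbind(1, 1)); empty$bits[] <- FALSE
  esp0 <- assemble_esp(empty, empty)
  expect_false(any(esp0$restricted$bits))
})
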