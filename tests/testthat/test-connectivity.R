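make_two_cells <- function(sep_cols, cell_size = 30) {
  bits <- matrix(FALSE, 3, sep_cols + 2)
  bits[2, 1] <- TRUE; bits[2, sep_cols + 2] <- TRUE
  patch_set_from_mask(bits, cell_size)
}

test_that("patch distance matches hand cases and an exhaustive scan", {
  ps <- make_two_cells(4)  # single cells 5 columns apart
  p1 <- ps$patches[[1]]; p2 <- ps$patches[[2]]
  expect_equal(patch_distance(p1, p1, 30), 0)
  expect_equal(patch_distance(p1, p2, 30), 150)

  set.seed(31)
  bits <- matrix(runif(400) < 0.08, 20, 20)
  ps <- patch_set_from_mask(bits, 30)
  if (length(ps$patches) >= 2) {
    a <- ps$patches[[1]]; b <- ps$patches[[2]]
    # exhaustive all-pairs over every cell (not just boundary)
    dr <- outer(a$cells[, 1], b$cells[, 1], "-")
    dc <- outer(a$cells[, 2], b$cells[, 2], "-")
    expected <- if (min(pmax(abs(dr), abs(dc))) <= 1) 0 else sqrt(min(dr^2 + dc^2)) * 30
    expect_equal(patch_distance(a, b, 30), expected)
  }
})

test_that("dispersal kernel is calibrated by the threshold/probability pair", {
  expect_equal(direct_probability(0), 1)
  expect_equal(direct_probability(1500, 1500, 0.5), 0.5)
  expect_equal(direct_probability(3000, 1500, 0.5), 0.25)
  expect_equal(direct_probability(1000, 1500, 0.5, mode = "hard"), 0.5)
  expect_equal(direct_probability(2000, 1500, 0.5, mode = "hard"), 0)
})

test_that("max-product path probability uses stepping stones and matches enumeration", {
  # 3 patches in a line: direct p13 tiny, two steps of 0.6 give 0.36
  P <- diag(3)
  P[1, 2] <- P[2, 1] <- 0.6
  P[2, 3] <- P[3, 2] <- 0.6
  P[1, 3] <- P[3, 1] <- 0.01
  g <- structure(list(areas = c(1, 1, 1), pij_direct = P, AL = 3, ids = 1:3),
                 class = "connectivity_graph")
  expect_equal(max_product_probability(g, 1, 1), 1)
  expect_equal(max_product_probability(g, 1, 3), 0.36)

  set.seed(41)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    P <- matrix(0, n, n)
    P[upper.tri(P)] <- ifelse(runif(n * (n - 1) / 2) < 0.3, 0,
                              runif(n * (n - 1) / 2))
    P <- P + t(P); diag(P) <- 1
    g <- structure(list(areas = runif(n, 1, 10), pij_direct = P, AL = 10,
                        ids = seq_len(n)), class = "connectivity_graph")
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      expect_equal(max_product_probability(g, i, j), bf_max_product(P, i, j),
                   tolerance = 1e-9)
  }
})

test_that("PC matches closed forms and the naive summation oracle", {
  # one patch covering all habitat
  g1 <- structure(list(areas = 5, pij_direct = matrix(1, 1, 1), AL = 5, ids = 1L),
                  class = "connectivity_graph")
  expect_equal(compute_pc(g1), 1)

  # two mutually unreachable patches
  P <- diag(2)
  g2 <- structure(list(areas = c(3, 4), pij_direct = P, AL = 7, ids = 1:2),
                  class = "connectivity_graph")
  expect_equal(compute_pc(g2), (9 + 16) / 49)

  set.seed(42)
  n <- 5
  P <- matrix(0, n, n)
  P[upper.tri(P)] <- runif(n * (n - 1) / 2)
  P <- P + t(P); diag(P) <- 1
  a <- runif(n, 1, 10)
  g3 <- structure(list(areas = a, pij_direct = P, AL = sum(a), ids = seq_len(n)),
                  class = "connectivity_graph")
  expect_equal(compute_pc(g3), bf_pc(P, a, sum(a)), tolerance = 1e-9)

  # monotonicity: raising a direct probability never lowers PC
  P2 <- P; P2[1, 2] <- P2[2, 1] <- min(1, P[1, 2] + 0.3)
  g4 <- g3; g4$pij_direct <- P2
  expect_gte(compute_pc(g4), compute_pc(g3))
})

test_that("dPC follows removal closed forms and stays non-negative", {
  g1 <- structure(list(areas = 5, pij_direct = matrix(1, 1, 1), AL = 5, ids = 1L),
                  class = "connectivity_graph")
  expect_equal(compute_dpc(g1, 1), 100)

  # an isolated tiny patch: dPC = 100 a_k^2 / (AL^2 PC)
  P <- diag(3); P[1, 2] <- P[2, 1] <- 0.8
  a <- c(50, 60, 2)
  g <- structure(list(areas = a, pij_direct = P, AL = sum(a), ids = 1:3),
                 class = "connectivity_graph")
  PC <- compute_pc(g)
  expect_equal(compute_dpc(g, 3), 100 * a[3]^2 / (sum(a)^2 * PC), tolerance = 1e-9)

  set.seed(43)
  for (rep in 1:3) {
    n <- sample(3:6, 1)
    P <- matrix(0, n, n)
    P[upper.tri(P)] <- runif(n * (n - 1) / 2)
    P <- P + t(P); diag(P) <- 1
    a <- runif(n, 1, 10)
    g <- structure(list(areas = a, pij_direct = P, AL = sum(a), ids = seq_len(n)),
                   class = "connectivity_graph")
    tab <- compute_dpc(g)
    expect_true(all(tab$dPC >= -1e-9))
    # relabeling invariance: permuting patches permutes dPC
    perm <- sample(n)
    gp <- g; gp$areas <- a[perm]; gp$pij_direct <- P[perm, perm]; gp$ids <- seq_len(n)
    tabp <- compute_dpc(gp)
    expect_equal(tabp$dPC, tab$dPC[perm], tolerance = 1e-9)
  }
})

test_that("duplicated symmetric patches share the same dPC", {
  P <- diag(2); P[1, 2] <- P[2, 1] <- 0.4
  g <- structure(list(areas = c(5, 5), pij_direct = P, AL = 10, ids = 1:2),
                 class = "connectivity_graph")
  tab <- compute_dpc(g)
  expect_equal(tab$dPC[1], tab$dPC[2], tolerance = 1e-12)
})

test_that("graph construction from patches wires distances into probabilities", {
  ps <- make_two_cells(4)  # 150 m apart at 30 m cells
  g <- build_connectivity_graph(ps, threshold = 1500, p_thr = 0.5)
  expect_equal(g$pij_direct[1, 2], exp(log(0.5) / 1500 * 150))
  expect_equal(g$AL, sum(patch_areas(ps)))
  expect_equal(diag(g$pij_direct), c(1, 1))
})

test_that("source selection applies the dPC and water rules", {
  bits <- matrix(FALSE, 40, 40)
  bits[2:12, 2:12] <- TRUE       # core A
  bits[25:35, 25:35] <- TRUE     # core B
  cores <- patch_set_from_mask(bits, 30)
  dpc_none <- data.frame(id = 1:2, area_hm2 = patch_areas(cores), dPC = c(0.5, 0.9))
  sel <- select_sources(cores, dpc_none, NULL, dpc_min = 1)
  expect_length(sel$patches, 0)

  dpc_some <- data.frame(id = 1:2, area_hm2 = patch_areas(cores), dPC = c(5, 0.9))
  # compact lake 120 hm^2: 37x37 cells at 30 m = 123.2 hm^2, elongation ~ 2
  lake <- matrix(FALSE, 80, 80); lake[10:46, 10:46] <- TRUE
  water <- patch_set_from_mask(lake, 30)
  sel <- select_sources(cores, dpc_some, water, dpc_min = 1, water_min_area = 100)
  expect_length(sel$patches, 2)
  expect_setequal(vapply(sel$patches, `[[`, character(1), "type"),
                  c("core", "water"))

  # 120 hm^2 channel: 2 x 667 cells = 120 hm^2, elongation >> 10 -> river
  chan <- matrix(FALSE, 4, 700); chan[2:3, 10:676] <- TRUE
  water2 <- patch_set_from_mask(chan, 30)
  sel2 <- select_sources(cores, dpc_some, water2, dpc_min = 1, water_min_area = 100)
  expect_length(sel2$patches, 1)
  expect_equal(sel2$patches[[1]]$type, "core")
})
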