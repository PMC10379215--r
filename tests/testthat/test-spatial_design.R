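test_that("distances are scaled so the closest spots sit at distance 1", {
  g <- make_grid_coords(10)
  off <- g$D[upper.tri(g$D)]
  expect_equal(min(off), 1)
  expect_equal(g$D[1, 2], 1)        # rook neighbours
  expect_equal(g$D[1, 12], sqrt(2)) # diagonal neighbours
  # a single gap defines the unit
  g2 <- compute_scaled_distances(cbind(c(0, 0), c(0, 3)))
  expect_equal(g2$D[1, 2], 1)
  # collinear spots
  g3 <- compute_scaled_distances(cbind(c(0, 2, 4), c(0, 0, 0)))
  expect_equal(unname(g3$D), rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0)))
  expect_error(compute_scaled_distances(cbind(c(1, 1), c(2, 2))),
               "coincide")
  expect_warning(compute_scaled_distances(cbind(c(0, 0, 1), c(0, 0, 0))),
                 "duplicate")
})

test_that("pair selection respects thresholds, self-pairs and ordering", {
  g <- make_grid_coords(10)
  expect_equal(nrow(select_pairs(g)), 10000) # N^2
  p1 <- select_pairs(g, max_distance = 1)
  # self + rook-adjacent only
  expect_true(all(g$D[p1] <= 1))
  expect_equal(nrow(p1), 100 + 2 * (2 * 9 * 10))
  # a threshold beyond the grid diameter keeps all pairs
  expect_equal(nrow(select_pairs(g, max_distance = 9 * sqrt(2))), 10000)
  expect_equal(nrow(select_pairs(g, include_self = FALSE)), 9900)
  # deterministic sender-major order
  p <- select_pairs(toy_geometry())
  expect_equal(p[1:5, 1], c(1L, 1L, 1L, 1L, 2L))
  expect_equal(p[1:5, 2], c(1L, 2L, 3L, 4L, 1L))
})

test_that("design entries are proportion products with exponential decay", {
  # two spot types, one-hot memberships, D = 5 between spots 1 and 2
  geom <- compute_scaled_distances(cbind(c(0, 0, 1), c(0, 5, 0)),
                                   c("a", "b", "c"))
  expect_equal(geom$D[1, 2], 5)
  props <- cell_type_proportions(rbind(c(1, 0), c(0, 1), c(1, 0)),
                                 c("T1", "T2"), geom$spot_ids)
  pairs <- rbind(c(1, 1), c(1, 2))
  d <- build_design_matrix(props, geom, pairs, rho = 0.5)
  # self-pair, memberships 1: covariate exactly 1
  expect_equal(d$X[1, "T1->T1"], 1)
  # rho = 0.5, D = 5, memberships 1: exp(-2.5)
  expect_equal(d$X[2, "T1->T2"], exp(-2.5), tolerance = 1e-12)
  expect_equal(unname(d$X[2, "T1->T2"]), 0.0821, tolerance = 1e-3)
  # any zero membership zeroes the covariate
  expect_equal(unname(d$X[2, "T2->T1"]), 0)
  expect_error(build_design_matrix(props, geom, pairs, rho = 0), "positive")
})

test_that("decay covariates decrease in distance and in rho", {
  geom <- make_grid_coords(5)
  props <- cell_type_proportions(matrix(0.5, 25, 2), c("A", "B"),
                                 geom$spot_ids)
  pairs <- cbind(1L, 1:25)
  d1 <- build_design_matrix(props, geom, pairs, rho = 0.5)
  ord <- order(geom$D[1, ])
  expect_true(all(diff(d1$X[ord, 1][!duplicated(geom$D[1, ][ord])]) < 0))
  for (rho2 in c(0.8, 1.5, 3)) {
    d2 <- build_design_matrix(props, geom, pairs, rho = rho2)
    far <- geom$D[pairs] > 0
    expect_true(all(d2$X[far, 1] < d1$X[far, 1]))
  }
})

test_that("binarization one-hots the modal type with first-index ties", {
  props <- cell_type_proportions(rbind(c(0.5, 0.3, 0.2), c(0.5, 0.5, 0),
                                       c(0, 1, 0)),
                                 c("A", "B", "C"), c("s1", "s2", "s3"))
  b <- binarize_proportions(props)
  expect_equal(unname(b$M), rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(binarize_proportions(b)$M, b$M) # idempotent
  expect_equal(rowSums(b$M), setNames(rep(1, 3), c("s1", "s2", "s3")))
})

test_that("interaction filtering drops zero-mass interactions", {
  geom <- toy_geometry()
  # type B never present
  props <- cell_type_proportions(cbind(A = rep(1, 4), B = rep(0, 4)),
                                 spot_ids = geom$spot_ids)
  pairs <- select_pairs(geom)
  kept <- filter_interactions(props, geom, pairs, rho = 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(unname(kept[1, ]), c(1L, 1L))
  # dense positive proportions: min_mass = 0 keeps all G^2
  set.seed(3)
  props2 <- generate_proportions(4, 3, geom$spot_ids)
  expect_equal(nrow(filter_interactions(props2, geom, pairs, 0.5, 0)), 9)
  # one-hot types that never co-occur within the threshold
  geom2 <- compute_scaled_distances(cbind(c(0, 10), c(0, 0)), c("u", "v"))
  props3 <- cell_type_proportions(rbind(c(1, 0), c(0, 1)), c("A", "B"),
                                  c("u", "v"))
  self_only <- select_pairs(geom2, max_distance = 0.5)
  kept3 <- filter_interactions(props3, geom2, self_only, rho = 0.5)
  expect_false(any(kept3[, 1] == 1 & kept3[, 2] == 2))
  expect_false(any(kept3[, 1] == 2 & kept3[, 2] == 1))
})

test_that("design built on all pairs then row-subset matches thresholded design", {
  sim <- small_sim()
  geom <- sim$inputs$geom
  props <- sim$inputs$props
  all_pairs <- select_pairs(geom)
  thr <- select_pairs(geom, max_distance = 2)
  d_all <- build_design_matrix(props, geom, all_pairs, 0.5)
  d_thr <- build_design_matrix(props, geom, thr, 0.5)
  keep <- geom$D[all_pairs] <= 2
  expect_equal(d_all$X[keep, ], d_thr$X)
})

test_that("standardization yields unit-variance columns and is idempotent", {
  sim <- small_sim()
  d <- build_design_matrix(sim$inputs$props, sim$inputs$geom,
                           sim$inputs$pairs, 0.5)
  s <- standardize_design(d)
  expect_equal(unname(apply(s$X, 2, sd)), rep(1, ncol(s$X)))
  expect_equal(unname(colMeans(s$X)), rep(0, ncol(s$X)), tolerance = 1e-12)
  expect_identical(standardize_design(s)$X, s$X)
})
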