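test_that("grid geometry has the expected size and diameter", {
  g <- make_grid_coords(10)
  expect_length(g$spot_ids, 100)
  g2 <- make_grid_coords(2)
  expect_length(g2$spot_ids, 4)
  expect_equal(max(g2$D), sqrt(2))
  for (gs in c(3, 5, 8)) {
    gg <- make_grid_coords(gs)
    expect_lte(max(gg$D), sqrt(2) * (gs - 1))
  }
})

test_that("proportions are uniform draws rescaled to unit row sums", {
  set.seed(1)
  p <- generate_proportions(50, 4)
  expect_equal(unname(rowSums(p$M)), rep(1, 50), tolerance = 1e-12)
  expect_true(all(p$M >= 0 & p$M <= 1))
  p1 <- generate_proportions(10, 1)
  expect_equal(unname(p1$M[, 1]), rep(1, 10))
  # symmetry: each column averages ~ 1/G
  big <- generate_proportions(5000, 4)
  expect_equal(unname(colMeans(big$M)), rep(0.25, 4), tolerance = 0.02)
})

test_that("coefficients are signed, bounded away from zero and sparsified", {
  set.seed(2)
  co <- generate_coefficients(5, delta = 0.6)
  expect_equal(sum(co$beta == 0), round(0.6 * 25))
  nz <- co$beta[co$beta != 0]
  expect_true(all(abs(nz) >= 0.1 & abs(nz) <= 0.5))
  expect_true(co$beta0 >= -2.5 && co$beta0 <= -1.5) # mixture - 2
  all0 <- generate_coefficients(4, delta = 1)
  expect_true(all(all0$beta == 0))
  dense <- generate_coefficients(4, delta = 0)
  expect_false(any(abs(dense$beta) < 0.1))
})

test_that("scenarios round-trip through YAML configuration", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("grid_side: 6", "G: 4", "delta: 0.8", "generator: hurdle",
               "seed: 42"), f)
  sc <- load_scenario(f)
  expect_equal(sc$grid_side, 6L)
  expect_equal(sc$G, 4L)
  expect_equal(sc$delta, 0.8)
  expect_equal(sc$generator, "hurdle")
  expect_equal(sc$phi, 3) # default retained
  writeLines("nonsense: 1", f)
  expect_error(load_scenario(f), "unknown scenario field")
})

test_that("scenario inputs are fixed by the base seed across generators", {
  a <- scenario_inputs(simulation_scenario(grid_side = 5, G = 3, seed = 77,
                                           generator = "cpg"))
  b <- scenario_inputs(simulation_scenario(grid_side = 5, G = 3, seed = 77,
                                           generator = "hurdle"))
  expect_identical(a$beta, b$beta)
  expect_identical(a$nu_l, b$nu_l)
  expect_identical(a$props$M, b$props$M)
  # replicates share structure but differ in outcome noise
  s1 <- simulate_cpg_dataset(a, rep = 1)
  s2 <- simulate_cpg_dataset(a, rep = 2)
  expect_false(identical(s1$scores, s2$scores))
  expect_identical(simulate_cpg_dataset(a, rep = 1)$scores, s1$scores)
})

test_that("both generators target the same mean and expected zero behavior", {
  sc <- simulation_scenario(grid_side = 8, G = 3, seed = 5, phi = 3, p = 1.5)
  inputs <- scenario_inputs(sc)
  # oracle mean: rebuild the linear predictor directly
  d <- standardize_design(build_design_matrix(inputs$props, inputs$geom,
                                              inputs$pairs, sc$rho_true))
  mu <- exp(inputs$beta0 + drop(d$X %*% inputs$beta) +
              inputs$nu_l[d$sender_idx] + inputs$nu_r[d$receiver_idx])
  reps_cpg <- sapply(1:6, function(r) mean(simulate_cpg_dataset(inputs, r)$scores))
  reps_hur <- sapply(1:6, function(r) mean(simulate_hurdle_dataset(inputs, r)$scores))
  expect_equal(mean(reps_cpg), mean(mu), tolerance = 0.05)
  expect_equal(mean(reps_hur), mean(mu), tolerance = 0.05)
  expect_equal(mean(reps_cpg), mean(reps_hur), tolerance = 0.05)
  # hurdle: nonzero draws strictly positive
  h <- simulate_hurdle_dataset(inputs, 1)
  expect_true(all(h$scores[h$scores != 0] > 0))
  # lower intercept means more zeros
  lo <- inputs
  lo$beta0 <- inputs$beta0 - 2
  expect_gt(mean(simulate_cpg_dataset(lo, 1)$scores == 0),
            mean(simulate_cpg_dataset(inputs, 1)$scores == 0))
})

test_that("one-hot spot labels inflate the FDR relative to the full proportions", {
  sc <- simulation_scenario(grid_side = 10, G = 5, rho_true = 0.4,
                            delta = 0.6, phi = 3, p = 1.5, n_reps = 3,
                            seed = 101)
  cfg <- sampler_config(n_tune = 800, n_main = 1600, n_burn = 400,
                        seed = 101)
  mp <- suppressWarnings(run_scenario(sc, cfg, variant = "maxprop"))
  bc <- suppressWarnings(run_scenario(sc, cfg, variant = "batcom"))
  # discarding within-spot heterogeneity misattributes communication:
  # many confident wrong calls, while the full model stays near nominal
  expect_gt(mean(mp$per_rep$FDR), 0.2)
  expect_lt(mean(bc$per_rep$FDR), 0.25)
  expect_gt(mean(mp$per_rep$FDR), mean(bc$per_rep$FDR))
})

test_that("sign-aware confusion rules classify discoveries correctly", {
  mk_result <- function(est, adj) {
    data.frame(estimate = est, adjusted_p = adj)
  }
  truth <- c(0.3, -0.2, 0, 0, 0.4)
  # oracle: p = 0 for correct-sign nonzero truths, 1 elsewhere
  oracle <- mk_result(truth, ifelse(truth != 0, 0, 1))
  m <- evaluate_performance(oracle, truth)
  expect_equal(c(m$TPR, m$FPR, m$AUC), c(1, 0, 1))
  expect_equal(m$FDR, 0)
  # wrong-sign significant estimate on nonzero truth counts as FP
  flipped <- mk_result(c(-0.3, -0.2, 0.1, 0.1, 0.4), c(0, 0, 1, 1, 0))
  m2 <- evaluate_performance(flipped, truth)
  expect_equal(m2$FP, 1)
  expect_equal(m2$TP, 2)
  expect_equal(m2$FN, 0)
  # nothing significant on all-zero truth: FDR and FPR zero
  m3 <- evaluate_performance(mk_result(rep(0.1, 4), rep(1, 4)), rep(0, 4))
  expect_equal(c(m3$FDR, m3$FPR), c(0, 0))
  # counts partition the tested coefficients (random property)
  set.seed(9)
  for (i in 1:10) {
    n <- 20
    tr <- ifelse(runif(n) < 0.5, 0, runif(n, -0.5, 0.5))
    res <- mk_result(rnorm(n, tr, 0.2), runif(n))
    mm <- evaluate_performance(res, tr)
    expect_equal(mm$TP + mm$TN + mm$FP + mm$FN, n)
  }
  # AUC invariant to strictly monotone transforms of the p-values
  res <- mk_result(rnorm(20, truth <- rep(c(0.3, 0), 10), 0.1),
                   adj <- runif(20))
  a1 <- evaluate_performance(res, truth)$AUC
  res2 <- res
  res2$adjusted_p <- plogis(5 * qlogis(pmin(pmax(adj, 1e-12), 1 - 1e-12)))
  expect_equal(evaluate_performance(res2, truth)$AUC, a1)
})
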