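test_that("the analytic gradient matches finite differences", {
  sim <- small_sim()
  design <- standardize_design(build_design_matrix(
    sim$inputs$props, sim$inputs$geom, sim$inputs$pairs, 0.5))
  model <- batcom_model(sim$scores, design)
  t <- integer(length(model$c))
  t[model$nz] <- 1L
  set.seed(4)
  for (i in 1:5) {
    par <- model$init + rnorm(length(model$init), 0, 0.1)
    lg <- log_posterior_and_grad(par, model, t)
    fd <- fd_gradient(par, model, t)
    expect_lt(max(abs(lg$grad - fd) / pmax(abs(fd), 1e-8)), 1e-5)
  }
})

test_that("with no data the posterior gradient is the prior score", {
  model <- prior_only_model(k_types = 2L)
  par <- c(0.7, 0.3, -0.4, 0.5, 0.2, 0.1, 0.6) # b0, 4 betas, logphi, theta
  lg <- log_posterior_and_grad(par, model, integer(0))
  k <- ncol(model$X)
  expect_equal(lg$grad[1 + seq_len(k)], -par[1 + seq_len(k)]) # N(0,1) score
  expect_equal(lg$grad[1], -par[1] / 100^2)
  expect_equal(lg$grad[k + 2], -par[k + 2] / 100)
  expect_equal(lg$grad[k + 3], 1 - 2 * plogis(par[k + 3]))
})

test_that("random-effect initialization respects symmetry and perturbations", {
  geom <- make_grid_coords(3)
  N <- 9
  props <- cell_type_proportions(matrix(0.5, N, 2), c("A", "B"),
                                 geom$spot_ids)
  pairs <- select_pairs(geom)
  design <- build_design_matrix(props, geom, pairs, 0.5)
  # identical spots with identical outcomes: all offsets equal by symmetry
  sym <- comm_score_set(pairs, rep(1, nrow(pairs)), "sym")
  re <- suppressWarnings(initialize_random_effects(sym, design))
  expect_lt(diff(range(re$nu_l)), 1e-6)
  expect_lt(diff(range(re$nu_r)), 1e-6)
  # inflating every score sent by one spot raises its sender offset most
  sim <- small_sim(seed = 21)
  boosted <- sim$scores
  hot <- boosted$pair_index[, 1] == 5
  boosted <- comm_score_set(boosted$pair_index,
                            ifelse(hot, boosted$scores * 8 + 1,
                                   boosted$scores), "boost")
  d2 <- standardize_design(build_design_matrix(
    sim$inputs$props, sim$inputs$geom, sim$inputs$pairs, 0.5))
  re2 <- suppressWarnings(initialize_random_effects(boosted, d2))
  expect_equal(which.max(re2$nu_l), 5L)
  # offsets generated as zero: estimates centered at zero and the noise
  # around zero shrinks as the grid grows
  fit_nu <- function(grid_side) {
    sc0 <- simulation_scenario(grid_side = grid_side, G = 2,
                               nu_var = 1e-12, seed = 31)
    inp0 <- scenario_inputs(sc0)
    s0 <- simulate_cpg_dataset(inp0, 1)
    d0 <- standardize_design(build_design_matrix(inp0$props, inp0$geom,
                                                 inp0$pairs, 0.5))
    suppressWarnings(initialize_random_effects(s0, d0))
  }
  re_small <- fit_nu(4)
  re_big <- fit_nu(8)
  expect_lt(abs(mean(re_big$nu_l)), 0.2)
  expect_lt(mean(abs(re_big$nu_l)), mean(abs(re_small$nu_l)))
  expect_error(initialize_random_effects(
    comm_score_set(pairs, rep(0, nrow(pairs)), "z"), design), "zero")
})

test_that("tuning reaches the window from different starts and rejects degenerate data", {
  sim <- small_sim(grid_side = 5L, G = 2L)
  design <- standardize_design(build_design_matrix(
    sim$inputs$props, sim$inputs$geom, sim$inputs$pairs, 0.5))
  model <- batcom_model(sim$scores, design)
  for (eps0 in c(0.02, 0.04)) {
    cfg <- sampler_config(n_tune = 600, n_main = 500, n_burn = 150,
                          seed = 17, step_size = eps0)
    tuned <- suppressWarnings(tune_sampler(model, cfg))
    expect_gte(tuned$tuning_acceptance, 0.45)
    expect_lte(tuned$tuning_acceptance, 0.65)
  }
  # all-zero outcome: nothing to augment
  zero_scores <- comm_score_set(sim$inputs$pairs,
                                rep(0, nrow(sim$inputs$pairs)), "z")
  re0 <- list(nu_l = rep(0, 25), nu_r = rep(0, 25), b0 = 0,
              beta = rep(0, ncol(design$X)), logphi = 0, theta = 0)
  zm <- batcom_model(zero_scores, design, re0)
  expect_error(tune_sampler(zm, quick_cfg()), "zero")
})

test_that("a fixed seed reproduces the chain bit for bit", {
  sim <- small_sim(grid_side = 4L, G = 2L)
  cfg <- quick_cfg(seed = 12)
  design <- standardize_design(build_design_matrix(
    sim$inputs$props, sim$inputs$geom, sim$inputs$pairs, 0.5))
  model <- batcom_model(sim$scores, design)
  run_once <- function() {
    cfg2 <- tune_sampler(model, cfg)
    run_mcmc(model, cfg2)
  }
  s1 <- run_once()
  s2 <- run_once()
  expect_identical(s1$draws, s2$draws)
  expect_identical(s1$acceptance_rate, s2$acceptance_rate)
})

test_that("prior-only sampling recovers the prior moments", {
  model <- prior_only_model(k_types = 2L)
  k <- ncol(model$X)
  cfg <- sampler_config(n_tune = 100, n_main = 6000, n_burn = 1000,
                        seed = 3, step_size = 1,
                        mass_diagonal = c(1 / 100^2, rep(1, k), 1 / 100,
                                          3 / pi^2))
  s <- run_mcmc(model, cfg)
  betas <- s$draws[, 1 + seq_len(k)]
  expect_lt(abs(mean(betas)), 0.15)
  expect_equal(sd(as.vector(betas)), 1, tolerance = 0.12)
  expect_equal(sd(s$draws[, "b0"]), 100, tolerance = 0.25)
  expect_equal(sd(s$draws[, "logphi"]), 10, tolerance = 0.25)
  # theta ~ Logistic(0, 1): variance pi^2 / 3
  expect_equal(var(s$draws[, "theta"]), pi^2 / 3, tolerance = 0.3)
})

test_that("Wald statistics, pseudo-p-values and BH adjustment are correct", {
  # draws engineered to exact moments: mean 0.4, sd 0.2 -> W = 4
  z <- scale(seq(-3, 3, length.out = 1000))[, 1] # exact mean 0, sd 1
  mk <- function(mean, sd) mean + sd * z
  draws <- cbind(b0 = mk(0, 1), "A->A" = mk(0.4, 0.2), "A->B" = mk(0, 0.3),
                 "B->A" = mk(-0.6, 0.1), logphi = mk(0, 1), theta = mk(0, 1))
  samples <- structure(list(
    draws = draws, acceptance_rate = 0.5, rho = 0.5,
    kept_interactions = rbind(c(1, 1), c(1, 2), c(2, 1)),
    type_names = c("A", "B")), class = "posterior_samples")
  res <- wald_inference(samples)
  expect_equal(res$W[1], 4, tolerance = 1e-12)
  expect_equal(res$p[1], pchisq(4, 1, lower.tail = FALSE))
  expect_equal(res$p[1], 0.0455, tolerance = 1e-3)
  expect_equal(res$W[2], 0, tolerance = 1e-20)
  expect_equal(res$p[2], 1)
  expect_equal(res$sign, sign(res$estimate))
  expect_equal(res$sign[c(1, 3)], c(1, -1))
  # BH: adjusted >= raw, monotone in rank, equal to hand-computed values
  expect_true(all(res$adjusted_p >= res$p))
  expect_equal(res$adjusted_p, p.adjust(res$p, "BH"))
  ord <- order(res$p)
  expect_true(all(diff(res$adjusted_p[ord]) >= 0))
  expect_equal(res$significant, res$adjusted_p < 0.05)
})

test_that("WAIC2 reduces to -2 lppd under constant likelihood and selects rho", {
  sim <- small_sim(grid_side = 4L, G = 2L)
  design <- standardize_design(build_design_matrix(
    sim$inputs$props, sim$inputs$geom, sim$inputs$pairs, 0.5))
  model <- batcom_model(sim$scores, design)
  cfg <- quick_cfg(seed = 5)
  cfg2 <- tune_sampler(model, cfg)
  samples <- run_mcmc(model, cfg2)
  # constant draws: variance term vanishes
  const <- samples
  const$draws <- samples$draws[rep(1, 200), ]
  cp <- batcom:::.cpg_at(samples$draws[1, ], model)
  ll <- cpg_marginal_logpdf(model$c, cpg_params(cp$lam, cp$alpha, cp$gam),
                            rel_tol = 1e-10)
  expect_equal(compute_waic2(const, model), -2 * sum(ll), tolerance = 1e-8)
  # thinning changes WAIC2 only slightly
  w1 <- compute_waic2(samples, model, thin = 1)
  w2 <- compute_waic2(samples, model, thin = 2)
  expect_lt(abs(w1 - w2) / abs(w1), 0.01)
  # single-value grid returns that value
  builder <- function(rho) build_design_matrix(sim$inputs$props,
                                               sim$inputs$geom,
                                               sim$inputs$pairs, rho)
  sel <- select_rho(sim$scores, builder, rho_grid = 0.5, config = cfg)
  expect_equal(sel$best_rho, 0.5)
  expect_equal(nrow(sel$table), 1)
})

test_that("the logistic variant is regularized, reproducible and guarded", {
  sim <- small_sim(seed = 13, grid_side = 4L, G = 2L)
  design <- standardize_design(build_design_matrix(
    sim$inputs$props, sim$inputs$geom, sim$inputs$pairs, 0.5))
  cfg <- quick_cfg(seed = 8)
  f1 <- fit_logistics_variant(sim$scores, design, cfg)
  f2 <- fit_logistics_variant(sim$scores, design, cfg)
  expect_identical(f1$samples$draws, f2$samples$draws)
  expect_true(all(is.finite(f1$result$estimate)))
  # perfectly separated outcome still yields finite estimates under the prior
  sep_scores <- comm_score_set(sim$scores$pair_index,
                               as.numeric(design$X[, 1] > 0), "sep")
  f3 <- fit_logistics_variant(sep_scores, design, quick_cfg(seed = 9))
  expect_true(all(is.finite(f3$result$estimate)))
  expect_true(all(abs(f3$result$estimate) < 20))
  all0 <- comm_score_set(sim$scores$pair_index,
                         rep(0, nrow(sim$scores$pair_index)), "z")
  expect_error(fit_logistics_variant(all0, design, cfg), "constant")
})

test_that("the logistic variant keeps type I error near nominal under the null", {
  sc <- simulation_scenario(grid_side = 6, G = 3, rho_true = 0.5, delta = 1,
                            phi = 3, p = 1.5, seed = 66)
  inp <- scenario_inputs(sc)
  design <- standardize_design(build_design_matrix(inp$props, inp$geom,
                                                   inp$pairs, 0.5))
  pv <- unlist(lapply(1:10, function(r) {
    scores <- simulate_cpg_dataset(inp, r)
    fit_logistics_variant(scores, design,
                          sampler_config(n_tune = 250, n_main = 500,
                                         n_burn = 150,
                                         seed = 66 + 3 * r))$result$p
  }))
  # coarse calibration band: neither inflated nor collapsed
  expect_lt(mean(pv < 0.05), 0.15)
  expect_gt(mean(pv < 0.5), 0.25)
})
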