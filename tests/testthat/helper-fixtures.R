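# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except in the io tests, which write their own temp files.

# small expression matrix with hand-set values
toy_expression <- function() {
  v <- rbind(s1 = c(2, 4, 0, 1),
             s2 = c(1, 2, 3, 0),
             s3 = c(0, 0, 5, 2),
             s4 = c(3, 1, 1, 1))
  colnames(v) <- c("LigA", "LigB", "RecA", "RecB")
  expression_matrix(v)
}

# 2x2 unit grid geometry
toy_geometry <- function() {
  compute_scaled_distances(cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)),
                           paste0("s", 1:4))
}

# reduced sampler settings for unit tests
quick_cfg <- function(seed = 1L, n_tune = 250L, n_main = 500L,
                      n_burn = 150L) {
  sampler_config(n_tune = n_tune, n_main = n_main, n_burn = n_burn,
                 seed = seed)
}

# small simulated dataset: 6x6 grid, 3 cell types
small_sim <- function(seed = 7L, delta = 0.5, rho_true = 0.5, phi = 3,
                      p = 1.5, grid_side = 6L, G = 3L) {
  sc <- simulation_scenario(grid_side = grid_side, G = G,
                            rho_true = rho_true, delta = delta,
                            phi = phi, p = p, seed = seed)
  inputs <- scenario_inputs(sc)
  list(scenario = sc, inputs = inputs,
       scores = simulate_cpg_dataset(inputs, rep = 1))
}

# data-free model (prior-only target) with k interaction covariates
prior_only_model <- function(k_types = 2L) {
  geom <- toy_geometry()
  props <- cell_type_proportions(matrix(1 / k_types, 4, k_types),
                                 paste0("T", seq_len(k_types)),
                                 geom$spot_ids)
  pairs0 <- matrix(integer(0), 0, 2)
  design <- build_design_matrix(props, geom, pairs0, rho = 0.5)
  scores0 <- comm_score_set(pairs0, numeric(0), "empty")
  re0 <- list(nu_l = rep(0, 4), nu_r = rep(0, 4), b0 = 0,
              beta = rep(0, ncol(design$X)), logphi = 0, theta = 0)
  batcom_model(scores0, design, re0)
}

# finite-difference gradient of the log posterior
fd_gradient <- function(par, model, t) {
  vapply(seq_along(par), function(j) {
    h <- 1e-5 * max(1, abs(par[j]))
    e <- numeric(length(par)); e[j] <- h
    (log_posterior_and_grad(par + e, model, t)$lp -
       log_posterior_and_grad(par - e, model, t)$lp) / (2 * h)
  }, numeric(1))
}
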