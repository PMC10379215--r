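#' Simulation scenario
#'
#' Study conditions for the synthetic benchmarks: spots on a regular square
#' grid, cell-type proportions drawn uniformly and row-rescaled, sparse
#' signed interaction coefficients, spot random effects, and zero-inflated
#' scores drawn either from the compound Poisson-Gamma model itself or from
#' a pseudo-hurdle Gamma model with the same mean structure.
#'
#' @param grid_side spots per grid side (default 10, i.e. 100 spots).
#' @param G number of cell types.
#' @param rho_true distance-decay rate used to generate the data.
#' @param delta fraction of the `G^2` interaction coefficients set to zero.
#' @param phi,p Tweedie dispersion and power index of the generator.
#' @param nu_var variance of the spot random effects (`N(0, 0.4)` default).
#' @param n_reps replicate datasets per scenario.
#' @param seed base seed; fixes the proportions, coefficients and random
#'   effects for the whole scenario family, while per-replicate sub-seeds
#'   vary only the outcome noise.
#' @param generator `"cpg"` or `"hurdle"`.
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(grid_side = 10L, G = 5L, rho_true = 0.5,
                                delta = 0.6, phi = 3, p = 1.5, nu_var = 0.4,
                                n_reps = 10L, seed = 1L,
                                generator = c("cpg", "hurdle")) {
  generator <- match.arg(generator)
  stopifnot(grid_side >= 2, G >= 1, rho_true > 0, delta >= 0, delta <= 1,
            phi > 0, p > 1, p < 2, nu_var >= 0)
  structure(list(grid_side = as.integer(grid_side), G = as.integer(G),
                 rho_true = rho_true, delta = delta, phi = phi, p = p,
                 nu_var = nu_var, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), generator = generator),
            class = "simulation_scenario")
}

#' Read a simulation scenario from a YAML file
#'
#' The file holds any subset of the [simulation_scenario()] fields, e.g.
#' `grid_side: 10`, `G: 5`, `generator: hurdle`; unset fields keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A [simulation_scenario].
#' @export
load_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(simulation_scenario))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
  do.call(simulation_scenario, y)
}

#' Regular square grid of spots
#'
#' Unit-spaced lattice; after adjacency scaling, rook-adjacent spots are at
#' distance 1 and diagonal neighbours at `sqrt(2)`.
#'
#' @param grid_side spots per side, `>= 2`.
#' @return A [spot_geometry][compute_scaled_distances].
#' @export
make_grid_coords <- function(grid_side) {
  stopifnot(grid_side >= 2)
  g <- as.integer(grid_side)
  coords <- as.matrix(expand.grid(x = seq_len(g) - 1L, y = seq_len(g) - 1L))
  compute_scaled_distances(coords, sprintf("spot%03d", seq_len(g^2)))
}

#' Random cell-type proportions
#'
#' Each entry drawn from U(0, 1), rows rescaled to sum to 1; `G = 1`
#' degenerates to an all-ones column. Uses the current RNG stream.
#'
#' @param N number of spots.
#' @param G number of cell types.
#' @param spot_ids optional spot labels.
#' @return A [cell_type_proportions].
#' @export
generate_proportions <- function(N, G, spot_ids = NULL) {
  stopifnot(N >= 1, G >= 1)
  M <- matrix(stats::runif(N * G), N, G)
  M <- M / rowSums(M)
  cell_type_proportions(M, paste0("CT", seq_len(G)),
                        spot_ids %||% sprintf("spot%03d", seq_len(N)))
}

#' Sparse signed interaction coefficients
#'
#' Draws a dense coefficient vector from the equal mixture
#' `0.5 U(0.1, 0.5) + 0.5 U(-0.5, -0.1)` (effects bounded away from zero),
#' zeroes a uniformly chosen subset of `round(delta * G^2)` of them, and
#' shifts the intercept by -2 so mean scores resemble real spatial
#' transcriptomics data.
#'
#' @param G number of cell types.
#' @param delta sparsity rate in `[0, 1]`.
#' @return List with `beta0` (intercept, -2 shift included) and `beta`
#'   (length `G^2`, ordered sender-major to match
#'   [build_design_matrix()] columns).
#' @export
generate_coefficients <- function(G, delta) {
  stopifnot(delta >= 0, delta <= 1)
  mix <- function(n) sample(c(-1, 1), n, replace = TRUE) *
    stats::runif(n, 0.1, 0.5)
  beta0 <- mix(1) - 2
  beta <- mix(G^2)
  nzero <- round(delta * G^2)
  if (nzero > 0) beta[sample.int(G^2, nzero)] <- 0
  list(beta0 = beta0, beta = beta)
}

#' Fixed inputs of a scenario family
#'
#' Draws the grid, proportions, coefficients and spot random effects under
#' the scenario's base seed. These stay fixed across replicates and across
#' scenarios sharing a seed, so that only the outcome noise varies.
#'
#' @param scenario a [simulation_scenario].
#' @return List with `geom`, `props`, `beta0`, `beta`, `nu_l`, `nu_r`,
#'   `pairs` (all ordered spot pairs) and the scenario.
#' @export
scenario_inputs <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  geom <- make_grid_coords(scenario$grid_side)
  N <- length(geom$spot_ids)
  props <- generate_proportions(N, scenario$G, geom$spot_ids)
  coefs <- generate_coefficients(scenario$G, scenario$delta)
  sdv <- sqrt(scenario$nu_var)
  list(geom = geom, props = props, beta0 = coefs$beta0, beta = coefs$beta,
       nu_l = stats::rnorm(N, 0, sdv), nu_r = stats::rnorm(N, 0, sdv),
       pairs = select_pairs(geom), scenario = scenario)
}

# Mean over the full pair list at the true rho. Effects act on standardized
# covariates so that effect sizes are comparable across G and rho scenarios
# and the intercept alone pins the overall score level.
.sim_mu <- function(inputs) {
  sc <- inputs$scenario
  d <- standardize_design(build_design_matrix(inputs$props, inputs$geom,
                                              inputs$pairs, sc$rho_true))
  exp(inputs$beta0 + drop(d$X %*% inputs$beta) +
        inputs$nu_l[d$sender_idx] + inputs$nu_r[d$receiver_idx])
}

#' Simulate scores from the compound Poisson-Gamma model
#'
#' Per spot pair, the Tweedie mean `mu = exp(beta0 + x'beta + nu_l + nu_r)`
#' (built at the true decay rate) is converted to compound Poisson-Gamma
#' parameters and one score is drawn. The replicate index seeds the outcome
#' noise; the structural inputs come fixed from [scenario_inputs()].
#'
#' @param inputs output of [scenario_inputs()].
#' @param rep replicate index (sub-seed `seed + 1000 * rep`).
#' @return A [comm_score_set] over all ordered spot pairs.
#' @export
simulate_cpg_dataset <- function(inputs, rep = 1L) {
  sc <- inputs$scenario
  mu <- .sim_mu(inputs)
  set.seed(sc$seed + 1000L * as.integer(rep))
  alpha <- (2 - sc$p) / (sc$p - 1)
  lam <- mu^(2 - sc$p) / (sc$phi * (2 - sc$p))
  gam <- sc$phi * (sc$p - 1) * mu^(sc$p - 1)
  comm_score_set(inputs$pairs, rcpg_cpp(lam, alpha, gam), "simulated-cpg")
}

#' Simulate scores from the pseudo-hurdle Gamma model
#'
#' A generator structurally different from the fitted likelihood but with
#' the same mean: `Pr(C = 0) = 1 / (1 + mu)`, and positive scores follow a
#' Gamma with shape `alpha_new ~ U(0.5, 5)` (one draw per dataset) and scale
#' `(1 + mu) / alpha_new`, so the nonzero mean is `1 + mu` and the overall
#' mean is `mu`.
#'
#' @inheritParams simulate_cpg_dataset
#' @return A [comm_score_set] over all ordered spot pairs.
#' @export
simulate_hurdle_dataset <- function(inputs, rep = 1L) {
  sc <- inputs$scenario
  mu <- .sim_mu(inputs)
  set.seed(sc$seed + 1000L * as.integer(rep))
  alpha_new <- stats::runif(1, 0.5, 5)
  n <- length(mu)
  zero <- stats::runif(n) < 1 / (1 + mu)
  x <- stats::rgamma(n, shape = alpha_new, scale = (1 + mu) / alpha_new)
  x[zero] <- 0
  comm_score_set(inputs$pairs, x, "simulated-hurdle")
}

#' Sign-aware confusion metrics for one fitted replicate
#'
#' Applies the sign-aware confusion rules: a discovery (adjusted p below
#' `p_cutoff`) is a true positive only when the truth is nonzero *and* the
#' estimated sign matches; a discovery on a zero truth or with a mismatched
#' sign is a false positive; non-discoveries split into true negatives (zero
#' truth) and false negatives (nonzero truth). The ROC sweeps the adjusted
#' p-value cutoff and the AUC uses the trapezoid rule. The observed FDR is
#' defined as 0 when there are no discoveries.
#'
#' @param result a `ccc_result` from [wald_inference()].
#' @param truth numeric vector of true coefficients aligned with the rows of
#'   `result`.
#' @param p_cutoff significance cutoff on the adjusted p-value.
#' @return List with counts `TP`, `TN`, `FP`, `FN` and rates `TPR`, `FPR`,
#'   `FDR`, `AUC`.
#' @export
evaluate_performance <- function(result, truth, p_cutoff = 0.05) {
  stopifnot(nrow(result) == length(truth))
  confusion <- function(cut) {
    sig <- result$adjusted_p < cut
    match_sign <- sign(result$estimate) == sign(truth)
    nz <- truth != 0
    TP <- sum(sig & nz & match_sign)
    FP <- sum(sig & (!nz | !match_sign))
    TN <- sum(!sig & !nz)
    FN <- sum(!sig & nz)
    c(TP = TP, FP = FP, TN = TN, FN = FN)
  }
  cm <- confusion(p_cutoff)
  TPR <- if (cm["TP"] + cm["FN"] > 0) cm[["TP"]] / (cm[["TP"]] + cm[["FN"]])
         else NA_real_
  FPR <- if (cm["FP"] + cm["TN"] > 0) cm[["FP"]] / (cm[["FP"]] + cm[["TN"]])
         else NA_real_
  FDR <- if (cm["TP"] + cm["FP"] > 0) cm[["FP"]] / (cm[["TP"]] + cm[["FP"]])
         else 0
  # ROC over adjusted-p cutoffs
  AUC <- NA_real_
  if (any(truth != 0) && any(truth == 0)) {
    cuts <- c(sort(unique(result$adjusted_p)), max(result$adjusted_p) + 1)
    pts <- t(vapply(cuts, function(ct) {
      cc <- confusion(ct)
      c(fpr = if (cc["FP"] + cc["TN"] > 0)
          cc[["FP"]] / (cc[["FP"]] + cc[["TN"]]) else 0,
        tpr = if (cc["TP"] + cc["FN"] > 0)
          cc[["TP"]] / (cc[["TP"]] + cc[["FN"]]) else 0)
    }, numeric(2)))
    pts <- rbind(c(0, 0), pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
    AUC <- sum(diff(pts[, 1]) * (utils::head(pts[, 2], -1) +
                                   utils::tail(pts[, 2], -1)) / 2)
  }
  list(TP = cm[["TP"]], TN = cm[["TN"]], FP = cm[["FP"]], FN = cm[["FN"]],
       TPR = TPR, FPR = FPR, FDR = FDR, AUC = AUC)
}

#' Run a full simulation scenario
#'
#' Generates `n_reps` replicate datasets under the scenario, fits the chosen
#' model variant at `rho_hat` to each, and reports the sign-aware confusion
#' metrics per replicate together with their means and standard deviations.
#'
#' @param scenario a [simulation_scenario].
#' @param config a [sampler_config]; its seed is re-derived per replicate.
#' @param rho_hat decay rate used for fitting (default 0.5, the recommended
#'   all-purpose choice).
#' @param max_distance optional scaled-distance threshold restricting the
#'   fitted spot pairs.
#' @param variant model variant passed to [batcom()].
#' @param reps how many replicates to run (default `scenario$n_reps`).
#' @return An `evaluation_report`: list with `per_rep` (data frame) and
#'   `summary` (mean and sd per metric).
#' @export
run_scenario <- function(scenario, config = sampler_config(), rho_hat = 0.5,
                         max_distance = NULL, variant = "batcom",
                         reps = scenario$n_reps) {
  inputs <- scenario_inputs(scenario)
  gen <- if (scenario$generator == "cpg") simulate_cpg_dataset
         else simulate_hurdle_dataset
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    scores <- gen(inputs, rep = r)
    cfg <- config
    cfg$seed <- config$seed + 7919L * r
    fit <- batcom(scores, inputs$props, inputs$geom, rho = rho_hat,
                  max_distance = max_distance, variant = variant,
                  config = cfg)
    truth <- inputs$beta[interaction_index(fit$design$kept_interactions,
                                           scenario$G)]
    m <- evaluate_performance(fit$result, truth)
    rows[[r]] <- data.frame(rep = r, TP = m$TP, TN = m$TN, FP = m$FP,
                            FN = m$FN, TPR = m$TPR, FPR = m$FPR,
                            FDR = m$FDR, AUC = m$AUC)
  }
  per_rep <- do.call(rbind, rows)
  metrics <- c("TPR", "FPR", "FDR", "AUC")
  structure(list(
    per_rep = per_rep,
    summary = data.frame(metric = metrics,
                         mean = vapply(metrics, function(m)
                           mean(per_rep[[m]], na.rm = TRUE), numeric(1)),
                         sd = vapply(metrics, function(m)
                           stats::sd(per_rep[[m]], na.rm = TRUE), numeric(1)),
                         row.names = NULL),
    scenario = scenario, rho_hat = rho_hat, variant = variant),
    class = "evaluation_report")
}

#' Linear index of (g1, g2) interactions in the coefficient vector
#'
#' Coefficients are stored sender-major: interaction (g1, g2) sits at
#' `(g1 - 1) * G + g2`.
#'
#' @param kept two-column matrix of (g1, g2) indices.
#' @param G number of cell types.
#' @return Integer vector of positions.
#' @export
interaction_index <- function(kept, G) {
  (kept[, 1] - 1L) * G + kept[, 2]
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s generator, %d reps, rho_hat = %g\n",
              x$scenario$generator, nrow(x$per_rep), x$rho_hat))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
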